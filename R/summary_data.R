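#' Read a table of harmonized GWAS summary statistics
#'
#' Reads a delimited text file (tab-separated by default) of per-variant
#' association estimates with an exposure and an outcome. Inputs are assumed
#' pre-harmonized so that effect sizes refer to a consistent effect allele;
#' no strand-flipping or allele harmonization is performed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical field names
#'   (`variant_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, and optionally
#'   `effect_allele`, `other_allele`) to the column names used in the file.
#'   Fields absent from the map are looked up under their canonical names.
#' @param sep Field separator, default tab.
#'
#' @return A `data.frame` of class `variant_summary` with columns
#'   `variant_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out` and, when present
#'   in the file, `effect_allele` and `other_allele`, one row per variant in
#'   file order.
#'
#' @details Required numeric fields must parse as finite numbers; the
#'   missing-value tokens `"NA"` and `""` are rejected in required fields and
#'   carried through in the optional allele columns. Standard errors must be
#'   strictly positive and variant identifiers unique. Errors name the
#'   offending row (1-based, excluding the header) and field. A warning is
#'   emitted if any `beta_exp` is negative, since a consistent
#'   exposure-increasing allele coding is the usual convention.
#'
#' @export
read_summary_table <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path)) {
    stop("summary table not found: ", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)

  required <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out")
  optional <- c("effect_allele", "other_allele")
  resolve <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) {
      column_map[[field]]
    } else {
      field
    }
  }
  src <- vapply(c(required, optional), resolve, character(1))
  names(src) <- c(required, optional)

  missing_req <- src[required][!(src[required] %in% names(raw))]
  if (length(missing_req) > 0) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }

  parse_numeric <- function(field) {
    txt <- raw[[src[[field]]]]
    bad <- is.na(txt) | txt == "" | txt == "NA"
    if (any(bad)) {
      stop("missing value in required field '", field, "' at row ",
           which(bad)[1])
    }
    val <- suppressWarnings(as.numeric(txt))
    if (any(!is.finite(val))) {
      stop("non-numeric value in field '", field, "' at row ",
           which(!is.finite(val))[1], ": '", txt[which(!is.finite(val))[1]], "'")
    }
    val
  }

  out <- data.frame(variant_id = raw[[src[["variant_id"]]]],
                    stringsAsFactors = FALSE)
  if (any(out$variant_id == "" | is.na(out$variant_id))) {
    stop("empty variant_id at row ",
         which(out$variant_id == "" | is.na(out$variant_id))[1])
  }
  if (anyDuplicated(out$variant_id)) {
    dup <- out$variant_id[duplicated(out$variant_id)][1]
    stop("duplicate variant_id: '", dup, "'")
  }
  for (field in c("beta_exp", "se_exp", "beta_out", "se_out")) {
    out[[field]] <- parse_numeric(field)
  }
  for (field in c("se_exp", "se_out")) {
    bad <- out[[field]] <= 0
    if (any(bad)) {
      stop("non-positive standard error in field '", field, "' at row ",
           which(bad)[1], " (variant '", out$variant_id[which(bad)[1]], "')")
    }
  }
  for (field in optional) {
    if (src[[field]] %in% names(raw)) {
      out[[field]] <- raw[[src[[field]]]]
    }
  }
  if (any(out$beta_exp < 0)) {
    warning(sum(out$beta_exp < 0), " variant(s) have negative beta_exp; ",
            "inputs are expected to be coded to a consistent ",
            "exposure-increasing allele")
  }
  class(out) <- c("variant_summary", "data.frame")
  out
}

#' Write a per-variant clustering results table
#'
#' Writes a tab-separated table with columns `variant_id`, `ratio_estimate`,
#' `ratio_se`, `cluster`, `cluster_mean`, `inclusion_probability`. The
#' `cluster` column carries a substantive cluster index (`"1"`, `"2"`, ...)
#' or one of the literal labels `"null"`, `"junk"`, `"unassigned"`.
#' Numeric fields are formatted with enough digits that re-reading
#' reproduces the doubles exactly.
#'
#' @param records A data.frame with the six columns above (as produced by
#'   [variant_results()]).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @seealso [read_variant_results()]
#' @export
write_variant_results <- function(records, path) {
  cols <- c("variant_id", "ratio_estimate", "ratio_se", "cluster",
            "cluster_mean", "inclusion_probability")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ok_label <- grepl("^[0-9]+$", records$cluster) |
    records$cluster %in% c("null", "junk", "unassigned")
  if (nrow(records) > 0 && !all(ok_label)) {
    stop("invalid cluster label: '", records$cluster[!ok_label][1], "'")
  }
  out <- records[, cols, drop = FALSE]
  fmt <- function(x) {
    ifelse(is.na(x), "NA", vapply(x, format, character(1), digits = 17))
  }
  for (nm in c("ratio_estimate", "ratio_se", "cluster_mean",
               "inclusion_probability")) {
    out[[nm]] <- fmt(as.numeric(out[[nm]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a per-variant clustering results table
#'
#' Inverse of [write_variant_results()]: parses the numeric columns and keeps
#' cluster labels as character.
#'
#' @param path Path to a results TSV written by [write_variant_results()].
#' @return A data.frame with the six results columns.
#' @export
read_variant_results <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  for (nm in c("ratio_estimate", "ratio_se", "cluster_mean",
               "inclusion_probability")) {
    raw[[nm]] <- as.numeric(raw[[nm]])
  }
  raw
}
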