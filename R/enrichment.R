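#' Read a long-format variant-trait association table
#'
#' Tab-separated file with columns `variant_id`, `trait`, `p_value`. Variants
#' may be missing for some traits (e.g. absent from the lookup dataset); each
#' (variant, trait) pair must be unique.
#'
#' @param path Path to the TSV.
#' @return A data.frame with the three columns.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("variant_id", "trait", "p_value")
  if (!all(need %in% names(tab))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  tab$p_value <- as.numeric(tab$p_value)
  if (any(!is.finite(tab$p_value)) || any(tab$p_value < 0 | tab$p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  if (anyDuplicated(tab[, c("variant_id", "trait")])) {
    stop("duplicate (variant_id, trait) pair in trait table")
  }
  tab
}

#' True- and false-positive association rates for a cluster
#'
#' For one trait and a p-value threshold: the true-positive rate is the
#' proportion of in-cluster variants associated with the trait (p strictly
#' below the threshold); the false-positive rate is the proportion of
#' out-of-cluster variants associated. Variants with no entry for the trait
#' are excluded from both numerator and denominator, so the denominators
#' count only variants with data.
#'
#' @param cluster_members Character vector of in-cluster variant ids (must be
#'   a subset of `all_variants`).
#' @param all_variants Character vector of all variant ids in the analysis.
#' @param table Association data.frame (`variant_id`, `trait`, `p_value`).
#' @param trait Trait name to evaluate.
#' @param threshold Association p-value threshold, in (0, 1); strict `<`.
#' @return A one-row data.frame: `trait`, `threshold`, `tp_count`,
#'   `tp_denom`, `fp_count`, `fp_denom`, `tp_rate`, `fp_rate`.
#' @export
association_rates <- function(cluster_members, all_variants, table, trait,
                              threshold) {
  if (!all(cluster_members %in% all_variants)) {
    stop("cluster_members must be a subset of all_variants")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sub <- table[table$trait == trait & table$variant_id %in% all_variants, ]
  in_cl <- sub$variant_id %in% cluster_members
  tp_denom <- sum(in_cl)
  fp_denom <- sum(!in_cl)
  if (tp_denom == 0) {
    stop("no in-cluster variant has data for trait '", trait, "'")
  }
  assoc <- sub$p_value < threshold
  tp <- sum(assoc & in_cl)
  fp <- sum(assoc & !in_cl)
  data.frame(trait = trait, threshold = threshold,
             tp_count = tp, tp_denom = tp_denom,
             fp_count = fp, fp_denom = fp_denom,
             tp_rate = tp / tp_denom,
             fp_rate = if (fp_denom > 0) fp / fp_denom else 0,
             stringsAsFactors = FALSE)
}

#' Exact hypergeometric test of cluster-association independence
#'
#' Tests whether association with a trait is independent of cluster
#' membership, conditioning on the 2x2 margins. Under independence the
#' number of associated in-cluster variants is hypergeometric with
#' population `tp_denom + fp_denom`, `tp_count + fp_count` total associated
#' variants and `tp_denom` draws. Computed by exact summation of the
#' hypergeometric mass function — no large-sample approximation.
#'
#' @param tp_count,tp_denom Associated / total in-cluster variants with data.
#' @param fp_count,fp_denom Associated / total out-of-cluster variants with
#'   data.
#' @param tail `"upper"` (default): enrichment, `P(X >= tp_count)`;
#'   `"two_sided"`: sums the probability of all tables at most as probable
#'   as the observed one.
#' @return The exact p-value, in (0, 1].
#' @export
hypergeom_independence_test <- function(tp_count, tp_denom, fp_count,
                                        fp_denom,
                                        tail = c("upper", "two_sided")) {
  tail <- match.arg(tail)
  if (tp_count > tp_denom || fp_count > fp_denom ||
      min(tp_count, tp_denom, fp_count, fp_denom) < 0) {
    stop("inconsistent counts")
  }
  pop <- tp_denom + fp_denom
  succ <- tp_count + fp_count
  support <- max(0, succ - fp_denom):min(succ, tp_denom)
  mass <- stats::dhyper(support, succ, pop - succ, tp_denom)
  if (tail == "upper") {
    p <- sum(mass[support >= tp_count])
  } else {
    obs <- mass[support == tp_count]
    p <- sum(mass[mass <= obs * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Scan all traits for enrichment in a cluster
#'
#' For each trait and threshold, computes the true/false-positive association
#' rates ([association_rates()]) and the exact hypergeometric independence
#' p-value, and ranks results by ascending p-value. P-values are raw: no
#' multiple-testing correction is applied by default (a trait table typically
#' contains many overlapping or synonymous traits, making a principled
#' correction difficult); an optional Benjamini-Hochberg column can be
#' requested.
#'
#' @inheritParams association_rates
#' @param thresholds Numeric vector of association thresholds; default
#'   `c(1e-5, 1e-8)`.
#' @param tail Passed to [hypergeom_independence_test()].
#' @param bh If `TRUE`, append a Benjamini-Hochberg adjusted p-value column
#'   (computed within each threshold).
#' @return A data.frame with one row per (trait, threshold), columns as
#'   [association_rates()] plus `p_value` (and `p_bh` if requested), sorted
#'   by ascending `p_value`. Traits with no in-cluster data at a threshold
#'   are skipped.
#' @export
scan_traits <- function(cluster_members, all_variants, table,
                        thresholds = c(1e-5, 1e-8),
                        tail = c("upper", "two_sided"), bh = FALSE) {
  tail <- match.arg(tail)
  if (nrow(table) == 0) stop("empty trait table")
  traits <- unique(table$trait)
  rows <- list()
  for (th in thresholds) {
    for (tr in traits) {
      r <- tryCatch(
        association_rates(cluster_members, all_variants, table, tr, th),
        error = function(e) NULL)
      if (is.null(r)) next
      r$p_value <- hypergeom_independence_test(r$tp_count, r$tp_denom,
                                               r$fp_count, r$fp_denom,
                                               tail = tail)
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (bh) {
    out$p_bh <- NA_real_
    for (th in thresholds) {
      i <- out$threshold == th
      out$p_bh[i] <- stats::p.adjust(out$p_value[i], method = "BH")
    }
  }
  out[order(out$p_value), , drop = FALSE]
}
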