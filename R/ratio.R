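#' Ratio (Wald) estimate for a single variant
#'
#' The per-variant causal estimate: the genetic association with the outcome
#' divided by the genetic association with the exposure.
#'
#' @param beta_outcome Association estimate with the outcome.
#' @param beta_exposure Association estimate with the exposure; must be
#'   nonzero.
#' @return `beta_outcome / beta_exposure`.
#' @export
ratio_estimate <- function(beta_outcome, beta_exposure) {
  if (any(beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure is zero")
  }
  beta_outcome / beta_exposure
}

#' First-order delta-method standard error of a ratio estimate
#'
#' Treats the exposure association as known: `se_outcome / |beta_exposure|`.
#' The absolute value keeps the result positive (a standard error is a scale
#' parameter).
#'
#' @param se_outcome Standard error of the outcome association; positive.
#' @param beta_exposure Nonzero exposure association estimate.
#' @return Positive standard error.
#' @export
ratio_se_first_order <- function(se_outcome, beta_exposure) {
  if (any(beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure is zero")
  }
  if (any(se_outcome <= 0)) {
    stop("se_outcome must be positive")
  }
  se_outcome / abs(beta_exposure)
}

#' Second-order delta-method standard error of a ratio estimate
#'
#' Propagates uncertainty in both association estimates:
#' \deqn{\sqrt{se_Y^2/\beta_X^2 + \beta_Y^2 se_X^2/\beta_X^4
#'       - 2\rho\,\beta_Y se_Y se_X/\beta_X^3}.}
#' `rho` is the correlation between the exposure and outcome association
#' estimates; it is zero in a two-sample design and otherwise must be
#' supplied by the user (a sensitivity analysis over `rho` is advisable).
#'
#' @param beta_exposure Nonzero exposure association estimate.
#' @param beta_outcome Outcome association estimate.
#' @param se_exposure Standard error of the exposure association
#'   (non-negative; zero recovers the first-order formula).
#' @param se_outcome Positive standard error of the outcome association.
#' @param rho Correlation of the two association estimates, in \[-1, 1\].
#' @return Positive standard error.
#' @export
ratio_se_second_order <- function(beta_exposure, beta_outcome,
                                  se_exposure, se_outcome, rho = 0) {
  if (any(beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure is zero")
  }
  if (any(se_outcome <= 0) || any(se_exposure < 0)) {
    stop("standard errors must be positive (se_exposure may be zero)")
  }
  if (any(abs(rho) > 1)) {
    stop("rho must lie in [-1, 1]")
  }
  v <- se_outcome^2 / beta_exposure^2 +
    beta_outcome^2 * se_exposure^2 / beta_exposure^4 -
    2 * rho * beta_outcome * se_outcome * se_exposure / beta_exposure^3
  if (any(v <= 0)) {
    stop("invalid correlation: variance expression non-positive under rho = ",
         rho)
  }
  sqrt(v)
}

#' Build a ratio dataset from variant summary statistics
#'
#' Applies [ratio_estimate()] and the selected delta-method standard error to
#' each variant. Variants with a zero exposure association cannot be used as
#' instruments; they are excluded and listed in the `excluded` attribute.
#'
#' @param variants A `variant_summary` data.frame (see
#'   [read_summary_table()]), or any data.frame with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param se_order `"first"` (default) or `"second"`.
#' @param rho Estimate correlation used by the second-order formula;
#'   default 0 (two-sample setting).
#' @return An object of class `ratio_dataset`: a data.frame with columns
#'   `variant_id`, `theta_hat`, `sigma_hat` and attributes `se_order`, `rho`
#'   and `excluded` (character vector of excluded variant ids).
#' @export
build_ratio_dataset <- function(variants, se_order = c("first", "second"),
                                rho = 0) {
  se_order <- match.arg(se_order)
  if (nrow(variants) == 0) {
    stop("empty variant list")
  }
  degenerate <- variants$beta_exp == 0
  excluded <- variants$variant_id[degenerate]
  keep <- variants[!degenerate, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("all variants have zero beta_exp; no usable instruments")
  }
  theta <- ratio_estimate(keep$beta_out, keep$beta_exp)
  sigma <- if (se_order == "first") {
    ratio_se_first_order(keep$se_out, keep$beta_exp)
  } else {
    ratio_se_second_order(keep$beta_exp, keep$beta_out,
                          keep$se_exp, keep$se_out, rho)
  }
  out <- data.frame(variant_id = keep$variant_id,
                    theta_hat = theta,
                    sigma_hat = sigma,
                    stringsAsFactors = FALSE)
  attr(out, "se_order") <- se_order
  attr(out, "rho") <- rho
  attr(out, "excluded") <- excluded
  class(out) <- c("ratio_dataset", "data.frame")
  out
}

#' @export
print.ratio_dataset <- function(x, ...) {
  cat("Ratio dataset:", nrow(x), "variants (",
      attr(x, "se_order"), "-order SEs, rho = ", attr(x, "rho"), ")\n",
      sep = "")
  excl <- attr(x, "excluded")
  if (length(excl) > 0) {
    cat("Excluded (zero exposure association):",
        paste(excl, collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
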