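#' Bayesian information criterion for a fitted mixture
#'
#' The mixture with K substantive clusters has 2K + 1 free parameters: K
#' cluster means and K + 2 mixing proportions constrained to sum to one
#' (the junk-component parameters are fixed functions of the data, not free).
#' BIC = (2K + 1) log(J) - 2 log-likelihood; smaller is better.
#'
#' @param fit An `em_fit`.
#' @param J Number of variants.
#' @return The BIC value.
#' @export
bic <- function(fit, J) {
  if (J < 1) stop("J must be at least 1")
  if (!is.finite(fit$log_likelihood)) stop("fit has non-finite log-likelihood")
  (2 * fit$params$K + 1) * log(J) - 2 * fit$log_likelihood
}

#' Scan over the number of substantive clusters
#'
#' Fits the mixture for K = 0, 1, 2, ... by multi-start EM and selects the K
#' minimizing BIC. The scan stops early once BIC has increased for
#' `patience` consecutive values of K (evidence that it is now increasing
#' monotonically), or at `k_max`.
#'
#' @param data A `ratio_dataset`.
#' @param k_max Largest K to consider; default `min(J, 10)`.
#' @param patience Consecutive BIC increases required to stop early;
#'   default 2.
#' @param n_starts,delta,max_iter,seed Passed to [fit_em_multistart()];
#'   each K derives its own sub-seed from `seed`.
#' @return An object of class `cluster_scan`: list with `fits` (one `em_fit`
#'   per scanned K, named by K), `bics` (named numeric vector), `best_K`,
#'   `best_fit`, and `failures` (error messages per failed K, if any).
#' @export
scan_cluster_number <- function(data, k_max = NULL, patience = 2,
                                n_starts = 25, delta = 1e-5, max_iter = 500,
                                seed = 1) {
  J <- nrow(data)
  if (J < 1) stop("empty dataset")
  if (is.null(k_max)) k_max <- min(J, 10)
  k_max <- min(k_max, J)
  junk <- junk_component_params(data$theta_hat, data$sigma_hat)
  set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max, k_max + 1)
  fits <- list()
  bics <- numeric(0)
  failures <- character(0)
  consec_incr <- 0
  last_bic <- NA_real_
  for (K in 0:k_max) {
    fit <- tryCatch(
      fit_em_multistart(data, K, n_starts = n_starts, delta = delta,
                        max_iter = max_iter, seed = k_seeds[K + 1],
                        junk = junk),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[as.character(K)] <- conditionMessage(fit)
      next
    }
    b <- bic(fit, J)
    fits[[as.character(K)]] <- fit
    bics[as.character(K)] <- b
    if (!is.na(last_bic) && b > last_bic) {
      consec_incr <- consec_incr + 1
    } else {
      consec_incr <- 0
    }
    last_bic <- b
    if (consec_incr >= patience) break
  }
  if (length(fits) == 0) {
    stop("no value of K could be fitted; first failure: ", failures[1])
  }
  best_K <- as.integer(names(bics)[which.min(bics)])
  out <- list(fits = fits,
              bics = bics,
              best_K = best_K,
              best_fit = fits[[as.character(best_K)]],
              failures = failures)
  class(out) <- "cluster_scan"
  out
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat("BIC scan over number of substantive clusters\n")
  tab <- data.frame(K = as.integer(names(x$bics)),
                    BIC = unname(x$bics),
                    log_likelihood = vapply(x$fits, function(f)
                      f$log_likelihood, numeric(1)))
  print(tab, row.names = FALSE)
  cat("Selected K =", x$best_K, "\n")
  invisible(x)
}
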