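# Independent oracles and fixture builders shared across tests.

# Write a summary-statistics TSV and return its path.
write_summary_fixture <- function(df, path = tempfile(fileext = ".tsv"),
                                  col_names = names(df)) {
  out <- df
  names(out) <- col_names
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small well-formed summary table.
summary_fixture_df <- function(n = 3) {
  set.seed(99)
  data.frame(variant_id = paste0("rs", seq_len(n)),
             beta_exp = round(stats::runif(n, 0.05, 0.3), 4),
             se_exp = round(stats::runif(n, 0.01, 0.05), 4),
             beta_out = round(stats::rnorm(n, 0, 0.1), 4),
             se_out = round(stats::runif(n, 0.01, 0.05), 4),
             stringsAsFactors = FALSE)
}

# Brute-force Rand index: loop over all unordered pairs.
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / tot
}

# All set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, m) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(m + 1)) grow(c(prefix, v), max(m, v))
  }
  grow(integer(0), 0)
  out
}

# Exhaustive hypergeometric upper-tail p-value via binomial coefficients:
# P(X >= tp) for X the count of associated in-cluster variants, conditioning
# on the 2x2 margins. Deliberately avoids dhyper/phyper.
hypergeom_oracle <- function(tp, tp_denom, fp, fp_denom) {
  pop <- tp_denom + fp_denom
  succ <- tp + fp
  xs <- max(0, succ - fp_denom):min(succ, tp_denom)
  probs <- choose(tp_denom, xs) * choose(fp_denom, succ - xs) /
    choose(pop, succ)
  sum(probs[xs >= tp])
}

# Direct term-by-term mixture log-likelihood (no log-sum-exp); the naive
# reference for mixture_log_likelihood().
loglik_oracle <- function(theta_hat, sigma_hat, params) {
  K <- params$K
  total <- 0
  for (j in seq_along(theta_hat)) {
    dens <- params$proportions[1] *
      stats::dnorm(theta_hat[j], 0, sigma_hat[j])
    if (K > 0) {
      for (k in seq_len(K)) {
        dens <- dens + params$proportions[k + 1] *
          stats::dnorm(theta_hat[j], params$cluster_means[k], sigma_hat[j])
      }
    }
    tj <- stats::dt((theta_hat[j] - params$junk$mu) / params$junk$psi,
                    df = params$junk$nu) / params$junk$psi
    dens <- dens + params$proportions[K + 2] * tj
    total <- total + log(dens)
  }
  total
}

# Minimal ratio_dataset constructor for synthetic tests.
make_ratio_dataset <- function(theta_hat, sigma_hat,
                               ids = sprintf("v%03d", seq_along(theta_hat))) {
  out <- data.frame(variant_id = ids, theta_hat = theta_hat,
                    sigma_hat = sigma_hat, stringsAsFactors = FALSE)
  attr(out, "se_order") <- "first"
  attr(out, "rho") <- 0
  attr(out, "excluded") <- character(0)
  class(out) <- c("ratio_dataset", "data.frame")
  out
}

# Random valid mixture parameters for property tests.
random_params <- function(K, junk) {
  p <- stats::runif(K + 2, 0.1, 1)
  p <- p / sum(p)
  means <- sort(stats::rnorm(K, 0, 2))
  out <- list(K = K, cluster_means = means, proportions = p, junk = junk)
  class(out) <- "mixture_params"
  out
}
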