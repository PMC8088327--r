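#' Junk-component parameters
#'
#' The junk cluster absorbs ratio estimates that fit neither the null nor any
#' substantive cluster. It is a generalized (location-scale) Student-t
#' distribution with `nu = 4` degrees of freedom, location `mu` equal to the
#' sample mean of all ratio estimates, and scale
#' `psi = |max(theta_hat) - min(theta_hat)| + 2 * max(sigma_hat)`, i.e. wide
#' enough to cover the whole observed range. These parameters are computed
#' once from the data and held fixed during EM.
#'
#' @param theta_hat Vector of ratio estimates.
#' @param sigma_hat Vector of positive standard errors, same length.
#' @param nu Degrees of freedom, default 4.
#' @return A list of class `junk_component` with elements `mu`, `psi`, `nu`.
#' @export
junk_component_params <- function(theta_hat, sigma_hat, nu = 4) {
  if (length(theta_hat) < 1) {
    stop("empty input")
  }
  if (length(sigma_hat) != length(theta_hat) || any(sigma_hat <= 0)) {
    stop("sigma_hat must be positive and match theta_hat in length")
  }
  out <- list(mu = mean(theta_hat),
              psi = abs(max(theta_hat) - min(theta_hat)) + 2 * max(sigma_hat),
              nu = nu)
  class(out) <- "junk_component"
  out
}

#' Log density of a single mixture component
#'
#' Null and substantive components are normal with the variant's own standard
#' error as standard deviation; the junk component is a location-scale
#' Student-t with the fixed parameters from [junk_component_params()].
#'
#' @param x Point(s) at which to evaluate (ratio estimates).
#' @param component `"null"`, `"substantive"`, or `"junk"`.
#' @param sigma_j Observation-specific standard error (normal components).
#' @param theta_k Substantive cluster mean (required when
#'   `component = "substantive"`).
#' @param junk A `junk_component` (required when `component = "junk"`).
#' @return Log density value(s).
#' @export
component_log_density <- function(x, component = c("null", "substantive",
                                                   "junk"),
                                  sigma_j = NULL, theta_k = NULL,
                                  junk = NULL) {
  component <- match.arg(component)
  if (any(!is.finite(x))) {
    stop("non-finite observation")
  }
  switch(component,
    null = {
      if (is.null(sigma_j) || any(sigma_j <= 0)) stop("sigma_j must be positive")
      stats::dnorm(x, mean = 0, sd = sigma_j, log = TRUE)
    },
    substantive = {
      if (is.null(sigma_j) || any(sigma_j <= 0)) stop("sigma_j must be positive")
      if (is.null(theta_k)) stop("theta_k required for a substantive component")
      stats::dnorm(x, mean = theta_k, sd = sigma_j, log = TRUE)
    },
    junk = {
      if (is.null(junk)) stop("junk component parameters required")
      stats::dt((x - junk$mu) / junk$psi, df = junk$nu, log = TRUE) -
        log(junk$psi)
    }
  )
}

# J x (K + 2) matrix of component log densities, columns (null, 1..K, junk).
# The null and junk columns do not depend on the cluster means, so callers
# inside the EM loop precompute them and pass them in.
.log_density_matrix <- function(theta_hat, sigma_hat, cluster_means, junk,
                                null_ld = NULL, junk_ld = NULL) {
  J <- length(theta_hat)
  K <- length(cluster_means)
  if (is.null(null_ld)) {
    null_ld <- stats::dnorm(theta_hat, 0, sigma_hat, log = TRUE)
  }
  if (is.null(junk_ld)) {
    junk_ld <- stats::dt((theta_hat - junk$mu) / junk$psi, df = junk$nu,
                         log = TRUE) - log(junk$psi)
  }
  if (K > 0) {
    a <- theta_hat / sigma_hat
    b <- 1 / sigma_hat
    lnc <- -log(sigma_hat) - 0.5 * log(2 * pi)
    sub <- lnc - 0.5 * (a - outer(b, cluster_means))^2
    cbind(null_ld, sub, junk_ld, deparse.level = 0)
  } else {
    cbind(null_ld, junk_ld, deparse.level = 0)
  }
}

# Row-wise log-sum-exp with the responsibilities as a by-product.
.row_lse <- function(lm) {
  J <- nrow(lm)
  mx <- lm[cbind(seq_len(J), max.col(lm, ties.method = "first"))]
  if (any(!is.finite(mx))) {
    stop("all component densities underflow for some observation; ",
         "pathological scale")
  }
  w <- exp(lm - mx)
  s <- rowSums(w)
  list(log_like = mx + log(s), resp = w / s)
}

#' Mixture log-likelihood
#'
#' Sum over variants of the log of the mixture density: null component
#' (normal, mean 0), K substantive components (normal, means `theta_k`) and
#' the junk component (location-scale t), each with its mixing proportion.
#' Accumulated with a per-observation log-sum-exp to avoid underflow.
#'
#' @param data A `ratio_dataset`.
#' @param params A `mixture_params` object (see [initialize_parameters()]).
#' @return The log-likelihood (scalar).
#' @export
mixture_log_likelihood <- function(data, params) {
  .check_params(params)
  lm <- .log_density_matrix(data$theta_hat, data$sigma_hat,
                            params$cluster_means, params$junk)
  lm <- lm + rep(log(params$proportions), each = nrow(lm))
  sum(.row_lse(lm)$log_like)
}

.check_params <- function(params) {
  K <- params$K
  if (length(params$cluster_means) != K) {
    stop("cluster_means length does not match K")
  }
  if (length(params$proportions) != K + 2) {
    stop("proportions must have length K + 2")
  }
  if (abs(sum(params$proportions) - 1) > 1e-8 || any(params$proportions < 0)) {
    stop("proportions must be non-negative and sum to 1")
  }
  invisible(TRUE)
}

.new_params <- function(cluster_means, proportions, junk) {
  out <- list(K = length(cluster_means),
              cluster_means = cluster_means,
              proportions = proportions,
              junk = junk)
  class(out) <- "mixture_params"
  out
}

# k-means++-style seeding for 1-d data, then Lloyd iterations.
.kmeans_1d <- function(x, K) {
  ux <- unique(x)
  if (length(ux) < K) {
    stop("fewer distinct points (", length(ux), ") than clusters (", K, ")")
  }
  if (K == 1) {
    # Lloyd with a single center converges to the grand mean in one step;
    # stats::kmeans cannot take a 1x1 center matrix (length-1 centers are
    # read as the number of clusters).
    return(list(centers = matrix(mean(x)), cluster = rep(1L, length(x))))
  }
  centers <- numeric(K)
  centers[1] <- x[sample.int(length(x), 1)]
  if (K > 1) {
    for (k in 2:K) {
      d2 <- vapply(x, function(xi) min((xi - centers[seq_len(k - 1)])^2),
                   numeric(1))
      if (sum(d2) == 0) {
        centers[k:K] <- sample(setdiff(ux, centers[seq_len(k - 1)]), K - k + 1)
        break
      }
      centers[k] <- x[sample.int(length(x), 1, prob = d2)]
    }
  }
  stats::kmeans(x, centers = matrix(unique(centers), ncol = 1),
                iter.max = 50, algorithm = "Lloyd")
}

#' Random initialization of mixture parameters
#'
#' For `K > 0`, the substantive cluster means are the centroids of a k-means
#' run on the ratio estimates (unweighted, so initialization ignores the
#' estimate uncertainties). The null and junk proportions are drawn
#' independently from Uniform(0.05, 0.4) — so a priori between 10% and 80% of
#' mass sits in the null-plus-junk pair — and the substantive proportions are
#' the k-means occupancy fractions scaled to the remaining mass. For
#' `K = 0`, the two drawn proportions are renormalized to sum to 1.
#'
#' Uses R's global RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param data A `ratio_dataset`.
#' @param K Number of substantive clusters (non-negative, at most `J`).
#' @param junk Optional precomputed `junk_component`; computed from the data
#'   if omitted.
#' @return A `mixture_params` object.
#' @export
initialize_parameters <- function(data, K, junk = NULL) {
  J <- nrow(data)
  if (K > J) {
    stop("K (", K, ") exceeds the number of variants (", J, ")")
  }
  if (is.null(junk)) {
    junk <- junk_component_params(data$theta_hat, data$sigma_hat)
  }
  pi_null <- stats::runif(1, 0.05, 0.4)
  pi_junk <- stats::runif(1, 0.05, 0.4)
  if (K == 0) {
    prop <- c(pi_null, pi_junk) / (pi_null + pi_junk)
    return(.new_params(numeric(0), prop, junk))
  }
  km <- .kmeans_1d(data$theta_hat, K)
  means <- as.numeric(km$centers)
  occ <- tabulate(km$cluster, nbins = length(means)) / J
  ord <- order(means)
  means <- means[ord]
  occ <- occ[ord]
  prop <- c(pi_null, occ * (1 - pi_null - pi_junk), pi_junk)
  .new_params(means, prop, junk)
}

#' Expectation step: responsibilities
#'
#' Computes the conditional probability that each variant belongs to each
#' component, proportional to proportion times component density, normalized
#' per row in log space.
#'
#' @param data A `ratio_dataset`.
#' @param params A `mixture_params`.
#' @return A J x (K + 2) matrix (columns: null, substantive 1..K, junk) whose
#'   rows sum to 1.
#' @export
e_step <- function(data, params) {
  .check_params(params)
  lm <- .log_density_matrix(data$theta_hat, data$sigma_hat,
                            params$cluster_means, params$junk)
  lm <- lm + rep(log(params$proportions), each = nrow(lm))
  resp <- .row_lse(lm)$resp
  colnames(resp) <- .component_names(params$K)
  resp
}

.component_names <- function(K) {
  c("null", if (K > 0) paste0("cluster", seq_len(K)), "junk")
}

#' Maximization step: update cluster means and proportions
#'
#' Each substantive cluster mean is updated to a responsibility-weighted
#' inverse-variance-weighted (IVW) average of the ratio estimates; the null
#' mean stays fixed at zero and the junk parameters are never re-estimated.
#' Proportions are updated to the mean responsibility per component.
#'
#' @param data A `ratio_dataset`.
#' @param resp Responsibility matrix from [e_step()].
#' @param junk The fixed `junk_component`.
#' @param prev_means Previous substantive means, used to hold a cluster in
#'   place when its total responsibility falls below `empty_tol` (an "empty"
#'   cluster whose IVW update would be 0/0).
#' @param empty_tol Total-responsibility threshold below which a cluster is
#'   treated as empty; default `1e-3`.
#' @return A `mixture_params` with updated means (unsorted; sorting is done
#'   once at the end of an EM run) and proportions, plus an `empty` attribute
#'   flagging clusters held at their previous mean.
#' @export
m_step <- function(data, resp, junk, prev_means = NULL, empty_tol = 1e-3) {
  J <- nrow(data)
  Kc <- ncol(resp)
  K <- Kc - 2
  if (max(abs(rowSums(resp) - 1)) > 1e-6) {
    stop("responsibility rows must sum to 1")
  }
  prop <- colMeans(resp)
  if (K > 0) {
    inv_var <- 1 / data$sigma_hat^2
    w <- resp[, 2:(K + 1), drop = FALSE] * inv_var
    tot <- colSums(resp[, 2:(K + 1), drop = FALSE])
    means <- colSums(w * data$theta_hat) / colSums(w)
    empty <- tot < empty_tol
    if (any(empty)) {
      if (is.null(prev_means)) {
        stop("cluster ", which(empty)[1],
             " has numerically zero responsibility and no previous mean")
      }
      means[empty] <- prev_means[empty]
    }
  } else {
    means <- numeric(0)
    empty <- logical(0)
  }
  out <- .new_params(means, prop, junk)
  attr(out, "empty") <- empty
  out
}

#' Fit the mixture by EM from one initialization
#'
#' Alternates [e_step()] and [m_step()] until the log-likelihood increment
#' falls below `delta` or `max_iter` iterations are reached. The returned
#' parameters are canonicalized: substantive means sorted ascending, with
#' proportions and responsibility columns permuted to match, so fits are
#' comparable regardless of internal component order.
#'
#' @param data A `ratio_dataset`.
#' @param K Number of substantive clusters.
#' @param init A `mixture_params` initialization (see
#'   [initialize_parameters()]).
#' @param delta Convergence tolerance on the log-likelihood increment,
#'   default `1e-5`.
#' @param max_iter Maximum number of EM iterations, default 500.
#' @return An object of class `em_fit`: list with `params`,
#'   `responsibilities`, `log_likelihood`, `n_iterations`, `converged`,
#'   `empty_clusters`, and the `data` it was fitted to.
#' @export
fit_em_single_start <- function(data, K, init, delta = 1e-5, max_iter = 500) {
  .check_params(init)
  if (init$K != K) stop("init has K = ", init$K, ", expected ", K)
  theta_hat <- data$theta_hat
  sigma_hat <- data$sigma_hat
  J <- length(theta_hat)
  junk <- init$junk
  null_ld <- stats::dnorm(theta_hat, 0, sigma_hat, log = TRUE)
  junk_ld <- stats::dt((theta_hat - junk$mu) / junk$psi, df = junk$nu,
                       log = TRUE) - log(junk$psi)
  params <- init
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  persistent_empty <- rep(FALSE, K)
  repeat {
    lm <- .log_density_matrix(theta_hat, sigma_hat, params$cluster_means,
                              junk, null_ld = null_ld, junk_ld = junk_ld)
    lm <- lm + rep(log(params$proportions), each = J)
    es <- .row_lse(lm)
    ll <- sum(es$log_like)
    if (!is.finite(ll)) stop("non-finite log-likelihood during EM")
    if (ll - ll_prev < delta && iter >= 1) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    params <- m_step(data, es$resp, junk,
                     prev_means = params$cluster_means)
    if (K > 0) persistent_empty <- persistent_empty | attr(params, "empty")
    iter <- iter + 1
  }
  resp <- es$resp
  # canonical order: substantive means ascending
  if (K > 1) {
    ord <- order(params$cluster_means)
    params$cluster_means <- params$cluster_means[ord]
    params$proportions <- params$proportions[c(1, 1 + ord, K + 2)]
    resp <- resp[, c(1, 1 + ord, K + 2), drop = FALSE]
    persistent_empty <- persistent_empty[ord]
  }
  colnames(resp) <- .component_names(K)
  out <- list(params = params,
              responsibilities = resp,
              log_likelihood = ll,
              n_iterations = iter,
              converged = converged,
              empty_clusters = persistent_empty,
              data = data)
  class(out) <- "em_fit"
  out
}

#' Fit the mixture by EM with multiple random initializations
#'
#' EM converges to a local optimum that can depend on the starting point, so
#' the fit is repeated from `n_starts` independent initializations and the
#' fit with the largest final log-likelihood is returned. Each start draws
#' its own sub-seed from the master `seed`, making the whole procedure
#' reproducible.
#'
#' @inheritParams fit_em_single_start
#' @param n_starts Number of random initializations, default 25.
#' @param seed Master seed (integer).
#' @param junk Optional precomputed `junk_component` shared across starts.
#' @return The best `em_fit`, with `n_starts`, `seed` and the per-start final
#'   log-likelihoods (`start_log_likelihoods`) recorded.
#' @export
fit_em_multistart <- function(data, K, n_starts = 25, delta = 1e-5,
                              max_iter = 500, seed = 1, junk = NULL) {
  if (n_starts < 1) stop("n_starts must be at least 1")
  if (is.null(junk)) {
    junk <- junk_component_params(data$theta_hat, data$sigma_hat)
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_starts)
  best <- NULL
  lls <- rep(NA_real_, n_starts)
  errors <- character(0)
  for (s in seq_len(n_starts)) {
    set.seed(sub_seeds[s])
    fit <- tryCatch({
      init <- initialize_parameters(data, K, junk = junk)
      fit_em_single_start(data, K, init, delta = delta, max_iter = max_iter)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    lls[s] <- fit$log_likelihood
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("all ", n_starts, " EM starts failed; first error: ", errors[1])
  }
  best$n_starts <- n_starts
  best$seed <- seed
  best$start_log_likelihoods <- lls
  best
}

#' @export
print.em_fit <- function(x, ...) {
  K <- x$params$K
  cat("EM fit: K =", K, "substantive cluster(s),",
      nrow(x$responsibilities), "variants\n")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 8),
      "| iterations:", x$n_iterations,
      "| converged:", x$converged, "\n")
  if (K > 0) {
    cat("  cluster means:",
        paste(format(x$params$cluster_means, digits = 4), collapse = ", "),
        "\n")
  }
  cat("  proportions (null, clusters, junk):",
      paste(format(x$params$proportions, digits = 3), collapse = ", "), "\n")
  invisible(x)
}
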