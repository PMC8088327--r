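test_that("junk-component parameters follow the range-plus-spread rule", {
  j <- junk_component_params(c(-1, 0, 2), c(0.1, 0.2, 0.3))
  expect_equal(j$mu, 1 / 3)
  expect_equal(j$psi, 3.6)
  expect_equal(j$nu, 4)
  j1 <- junk_component_params(0.5, 0.2)
  expect_equal(j1$mu, 0.5)
  expect_equal(j1$psi, 0.4)
  jc <- junk_component_params(rep(1.2, 4), c(0.1, 0.3, 0.2, 0.05))
  expect_equal(jc$mu, 1.2)
  expect_equal(jc$psi, 0.6)
  expect_error(junk_component_params(numeric(0), numeric(0)), "empty")
})

test_that("component log densities have the right closed forms", {
  expect_equal(component_log_density(0, "null", sigma_j = 1),
               -0.5 * log(2 * pi))
  expect_equal(component_log_density(1.3, "substantive", sigma_j = 0.2,
                                     theta_k = 1.3),
               dnorm(0, 0, 0.2, log = TRUE))
  junk <- list(mu = 0.7, psi = 2, nu = 4)
  # standard t4 density at 0 is Gamma(2.5) / (sqrt(4*pi) * Gamma(2)) = 0.375
  expect_equal(component_log_density(0.7, "junk", junk = junk),
               log(0.375 / 2))
  for (c_off in c(0.3, 1.1, 5)) {
    expect_equal(component_log_density(junk$mu + c_off, "junk", junk = junk),
                 component_log_density(junk$mu - c_off, "junk", junk = junk))
  }
})

test_that("mixture log-likelihood matches a term-by-term oracle", {
  set.seed(7)
  d <- make_ratio_dataset(c(-0.5, 0.1, 0.45, 0.8, 1.2),
                          c(0.1, 0.05, 0.2, 0.15, 0.3))
  junk <- junk_component_params(d$theta_hat, d$sigma_hat)
  params <- random_params(2, junk)
  expect_equal(mixture_log_likelihood(d, params),
               loglik_oracle(d$theta_hat, d$sigma_hat, params),
               tolerance = 1e-10)
  # single-component reduction: only the null active
  p0 <- list(K = 0, cluster_means = numeric(0), proportions = c(1, 0),
             junk = junk)
  class(p0) <- "mixture_params"
  d1 <- make_ratio_dataset(0.2, 0.1)
  expect_equal(mixture_log_likelihood(d1, p0),
               dnorm(0.2, 0, 0.1, log = TRUE))
  # additivity over observations
  per_obs <- vapply(seq_len(nrow(d)), function(j)
    mixture_log_likelihood(make_ratio_dataset(d$theta_hat[j],
                                              d$sigma_hat[j]), params),
    numeric(1))
  expect_equal(mixture_log_likelihood(d, params), sum(per_obs),
               tolerance = 1e-10)
  bad <- params
  bad$proportions <- bad$proportions * 2
  expect_error(mixture_log_likelihood(d, bad), "sum to 1")
})

test_that("initialization finds well-separated k-means centroids", {
  set.seed(31)
  d <- make_ratio_dataset(c(rnorm(10, -5, 0.1), rnorm(10, 5, 0.1)),
                          rep(0.1, 20))
  init <- initialize_parameters(d, 2)
  expect_lt(abs(init$cluster_means[1] - (-5)), 0.2)
  expect_lt(abs(init$cluster_means[2] - 5), 0.2)
})

test_that("initial proportions satisfy the null-plus-junk mass bounds", {
  set.seed(5)
  d <- make_ratio_dataset(rnorm(30), rep(0.2, 30))
  for (K in c(0, 1, 3)) {
    for (i in 1:20) {
      init <- initialize_parameters(d, K)
      expect_equal(sum(init$proportions), 1, tolerance = 1e-10)
      mass <- init$proportions[1] + init$proportions[K + 2]
      if (K == 0) {
        # with no substantive clusters the two components carry all mass
        expect_equal(mass, 1, tolerance = 1e-10)
      } else {
        expect_gt(mass, 0.1 - 1e-12)
        expect_lt(mass, 0.8 + 1e-12)
      }
    }
  }
  expect_error(initialize_parameters(make_ratio_dataset(1:3 / 10,
                                                        rep(0.1, 3)), 5),
               "exceeds")
})

test_that("responsibilities are normalized and concentrate when data do", {
  set.seed(11)
  d <- make_ratio_dataset(rnorm(20), runif(20, 0.05, 0.4))
  junk <- junk_component_params(d$theta_hat, d$sigma_hat)
  for (K in c(0, 1, 3)) {
    params <- random_params(K, junk)
    r <- e_step(d, params)
    expect_equal(rowSums(r), rep(1, 20), tolerance = 1e-10)
    expect_true(all(r >= 0 & r <= 1))
  }
  # a variant sitting exactly on a cluster mean with tiny SE is captured
  d2 <- make_ratio_dataset(c(0.5, 0), c(1e-6, 0.1))
  p1 <- list(K = 1, cluster_means = 0.5, proportions = c(0.3, 0.4, 0.3),
             junk = junk)
  class(p1) <- "mixture_params"
  r2 <- e_step(d2, p1)
  expect_gt(r2[1, 2], 0.999)
  # two clusters with equal means and proportions split evenly
  p2 <- list(K = 2, cluster_means = c(0.5, 0.5),
             proportions = c(0.2, 0.3, 0.3, 0.2), junk = junk)
  class(p2) <- "mixture_params"
  r3 <- e_step(d2, p2)
  expect_equal(r3[, 2], r3[, 3], tolerance = 1e-12)
})

test_that("M-step updates are responsibility-weighted IVW estimates", {
  junk <- list(mu = 0, psi = 2, nu = 4)
  d <- make_ratio_dataset(c(0.4, 0.6), c(0.1, 0.1))
  resp <- cbind(0, c(1, 1), 0)
  p <- m_step(d, resp, junk)
  expect_equal(p$cluster_means, 0.5)
  d2 <- make_ratio_dataset(c(0, 1), c(0.1, 0.2))
  p2 <- m_step(d2, resp, junk)
  expect_equal(p2$cluster_means, 0.2)
  # uniform responsibilities give uniform proportions
  K <- 2
  d3 <- make_ratio_dataset(rnorm(6), rep(0.1, 6))
  resp3 <- matrix(1 / (K + 2), nrow = 6, ncol = K + 2)
  p3 <- m_step(d3, resp3, junk)
  expect_equal(p3$proportions, rep(1 / (K + 2), K + 2))
  # empty-cluster guard holds the previous mean
  resp4 <- cbind(c(1, 1), 0, c(0, 0), 0)
  p4 <- m_step(make_ratio_dataset(c(0.1, -0.1), c(0.1, 0.1)), resp4, junk,
               prev_means = c(0.25, 0.75))
  expect_equal(p4$cluster_means[2], 0.75)
  expect_true(attr(p4, "empty")[2])
})

test_that("EM ascends the likelihood and recovers separated clusters", {
  set.seed(21)
  d <- make_ratio_dataset(c(rnorm(20, -1, 0.05), rnorm(20, 1, 0.05)),
                          rep(0.05, 40))
  junk <- junk_component_params(d$theta_hat, d$sigma_hat)
  init <- initialize_parameters(d, 2, junk = junk)
  # manual EM loop: per-iteration log-likelihood must be non-decreasing
  params <- init
  ll_seq <- numeric(0)
  for (i in 1:40) {
    ll_seq <- c(ll_seq, mixture_log_likelihood(d, params))
    r <- e_step(d, params)
    params <- m_step(d, r, junk, prev_means = params$cluster_means)
  }
  expect_true(all(diff(ll_seq) >= -1e-8))
  fit <- fit_em_single_start(d, 2, init)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$cluster_means[1] - (-1)), 0.05)
  expect_lt(abs(fit$params$cluster_means[2] - 1), 0.05)
  # stored log-likelihood is the likelihood of the returned parameters
  expect_equal(fit$log_likelihood, mixture_log_likelihood(d, fit$params),
               tolerance = 1e-8)
  expect_equal(rowSums(fit$responsibilities), rep(1, 40), tolerance = 1e-10)
  expect_equal(sum(fit$params$proportions), 1, tolerance = 1e-10)
})

test_that("delta = Inf stops after a single iteration pair", {
  set.seed(2)
  d <- make_ratio_dataset(rnorm(10), rep(0.1, 10))
  init <- initialize_parameters(d, 1)
  fit <- fit_em_single_start(d, 1, init, delta = Inf)
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1)
})

test_that("IVW limit: with tiny SEs the fitted means are per-group IVW", {
  set.seed(13)
  true_means <- c(-0.6, 0.9)
  grp <- rep(1:2, each = 15)
  sigma <- runif(30, 1e-4, 2e-4)
  theta <- true_means[grp] + rnorm(30, 0, 1e-6)
  d <- make_ratio_dataset(theta, sigma)
  fit <- fit_em_multistart(d, 2, n_starts = 5, seed = 8)
  ivw <- vapply(1:2, function(g)
    sum(theta[grp == g] / sigma[grp == g]^2) /
      sum(1 / sigma[grp == g]^2), numeric(1))
  expect_equal(fit$params$cluster_means, sort(ivw), tolerance = 1e-6)
})

test_that("multi-start selection is reproducible and maximal", {
  set.seed(17)
  d <- make_ratio_dataset(c(rnorm(15, 0.5, 0.2), rnorm(15, -0.2, 0.2)),
                          runif(30, 0.05, 0.3))
  fit1 <- fit_em_multistart(d, 2, n_starts = 10, seed = 42)
  fit2 <- fit_em_multistart(d, 2, n_starts = 10, seed = 42)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$responsibilities, fit2$responsibilities)
  expect_identical(fit1$log_likelihood, fit2$log_likelihood)
  expect_true(all(fit1$log_likelihood >=
                    fit1$start_log_likelihoods[
                      !is.na(fit1$start_log_likelihoods)]))
  # n_starts = 1 reduces to a single start with the derived sub-seed
  single <- fit_em_multistart(d, 2, n_starts = 1, seed = 9)
  set.seed(9)
  sub <- sample.int(.Machine$integer.max, 1)
  set.seed(sub)
  junk <- junk_component_params(d$theta_hat, d$sigma_hat)
  init <- initialize_parameters(d, 2, junk = junk)
  manual <- fit_em_single_start(d, 2, init)
  expect_equal(single$params, manual$params)
  expect_equal(single$log_likelihood, manual$log_likelihood)
})

test_that("canonical ordering sorts means with matching columns", {
  set.seed(3)
  d <- make_ratio_dataset(c(rnorm(10, 2, 0.05), rnorm(10, -2, 0.05)),
                          rep(0.05, 20))
  fit <- fit_em_multistart(d, 2, n_starts = 6, seed = 77)
  expect_equal(fit$params$cluster_means, sort(fit$params$cluster_means))
  # the column responsible for the low-mean cluster captures the low points
  expect_gt(mean(fit$responsibilities[11:20, 2]), 0.9)
  expect_gt(mean(fit$responsibilities[1:10, 3]), 0.9)
})
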