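#' Benchmark scenario presets
#'
#' Four standard scenarios for the summary-statistics simulator. Scenarios 1
#' and 2 contain 90 null variants (no substantive clusters); Scenarios 3 and
#' 4 contain a null cluster of 10, a junk cluster of 10 (per-variant effects
#' drawn standard normal) and three substantive clusters of 10, 20 and 40
#' variants with causal effects 0.4, -0.4 and 0.8. Scenarios 1 and 3 have no
#' overdispersion (`tau = 1`); Scenarios 2 and 4 inflate the outcome
#' sampling variance twofold (`tau = 2`) while the reported standard errors
#' do not reflect the inflation.
#'
#' @param id Scenario number, 1 to 4.
#' @param N Notional GWAS sample size (e.g. 1000 or 5000).
#' @return An object of class `sim_scenario`: list with a `clusters`
#'   data.frame (`label`, `effect`, `count`; `effect` is `NA` for the junk
#'   cluster), `tau`, `N` and `J`.
#' @export
scenario_preset <- function(id, N) {
  if (!id %in% 1:4) stop("unknown scenario id: ", id)
  clusters <- if (id %in% c(1, 2)) {
    data.frame(label = "null", effect = 0, count = 90,
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("c1", "c2", "c3", "junk", "null"),
               effect = c(0.4, -0.4, 0.8, NA, 0),
               count = c(10, 20, 40, 10, 10),
               stringsAsFactors = FALSE)
  }
  out <- list(clusters = clusters,
              tau = if (id %in% c(1, 3)) 1 else 2,
              N = N,
              J = sum(clusters$count),
              id = id)
  class(out) <- "sim_scenario"
  out
}

#' Simulate GWAS summary statistics under a scenario
#'
#' Generates per-variant exposure and outcome association estimates imitating
#' linear-regression coefficients of a unit-variance trait on a SNP. For each
#' variant: minor allele frequency `MAF ~ Uniform(0.05, 0.5)`; true exposure
#' effect `mu_bx ~ N(0, 1)`; sampling variance `v = 1 / (N MAF (1 - MAF))`;
#' `beta_exp ~ N(mu_bx, v)`; `beta_out ~ N(theta_j beta_exp, tau v)` where
#' `theta_j` is the variant's causal effect (drawn `N(0, 1)` per variant in
#' the junk cluster). The reported standard errors are `sqrt(v)` for both
#' traits — deliberately excluding `tau`, so overdispersed scenarios exhibit
#' unmodeled excess heterogeneity.
#'
#' Uses R's global RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param scenario A `sim_scenario` from [scenario_preset()] or of the same
#'   shape.
#' @return An object of class `sim_dataset`: list with `summaries` (a
#'   `variant_summary` data.frame), `true_labels` (character) and
#'   `true_effects` (numeric).
#' @export
simulate_summary_data <- function(scenario) {
  J <- scenario$J
  N <- scenario$N
  tau <- scenario$tau
  labels <- rep(scenario$clusters$label, scenario$clusters$count)
  effects <- rep(scenario$clusters$effect, scenario$clusters$count)
  is_junk <- labels == "junk"
  effects[is_junk] <- stats::rnorm(sum(is_junk))
  maf <- stats::runif(J, 0.05, 0.5)
  mu_bx <- stats::rnorm(J)
  v <- 1 / (N * maf * (1 - maf))
  beta_exp <- stats::rnorm(J, mu_bx, sqrt(v))
  beta_out <- stats::rnorm(J, effects * beta_exp, sqrt(tau * v))
  summaries <- data.frame(variant_id = sprintf("snp_%03d", seq_len(J)),
                          beta_exp = beta_exp,
                          se_exp = sqrt(v),
                          beta_out = beta_out,
                          se_out = sqrt(v),
                          stringsAsFactors = FALSE)
  class(summaries) <- c("variant_summary", "data.frame")
  out <- list(summaries = summaries,
              true_labels = labels,
              true_effects = effects)
  class(out) <- "sim_dataset"
  out
}

#' Rand index between two partitions
#'
#' The fraction of unordered element pairs on which two partitions agree:
#' pairs grouped together in both, or separated in both. Invariant to label
#' permutation; 1 means identical partitions.
#'
#' @param labels_a,labels_b Equal-length label vectors (any type coercible to
#'   factor).
#' @param exclude Optional logical or integer index of elements to drop
#'   before counting pairs (e.g. true junk variants, or unassigned variants
#'   under conservative reporting).
#' @return The Rand index, in \[0, 1\].
#' @export
rand_index <- function(labels_a, labels_b, exclude = NULL) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must have equal length")
  }
  keep <- rep(TRUE, length(labels_a))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- !exclude else keep[exclude] <- FALSE
  }
  a <- labels_a[keep]
  b <- labels_b[keep]
  n <- length(a)
  if (n < 2) stop("fewer than 2 elements after exclusions")
  tab <- table(a, b)
  nij2 <- sum(choose(tab, 2))
  ni2 <- sum(choose(rowSums(tab), 2))
  nj2 <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  # agreements = together in both + apart in both
  (tot + 2 * nij2 - ni2 - nj2) / tot
}

# One full pipeline run on a simulated dataset; internal workhorse shared by
# run_simulation_study() and the acceptance harness.
.simulation_rep <- function(scenario, rep_seed, n_starts = 25, k_max = 5,
                            patience = 2, delta = 1e-5, max_iter = 500,
                            prob_threshold = 0.8, min_cluster_size = 4) {
  set.seed(rep_seed)
  sim <- simulate_summary_data(scenario)
  scan_seed <- sample.int(.Machine$integer.max, 1)
  data <- build_ratio_dataset(sim$summaries, se_order = "first")
  scan <- scan_cluster_number(data, k_max = k_max, patience = patience,
                              n_starts = n_starts, delta = delta,
                              max_iter = max_iter, seed = scan_seed)
  fit <- scan$best_fit
  ids <- data$variant_id
  a <- assign_version_a(fit$responsibilities, ids)
  b <- assign_version_b(fit$responsibilities, ids,
                        prob_threshold = prob_threshold,
                        min_cluster_size = min_cluster_size)
  truth <- sim$true_labels[match(ids, sim$summaries$variant_id)]
  junk_truth <- truth == "junk"
  rand_a <- rand_index(truth, a$cluster, exclude = junk_truth)
  rand_b <- rand_index(truth, b$cluster,
                       exclude = junk_truth | b$cluster == "unassigned")
  sub_a <- a$cluster[!(a$cluster %in% c("null", "junk"))]
  sub_b <- b$cluster[!(b$cluster %in% c("null", "junk", "unassigned"))]
  counts_a <- table(sub_a)
  ord <- order(as.integer(counts_a), decreasing = TRUE)
  mean_of <- function(lbl) fit$params$cluster_means[as.integer(lbl)]
  list(best_K = scan$best_K,
       n_substantive_a = length(counts_a),
       n_substantive_b = length(unique(sub_b)),
       n_clusters_a = length(counts_a) + 1L,
       n_clusters_b = length(unique(sub_b)) + 1L,
       rand_a = rand_a,
       rand_b = rand_b,
       mean_largest_a = if (length(counts_a) >= 1)
         mean_of(names(counts_a)[ord[1]]) else NA_real_,
       mean_second_a = if (length(counts_a) >= 2)
         mean_of(names(counts_a)[ord[2]]) else NA_real_,
       mean_third_a = if (length(counts_a) >= 3)
         mean_of(names(counts_a)[ord[3]]) else NA_real_,
       cluster_means = fit$params$cluster_means,
       fit = fit,
       scan = scan,
       assignments_a = a,
       assignments_b = b,
       sim = sim)
}

#' Run a replicated simulation study
#'
#' For each scenario: simulates `n_reps` datasets, runs the full pipeline
#' (ratio estimation with first-order standard errors, BIC scan over the
#' number of clusters, assignment under both reporting conventions), and
#' records per-replicate the Rand index against the truth, the number of
#' reported clusters (substantive + 1 for the null cluster), and the
#' estimated substantive means. True junk variants are excluded from the
#' Rand index; under the conservative convention (version B) unassigned
#' variants are excluded too.
#'
#' @param scenario_ids Vector of scenario numbers (subset of 1:4).
#' @param N Notional GWAS sample size.
#' @param n_reps Number of simulated datasets per scenario.
#' @param seed Master seed; each replicate derives its own sub-seed.
#' @param n_starts,k_max,patience,delta,max_iter EM / scan configuration.
#' @param prob_threshold,min_cluster_size Version-B reporting thresholds.
#' @return A list with `per_rep` (data.frame, one row per scenario x
#'   replicate) and `summary` (per scenario: median and first/ninth deciles
#'   of the Rand indices and reported cluster counts, and the fraction of
#'   replicates reporting at least one substantive cluster under each
#'   convention).
#' @export
run_simulation_study <- function(scenario_ids, N, n_reps, seed = 1,
                                 n_starts = 25, k_max = 5, patience = 2,
                                 delta = 1e-5, max_iter = 500,
                                 prob_threshold = 0.8, min_cluster_size = 4) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(scenario_ids) * n_reps),
                      nrow = length(scenario_ids))
  rows <- list()
  for (si in seq_along(scenario_ids)) {
    scenario <- scenario_preset(scenario_ids[si], N)
    for (r in seq_len(n_reps)) {
      res <- tryCatch(
        .simulation_rep(scenario, rep_seeds[si, r], n_starts = n_starts,
                        k_max = k_max, patience = patience, delta = delta,
                        max_iter = max_iter, prob_threshold = prob_threshold,
                        min_cluster_size = min_cluster_size),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("scenario ", scenario_ids[si], " rep ", r, " failed: ",
                conditionMessage(res))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scenario_ids[si], rep = r, seed = rep_seeds[si, r],
        best_K = res$best_K,
        n_substantive_a = res$n_substantive_a,
        n_substantive_b = res$n_substantive_b,
        n_clusters_a = res$n_clusters_a,
        n_clusters_b = res$n_clusters_b,
        rand_a = res$rand_a, rand_b = res$rand_b,
        mean_largest_a = res$mean_largest_a,
        mean_second_a = res$mean_second_a,
        mean_third_a = res$mean_third_a,
        cluster_means = paste(format(res$cluster_means, digits = 6),
                              collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  dec <- function(x) stats::quantile(x, c(0.1, 0.5, 0.9), na.rm = TRUE)
  summ <- do.call(rbind, lapply(unique(per_rep$scenario), function(s) {
    d <- per_rep[per_rep$scenario == s, ]
    data.frame(scenario = s,
               n_reps = nrow(d),
               rand_a_median = dec(d$rand_a)[2],
               rand_a_d1 = dec(d$rand_a)[1], rand_a_d9 = dec(d$rand_a)[3],
               rand_b_median = dec(d$rand_b)[2],
               rand_b_d1 = dec(d$rand_b)[1], rand_b_d9 = dec(d$rand_b)[3],
               n_clusters_a_median = dec(d$n_clusters_a)[2],
               n_clusters_b_median = dec(d$n_clusters_b)[2],
               frac_substantive_a = mean(d$n_substantive_a >= 1),
               frac_substantive_b = mean(d$n_substantive_b >= 1),
               row.names = NULL)
  }))
  list(per_rep = per_rep, summary = summ)
}
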