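#' Assign every variant to its most probable cluster (version A)
#'
#' Each variant is assigned to the component with the greatest conditional
#' probability (responsibility). Ties break toward the lower column index,
#' i.e. the null cluster first, then substantive clusters in ascending-mean
#' order, then junk.
#'
#' @param resp Responsibility matrix (columns: null, substantive 1..K, junk).
#' @param ids Character vector of variant ids, one per row.
#' @return A data.frame with columns `variant_id`, `cluster` (character:
#'   `"null"`, `"junk"`, or a substantive index `"1"`, `"2"`, ...) and
#'   `probability` (the maximal responsibility).
#' @export
assign_version_a <- function(resp, ids) {
  if (length(ids) != nrow(resp)) stop("ids must match responsibility rows")
  K <- ncol(resp) - 2
  idx <- max.col(resp, ties.method = "first")
  labels <- c("null", if (K > 0) as.character(seq_len(K)), "junk")
  data.frame(variant_id = ids,
             cluster = labels[idx],
             probability = resp[cbind(seq_len(nrow(resp)), idx)],
             stringsAsFactors = FALSE)
}

#' Conservative cluster assignment (version B)
#'
#' Variants are assigned to their most probable cluster only when that
#' probability reaches `prob_threshold` (default 0.8); otherwise they are
#' left unassigned. Any substantive cluster that ends up with fewer than
#' `min_cluster_size` assigned variants (default 4) is then dissolved, its
#' members becoming unassigned; the null and junk clusters are never
#' dissolved. Dissolution is applied once, not iterated. This convention
#' discourages reporting clusters evidenced by only a few variants.
#'
#' @inheritParams assign_version_a
#' @param prob_threshold Minimal responsibility for assignment (inclusive),
#'   in (0, 1].
#' @param min_cluster_size Minimal number of assigned variants for a
#'   substantive cluster to be reported.
#' @return As [assign_version_a()], with `"unassigned"` as an extra possible
#'   label; `probability` always carries the row maximum.
#' @export
assign_version_b <- function(resp, ids, prob_threshold = 0.8,
                             min_cluster_size = 4) {
  if (prob_threshold <= 0 || prob_threshold > 1) {
    stop("prob_threshold must be in (0, 1]")
  }
  if (min_cluster_size < 1) stop("min_cluster_size must be at least 1")
  out <- assign_version_a(resp, ids)
  out$cluster[out$probability < prob_threshold] <- "unassigned"
  substantive <- !(out$cluster %in% c("null", "junk", "unassigned"))
  counts <- table(out$cluster[substantive])
  dissolve <- names(counts)[counts < min_cluster_size]
  out$cluster[out$cluster %in% dissolve] <- "unassigned"
  out
}

#' Summarize a fitted clustering
#'
#' One row per component (plus unassigned, when present): the number of
#' assigned variants, the cluster mean (0 for null, the fitted mean for
#' substantive clusters, none for junk/unassigned) and, for substantive
#' clusters, a responsibility-weighted IVW standard error of the mean,
#' `sqrt(1 / sum_j r_jk / sigma_j^2)` — the uncertainty the EM mean update
#' itself implies.
#'
#' @param fit An `em_fit`.
#' @param assignments Assignment data.frame from [assign_version_a()] or
#'   [assign_version_b()] derived from `fit`.
#' @return A data.frame with columns `cluster`, `n_assigned`, `mean`,
#'   `mean_se`; substantive rows appear in ascending-mean order.
#' @export
summarize_clusters <- function(fit, assignments) {
  K <- fit$params$K
  sigma <- fit$data$sigma_hat
  labels <- c("null", if (K > 0) as.character(seq_len(K)), "junk")
  if (any(assignments$cluster == "unassigned")) {
    labels <- c(labels, "unassigned")
  }
  n_assigned <- vapply(labels, function(l) sum(assignments$cluster == l),
                       integer(1))
  means <- rep(NA_real_, length(labels))
  ses <- rep(NA_real_, length(labels))
  means[labels == "null"] <- 0
  if (K > 0) {
    for (k in seq_len(K)) {
      i <- which(labels == as.character(k))
      means[i] <- fit$params$cluster_means[k]
      ses[i] <- sqrt(1 / sum(fit$responsibilities[, k + 1] / sigma^2))
    }
  }
  data.frame(cluster = labels,
             n_assigned = unname(n_assigned),
             mean = means,
             mean_se = ses,
             stringsAsFactors = FALSE)
}

#' Per-variant results table
#'
#' Joins a fit and an assignment into the exportable per-variant table:
#' ratio estimate, its standard error, assigned cluster, that cluster's
#' mean (0 for null, none for junk/unassigned) and the inclusion
#' probability (maximal responsibility).
#'
#' @inheritParams summarize_clusters
#' @return A data.frame with columns `variant_id`, `ratio_estimate`,
#'   `ratio_se`, `cluster`, `cluster_mean`, `inclusion_probability`, suitable
#'   for [write_variant_results()].
#' @export
variant_results <- function(fit, assignments) {
  cluster_mean <- rep(NA_real_, nrow(assignments))
  cluster_mean[assignments$cluster == "null"] <- 0
  for (k in seq_len(fit$params$K)) {
    cluster_mean[assignments$cluster == as.character(k)] <-
      fit$params$cluster_means[k]
  }
  data.frame(variant_id = assignments$variant_id,
             ratio_estimate = fit$data$theta_hat,
             ratio_se = fit$data$sigma_hat,
             cluster = assignments$cluster,
             cluster_mean = cluster_mean,
             inclusion_probability = assignments$probability,
             stringsAsFactors = FALSE)
}
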