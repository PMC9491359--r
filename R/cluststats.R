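#' Cluster-based permutation test configuration
#'
#' Defaults follow the standard sensor-space setup for testing SNR against
#' the noise level: null value 1, cluster-forming alpha 0.05 (one-tailed
#' Student t quantile at n - 1 df), overall alpha 0.05, minimum of 2
#' suprathreshold neighboring channels per cluster member, 5,000 sign-flip
#' randomizations.
#'
#' @param null_value value tested against (1 = SNR noise level).
#' @param cluster_alpha alpha for the cluster-forming threshold.
#' @param alpha significance level for cluster p-values.
#' @param n_permutations Monte Carlo randomizations.
#' @param tail only `"greater"` is supported (SNR above noise).
#' @param min_neighbors minimum suprathreshold neighbors per cluster member.
#' @param seed seed for the sign flips.
#' @return list of class `cluster_test_config`.
#' @export
cluster_test_config <- function(null_value = 1, cluster_alpha = 0.05,
                                alpha = 0.05, n_permutations = 5000,
                                tail = "greater", min_neighbors = 2,
                                seed = 1L) {
  tail <- match.arg(tail, "greater")
  stopifnot(cluster_alpha > 0, cluster_alpha < 1, alpha > 0, alpha < 1,
            n_permutations >= 1)
  structure(list(null_value = null_value, cluster_alpha = cluster_alpha,
                 alpha = alpha, n_permutations = as.integer(n_permutations),
                 tail = tail, min_neighbors = as.integer(min_neighbors),
                 seed = as.integer(seed)),
            class = "cluster_test_config")
}

#' One-sample t statistic per sensor
#'
#' `t = (mean - null_value) / (sd / sqrt(n))` with the n-1 sample sd, per
#' sensor (column). Zero-variance sensors get `+Inf` / `-Inf` according to
#' the sign of the mean deviation (0 if the mean equals the null): a sensor
#' identically above the null is treated as suprathreshold rather than
#' dropped.
#'
#' @param responses subjects x sensors numeric matrix.
#' @param null_value scalar null value.
#' @return list with `t` (per sensor), `df` (`n - 1`), `n`.
#' @export
one_sample_tmap <- function(responses, null_value = 1) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n < 2) stop("need at least 2 subjects for a one-sample t-test")
  m <- colMeans(responses) - null_value
  ss <- colSums(responses^2) - n * colMeans(responses)^2
  v <- pmax(ss, 0) / (n - 1)
  tt <- ifelse(v > 0, m / sqrt(v / n), sign(m) * Inf)
  tt[v == 0 & m == 0] <- 0
  list(t = as.numeric(tt), df = n - 1L, n = n)
}

#' Form candidate clusters from a thresholded t map
#'
#' Three steps: (i) mark sensors with `t >= threshold`; (ii) iteratively
#' prune marked sensors having fewer than `min_neighbors` marked neighbors,
#' to a fixed point (the `minnbchan` rule); (iii) split survivors into
#' connected components under the adjacency graph. Each cluster's statistic
#' is the sum of its members' t values.
#'
#' @param tmap numeric per-sensor t values (`Inf` allowed).
#' @param threshold cluster-forming threshold (finite).
#' @param adjacency an [build_adjacency()] graph.
#' @param min_neighbors minimum marked neighbors per surviving sensor.
#' @return list of clusters, each `list(members, statistic)`, sorted by
#'   decreasing statistic; empty list if nothing survives.
#' @export
form_clusters <- function(tmap, threshold, adjacency, min_neighbors = 2) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  A <- adjacency$matrix
  sup <- !is.na(tmap) & tmap >= threshold
  if (min_neighbors > 0) {
    repeat {
      cnt <- as.integer(A %*% sup)
      drop <- sup & cnt < min_neighbors
      if (!any(drop)) break
      sup[drop] <- FALSE
    }
  }
  if (!any(sup)) return(list())
  comps <- graph_components(A, which(sup))
  out <- lapply(comps, function(members)
    list(members = members, statistic = sum(tmap[members])))
  out[order(vapply(out, `[[`, numeric(1), "statistic"), decreasing = TRUE)]
}

# t maps for a block of sign-flip permutations, computed from flipped means
# only: sums of squares of deviations are invariant under sign flips.
.perm_tmaps <- function(dev, signs) {
  n <- nrow(dev)
  ss <- colSums(dev^2)
  M <- crossprod(signs, dev) / n            # n_perm x n_sensors flipped means
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  tt <- M / sqrt(pmax(V, 0) / n)
  zero <- V <= 0
  tt[zero] <- sign(M[zero]) * Inf
  tt[zero & M == 0] <- 0
  tt
}

#' One-sample cluster-based permutation test against a constant
#'
#' Tests, per sensor, whether responses exceed `null_value` (one-tailed),
#' controlling the family-wise error over sensors with the cluster-based
#' permutation method: per-sensor t values are thresholded at the Student t
#' quantile `qt(1 - cluster_alpha, n - 1)`, suprathreshold sensors are
#' grouped into spatially connected clusters (with the minimum-neighbor
#' pruning rule), and each observed cluster's summed t is compared with the
#' Monte Carlo distribution of the maximum cluster statistic under random
#' sign flips of each subject's deviation from the null — the exact
#' one-sample equivalent of permuting condition labels against a constant
#' pseudo-condition (an "array of ones" for SNR data). Permutations with no
#' surviving cluster contribute a maximum of 0. p-values use the +1
#' correction: `p = (1 + #{perm max >= observed}) / (1 + n_permutations)`;
#' clusters with `p <= alpha` are flagged significant.
#'
#' @param responses subjects x sensors matrix of per-sensor scalars (e.g.,
#'   oddball-response SNRs).
#' @param adjacency an [build_adjacency()] graph over the same sensors.
#' @param config a [cluster_test_config()].
#' @return object of class `cluster_test_result`: `tmap`, `df`,
#'   `threshold`, `clusters` (members, sensor ids, statistic, p,
#'   significant), `perm_max` (the Monte Carlo max-statistic distribution),
#'   `config`, `n_subjects`.
#' @export
cluster_permutation_test <- function(responses, adjacency,
                                     config = cluster_test_config()) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  ns <- ncol(responses)
  if (ns != nrow(adjacency$matrix))
    stop("responses have ", ns, " sensors but adjacency covers ",
         nrow(adjacency$matrix))
  tres <- one_sample_tmap(responses, config$null_value)
  threshold <- qt(1 - config$cluster_alpha, df = tres$df)
  observed <- form_clusters(tres$t, threshold, adjacency,
                            config$min_neighbors)

  dev <- sweep(responses, 2, rep(config$null_value, ns))
  set.seed(config$seed)
  signs <- matrix(sample(c(-1, 1), n * config$n_permutations, replace = TRUE),
                  n, config$n_permutations)
  perm_max <- numeric(config$n_permutations)
  block <- 500L
  done <- 0L
  while (done < config$n_permutations) {
    take <- seq_len(min(block, config$n_permutations - done)) + done
    tP <- .perm_tmaps(dev, signs[, take, drop = FALSE])
    for (j in seq_along(take)) {
      cl <- form_clusters(tP[j, ], threshold, adjacency,
                          config$min_neighbors)
      perm_max[take[j]] <- if (length(cl)) cl[[1]]$statistic else 0
    }
    done <- done + length(take)
  }

  clusters <- lapply(observed, function(cl) {
    p <- (1 + sum(perm_max >= cl$statistic)) / (1 + config$n_permutations)
    list(members = cl$members,
         sensors = adjacency$sensor[cl$members],
         statistic = cl$statistic,
         p = p,
         significant = p <= config$alpha)
  })
  structure(list(tmap = tres$t, df = tres$df, n_subjects = n,
                 threshold = threshold, clusters = clusters,
                 perm_max = perm_max, config = config,
                 sensor = adjacency$sensor),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("<cluster_test_result> one-tailed one-sample cluster permutation ",
      "test vs ", x$config$null_value, "\n", sep = "")
  cat("  n = ", x$n_subjects, " (df = ", x$df, "), threshold t = ",
      round(x$threshold, 3), ", ", x$config$n_permutations,
      " randomizations\n", sep = "")
  if (!length(x$clusters)) {
    cat("  no clusters\n")
  } else for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d sensors, sum t(%d) = %.2f, p = %.4g%s\n",
                i, length(cl$members), x$df, cl$statistic, cl$p,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Export a cluster test result
#'
#' Writes a JSON report (config, df, threshold, clusters with sensor ids,
#' statistics and Monte Carlo p values) and, optionally, a TSV t-map.
#'
#' @param result a `cluster_test_result`.
#' @param path JSON output path.
#' @param tmap_path optional TSV path for the per-sensor t map.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(result, path, tmap_path = NULL) {
  rep <- list(
    test = "one-sample cluster-based permutation (sign-flip Monte Carlo)",
    null_value = result$config$null_value,
    tail = result$config$tail,
    df = result$df,
    n_subjects = result$n_subjects,
    threshold_t = result$threshold,
    cluster_alpha = result$config$cluster_alpha,
    alpha = result$config$alpha,
    n_permutations = result$config$n_permutations,
    min_neighbors = result$config$min_neighbors,
    seed = result$config$seed,
    zero_variance_sensors = result$sensor[is.infinite(result$tmap)],
    clusters = lapply(result$clusters, function(cl)
      list(sensors = cl$sensors, statistic = cl$statistic, p = cl$p,
           significant = cl$significant)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if (!is.null(tmap_path))
    write.table(data.frame(sensor = result$sensor, t = result$tmap),
                tmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
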