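#' Temporal similarity topography
#'
#' The temporal RSA first stage: at every electrode, the Pearson correlation
#' between the two trials' time series over the analysis interval for every
#' item pair, averaged per condition per participant. Localizes the
#' similarity effect over the scalp rather than in time. The default
#' interval spans the whole pre-idiom-final epoch (-1,100 to 0 ms, endpoints
#' included).
#'
#' @param epochs an [epoch_set()].
#' @param design a [enumerate_pairs()] result.
#' @param interval c(lo, hi) ms.
#' @param fisher_z average correlations through the Fisher z transform
#'   (off by default).
#' @return a \code{topo_similarity}: list with \code{values} (participants x
#'   conditions x electrodes mean r), \code{electrodes} (label table),
#'   \code{interval}, \code{grand} (conditions x electrodes grand average),
#'   \code{n_pairs}, \code{dropped}.
#' @export
temporal_similarity_map <- function(epochs, design, interval = c(-1100, 0),
                                    fisher_z = FALSE) {
  item_ids <- attr(design, "item_ids")
  parts <- unique(epochs$trials$participant)
  idx <- window_index(epochs$time, interval, "interval")
  n_el <- nrow(epochs$channels)
  iw <- pair_index(design[design$condition == "within", ], item_ids)
  ib <- pair_index(design[design$condition == "between", ], item_ids)
  vals <- array(NA_real_, c(length(parts), 2L, n_el),
                dimnames = list(parts, c("within", "between"),
                                epochs$channels$label))
  n_pairs <- matrix(0L, length(parts), 2L,
                    dimnames = list(parts, c("within", "between")))
  dropped <- 0L
  for (p in seq_along(parts)) {
    A <- participant_array(epochs, parts[p], item_ids)
    present <- !is.na(A[, 1L, 1L])
    ok_w <- present[((iw - 1L) %% length(item_ids)) + 1L] &
            present[((iw - 1L) %/% length(item_ids)) + 1L]
    ok_b <- present[((ib - 1L) %% length(item_ids)) + 1L] &
            present[((ib - 1L) %/% length(item_ids)) + 1L]
    n_pairs[p, ] <- c(sum(ok_w), sum(ok_b))
    dropped <- dropped + sum(!ok_w) + sum(!ok_b)
    if (any(n_pairs[p, ] == 0L))
      abort("NoPairsError",
            sprintf("participant %s has no usable pairs in a condition",
                    parts[p]))
    A[!present, , ] <- 0
    for (e in seq_len(n_el)) {
      r <- row_corr(A[, e, idx])
      vals[p, 1L, e] <- cond_mean(r, iw[ok_w], fisher_z)
      vals[p, 2L, e] <- cond_mean(r, ib[ok_b], fisher_z)
    }
  }
  structure(list(values = vals, electrodes = epochs$channels,
                 interval = interval, n_pairs = n_pairs, dropped = dropped,
                 participants = parts,
                 grand = apply(vals, c(2L, 3L), mean)),
            class = "topo_similarity")
}

#' @export
print.topo_similarity <- function(x, ...) {
  diff <- x$grand[1, ] - x$grand[2, ]
  cat(sprintf(
    "Temporal similarity topography: %d participants, %d electrodes, %g..%g ms\n",
    length(x$participants), ncol(x$grand), x$interval[1], x$interval[2]))
  cat(sprintf("  grand within-between difference: %.4f..%.4f (max at %s)\n",
              min(diff), max(diff), names(which.max(diff))))
  invisible(x)
}

#' @export
plot.topo_similarity <- function(x, what = c("difference", "within", "between"),
                                 ...) {
  what <- match.arg(what)
  v <- switch(what, difference = x$grand[1, ] - x$grand[2, ],
              within = x$grand[1, ], between = x$grand[2, ])
  # simple top-down projection of the head sphere
  px <- x$electrodes$x
  py <- x$electrodes$y
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  col <- pal[cut(v, 64, labels = FALSE)]
  graphics::plot(px, py, pch = 21, bg = col, cex = 2.2, asp = 1,
                 xlab = "left-right", ylab = "posterior-anterior",
                 main = sprintf("temporal similarity (%s)", what), ...)
  graphics::text(px, py, x$electrodes$label, cex = 0.4, pos = 3)
  invisible(x)
}

#' Cluster-based permutation test over electrodes
#'
#' Tests the within- minus between-pair temporal-similarity difference at
#' each electrode with a permutation of condition labels within participant
#' (sign flip of the difference), then controls the familywise error over
#' the scalp with an adjacency-cluster statistic: electrodes whose
#' permutation p is at or below \code{alpha_electrode} compose connected
#' clusters, each summarized by its size (electrode count; a
#' summed-mean-difference "mass" statistic is available behind the
#' \code{statistic} flag). A cluster's p-value compares its statistic with
#' the permutation distribution of the maximal cluster statistic, obtained
#' by thresholding every permutation's electrode statistics against the
#' same permutation distribution.
#'
#' @param topo a [temporal_similarity_map()] result.
#' @param adjacency an [build_adjacency()] result over the same electrodes.
#' @param alpha_electrode per-electrode threshold for cluster forming.
#' @param n_perm number of permutations.
#' @param statistic \code{"size"} (electrode count, default) or \code{"mass"}.
#' @param seed integer seed (mandatory).
#' @return an \code{electrode_cluster_result}: data frame of clusters
#'   (\code{electrodes} as comma-joined labels, \code{size}, \code{mass},
#'   \code{p}) with a per-electrode table (observed mean difference and
#'   permutation p) in \code{attr(, "electrode_table")}.
#' @export
cluster_permutation_electrodes <- function(topo, adjacency,
                                           alpha_electrode = 0.05,
                                           n_perm = 1000,
                                           statistic = c("size", "mass"),
                                           seed = NULL) {
  statistic <- match.arg(statistic)
  labs <- dimnames(topo$values)[[3]]
  if (!identical(sort(labs), sort(rownames(adjacency))))
    abort("ConfigError", "topography and adjacency electrode sets differ")
  adjacency <- adjacency[labs, labs]
  n <- dim(topo$values)[1]
  if (n < 3L) abort("ConfigError", "need at least 3 participants")
  D <- topo$values[, 1L, ] - topo$values[, 2L, ] # participants x electrodes
  with_seed(seed, {
    S <- flip_matrix(n_perm, n)
    P <- (S %*% D) / n # mean differences; row 1 = observed
    obs <- P[1L, ]
    Pn <- abs(P[-1L, , drop = FALSE])
    # permutation p per electrode: share of the null at or above |stat|
    p_obs <- colMeans(sweep(Pn, 2L, abs(obs), ">=") * 1)
    # p of each permutation's own statistic within the same null (ties >=)
    n_ge <- apply(Pn, 2L, function(col) {
      length(col) - rank(col, ties.method = "min") + 1L
    })
    sig_null <- n_ge / n_perm <= alpha_electrode
    # significant neighbors compose clusters, irrespective of the sign of
    # their mean difference (two-sided electrode test)
    cluster_rows <- function(sig) {
      nodes <- which(sig)
      if (!length(nodes)) return(list())
      connected_components(adjacency, nodes)
    }
    null_max <- vapply(seq_len(n_perm), function(b) {
      cls <- cluster_rows(sig_null[b, ])
      if (!length(cls)) return(0)
      if (statistic == "size") max(lengths(cls))
      else max(vapply(cls, function(i) abs(sum(Pn[b, i])), 0))
    }, 0)
    cls <- cluster_rows(p_obs <= alpha_electrode)
    res <- data.frame(
      electrodes = vapply(cls, function(i) paste(labs[i], collapse = ","), ""),
      size = lengths(cls),
      mass = vapply(cls, function(i) sum(obs[i]), 0))
    stat_obs <- if (statistic == "size") res$size else abs(res$mass)
    res$p <- vapply(stat_obs, function(s) mean(null_max >= s), 0)
    structure(res,
              electrode_table = data.frame(label = labs, difference = obs,
                                           p = p_obs),
              alpha_electrode = alpha_electrode, n_perm = n_perm,
              statistic = statistic, seed = seed,
              null_quantiles = stats::quantile(null_max,
                                               c(0.5, 0.9, 0.95, 0.99)),
              class = c("electrode_cluster_result", "data.frame"))
  })
}

#' @export
print.electrode_cluster_result <- function(x, ...) {
  cat(sprintf("Electrode-cluster permutation (%s statistic, %d permutations)\n",
              attr(x, "statistic"), attr(x, "n_perm")))
  if (!nrow(x)) cat("  no suprathreshold electrodes\n")
  else print.data.frame(x, row.names = FALSE)
  invisible(x)
}
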