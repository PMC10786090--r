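#' Pearson product-moment correlation
#'
#' The package's correlation primitive: \eqn{r = \sum (x-\bar x)(y-\bar y) /
#' \sqrt{\sum(x-\bar x)^2 \sum(y-\bar y)^2}}. Symmetric and invariant to
#' affine rescaling of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @examples
#' pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)) # 0.6
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort("ConfigError", "x and y must have equal length >= 3")
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den < 1e-24)
    abort("ZeroVarianceError", "zero-variance input to pearson()")
  sum(xc * yc) / den
}

#' Spatial similarity timecourse
#'
#' The spatial RSA first stage: at every timepoint, the channel-pattern
#' (across-electrode) Pearson correlation between the two trials of every
#' item pair, averaged per condition (within / between) per participant.
#' Pairs whose member trial is missing (e.g. rejected) are dropped silently
#' and counted; zero-variance patterns likewise.
#'
#' @param epochs an [epoch_set()].
#' @param design a [enumerate_pairs()] result.
#' @param fisher_z average correlations through the Fisher z transform
#'   (off by default: raw r values are averaged).
#' @return a \code{similarity_timecourse}: list with \code{values}
#'   (participants x conditions x timepoints array of mean r), \code{n_pairs}
#'   (usable pairs per participant x condition), \code{time},
#'   \code{participants}, \code{dropped} (pairs lost to missing trials),
#'   and the grand average (\code{grand}, conditions x timepoints).
#' @export
spatial_similarity_timecourse <- function(epochs, design, fisher_z = FALSE) {
  item_ids <- attr(design, "item_ids")
  parts <- unique(epochs$trials$participant)
  n_time <- length(epochs$time)
  iw <- pair_index(design[design$condition == "within", ], item_ids)
  ib <- pair_index(design[design$condition == "between", ], item_ids)
  vals <- array(NA_real_, c(length(parts), 2L, n_time),
                dimnames = list(parts, c("within", "between"), NULL))
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
    A[!present, , ] <- 0 # row_corr will not be read at masked pairs
    for (t in seq_len(n_time)) {
      r <- row_corr(A[, , t])
      vals[p, 1L, t] <- cond_mean(r, iw[ok_w], fisher_z)
      vals[p, 2L, t] <- cond_mean(r, ib[ok_b], fisher_z)
    }
  }
  structure(list(values = vals, n_pairs = n_pairs, time = epochs$time,
                 participants = parts, dropped = dropped,
                 grand = apply(vals, c(2L, 3L), mean)),
            class = "similarity_timecourse")
}

#' @export
print.similarity_timecourse <- function(x, ...) {
  cat(sprintf(
    "Spatial similarity timecourse: %d participants, %g..%g ms (%d samples)\n",
    length(x$participants), min(x$time), max(x$time), length(x$time)))
  cat(sprintf("  pairs/participant: %d within, %d between; %d pair(s) dropped\n",
              x$n_pairs[1, 1], x$n_pairs[1, 2], x$dropped))
  invisible(x)
}

#' @export
plot.similarity_timecourse <- function(x, windows = list(c(-200, 0)), ...) {
  graphics::matplot(x$time, t(x$grand), type = "l", lty = 1,
                    col = c("#2166ac", "#b2182b"),
                    xlab = "time (ms, 0 = idiom-final onset)",
                    ylab = "mean pattern correlation r", ...)
  for (w in windows)
    graphics::rect(w[1], graphics::par("usr")[3], w[2],
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topleft", c("within", "between"), lty = 1,
                   col = c("#2166ac", "#b2182b"), bty = "n")
  invisible(x)
}

#' Predictive-window test
#'
#' Paired two-sided t-test across participants of the window-averaged
#' within-pair versus between-pair mean similarity. The default window is
#' the last 200 ms before idiom-final onset, where pre-activation of the
#' upcoming phonology is expected to surface.
#'
#' @param tc a [spatial_similarity_timecourse()] result.
#' @param window c(lo, hi) ms, closed on both ends.
#' @return list with \code{t}, \code{p}, \code{df}, \code{window} and
#'   \code{participant_means} (per-participant window means by condition).
#' @export
window_test <- function(tc, window = c(-200, 0)) {
  if (length(tc$participants) < 3L)
    abort("ConfigError", "need at least 3 participants")
  idx <- window_index(tc$time, window)
  w <- rowMeans(tc$values[, 1L, idx, drop = FALSE], dims = 1L)
  b <- rowMeans(tc$values[, 2L, idx, drop = FALSE], dims = 1L)
  if (stats::sd(w - b) < 1e-15) {
    # degenerate: identical conditions for every participant
    eq <- abs(mean(w - b)) < 1e-15
    return(list(t = if (eq) 0 else sign(mean(w - b)) * Inf,
                p = if (eq) 1 else 0, df = length(w) - 1, window = window,
                participant_means = data.frame(participant = tc$participants,
                                               within = w, between = b)))
  }
  tt <- stats::t.test(w, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       window = window,
       participant_means = data.frame(participant = tc$participants,
                                      within = w, between = b))
}

#' Cluster-based permutation test over time
#'
#' Tests the within- minus between-pair similarity difference across a time
#' span while controlling the familywise error over timepoints. A paired t
#' is computed at each timepoint; maximal runs of adjacent timepoints with
#' two-sided p below \code{alpha_cluster} and a consistent sign form
#' clusters, each summarized by its mass (summed t; a run-length "size"
#' statistic is available behind the \code{statistic} flag). The null
#' distribution is the per-permutation maximum cluster statistic under
#' random exchange of the condition labels within participant — a sign flip
#' of each participant's difference timecourse. A cluster's p-value is the
#' proportion of the null at or above its |mass|, ties counting against
#' significance.
#'
#' @param tc a [spatial_similarity_timecourse()] result.
#' @param span c(lo, hi) ms analysis span (e.g. the pre-onset epoch
#'   c(-1100, 0), or c(0, 600) post-onset).
#' @param alpha_cluster per-timepoint threshold for cluster forming.
#' @param n_perm number of label permutations.
#' @param statistic cluster summary: \code{"mass"} (summed t, default) or
#'   \code{"size"} (run length).
#' @param seed integer seed (mandatory).
#' @return a \code{cluster_result}: data frame of clusters (\code{start},
#'   \code{end} ms, \code{mass}, \code{size}, \code{p}) with the threshold,
#'   permutation count and null-distribution quantiles as attributes.
#' @export
cluster_permutation_time <- function(tc, span = c(-1100, 0),
                                     alpha_cluster = 0.05, n_perm = 1000,
                                     statistic = c("mass", "size"),
                                     seed = NULL) {
  statistic <- match.arg(statistic)
  n <- length(tc$participants)
  if (n < 3L) abort("ConfigError", "need at least 3 participants")
  idx <- window_index(tc$time, span, "span")
  D <- tc$values[, 1L, idx] - tc$values[, 2L, idx]
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = n - 1L)
  with_seed(seed, {
    S <- flip_matrix(n_perm, n)
    Tm <- flip_t(D, S)
    tobs <- Tm[1L, ]
    null_max <- vapply(seq_len(n_perm) + 1L,
                       function(i) max_cluster_stat(Tm[i, ], tcrit, statistic),
                       0)
    runs <- t_runs(tobs, tcrit)
    cl <- data.frame(
      start = vapply(runs, function(i) tc$time[idx][min(i)], 0),
      end = vapply(runs, function(i) tc$time[idx][max(i)], 0),
      mass = vapply(runs, function(i) sum(tobs[i]), 0),
      size = lengths(runs))
    stat_obs <- if (statistic == "mass") abs(cl$mass) else cl$size
    cl$p <- vapply(stat_obs, function(s) mean(null_max >= s), 0)
    structure(cl,
              span = span, alpha_cluster = alpha_cluster, n_perm = n_perm,
              statistic = statistic, seed = seed,
              null_quantiles = stats::quantile(null_max,
                                               c(0.5, 0.9, 0.95, 0.99)),
              class = c("cluster_result", "data.frame"))
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Time-cluster permutation (%s statistic, %d permutations, span %g..%g ms)\n",
              attr(x, "statistic"), attr(x, "n_perm"),
              attr(x, "span")[1], attr(x, "span")[2]))
  if (!nrow(x)) cat("  no suprathreshold clusters\n")
  else print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Significant clusters of a cluster result
#'
#' @param x a \code{cluster_result} or \code{electrode_cluster_result}.
#' @param alpha cluster-level significance threshold (clusters with
#'   \code{p <= alpha}; ties already count against significance in the
#'   permutation p-value itself).
#' @return the significant subset, same class.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  x[x$p <= alpha, , drop = FALSE]
}

# Per-participant x pair matrix of window-averaged pattern correlations.
# Shared by the matched-subsample control and the pair-level table.
pair_window_corr <- function(epochs, design, window) {
  item_ids <- attr(design, "item_ids")
  parts <- unique(epochs$trials$participant)
  idx <- window_index(epochs$time, window)
  ip <- pair_index(design, item_ids)
  out <- matrix(NA_real_, length(parts), nrow(design),
                dimnames = list(parts, NULL))
  for (p in seq_along(parts)) {
    A <- participant_array(epochs, parts[p], item_ids)
    present <- !is.na(A[, 1L, 1L])
    A[!present, , ] <- 0
    acc <- 0
    for (t in idx) acc <- acc + row_corr(A[, , t])
    r <- acc / length(idx)
    ok <- present[((ip - 1L) %% length(item_ids)) + 1L] &
          present[((ip - 1L) %/% length(item_ids)) + 1L]
    v <- r[ip]
    v[!ok] <- NA_real_
    out[p, ] <- v
  }
  out
}

#' Matched-subsample control test
#'
#' Re-runs the predictive-window comparison with the between-pair
#' correlations randomly subsampled (without replacement, one draw per
#' participant) to the number of within-pairs, removing the imbalance in
#' pair counts. The pair count affects only the variance of a condition
#' mean, not its expectation, so the full and subsampled between means agree
#' up to subsampling noise.
#'
#' @param epochs an [epoch_set()].
#' @param design a [enumerate_pairs()] result.
#' @param window analysis window, ms.
#' @param seed integer seed.
#' @return list with \code{t}, \code{p}, \code{df}, per-participant means
#'   (\code{within}, \code{between_full}, \code{between_sub}), and the
#'   subsampled pair indices per participant.
#' @export
matched_subsample_test <- function(epochs, design, window = c(-200, 0),
                                   seed = NULL) {
  pw <- pair_window_corr(epochs, design, window)
  wi <- which(design$condition == "within")
  bi <- which(design$condition == "between")
  if (length(bi) < length(wi))
    abort("ConfigError", "fewer between- than within-pairs")
  with_seed(seed, {
    w_mean <- rowMeans(pw[, wi, drop = FALSE], na.rm = TRUE)
    b_full <- rowMeans(pw[, bi, drop = FALSE], na.rm = TRUE)
    sub <- lapply(seq_len(nrow(pw)), function(p) {
      ok <- bi[!is.na(pw[p, bi])]
      sort(sample(ok, min(length(wi), length(ok))))
    })
    b_sub <- vapply(seq_len(nrow(pw)),
                    function(p) mean(pw[p, sub[[p]]]), 0)
    tt <- stats::t.test(w_mean, b_sub, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), window = window,
         participant_means = data.frame(participant = rownames(pw),
                                        within = w_mean,
                                        between_full = b_full,
                                        between_sub = b_sub),
         subsample = sub)
  })
}
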