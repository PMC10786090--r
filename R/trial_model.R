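#' Build the pair-level similarity table
#'
#' One row per usable (participant, pair): the neural similarity
#' (window-averaged channel-pattern correlation between the pair's two
#' trials, default window -200..0 ms) alongside the pair's phonological,
#' semantic and orthographic stimulus similarities read from
#' third-character similarity matrices. Pairs that lost a trial to
#' rejection are dropped and counted in \code{attr(, "dropped")}.
#'
#' @param epochs an [epoch_set()].
#' @param design a [enumerate_pairs()] result.
#' @param covariates named list of labelled similarity matrices; must cover
#'   \code{phonological}, \code{semantic} and \code{orthographic} for the
#'   standard model (any non-empty set is accepted).
#' @param window neural-similarity window, ms.
#' @return a \code{pair_table} data frame with columns \code{participant},
#'   \code{item_a}, \code{item_b}, \code{condition}, \code{neural_r} and one
#'   column per covariate.
#' @export
build_pair_table <- function(epochs, design, covariates, window = c(-200, 0)) {
  if (!is.list(covariates) || is.null(names(covariates)) ||
      !length(covariates))
    abort("MissingEntryError", "'covariates' must be a named list of matrices")
  cov_vals <- lapply(covariates, pair_values, design = design)
  pw <- pair_window_corr(epochs, design, window)
  n_pair <- nrow(design)
  parts <- rownames(pw)
  out <- data.frame(
    participant = rep(parts, each = n_pair),
    item_a = rep(design$item_a, length(parts)),
    item_b = rep(design$item_b, length(parts)),
    condition = rep(design$condition, length(parts)),
    neural_r = as.vector(t(pw)),
    stringsAsFactors = FALSE)
  for (nm in names(cov_vals)) out[[nm]] <- rep(cov_vals[[nm]], length(parts))
  dropped <- sum(is.na(out$neural_r))
  out <- out[!is.na(out$neural_r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "window") <- window
  class(out) <- c("pair_table", "data.frame")
  out
}

#' @rdname build_pair_table
#' @param table a pair table.
#' @param path TSV output path.
#' @export
write_pair_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-stage regression of neural on stimulus similarity
#'
#' A summary-statistics substitute for a mixed-effects model of pair-level
#' neural similarity: stage 1 fits ordinary least squares per participant
#' with the predictors standardized within participant (plus an intercept);
#' stage 2 tests each coefficient against zero with a one-sample two-sided
#' t-test across participants. With one observation set per participant
#' this gives fixed-effect inference equivalent in spirit to a
#' random-intercept + random-slope model, without a mixed-model dependency;
#' the stage-1 design matrix can be exported with [write_pair_table()] for
#' users who want to refit the original formulation externally.
#'
#' Predictors that are constant within a participant cannot be standardized
#' and receive an NA coefficient for that participant; stage 2 then uses the
#' participants with defined coefficients.
#'
#' @param table a [build_pair_table()] result (or compatible data frame).
#' @param predictors covariate columns to enter jointly.
#' @param kappa_max condition-number bound on the standardized design; a
#'   larger value raises a collinearity error.
#' @return a \code{two_stage_fit}: list with \code{coefficients}
#'   (participants x terms matrix), \code{group} (term, estimate = mean
#'   coefficient, t, df, p), \code{n_rows} per participant.
#' @export
two_stage_regression <- function(table,
                                 predictors = c("phonological", "semantic",
                                                "orthographic"),
                                 kappa_max = 1e8) {
  miss <- setdiff(c("participant", "neural_r", predictors), names(table))
  if (length(miss))
    abort("MissingEntryError",
          paste("pair table lacks columns:", paste(miss, collapse = ", ")))
  parts <- unique(table$participant)
  terms <- c("(Intercept)", predictors)
  coefs <- matrix(NA_real_, length(parts), length(terms),
                  dimnames = list(parts, terms))
  n_rows <- integer(length(parts))
  for (p in seq_along(parts)) {
    d <- table[table$participant == parts[p], , drop = FALSE]
    n_rows[p] <- nrow(d)
    if (nrow(d) < length(predictors) + 2L)
      abort("InsufficientRowsError",
            sprintf("participant %s has %d rows; need >= %d",
                    parts[p], nrow(d), length(predictors) + 2L))
    Z <- vapply(predictors, function(v) {
      s <- stats::sd(d[[v]])
      if (is.na(s) || s < 1e-12) rep(NA_real_, nrow(d))
      else (d[[v]] - mean(d[[v]])) / s
    }, numeric(nrow(d)))
    usable <- colSums(is.na(Z)) == 0L
    X <- cbind(`(Intercept)` = 1, Z[, usable, drop = FALSE])
    if (ncol(X) > 1L && kappa(X, exact = TRUE) > kappa_max)
      abort("CollinearityError",
            sprintf("standardized design for participant %s is collinear",
                    parts[p]))
    fit <- stats::lm.fit(X, d$neural_r)
    coefs[p, c("(Intercept)", predictors[usable])] <- fit$coefficients
  }
  group <- do.call(rbind, lapply(terms, function(tm) {
    v <- coefs[, tm]
    v <- v[!is.na(v)]
    if (length(v) < 3L)
      return(data.frame(term = tm, estimate = mean(v), t = NA_real_,
                        df = NA_real_, p = NA_real_, n = length(v)))
    if (stats::sd(v) < 1e-15) # degenerate: identical coefficients
      return(data.frame(term = tm, estimate = mean(v),
                        t = if (abs(mean(v)) > 1e-15) Inf else 0,
                        df = length(v) - 1,
                        p = if (abs(mean(v)) > 1e-15) 0 else 1, n = length(v)))
    tt <- stats::t.test(v)
    data.frame(term = tm, estimate = mean(v), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, n = length(v))
  }))
  rownames(group) <- NULL
  structure(list(coefficients = coefs, group = group, n_rows = n_rows,
                 predictors = predictors),
            class = "two_stage_fit")
}

#' @export
coef.two_stage_fit <- function(object, ...) {
  stats::setNames(object$group$estimate, object$group$term)
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat(sprintf(
    "Two-stage regression: %d participants, %d-%d pairs each\n",
    nrow(x$coefficients), min(x$n_rows), max(x$n_rows)))
  print.data.frame(x$group, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.two_stage_fit <- function(object, ...) {
  cat("Stage-1 coefficient spread across participants:\n")
  print(apply(object$coefficients, 2L, stats::quantile,
              probs = c(0.25, 0.5, 0.75), na.rm = TRUE), digits = 4)
  cat("\nStage-2 group tests:\n")
  print.data.frame(object$group, row.names = FALSE, digits = 4)
  invisible(object)
}
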