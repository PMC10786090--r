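# Shared internals for both RSA flavours: fast pairwise row correlations,
# vectorized paired t statistics under sign-flip permutation, and
# suprathreshold run/cluster finding.

# Pairwise Pearson correlation between the rows of X (items x features).
# Rows with (near-)zero variance or NA entries yield NA correlations; the
# caller drops those pairs and logs the count.
row_corr <- function(X) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  ss <- rowSums(Xc^2)
  bad <- !is.finite(ss) | ss < 1e-24
  Xc[bad, ] <- 0
  r <- tcrossprod(Xc) / sqrt(tcrossprod(ss))
  r[bad, ] <- NA_real_
  r[, bad] <- NA_real_
  r
}

# Linear indices of design pairs into an n x n item-correlation matrix.
pair_index <- function(design, item_ids) {
  ia <- match(design$item_a, item_ids)
  ib <- match(design$item_b, item_ids)
  if (anyNA(ia) || anyNA(ib))
    abort("MissingEntryError", "design references items absent from the data")
  (ib - 1L) * length(item_ids) + ia
}

# Condition-wise mean of r at linear indices, optionally through Fisher z.
cond_mean <- function(r, idx, fisher_z = FALSE) {
  v <- r[idx]
  if (fisher_z) {
    v <- atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12))
    tanh(mean(v, na.rm = TRUE))
  } else mean(v, na.rm = TRUE)
}

# Per-column paired t statistics of a participants x variables difference
# matrix under sign-flip permutation. S is a permutations x participants
# matrix of +/-1 (first row all +1 gives the observed statistic). Sums of
# squares are sign-invariant, so everything vectorizes.
flip_t <- function(D, S) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ss <- rep(colSums(D^2), each = nrow(S))
  v <- (ss - n * M^2) / (n - 1)
  v[v < 1e-24] <- 1e-24
  M / sqrt(v / n)
}

# Maximal runs of suprathreshold, sign-consistent entries of a t vector.
# Returns a list of index vectors.
t_runs <- function(tvec, tcrit) {
  state <- sign(tvec) * (abs(tvec) > tcrit)
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0
  mapply(function(s, e) s:e, starts[keep], ends[keep], SIMPLIFY = FALSE)
}

# Max |summed t| (statistic = "mass") or max run length ("size") over the
# clusters of one t vector; 0 when no suprathreshold run exists.
max_cluster_stat <- function(tvec, tcrit, statistic) {
  runs <- t_runs(tvec, tcrit)
  if (!length(runs)) return(0)
  if (statistic == "mass") max(abs(vapply(runs, function(i) sum(tvec[i]), 0)))
  else max(lengths(runs))
}

# +/-1 sign-flip matrix with the observed assignment first.
flip_matrix <- function(n_perm, n) {
  rbind(rep(1, n),
        matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm))
}
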