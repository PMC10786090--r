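#' Packaged 62-channel extended 10-20 montage
#'
#' Unit-sphere head coordinates for a 62-electrode extended 10-20 layout
#' (+x = right ear, +y = nasion, +z = vertex). For reduced channel counts a
#' spatially contiguous sub-layout is grown outward from Cz over the full
#' montage's adjacency graph, so that scaled-down simulations keep a
#' connected, realistic geometry.
#'
#' @param n_channels number of electrodes (2..62).
#' @return data frame with columns \code{label}, \code{x}, \code{y}, \code{z}.
#' @export
montage_layout <- function(n_channels = 62L) {
  m <- utils::read.delim(system.file("extdata", "montage62.tsv",
                                     package = "phonrsa"),
                         stringsAsFactors = FALSE)
  if (n_channels > nrow(m) || n_channels < 2L)
    abort("ConfigError",
          sprintf("n_channels must be in 2..%d for the packaged montage",
                  nrow(m)))
  if (n_channels == nrow(m)) return(m)
  adj <- build_adjacency(m)
  patch <- grow_patch(adj, "Cz", n_channels,
                      coords = as.matrix(m[, c("x", "y", "z")]))
  m[match(patch, m$label), , drop = FALSE]
}

#' Electrode adjacency by distance threshold
#'
#' Two electrodes are neighbors when their Euclidean distance is at most
#' \code{threshold}. The default threshold, 1.3 times the median
#' nearest-neighbor distance, connects each electrode of the packaged
#' montage to its immediate ring (2-6 neighbors) while keeping the graph
#' connected.
#'
#' @param coordinates data frame with \code{label}, \code{x}, \code{y},
#'   \code{z} (or a numeric matrix with rownames).
#' @param threshold distance cutoff; \code{NULL} for the default.
#' @return an \code{electrode_adjacency}: logical symmetric matrix with a
#'   zero diagonal, electrode labels as dimnames, and the construction
#'   parameters stored as attributes.
#' @export
build_adjacency <- function(coordinates, threshold = NULL) {
  if (is.data.frame(coordinates)) {
    labs <- coordinates$label
    xyz <- as.matrix(coordinates[, c("x", "y", "z")])
  } else {
    labs <- rownames(coordinates)
    xyz <- coordinates
  }
  if (nrow(xyz) < 2L)
    abort("ConfigError", "need at least 2 electrodes")
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  if (min(d) < 1e-12)
    abort("DegenerateLayoutError", "two electrodes coincide")
  if (is.null(threshold)) threshold <- 1.3 * stats::median(apply(d, 1L, min))
  if (threshold <= 0) abort("ConfigError", "'threshold' must be positive")
  adj <- d <= threshold
  dimnames(adj) <- list(labs, labs)
  structure(adj, threshold = threshold,
            class = c("electrode_adjacency", "matrix", "array"))
}

# Connected components of a node subset under a logical adjacency matrix.
# Returns a list of integer index vectors (into `nodes`).
connected_components <- function(adj, nodes) {
  comps <- list()
  left <- nodes
  while (length(left)) {
    comp <- left[1L]
    frontier <- comp
    left <- left[-1L]
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0L)
      frontier <- intersect(nb, left)
      comp <- c(comp, frontier)
      left <- setdiff(left, frontier)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Grow a contiguous electrode patch
#'
#' Deterministic breadth-first growth from a start electrode, admitting
#' nearest (by coordinate distance, when supplied) frontier electrodes
#' first. Used to place ground-truth effect patches and to carve contiguous
#' sub-layouts out of the full montage.
#'
#' @param adjacency an [build_adjacency()] result.
#' @param start electrode label to grow from.
#' @param size patch size.
#' @param coords optional coordinate matrix (rows ordered as the adjacency)
#'   used to rank frontier electrodes by distance from the start.
#' @return character vector of \code{size} electrode labels.
#' @export
grow_patch <- function(adjacency, start, size, coords = NULL) {
  labs <- rownames(adjacency)
  s <- match(start, labs)
  if (is.na(s)) abort("ConfigError", sprintf("unknown electrode '%s'", start))
  patch <- s
  while (length(patch) < size) {
    nb <- setdiff(which(colSums(adjacency[patch, , drop = FALSE]) > 0L), patch)
    if (!length(nb))
      abort("ConfigError", "adjacency component smaller than requested patch")
    if (!is.null(coords)) {
      d0 <- sqrt(colSums((t(coords[nb, , drop = FALSE]) - coords[s, ])^2))
      nb <- nb[order(d0, nb)]
    }
    patch <- c(patch, nb[seq_len(min(length(nb), size - length(patch)))])
  }
  labs[patch]
}
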