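#' Read or write a stimulus table
#'
#' The stimulus TSV has one row per item with columns \code{item_id},
#' \code{char1..char4} (symbol sequence), \code{syl1..syl4} (compact pinyin,
#' e.g. \code{"ji1"}), \code{set_id} and optionally \code{cloze} (proportion
#' in \[0, 1\]). Items within a set share the third syllable — the
#' phonological overlap the design manipulates.
#'
#' @param path file path (UTF-8 TSV).
#' @return `read_stimuli`: a validated stimulus data frame.
#' @seealso [validate_items()], [generate_stimuli()]
#' @export
read_stimuli <- function(path) {
  items <- utils::read.delim(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  validate_items(items)
}

#' @rdname read_stimuli
#' @param items stimulus data frame.
#' @export
write_stimuli <- function(items, path) {
  utils::write.table(items, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a stimulus table
#'
#' Checks the structural invariants the pair design relies on: unique item
#' ids, four parseable syllables per item, and — crucially — that all items
#' sharing a \code{set_id} carry an identical third syllable (onset, rime
#' and tone all equal), since within-set pairs are defined by that overlap.
#'
#' @param items data frame with columns \code{item_id}, \code{syl1..syl4},
#'   \code{set_id} (and optionally \code{char1..char4}, \code{cloze}).
#' @return the validated items, invisibly classed for downstream use.
#' @export
validate_items <- function(items) {
  need <- c("item_id", paste0("syl", 1:4), "set_id")
  if (!is.data.frame(items) || nrow(items) == 0L)
    abort("ConfigError", "'items' must be a non-empty data frame")
  miss <- setdiff(need, names(items))
  if (length(miss))
    abort("ConfigError",
          paste("missing stimulus columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(items$item_id))
    abort("DuplicateIdError",
          sprintf("duplicated item_id: %s",
                  items$item_id[duplicated(items$item_id)][1]))
  for (p in 1:4) parse_syllable(items[[paste0("syl", p)]]) # errors if malformed
  # identical third syllable within every set (string identity == component
  # identity for compact pinyin tokens)
  for (s in unique(items$set_id)) {
    syl3 <- items$syl3[items$set_id == s]
    if (length(unique(syl3)) > 1L)
      abort("SetConsistencyError",
            sprintf("set '%s' mixes third syllables: %s", s,
                    paste(unique(syl3), collapse = ", ")))
  }
  if (!is.null(items$cloze) &&
      any(!is.na(items$cloze) & (items$cloze < 0 | items$cloze > 1)))
    abort("ConfigError", "cloze must lie in [0, 1]")
  items
}

#' Enumerate within- and between-set item pairs
#'
#' All unordered cross-item pairs, labelled \code{within} when the two items
#' share a \code{set_id} (and therefore the third syllable) and
#' \code{between} otherwise. For the full design of 10 sets of 10 items this
#' yields 45 within-pairs per set, 450 within-pairs in total and 4,500
#' between-pairs.
#'
#' @param items validated stimulus data frame (see [validate_items()]).
#' @return a \code{pair_design} data frame with columns \code{item_a},
#'   \code{item_b}, \code{condition} (factor within/between); item ordering
#'   of the source table is kept in \code{attr(, "item_ids")}.
#' @examples
#' items <- generate_stimuli(sim_config(n_sets = 3, items_per_set = 3, seed = 1))
#' table(enumerate_pairs(items)$condition)
#' @export
enumerate_pairs <- function(items) {
  items <- validate_items(items)
  n <- nrow(items)
  if (n < 2L) {
    pairs <- data.frame(item_a = character(0), item_b = character(0),
                        condition = factor(character(0),
                                           levels = c("within", "between")))
  } else {
    idx <- utils::combn(n, 2L)
    pairs <- data.frame(
      item_a = items$item_id[idx[1, ]],
      item_b = items$item_id[idx[2, ]],
      condition = factor(
        ifelse(items$set_id[idx[1, ]] == items$set_id[idx[2, ]],
               "within", "between"),
        levels = c("within", "between"))
    )
  }
  structure(pairs, item_ids = items$item_id, class = c("pair_design", "data.frame"))
}

#' @export
print.pair_design <- function(x, ...) {
  cat(sprintf("Pair design: %d items, %d within-pairs, %d between-pairs\n",
              length(attr(x, "item_ids")),
              sum(x$condition == "within"), sum(x$condition == "between")))
  invisible(x)
}

#' Stimulus similarity matrix at a character position
#'
#' For \code{kind = "phonological"} the N x N matrix of pairwise
#' [syllable_similarity()] values at the given character position (the
#' design manipulates position 3). Orthographic and semantic similarities
#' are consumed as externally supplied matrices (\code{kind = "external"}
#' with a TSV path or matrix \code{source}): their published coding schemes
#' are not reimplemented here.
#'
#' @param items validated stimulus data frame.
#' @param position character position 1..4 (phonological kind only).
#' @param kind "phonological" or "external".
#' @param source for external matrices: a TSV path (square matrix with
#'   item_id header row and column) or a numeric matrix with dimnames.
#' @param weights passed to [syllable_similarity()].
#' @return a symmetric matrix with unit diagonal, dimnames = item ids.
#' @export
stimulus_similarity_matrix <- function(items, position = 3L,
                                       kind = c("phonological", "external"),
                                       source = NULL,
                                       weights = c(0.4, 0.4, 0.2)) {
  kind <- match.arg(kind)
  items <- validate_items(items)
  ids <- items$item_id
  if (kind == "external") {
    m <- if (is.character(source)) read_similarity_matrix(source) else source
    if (!is.matrix(m) || is.null(rownames(m)))
      abort("MissingEntryError", "external source must be a labelled matrix or TSV path")
    miss <- setdiff(ids, rownames(m))
    if (length(miss) || length(setdiff(ids, colnames(m))))
      abort("MissingEntryError",
            paste("external matrix lacks entries for:",
                  paste(utils::head(miss, 5L), collapse = ", ")))
    m <- m[ids, ids, drop = FALSE]
    return(m)
  }
  if (!position %in% 1:4)
    abort("ConfigError", "'position' must be 1, 2, 3 or 4")
  if (!is.numeric(weights) || length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    abort("WeightError", "'weights' must be 3 nonnegative numbers summing to 1")
  syl <- parse_syllable(items[[paste0("syl", position)]])
  same <- function(v) outer(v, v, "==")
  m <- weights[1] * same(syl$initial) + weights[2] * same(syl$final) +
       weights[3] * same(syl$tone)
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

#' @rdname stimulus_similarity_matrix
#' @param path TSV with an item_id header row and first column.
#' @export
read_similarity_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1L, check.names = FALSE,
                         fileEncoding = "UTF-8")
  as.matrix(d)
}

#' @rdname stimulus_similarity_matrix
#' @param m labelled similarity matrix.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.table(cbind(item_id = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Contrast pair-level stimulus similarity between conditions
#'
#' Welch two-sample t-test of the pair-level similarity values for
#' within-pairs against between-pairs; used to confirm that the target
#' position separates the conditions while the non-target positions are
#' matched.
#'
#' @param matrix similarity matrix over the design's items.
#' @param design a [enumerate_pairs()] result.
#' @return list with \code{mean_within}, \code{mean_between},
#'   \code{t_statistic}, \code{p_value}, \code{df}.
#' @export
compare_pair_similarity <- function(matrix, design) {
  v <- pair_values(matrix, design)
  w <- v[design$condition == "within"]
  b <- v[design$condition == "between"]
  if (length(w) < 2L || length(b) < 2L)
    abort("DegenerateConditionError",
          "need at least 2 pairs per condition for a t-test")
  if (stats::sd(w) < 1e-15 && stats::sd(b) < 1e-15) {
    # degenerate: constant conditions; t is 0 for equal means
    eq <- abs(mean(w) - mean(b)) < 1e-15
    return(list(mean_within = mean(w), mean_between = mean(b),
                t_statistic = if (eq) 0 else sign(mean(w) - mean(b)) * Inf,
                p_value = if (eq) 1 else 0, df = NA_real_))
  }
  tt <- stats::t.test(w, b, var.equal = FALSE)
  list(mean_within = mean(w), mean_between = mean(b),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

# Pair-level lookup of a labelled similarity matrix.
pair_values <- function(matrix, design) {
  miss <- setdiff(unique(c(design$item_a, design$item_b)), rownames(matrix))
  if (length(miss))
    abort("MissingEntryError",
          paste("similarity matrix lacks items:",
                paste(utils::head(miss, 5L), collapse = ", ")))
  matrix[cbind(design$item_a, design$item_b)]
}
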