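# Shared fixtures, built in code at test time.

# Reduced-dimension study configuration used for simulation-based checks:
# 12 participants, 4 sets x 4 items, a contiguous 16-channel sub-montage,
# 125 Hz. Effect structure and noise keep the full-scale defaults.
scaled_config <- function(seed, ...) {
  sim_config(n_participants = 12L, n_sets = 4L, items_per_set = 4L,
             n_channels = 16L, sampling_rate = 125, seed = seed, ...)
}

# Three toy items spanning the pairwise syllable relations: shared third
# syllable (a, b), tone-only difference (a vs c at position 1), unrelated.
toy_items <- function() {
  data.frame(
    item_id = c("a", "b", "c"),
    char1 = c("c1", "c2", "c3"), char2 = c("c4", "c5", "c6"),
    char3 = c("c7", "c8", "c9"), char4 = c("c10", "c11", "c12"),
    syl1 = c("ji1", "ma3", "ji2"),
    syl2 = c("wo3", "wo3", "han4"),
    syl3 = c("shi4", "shi4", "tou2"),
    syl4 = c("niao3", "lu4", "dao4"),
    set_id = c("s1", "s1", "s2"),
    stringsAsFactors = FALSE)
}

# Minimal epoch container around an explicit data array.
tiny_epochs <- function(data, sampling_rate = 250, t_start = -1400,
                        participants = NULL, item_ids = NULL) {
  d <- dim(data)
  time <- t_start + (seq_len(d[3]) - 1L) * 1000 / sampling_rate
  chan <- montage_layout(d[2])
  if (is.null(participants)) participants <- rep("p001", d[1])
  if (is.null(item_ids)) item_ids <- sprintf("item%03d", seq_len(d[1]))
  epoch_set(data, time, chan, data.frame(participant = participants,
                                         item_id = item_ids),
            sampling_rate)
}

# Synthetic similarity-timecourse object with given participant x condition
# x time values; used to exercise the inference layer directly.
fake_timecourse <- function(values, sampling_rate = 125, t_start = -1400) {
  parts <- sprintf("p%03d", seq_len(dim(values)[1]))
  dimnames(values) <- list(parts, c("within", "between"), NULL)
  structure(list(values = values, n_pairs = matrix(10L, dim(values)[1], 2L),
                 time = t_start + (seq_len(dim(values)[3]) - 1L) *
                   1000 / sampling_rate,
                 participants = parts, dropped = 0L,
                 grand = apply(values, c(2L, 3L), mean)),
            class = "similarity_timecourse")
}

# Synthetic topography object, participants x conditions x electrodes.
fake_topo <- function(values, labels) {
  parts <- sprintf("p%03d", seq_len(dim(values)[1]))
  dimnames(values) <- list(parts, c("within", "between"), labels)
  structure(list(values = values,
                 electrodes = montage_layout(length(labels)),
                 interval = c(-1100, 0),
                 n_pairs = matrix(10L, dim(values)[1], 2L), dropped = 0L,
                 participants = parts,
                 grand = apply(values, c(2L, 3L), mean)),
            class = "topo_similarity")
}
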