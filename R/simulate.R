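#' Simulation configuration
#'
#' Collects every parameter of the synthetic experiment. The defaults mirror
#' the study design the package targets: 29 participants, 100 items in 10
#' sets of 10, 62 channels at 250 Hz, 2,000-ms epochs from -1,400 to +600 ms
#' around idiom-final onset (baseline -1,400..-1,100, idiom-initial
#' -1,100..-500, interval -500..0, idiom-final 0..600), and a set-shared
#' spatial pattern whose envelope turns on 200 ms before idiom-final onset.
#'
#' @section Signal model:
#' \deqn{x_{p,i,c,t} = A\,e(t)\,w_{s(i),c} + B\,e(t)\,v_{p,i,c}
#'   + \epsilon_{p,i,c,t}}
#' where \eqn{w_s} (one unit-norm channel vector per set) is shared by all
#' items of a set across all participants, \eqn{v_{p,i}} is an
#' item-specific pattern idiosyncratic to each participant (a common item
#' pattern would put a stimulus-driven offset into every participant's
#' within-between difference, outside what participant-level inference
#' models), \eqn{e(t)} ramps linearly
#' from 0 at \code{effect_onset} to 1 at \code{effect_onset + effect_ramp},
#' and the noise is channel-wise AR(1) (coefficient \code{ar}, innovation sd
#' \code{innovation_sd}) plus white noise (\code{white_sd}), all in
#' microvolts. At envelope 1 the expected within-pair minus between-pair
#' channel-pattern correlation is approximately
#' \eqn{A^2 / (A^2 + B^2 + C\sigma^2)} with \eqn{C} the channel count and
#' \eqn{\sigma^2 = innovation\_sd^2/(1-ar^2) + white\_sd^2} the per-channel
#' noise variance.
#'
#' Amplitudes are free parameters of the generator, not estimates of any
#' real dataset; the defaults put the per-channel evoked signal near 6
#' microvolts against ~10 microvolts of single-trial noise, which yields
#' high power for the pre-onset tests at both full and reduced dimensions.
#'
#' @param n_participants,n_sets,items_per_set design counts.
#' @param n_channels,sampling_rate,epoch_span recording geometry; span in ms
#'   relative to idiom-final onset.
#' @param effect_onset,effect_ramp envelope onset and linear ramp length, ms.
#' @param shared_amplitude,item_amplitude microvolt scaling of the
#'   set-shared and item-specific patterns.
#' @param noise list with \code{ar} in \[0,1), \code{innovation_sd},
#'   \code{white_sd} (microvolts).
#' @param channel_layout coordinate data frame; \code{NULL} for the packaged
#'   montage (contiguous sub-layout when \code{n_channels < 62}).
#' @param effect_channels electrode labels carrying the patterns;
#'   \code{NULL} = all channels.
#' @param seed integer; mandatory for every stochastic step.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_participants = 29L, n_sets = 10L, items_per_set = 10L,
                       n_channels = 62L, sampling_rate = 250,
                       epoch_span = c(-1400, 600),
                       effect_onset = -200, effect_ramp = 100,
                       shared_amplitude = 45, item_amplitude = 15,
                       noise = list(ar = 0.5, innovation_sd = 8, white_sd = 4),
                       channel_layout = NULL, effect_channels = NULL,
                       seed = NULL) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_sets = as.integer(n_sets),
              items_per_set = as.integer(items_per_set),
              n_channels = as.integer(n_channels),
              sampling_rate = sampling_rate, epoch_span = epoch_span,
              effect_onset = effect_onset, effect_ramp = effect_ramp,
              shared_amplitude = shared_amplitude,
              item_amplitude = item_amplitude, noise = noise,
              channel_layout = channel_layout,
              effect_channels = effect_channels, seed = seed)
  if (any(c(cfg$n_participants, cfg$n_sets, cfg$items_per_set) < 1L))
    abort("ConfigError", "design counts must be positive")
  if (length(epoch_span) != 2L || epoch_span[1] >= epoch_span[2])
    abort("ConfigError", "epoch_span must be c(t_min, t_max), t_min < t_max")
  if (effect_onset < epoch_span[1] || effect_onset > epoch_span[2])
    abort("ConfigError", "effect_onset must lie within epoch_span")
  if (!is.list(noise) || is.null(noise$ar) || noise$ar < 0 || noise$ar >= 1)
    abort("ConfigError", "noise$ar must lie in [0, 1)")
  if (effect_ramp < 0) abort("ConfigError", "effect_ramp must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Uniform time grid for a config; includes t = 0 for the default span.
config_time <- function(config) {
  step <- 1000 / config$sampling_rate
  n <- round((config$epoch_span[2] - config$epoch_span[1]) / step)
  config$epoch_span[1] + (seq_len(n) - 1L) * step
}

# Per-sample envelope gain: 0 strictly before onset, linear ramp to 1.
effect_envelope <- function(config, time = config_time(config)) {
  if (config$effect_ramp == 0) return(as.numeric(time >= config$effect_onset))
  pmin(pmax((time - config$effect_onset) / config$effect_ramp, 0), 1)
}

# Toy pinyin inventory for synthetic stimuli.
.syllable_pool <- function() {
  ini <- c("b", "p", "m", "f", "d", "t", "n", "l", "g", "k", "h",
           "j", "q", "x", "zh", "ch", "sh", "r", "z", "c", "s", "y", "w")
  fin <- c("a", "o", "e", "i", "u", "ai", "ei", "ao", "ou", "an", "en",
           "ang", "eng", "ong", "in", "ing")
  as.vector(outer(as.vector(outer(ini, fin, paste0)), 1:4, paste0))
}

#' Generate synthetic set-structured stimuli
#'
#' Toy idiom items with the design's defining property: all items of a set
#' share the third syllable exactly (onset, rime and tone), while syllables
#' at positions 1, 2 and 4 are drawn from the toy pinyin inventory without
#' repetition within a set, so non-target positions are phonologically
#' matched between conditions. Cloze probabilities are drawn near 0.97,
#' emulating highly predictable idiom endings.
#'
#' @param config a [sim_config()] (uses the design counts and seed).
#' @return a validated stimulus data frame (see [validate_items()]).
#' @export
generate_stimuli <- function(config) {
  pool <- .syllable_pool()
  n_items <- config$n_sets * config$items_per_set
  if (n_items > length(pool) || config$items_per_set > length(pool) ||
      config$n_sets > length(pool))
    abort("ConfigError", "design larger than the toy syllable inventory")
  with_seed(sub_seed(config$seed, "stimuli"), {
    syl3 <- sample(pool, config$n_sets)
    draw_pos <- function() {
      as.vector(vapply(seq_len(config$n_sets),
                       function(s) sample(pool, config$items_per_set),
                       character(config$items_per_set)))
    }
    items <- data.frame(
      item_id = sprintf("item%03d", seq_len(n_items)),
      char1 = sprintf("c%03d", seq_len(n_items)),
      char2 = sprintf("c%03d", n_items + seq_len(n_items)),
      char3 = sprintf("c%03d", 2L * n_items + seq_len(n_items)),
      char4 = sprintf("c%03d", 3L * n_items + seq_len(n_items)),
      syl1 = draw_pos(), syl2 = draw_pos(),
      syl3 = rep(syl3, each = config$items_per_set),
      syl4 = draw_pos(),
      set_id = rep(sprintf("set%02d", seq_len(config$n_sets)),
                   each = config$items_per_set),
      cloze = round(stats::rbeta(n_items, 60, 2), 3),
      stringsAsFactors = FALSE)
    validate_items(items)
  })
}

# Unit-norm random channel pattern supported on `support` (channel indices).
unit_pattern <- function(n_channels, support) {
  v <- numeric(n_channels)
  g <- stats::rnorm(length(support))
  v[support] <- g / sqrt(sum(g^2))
  v
}

#' Generate a synthetic epoched-EEG dataset with known ground truth
#'
#' Simulates one trial per item per participant under the signal model
#' documented in [sim_config()]. Within-set item pairs share the set pattern
#' \eqn{w_s}, so their channel patterns correlate wherever the envelope is
#' on; before \code{effect_onset} the data are pure noise and within- and
#' between-pair correlations are equal in expectation.
#'
#' @param config a [sim_config()] with a seed.
#' @param items stimulus table from [generate_stimuli()] (or compatible);
#'   \code{NULL} to generate one from \code{config}.
#' @return list with \code{epochs} (an [epoch_set()]) and \code{truth}:
#'   \code{set_patterns} (sets x channels), \code{item_patterns}
#'   (participants x items x channels), \code{envelope}, effect channel
#'   labels and a config echo.
#' @export
generate_dataset <- function(config, items = NULL) {
  if (is.null(items)) items <- generate_stimuli(config)
  items <- validate_items(items)
  n_items <- nrow(items)
  layout <- if (is.null(config$channel_layout))
    montage_layout(config$n_channels) else config$channel_layout
  if (nrow(layout) != config$n_channels)
    abort("ConfigError", "channel_layout rows must equal n_channels")
  eff <- if (is.null(config$effect_channels)) layout$label
         else config$effect_channels
  support <- match(eff, layout$label)
  if (anyNA(support))
    abort("ConfigError", "effect_channels not all present in the layout")
  time <- config_time(config)
  env <- effect_envelope(config, time)
  sets <- unique(items$set_id)
  n_tr <- config$n_participants * n_items
  with_seed(sub_seed(config$seed, "dataset"), {
    W <- t(vapply(sets, function(s) unit_pattern(config$n_channels, support),
                  numeric(config$n_channels)))
    rownames(W) <- sets
    # Item patterns are participant-specific (idiosyncratic item responses).
    # A single item pattern common to all participants would add a
    # stimulus-driven offset to every participant's within-between
    # difference, which participant-level inference cannot absorb; the
    # set-shared pattern — the representational content of interest — is
    # common to all participants.
    V <- array(stats::rnorm(config$n_participants * n_items *
                              config$n_channels),
               c(config$n_participants, n_items, config$n_channels))
    V[, , -support] <- 0
    nrm <- sqrt(rowSums(V^2, dims = 2L))
    V <- V / as.vector(nrm)
    dimnames(V) <- list(NULL, items$item_id, NULL)
    # set-level deterministic signal component, channels x samples
    sig_set <- lapply(sets, function(s)
      outer(config$shared_amplitude * W[s, ], env))
    names(sig_set) <- sets
    data <- array(0, c(n_tr, config$n_channels, length(time)))
    trials <- data.frame(
      participant = rep(sprintf("p%03d", seq_len(config$n_participants)),
                        each = n_items),
      item_id = rep(items$item_id, config$n_participants),
      stringsAsFactors = FALSE)
    # AR(1) + white noise, vectorized over trials x channels per sample
    phi <- config$noise$ar
    isd <- config$noise$innovation_sd
    wsd <- config$noise$white_sd
    nc <- n_tr * config$n_channels
    e <- matrix(stats::rnorm(nc, sd = isd / sqrt(1 - phi^2)), n_tr)
    for (t in seq_along(time)) {
      data[, , t] <- e + matrix(stats::rnorm(nc, sd = wsd), n_tr)
      if (t < length(time))
        e <- phi * e + matrix(stats::rnorm(nc, sd = isd), n_tr)
    }
    item_of_trial <- match(trials$item_id, items$item_id)
    part_of_trial <- rep(seq_len(config$n_participants), each = n_items)
    for (tr in seq_len(n_tr)) {
      i <- item_of_trial[tr]
      data[tr, , ] <- data[tr, , ] + sig_set[[items$set_id[i]]] +
        outer(config$item_amplitude * V[part_of_trial[tr], i, ], env)
    }
    epochs <- epoch_set(data, time, layout, trials, config$sampling_rate,
                        log = sprintf("simulated (seed %s)", config$seed))
    truth <- list(set_patterns = W, item_patterns = V, envelope = env,
                  effect_channels = eff, config = config)
    list(epochs = epochs, truth = truth)
  })
}

#' Inject out-of-range artifact samples
#'
#' Marks an exact number of trials — \code{round(fraction * n_trials)},
#' sampled without replacement — with a single extreme sample of absolute
#' amplitude \code{magnitude} at a random channel/sample position, to
#' exercise amplitude-based rejection. The injected positions are recorded
#' in \code{attr(, "artifact_trials")}.
#'
#' @param epochs an [epoch_set()].
#' @param fraction proportion of trials to contaminate, in \[0, 1\].
#' @param magnitude absolute amplitude of the injected sample (microvolts);
#'   choose above the intended rejection threshold.
#' @param seed integer seed.
#' @return the modified [epoch_set()] with the injection record attached.
#' @export
inject_artifacts <- function(epochs, fraction, magnitude = 150, seed) {
  if (fraction < 0 || fraction > 1)
    abort("ConfigError", "'fraction' must lie in [0, 1]")
  n_tr <- dim(epochs$data)[1]
  k <- round(fraction * n_tr)
  if (k == 0L) {
    attr(epochs, "artifact_trials") <- integer(0)
    return(epochs)
  }
  with_seed(seed, {
    hit <- sort(sample.int(n_tr, k))
    ch <- sample.int(dim(epochs$data)[2], k, replace = TRUE)
    sm <- sample.int(dim(epochs$data)[3], k, replace = TRUE)
    sign <- sample(c(-1, 1), k, replace = TRUE)
    for (i in seq_len(k))
      epochs$data[hit[i], ch[i], sm[i]] <- sign[i] * magnitude
    epochs$log <- c(epochs$log,
                    sprintf("injected %d artifact trials (|%g| uV)", k, magnitude))
    attr(epochs, "artifact_trials") <- hit
    epochs
  })
}

#' Simulate a pair-level similarity table with known coefficients
#'
#' Generates the pair-level table the two-stage regression consumes directly
#' from a linear model with known ground-truth coefficients, bypassing the
#' EEG stage: per participant and pair,
#' \deqn{r = \beta_0 + u_p + \sum_k \beta_k z_k + \varepsilon,}
#' where \eqn{z_k} are the within-participant standardized phonological,
#' semantic and orthographic pair similarities, \eqn{u_p} a participant
#' intercept and \eqn{\varepsilon} Gaussian noise. Because the generator
#' works on the same standardized scale the model estimates, the recovery
#' target \eqn{\beta_k} is exact — the tool for calibrating and validating
#' the regression stage in isolation.
#'
#' @param items stimulus table; phonological similarity is computed from it
#'   at position 3.
#' @param beta named numeric: true coefficients for \code{phonological},
#'   \code{semantic}, \code{orthographic} (standardized-predictor scale).
#' @param intercept,participant_sd,noise_sd fixed intercept, sd of the
#'   participant intercepts, and residual sd (correlation units).
#' @param n_participants number of participants.
#' @param seed integer seed.
#' @return a pair-level data frame (see [build_pair_table()]) with the true
#'   coefficients in \code{attr(, "beta")}.
#' @export
simulate_pair_table <- function(items,
                                beta = c(phonological = 0.05, semantic = 0,
                                         orthographic = 0),
                                intercept = 0.05, participant_sd = 0.02,
                                noise_sd = 0.05, n_participants = 12L,
                                seed = NULL) {
  items <- validate_items(items)
  design <- enumerate_pairs(items)
  with_seed(seed, {
    phon <- pair_values(stimulus_similarity_matrix(items, 3L), design)
    n <- nrow(design)
    sem <- stats::runif(n)
    orth <- stats::runif(n)
    z <- function(v) (v - mean(v)) / stats::sd(v)
    mu <- beta[["phonological"]] * z(phon) + beta[["semantic"]] * z(sem) +
          beta[["orthographic"]] * z(orth)
    out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
      data.frame(participant = sprintf("p%03d", p),
                 item_a = design$item_a, item_b = design$item_b,
                 condition = design$condition,
                 neural_r = intercept + stats::rnorm(1, sd = participant_sd) +
                   mu + stats::rnorm(n, sd = noise_sd),
                 phonological = phon, semantic = sem, orthographic = orth,
                 stringsAsFactors = FALSE)
    }))
    attr(out, "beta") <- beta
    out
  })
}
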