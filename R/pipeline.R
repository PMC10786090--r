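#' Read and validate a run configuration
#'
#' YAML configuration for [run_pipeline()]. Top-level keys:
#' \describe{
#'   \item{seed}{integer; mandatory.}
#'   \item{out}{output directory.}
#'   \item{simulation}{arguments for [sim_config()] — used when no
#'     \code{epochs} directory is given.}
#'   \item{stimuli}{path to a stimulus TSV (optional with simulation).}
#'   \item{epochs}{path to an epoch container directory (optional).}
#'   \item{covariates}{named paths to semantic/orthographic matrix TSVs
#'     (optional; phonological similarity is always computed from the
#'     stimuli).}
#'   \item{analysis}{windows, span, interval, alpha, n_perm,
#'     reject_threshold, baseline_window, adjacency_threshold,
#'     subsample_between, write_epochs.}
#' }
#' Unknown keys raise a configuration error. All analysis defaults mirror
#' the target design: baseline -1,400..-1,100 ms, rejection at 120
#' microvolts, predictive window -200..0 ms, post-onset window 0..600 ms,
#' cluster span -1,100..0 ms, temporal interval -1,100..0 ms, alpha 0.05,
#' 1,000 permutations.
#'
#' @param path YAML file path.
#' @return a validated \code{run_config} list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

default_analysis <- function() {
  list(baseline_window = c(-1400, -1100), reject_threshold = 120,
       predictive_window = c(-200, 0), post_window = c(0, 600),
       cluster_span = c(-1100, 0), temporal_interval = c(-1100, 0),
       alpha = 0.05, n_perm = 1000, adjacency_threshold = NULL,
       subsample_between = TRUE, write_epochs = FALSE)
}

#' @rdname read_run_config
#' @param config a configuration list.
#' @export
validate_run_config <- function(config) {
  known <- c("seed", "out", "simulation", "stimuli", "epochs", "covariates",
             "analysis")
  extra <- setdiff(names(config), known)
  if (length(extra))
    abort("ConfigError",
          paste("unknown config keys:", paste(extra, collapse = ", ")))
  if (is.null(config$seed))
    abort("SeedError", "run config must set an integer 'seed'")
  if (is.null(config$out))
    abort("ConfigError", "run config must set an output directory 'out'")
  an <- default_analysis()
  bad <- setdiff(names(config$analysis), names(an))
  if (length(bad))
    abort("ConfigError",
          paste("unknown analysis keys:", paste(bad, collapse = ", ")))
  an[names(config$analysis)] <- config$analysis
  config$analysis <- an
  for (w in c("baseline_window", "predictive_window", "post_window",
              "cluster_span", "temporal_interval")) {
    v <- an[[w]]
    if (length(v) != 2L || !is.numeric(unlist(v)) ||
        unlist(v)[1] > unlist(v)[2])
      abort("ConfigError", sprintf("analysis$%s must be c(lo, hi)", w))
    config$analysis[[w]] <- as.numeric(unlist(v))
  }
  if (is.null(config$epochs) && is.null(config$simulation))
    abort("ConfigError", "config needs either 'epochs' or 'simulation'")
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulation (or loading) -> preprocessing -> spatial RSA
#' (timecourse, predictive-window and post-onset tests, pre-onset time
#' cluster permutation, optional matched-subsample control) -> temporal RSA
#' (topography, electrode cluster permutation) -> pair-level two-stage
#' regression (when covariates are available), writing every stage's
#' outputs plus a manifest and a human-readable summary to the output
#' directory. Each stochastic stage consumes a deterministic sub-seed
#' derived by hashing the master seed with the stage name, so identical
#' config + seed reproduces every output byte for byte.
#'
#' @param config a \code{run_config} list (see [read_run_config()]) or a
#'   YAML path.
#' @return a \code{pipeline_report} list with every stage result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  an <- config$analysis
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "stimuli"
    scfg <- if (!is.null(config$simulation))
      do.call(sim_config, c(config$simulation,
                            list(seed = sub_seed(config$seed, "simulate"))))
    items <- if (!is.null(config$stimuli)) read_stimuli(config$stimuli)
             else generate_stimuli(scfg)
    write_stimuli(items, file.path(out, "stimuli.tsv"))
    design <- enumerate_pairs(items)

    stage <- "epochs"
    if (!is.null(config$epochs)) {
      epochs <- read_epochs(config$epochs)
    } else {
      epochs <- generate_dataset(scfg, items)$epochs
    }
    if (isTRUE(an$write_epochs)) write_epochs(epochs, file.path(out, "epochs"))

    stage <- "preprocess"
    epochs <- baseline_correct(epochs, an$baseline_window)
    rej <- reject_amplitude(epochs, an$reject_threshold)
    write_rejection_report(rej, epochs, an$reject_threshold,
                           file.path(out, "rejection.json"))
    epochs <- rej$epochs

    stage <- "spatial_rsa"
    tc <- spatial_similarity_timecourse(epochs, design)
    write_timecourse_tsv(tc, file.path(out, "timecourse.tsv"))
    wt_pre <- window_test(tc, an$predictive_window)
    wt_post <- window_test(tc, an$post_window)
    cl_time <- cluster_permutation_time(
      tc, an$cluster_span, alpha_cluster = an$alpha, n_perm = an$n_perm,
      seed = sub_seed(config$seed, "cluster_time"))
    jsonlite::write_json(
      list(predictive = wt_pre[c("t", "p", "df", "window")],
           post_onset = wt_post[c("t", "p", "df", "window")]),
      file.path(out, "window_tests.json"), auto_unbox = TRUE, digits = NA)
    write_cluster_json(cl_time, file.path(out, "clusters_time.json"))
    sub <- NULL
    if (isTRUE(an$subsample_between)) {
      sub <- matched_subsample_test(epochs, design, an$predictive_window,
                                    seed = sub_seed(config$seed, "subsample"))
      jsonlite::write_json(sub[c("t", "p", "df", "window")],
                           file.path(out, "subsample_test.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    stage <- "temporal_rsa"
    topo <- temporal_similarity_map(epochs, design, an$temporal_interval)
    adjacency <- build_adjacency(epochs$channels, an$adjacency_threshold)
    cl_el <- cluster_permutation_electrodes(
      topo, adjacency, alpha_electrode = an$alpha, n_perm = an$n_perm,
      seed = sub_seed(config$seed, "cluster_electrodes"))
    write_topography_tsv(topo, file.path(out, "topography.tsv"))
    write_cluster_json(cl_el, file.path(out, "clusters_electrodes.json"))

    stage <- "trial_model"
    fit <- NULL
    covs <- list(phonological = stimulus_similarity_matrix(items, 3L))
    for (nm in names(config$covariates)) {
      src <- config$covariates[[nm]]
      if (is.character(src) && !file.exists(src))
        abort("MissingEntryError",
              sprintf("covariate file '%s' (%s) not found", src, nm))
      covs[[nm]] <- stimulus_similarity_matrix(items, kind = "external",
                                               source = src)
    }
    if (all(c("semantic", "orthographic") %in% names(covs))) {
      ptab <- build_pair_table(epochs, design, covs, an$predictive_window)
      write_pair_table(ptab, file.path(out, "pair_table.tsv"))
      fit <- two_stage_regression(ptab)
      jsonlite::write_json(list(group = fit$group,
                                coefficients = as.data.frame(fit$coefficients)),
                           file.path(out, "regression.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    stage <- "report"
    res <- list(items = items, design = design, epochs = epochs,
                rejected = rej$rejected, timecourse = tc,
                window_pre = wt_pre, window_post = wt_post,
                clusters_time = cl_time, subsample = sub,
                topography = topo, clusters_electrodes = cl_el,
                regression = fit, config = config)
    write_manifest(config, out)
    writeLines(pipeline_summary(res), file.path(out, "summary.txt"))
    class(res) <- "pipeline_report"
    invisible(res)
  }, phonrsa_error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, e$message)
    stop(e)
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(pipeline_summary(x), sep = "\n")
  invisible(x)
}

pipeline_summary <- function(res) {
  sig_t <- significant_clusters(res$clusters_time)
  sig_e <- significant_clusters(res$clusters_electrodes)
  c(sprintf("items: %d (%d sets); pairs: %d within / %d between",
            nrow(res$items), length(unique(res$items$set_id)),
            sum(res$design$condition == "within"),
            sum(res$design$condition == "between")),
    sprintf("trials rejected: %d", length(res$rejected)),
    sprintf("predictive window [%g, %g] ms: t = %.3f, p = %.4g",
            res$window_pre$window[1], res$window_pre$window[2],
            res$window_pre$t, res$window_pre$p),
    sprintf("post-onset window [%g, %g] ms: t = %.3f, p = %.4g",
            res$window_post$window[1], res$window_post$window[2],
            res$window_post$t, res$window_post$p),
    if (nrow(sig_t)) sprintf(
      "pre-onset time clusters (p <= 0.05): %s",
      paste(sprintf("[%g, %g] ms (mass %.1f, p %.3f)", sig_t$start,
                    sig_t$end, sig_t$mass, sig_t$p), collapse = "; "))
    else "pre-onset time clusters (p <= 0.05): none",
    if (!is.null(res$subsample)) sprintf(
      "matched-subsample control: t = %.3f, p = %.4g",
      res$subsample$t, res$subsample$p),
    if (nrow(sig_e)) sprintf(
      "electrode clusters (p <= 0.05): %s",
      paste(sprintf("{%s} (size %d, p %.3f)", sig_e$electrodes, sig_e$size,
                    sig_e$p), collapse = "; "))
    else "electrode clusters (p <= 0.05): none",
    if (!is.null(res$regression)) sprintf(
      "regression: %s",
      paste(sprintf("%s = %.4f (p %.3g)", res$regression$group$term,
                    res$regression$group$estimate, res$regression$group$p),
            collapse = ", ")))
}

write_timecourse_tsv <- function(tc, path) {
  d <- expand.grid(time = tc$time, condition = c("within", "between"),
                   participant = tc$participants, stringsAsFactors = FALSE)
  d$r <- as.vector(aperm(tc$values, c(3L, 2L, 1L)))
  utils::write.table(d[, c("participant", "condition", "time", "r")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_topography_tsv <- function(topo, path) {
  labs <- dimnames(topo$values)[[3]]
  d <- expand.grid(electrode = labs, condition = c("within", "between"),
                   participant = topo$participants, stringsAsFactors = FALSE)
  d$r <- as.vector(aperm(topo$values, c(3L, 2L, 1L)))
  utils::write.table(d[, c("participant", "condition", "electrode", "r")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_cluster_json <- function(cl, path) {
  jsonlite::write_json(
    list(clusters = as.data.frame(cl),
         statistic = attr(cl, "statistic"), n_perm = attr(cl, "n_perm"),
         seed = attr(cl, "seed"),
         null_quantiles = as.list(attr(cl, "null_quantiles"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_manifest <- function(config, out) {
  inputs <- Filter(Negate(is.null),
                   list(stimuli = config$stimuli,
                        semantic = config$covariates$semantic,
                        orthographic = config$covariates$orthographic))
  digests <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(list(
    package = "phonrsa",
    version = as.character(utils::packageVersion("phonrsa")),
    seed = config$seed,
    sub_seeds = list(simulate = sub_seed(config$seed, "simulate"),
                     cluster_time = sub_seed(config$seed, "cluster_time"),
                     subsample = sub_seed(config$seed, "subsample"),
                     cluster_electrodes = sub_seed(config$seed,
                                                   "cluster_electrodes")),
    analysis = config$analysis,
    simulation = config$simulation,
    input_digests = digests
  ), file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
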