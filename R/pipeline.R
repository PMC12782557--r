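#' End-to-end analysis pipeline
#'
#' Orchestrates simulate -> learner -> pupil synthesis -> preprocessing ->
#' epochs -> window summaries -> correlation time courses -> cluster
#' statistics -> window ANOVA -> mixed-model comparison on a validated
#' configuration. Every source of randomness derives from the seeds in the
#' configuration, so reruns are bit-identical.
#' @name pipeline
NULL

#' Build and validate an analysis configuration
#'
#' @param task "cue_target" or "lettercolor".
#' @param nSubjects number of simulated participants.
#' @param nTrials trials per participant (task default if NULL).
#' @param seed master seed; per-subject seeds derive from it.
#' @param betas planted pupil loadings (see \code{\link{synthesizePupil}}).
#' @param fs sampling rate of the synthetic recordings (Hz).
#' @param baseline,early,late analysis windows (s, half-open).
#' @param band,filterOrder band-pass parameters.
#' @param derivThreshold,pad_s artifact handling parameters; the default
#'   threshold resolves to a 5000 units/s rate of change (10 units per
#'   sample at a 500 Hz device rate) expressed per sample at \code{fs}.
#' @param nPerm,clusterAlpha,q cluster/FDR parameters.
#' @param amplitudeNoiseSd,sampleNoiseSd,blinkRatePerMin noise injection.
#' @param nFolds mixed-model cross-validation folds.
#' @return validated config list (class "pupilinfo_config").
#' @export
analysisConfig <- function(task = c("cue_target", "lettercolor"),
                           nSubjects = 24, nTrials = NULL, seed = 1,
                           betas = list(beta0 = 2, betaDKL = 50),
                           fs = 50,
                           baseline = c(-0.5, 0),
                           early = c(0.75, 1.25), late = c(2.5, 3.0),
                           band = c(0.01, 6), filterOrder = 3,
                           derivThreshold = NULL, pad_s = 0.15,
                           nPerm = 1000, clusterAlpha = 0.05, q = 0.05,
                           amplitudeNoiseSd = 1, sampleNoiseSd = 0,
                           blinkRatePerMin = 0, nFolds = 10) {
  task <- match.arg(task)
  if (is.null(nTrials))
    nTrials <- switch(task, cue_target = 200L, lettercolor = 250L)
  # "units per sample" scales with fs: 10 units/sample is a 500 Hz
  # convention, i.e. a 5000 units/s rate of change
  if (is.null(derivThreshold)) derivThreshold <- 10 * 500 / fs
  cfg <- list(task = task, nSubjects = nSubjects, nTrials = nTrials,
              seed = seed, betas = betas, fs = fs, baseline = baseline,
              early = early, late = late, band = band,
              filterOrder = filterOrder, derivThreshold = derivThreshold,
              pad_s = pad_s, nPerm = nPerm, clusterAlpha = clusterAlpha,
              q = q, amplitudeNoiseSd = amplitudeNoiseSd,
              sampleNoiseSd = sampleNoiseSd,
              blinkRatePerMin = blinkRatePerMin, nFolds = nFolds)
  validateConfig(cfg)
  class(cfg) <- "pupilinfo_config"
  cfg
}

#' Validate an analysis configuration
#' @param cfg config list.
#' @return invisibly TRUE; stops with a schema error otherwise.
#' @export
validateConfig <- function(cfg) {
  err <- function(...) stop("schema error: ", ...)
  for (w in list(cfg$baseline, cfg$early, cfg$late))
    if (length(w) != 2 || w[1] >= w[2]) err("windows must be c(lo, hi)")
  if (cfg$early[2] > cfg$late[1] && cfg$late[2] > cfg$early[1])
    err("early and late windows overlap")
  if (cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2])
    err("invalid band edges")
  if (cfg$band[2] >= cfg$fs / 2) err("band high edge must be < Nyquist")
  if (cfg$nSubjects < 2) err("need >= 2 subjects")
  if (cfg$nTrials < 10) err("need >= 10 trials")
  if (cfg$nPerm < 100) err("nPerm must be >= 100")
  invisible(TRUE)
}

simulate_subject <- function(cfg, subj) {
  seed_s <- cfg$seed * 10000L + subj
  if (cfg$task == "cue_target") {
    trials <- genCueTargetSequence(
      cfg$nTrials,
      mapping = if (subj %% 2 == 1) "condition1" else "condition2",
      seed = seed_s)
    trials <- simulateBehavior(trials, "probability_matching",
                               seed = seed_s + 1L)
    info <- runLearner(trials$event, uniformPrior(4))
  } else {
    ob <- genOddballSequence(seed = seed_s)
    prior <- oddballPrior(ob$trials$event, ob$trials$is_oddball, K = 36)
    trials <- genLettercolorSequence(ob$assignment, cfg$nTrials,
                                     seed = seed_s + 2L)
    trials <- simulateBehavior(trials, "fixed_accuracy", p = 0.8,
                               seed = seed_s + 1L)
    names(trials)[names(trials) == "condition"] <- "frequency"
    info <- runLearner(trials$event, prior)
  }
  cbind(trials[setdiff(names(trials), c("event", "trial"))], info,
        subject = subj)
}

process_subject <- function(cfg, tab) {
  syn <- synthesizePupil(tab, betas = cfg$betas, fs = cfg$fs,
                         amplitudeNoiseSd = cfg$amplitudeNoiseSd,
                         sampleNoiseSd = cfg$sampleNoiseSd,
                         blinkRatePerMin = cfg$blinkRatePerMin,
                         seed = cfg$seed * 10000L + tab$subject[1] + 5000L)
  pre <- preprocessPupil(syn$recording, syn$annotations,
                         derivThreshold = cfg$derivThreshold,
                         pad_s = cfg$pad_s, band = cfg$band,
                         filterOrder = cfg$filterOrder)
  ep <- extractEpochs(pre$recording, syn$onsets_s,
                      window = c(cfg$baseline[1], cfg$late[2]),
                      labels = tab)
  bw <- baselineAndWindow(ep, baseline = cfg$baseline,
                          windows = list(early = cfg$early,
                                         late = cfg$late))
  bw
}

#' Run the full pipeline
#'
#' @param config from \code{\link{analysisConfig}}.
#' @return result bundle (class "pupilinfo_bundle"): \code{trialTable}
#'   (per-trial model variables and window means), \code{epochs} (pooled
#'   baseline-corrected \linkS4class{EpochSet}), \code{corr} (list of
#'   \linkS4class{CorrTimecourse} per variable), \code{clusters} (list of
#'   cluster-test results), \code{anova} (early-window frequency x
#'   accuracy ANOVA, when estimable), \code{hlm} (Model 1 vs Model 2
#'   comparison on the early window), \code{config}, \code{meta}.
#' @export
runPipeline <- function(config) {
  validateConfig(config)
  cfg <- config
  subj_tabs <- lapply(seq_len(cfg$nSubjects),
                      function(s) simulate_subject(cfg, s))
  bws <- lapply(subj_tabs, function(tab) process_subject(cfg, tab))
  time_axis <- epochTime(bws[[1]]$epochs)
  data <- do.call(rbind, lapply(bws, function(b) epochData(b$epochs)))
  labels <- do.call(rbind, lapply(bws, function(b) epochLabels(b$epochs)))
  baselines <- unlist(lapply(bws, function(b) epochBaselines(b$epochs)))
  epochs <- new("EpochSet", data = data, time = time_axis,
                baselines = baselines, labels = labels)
  trialTable <- do.call(rbind, lapply(bws, `[[`, "table"))
  names(trialTable)[names(trialTable) == "early"] <- "early"
  # restrict cluster statistics to the post-feedback interval
  post <- time_axis >= 0
  corr <- clusters <- list()
  for (v in c("I", "H", "DKL")) {
    tc <- correlationTimecourse(epochs, v)
    corr[[v]] <- tc
    z <- fisherZ(tc)
    clusters[[v]] <- clusterPermutationTest(
      z[, post, drop = FALSE], nPerm = cfg$nPerm,
      clusterAlpha = cfg$clusterAlpha, seed = cfg$seed,
      time = time_axis[post])
  }
  anova_res <- tryCatch({
    long <- data.frame(subject = trialTable$subject,
                       value = trialTable$early,
                       frequency = trialTable$frequency,
                       accuracy = factor(trialTable$accuracy))
    windowFactorialAnova(long, c("frequency", "accuracy"))
  }, error = function(e) NULL)
  hlm_tab <- data.frame(pupil = trialTable$early, I = trialTable$I,
                        H = trialTable$H, DKL = trialTable$DKL,
                        baseline = trialTable$baseline,
                        rt = trialTable$rt,
                        subject = trialTable$subject)
  hlm <- fitAndCompareHlm(hlm_tab, nFolds = cfg$nFolds, seed = cfg$seed)
  bundle <- list(trialTable = trialTable, epochs = epochs, corr = corr,
                 clusters = clusters, anova = anova_res, hlm = hlm,
                 config = cfg,
                 meta = list(seed = cfg$seed, version = as.character(
                   utils::packageVersion("pupilinfo")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  class(bundle) <- "pupilinfo_bundle"
  bundle
}

#' Write a result bundle to disk
#'
#' Writes the trial table, correlation time courses and cluster tables as
#' TSV, the ANOVA and model-comparison results as JSON, and a plain-text
#' summary naming the resolved seed.
#'
#' @param bundle from \code{\link{runPipeline}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeReport <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(outDir, "trial_table.tsv")
  write_tsv(bundle$trialTable, p); paths <- c(paths, p)
  ct <- do.call(rbind, lapply(names(bundle$corr), function(v) {
    g <- groupAverageFisher(bundle$corr[[v]])
    cbind(variable = v, subset = bundle$corr[[v]]@subset, g)
  }))
  p <- file.path(outDir, "corr_timecourse.tsv")
  write_tsv(ct, p); paths <- c(paths, p)
  cl <- do.call(rbind, lapply(names(bundle$clusters), function(v) {
    d <- bundle$clusters[[v]]$clusters
    if (!nrow(d)) return(NULL)
    cbind(variable = v, d)
  }))
  p <- file.path(outDir, "clusters.tsv")
  write_tsv(if (is.null(cl)) data.frame(variable = character(),
                                        start_s = numeric(),
                                        end_s = numeric(),
                                        mass = numeric(),
                                        p_value = numeric()) else cl, p)
  paths <- c(paths, p)
  if (!is.null(bundle$anova)) {
    p <- file.path(outDir, "anova.json")
    jsonlite::write_json(bundle$anova$effects, p, digits = NA)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "hlm.json")
  jsonlite::write_json(list(
    model1 = list(coefficients = bundle$hlm$model1$coefficients,
                  elpd = bundle$hlm$model1$elpd),
    model2 = list(coefficients = bundle$hlm$model2$coefficients,
                  elpd = bundle$hlm$model2$elpd),
    dElpd = bundle$hlm$dElpd, se = bundle$hlm$se,
    ratio = bundle$hlm$ratio, preferred = bundle$hlm$preferred),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  sig <- if (is.null(cl)) data.frame() else cl[cl$p_value < 0.05, ]
  summary_lines <- c(
    sprintf("pupilinfo run (seed %d, task %s, %d subjects x %d trials)",
            bundle$meta$seed, bundle$config$task, bundle$config$nSubjects,
            bundle$config$nTrials),
    sprintf("config hash: %08x", {
      s <- utf8ToInt(paste(unlist(bundle$config), collapse = "|"))
      sum(s * seq_along(s)) %% 2147483647
    }),
    if (nrow(sig) == 0) "no significant clusters" else
      sprintf("significant cluster: %s [%.2f, %.2f] s (p = %.4f)",
              sig$variable, sig$start_s, sig$end_s, sig$p_value),
    sprintf("model comparison: preferred Model %d (|dELPD|/SE = %.2f)",
            bundle$hlm$preferred, bundle$hlm$ratio))
  p <- file.path(outDir, "summary.txt")
  writeLines(summary_lines, p); paths <- c(paths, p)
  invisible(paths)
}
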