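#' Pipeline configuration
#'
#' Builds and validates the configuration driving [runPipeline()]. Defaults
#' are desk-scale: they exercise every stage end-to-end on synthetic data in
#' minutes. `stages` toggles individual stages; a stage whose upstream inputs
#' are disabled fails validation. A configuration can also be read from a
#' YAML file (`pipelineConfigFromYAML`), where it is validated the same way.
#'
#' @param seed master seed; every stage derives its own substream from it.
#' @param ... overrides of the default fields (see the returned list).
#' @return validated config list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, behavior = TRUE, ddm = TRUE, tfr = TRUE,
                  permtest = TRUE, source = TRUE, connectivity = TRUE,
                  regress = TRUE),
    nSubjects = 8L,
    trialsPerCondition = 60L,
    outlierK = 2,
    ddm = list(minTrials = 15L, restarts = 2L, dt = 1e-3),
    neural = list(sfreq = 128, epochWindow = c(-1, 1), nTrialsPerCond = 20L,
                  band = "beta", order = 2L,
                  couplingGainRange = c(0.25, 0.55), sensorNoiseSd = 0.05,
                  erGain = 0.8),
    tfr = list(freqs = seq(4, 30, by = 2), width = 5.5, gaussLen = 3,
               baseline = c(-0.2, 0)),
    permtest = list(nPerm = 200L, alpha = 0.05),
    source = list(nVoxels = 64L, nChannels = 24L, reg = 0.05, pct = 10,
                  eps = 1.5, minPts = 2L, window = c(-0.5, 1)),
    connectivity = list(p = 2L, hiddenUnits = 8L, maxit = 150L,
                        restarts = 1L, decay = 1e-3),
    regress = list(folds = 5L, hiddenUnits = 4L, decay = 0.05)
  )
  cfg <- modifyList(cfg, list(...))
  validatePipelineConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with config fields.
#' @export
pipelineConfigFromYAML <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

validatePipelineConfig <- function(cfg) {
  st <- cfg$stages
  need <- list(behavior = "simulate", ddm = "behavior", tfr = "simulate",
               permtest = "tfr", source = "tfr",
               connectivity = "source", regress = c("connectivity", "ddm"))
  for (stage in names(need)) {
    if (isTRUE(st[[stage]]) && !all(unlist(st[need[[stage]]])))
      stop(sprintf("stage '%s' requires stage(s) %s", stage,
                   paste(need[[stage]], collapse = ", ")))
  }
  stopifnot(cfg$nSubjects >= 2, cfg$trialsPerCondition >= 1,
            cfg$regress$folds >= 2, cfg$source$eps > 0,
            cfg$neural$sfreq >= 2 * max(cfg$tfr$freqs))
  if (isTRUE(st$regress) && cfg$nSubjects < cfg$regress$folds)
    stop("regress stage needs nSubjects >= folds")
  invisible(cfg)
}

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic working-memory gating analysis
#'
#' Executes simulate -> behavior -> ddm -> tfr -> permtest -> source ->
#' connectivity -> regress on synthetic data with known ground truth and
#' writes every artifact (TSV with a provenance header carrying the config
#' hash and seed; JSON reports) into `outDir`. Deterministic: the same config
#' and seed produce byte-identical TSV outputs.
#'
#' The synthetic cohort couples the decision threshold to the neural arm:
#' each subject has a coupling gain that both scales the directed source
#' coupling (hence the estimated connectivity) and their boundary-separation
#' parameters, while the drift rate varies independently - so the final
#' regression stage should predict a better than v.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  hdr <- c(sprintf("config_hash: %s", hash),
           sprintf("seed: %d", config$seed))
  res <- list(configHash = hash)
  st <- config$stages
  timing <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # per-subject ground truth: coupling gain drives both the neural coupling
  # and the boundary separation; drift rate is independent noise
  set.seed(childSeed(config$seed, 1L))
  gr <- config$neural$couplingGainRange
  gain <- runif(config$nSubjects, gr[1], gr[2])
  vSubj <- rnorm(config$nSubjects, 0.05, 0.15)
  aScale <- 0.85 + 0.5 * (gain - mean(gr)) / diff(gr)

  if (isTRUE(st$simulate)) {
    t0 <- tic()
    trials <- do.call(rbind, lapply(seq_len(config$nSubjects), function(s) {
      base <- cohortSpec(1, config$trialsPerCondition, seed = 1)$ddmParamsByCondition
      pars <- lapply(base, function(p)
        ddmParams(a = p$a * aScale[s], v = vSubj[s], t0 = p$t0))
      tr <- genBehavior(cohortSpec(1, config$trialsPerCondition,
                                   ddmParamsByCondition = pars,
                                   seed = childSeed(config$seed, 2L, s)),
                        dt = config$ddm$dt)
      tr$subject <- sprintf("sub%03d", s)
      tr
    }))
    writeTrials(trials, file.path(outDir, "trials.tsv"), header = hdr)
    res$trials <- trials
    timing$simulate <- lap(t0)
  }

  if (isTRUE(st$behavior)) {
    t0 <- tic()
    filtered <- filterOutliers(res$trials, k = config$outlierK)
    summary <- summarizeConditions(filtered)
    wide <- matrix(summary$mean_rt_s[order(summary$subject,
                                           summary$trial_type,
                                           summary$switching)],
                   nrow = config$nSubjects, byrow = TRUE)
    # columns: expand.grid(switching, trial_type) order after the sort above:
    # (nonswitch, switch) x (comparison, reference)
    anova <- rmAnova(wide, c("Switching", "TrialType"))
    cellMeans <- vapply(GATING_CONDITIONS, function(cc)
      mean(summary$mean_rt_s[summary$condition == cc], na.rm = TRUE),
      numeric(1))
    gating <- gatingContrast(cellMeans, measure = "mean_rt_s")
    writeTSV(summary, file.path(outDir, "condition_summary.tsv"), hdr)
    writeTSV(anova, file.path(outDir, "behavior_anova.tsv"), hdr)
    writeReport(list(config_hash = hash, gating = gating,
                     excluded = attr(filtered, "subjectFlags")$subject[
                       attr(filtered, "subjectFlags")$excluded]),
                file.path(outDir, "gating.json"))
    res$behavior <- list(summary = summary, anova = anova, gating = gating,
                         filtered = filtered)
    timing$behavior <- lap(t0)
  }

  if (isTRUE(st$ddm)) {
    t0 <- tic()
    fits <- fitDDM(res$behavior$filtered,
                   nRestarts = config$ddm$restarts,
                   seed = childSeed(config$seed, 3L),
                   minTrials = config$ddm$minTrials)
    writeTSV(fits, file.path(outDir, "ddm_fits.tsv"), hdr)
    res$ddm <- fits
    timing$ddm <- lap(t0)
  }

  neuralNeeded <- isTRUE(st$tfr) || isTRUE(st$source)
  if (neuralNeeded) {
    t0 <- tic()
    lf <- makeLeadfield(config$source$nVoxels, config$source$nChannels,
                        seed = childSeed(config$seed, 4L))
    vox <- voxelPositions(lf)
    # two planted sources at well-separated voxels
    srcVox <- c(which.min(rowSums((vox - matrix(apply(vox, 2, min),
                  nrow(vox), 3, byrow = TRUE))^2)),
                which.min(rowSums((vox - matrix(apply(vox, 2, max),
                  nrow(vox), 3, byrow = TRUE))^2)))
    nT <- round(diff(config$neural$epochWindow) * config$neural$sfreq) + 1
    subjEpochs <- lapply(seq_len(config$nSubjects), function(s) {
      cs <- function(g) couplingSpec(
        M = 2, p = config$neural$order,
        linearCoeffs = list(matrix(c(0.5, g, 0, 0.5), 2, 2),
                            matrix(c(-0.2, 0, 0, -0.2), 2, 2)),
        noiseSd = 1, band = config$neural$band)
      mkEp <- function(g, cond, off, er = 0) {
        src <- genCoupledSources(cs(g), config$neural$nTrialsPerCond, nT,
                                 seed = childSeed(config$seed, 5L, s, off),
                                 sfreq = config$neural$sfreq)
        if (er > 0) {
          # event-related amplitude increase after stimulus onset
          onset <- (nT + 1L) %/% 2L
          src$data[, onset:nT, ] <- src$data[, onset:nT, ] * (1 + er)
        }
        genSensorEpochs(src$data, lf, srcVox,
                        sensorNoiseSd = config$neural$sensorNoiseSd,
                        sfreq = config$neural$sfreq,
                        conditions = rep(cond, config$neural$nTrialsPerCond),
                        seed = childSeed(config$seed, 6L, s, off))
      }
      # switch trials carry the subject's directed coupling plus an
      # event-related power increase; nonswitch trials carry neither
      list(switch = mkEp(gain[s], "switch-reference", 1L,
                         er = config$neural$erGain),
           nonswitch = mkEp(0, "nonswitch-reference", 2L))
    })
    res$leadfield <- lf
    res$sourceVoxels <- srcVox
    timing$neural_sim <- lap(t0)
  }

  if (isTRUE(st$tfr)) {
    t0 <- tic()
    band <- config$neural$band
    maps <- lapply(subjEpochs, function(ep) {
      tfS <- dbBaseline(morletTFR(ep$switch, freqs = config$tfr$freqs,
                                  width = config$tfr$width,
                                  gaussLen = config$tfr$gaussLen),
                        window = config$tfr$baseline)
      tfN <- dbBaseline(morletTFR(ep$nonswitch, freqs = config$tfr$freqs,
                                  width = config$tfr$width,
                                  gaussLen = config$tfr$gaussLen),
                        window = config$tfr$baseline)
      list(S = bandAverage(tfS, band, condition = "switch-reference"),
           N = bandAverage(tfN, band, condition = "nonswitch-reference"))
    })
    res$bandMaps <- maps
    timing$tfr <- lap(t0)
  }

  if (isTRUE(st$permtest)) {
    t0 <- tic()
    nC <- config$source$nChannels
    # common unmasked time support across subjects
    okT <- Reduce(`&`, lapply(res$bandMaps, function(m)
      !apply(is.na(m$S) | is.na(m$N), 2, any)))
    condA <- aperm(simplify2array(lapply(res$bandMaps, function(m)
      m$S[, okT])), c(3, 1, 2))
    condB <- aperm(simplify2array(lapply(res$bandMaps, function(m)
      m$N[, okT])), c(3, 1, 2))
    adj <- channelAdjacency(channelPositions(res$leadfield))
    ct <- clusterPermTest(condA, condB, adj, nPerm = config$permtest$nPerm,
                          alpha = config$permtest$alpha,
                          seed = childSeed(config$seed, 7L))
    writeReport(list(config_hash = hash,
                     n_clusters = length(ct$clusters),
                     min_p = ct$p,
                     clusters = lapply(ct$clusters, function(cl)
                       list(stat = cl$stat, p = cl$p,
                            polarity = cl$polarity,
                            n_points = nrow(cl$points)))),
                file.path(outDir, "permtest.json"))
    res$permtest <- ct
    timing$permtest <- lap(t0)
  }

  if (isTRUE(st$source)) {
    t0 <- tic()
    subjSources <- lapply(seq_len(config$nSubjects), function(s) {
      ep <- subjEpochs[[s]]
      all <- EpochArray(
        array(c(epochData(ep$switch), epochData(ep$nonswitch)),
              dim = dim(epochData(ep$switch)) + c(0, 0,
                    dim(epochData(ep$nonswitch))[3])),
        sfreq = samplingRate(ep$switch), times = epochTimes(ep$switch),
        channelNames = channelNames(ep$switch),
        channelPositions = channelPositions(ep$switch),
        conditions = c(conditionLabels(ep$switch),
                       conditionLabels(ep$nonswitch)))
      filt <- lcmvCommonFilter(all, res$leadfield, reg = config$source$reg)
      list(S = reconstructSources(filt, ep$switch),
           N = reconstructSources(filt, ep$nonswitch),
           times = epochTimes(ep$switch))
    })
    effect <- rowMeans(vapply(subjSources, function(x)
      sourceGatingContrast(x$S, x$N), numeric(config$source$nVoxels)))
    sel <- selectTopVoxels(effect, pct = config$source$pct)
    db <- dbscanCluster(voxelPositions(res$leadfield)[sel, , drop = FALSE],
                        eps = config$source$eps, minPts = config$source$minPts)
    clusterVox <- lapply(seq_len(nrow(db$clusters)), function(k)
      sel[db$assignment == db$clusters$cluster_id[k]])
    writeTSV(db$clusters, file.path(outDir, "source_clusters.tsv"), hdr)
    res$source <- list(effect = effect, selected = sel, clusters = db,
                       clusterVox = clusterVox, subjSources = subjSources)
    timing$source <- lap(t0)
  }

  if (isTRUE(st$connectivity)) {
    t0 <- tic()
    cv <- res$source$clusterVox
    if (length(cv) < 2)
      stop("connectivity stage needs >= 2 source clusters")
    conns <- lapply(seq_len(config$nSubjects), function(s) {
      ss <- res$source$subjSources[[s]]
      nsMean <- apply(ss$N, c(1, 2), mean)
      sigs <- extractClusterSignals(ss$S, cv, nsMean, ss$times,
                                    window = config$source$window)
      trialsTs <- lapply(seq_len(ncol(sigs[[1]]$data)), function(tr)
        t(vapply(sigs, function(sg) sg$data[, tr],
                 numeric(nrow(sigs[[1]]$data)))))
      cm <- estimateConnectivity(trialsTs, p = config$connectivity$p,
                                 hiddenUnits = config$connectivity$hiddenUnits,
                                 decay = config$connectivity$decay,
                                 maxit = config$connectivity$maxit,
                                 restarts = config$connectivity$restarts,
                                 seed = childSeed(config$seed, 8L, s),
                                 band = config$neural$band,
                                 process = "opening")
      normalizeConnectivity(list(cm))[[1]]
    })
    tab <- do.call(rbind, lapply(seq_along(conns), function(s) {
      cm <- conns[[s]]
      M <- nrow(linC(cm))
      idx <- which(row(linC(cm)) != col(linC(cm)))
      data.frame(subject = sprintf("sub%03d", s),
                 source = row(linC(cm))[idx], target = col(linC(cm))[idx],
                 lC = linC(cm)[idx], NC = nonlinC(cm)[idx],
                 band = cm@band, process = cm@process,
                 normalized = isNormalized(cm))
    }))
    writeTSV(tab, file.path(outDir, "connectivity.tsv"), hdr)
    res$connectivity <- conns
    timing$connectivity <- lap(t0)
  }

  if (isTRUE(st$regress)) {
    t0 <- tic()
    X <- t(vapply(res$connectivity, function(cm)
      unlist(averageNonself(cm)), numeric(2)))
    aHat <- vapply(split(res$ddm$a, res$ddm$subject), mean, numeric(1),
                   na.rm = TRUE)
    vHat <- vapply(split(res$ddm$v, res$ddm$subject), mean, numeric(1),
                   na.rm = TRUE)
    regA <- fitPredictCV(X, aHat, hiddenUnits = config$regress$hiddenUnits,
                         folds = config$regress$folds,
                         decay = config$regress$decay,
                         seed = childSeed(config$seed, 9L), target = "a",
                         band = config$neural$band, process = "opening")
    regV <- fitPredictCV(X, vHat, hiddenUnits = config$regress$hiddenUnits,
                         folds = config$regress$folds,
                         decay = config$regress$decay,
                         seed = childSeed(config$seed, 9L), target = "v",
                         band = config$neural$band, process = "opening")
    writeReport(list(config_hash = hash, a = regA, v = regV),
                file.path(outDir, "regression.json"))
    res$regress <- list(a = regA, v = regV)
    timing$regress <- lap(t0)
  }

  writeReport(list(config_hash = hash, seed = config$seed,
                   timing_s = timing),
              file.path(outDir, "pipeline.json"))
  res$timing <- timing
  invisible(res)
}

writeTSV <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
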