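# Desk-scale benchmark harness and the resumable end-to-end pipeline.

#' Construct a benchmark specification
#'
#' Defaults define the package's standard phantom benchmark: 60 training and
#' 15 test phantoms (64 x 64, annotation jitter 1.5 px), depth-3 base U-Nets
#' with 8 base filters, ensemble size 5 with the \{0.1, ..., 1.0\} lambda
#' grid, 20 training epochs, 5 repeats with distinct master seeds. The
#' training configuration uses Adam with learning rate 5e-3 and batch size 8
#' -- scaled to the benchmark's roughly 150 optimizer steps (see the methods
#' vignette).
#'
#' @param phantomConfig phantom generator settings.
#' @param nTrain,nTest dataset sizes.
#' @param KValues ensemble sizes to report (nested subsets of one trained
#'   ensemble of size max(KValues), mirroring an ensemble-size study that
#'   trains the base models once).
#' @param repeats repeated trainings; masterSeeds must have this length.
#' @param masterSeeds one seed per repeat.
#' @param methods subset of "saen" (supervision-augmented ensemble),
#'   "rwi" (random-weight-initialization ensemble), "single" (one fully
#'   supervised model).
#' @param unetConfig base-learner architecture.
#' @param oracleConfig Bayesian oracle architecture (dropout > 0).
#' @param trainConfig optimization settings.
#' @param mcSamples Monte-Carlo samples T for uncertainty estimation.
#' @param lambdaGrid candidate thresholds.
#' @return A [BenchmarkSpec-class].
#' @export
benchmarkSpec <- function(phantomConfig = saen::phantomConfig(),
                          nTrain = 60L, nTest = 15L, KValues = c(1L, 3L, 5L),
                          repeats = 5L,
                          masterSeeds = 100L + seq_len(repeats),
                          methods = c("saen", "single"),
                          unetConfig = saen::unetConfig(
                            inChannels = phantomConfig@nChannels),
                          oracleConfig = bayesianUnetConfig(
                            inChannels = phantomConfig@nChannels),
                          trainConfig = saen::trainConfig(
                            learningRate = 5e-3, batchSize = 8L,
                            epochs = 20L),
                          mcSamples = 20L,
                          lambdaGrid = seq(0.1, 1, by = 0.1)) {
  new("BenchmarkSpec", phantomConfig = phantomConfig,
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      KValues = as.integer(sort(KValues)), repeats = as.integer(repeats),
      masterSeeds = as.integer(masterSeeds), methods = methods,
      unetConfig = unetConfig, oracleConfig = oracleConfig,
      trainConfig = trainConfig, mcSamples = as.integer(mcSamples),
      lambdaGrid = as.numeric(lambdaGrid))
}

.predictMemberMaps <- function(members, testImages) {
  lapply(members, function(m)
    lapply(testImages, function(x) predictProbabilities(m, x)@probabilities))
}

.evalFused <- function(memberMaps, K, testClean) {
  rows <- lapply(seq_along(testClean), function(i) {
    pred <- fuse(lapply(memberMaps[seq_len(K)], `[[`, i))
    computeMetrics(pred@segmentation, testClean[[i]])
  })
  colMeans(do.call(rbind, rows)[, c("dice", "h95", "recall", "lesion_f1",
                                    "recall_large", "recall_small")],
           na.rm = TRUE)
}

.memberDice <- function(memberMaps, testClean) {
  vapply(memberMaps, function(maps)
    mean(vapply(seq_along(testClean), function(i)
      diceScore(.asBinaryInteger(maps[[i]][, , 2] >= 0.5), testClean[[i]]),
      numeric(1))), numeric(1))
}

#' Run the phantom benchmark
#'
#' For every repeat (master seed) the requested methods are trained on the
#' same phantom dataset and evaluated on the held-out phantoms against their
#' clean labels. Ensembles of every requested size K reuse the first K of
#' max(KValues) trained members. Any failing cell is recorded and skipped;
#' the remaining cells proceed.
#'
#' @param spec a [BenchmarkSpec-class].
#' @param outDir optional directory; when given, `results.tsv` and
#'   `summary.tsv` are written there.
#' @param keepModels retain trained oracles/ensembles in the result (for
#'   downstream analyses such as uncertainty-map inspection).
#' @param verbose print per-cell progress.
#' @return A list with `results` (tidy data.frame: method, K, repeat,
#'   master_seed, metrics, mean_member_dice), `summary` (mean and SD per
#'   method x K), `failures`, and -- with `keepModels` -- `models`.
#' @export
runBenchmark <- function(spec, outDir = NULL, keepModels = FALSE,
                         verbose = FALSE) {
  validObject(spec)
  say <- function(...) if (verbose) message(sprintf(...))
  train <- generateDataset(spec@phantomConfig, spec@nTrain,
                           seed = spec@phantomConfig@seed)
  test <- generateDataset(spec@phantomConfig, spec@nTest,
                          seed = .deriveSeed(spec@phantomConfig@seed, 999983L))
  testImages <- lapply(test, function(s) gaussianNormalize(s@image))
  testClean <- lapply(test, cleanLabel)
  maxK <- max(spec@KValues)
  rows <- list(); failures <- list(); models <- list()

  addRow <- function(method, K, rep, ms, metrics, meanMember) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, K = K, rep = rep, master_seed = ms,
      t(metrics), mean_member_dice = meanMember, stringsAsFactors = FALSE)
  }
  runCell <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      failures[[length(failures) + 1L]] <<- list(cell = tag,
                                                 error = conditionMessage(e))
      say("cell %s failed: %s", tag, conditionMessage(e))
      NULL
    })
  }

  for (r in seq_len(spec@repeats)) {
    ms <- spec@masterSeeds[r]
    repModels <- list()
    if ("saen" %in% spec@methods) {
      runCell(sprintf("saen/rep%d", r), {
        say("repeat %d: training oracle", r)
        tcOracle <- spec@trainConfig
        tcOracle@seed <- .deriveSeed(ms, 500000L)
        oracle <- trainUncertaintyOracle(train, spec@oracleConfig, tcOracle)
        say("repeat %d: training %d supervision-augmented members", r, maxK)
        ens <- trainEnsemble(train, oracle, K = maxK, grid = spec@lambdaGrid,
                             unetConfig = spec@unetConfig,
                             trainConfig = spec@trainConfig, masterSeed = ms,
                             T = spec@mcSamples)
        maps <- .predictMemberMaps(ens@members, testImages)
        md <- .memberDice(maps, testClean)
        for (K in spec@KValues)
          addRow("saen", K, r, ms, .evalFused(maps, K, testClean),
                 mean(md[seq_len(K)]))
        repModels$oracle <- oracle
        repModels$saen <- ens
        repModels$saen_member_dice <- md
      })
    }
    if ("rwi" %in% spec@methods) {
      runCell(sprintf("rwi/rep%d", r), {
        say("repeat %d: training %d RWI members", r, maxK)
        rwi <- trainRwiBaseline(train, K = maxK,
                                unetConfig = spec@unetConfig,
                                trainConfig = spec@trainConfig,
                                masterSeed = .deriveSeed(ms, 700000L))
        maps <- .predictMemberMaps(rwi@members, testImages)
        md <- .memberDice(maps, testClean)
        for (K in spec@KValues)
          addRow("rwi", K, r, ms, .evalFused(maps, K, testClean),
                 mean(md[seq_len(K)]))
        repModels$rwi <- rwi
        repModels$rwi_member_dice <- md
      })
    }
    if ("single" %in% spec@methods) {
      runCell(sprintf("single/rep%d", r), {
        say("repeat %d: training single baseline", r)
        tcS <- spec@trainConfig
        tcS@seed <- .deriveSeed(ms, 600000L)
        single <- trainBaseModel(train, NULL, spec@unetConfig, tcS,
                                 lambda = 1.0)
        maps <- .predictMemberMaps(list(single), testImages)
        addRow("single", 1L, r, ms, .evalFused(maps, 1L, testClean),
               .memberDice(maps, testClean))
        repModels$single <- single
      })
    }
    if (keepModels) models[[r]] <- repModels
  }
  results <- do.call(rbind, rows)
  summary <- if (!is.null(results)) {
    agg <- stats::aggregate(results[, c("dice", "h95", "recall", "lesion_f1")],
                            by = list(method = results$method, K = results$K),
                            function(x) c(mean = mean(x), sd = stats::sd(x)))
    do.call(data.frame, agg)
  } else NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(outDir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(outDir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out <- list(results = results, summary = summary, failures = failures,
              test = test)
  if (keepModels) out$models <- models
  out
}

# ---------------------------------------------------------------------------
# Resumable end-to-end pipeline with on-disk stage artifacts.

.stageSidecar <- function(dir, stage) file.path(dir, paste0(stage, ".done.json"))

.stageFresh <- function(dir, stage, params) {
  sc <- .stageSidecar(dir, stage)
  if (!file.exists(sc)) return(FALSE)
  prev <- tryCatch(jsonlite::read_json(sc), error = function(e) NULL)
  identical(prev$hash, .paramHash(params))
}

.paramHash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.stageMark <- function(dir, stage, params, artifacts) {
  jsonlite::write_json(list(stage = stage, hash = .paramHash(params),
                            artifacts = artifacts,
                            time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       .stageSidecar(dir, stage), auto_unbox = TRUE)
}

#' Run the full pipeline with resumable on-disk stages
#'
#' Stages: phantom generation, oracle training, uncertainty-map estimation,
#' mask generation, ensemble training, prediction, evaluation. Each stage
#' writes its artifacts plus a JSON sidecar holding a hash of the stage
#' parameters; a rerun with unchanged parameters skips completed stages. A
#' missing upstream artifact aborts with an error naming the stage to run
#' first.
#'
#' @param workDir working directory for all artifacts.
#' @param phantomConfig,nTrain,nTest phantom dataset definition.
#' @param K,lambdaGrid,T ensemble and uncertainty settings.
#' @param unetConfig,oracleConfig,trainConfig model and training settings.
#' @param seed master seed.
#' @param force rerun every stage even if up to date.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the per-test-sample metrics data.frame and
#'   the artifact directory layout.
#' @export
endToEnd <- function(workDir, phantomConfig = saen::phantomConfig(),
                     nTrain = 12L, nTest = 4L, K = 3L,
                     lambdaGrid = seq(0.1, 1, by = 0.1), T = 10L,
                     unetConfig = saen::unetConfig(
                       inChannels = phantomConfig@nChannels),
                     oracleConfig = bayesianUnetConfig(
                       inChannels = phantomConfig@nChannels),
                     trainConfig = saen::trainConfig(
                       learningRate = 5e-3, batchSize = 8L, epochs = 4L),
                     seed = 1L, force = FALSE, verbose = FALSE) {
  dir.create(workDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  cfgList <- list(phantom = .phantomConfigAsList(phantomConfig),
                  nTrain = nTrain, nTest = nTest, K = K, grid = lambdaGrid,
                  T = T, seed = seed,
                  epochs = trainConfig@epochs, lr = trainConfig@learningRate)

  phantomDir <- file.path(workDir, "phantom")
  oraclePath <- file.path(workDir, "oracle.rds")
  uncDir <- file.path(workDir, "uncertainty")
  maskDir <- file.path(workDir, "masks")
  ensDir <- file.path(workDir, "ensemble")
  predDir <- file.path(workDir, "predictions")
  metricsPath <- file.path(workDir, "metrics.tsv")

  # -- stage: phantom ------------------------------------------------------
  pPhantom <- c(cfgList["phantom"], cfgList[c("nTrain", "nTest", "seed")])
  if (force || !.stageFresh(workDir, "phantom", pPhantom)) {
    say("stage phantom: generating %d + %d samples", nTrain, nTest)
    train <- generateDataset(phantomConfig, nTrain, seed = seed)
    test <- generateDataset(phantomConfig, nTest, seed = .deriveSeed(seed, 999983L))
    writePhantomDataset(c(train, test), phantomDir)
    .stageMark(workDir, "phantom", pPhantom, phantomDir)
  }
  if (!file.exists(file.path(phantomDir, "manifest.tsv")))
    stop("phantom stage artifacts missing; run the 'phantom' stage first")
  allSamples <- readPhantomDataset(phantomDir)
  train <- allSamples[seq_len(nTrain)]
  test <- allSamples[nTrain + seq_len(nTest)]

  # -- stage: oracle -------------------------------------------------------
  if (force || !.stageFresh(workDir, "oracle", cfgList)) {
    say("stage oracle: training Bayesian U-Net")
    tc <- trainConfig
    tc@seed <- .deriveSeed(seed, 500000L)
    oracle <- trainUncertaintyOracle(train, oracleConfig, tc)
    writeModelCheckpoint(oracle, oraclePath)
    .stageMark(workDir, "oracle", cfgList, oraclePath)
  }
  if (!file.exists(oraclePath))
    stop("oracle checkpoint missing; run the 'oracle' stage first")
  oracle <- readModelCheckpoint(oraclePath)

  # -- stage: uncertainty --------------------------------------------------
  if (force || !.stageFresh(workDir, "uncertainty", cfgList)) {
    say("stage uncertainty: %d MC samples per image", T)
    dir.create(uncDir, showWarnings = FALSE)
    for (i in seq_along(train)) {
      u <- estimateUncertainty(oracle, gaussianNormalize(train[[i]]@image),
                               T = T, seed = .deriveSeed(seed, i))
      writeUncertaintyMap(u, file.path(uncDir, sprintf("unc_%03d.nii.gz", i)),
                          meta = list(T = T, seed = .deriveSeed(seed, i),
                                      theta = oracleConfig@dropoutRate))
    }
    .stageMark(workDir, "uncertainty", cfgList, uncDir)
  }

  # -- stage: masks --------------------------------------------------------
  sched <- sampleLambdaSchedule(K, lambdaGrid, seed = seed)
  if (force || !.stageFresh(workDir, "masks", cfgList)) {
    say("stage masks: lambdas %s", paste(sched@lambdas, collapse = ", "))
    for (k in seq_len(K)) {
      lamDir <- file.path(maskDir, sprintf("lambda_%04.2f", sched@lambdas[k]))
      dir.create(lamDir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(train)) {
        up <- file.path(uncDir, sprintf("unc_%03d.nii.gz", i))
        if (!file.exists(up))
          stop("uncertainty map ", up,
               " missing; run the 'uncertainty' stage first")
        v <- RNifti::readNifti(up)
        u <- new("UncertaintyMap", values = matrix(as.numeric(v), nrow(v)),
                 normalized = TRUE, normalizationStats = c(NA_real_, NA_real_))
        writeSupervisionMask(makeMask(u, sched@lambdas[k],
                                      sourceSampleId = sprintf("%03d", i)),
                             file.path(lamDir, sprintf("mask_%03d.nii.gz", i)))
      }
    }
    .stageMark(workDir, "masks", cfgList, maskDir)
  }

  # -- stage: ensemble -----------------------------------------------------
  if (force || !.stageFresh(workDir, "ensemble", cfgList)) {
    dir.create(ensDir, showWarnings = FALSE)
    members <- vector("list", K)
    for (k in seq_len(K)) {
      lam <- sched@lambdas[k]
      lamDir <- file.path(maskDir, sprintf("lambda_%04.2f", lam))
      masks <- lapply(seq_along(train), function(i) {
        mp <- file.path(lamDir, sprintf("mask_%03d.nii.gz", i))
        m <- tryCatch(suppressWarnings(RNifti::readNifti(mp)),
                      error = function(e) NULL)
        if (is.null(m))
          stop("supervision mask ", mp, " is missing or unreadable; ",
               "rerun the 'masks' stage")
        new("SupervisionMask",
            mask = .asBinaryInteger(matrix(as.numeric(m), nrow(m))),
            lambdaUsed = lam, sourceSampleId = sprintf("%03d", i))
      })
      say("stage ensemble: member %d (lambda %.2f)", k, lam)
      tc <- trainConfig
      tc@seed <- .deriveSeed(seed, 1000L + k)
      members[[k]] <- trainBaseModel(train, masks, unetConfig, tc,
                                     lambda = lam)
      writeModelCheckpoint(members[[k]],
                           file.path(ensDir, sprintf("member_%d.rds", k)))
    }
    jsonlite::write_json(
      list(K = K, lambdas = sched@lambdas, seed = seed,
           fingerprints = lapply(members, function(m)
             m@fingerprint[c("lambda", "seed", "epochs")])),
      file.path(ensDir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
    .stageMark(workDir, "ensemble", cfgList, ensDir)
  }
  ensMeta <- jsonlite::read_json(file.path(ensDir, "ensemble.json"))
  members <- lapply(seq_len(K), function(k)
    readModelCheckpoint(file.path(ensDir, sprintf("member_%d.rds", k))))
  ensemble <- new("EnsembleModel", members = members, schedule = sched,
                  fusion = "mean_probability")

  # -- stage: predict ------------------------------------------------------
  if (force || !.stageFresh(workDir, "predict", cfgList)) {
    dir.create(predDir, showWarnings = FALSE)
    for (i in seq_along(test)) {
      say("stage predict: test sample %d", i)
      pred <- predictEnsemble(ensemble, test[[i]]@image)
      RNifti::writeNifti(
        RNifti::asNifti(pred@fusedProbability@probabilities[, , 2]),
        file.path(predDir, sprintf("prob_%03d.nii.gz", i)), datatype = "double")
      RNifti::writeNifti(RNifti::asNifti(pred@segmentation),
                         file.path(predDir, sprintf("seg_%03d.nii.gz", i)),
                         datatype = "uint8")
      RNifti::writeNifti(RNifti::asNifti(pred@uncertainty@values),
                         file.path(predDir, sprintf("unc_%03d.nii.gz", i)),
                         datatype = "double")
    }
    .stageMark(workDir, "predict", cfgList, predDir)
  }

  # -- stage: evaluate -----------------------------------------------------
  rows <- lapply(seq_along(test), function(i) {
    sp <- file.path(predDir, sprintf("seg_%03d.nii.gz", i))
    if (!file.exists(sp))
      stop("prediction ", sp, " missing; run the 'predict' stage first")
    seg <- RNifti::readNifti(sp)
    cbind(sample = i,
          computeMetrics(.asBinaryInteger(matrix(as.numeric(seg), nrow(seg))),
                         test[[i]]@cleanLabel))
  })
  metrics <- do.call(rbind, rows)
  utils::write.table(metrics, metricsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .stageMark(workDir, "evaluate", cfgList, metricsPath)
  invisible(list(metrics = metrics, workDir = workDir,
                 dirs = list(phantom = phantomDir, oracle = oraclePath,
                             uncertainty = uncDir, masks = maskDir,
                             ensemble = ensDir, predictions = predDir)))
}

.phantomConfigAsList <- function(cfg)
  list(H = cfg@imageHeight, W = cfg@imageWidth, C = cfg@nChannels,
       nPv = cfg@nPeriventricular, nDeep = cfg@nDeep,
       radius = cfg@lesionRadiusRange, blur = cfg@boundaryBlurSigma,
       jitter = cfg@annotationJitterSigma, noise = cfg@noiseSd,
       seed = cfg@seed)
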