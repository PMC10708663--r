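## Orchestration: simulate/load -> preprocess -> split -> select ->
## fit -> evaluate, as one reproducible, configured run.

.defaultRunConfig <- function() {
  list(synthetic = NULL, input = NULL,
       preprocess = list(),
       splitRatio = 4 / 5,
       select = NULL,
       model = list(name = "plsr"),
       cvFolds = 5,
       seed = 1)
}

#' Run the full analysis pipeline
#'
#' Executes the standard workflow on either a synthetic dataset or a
#' sample-table CSV: (optional) preprocessing, Kennard-Stone 4:1
#' partitioning, optional wavelength selection on the calibration set,
#' model fitting (`plsr`, `svmr`, `rbfnn` or `seresnet`), and metric
#' assembly. Every stochastic stage derives from `config$seed`, so two
#' runs with an identical config produce identical artifacts.
#'
#' @param config a named list (or path to a YAML file) with fields:
#'   `synthetic` (arguments for [SyntheticConfig()]) *or* `input`
#'   (`list(sampleTable = <csv path>)`); `preprocess` (steps for
#'   [preprocSpec()]); `splitRatio` (default 4/5); `select`
#'   (`list(method = "cars"|"spa"|"uve", target = <analyte index>, ...)`
#'   or NULL); `model` (`list(name = ..., <hyperparameters>)`);
#'   `cvFolds` (0 disables cross-validation metrics); `seed`.
#' @param outputDir optional directory for artifacts: `manifest.json`,
#'   `split.csv`, `selection.json`, `metrics.csv` / `metrics.json`.
#' @return A [MetricsReport-class].
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(.defaultRunConfig(), config)
  hasSyn <- !is.null(config$synthetic)
  hasInp <- !is.null(config$input)
  if (hasSyn == hasInp)
    stop("validation error: exactly one of 'synthetic' or 'input' required")
  seed <- as.integer(config$seed)
  if (!is.null(outputDir))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  ## -- stage: data ---------------------------------------------------------
  stage <- "simulate/load"
  res <- tryCatch({
    if (hasSyn) {
      synArgs <- config$synthetic
      synArgs$seed <- synArgs$seed %||% seed
      syn <- do.call(SyntheticConfig, synArgs)
      ds <- generateDataset(syn,
                            keepPatches = config$model$name == "seresnet")
      ds$samples
    } else {
      readSampleTable(config$input$sampleTable)
    }
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  samples <- res
  Y <- concentrations(samples)
  X <- t(spectraMatrix(samples))            # samples x bands

  ## -- stage: preprocess ---------------------------------------------------
  stage <- "preprocess"
  spec <- preprocSpec(config$preprocess)
  pp <- applyPreproc(X, spec,
                     delta = median(diff(wavelengths(samples))))
  Xp <- pp$x

  ## -- stage: split --------------------------------------------------------
  stage <- "split"
  split <- kennardStoneSplit(Xp, ratio = config$splitRatio)
  cal <- split@calibration; tst <- split@test
  if (!is.null(outputDir))
    write.csv(data.frame(
      sample = c(cal, tst),
      set = rep(c("calibration", "test"), c(length(cal), length(tst)))),
      file.path(outputDir, "split.csv"), row.names = FALSE)

  ## -- stage: select -------------------------------------------------------
  stage <- "select"
  bands <- seq_len(ncol(Xp))
  selection <- NULL
  if (!is.null(config$select)) {
    sl <- config$select
    tgt <- sl$target %||% 1
    selection <- switch(match.arg(sl$method, c("cars", "spa", "uve")),
      cars = carsSelect(Xp[cal, , drop = FALSE], Y[cal, tgt],
                        nRuns = sl$nRuns %||% 50,
                        cvFolds = sl$cvFolds %||% 5, seed = seed),
      spa = spaSelect(Xp[cal, , drop = FALSE],
                      kMax = sl$kMax %||% min(30, length(cal) - 1),
                      y = Y[cal, tgt], seed = seed),
      uve = uveSelect(Xp[cal, , drop = FALSE], Y[cal, tgt],
                      nComponents = sl$nComponents %||% 5, seed = seed))
    bands <- selectedBands(selection)
    if (!is.null(outputDir))
      jsonlite::write_json(
        list(method = selection@method, bands = bands,
             wavelengths = wavelengths(samples)[bands]),
        file.path(outputDir, "selection.json"), auto_unbox = TRUE)
  }
  Xs <- Xp[, bands, drop = FALSE]

  ## -- stage: fit + evaluate -----------------------------------------------
  stage <- "fit"
  mdl <- config$model
  name <- match.arg(mdl$name, c("plsr", "svmr", "rbfnn", "seresnet"))
  cvFactory <- NULL
  report <- tryCatch({
    if (name == "seresnet") {
      pat <- patches(samples)
      if (is.null(pat)) stop("seresnet requires patches in the SampleSet")
      arch <- do.call(deskArchitectureSpec,
                      list(inputShape = c(dim(pat[[1]])[1:2],
                                          dim(pat[[1]])[3])))
      tc <- TrainConfig(learningRate = mdl$learningRate %||% 2e-3,
                        epochs = mdl$epochs %||% 120,
                        batchSize = mdl$batchSize %||% 32, seed = seed)
      nModels <- mdl$nModels %||% 4
      net <- trainEnsemble(arch, pat[cal], Y[cal, , drop = FALSE], tc,
                           nModels = nModels)
      yCalHat <- predict(net, pat[cal])
      yTstHat <- predict(net, pat[tst])
    } else {
      fitFun <- switch(name,
        plsr = function(X, Y) {
          nc <- mdl$nComponents %||%
            plsrCV(X, Y, nCompMax = mdl$nCompMax %||% 15,
                   seed = seed)$best
          plsrFit(X, Y, nc)
        },
        svmr = function(X, Y) svmrFit(X, Y, tune = mdl$tune %||% FALSE,
                                      seed = seed),
        rbfnn = function(X, Y) rbfnnFit(X, Y,
                                        nCenters = mdl$nCenters %||%
                                          max(2, nrow(X) %/% 3),
                                        seed = seed))
      fit <- fitFun(Xs[cal, , drop = FALSE], Y[cal, , drop = FALSE])
      cvFactory <- if (config$cvFolds >= 2) fitFun
      yCalHat <- predict(fit, Xs[cal, , drop = FALSE])
      yTstHat <- predict(fit, Xs[tst, , drop = FALSE])
    }
    metricsReport(Y[cal, , drop = FALSE], yCalHat,
                  Y[tst, , drop = FALSE], yTstHat,
                  cvFactory = cvFactory,
                  Xcal = Xs[cal, , drop = FALSE],
                  folds = max(2, config$cvFolds), seed = seed,
                  model = name)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  if (!is.null(outputDir)) {
    ## cache predictions so the evaluate stage can be replayed alone
    predDf <- rbind(
      data.frame(sample = cal, set = "calibration",
                 as.data.frame(Y[cal, , drop = FALSE]),
                 setNames(as.data.frame(yCalHat),
                          paste0("pred_", colnames(Y)))),
      data.frame(sample = tst, set = "test",
                 as.data.frame(Y[tst, , drop = FALSE]),
                 setNames(as.data.frame(yTstHat),
                          paste0("pred_", colnames(Y)))))
    ## full double precision so the evaluate stage replays bit-exactly
    num <- vapply(predDf, is.numeric, logical(1))
    predDf[num] <- lapply(predDf[num], function(v) sprintf("%.17g", v))
    write.csv(predDf, file.path(outputDir, "predictions.csv"),
              row.names = FALSE)
    writeMetricsReport(report, file.path(outputDir, "metrics"))
    manifest <- list(
      configHash = rlang::hash(config),
      seed = seed,
      model = name,
      nSamples = ncol(spectraMatrix(samples)),
      nBands = length(bands),
      package = as.character(utils::packageVersion("hsiQuant")),
      rVersion = R.version.string)
    jsonlite::write_json(manifest,
                         file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' Replay the evaluate stage from cached pipeline artifacts
#'
#' Rebuilds the [MetricsReport-class] from `predictions.csv` written by
#' [runPipeline()]. Because the metrics are pure functions of the cached
#' predictions, the replayed report is bit-identical to the original
#' (cross-validation columns excepted: they require refitting and are
#' left `NA`).
#'
#' @param outputDir directory holding `predictions.csv`.
#' @param model model label for the report (default from the manifest if
#'   present).
#' @return A [MetricsReport-class].
#' @export
evaluateArtifacts <- function(outputDir, model = NULL) {
  df <- read.csv(file.path(outputDir, "predictions.csv"),
                 check.names = FALSE)
  an <- intersect(analyteNames(), colnames(df))
  if (length(an) == 0)
    an <- setdiff(grep("^pred_", colnames(df), value = TRUE,
                       invert = TRUE), c("sample", "set"))
  if (is.null(model)) {
    mf <- file.path(outputDir, "manifest.json")
    model <- if (file.exists(mf))
      jsonlite::read_json(mf)$model else "model"
  }
  cal <- df$set == "calibration"
  Y <- as.matrix(df[, an, drop = FALSE])
  Yhat <- as.matrix(df[, paste0("pred_", an), drop = FALSE])
  colnames(Yhat) <- an
  metricsReport(Y[cal, , drop = FALSE], Yhat[cal, , drop = FALSE],
                Y[!cal, , drop = FALSE], Yhat[!cal, , drop = FALSE],
                model = model)
}
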