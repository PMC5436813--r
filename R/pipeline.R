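# End-to-end driver: synthetic corpus -> language models -> covariates ->
# design -> voxelwise GLM -> group t maps -> cluster-extent correction ->
# conjunction. Everything is a pure function of (config, seed).

#' Pipeline configuration
#'
#' Defaults reproduce the analysis constants (voxel p 0.005, 1,000
#' Monte-Carlo simulations, trigram order, TR 0.88 s, 3.5 mm voxels) at
#' desk scale: 500-word vocabulary, 3 base tags, 50,000 training
#' sentences, 3 stories of roughly 300 words each with reversed
#' counterparts, 12 subjects, a 20 x 20 x 20 volume.
#'
#' @param ... overrides of the default fields.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    vocabSize = 500L, zipfExponent = 1,
    trainSentences = 50000L, meanSentenceLength = 8,
    nStories = 3L, storyDuration = 150, speechRate = 2,
    nSubjects = 12L, dim = c(20L, 20L, 20L), voxelSize = 3.5,
    tr = 0.88, order = 3L, lambda = c(0.1, 0.2, 0.7), addK = 1,
    voxelP = 0.005, nIter = 1000L, connectivity = 26L, tail = "one",
    alpha = 0.05, effectSD = 1, sigma = 1, ar1 = 0.3, noiseFWHM = 7,
    subjectSD = 0.1, microtime = 16L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = c("PipelineConfig", "list"))
}

# independent sub-seeds below 2^31, derived deterministically
.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 9973L) %% 2147483647L
}

#' Train the three stream models on synthetic corpora
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with \code{lexicon}, \code{corpus}, and trained
#'   \code{lexModel}, \code{posModel}, \code{phoModel}.
#' @export
trainStreamModels <- function(config = pipelineConfig()) {
  lexicon <- generateLexicon(config$vocabSize, config$zipfExponent,
                             seed = .stageSeed(config$seed, 1L))
  corpus <- generateCorpus(lexicon,
                           nSentences = config$trainSentences,
                           meanLength = config$meanSentenceLength,
                           seed = .stageSeed(config$seed, 2L))
  lam <- config$lambda
  list(
    lexicon = lexicon, corpus = corpus,
    lexModel = trainNGram(corpus$words, config$order, lam,
                          addK = config$addK),
    posModel = trainNGram(corpus$pos, config$order, lam,
                          addK = config$addK),
    phoModel = trainNGram(corpus$phonemes, config$order, lam,
                          addK = config$addK))
}

#' Build transcripts, covariates and the multi-run design
#'
#' Generates one transcript per story, computes its six covariates, and
#' assembles the block-diagonal design with a real and a reversed run
#' per story (the reversed run reusing the story's regressors).
#'
#' @param models result of \code{\link{trainStreamModels}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with \code{transcripts}, \code{covariates} (lists per
#'   story) and \code{design} (a \linkS4class{DesignMatrix} with
#'   zeroed motion columns as a template).
#' @export
buildStimulusDesign <- function(models, config = pipelineConfig()) {
  nVol <- ceiling(config$storyDuration / config$tr)
  transcripts <- lapply(seq_len(config$nStories), function(i)
    generateTranscript(models$lexicon,
                       totalDuration = config$storyDuration,
                       rate = config$speechRate,
                       storyId = sprintf("story%d", i),
                       seed = .stageSeed(config$seed, 10L + i)))
  covariates <- lapply(transcripts, function(tr)
    buildCovariates(tr, models$lexModel, models$posModel,
                    models$phoModel))
  runs <- list()
  for (i in seq_len(config$nStories)) {
    for (rev in c(FALSE, TRUE)) {
      runs[[length(runs) + 1L]] <- list(
        name = sprintf("story%d%s", i, if (rev) "_rev" else ""),
        pair = sprintf("story%d", i), reversed = rev,
        covariates = covariates[[i]],
        motion = matrix(0, nVol, 6L), nVolumes = nVol)
    }
  }
  design <- assembleDesign(runs, tr = config$tr,
                           microtime = config$microtime)
  list(transcripts = transcripts, covariates = covariates,
       design = design)
}

#' Run the full analysis end to end
#'
#' Trains the three trigram models on synthetic corpora, builds the
#' covariates and design, simulates BOLD data with planted ROI effects,
#' fits the voxelwise GLM per subject, forms real-minus-reversed
#' contrasts, computes group t maps, corrects them by Monte-Carlo
#' cluster extent matched to the estimated contrast-map smoothness, and
#' intersects the significant maps (conjunction-null analysis).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, covariate tables, the
#'   design, group stat maps (NIfTI), cluster tables and a JSON log of
#'   parameters and seeds are written there.
#' @param verbose print stage progress.
#' @return list with elements \code{models}, \code{stimulus},
#'   \code{truth}, \code{groupMaps}, \code{smoothness},
#'   \code{extents}, \code{significant} (per covariate: binary map +
#'   cluster table), \code{conjunctions} (pairwise and three-way),
#'   \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  say("training stream models ...")
  models <- trainStreamModels(config)
  say("building transcripts and design ...")
  stim <- buildStimulusDesign(models, config)
  truth <- groundTruth(stim$design, dim = config$dim,
                       effectSD = config$effectSD, sigma = config$sigma,
                       ar1 = config$ar1, fwhm = config$noiseFWHM,
                       voxelSize = config$voxelSize,
                       subjectSD = config$subjectSD)
  say("simulating BOLD data for ", config$nSubjects, " subjects ...")
  subjects <- generateBold(stim$design, truth, config$nSubjects,
                           tr = config$tr,
                           seed = .stageSeed(config$seed, 20L))
  covs <- names(truth$rois)
  contrasts <- lapply(covs, function(cov) vector("list",
                                                 config$nSubjects))
  names(contrasts) <- covs
  say("fitting voxelwise GLMs ...")
  subjFWHM <- matrix(0, length(subjects), 3L)
  for (s in seq_along(subjects)) {
    fit <- fitVoxelwise(subjects[[s]]$vol, subjects[[s]]$design)
    for (cov in covs)
      contrasts[[cov]][[s]] <-
        contrastRealVsReversed(fit, cov, subjects[[s]]$subject)
    # residual-based smoothness: the model has absorbed the planted
    # signal, so residual fields carry the noise correlation structure
    subjFWHM[s, ] <- estimateSmoothness(
      residualSeries(fit), mask = subjects[[s]]$vol@mask,
      voxelSize = config$voxelSize)$fwhm
  }
  say("group statistics and cluster correction ...")
  groupMaps <- lapply(contrasts, groupTTest)
  resFWHM <- colMeans(subjFWHM)
  smoothness <- lapply(covs, function(cov)
    structure(list(fwhm = resFWHM,
                   voxelSize = rep(config$voxelSize, length.out = 3),
                   rho = NULL),
              class = "SmoothnessEstimate"))
  names(smoothness) <- covs
  extents <- lapply(covs, function(cov)
    simulateExtentThreshold(config$dim, smoothness = smoothness[[cov]],
                            voxelP = config$voxelP,
                            nIter = config$nIter,
                            seed = .stageSeed(config$seed, 30L),
                            connectivity = config$connectivity,
                            alpha = config$alpha, covariate = cov))
  names(extents) <- covs
  significant <- lapply(covs, function(cov)
    applyClusterThreshold(groupMaps[[cov]], extents[[cov]],
                          tail = config$tail))
  names(significant) <- covs
  sigMaps <- lapply(significant, `[[`, "map")
  conjunctions <- list(
    lex_pos = conjunction(sigMaps[c("ppl_lex", "ppl_pos")]),
    lex_pho = conjunction(sigMaps[c("ppl_lex", "ppl_pho")]),
    pos_pho = conjunction(sigMaps[c("ppl_pos", "ppl_pho")]),
    all = conjunction(sigMaps))
  res <- list(models = models, stimulus = stim, truth = truth,
              groupMaps = groupMaps, smoothness = smoothness,
              extents = extents, significant = significant,
              conjunctions = conjunctions, config = config)
  if (!is.null(outDir)) .writePipelineArtifacts(res, outDir)
  res
}

.writePipelineArtifacts <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(res$stimulus$covariates))
    writeCovariates(res$stimulus$covariates[[i]],
                    file.path(outDir, sprintf("story%d_covariates.tsv",
                                              i)))
  writeDesign(res$stimulus$design, file.path(outDir, "design.tsv"))
  for (cov in names(res$groupMaps)) {
    writeNIfTI(res$groupMaps[[cov]],
               file.path(outDir, paste0("group_t_", cov, ".nii.gz")))
    writeNIfTI(res$significant[[cov]]$map,
               file.path(outDir, paste0("sig_", cov, ".nii.gz")))
    writeClusterTable(res$significant[[cov]]$clusters,
                      file.path(outDir, paste0("clusters_", cov,
                                               ".tsv")))
  }
  for (cj in names(res$conjunctions))
    writeNIfTI(res$conjunctions[[cj]],
               file.path(outDir, paste0("conjunction_", cj, ".nii.gz")))
  log <- list(
    package = "perplexityBOLD",
    version = as.character(utils::packageVersion("perplexityBOLD")),
    rVersion = R.version.string,
    config = unclass(res$config),
    extentK = vapply(res$extents, extentK, integer(1)),
    smoothnessFWHM = lapply(res$smoothness, `[[`, "fwhm"))
  jsonlite::write_json(log, file.path(outDir, "pipeline_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Dice overlap coefficient between two binary maps
#'
#' @param a,b logical arrays of identical shape.
#' @return 2|a AND b| / (|a| + |b|); NaN when both are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
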