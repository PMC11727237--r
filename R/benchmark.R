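#' End-to-end planted-signal benchmark
#'
#' Runs the whole pipeline on a generated synthetic study and measures how
#' well the trained predictor recovers each compound's planted true pathway:
#' generate a bundle (disjoint pathways, so every annotated compound has
#' exactly one positive -- its planted mechanism -- and the top-N chance level
#' is N / nPathways), curate pathways / graph / compounds, label and sample
#' negatives 3:1, split 0.8/0.1/0.1, fingerprint, train a scaled predictor,
#' and evaluate truth-based top-N accuracy on a held-out set.
#'
#' The default scale (60 genes, 15 pathways of 4 genes, 300 compounds,
#' planted shift 3 against unit noise) trains in well under a minute on one
#' CPU; the scaled model keeps the published architecture's shape (two sGCN
#' channels; four dense layers; dropout 0.2/0.5/0.5/0.5/0.2) at desk widths.
#'
#' @param effectSize planted mean shift on true-pathway genes (default 3; use
#'   0 for a null run).
#' @param seed integer seed driving generation, sampling and training.
#' @param nGenes,nPathways,nCompounds study size (defaults 60 / 15 / 300).
#' @param noiseSd signature noise SD (default 1).
#' @param nBits fingerprint width for the scaled model (default 256).
#' @param denseWidths scaled dense widths (default c(64, 48, 32, 16)).
#' @param sgcnChannels scaled channel count (default 2).
#' @param learningRate,maxEpochs,patience,batchSize scaled optimizer settings
#'   (defaults 5e-3 / 300 / 30 / 32).
#' @param topN N values evaluated (default c(1, 3, 5)).
#' @param evalSet which split to evaluate: "validation" (default) or "test".
#' @param dir directory for the generated bundle (default temporary).
#' @return list: \code{accuracy} (a \code{gdop_topn} data.frame),
#'   \code{model}, \code{split}, \code{pairs}, \code{curationReport},
#'   \code{chance} (analytic top-N chance levels), \code{fixture}.
#' @export
syntheticBenchmark <- function(effectSize = 3, seed = 42, nGenes = 60,
                               nPathways = 15, nCompounds = 300, noiseSd = 1,
                               nBits = 256, denseWidths = c(64, 48, 32, 16),
                               sgcnChannels = 2, learningRate = 5e-3,
                               maxEpochs = 300, patience = 30, batchSize = 32,
                               topN = c(1, 3, 5), evalSet = "validation",
                               dir = tempfile("gdop_bench_")) {
  pwSize <- nGenes %/% nPathways
  scfg <- syntheticConfig(nGenes = nGenes, nPathways = nPathways,
                          pathwaySizeRange = c(pwSize, pwSize),
                          nCompounds = nCompounds, effectSize = effectSize,
                          noiseSd = noiseSd, disjointPathways = TRUE,
                          seed = seed)
  fx <- makeFixture(scfg, dir)
  d <- loadFixture(fx)
  pos <- assignPositiveLabels(d$compounds, d$pathways)
  neg <- sampleNegatives(pos, d$pathways, ratio = 3, seed = seed)
  pairs <- rbind(pos, neg)
  sp <- splitDataset(d$compounds, seed = seed)
  fps <- fingerprintMatrix(d$compounds, nBits = nBits)
  cfg <- gdopConfig(sgcnChannels = sgcnChannels, denseWidths = denseWidths,
                    learningRate = learningRate, maxEpochs = maxEpochs,
                    patience = patience, batchSize = batchSize, seed = seed)
  model <- initGdopModel(cfg, d$geneSpace, pathwayIds(d$pathways),
                         nBits = nBits)
  model <- trainGdop(model, profileMatrix(d$compounds), fps, pairs, sp,
                     d$operator)
  evalIds <- intersect(sp[[evalSet]], unique(pos$compound_id))
  rankings <- predictRankAll(model,
                             profileMatrix(d$compounds)[evalIds, , drop = FALSE],
                             fps[evalIds, , drop = FALSE], d$operator)
  truth <- setNames(as.list(d$truth$pathway_id), d$truth$compound_id)[evalIds]
  acc <- topNAccuracy(rankings, truth, n = topN)
  list(accuracy = acc, model = model, split = sp, pairs = pairs,
       curationReport = attr(d$compounds, "report"),
       chance = setNames(pmin(topN / nPathways, 1), paste0("top", topN)),
       fixture = fx)
}
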