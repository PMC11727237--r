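#' Configuration for the planted-signal synthetic generator
#'
#' Describes a synthetic study with the statistical structure the predictor
#' assumes: a sparse gene-gene interaction graph whose pathway members are
#' preferentially connected, pathway gene sets of bounded size, per-compound
#' replicate signatures whose mean carries a perturbation localized to the
#' compound's (single) true pathway, and target annotations drawn from that
#' pathway. Fractions of compounds with missing targets or corrupted SMILES,
#' and a replicate-count range straddling the 5-signature cutoff, exercise the
#' curation filters.
#'
#' @param nGenes landmark genes (default 100).
#' @param graphEdgeProb background edge probability (default 0.02).
#' @param pathwayEdgeProb elevated edge probability between members of one
#'   pathway, so graph propagation is informative (default 0.25).
#' @param nPathways pathway count (default 20).
#' @param pathwaySizeRange inclusive member-count range (default c(5, 65),
#'   matching the curated label space's 65-gene cap).
#' @param nCompounds compound count (default 100).
#' @param signaturesPerCompoundRange inclusive replicate-count range (default
#'   c(3, 8), straddling the 5-replicate cutoff).
#' @param effectSize mean shift added to true-pathway member genes in every
#'   signature (default 3).
#' @param noiseSd per-gene signature noise SD (default 1).
#' @param targetsPerCompound annotated targets drawn from the true pathway
#'   (default 2, capped at the pathway size).
#' @param fractionMissingTargets compounds left unannotated (default 0.05).
#' @param fractionBadSmiles compounds given a corrupted SMILES (default 0.05).
#' @param disjointPathways draw pathways as disjoint gene subsets (a random
#'   partition) instead of independent random subsets (default FALSE). With
#'   disjoint pathways each annotated compound has exactly one positive
#'   pathway -- its planted mechanism -- so top-N chance levels take their
#'   textbook value N / nPathways; requires the sizes to fit in
#'   \code{nGenes}.
#' @param seed integer RNG seed.
#' @return list of class \code{gdop_synth_config}.
#' @export
syntheticConfig <- function(nGenes = 100, graphEdgeProb = 0.02,
                            pathwayEdgeProb = 0.25, nPathways = 20,
                            pathwaySizeRange = c(5, 65), nCompounds = 100,
                            signaturesPerCompoundRange = c(3, 8),
                            effectSize = 3, noiseSd = 1,
                            targetsPerCompound = 2,
                            fractionMissingTargets = 0.05,
                            fractionBadSmiles = 0.05,
                            disjointPathways = FALSE, seed = 1) {
  stopifnot(nGenes >= 2, nPathways >= 2, nCompounds >= 1,
            pathwaySizeRange[1] >= 1,
            pathwaySizeRange[2] >= pathwaySizeRange[1],
            signaturesPerCompoundRange[1] >= 1, noiseSd > 0,
            graphEdgeProb >= 0, graphEdgeProb <= 1,
            pathwayEdgeProb >= 0, pathwayEdgeProb <= 1,
            fractionMissingTargets >= 0, fractionMissingTargets <= 1,
            fractionBadSmiles >= 0, fractionBadSmiles <= 1)
  if (pathwaySizeRange[2] > nGenes)
    stop("pathwaySizeRange exceeds nGenes")
  structure(as.list(environment()), class = "gdop_synth_config")
}

#' Bundled valid drug-like SMILES
#'
#' A deterministic list of ~200 valid small-molecule SMILES built from
#' para-substituted aromatic templates, indexed by compound number by the
#' generator so fingerprints vary across compounds without an external
#' structure generator.
#'
#' @return character vector of SMILES strings.
#' @export
builtinSmiles <- function() {
  heads <- c("", "C", "CC", "CCC", "CC(C)", "OC", "OCC", "CO", "NC",
             "CN(C)", "CC(=O)N", "CC(=O)O", "C(=O)N", "N#C", "CCS")
  tails <- c("F", "Cl", "Br", "C", "CC", "O", "N", "CCO", "C(=O)O",
             "C(=O)N", "C#N", "OC", "N(C)C", "CO")
  as.vector(t(outer(heads, tails, function(h, t)
    paste0(h, "c1ccc(", t, ")cc1"))))
}

#' Generate a synthetic fixture bundle on disk
#'
#' Writes the exact plain-text formats the curation modules read --
#' \code{pathways.gmt}, \code{edges.tsv}, \code{signatures.tsv},
#' \code{compounds.csv} -- plus \code{truth.tsv} mapping each compound to its
#' planted true pathway. Regeneration under an equal seed is byte-identical.
#'
#' Generation: genes \code{G1..Gn}; an Erdos-Renyi background graph at
#' \code{graphEdgeProb} densified with within-pathway edges at
#' \code{pathwayEdgeProb} (background-only edges carry combined scores
#' 600-1000 so the 800 threshold is exercised; within-pathway edges carry
#' 800-1000); pathways as random gene subsets within the size range; each
#' compound one true pathway, targets drawn from its genes (or omitted for
#' the missing-targets fraction), a SMILES from \code{\link{builtinSmiles}}
#' (corrupted with an unbalanced parenthesis for the bad-SMILES fraction),
#' and each replicate signature \eqn{N(0, noiseSd)} per gene plus
#' \code{effectSize} on true-pathway member genes.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param dir output directory (created if missing).
#' @return list of class \code{gdop_fixture}: file \code{paths}, the
#'   \code{config}, and the in-memory \code{truth} table.
#' @export
# uniform draw over an inclusive integer range; immune to base sample()'s
# scalar convention (sample(4, n) draws from 1:4, not the constant 4)
.sampleRange <- function(range, n) {
  choices <- seq(range[1], range[2])
  choices[sample.int(length(choices), n, replace = TRUE)]
}

makeFixture <- function(config, dir = tempfile("gdop_fixture_")) {
  stopifnot(inherits(config, "gdop_synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(config$seed)
  genes <- paste0("G", seq_len(config$nGenes))

  # pathways: random subsets, sizes uniform in range
  sizes <- .sampleRange(config$pathwaySizeRange, config$nPathways)
  pwIds <- sprintf("PW%03d", seq_len(config$nPathways))
  if (config$disjointPathways) {
    if (sum(sizes) > config$nGenes)
      stop("disjoint pathways need sum(sizes) <= nGenes; got ", sum(sizes),
           " over ", config$nGenes, " genes")
    pool <- sample(genes, sum(sizes))
    stops <- cumsum(sizes)
    sets <- lapply(seq_along(sizes), function(p)
      sort(pool[(stops[p] - sizes[p] + 1L):stops[p]]))
  } else {
    sets <- lapply(sizes, function(s) sort(sample(genes, s)))
  }
  coll <- PathwayCollection(pwIds, paste("synthetic pathway", pwIds), sets)
  gmtPath <- file.path(dir, "pathways.gmt")
  writeGMT(coll, gmtPath)

  # graph: background + within-pathway densification
  pairs <- which(upper.tri(matrix(TRUE, config$nGenes, config$nGenes)),
                 arr.ind = TRUE)
  inPw <- rep(FALSE, nrow(pairs))
  gi <- match(genes, genes)
  for (s in sets) {
    idx <- match(s, genes)
    member <- pairs[, 1] %in% idx & pairs[, 2] %in% idx
    inPw <- inPw | member
  }
  u <- runif(nrow(pairs))
  keep <- (!inPw & u < config$graphEdgeProb) |
    (inPw & u < config$pathwayEdgeProb)
  scores <- integer(sum(keep))
  kInPw <- inPw[keep]
  scores[kInPw] <- sample(800:1000, sum(kInPw), replace = TRUE)
  scores[!kInPw] <- sample(600:1000, sum(!kInPw), replace = TRUE)
  edges <- data.frame(gene_a = genes[pairs[keep, 1]],
                      gene_b = genes[pairs[keep, 2]],
                      combined_score = scores)
  edgePath <- file.path(dir, "edges.tsv")
  write.table(edges, edgePath, sep = "\t", quote = FALSE, row.names = FALSE)

  # compounds
  cIds <- sprintf("C%04d", seq_len(config$nCompounds))
  truePw <- sample(config$nPathways, config$nCompounds, replace = TRUE)
  smilesPool <- builtinSmiles()
  smiles <- smilesPool[(seq_len(config$nCompounds) - 1L) %%
                         length(smilesPool) + 1L]
  missTarget <- runif(config$nCompounds) < config$fractionMissingTargets
  badSmiles <- runif(config$nCompounds) < config$fractionBadSmiles
  smiles[badSmiles] <- paste0(smiles[badSmiles], "(")
  targets <- lapply(seq_len(config$nCompounds), function(i) {
    if (missTarget[i]) return(character())
    pw <- sets[[truePw[i]]]
    sort(sample(pw, min(config$targetsPerCompound, length(pw))))
  })
  compounds <- data.frame(compound_id = cIds, smiles = smiles,
                          targets = vapply(targets, paste,
                                           character(1), collapse = "|"))
  compPath <- file.path(dir, "compounds.csv")
  write.table(compounds, compPath, sep = ",", quote = FALSE,
              row.names = FALSE)

  # replicate signatures
  nSig <- .sampleRange(config$signaturesPerCompoundRange, config$nCompounds)
  plates <- sprintf("PL%02d", 1:6)
  doses <- c("0.1uM", "1uM", "10uM")
  times <- c("6h", "24h")
  cells <- c("A375", "MCF7", "PC3")
  rows <- vector("list", config$nCompounds)
  for (i in seq_len(config$nCompounds)) {
    memberIdx <- match(sets[[truePw[i]]], genes)
    prof <- matrix(rnorm(nSig[i] * config$nGenes, 0, config$noiseSd),
                   nSig[i], config$nGenes)
    prof[, memberIdx] <- prof[, memberIdx] + config$effectSize
    meta <- data.frame(signature_id = sprintf("%s_s%d", cIds[i],
                                              seq_len(nSig[i])),
                       compound_id = cIds[i],
                       plate = sample(plates, nSig[i], replace = TRUE),
                       dose = sample(doses, nSig[i], replace = TRUE),
                       time = sample(times, nSig[i], replace = TRUE),
                       cell_line = sample(cells, nSig[i], replace = TRUE))
    vals <- as.data.frame(matrix(sprintf("%.6f", prof), nSig[i],
                                 config$nGenes))
    names(vals) <- genes
    rows[[i]] <- cbind(meta, vals)
  }
  sigTab <- do.call(rbind, rows)
  sigPath <- file.path(dir, "signatures.tsv")
  write.table(sigTab, sigPath, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- data.frame(compound_id = cIds, pathway_id = pwIds[truePw])
  truthPath <- file.path(dir, "truth.tsv")
  write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(dir = dir,
                 paths = list(pathways = gmtPath, edges = edgePath,
                              signatures = sigPath, compounds = compPath,
                              truth = truthPath),
                 config = config, truth = truth),
            class = "gdop_fixture")
}

#' @export
print.gdop_fixture <- function(x, ...) {
  cat("gdop synthetic fixture in", x$dir, "\n")
  cat(sprintf("  %d genes, %d pathways, %d compounds (seed %d)\n",
              x$config$nGenes, x$config$nPathways, x$config$nCompounds,
              x$config$seed))
  invisible(x)
}

#' Analytic expectation of compounds surviving curation
#'
#' Under the generator's independence assumptions, the expected number of
#' compounds retained by the three molecule filters is
#' \deqn{n \cdot (1 - f_{missing}) \cdot (1 - f_{bad}) \cdot P(n_{sig} \ge min)}
#' with the replicate count uniform on the configured integer range. Used to
#' property-test the curation filters against observed retention.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param minSignatures curation replicate cutoff (default 5).
#' @return expected retained-compound count (real number).
#' @export
expectedCurationCounts <- function(config, minSignatures = 5) {
  stopifnot(inherits(config, "gdop_synth_config"))
  rng <- seq(config$signaturesPerCompoundRange[1],
             config$signaturesPerCompoundRange[2])
  pSig <- mean(rng >= minSignatures)
  config$nCompounds * (1 - config$fractionMissingTargets) *
    (1 - config$fractionBadSmiles) * pSig
}

#' Load a fixture bundle through the package readers
#'
#' Convenience wrapper running the full curation path on a generated bundle:
#' read + filter pathways, build the PPI network and operator, read
#' signatures and compound metadata, curate compounds.
#'
#' @param fixture a \code{gdop_fixture} (or a directory containing the bundle
#'   files).
#' @param maxGenes,scoreThreshold,minSignatures curation settings (defaults
#'   65, 800, 5).
#' @return list: \code{pathways}, \code{geneSpace}, \code{network},
#'   \code{operator}, \code{compounds}, \code{truth}.
#' @export
loadFixture <- function(fixture, maxGenes = 65, scoreThreshold = 800,
                        minSignatures = 5) {
  dir <- if (inherits(fixture, "gdop_fixture")) fixture$dir else fixture
  pw <- filterPathways(readGMT(file.path(dir, "pathways.gmt")),
                       maxGenes = maxGenes)
  sigTab <- read.delim(file.path(dir, "signatures.tsv"), nrows = 1,
                       check.names = FALSE)
  gs <- GeneSpace(setdiff(names(sigTab),
                          c("signature_id", "compound_id", "plate", "dose",
                            "time", "cell_line")))
  net <- loadPPIEdges(file.path(dir, "edges.tsv"), gs,
                      scoreThreshold = scoreThreshold)
  sigs <- readSignatures(file.path(dir, "signatures.tsv"), gs)
  meta <- readCompoundMeta(file.path(dir, "compounds.csv"))
  comp <- curateCompounds(sigs, meta, gs, minSignatures = minSignatures)
  truth <- read.delim(file.path(dir, "truth.tsv"),
                      colClasses = "character")
  list(pathways = pw, geneSpace = gs, network = net,
       operator = propagationOperator(net), compounds = comp, truth = truth)
}
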