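#' Read a replicate signature matrix
#'
#' TSV with columns \code{signature_id}, \code{compound_id}, the metadata
#' columns \code{plate}, \code{dose}, \code{time}, \code{cell_line}
#' (informational only), then one column per gene of the gene space. Profile
#' values are z-score-like real numbers; each row is one replicate
#' measurement of one compound.
#'
#' @param path path to the signature TSV.
#' @param geneSpace a \linkS4class{GeneSpace}; the gene columns must cover it.
#' @return list with \code{profiles} (signatures x genes matrix, gene order of
#'   the gene space), \code{compound_id} (character) and \code{meta}
#'   (data.frame of the metadata columns).
#' @export
readSignatures <- function(path, geneSpace) {
  stopifnot(is(geneSpace, "GeneSpace"))
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  metaCols <- c("signature_id", "compound_id", "plate", "dose", "time",
                "cell_line")
  if (!all(metaCols %in% names(tab)))
    stop("signature table must have columns ", paste(metaCols, collapse = ", "))
  missing <- setdiff(geneSpace@genes, names(tab))
  if (length(missing))
    stop("signature table lacks gene columns: ",
         paste(head(missing, 5), collapse = ", "))
  profiles <- as.matrix(tab[, geneSpace@genes, drop = FALSE])
  if (!is.numeric(profiles) || !all(is.finite(profiles)))
    stop("non-finite or non-numeric profile values")
  rownames(profiles) <- tab$signature_id
  list(profiles = profiles,
       compound_id = as.character(tab$compound_id),
       meta = tab[, c("signature_id", "plate", "dose", "time", "cell_line")])
}

#' Read the compound metadata table
#'
#' CSV with columns \code{compound_id}, \code{smiles} and \code{targets}
#' (pipe-separated gene symbols; empty for unannotated compounds).
#'
#' @param path path to the CSV.
#' @return data.frame with columns \code{compound_id}, \code{smiles} and a
#'   list-column \code{targets}.
#' @export
readCompoundMeta <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("compound_id", "smiles", "targets")
  if (!all(need %in% names(tab)))
    stop("compound table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$compound_id)) stop("duplicate compound_id")
  tab$targets <- lapply(strsplit(tab$targets, "|", fixed = TRUE),
                        function(t) unique(t[nzchar(t)]))
  tab
}

#' Curate compounds: target, replicate-count and structure filters
#'
#' Applies the three molecule filters: a compound is dropped if it lacks
#' target annotation, has fewer than \code{minSignatures} replicate signatures
#' (so exactly 5 is kept under the default), or its SMILES cannot be parsed.
#' Surviving compounds get one profile each: the unweighted arithmetic mean of
#' all their signatures, ignoring plate, dose, treatment time and cell line.
#' Compounds present in the signatures but absent from the metadata are
#' excluded and counted in the curation report (attribute \code{"report"}).
#'
#' @param signatures list as returned by \code{\link{readSignatures}}.
#' @param metadata data.frame as returned by \code{\link{readCompoundMeta}}.
#' @param geneSpace the shared \linkS4class{GeneSpace}.
#' @param minSignatures minimum replicate count to retain (default 5).
#' @return a \linkS4class{CompoundSet}; attribute \code{"report"} counts the
#'   compounds removed by each filter.
#' @export
curateCompounds <- function(signatures, metadata, geneSpace,
                            minSignatures = 5) {
  stopifnot(is(geneSpace, "GeneSpace"),
            ncol(signatures$profiles) == length(geneSpace))
  cid <- signatures$compound_id
  allIds <- unique(cid)
  counts <- table(cid)[allIds]

  m <- match(allIds, metadata$compound_id)
  noMeta <- is.na(m)
  smiles <- ifelse(noMeta, NA_character_, metadata$smiles[m])
  targets <- metadata$targets[m]
  targets[noMeta] <- list(character())

  noTarget <- !noMeta & lengths(targets) == 0L
  fewSig <- as.integer(counts) < minSignatures
  canon <- rep(NA_character_, length(allIds))
  ok <- !noMeta & !noTarget & !fewSig
  canon[ok] <- vapply(smiles[ok], function(s)
    tryCatch(validateSmiles(s), error = function(e) NA_character_),
    character(1))
  badSmiles <- ok & is.na(canon)
  keep <- ok & !badSmiles

  kept <- allIds[keep]
  profiles <- matrix(0, nrow = length(kept), ncol = length(geneSpace),
                     dimnames = list(kept, geneSpace@genes))
  for (id in kept) {
    rows <- which(cid == id)
    profiles[id, ] <- colMeans(signatures$profiles[rows, , drop = FALSE])
  }

  out <- new("CompoundSet", ids = kept, smiles = canon[keep],
             targets = targets[keep],
             profiles = profiles,
             nSignatures = as.integer(counts)[keep], geneSpace = geneSpace)
  attr(out, "report") <- list(input = length(allIds),
                              no_metadata = sum(noMeta),
                              no_targets = sum(noTarget),
                              too_few_signatures = sum(fewSig & !noMeta),
                              bad_smiles = sum(badSmiles),
                              retained = length(kept))
  out
}

#' Positive pathway labels from target annotations
#'
#' A (compound, pathway) pair is positive exactly when at least one annotated
#' target gene of the compound is a member of the pathway. Compounds with no
#' positive pathway are retained in the set but flagged (attribute
#' \code{"flagged"}): they contribute no supervised signal yet can still be
#' scored at inference.
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param pathways the curated \linkS4class{PathwayCollection}.
#' @return data.frame of labeled pairs with columns \code{compound_id},
#'   \code{pathway_id}, \code{label} (here all \code{"positive"}).
#' @export
assignPositiveLabels <- function(compounds, pathways) {
  stopifnot(is(compounds, "CompoundSet"), is(pathways, "PathwayCollection"))
  sets <- pathwayGenes(pathways)
  rows <- lapply(seq_along(compounds@ids), function(ci) {
    hit <- vapply(sets, function(g) any(compounds@targets[[ci]] %in% g),
                  logical(1))
    if (any(hit))
      data.frame(compound_id = compounds@ids[ci],
                 pathway_id = pathwayIds(pathways)[hit],
                 label = "positive", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compound_id = character(), pathway_id = character(),
                      label = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flagged") <-
    setdiff(compounds@ids, unique(out$compound_id))
  out
}

#' Sample negative pathways for each positive
#'
#' For every compound with \eqn{k} positive pathways, draws \eqn{ratio \cdot k}
#' distinct pathways uniformly at random, without replacement, from the
#' pathways that are not positive for that compound (the per-compound reading
#' of random cross-combination of compounds and pathways), labeled negative.
#' Deterministic given \code{seed}. When fewer than \eqn{ratio \cdot k}
#' non-positive pathways exist, all of them are drawn and a warning is
#' emitted.
#'
#' @param positives data.frame from \code{\link{assignPositiveLabels}}.
#' @param pathways the curated \linkS4class{PathwayCollection}.
#' @param ratio negatives per positive (default 3).
#' @param seed integer RNG seed.
#' @return data.frame of negative pairs (\code{label == "negative"}).
#' @export
sampleNegatives <- function(positives, pathways, ratio = 3, seed) {
  stopifnot(ratio >= 1, is(pathways, "PathwayCollection"))
  allP <- pathwayIds(pathways)
  stopifnot(all(positives$pathway_id %in% allP))
  withr::local_seed(seed)
  byCompound <- split(positives$pathway_id, positives$compound_id)
  # stable order: first appearance in the positives table
  byCompound <- byCompound[unique(positives$compound_id)]
  rows <- lapply(names(byCompound), function(id) {
    pos <- byCompound[[id]]
    pool <- setdiff(allP, pos)
    want <- ratio * length(pos)
    if (length(pool) < want) {
      warning("compound ", id, ": only ", length(pool),
              " non-positive pathways available for ", want, " negatives")
      want <- length(pool)
    }
    data.frame(compound_id = id,
               pathway_id = sample(pool, want, replace = FALSE),
               label = "negative", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(compound_id = character(), pathway_id = character(),
                      label = character(), stringsAsFactors = FALSE)
  out
}

#' Random train/validation/test split of compounds
#'
#' Random permutation of the compound ids under \code{seed}, then contiguous
#' slicing: the train size is the floor of its fraction, the validation size
#' is its fraction rounded to the nearest integer, and the remainder goes to
#' test (under the default 0.8/0.1/0.1 fractions, 2338 compounds give
#' 1870/234/234). The three sets are disjoint and cover all ids.
#'
#' @param compoundIds character vector of compound ids (or a
#'   \linkS4class{CompoundSet}).
#' @param fractions numeric length-3 (train, validation, test), summing to 1.
#' @param seed integer RNG seed.
#' @return list of class \code{gdop_split}: \code{train}, \code{validation},
#'   \code{test} (character vectors) and \code{seed}.
#' @export
splitDataset <- function(compoundIds, fractions = c(0.8, 0.1, 0.1), seed) {
  if (is(compoundIds, "CompoundSet")) compoundIds <- compoundIds@ids
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  n <- length(compoundIds)
  if (n < 3) stop("need at least 3 compounds to split")
  withr::local_seed(seed)
  perm <- sample(compoundIds)
  nTrain <- floor(fractions[1] * n)
  nVal <- min(round(fractions[2] * n), n - nTrain - 1)
  out <- list(train = perm[seq_len(nTrain)],
              validation = perm[nTrain + seq_len(nVal)],
              test = perm[(nTrain + nVal + 1):n],
              seed = seed)
  class(out) <- "gdop_split"
  out
}

#' @export
print.gdop_split <- function(x, ...) {
  cat(sprintf("gdop split (seed %d): train %d / validation %d / test %d\n",
              x$seed, length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}
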