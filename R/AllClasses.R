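#' @import methods
#' @importFrom stats rnorm rbinom runif setNames
#' @importFrom utils read.delim write.table head
NULL

#' Ordered landmark-gene vocabulary
#'
#' A \code{GeneSpace} fixes the ordered set of landmark genes that defines both
#' the node order of the protein-protein-interaction graph and the dimension of
#' every expression profile. The order is fixed for the lifetime of a model; in
#' the L1000 setting this is the 978-gene landmark panel.
#'
#' @slot genes character vector of unique gene symbols, order significant.
#' @export
setClass("GeneSpace", representation(genes = "character"))

setValidity("GeneSpace", function(object) {
  if (length(object@genes) == 0L) return("gene space must be non-empty")
  if (anyDuplicated(object@genes)) return("gene symbols must be unique")
  if (any(is.na(object@genes) | object@genes == "")) return("empty gene symbol")
  TRUE
})

#' @param genes character vector of gene symbols (order preserved, no duplicates).
#' @rdname GeneSpace-class
#' @export
GeneSpace <- function(genes) new("GeneSpace", genes = as.character(genes))

#' @param x a \code{GeneSpace}.
#' @rdname GeneSpace-class
#' @export
setMethod("length", "GeneSpace", function(x) length(x@genes))

#' Gene symbols of an object
#' @param x an object with a gene vocabulary.
#' @param ... unused.
#' @export
setGeneric("geneSymbols", function(x, ...) standardGeneric("geneSymbols"))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "GeneSpace", function(x, ...) x@genes)

setMethod("show", "GeneSpace", function(object) {
  cat("GeneSpace with", length(object@genes), "genes:",
      paste(head(object@genes, 4), collapse = ", "),
      if (length(object@genes) > 4) "..." else "", "\n")
})

#' Curated pathway gene-set collection
#'
#' Ordered collection of pathway gene sets (the prediction label space).
#' Pathway ids are unique; load order is preserved so the pathway index is
#' stable and deterministic.
#'
#' @slot ids character, unique pathway names.
#' @slot descriptions character, free-text descriptions (same length as ids).
#' @slot geneSets list of character vectors of member gene symbols, no
#'   duplicates within a set.
#' @export
setClass("PathwayCollection",
         representation(ids = "character", descriptions = "character",
                        geneSets = "list"))

setValidity("PathwayCollection", function(object) {
  n <- length(object@ids)
  if (length(object@descriptions) != n || length(object@geneSets) != n)
    return("ids, descriptions and geneSets must have equal length")
  if (anyDuplicated(object@ids)) return("pathway ids must be unique")
  if (n > 0 && any(is.na(object@ids) | object@ids == ""))
    return("pathway ids must be non-empty")
  if (any(vapply(object@geneSets, function(g) length(g) == 0L, logical(1))))
    return("every pathway must contain at least one gene")
  if (any(vapply(object@geneSets, anyDuplicated, integer(1)) > 0L))
    return("duplicate genes within a pathway")
  TRUE
})

#' @param ids,descriptions,geneSets parallel vectors/list defining the pathways.
#' @rdname PathwayCollection-class
#' @export
PathwayCollection <- function(ids = character(), descriptions = NULL,
                              geneSets = list()) {
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  new("PathwayCollection", ids = as.character(ids),
      descriptions = as.character(descriptions),
      geneSets = lapply(geneSets, as.character))
}

#' @param x a \code{PathwayCollection}.
#' @rdname PathwayCollection-class
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@ids))

#' Pathway identifiers
#' @param x a \code{PathwayCollection}.
#' @param ... unused.
#' @export
setGeneric("pathwayIds", function(x, ...) standardGeneric("pathwayIds"))

#' @rdname pathwayIds
#' @export
setMethod("pathwayIds", "PathwayCollection", function(x, ...) x@ids)

#' Pathway gene sets
#' @param x a \code{PathwayCollection}.
#' @param ... unused.
#' @return named list of member-gene character vectors.
#' @export
setGeneric("pathwayGenes", function(x, ...) standardGeneric("pathwayGenes"))

#' @rdname pathwayGenes
#' @export
setMethod("pathwayGenes", "PathwayCollection",
          function(x, ...) setNames(x@geneSets, x@ids))

#' @param i index vector (integer, logical or pathway id).
#' @param j,drop,... ignored.
#' @rdname PathwayCollection-class
#' @export
setMethod("[", "PathwayCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("PathwayCollection", ids = x@ids[i], descriptions = x@descriptions[i],
      geneSets = x@geneSets[i])
})

setMethod("show", "PathwayCollection", function(object) {
  sizes <- lengths(object@geneSets)
  cat("PathwayCollection with", length(object@ids), "pathways")
  if (length(object@ids))
    cat(sprintf(" (set sizes %d-%d)", min(sizes), max(sizes)))
  cat("\n")
  if (length(object@ids))
    cat(" ", paste(head(object@ids, 3), collapse = ", "),
        if (length(object@ids) > 3) "..." else "", "\n")
})

#' Score-filtered landmark PPI network
#'
#' Undirected gene-gene interaction graph restricted to a \code{GeneSpace},
#' with interactions kept at or above a confidence score threshold (STRING's
#' combined score, 0-1000 scale) and, by convention of the spectral encoder, a
#' self-connection on every node. Edges are stored once per unordered pair as
#' 1-based node indices into the gene space.
#'
#' @slot geneSpace the node vocabulary and ordering.
#' @slot edges data.frame with columns \code{i}, \code{j} (1-based node
#'   indices, \code{i <= j}) and \code{score} (integer).
#' @slot selfLoops logical, whether every node carries a self-connection.
#' @slot loadReport list of counts describing what the loader dropped.
#' @export
setClass("PPINetwork",
         representation(geneSpace = "GeneSpace", edges = "data.frame",
                        selfLoops = "logical", loadReport = "list"))

setValidity("PPINetwork", function(object) {
  n <- length(object@geneSpace)
  e <- object@edges
  if (!all(c("i", "j", "score") %in% names(e)))
    return("edges must have columns i, j, score")
  if (nrow(e) > 0) {
    if (any(e$i < 1 | e$i > n | e$j < 1 | e$j > n))
      return("edge endpoint outside gene space")
    if (any(e$i > e$j)) return("edges must be stored with i <= j")
    if (anyDuplicated(e[, c("i", "j")])) return("duplicate edge")
  }
  if (object@selfLoops && !all(seq_len(n) %in% e$i[e$i == e$j]))
    return("selfLoops set but some node lacks its self-connection")
  TRUE
})

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "PPINetwork", function(x, ...) x@geneSpace@genes)

#' Number of stored undirected edges (self-connections included)
#' @param x a \code{PPINetwork}.
#' @param ... unused.
#' @export
setGeneric("edgeCount", function(x, ...) standardGeneric("edgeCount"))

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "PPINetwork", function(x, ...) nrow(x@edges))

#' Edge table of a network
#' @param x a \code{PPINetwork}.
#' @param ... unused.
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "PPINetwork", function(x, ...) x@edges)

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork:", length(object@geneSpace), "nodes,",
      nrow(object@edges), "edges",
      if (object@selfLoops) "(including self-connections)" else "", "\n")
  if (length(object@loadReport))
    cat("  load report:",
        paste(names(object@loadReport), unlist(object@loadReport),
              sep = "=", collapse = ", "), "\n")
})

#' Curated compound set
#'
#' One row per compound surviving curation: a parseable structure, annotated
#' target genes, and at least the minimum number of replicate signatures, whose
#' unweighted mean over all plates/doses/times/cell lines forms the compound's
#' profile.
#'
#' @slot ids character compound identifiers, unique.
#' @slot smiles canonical SMILES strings, parallel to ids.
#' @slot targets list of annotated target gene symbol vectors.
#' @slot profiles numeric matrix, compounds x genes, rownames = ids, columns
#'   ordered as the gene space.
#' @slot nSignatures integer vector, number of replicate signatures averaged.
#' @slot geneSpace the profile vocabulary.
#' @export
setClass("CompoundSet",
         representation(ids = "character", smiles = "character",
                        targets = "list", profiles = "matrix",
                        nSignatures = "integer", geneSpace = "GeneSpace"))

setValidity("CompoundSet", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) return("compound ids must be unique")
  if (length(object@smiles) != n || length(object@targets) != n ||
      length(object@nSignatures) != n)
    return("slots out of step with ids")
  if (n > 0 && (nrow(object@profiles) != n ||
                ncol(object@profiles) != length(object@geneSpace)))
    return("profile matrix has wrong shape")
  if (n > 0 && !all(is.finite(object@profiles)))
    return("profiles must be finite")
  TRUE
})

#' @param x a \code{CompoundSet}.
#' @rdname CompoundSet-class
#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' Compound identifiers
#' @param x a \code{CompoundSet}.
#' @param ... unused.
#' @export
setGeneric("compoundIds", function(x, ...) standardGeneric("compoundIds"))

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "CompoundSet", function(x, ...) x@ids)

#' Averaged expression profiles
#' @param x a \code{CompoundSet}.
#' @param ... unused.
#' @return numeric matrix compounds x genes.
#' @export
setGeneric("profileMatrix", function(x, ...) standardGeneric("profileMatrix"))

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "CompoundSet", function(x, ...) x@profiles)

#' Annotated target genes
#' @param x a \code{CompoundSet}.
#' @param ... unused.
#' @export
setGeneric("targetGenes", function(x, ...) standardGeneric("targetGenes"))

#' @rdname targetGenes
#' @export
setMethod("targetGenes", "CompoundSet", function(x, ...)
  setNames(x@targets, x@ids))

#' Compound SMILES strings
#' @param x a \code{CompoundSet}.
#' @param ... unused.
#' @export
setGeneric("compoundSmiles", function(x, ...) standardGeneric("compoundSmiles"))

#' @rdname compoundSmiles
#' @export
setMethod("compoundSmiles", "CompoundSet", function(x, ...)
  setNames(x@smiles, x@ids))

#' @param i index vector (integer, logical or compound id).
#' @param j,drop,... ignored.
#' @rdname CompoundSet-class
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("CompoundSet", ids = x@ids[i], smiles = x@smiles[i],
      targets = x@targets[i],
      profiles = x@profiles[i, , drop = FALSE],
      nSignatures = x@nSignatures[i], geneSpace = x@geneSpace)
})

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet:", length(object@ids), "compounds over",
      length(object@geneSpace), "genes\n")
  if (length(object@ids))
    cat("  signatures per compound:", min(object@nSignatures), "-",
        max(object@nSignatures), "\n")
})
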