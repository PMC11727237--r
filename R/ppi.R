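#' Load a score-filtered PPI edge list onto a gene space
#'
#' Reads a STRING-style tab-separated edge list (columns \code{gene_a},
#' \code{gene_b}, \code{combined_score}, scores on the 0-1000 scale) and keeps
#' the edges whose endpoints are both in \code{geneSpace} and whose combined
#' score is greater than or equal to \code{scoreThreshold} (default 800).
#' Symmetric duplicates collapse to one undirected edge (the maximum score is
#' retained); edges touching unknown genes are silently dropped but counted in
#' the load report. With \code{addSelfLoops} every node receives a
#' self-connection, counted as an edge, as required by the spectral encoder.
#'
#' @param path path to the edge TSV (header \code{gene_a\tgene_b\tcombined_score}).
#' @param geneSpace a \linkS4class{GeneSpace} giving node identity and order.
#' @param scoreThreshold minimum combined score to keep an edge (default 800).
#' @param addSelfLoops add a self-connection on every node (default TRUE).
#' @return a \linkS4class{PPINetwork}.
#' @export
loadPPIEdges <- function(path, geneSpace, scoreThreshold = 800,
                         addSelfLoops = TRUE) {
  stopifnot(is(geneSpace, "GeneSpace"))
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(tab)))
    stop("edge table must have columns ", paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab$combined_score))
  if (anyNA(score) || any(score != floor(score)))
    stop("non-integer combined_score in edge table")
  score <- as.integer(score)

  i <- match(tab$gene_a, geneSpace@genes)
  j <- match(tab$gene_b, geneSpace@genes)
  unknown <- is.na(i) | is.na(j)
  low <- !unknown & score < scoreThreshold
  keep <- !unknown & !low
  report <- list(input = nrow(tab),
                 dropped_unknown_gene = sum(unknown),
                 dropped_low_score = sum(low))

  edges <- data.frame(i = pmin(i[keep], j[keep]),
                      j = pmax(i[keep], j[keep]),
                      score = score[keep])
  edges <- edges[edges$i != edges$j | rep(addSelfLoops, nrow(edges)), ,
                 drop = FALSE]
  if (nrow(edges)) {
    # undirected dedup, keeping the best score seen for a pair
    o <- order(edges$i, edges$j, -edges$score)
    edges <- edges[o, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
  }
  report$deduplicated <- sum(keep) - nrow(edges)

  if (addSelfLoops) {
    have <- edges$i[edges$i == edges$j]
    miss <- setdiff(seq_along(geneSpace@genes), have)
    if (length(miss))
      edges <- rbind(edges, data.frame(i = miss, j = miss,
                                       score = rep(1000L, length(miss))))
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new("PPINetwork", geneSpace = geneSpace, edges = edges,
      selfLoops = addSelfLoops, loadReport = report)
}

#' Symmetric-normalized spectral propagation operator
#'
#' Builds \eqn{S = D^{-1/2} A D^{-1/2}} from the binarized adjacency \eqn{A}
#' of the network (self-connections included; scores are used only for
#' thresholding upstream) with \eqn{D} its degree diagonal. All eigenvalues of
#' \eqn{S} lie in \eqn{[-1, 1]}; a node with only its self-connection maps to
#' a unit row/column. This is the single-hop filter the spectral graph
#' convolutional encoder applies in powers.
#'
#' @param network a \linkS4class{PPINetwork} with self-connections.
#' @return a symmetric sparse \code{Matrix} of side \code{length(geneSpace)}.
#' @export
propagationOperator <- function(network) {
  stopifnot(is(network, "PPINetwork"))
  if (!network@selfLoops)
    stop("propagation operator requires self-connections on every node")
  n <- length(network@geneSpace)
  e <- network@edges
  A <- Matrix::sparseMatrix(i = c(e$i, e$j[e$i != e$j]),
                            j = c(e$j, e$i[e$i != e$j]),
                            x = 1, dims = c(n, n),
                            dimnames = list(network@geneSpace@genes,
                                            network@geneSpace@genes))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) stop("node with zero degree")  # impossible with self-loops
  dinv <- 1 / sqrt(deg)
  S <- Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
  dimnames(S) <- list(network@geneSpace@genes, network@geneSpace@genes)
  methods::as(S, "symmetricMatrix")
}

#' Powers of the propagation operator
#'
#' Precomputes \eqn{X S^k} for \eqn{k = 0, \dots, order} for a batch of
#' profiles; the spectral encoder mixes these with its per-order channel
#' weights. Exposed because training precomputes them once per dataset.
#'
#' @param profiles numeric matrix, compounds x genes (gene order of the
#'   operator).
#' @param operator matrix from \code{\link{propagationOperator}}.
#' @param order highest operator power (filter order), >= 0.
#' @return list of length \code{order + 1} of compounds x genes matrices.
#' @export
operatorPowers <- function(profiles, operator, order) {
  stopifnot(ncol(profiles) == nrow(operator), order >= 0)
  out <- vector("list", order + 1L)
  out[[1L]] <- profiles
  if (order >= 1L)
    for (k in seq_len(order))
      out[[k + 1L]] <- as.matrix(out[[k]] %*% operator)
  out
}
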