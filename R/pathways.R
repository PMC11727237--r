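#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated gene-set format: one set per line, fields
#' \code{name}, \code{description}, then one or more gene symbols. Genes are
#' deduplicated within a set (first occurrence kept); line order is preserved
#' so the pathway index is deterministic. Gene-symbol case is preserved as
#' read; no identifier translation is attempted.
#'
#' @param path path to a GMT file.
#' @return a \linkS4class{PathwayCollection}.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(PathwayCollection())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ", ids[duplicated(ids)][1])
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  PathwayCollection(ids, descs, sets)
}

#' Write a pathway collection to a GMT file
#'
#' Inverse of \code{\link{readGMT}}: re-reading the written file yields an
#' identical collection.
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "PathwayCollection"))
  lines <- mapply(function(id, d, g) paste(c(id, d, g), collapse = "\t"),
                  collection@ids, collection@descriptions,
                  collection@geneSets)
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Curate a pathway label space by size and blacklist
#'
#' Removes large pathways -- those with more than \code{maxGenes} member genes
#' (a 65-gene cap by default, so a 65-gene set is kept and a 66-gene set is
#' excluded) -- because oversized sets describe general biology rather than a
#' specific mechanism of action, plus any pathway on an explicit blacklist of
#' mechanism-unrelated sets (seeded with the cytochrome-P450 substrate
#' grouping). Relative order is preserved and the filter is idempotent.
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param maxGenes maximum member-gene count to retain (default 65).
#' @param blacklist character vector of pathway names to drop; with
#'   \code{substringMatch = TRUE} entries are treated as substrings.
#' @param substringMatch match blacklist entries as fixed substrings of the
#'   pathway id rather than exact names.
#' @return the filtered \linkS4class{PathwayCollection}.
#' @export
filterPathways <- function(collection, maxGenes = 65,
                           blacklist = gdopDefaultBlacklist(),
                           substringMatch = FALSE) {
  stopifnot(is(collection, "PathwayCollection"), maxGenes >= 1)
  if (length(collection) == 0L) return(collection)
  sizes <- lengths(collection@geneSets)
  listed <- if (length(blacklist) == 0L) {
    rep(FALSE, length(collection))
  } else if (substringMatch) {
    Reduce(`|`, lapply(blacklist, function(b)
      grepl(b, collection@ids, fixed = TRUE)))
  } else {
    collection@ids %in% blacklist
  }
  keep <- sizes <= maxGenes & !listed
  collection[which(keep)]
}

#' Default pathway blacklist
#'
#' The one mechanism-unrelated pathway excluded by name from the Reactome
#' label space. Extend via the \code{blacklist} argument of
#' \code{\link{filterPathways}}.
#'
#' @return character vector of pathway names.
#' @export
gdopDefaultBlacklist <- function() {
  "CYTOCHROME_P450_ARRANGED_BY_SUBSTRATE_TYPE"
}
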