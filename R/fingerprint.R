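#' Validate and canonicalize a SMILES string
#'
#' Structure parsability is a curation criterion: compounds whose SMILES fail
#' here are excluded upstream. Validation is two-stage: a strict syntactic
#' check (allowed alphabet, balanced parentheses and brackets, matched
#' ring-closure digits), then a full structure parse and canonicalization via
#' OpenBabel (ChemmineOB). Two SMILES spellings of one molecule map to the
#' same canonical form.
#'
#' @param smiles a SMILES string.
#' @return the canonical SMILES.
#' @export
validateSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("SMILES must be a single non-empty string")
  .smilesSyntaxCheck(smiles)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("[[:space:]].*$", "", out)
  if (!nzchar(out)) stop("SMILES could not be parsed: ", smiles)
  out
}

# Reject strings OpenBabel would silently "repair": unbalanced parentheses or
# bracket atoms, unmatched ring-closure digits, characters outside the SMILES
# alphabet.
.smilesSyntaxCheck <- function(s) {
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\.%*]", s))
    stop("invalid character in SMILES: ", s)
  chars <- strsplit(s, "")[[1]]
  depthP <- cumsum((chars == "(") - (chars == ")"))
  if (any(depthP < 0) || depthP[length(depthP)] != 0)
    stop("unbalanced parentheses in SMILES: ", s)
  depthB <- cumsum((chars == "[") - (chars == "]"))
  if (any(depthB < 0 | depthB > 1) || depthB[length(depthB)] != 0)
    stop("unbalanced brackets in SMILES: ", s)
  # ring-closure tokens outside bracket atoms must pair up
  outside <- chars[depthB == 0]
  plain <- paste(outside, collapse = "")
  plain <- gsub("%[0-9]{2}", "R", plain)        # two-digit closures
  toks <- strsplit(plain, "")[[1]]
  digits <- toks[grepl("[0-9]", toks)]
  if (length(digits) && any(table(digits) %% 2 != 0))
    stop("unmatched ring closure in SMILES: ", s)
  invisible(TRUE)
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Encodes a molecule's 2D structure as a fixed-length binary vector by
#' iterative circular-substructure hashing (the ECFP family): each heavy atom
#' starts from an invariant of (element, heavy degree, implicit hydrogens,
#' ring membership); for each radius step up to \code{radius} the identifier
#' is rehashed with the sorted (bond order, neighbor identifier) pairs, and
#' substructure environments duplicating one already emitted (the same bond
#' set) are discarded. Identifiers are folded modulo \code{nBits} into a bit
#' vector. Deterministic, and invariant to the atom order of the input SMILES
#' because hashing operates on the canonicalized structure. Counts are
#' binarized (bit vector, not count vector). Defaults (radius 2, 2048 bits)
#' are the community-standard ECFP4-equivalent settings.
#'
#' @param smiles a valid SMILES string.
#' @param radius maximum circular-substructure radius (default 2).
#' @param nBits fingerprint length (default 2048).
#' @return object of class \code{gdop_fingerprint}: integer 0/1 vector of
#'   length \code{nBits} with attributes \code{radius} and \code{smiles}
#'   (canonical form).
#' @export
morganFingerprint <- function(smiles, radius = 2, nBits = 2048) {
  stopifnot(radius >= 0, nBits >= 1)
  canon <- validateSmiles(smiles)
  mol <- .parseStructure(canon)
  ids <- .circularIdentifiers(mol, radius)
  bits <- integer(nBits)
  bits[(ids %% nBits) + 1L] <- 1L
  structure(bits, class = "gdop_fingerprint", radius = radius, smiles = canon)
}

#' @export
print.gdop_fingerprint <- function(x, ...) {
  cat(sprintf("Morgan fingerprint: %d bits, radius %d, %d set, SMILES %s\n",
              length(x), attr(x, "radius"), sum(x), attr(x, "smiles")))
  invisible(x)
}

#' Fingerprint matrix for a compound set
#'
#' @param compounds a \linkS4class{CompoundSet} (SMILES already canonical).
#' @param radius,nBits see \code{\link{morganFingerprint}}.
#' @return integer 0/1 matrix, compounds x bits, rownames = compound ids.
#' @export
fingerprintMatrix <- function(compounds, radius = 2, nBits = 2048) {
  stopifnot(is(compounds, "CompoundSet"))
  fps <- lapply(compounds@smiles, morganFingerprint, radius = radius,
                nBits = nBits)
  out <- do.call(rbind, lapply(fps, as.integer))
  rownames(out) <- compounds@ids
  out
}

# canonical SMILES -> list(elements, bonds data.frame(a, b, order))
.parseStructure <- function(canon) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canon))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  if (length(bb) == 0L || is.null(dim(bb)) || nrow(bb) == 0L ||
      ncol(bb) < 3L) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  } else {
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                    Mg = 12, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
                    Ca = 20, Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53)

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)

# order-insensitive deterministic hash of an integer vector (31-ary
# polynomial over the Mersenne prime 2^31 - 1)
.hashInts <- function(v) {
  M <- 2147483647
  h <- 17
  for (x in v) h <- (h * 31 + (x %% M)) %% M
  as.integer(h)
}

# ECFP-style identifier generation with duplicate-environment removal
.circularIdentifiers <- function(mol, radius) {
  n <- length(mol$elements)
  bonds <- mol$bonds
  # ring membership: a bond is in a ring iff it is not a bridge
  inRing <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                     directed = FALSE)
    br <- igraph::bridges(g)
    ringBond <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    inRing[unique(c(bonds$a[ringBond], bonds$b[ringBond]))] <- TRUE
  }
  deg <- tabulate(c(bonds$a, bonds$b), nbins = n)
  bsum <- rep(0L, n)
  for (k in seq_len(nrow(bonds))) {
    o <- bonds$order[k]
    bsum[bonds$a[k]] <- bsum[bonds$a[k]] + o
    bsum[bonds$b[k]] <- bsum[bonds$b[k]] + o
  }
  elemNum <- ifelse(mol$elements %in% names(.ATOMIC_NUMBER),
                    .ATOMIC_NUMBER[mol$elements], 0)
  val <- ifelse(mol$elements %in% names(.DEFAULT_VALENCE),
                .DEFAULT_VALENCE[mol$elements], 0)
  nH <- pmax(0L, as.integer(val) - bsum)

  nbrs <- lapply(seq_len(n), function(i) {
    sel <- bonds$a == i | bonds$b == i
    data.frame(atom = ifelse(bonds$a[sel] == i, bonds$b[sel], bonds$a[sel]),
               order = bonds$order[sel], bond = which(sel))
  })

  id <- vapply(seq_len(n), function(i)
    .hashInts(c(elemNum[i], deg[i], nH[i], as.integer(inRing[i]))),
    integer(1))
  env <- replicate(n, integer(0), simplify = FALSE)
  features <- id
  seenEnvs <- character(0)

  for (r in seq_len(radius)) {
    if (n == 0L || nrow(bonds) == 0L) break
    newId <- id
    newEnv <- env
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (nrow(nb) == 0L) next
      ord <- order(nb$order, id[nb$atom])
      newId[i] <- .hashInts(c(r, id[i],
                              rbind(nb$order[ord], id[nb$atom[ord]])))
      newEnv[[i]] <- sort(unique(c(env[[i]], nb$bond,
                                   unlist(env[nb$atom]))))
    }
    grew <- which(vapply(seq_len(n), function(i)
      length(newEnv[[i]]) > length(env[[i]]), logical(1)))
    keys <- vapply(newEnv, function(e) paste(e, collapse = ","), character(1))
    for (key in unique(keys[grew])) {
      if (key %in% seenEnvs) next
      cand <- grew[keys[grew] == key]
      features <- c(features, min(newId[cand]))
      seenEnvs <- c(seenEnvs, key)
    }
    id <- newId
    env <- newEnv
  }
  unique(features)
}
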