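# in-code fixtures shared across test files

writeTempGMT <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

writeTempEdges <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# PPINetwork straight from a 0/1 adjacency matrix (no self-loops in A)
netFromAdj <- function(A, selfLoops = TRUE) {
  n <- nrow(A)
  gs <- GeneSpace(paste0("G", seq_len(n)))
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      score = rep(900L, nrow(idx)))
  if (selfLoops)
    edges <- rbind(edges, data.frame(i = seq_len(n), j = seq_len(n),
                                     score = 1000L))
  edges <- edges[order(edges$i, edges$j), ]
  new("PPINetwork", geneSpace = gs, edges = edges, selfLoops = selfLoops,
      loadReport = list())
}

randomAdj <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# independent dense oracle for the spectral encoder: explicit loops, dense
# matrix powers, no shared code with sgcnEncode/operatorPowers
denseSgcnOracle <- function(X, S, W) {
  S <- as.matrix(S)
  G <- ncol(X); C <- ncol(W); K <- nrow(W) - 1
  out <- matrix(0, nrow(X), G * C)
  for (b in seq_len(nrow(X))) {
    for (cc in seq_len(C)) {
      acc <- numeric(G)
      Sk <- diag(G)
      for (k in 0:K) {
        acc <- acc + as.numeric(Sk %*% X[b, ]) * W[k + 1, cc]
        Sk <- Sk %*% S
      }
      out[b, (cc - 1) * G + seq_len(G)] <- pmax(acc, 0)
    }
  }
  out
}

# minimal labeled-data setup around an 8-gene chain graph
tinyTrainingData <- function(nCompounds = 6, nPathways = 5, seed = 2,
                             nBits = 32) {
  set.seed(seed)
  gs <- GeneSpace(paste0("G", 1:8))
  A <- matrix(0, 8, 8)
  for (i in 1:7) A[i, i + 1] <- A[i + 1, i] <- 1
  net <- netFromAdj(A)
  ids <- paste0("C", seq_len(nCompounds))
  X <- matrix(rnorm(nCompounds * 8), nCompounds, 8,
              dimnames = list(ids, geneSymbols(gs)))
  FP <- matrix(rbinom(nCompounds * nBits, 1, 0.3), nCompounds, nBits,
               dimnames = list(ids, NULL))
  pw <- paste0("PW", seq_len(nPathways))
  pairs <- do.call(rbind, lapply(ids, function(id)
    data.frame(compound_id = id,
               pathway_id = sample(pw, 2),
               label = c("positive", "negative"))))
  split <- structure(list(train = ids[1:(nCompounds - 2)],
                          validation = ids[nCompounds - 1],
                          test = ids[nCompounds], seed = seed),
                     class = "gdop_split")
  list(gs = gs, operator = propagationOperator(net), X = X, FP = FP,
       pairs = pairs, split = split, pathwayIds = pw)
}
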