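test_that("config validation catches inconsistent dropout lists", {
  default <- gdopConfig()
  expect_identical(default$denseWidths, c(4096L, 3016L, 2048L, 1024L))
  expect_identical(default$dropoutRates, c(0.2, 0.5, 0.5, 0.5, 0.2))
  # four dense layers need five rates (the sGCN layer is included)
  expect_error(gdopConfig(dropoutRates = c(0.5, 0.5, 0.5, 0.2)),
               "length")
  expect_error(gdopConfig(dropoutRates = c(0.2, 0.5, 0.5, 0.5, 1.0)),
               "\\[0, 1\\)")
})

test_that("initialization is seeded and shape-consistent", {
  gs <- GeneSpace(paste0("G", 1:8))
  cfg <- gdopConfig(sgcnChannels = 2, denseWidths = c(16, 12, 8, 6),
                    seed = 3)
  m1 <- initGdopModel(cfg, gs, paste0("PW", 1:5), nBits = 32)
  m2 <- initGdopModel(cfg, gs, paste0("PW", 1:5), nBits = 32)
  expect_identical(m1@weights, m2@weights)
  expect_identical(dim(m1@weights$W1), c(8L * 2L + 32L, 16L))
  expect_identical(dim(m1@weights$Wout), c(6L, 5L))
  expect_error(initGdopModel(cfg, gs, "PW1", nBits = 32), "at least 2")
})

test_that("sGCN encoding reduces to the profile on a single node", {
  gs <- GeneSpace("G1")
  cfg <- gdopConfig(sgcnChannels = 1, sgcnOrder = 1,
                    denseWidths = c(4, 3, 2, 2))
  m <- initGdopModel(cfg, gs, c("A", "B"), nBits = 4)
  m@weights$sgcn <- matrix(c(1, 0), 2, 1)   # W0 = 1, W1 = 0
  S <- Matrix::Matrix(1, 1, 1)
  for (x in c(-2, 0.7)) {
    expect_equal(as.numeric(sgcnEncode(m, x, S)), max(0, x))
  }
})

test_that("sGCN encoding equals the dense spectral oracle", {
  set.seed(21)
  gs15 <- GeneSpace(paste0("G", 1:15))
  S <- propagationOperator(netFromAdj(randomAdj(15)))
  cfg <- gdopConfig(sgcnChannels = 3, sgcnOrder = 2,
                    denseWidths = c(8, 6, 4, 4))
  m <- initGdopModel(cfg, gs15, paste0("PW", 1:4), nBits = 8, seed = 7)
  X <- matrix(rnorm(5 * 15), 5, 15)
  expect_equal(sgcnEncode(m, X, S),
               denseSgcnOracle(X, S, m@weights$sgcn), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("sGCN encoding is permutation-equivariant", {
  set.seed(22)
  n <- 12
  A <- randomAdj(n)
  perm <- sample(n)
  P <- diag(n)[perm, ]
  gs <- GeneSpace(paste0("G", 1:n))
  cfg <- gdopConfig(sgcnChannels = 2, sgcnOrder = 1,
                    denseWidths = c(8, 6, 4, 4))
  m <- initGdopModel(cfg, gs, paste0("PW", 1:3), nBits = 8, seed = 9)
  x <- rnorm(n)
  S <- propagationOperator(netFromAdj(A))
  Sp <- propagationOperator(netFromAdj(P %*% A %*% t(P)))
  z <- sgcnEncode(m, x, S)
  zp <- sgcnEncode(m, as.numeric(P %*% x), Sp)
  # permuting genes permutes the latent within each channel block
  C <- 2
  for (cc in seq_len(C)) {
    blk <- (cc - 1) * n + seq_len(n)
    expect_equal(zp[1, blk], as.numeric(P %*% z[1, blk]),
                 tolerance = 1e-10)
  }
})

test_that("forward pass: zero head gives 0.5 and inference is deterministic", {
  td <- tinyTrainingData()
  cfg <- gdopConfig(sgcnChannels = 2, denseWidths = c(16, 12, 8, 6), seed = 5)
  m <- initGdopModel(cfg, td$gs, td$pathwayIds, nBits = 32)
  z <- sgcnEncode(m, td$X, td$operator)
  m0 <- m
  m0@weights$Wout <- m0@weights$Wout * 0
  m0@weights$bout <- m0@weights$bout * 0
  expect_equal(unname(gdopForward(m0, z, td$FP)),
               matrix(0.5, nrow(td$X), 5), tolerance = 1e-12)
  s1 <- gdopForward(m, z, td$FP, training = FALSE)
  s2 <- gdopForward(m, z, td$FP, training = FALSE)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("forward pass matches a hand-computed toy network", {
  gs <- GeneSpace(c("GA", "GB"))
  cfg <- gdopConfig(sgcnChannels = 1, sgcnOrder = 0,
                    denseWidths = 2, dropoutRates = c(0, 0))
  m <- initGdopModel(cfg, gs, c("P1", "P2"), nBits = 1)
  m@weights$sgcn <- matrix(1, 1, 1)
  m@weights$W1 <- rbind(c(1, 0), c(0, 1), c(0.5, -0.5))  # 2 genes + 1 fp bit
  m@weights$b1 <- c(0.1, -0.1)
  m@weights$Wout <- rbind(c(1, -1), c(2, 0))
  m@weights$bout <- c(0, 0.3)
  S <- Matrix::Diagonal(2)
  x <- c(0.4, -0.6); fp <- 1
  z <- pmax(x, 0)                                  # sGCN identity + ReLU
  h <- as.numeric(c(z, fp) %*% m@weights$W1) + m@weights$b1  # last dense: linear
  logits <- as.numeric(h %*% m@weights$Wout) + m@weights$bout
  expect_equal(as.numeric(gdopForward(m, sgcnEncode(m, x, S), fp)),
               1 / (1 + exp(-logits)), tolerance = 1e-8)
})

test_that("masked cross entropy is exact at 0.5 and ignores unlabeled scores", {
  scores <- matrix(0.5, 3, 4, dimnames = list(paste0("c", 1:3),
                                              paste0("P", 1:4)))
  pairs <- data.frame(compound_id = c("c1", "c1", "c2"),
                      pathway_id = c("P1", "P2", "P3"),
                      label = c("positive", "negative", "positive"))
  expect_equal(maskedCrossEntropy(scores, pairs), log(2), tolerance = 1e-9)

  set.seed(3)
  scores2 <- matrix(runif(12), 3, 4, dimnames = dimnames(scores))
  base <- maskedCrossEntropy(scores2, pairs)
  perturbed <- scores2
  perturbed["c3", ] <- runif(4)       # c3 has no labeled pairs
  perturbed["c1", "P4"] <- 0.99       # unlabeled pathway for c1
  expect_identical(maskedCrossEntropy(perturbed, pairs), base)

  eps <- 1e-9
  sharp <- scores2
  sharp[cbind(c(1, 2), c(1, 3))] <- 1 - eps
  sharp[1, 2] <- eps
  expect_lt(maskedCrossEntropy(sharp, pairs), 1e-8)
  expect_error(maskedCrossEntropy(scores, pairs[0, ]), "no labeled pairs")
})

test_that("training returns the best-validation checkpoint within patience", {
  td <- tinyTrainingData(nCompounds = 8)
  cfg <- gdopConfig(sgcnChannels = 2, denseWidths = c(16, 12, 8, 6),
                    learningRate = 5e-3, maxEpochs = 40, patience = 5,
                    batchSize = 4, seed = 5)
  m <- initGdopModel(cfg, td$gs, td$pathwayIds, nBits = 32)
  tm <- trainGdop(m, td$X, td$FP, td$pairs, td$split, td$operator)
  h <- tm@history
  expect_lte(nrow(h), 40L)
  best <- which.min(h$val_loss)
  # stopped no later than patience epochs after the best epoch
  expect_lte(nrow(h) - best, 5L)
  # returned weights reproduce the best validation loss
  valIds <- td$split$validation
  z <- sgcnEncode(tm, td$X[valIds, , drop = FALSE], td$operator)
  s <- gdopForward(tm, z, td$FP[valIds, , drop = FALSE])
  rownames(s) <- valIds
  vp <- td$pairs[td$pairs$compound_id %in% valIds, ]
  expect_equal(maskedCrossEntropy(s, vp), min(h$val_loss), tolerance = 1e-10)
  expect_true(tm@trained)
})

test_that("training is reproducible and checkpoints reload bit-identically", {
  td <- tinyTrainingData(nCompounds = 8)
  cfg <- gdopConfig(sgcnChannels = 2, denseWidths = c(16, 12, 8, 6),
                    learningRate = 5e-3, maxEpochs = 10, patience = 5,
                    batchSize = 4, seed = 5)
  m <- initGdopModel(cfg, td$gs, td$pathwayIds, nBits = 32)
  t1 <- trainGdop(m, td$X, td$FP, td$pairs, td$split, td$operator)
  t2 <- trainGdop(m, td$X, td$FP, td$pairs, td$split, td$operator)
  expect_identical(t1@history, t2@history)
  expect_identical(t1@weights, t2@weights)

  path <- withr::local_tempfile(fileext = ".rds")
  saveGdopModel(t1, path)
  reloaded <- loadGdopModel(path)
  r1 <- predictRank(t1, td$X[1, ], td$FP[1, ], td$operator)
  r2 <- predictRank(reloaded, td$X[1, ], td$FP[1, ], td$operator)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$pathway_id, r2$pathway_id)
})

test_that("rankings are complete, sorted, and tie-break by pathway index", {
  td <- tinyTrainingData()
  cfg <- gdopConfig(sgcnChannels = 2, denseWidths = c(16, 12, 8, 6), seed = 5)
  m <- initGdopModel(cfg, td$gs, td$pathwayIds, nBits = 32)
  m@trained <- TRUE

  # all-zero head: every score ties at 0.5 -> ranking follows pathway index
  m0 <- m
  m0@weights$Wout <- m0@weights$Wout * 0
  m0@weights$bout <- m0@weights$bout * 0
  r0 <- predictRank(m0, td$X[1, ], td$FP[1, ], td$operator)
  expect_identical(r0$pathway_id, td$pathwayIds)

  r <- predictRank(m, td$X[1, ], td$FP[1, ], td$operator)
  expect_setequal(r$pathway_id, td$pathwayIds)
  expect_true(all(diff(r$score) <= 0))
  # brute-force rank: 1 + strictly-greater count + earlier-index ties
  scores <- setNames(r$score[match(td$pathwayIds, r$pathway_id)],
                     td$pathwayIds)
  for (p in td$pathwayIds) {
    idx <- match(p, td$pathwayIds)
    expected <- 1 + sum(scores > scores[p]) +
      sum(scores == scores[p] & seq_along(scores) < idx)
    expect_identical(r$rank[match(p, r$pathway_id)], as.integer(expected))
  }

  mUntrained <- initGdopModel(cfg, td$gs, td$pathwayIds, nBits = 32)
  expect_error(predictRank(mUntrained, td$X[1, ], td$FP[1, ], td$operator),
               "trained")
})

test_that("top-N accuracy counts compounds with a hit in the top N", {
  mkRanking <- function(order) {
    r <- data.frame(rank = seq_along(order), pathway_id = order,
                    score = rev(seq_along(order)) / length(order))
    class(r) <- c("gdop_ranking", class(r))
    r
  }
  pw <- paste0("P", 1:6)
  rankings <- list(a = mkRanking(pw),                 # P1 first
                   b = mkRanking(rev(pw)),            # P1 last
                   c = mkRanking(pw[c(2, 3, 1, 4, 5, 6)]),
                   d = mkRanking(pw[c(4, 5, 6, 1, 2, 3)]))
  positives <- list(a = "P1", b = "P1", c = "P1", d = "P1")
  expect_equal(topNAccuracy(rankings, positives, n = 1)$accuracy, 0.25)
  expect_equal(topNAccuracy(rankings, positives, n = 3)$accuracy, 0.5)
  expect_equal(topNAccuracy(rankings, positives, n = 6)$accuracy, 1)
  acc <- topNAccuracy(rankings, positives, n = c(1, 2, 3, 6))$accuracy
  expect_true(all(diff(acc) >= 0))
  expect_error(topNAccuracy(rankings["a"], positives, n = 1), "missing")
  expect_error(topNAccuracy(rankings, list(a = character()), n = 1),
               "at least one")
})
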