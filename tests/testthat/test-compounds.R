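# direct in-memory signature/metadata builders
sigList <- function(gs, compound, profilesByRow) {
  n <- length(profilesByRow)
  list(profiles = do.call(rbind, profilesByRow),
       compound_id = rep(compound, n),
       meta = data.frame(signature_id = paste0(compound, "_s", seq_len(n)),
                         plate = "PL1", dose = "1uM", time = "6h",
                         cell_line = "A375"))
}

combineSigs <- function(...) {
  parts <- list(...)
  list(profiles = do.call(rbind, lapply(parts, `[[`, "profiles")),
       compound_id = unlist(lapply(parts, `[[`, "compound_id")),
       meta = do.call(rbind, lapply(parts, `[[`, "meta")))
}

gs2 <- GeneSpace(c("GA", "GB"))
meta3 <- data.frame(compound_id = c("c4", "c5", "cbad"),
                    smiles = c("CCO", "CCN", "C1CC"))
meta3$targets <- list("GA", "GB", "GA")

test_that("curation enforces the 5-signature boundary and SMILES parsability", {
  sigs <- combineSigs(
    sigList(gs2, "c4", replicate(4, c(0, 0), simplify = FALSE)),
    sigList(gs2, "c5", replicate(5, c(1, 1), simplify = FALSE)),
    sigList(gs2, "cbad", replicate(6, c(2, 2), simplify = FALSE)))
  out <- curateCompounds(sigs, meta3, gs2)
  expect_identical(compoundIds(out), "c5")     # 4 sigs out, 5 in, bad SMILES out
  rep <- attr(out, "report")
  expect_identical(rep$too_few_signatures, 1L)
  expect_identical(rep$bad_smiles, 1L)
  expect_identical(out@nSignatures, 5L)
})

test_that("profiles average over all signatures ignoring metadata", {
  sigs <- sigList(gs2, "cmp", list(c(1, 3), c(3, 5)))
  sigs$compound_id <- rep("cmp", 2)
  sigs$meta$dose <- c("0.1uM", "10uM")   # different doses still pooled
  sigs$profiles <- rbind(sigs$profiles, sigs$profiles[0, ])
  meta <- data.frame(compound_id = "cmp", smiles = "CCO")
  meta$targets <- list("GA")
  out <- curateCompounds(sigs, meta, gs2, minSignatures = 2)
  expect_equal(unname(profileMatrix(out)[1, ]), c(2, 4))

  # order invariance
  sigsRev <- sigs
  sigsRev$profiles <- sigs$profiles[2:1, ]
  outRev <- curateCompounds(sigsRev, meta, gs2, minSignatures = 2)
  expect_equal(profileMatrix(out), profileMatrix(outRev))
})

test_that("compounds missing from metadata are excluded and reported", {
  sigs <- sigList(gs2, "ghost", replicate(5, c(0, 0), simplify = FALSE))
  meta <- data.frame(compound_id = character(), smiles = character())
  meta$targets <- list()
  out <- curateCompounds(sigs, meta, gs2)
  expect_length(out, 0L)
  expect_identical(attr(out, "report")$no_metadata, 1L)
})

test_that("positive labels come from target-pathway gene overlap", {
  gs <- GeneSpace(paste0("G", 1:9))
  pw <- PathwayCollection(c("P1", "P2", "P3"),
                          geneSets = list(c("G1", "G2"), c("G2", "G5"),
                                          c("G7")))
  cs <- new("CompoundSet", ids = c("a", "b", "c"),
            smiles = rep("CCO", 3),
            targets = list("G1", c("G1", "G2"), "G9"),
            profiles = matrix(0, 3, 9,
                              dimnames = list(c("a", "b", "c"),
                                              geneSymbols(gs))),
            nSignatures = rep(5L, 3), geneSpace = gs)
  pos <- assignPositiveLabels(cs, pw)
  # brute force over every (compound, pathway) pair
  expected <- expand.grid(compound_id = c("a", "b", "c"),
                          pathway_id = c("P1", "P2", "P3"),
                          stringsAsFactors = FALSE)
  hit <- mapply(function(ci, pi)
    length(intersect(cs@targets[[match(ci, cs@ids)]],
                     pathwayGenes(pw)[[pi]])) > 0,
    expected$compound_id, expected$pathway_id)
  got <- paste(pos$compound_id, pos$pathway_id)
  expect_setequal(got, paste(expected$compound_id,
                             expected$pathway_id)[hit])
  expect_true(all(pos$label == "positive"))
  expect_identical(attr(pos, "flagged"), "c")   # G9 in no pathway
})

test_that("negative sampling is 3:1, disjoint from positives, seeded", {
  pw <- PathwayCollection(paste0("P", 1:30),
                          geneSets = replicate(30, "G1", simplify = FALSE))
  pos <- data.frame(compound_id = rep(paste0("c", 1:10), each = 2),
                    pathway_id = rep(c("P1", "P2"), 10),
                    label = "positive")
  neg <- sampleNegatives(pos, pw, ratio = 3, seed = 99)
  expect_identical(nrow(neg), 60L)
  expect_true(all(neg$label == "negative"))
  for (id in unique(pos$compound_id)) {
    mine <- neg$pathway_id[neg$compound_id == id]
    expect_length(mine, 6L)                      # 3 per positive
    expect_identical(anyDuplicated(mine), 0L)    # without replacement
    expect_length(intersect(mine, c("P1", "P2")), 0L)
  }
  expect_identical(sampleNegatives(pos, pw, ratio = 3, seed = 99), neg)
  expect_false(identical(sampleNegatives(pos, pw, ratio = 3, seed = 100),
                         neg))
})

test_that("negative sampling caps at the available pool with a warning", {
  pw <- PathwayCollection(paste0("P", 1:3),
                          geneSets = replicate(3, "G1", simplify = FALSE))
  pos <- data.frame(compound_id = "c1", pathway_id = "P1",
                    label = "positive")
  expect_warning(neg <- sampleNegatives(pos, pw, ratio = 3, seed = 1),
                 "non-positive")
  expect_identical(sort(neg$pathway_id), c("P2", "P3"))
})

test_that("splits are deterministic, disjoint, covering, correctly sized", {
  ids <- paste0("c", 1:10)
  sp <- splitDataset(ids, seed = 5)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 8L, validation = 1L, test = 1L))
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_identical(splitDataset(ids, seed = 5), sp)
  expect_false(identical(splitDataset(ids, seed = 6)$train, sp$train))
  expect_error(splitDataset(ids[1:2], seed = 1), "at least 3")

  # the published cohort proportions: 2338 compounds -> 1870/234/234
  big <- splitDataset(paste0("c", 1:2338), seed = 1)
  expect_identical(lengths(big[c("train", "validation", "test")]),
                   c(train = 1870L, validation = 234L, test = 234L))
})
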