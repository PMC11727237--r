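#' Model configuration
#'
#' Architecture and optimization settings for the on-target pathway predictor.
#' The spectral graph-convolutional encoder mixes operator powers
#' \eqn{S^0 \dots S^{sgcnOrder}} of a compound's profile into
#' \code{sgcnChannels} per-gene channels; the flattened, ReLU-activated latent
#' vector is concatenated with the Morgan fingerprint and passed through four
#' dense layers (default widths 4096, 3016, 2048, 1024; ReLU on every layer
#' except the last dense layer) to a linear output head with a per-pathway
#' sigmoid. Dropout rates map in order to (sGCN, dense1..dense4) and default
#' to 0.2, 0.5, 0.5, 0.5, 0.2. Training minimizes the mean binary cross
#' entropy over the labeled (positive + sampled-negative) pairs only, with
#' Adam, stopping early when the validation loss has not improved for
#' \code{patience} successive epochs.
#'
#' @param sgcnChannels output channels of the spectral encoder (default 4).
#' @param sgcnOrder highest operator power in the filter (default 1, i.e. one
#'   application of the normalized operator plus the identity term).
#' @param denseWidths widths of the dense stack (default
#'   \code{c(4096, 3016, 2048, 1024)}).
#' @param dropoutRates length \code{length(denseWidths) + 1}; first entry is
#'   the sGCN layer.
#' @param learningRate Adam step size (default 1e-4).
#' @param beta1,beta2,epsilon Adam moment decay and stabilizer constants.
#' @param maxEpochs hard epoch cap (default 100).
#' @param patience early-stopping patience in epochs on the validation loss
#'   (default 10).
#' @param batchSize compounds per minibatch (default 32); a compound's
#'   sampled negatives travel with its positives.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return list of class \code{gdop_config}.
#' @export
gdopConfig <- function(sgcnChannels = 4, sgcnOrder = 1,
                       denseWidths = c(4096, 3016, 2048, 1024),
                       dropoutRates = c(0.2, 0.5, 0.5, 0.5, 0.2),
                       learningRate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, maxEpochs = 100, patience = 10,
                       batchSize = 32, seed = 1) {
  if (length(dropoutRates) != length(denseWidths) + 1)
    stop("dropoutRates must have length(denseWidths) + 1 entries ",
         "(the first one is the sGCN layer)")
  if (any(dropoutRates < 0 | dropoutRates >= 1))
    stop("dropout rates must lie in [0, 1)")
  stopifnot(sgcnChannels >= 1, sgcnOrder >= 0, length(denseWidths) >= 1,
            learningRate > 0, patience >= 1, batchSize >= 1)
  structure(list(sgcnChannels = as.integer(sgcnChannels),
                 sgcnOrder = as.integer(sgcnOrder),
                 denseWidths = as.integer(denseWidths),
                 dropoutRates = as.numeric(dropoutRates),
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "gdop_config")
}

#' Trained or initialized predictor state
#'
#' Holds the spectral-encoder mixing weights, the dense-stack weights and
#' biases, the output head, and the gene space and pathway index the shapes
#' are tied to. Serializable with \code{\link{saveGdopModel}}; reloading
#' reproduces predictions bit-identically.
#'
#' @slot config a \code{gdop_config} list.
#' @slot geneSpace the \linkS4class{GeneSpace} profiles must match.
#' @slot pathwayIds ordered pathway label space.
#' @slot nBits fingerprint width the input layer expects.
#' @slot weights named list: \code{sgcn} ((order+1) x channels), then
#'   \code{W1..Wk, b1..bk, Wout, bout}.
#' @slot trained logical.
#' @slot history data.frame of per-epoch train/validation losses.
#' @export
setClass("GdopModel",
         representation(config = "list", geneSpace = "GeneSpace",
                        pathwayIds = "character", nBits = "integer",
                        weights = "list", trained = "logical",
                        history = "data.frame"))

setValidity("GdopModel", function(object) {
  cfg <- object@config
  w <- object@weights
  if (!all(dim(w$sgcn) == c(cfg$sgcnOrder + 1L, cfg$sgcnChannels)))
    return("sgcn weight shape inconsistent with config")
  inWidth <- length(object@geneSpace) * cfg$sgcnChannels + object@nBits
  widths <- c(inWidth, cfg$denseWidths)
  for (l in seq_along(cfg$denseWidths)) {
    if (!all(dim(w[[paste0("W", l)]]) == widths[c(l, l + 1)]))
      return(paste0("dense layer ", l, " weight shape mismatch"))
  }
  if (!all(dim(w$Wout) == c(widths[length(widths)],
                            length(object@pathwayIds))))
    return("output layer shape mismatch")
  TRUE
})

setMethod("show", "GdopModel", function(object) {
  cfg <- object@config
  cat("GdopModel:", if (object@trained) "trained" else "initialized", "\n")
  cat(sprintf("  sGCN: %d channel(s), filter order %d over %d genes\n",
              cfg$sgcnChannels, cfg$sgcnOrder, length(object@geneSpace)))
  cat(sprintf("  dense stack: %s -> %d pathways (fingerprint %d bits)\n",
              paste(cfg$denseWidths, collapse = "-"),
              length(object@pathwayIds), object@nBits))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s); best validation loss %.4f\n",
                nrow(object@history), min(object@history$val_loss)))
})

#' Initialize a predictor
#'
#' He-scaled Gaussian initialization of all weights, deterministic under
#' \code{seed}.
#'
#' @param config a \code{\link{gdopConfig}}.
#' @param geneSpace the profile \linkS4class{GeneSpace}.
#' @param pathwayIds ordered pathway label space (>= 2 pathways).
#' @param nBits fingerprint width (default 2048).
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return an untrained \linkS4class{GdopModel}.
#' @export
initGdopModel <- function(config, geneSpace, pathwayIds, nBits = 2048,
                          seed = config$seed) {
  stopifnot(inherits(config, "gdop_config"), is(geneSpace, "GeneSpace"))
  if (length(pathwayIds) < 2) stop("need at least 2 pathways")
  withr::local_seed(seed)
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  w <- list(sgcn = he(config$sgcnOrder + 1L, config$sgcnChannels))
  widths <- c(length(geneSpace) * config$sgcnChannels + nBits,
              config$denseWidths)
  for (l in seq_along(config$denseWidths)) {
    w[[paste0("W", l)]] <- he(widths[l], widths[l + 1])
    w[[paste0("b", l)]] <- numeric(widths[l + 1])
  }
  w$Wout <- he(widths[length(widths)], length(pathwayIds))
  w$bout <- numeric(length(pathwayIds))
  new("GdopModel", config = unclass(config), geneSpace = geneSpace,
      pathwayIds = as.character(pathwayIds), nBits = as.integer(nBits),
      weights = w, trained = FALSE,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()))
}

# inverted-dropout mask; all-ones at rate 0 or at inference
.dropMask <- function(nr, nc, rate, training) {
  if (!training || rate == 0) return(NULL)
  matrix(rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

.applyMask <- function(x, mask) if (is.null(mask)) x else x * mask

#' Spectral graph-convolutional encoding of expression profiles
#'
#' Computes the biological latent vectors: for a batch of profiles \eqn{X}
#' (compounds x genes) over propagation operator \eqn{S},
#' \deqn{Z = ReLU(\sum_{k=0}^{K} S^k X^T W_k)}
#' with one scalar mixing weight per (power, channel); the latent vector is
#' the node-by-channel activation flattened gene-major within each channel
#' block, so the dense stack sees gene-resolved features. Dropout at the sGCN
#' rate applies in training mode only.
#'
#' @param model a \linkS4class{GdopModel}.
#' @param profiles numeric matrix (compounds x genes) or a single profile
#'   vector, in the gene order of the model's gene space.
#' @param operator matrix from \code{\link{propagationOperator}}.
#' @param training apply dropout (default FALSE).
#' @return matrix compounds x (genes * channels).
#' @export
sgcnEncode <- function(model, profiles, operator, training = FALSE) {
  stopifnot(is(model, "GdopModel"))
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (ncol(profiles) != length(model@geneSpace))
    stop("profile length does not match the model's gene space")
  powers <- operatorPowers(profiles, operator, model@config$sgcnOrder)
  .sgcnForward(model@weights$sgcn, powers,
               model@config$dropoutRates[1], training)$z
}

# powers: list of X S^k matrices. Returns pre-activation, activation mask info.
.sgcnForward <- function(Wsgcn, powers, rate, training) {
  B <- nrow(powers[[1]]); G <- ncol(powers[[1]]); C <- ncol(Wsgcn)
  pre <- matrix(0, B, G * C)
  for (c in seq_len(C)) {
    acc <- matrix(0, B, G)
    for (k in seq_along(powers)) acc <- acc + powers[[k]] * Wsgcn[k, c]
    pre[, (c - 1L) * G + seq_len(G)] <- acc
  }
  act <- pmax(pre, 0)
  mask <- .dropMask(B, ncol(act), rate, training)
  list(pre = pre, z = .applyMask(act, mask), mask = mask)
}

#' Forward pass of the dense head
#'
#' Concatenates latent vectors with fingerprints and applies the dense stack
#' (ReLU on every dense layer except the last), per-layer dropout in training
#' mode, then the linear output head with a per-pathway sigmoid, giving scores
#' in (0, 1). Inference (training = FALSE) is deterministic.
#'
#' @param model a \linkS4class{GdopModel}.
#' @param latent matrix compounds x (genes * channels) from
#'   \code{\link{sgcnEncode}}.
#' @param fingerprints 0/1 matrix compounds x nBits (or a single fingerprint).
#' @param training apply dropout (default FALSE).
#' @return score matrix compounds x pathways, columns named by pathway id.
#' @export
gdopForward <- function(model, latent, fingerprints, training = FALSE) {
  stopifnot(is(model, "GdopModel"))
  if (is.null(dim(latent))) latent <- matrix(latent, nrow = 1)
  if (is.null(dim(fingerprints))) fingerprints <- matrix(as.integer(fingerprints),
                                                         nrow = 1)
  if (ncol(fingerprints) != model@nBits)
    stop("fingerprint width does not match the model")
  u <- cbind(latent, fingerprints)
  .denseForward(model, u, training)$scores
}

.denseForward <- function(model, u, training) {
  cfg <- model@config
  w <- model@weights
  L <- length(cfg$denseWidths)
  hs <- vector("list", L)      # post-dropout activations
  pres <- vector("list", L)    # pre-activations
  masks <- vector("list", L)
  h <- u
  for (l in seq_len(L)) {
    pre <- sweep(h %*% w[[paste0("W", l)]], 2, w[[paste0("b", l)]], `+`)
    act <- if (l < L) pmax(pre, 0) else pre   # no ReLU on the last dense layer
    masks[l] <- list(.dropMask(nrow(act), ncol(act), cfg$dropoutRates[l + 1],
                               training))
    h <- .applyMask(act, masks[[l]])
    pres[[l]] <- pre
    hs[[l]] <- h
  }
  logits <- sweep(h %*% w$Wout, 2, w$bout, `+`)
  scores <- 1 / (1 + exp(-logits))
  colnames(scores) <- model@pathwayIds
  list(scores = scores, logits = logits, u = u, pres = pres, hs = hs,
       masks = masks)
}

#' Masked binary cross entropy over labeled pairs
#'
#' Mean binary cross entropy over the labeled (positive and sampled-negative)
#' compound-pathway pairs only; scores of unlabeled pathways contribute
#' nothing. At uniform scores of 0.5 the loss equals \eqn{\ln 2} exactly.
#'
#' @param scores matrix compounds x pathways with compound-id rownames and
#'   pathway-id colnames.
#' @param pairs data.frame with columns \code{compound_id}, \code{pathway_id},
#'   \code{label} in \code{c("positive", "negative")}.
#' @return scalar loss.
#' @export
maskedCrossEntropy <- function(scores, pairs) {
  if (nrow(pairs) == 0L) stop("no labeled pairs")
  ri <- match(pairs$compound_id, rownames(scores))
  ci <- match(pairs$pathway_id, colnames(scores))
  if (anyNA(ri) || anyNA(ci))
    stop("pair references a compound or pathway without a score")
  s <- pmin(pmax(scores[cbind(ri, ci)], 1e-12), 1 - 1e-12)
  y <- as.numeric(pairs$label == "positive")
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

# label/mask matrices (compounds x pathways) from a pair table
.pairMatrices <- function(pairs, compoundIds, pathwayIds) {
  Y <- matrix(0, length(compoundIds), length(pathwayIds),
              dimnames = list(compoundIds, pathwayIds))
  M <- Y
  ri <- match(pairs$compound_id, compoundIds)
  ci <- match(pairs$pathway_id, pathwayIds)
  keep <- !is.na(ri)
  Y[cbind(ri[keep], ci[keep])] <- as.numeric(pairs$label[keep] == "positive")
  M[cbind(ri[keep], ci[keep])] <- 1
  list(Y = Y, M = M)
}

#' Train the predictor
#'
#' Minibatch Adam on the masked binary cross entropy, shuffling compounds each
#' epoch (a compound's labeled pairs always travel together). After every
#' epoch the full validation loss is computed without dropout; training stops
#' when it has not improved for \code{patience} successive epochs or at
#' \code{maxEpochs}, and the weights of the best-validation epoch are
#' returned. Fully reproducible under the config seed.
#'
#' @param model an initialized \linkS4class{GdopModel}.
#' @param profiles matrix compounds x genes, rownames = compound ids.
#' @param fingerprints 0/1 matrix compounds x nBits, rownames = compound ids.
#' @param pairs labeled pair data.frame (positives + negatives).
#' @param split a \code{gdop_split} from \code{\link{splitDataset}}.
#' @param operator matrix from \code{\link{propagationOperator}}.
#' @return the trained \linkS4class{GdopModel} with its epoch history.
#' @export
trainGdop <- function(model, profiles, fingerprints, pairs, split, operator) {
  stopifnot(is(model, "GdopModel"), inherits(split, "gdop_split"))
  cfg <- model@config
  trainIds <- intersect(split$train, unique(pairs$compound_id))
  valIds <- intersect(split$validation, unique(pairs$compound_id))
  if (length(trainIds) == 0 || length(valIds) == 0)
    stop("train and validation sets must contain labeled compounds")

  powersAll <- operatorPowers(profiles, operator, cfg$sgcnOrder)
  rows <- function(ids) match(ids, rownames(profiles))
  lm <- .pairMatrices(pairs, rownames(profiles), model@pathwayIds)

  w <- model@weights
  adam <- list(m = lapply(w, function(x) x * 0),
               v = lapply(w, function(x) x * 0), t = 0)
  best <- list(loss = Inf, w = w, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  bad <- 0L
  withr::local_seed(cfg$seed)

  valLoss <- function(w) {
    tmp <- model; tmp@weights <- w
    idx <- rows(valIds)
    pw <- lapply(powersAll, function(p) p[idx, , drop = FALSE])
    z <- .sgcnForward(w$sgcn, pw, 0, FALSE)$z
    fw <- .denseForward(tmp, cbind(z, fingerprints[idx, , drop = FALSE]),
                        FALSE)
    .bceMasked(fw$logits, lm$Y[idx, , drop = FALSE],
               lm$M[idx, , drop = FALSE])$loss
  }

  for (epoch in seq_len(cfg$maxEpochs)) {
    perm <- sample(trainIds)
    batches <- base::split(perm, ceiling(seq_along(perm) / cfg$batchSize))
    epochLoss <- 0; epochPairs <- 0
    for (b in batches) {
      idx <- rows(b)
      pw <- lapply(powersAll, function(p) p[idx, , drop = FALSE])
      g <- .gdopBackward(model, w, pw, fingerprints[idx, , drop = FALSE],
                         lm$Y[idx, , drop = FALSE],
                         lm$M[idx, , drop = FALSE])
      if (!is.finite(g$loss))
        stop("training diverged to a non-finite loss at epoch ", epoch)
      adam$t <- adam$t + 1
      for (nm in names(w)) {
        adam$m[[nm]] <- cfg$beta1 * adam$m[[nm]] + (1 - cfg$beta1) * g$grad[[nm]]
        adam$v[[nm]] <- cfg$beta2 * adam$v[[nm]] +
          (1 - cfg$beta2) * g$grad[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - cfg$beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - cfg$beta2^adam$t)
        w[[nm]] <- w[[nm]] - cfg$learningRate * mhat / (sqrt(vhat) + cfg$epsilon)
      }
      np <- sum(lm$M[idx, , drop = FALSE])
      epochLoss <- epochLoss + g$loss * np
      epochPairs <- epochPairs + np
    }
    vl <- valLoss(w)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epochLoss / epochPairs,
                                         val_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, w = w, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  model@weights <- best$w
  model@trained <- TRUE
  model@history <- history
  model
}

# masked BCE from logits (numerically stable) and its logit gradient
.bceMasked <- function(logits, Y, M) {
  np <- sum(M)
  if (np == 0) stop("no labeled pairs in batch")
  # log(1 + exp(x)) computed stably
  softplus <- ifelse(logits > 30, logits, log1p(exp(pmin(logits, 30))))
  perEntry <- softplus - Y * logits
  loss <- sum(perEntry * M) / np
  s <- 1 / (1 + exp(-logits))
  list(loss = loss, dlogits = (s - Y) * M / np)
}

# forward + backward over one batch; returns loss and gradients for all weights
.gdopBackward <- function(model, w, powers, fps, Y, M) {
  cfg <- model@config
  tmp <- model; tmp@weights <- w
  sg <- .sgcnForward(w$sgcn, powers, cfg$dropoutRates[1], TRUE)
  u <- cbind(sg$z, fps)
  fw <- .denseForward(tmp, u, TRUE)
  bce <- .bceMasked(fw$logits, Y, M)

  grad <- list()
  L <- length(cfg$denseWidths)
  hLast <- if (L >= 1) fw$hs[[L]] else u
  grad$Wout <- t(hLast) %*% bce$dlogits
  grad$bout <- colSums(bce$dlogits)
  d <- bce$dlogits %*% t(w$Wout)
  for (l in rev(seq_len(L))) {
    d <- .applyMask(d, fw$masks[[l]])
    if (l < L) d <- d * (fw$pres[[l]] > 0)
    hPrev <- if (l > 1) fw$hs[[l - 1]] else fw$u
    grad[[paste0("W", l)]] <- t(hPrev) %*% d
    grad[[paste0("b", l)]] <- colSums(d)
    d <- d %*% t(w[[paste0("W", l)]])
  }
  # split concatenation: latent block then fingerprint block
  G <- ncol(powers[[1]]); C <- cfg$sgcnChannels
  dz <- d[, seq_len(G * C), drop = FALSE]
  dz <- .applyMask(dz, sg$mask)
  dpre <- dz * (sg$pre > 0)
  gs <- matrix(0, cfg$sgcnOrder + 1L, C)
  for (c in seq_len(C)) {
    blk <- dpre[, (c - 1L) * G + seq_len(G), drop = FALSE]
    for (k in seq_len(cfg$sgcnOrder + 1L))
      gs[k, c] <- sum(powers[[k]] * blk)
  }
  grad$sgcn <- gs
  list(loss = bce$loss, grad = grad[names(w)])
}

#' Rank all pathways for one compound
#'
#' Scores every pathway in the model's label space for a compound's averaged
#' profile and fingerprint, and returns the full descending-score ordering;
#' ties break deterministically by ascending pathway index.
#'
#' @param model a trained \linkS4class{GdopModel}.
#' @param profile numeric profile vector over the model's gene space.
#' @param fingerprint 0/1 vector of the model's fingerprint width.
#' @param operator matrix from \code{\link{propagationOperator}}.
#' @param compoundId identifier recorded in the ranking (default "compound").
#' @return data.frame of class \code{gdop_ranking}: columns \code{rank},
#'   \code{pathway_id}, \code{score}, attribute \code{compound_id}.
#' @export
predictRank <- function(model, profile, fingerprint, operator,
                        compoundId = "compound") {
  stopifnot(is(model, "GdopModel"))
  if (!model@trained) stop("model has not been trained")
  z <- sgcnEncode(model, profile, operator, training = FALSE)
  scores <- drop(gdopForward(model, z, fingerprint, training = FALSE))
  o <- order(-scores, seq_along(scores))
  out <- data.frame(rank = seq_along(scores),
                    pathway_id = model@pathwayIds[o],
                    score = unname(scores[o]))
  attr(out, "compound_id") <- compoundId
  class(out) <- c("gdop_ranking", class(out))
  out
}

#' Rankings for a compound set
#'
#' @param model a trained \linkS4class{GdopModel}.
#' @param profiles matrix compounds x genes, rownames = compound ids.
#' @param fingerprints 0/1 matrix compounds x nBits, same rownames.
#' @param operator matrix from \code{\link{propagationOperator}}.
#' @return named list of \code{gdop_ranking} data.frames.
#' @export
predictRankAll <- function(model, profiles, fingerprints, operator) {
  stopifnot(is(model, "GdopModel"))
  if (!model@trained) stop("model has not been trained")
  z <- sgcnEncode(model, profiles, operator, training = FALSE)
  scores <- gdopForward(model, z, fingerprints, training = FALSE)
  out <- lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    o <- order(-s, seq_along(s))
    r <- data.frame(rank = seq_along(s), pathway_id = model@pathwayIds[o],
                    score = unname(s[o]))
    attr(r, "compound_id") <- rownames(profiles)[i]
    class(r) <- c("gdop_ranking", class(r))
    r
  })
  names(out) <- rownames(profiles)
  out
}

#' @export
print.gdop_ranking <- function(x, n = 10, ...) {
  cat("Pathway ranking for", attr(x, "compound_id"), "- top", n, "of",
      nrow(x), "\n")
  print.data.frame(head(x, n), row.names = FALSE)
  invisible(x)
}

#' Top-N accuracy of ranked predictions
#'
#' The proportion of evaluated compounds for which at least one true (positive)
#' pathway appears among the N highest-ranked predictions; the evaluation
#' N values used downstream are 100, 30 and 10. Monotone non-decreasing in N
#' and equal to 1 when N reaches the size of the label space.
#'
#' @param rankings named list of \code{gdop_ranking} data.frames (names =
#'   compound ids).
#' @param positives named list mapping compound id to its true pathway ids;
#'   every evaluated compound must have at least one.
#' @param n vector of N values (default \code{c(100, 30, 10)}).
#' @return data.frame of class \code{gdop_topn}: columns \code{n},
#'   \code{accuracy}, \code{n_compounds}.
#' @export
topNAccuracy <- function(rankings, positives, n = c(100, 30, 10)) {
  stopifnot(all(n >= 1))
  ids <- names(positives)
  if (any(lengths(positives[ids]) == 0))
    stop("every evaluated compound needs at least one positive pathway")
  if (!all(ids %in% names(rankings)))
    stop("missing ranking for compound(s): ",
         paste(head(setdiff(ids, names(rankings)), 3), collapse = ", "))
  acc <- vapply(n, function(N) {
    hit <- vapply(ids, function(id) {
      top <- rankings[[id]]$pathway_id[seq_len(min(N, nrow(rankings[[id]])))]
      any(positives[[id]] %in% top)
    }, logical(1))
    mean(hit)
  }, numeric(1))
  out <- data.frame(n = n, accuracy = acc, n_compounds = length(ids))
  class(out) <- c("gdop_topn", class(out))
  out
}

#' Save / load a predictor checkpoint
#'
#' Single-file archive of config, gene space, pathway index and weights;
#' reloading reproduces predictions bit-identically.
#'
#' @param model a \linkS4class{GdopModel}.
#' @param path file path for the checkpoint.
#' @return \code{path} (save) or the \linkS4class{GdopModel} (load).
#' @export
saveGdopModel <- function(model, path) {
  stopifnot(is(model, "GdopModel"))
  saveRDS(list(format = "gdop-checkpoint-1", config = model@config,
               genes = model@geneSpace@genes, pathwayIds = model@pathwayIds,
               nBits = model@nBits, weights = model@weights,
               trained = model@trained, history = model@history),
          path)
  invisible(path)
}

#' @rdname saveGdopModel
#' @export
loadGdopModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "gdop-checkpoint-1"))
    stop("not a gdop checkpoint: ", path)
  new("GdopModel", config = x$config, geneSpace = GeneSpace(x$genes),
      pathwayIds = x$pathwayIds, nBits = x$nBits, weights = x$weights,
      trained = x$trained, history = x$history)
}
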