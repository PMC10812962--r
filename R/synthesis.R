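## Synthesis module: data splitting protocol, region-weighted loss,
## training with early stopping, cross-validation, hyperparameter
## search and map prediction.

#' Subject-wise train/validation/test split
#'
#' Random subject-level partition (no subject's slices ever cross
#' subset boundaries) with subset sizes given by largest-remainder
#' rounding of `n * fraction`; remainder ties are broken in
#' train > val > test order. Deterministic under the seed.
#'
#' @param subjectIds Character vector (>= 3 unique ids).
#' @param fractions Named fractions (train, val, test) summing to 1.
#' @param seed Integer seed.
#' @return List of id vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
splitDataset <- function(subjectIds,
                         fractions = c(train = 0.65, val = 0.15, test = 0.20),
                         seed = 20260103) {
  n <- length(subjectIds)
  if (n < 3) stop("need at least 3 subjects to split")
  if (anyDuplicated(subjectIds)) stop("duplicate subject ids")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  sizes <- largestRemainder(n, fractions)
  if (any(sizes == 0))
    stop("a subset would be empty after rounding; use more subjects")
  shuffled <- withStream(seed, "split", sample(subjectIds))
  ends <- cumsum(sizes)
  list(train = shuffled[seq_len(ends[1])],
       val = shuffled[(ends[1] + 1):ends[2]],
       test = shuffled[(ends[2] + 1):ends[3]])
}

# Largest-remainder apportionment of n into round(n * fractions).
largestRemainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE) # stable: earlier wins ties
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Region-weighted synthesis loss
#'
#' `w * L2(cartilage) + L1(background)` where L2 is the mean squared
#' error over cartilage voxels, L1 the mean absolute error over the
#' complement of the cartilage mask (the remainder of the slice), and
#' `w = 1.5` by default. An empty cartilage region contributes 0 from
#' the L2 term. Variants `"l2"` and `"l1"` apply the plain unmasked
#' mean squared / absolute error.
#'
#' @param pred,truth 2D matrices (or same-shape arrays).
#' @param cartilageMask Logical mask, same shape.
#' @param weight Cartilage weight (default 1.5).
#' @param variant `"weighted_l2_l1"`, `"l2"` or `"l1"`.
#' @return Non-negative scalar.
#' @export
weightedLoss <- function(pred, truth, cartilageMask, weight = 1.5,
                         variant = "weighted_l2_l1") {
  stopifnot(identical(dim(pred), dim(truth)),
            identical(dim(pred), dim(cartilageMask)))
  e <- pred - truth
  switch(variant,
    weighted_l2_l1 = {
      l2 <- if (any(cartilageMask)) mean(e[cartilageMask]^2) else 0
      bg <- !cartilageMask
      l1 <- if (any(bg)) mean(abs(e[bg])) else 0
      weight * l2 + l1
    },
    l2 = mean(e^2),
    l1 = mean(abs(e)),
    stop("unknown loss variant: ", variant))
}

## Batch loss and gradient on (H, W, N, 1) arrays with (H, W, N) masks;
## the batch loss is the mean of per-slice losses.
batchLossGrad <- function(pred, truth, mask, weight, variant) {
  d <- dim(pred)
  N <- d[3]
  e <- pred - truth
  g <- array(0, d)
  total <- 0
  for (i in seq_len(N)) {
    ei <- e[, , i, 1]
    mi <- mask[, , i]
    if (variant == "weighted_l2_l1") {
      nc <- sum(mi); nb <- sum(!mi)
      l2 <- if (nc > 0) sum(ei[mi]^2) / nc else 0
      l1 <- if (nb > 0) sum(abs(ei[!mi])) / nb else 0
      total <- total + weight * l2 + l1
      gi <- matrix(0, d[1], d[2])
      if (nc > 0) gi[mi] <- weight * 2 * ei[mi] / nc
      if (nb > 0) gi[!mi] <- sign(ei[!mi]) / nb
    } else if (variant == "l2") {
      total <- total + mean(ei^2)
      gi <- 2 * ei / length(ei)
    } else {
      total <- total + mean(abs(ei))
      gi <- sign(ei) / length(ei)
    }
    g[, , i, 1] <- gi
  }
  list(loss = total / N, grad = g / N)
}

## Normalize a batch of map slices for the network: clip then divide.
normalizeSlices <- function(x, config) {
  x <- pmin(pmax(x, config@clipRange[1]), config@clipRange[2])
  x / config@intensityScale
}

## Assemble (H, W, N, 1) input/target arrays + (H, W, N) masks from a
## list of SlicePair.
stackPairs <- function(pairs, config) {
  H <- nrow(pairs[[1]]@t2Slice); W <- ncol(pairs[[1]]@t2Slice)
  N <- length(pairs)
  x <- array(0, c(H, W, N, 1))
  y <- array(0, c(H, W, N, 1))
  m <- array(FALSE, c(H, W, N))
  for (i in seq_len(N)) {
    x[, , i, 1] <- normalizeSlices(pairs[[i]]@t2Slice, config)
    y[, , i, 1] <- normalizeSlices(pairs[[i]]@t1rhoSlice, config)
    m[, , i] <- pairs[[i]]@cartilageMaskSlice
  }
  list(x = x, y = y, mask = m,
       subjects = vapply(pairs, function(p) p@subjectId, ""))
}

## Loss of a model over a stacked set (evaluation mode), in mini-batches.
evalLoss <- function(model, stacked, config) {
  N <- dim(stacked$x)[3]
  bs <- config@batchSize
  total <- 0
  for (start in seq(1, N, bs)) {
    idx <- start:min(start + bs - 1, N)
    fw <- unetForward(model, stacked$x[, , idx, , drop = FALSE],
                      training = FALSE)
    lg <- batchLossGrad(fw$pred, stacked$y[, , idx, , drop = FALSE],
                        stacked$mask[, , idx, drop = FALSE],
                        config@lossWeightCartilage, config@lossVariant)
    total <- total + lg$loss * length(idx)
  }
  total / N
}

#' Train a U-Net on slice pairs
#'
#' Adam optimization of the region-weighted loss on normalized slices
#' (clip to `clipRange`, divide by `intensityScale`). Training stops
#' when the validation loss has not improved for `earlyStopPatience`
#' epochs (or at `maxEpochs`); the best-validation checkpoint is
#' returned. Slices with no cartilage voxels train on the L1 term only
#' and are counted in the history. A NaN loss aborts with a diagnostic.
#'
#' @param model An untrained or pre-trained [UNetModel-class].
#' @param trainPairs,valPairs Lists of [SlicePair-class].
#' @param config A [TrainConfig-class].
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `history` (data.frame of per-epoch
#'   train/val loss) attached as an attribute.
#' @export
trainModel <- function(model, trainPairs, valPairs, config = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), length(trainPairs) > 0,
            length(valPairs) > 0)
  validObject(config)
  tr <- stackPairs(trainPairs, config)
  va <- stackPairs(valPairs, config)
  if (length(intersect(unique(tr$subjects), unique(va$subjects))))
    stop("split integrity violation: subjects shared between train and val")
  nEmptyCart <- sum(vapply(trainPairs,
                           function(p) !any(p@cartilageMaskSlice), TRUE))

  params <- model@params
  stats <- model@stats
  opt <- adamInit(params)
  N <- dim(tr$x)[3]
  bs <- min(config@batchSize, N)

  best <- list(loss = Inf, params = params, stats = stats, epoch = 0L)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), lr = numeric())
  wait <- 0L
  lrWait <- 0L
  lr <- config@learningRate

  withStream(config@seed, "train", {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(N)
      epochLoss <- 0
      m <- model
      for (start in seq(1, N, bs)) {
        idx <- ord[start:min(start + bs - 1, N)]
        m@params <- params; m@stats <- stats
        fw <- unetForward(m, tr$x[, , idx, , drop = FALSE], training = TRUE)
        stats <- fw$stats
        lg <- batchLossGrad(fw$pred, tr$y[, , idx, , drop = FALSE],
                            tr$mask[, , idx, drop = FALSE],
                            config@lossWeightCartilage, config@lossVariant)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        m@params <- params
        grads <- unetBackward(m, fw$caches, lg$grad)
        stepped <- adamStep(params, grads, opt, lr)
        params <- stepped$params
        opt <- stepped$state
        epochLoss <- epochLoss + lg$loss * length(idx)
      }
      m@params <- params; m@stats <- stats
      vl <- evalLoss(m, va, config)
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = epochLoss / N, valLoss = vl, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d train %.6f val %.6f lr %.2g", epoch,
                        epochLoss / N, vl, lr))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = params, stats = stats,
                     epoch = epoch)
        wait <- 0L
        lrWait <- 0L
      } else {
        wait <- wait + 1L
        lrWait <- lrWait + 1L
        if (wait >= config@earlyStopPatience) break
        # reduce-on-plateau: halve the rate when the validation loss
        # has not set a new best for lrDecayPatience epochs
        if (config@lrDecayFactor < 1 && lrWait >= config@lrDecayPatience) {
          lr <- lr * config@lrDecayFactor
          lrWait <- 0L
        }
      }
    }
  })

  out <- model
  out@params <- best$params
  out@stats <- best$stats
  out@trained <- TRUE
  out@config <- config
  attr(out, "history") <- history
  attr(out, "bestEpoch") <- best$epoch
  attr(out, "bestValLoss") <- best$loss
  attr(out, "nEmptyCartilageSlices") <- nEmptyCart
  out
}

#' Training history of a trained model
#' @param model A trained [UNetModel-class].
#' @return data.frame with per-epoch train/val loss.
#' @export
trainingHistory <- function(model) attr(model, "history")

#' Predict a T1rho map from a T2 map
#'
#' Slices are clipped and normalized exactly as during training,
#' predicted independently (batch-norm in inference mode, deterministic),
#' restacked to a 3D volume, rescaled to ms and clipped to the training
#' clip range.
#'
#' @param model A trained [UNetModel-class].
#' @param t2Map A [QuantMap-class] of kind `"T2"`.
#' @return A [QuantMap-class] of kind `"T1rho"`.
#' @export
predictMap <- function(model, t2Map) {
  stopifnot(is(model, "UNetModel"), is(t2Map, "QuantMap"))
  if (!model@trained) stop("model is not trained")
  config <- model@config
  v <- t2Map@values
  d <- dim(v)
  x <- array(aperm(v, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
  x <- normalizeSlices(x, config)
  fw <- unetForward(model, x, training = FALSE)
  pred <- fw$pred[, , , 1] * config@intensityScale
  pred <- pmin(pmax(pred, config@clipRange[1]), config@clipRange[2])
  out <- aperm(array(pred, c(d[2], d[3], d[1])), c(3, 1, 2))
  QuantMap(out, "T1rho", t2Map@spacing)
}

#' Rescaled-input baseline prediction
#'
#' Predicts T1rho as the input T2 map multiplied by the ratio of mean
#' cartilage T1rho to mean cartilage T2 in the training set: the
#' no-learning reference that a synthesis model must beat.
#'
#' @param t2Map A [QuantMap-class].
#' @param ratio Scalar cartilage mean ratio from the training set.
#' @return A [QuantMap-class] of kind `"T1rho"`.
#' @export
identityBaseline <- function(t2Map, ratio) {
  QuantMap(pmin(pmax(t2Map@values * ratio, 0), 150), "T1rho", t2Map@spacing)
}

#' Subject-level k-fold cross-validation
#'
#' Partitions the train+validation subject pool into `config@nFolds`
#' folds (the test set stays untouched); each fold serves once as the
#' validation set while the others train a fresh model. Reports the
#' per-fold validation cartilage NMSE and keeps per-fold predictions
#' for bookkeeping.
#'
#' @param pairsBySubject Named list: subject id -> list of
#'   [SlicePair-class].
#' @param truths,labelsList Named lists of truth maps
#'   ([QuantMap-class], T1rho) and [CompartmentLabels-class] per subject.
#' @param modelSpec A [SynthModelSpec-class].
#' @param config A [TrainConfig-class].
#' @return List with `folds` (data.frame fold/valSubjects/cartilage
#'   NMSE), `assignments`, `predictions`.
#' @export
crossValidate <- function(pairsBySubject, truths, labelsList,
                          modelSpec = tinyUNetSpec(),
                          config = trainConfig()) {
  ids <- names(pairsBySubject)
  k <- config@nFolds
  if (length(ids) < k) stop("fewer subjects than folds")
  shuffled <- withStream(config@seed, "cv", sample(ids))
  assignments <- stats::setNames(rep(seq_len(k), length.out = length(ids)),
                                 shuffled)

  rows <- list(); predsAll <- list()
  for (f in seq_len(k)) {
    valIds <- names(assignments)[assignments == f]
    trIds <- setdiff(names(assignments), valIds)
    model <- buildModel(modelSpec, seed = deriveSeed(config@seed,
                                                    paste0("cv-fold", f)))
    model <- trainModel(model,
                        unlist(pairsBySubject[trIds], recursive = FALSE),
                        unlist(pairsBySubject[valIds], recursive = FALSE),
                        config)
    nm <- vapply(valIds, function(id) {
      t2 <- QuantMap(vapply(pairsBySubject[[id]],
                            function(p) p@t2Slice, pairsBySubject[[id]][[1]]@t2Slice) |>
                       aperm(c(3, 1, 2)), "T2")
      pred <- predictMap(model, t2)
      predsAll[[id]] <<- pred
      nmse(pred, truths[[id]], cartilageMask(labelsList[[id]]))
    }, 1.0)
    rows[[f]] <- data.frame(fold = f,
                            valSubjects = paste(valIds, collapse = ","),
                            cartilageNMSE = mean(nm))
  }
  list(folds = do.call(rbind, rows), assignments = assignments,
       predictions = predsAll)
}

#' Hyperparameter grid search
#'
#' Exhaustive evaluation of a finite grid over loss variant, intensity
#' scale and learning rate; each candidate trains a fresh model and is
#' scored by validation cartilage NMSE. The winner is the argmin; the
#' full leaderboard (ascending NMSE) is returned.
#'
#' @param grid data.frame with columns among `lossVariant`,
#'   `intensityScale`, `learningRate`.
#' @param trainPairs,valPairs Slice-pair lists.
#' @param valTruths,valLabels Named lists for scoring the validation
#'   subjects.
#' @param modelSpec A [SynthModelSpec-class].
#' @param config Base [TrainConfig-class]; grid columns override it.
#' @return List with `best` (config row) and `leaderboard`.
#' @export
hyperparameterSearch <- function(grid, trainPairs, valPairs, valTruths,
                                 valLabels, modelSpec = tinyUNetSpec(),
                                 config = trainConfig()) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    if ("lossVariant" %in% names(grid)) cfg@lossVariant <- grid$lossVariant[i]
    if ("intensityScale" %in% names(grid))
      cfg@intensityScale <- grid$intensityScale[i]
    if ("learningRate" %in% names(grid))
      cfg@learningRate <- grid$learningRate[i]
    model <- buildModel(modelSpec, seed = deriveSeed(cfg@seed, "hpsearch"))
    model <- trainModel(model, trainPairs, valPairs, cfg)
    nm <- vapply(names(valTruths), function(id) {
      slices <- Filter(function(p) p@subjectId == id, valPairs)
      t2 <- QuantMap(aperm(vapply(slices, function(p) p@t2Slice,
                                  slices[[1]]@t2Slice), c(3, 1, 2)), "T2")
      pred <- predictMap(model, t2)
      nmse(pred, valTruths[[id]], cartilageMask(valLabels[[id]]))
    }, 1.0)
    scores[i] <- mean(nm)
  }
  leaderboard <- cbind(grid, cartilageNMSE = scores)
  leaderboard <- leaderboard[order(leaderboard$cartilageNMSE), , drop = FALSE]
  list(best = leaderboard[1, , drop = FALSE], leaderboard = leaderboard)
}
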