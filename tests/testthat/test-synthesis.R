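test_that("subject-wise split follows largest-remainder rounding", {
  ids <- sprintf("P%02d", 1:20)
  sp <- splitDataset(ids, c(train = 0.65, val = 0.15, test = 0.20), seed = 4)
  expect_equal(lengths(sp), c(train = 13L, val = 3L, test = 4L))

  # partition law: disjoint and exhaustive
  expect_setequal(unlist(sp), ids)
  expect_equal(anyDuplicated(unlist(sp)), 0L)

  # deterministic under seed
  expect_identical(splitDataset(ids, seed = 4), sp)
  expect_false(identical(splitDataset(ids, seed = 5), sp))

  # sizes for a non-exact case (n = 7: 4.55, 1.05, 1.4 -> 5, 1, 1)
  sp7 <- splitDataset(sprintf("Q%d", 1:7), seed = 1)
  expect_equal(lengths(sp7), c(train = 5L, val = 1L, test = 1L))
  expect_error(splitDataset(c("a", "b"), seed = 1), "at least 3")
})

test_that("weighted loss matches the hand-computed fixture", {
  # 2x2 image, cartilage = top row; truth [[10,20],[30,40]],
  # pred [[12,18],[33,40]] -> 1.5 * mean(4,4) + mean(3,0) = 7.5
  truth <- rbind(c(10, 20), c(30, 40))
  pred <- rbind(c(12, 18), c(33, 40))
  mask <- rbind(c(TRUE, TRUE), c(FALSE, FALSE))
  expect_equal(weightedLoss(pred, truth, mask), 7.5)
  expect_equal(weightedLoss(truth, truth, mask), 0)

  # doubling cartilage errors quadruples the L2 term only
  pred2 <- truth + (pred - truth) * ifelse(mask, 2, 1)
  l1 <- weightedLoss(pred, truth, mask)
  l2 <- weightedLoss(pred2, truth, mask)
  expect_equal(l2 - 1.5, 4 * (l1 - 1.5), tolerance = 1e-12)

  # empty cartilage region contributes 0 from the L2 term
  none <- matrix(FALSE, 2, 2)
  expect_equal(weightedLoss(pred, truth, none), mean(abs(pred - truth)))
})

test_that("weighted loss equals an independent recomputation on random tensors", {
  withr::with_seed(8, {
    for (i in 1:5) {
      p <- matrix(runif(64, 0, 1), 8)
      y <- matrix(runif(64, 0, 1), 8)
      m <- matrix(runif(64) > 0.6, 8)
      direct <- 1.5 * mean((p[m] - y[m])^2) + mean(abs(p[!m] - y[!m]))
      expect_equal(weightedLoss(p, y, m), direct, tolerance = 1e-12)
    }
  })
})

test_that("the batch loss gradient matches finite differences", {
  withr::with_seed(9, {
    pred <- array(runif(2 * 6 * 6), c(6, 6, 2, 1))
    truth <- array(runif(2 * 6 * 6), c(6, 6, 2, 1))
    mask <- array(runif(2 * 6 * 6) > 0.5, c(6, 6, 2))
  })
  lg <- qmapsynth:::batchLossGrad(pred, truth, mask, 1.5, "weighted_l2_l1")
  eps <- 1e-7
  for (i in sample(length(pred), 8)) {
    p1 <- pred; p1[i] <- p1[i] + eps
    p2 <- pred; p2[i] <- p2[i] - eps
    num <- (qmapsynth:::batchLossGrad(p1, truth, mask, 1.5, "weighted_l2_l1")$loss -
            qmapsynth:::batchLossGrad(p2, truth, mask, 1.5, "weighted_l2_l1")$loss) /
      (2 * eps)
    expect_equal(lg$grad[i], num, tolerance = 1e-5)
  }
})

test_that("model building is seeded, sized and shape-preserving", {
  spec <- tinyUNetSpec()
  m1 <- buildModel(spec, seed = 21)
  m2 <- buildModel(spec, seed = 21)
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params, buildModel(spec, seed = 22)@params))

  # tiny preset stays under 1e5 parameters, 8 conv layers
  expect_lt(parameterCount(m1), 1e5)
  expect_equal(nConvLayers(spec), 8L)

  x <- array(0, c(32, 32, 2, 1))
  fw <- qmapsynth:::unetForward(m1, x, training = FALSE)
  expect_identical(dim(fw$pred), dim(x))
  expect_true(all(is.finite(fw$pred)))

  expect_error(qmapsynth:::unetForward(m1, array(0, c(30, 30, 1, 1))),
               "divisible")
})

test_that("training learns the identity task and honors its contracts", {
  v <- pmin(pmax(40 + 25 * outer(sin(seq(0, 3, length.out = 32)),
                                 cos(seq(0, 3, length.out = 32))), 0), 150)
  mk <- function(i) {
    new("SlicePair", t2Slice = v, t1rhoSlice = v,
        cartilageMaskSlice = matrix(rep(c(TRUE, FALSE), each = 16,
                                        length.out = 1024), 32, 32),
        subjectId = paste0("A", i), sliceIndex = 1L)
  }
  pairs <- lapply(1:10, mk)
  valPairs <- lapply(11:12, mk)
  cfg <- trainConfig(maxEpochs = 200, earlyStopPatience = 200,
                     learningRate = 1e-2, lossVariant = "l2",
                     lrDecayPatience = 40, batchSize = 5, seed = 13)
  m <- buildModel(synthModelSpec(8, 3, batchNorm = FALSE), seed = 14)
  m <- trainModel(m, pairs, valPairs, cfg)
  h <- trainingHistory(m)
  expect_lte(nrow(h), cfg@maxEpochs)
  # best-checkpoint contract: returned model's val loss <= final epoch's
  expect_lte(attr(m, "bestValLoss"), h$valLoss[nrow(h)] + 1e-12)
  # the identity task is learnable
  expect_lt(attr(m, "bestValLoss"), 0.02 * h$valLoss[1])

  # split integrity is asserted on every run
  expect_error(trainModel(buildModel(tinyUNetSpec(), 1), pairs, pairs, cfg),
               "split integrity")

  # inference is deterministic and respects the clip contract
  t2 <- QuantMap(array(runif(2 * 32 * 32, 0, 200) |> pmin(150), c(2, 32, 32)),
                 "T2")
  p1 <- predictMap(m, t2)
  p2 <- predictMap(m, t2)
  expect_identical(p1@values, p2@values)
  expect_gte(min(p1@values), 0)
  expect_lte(max(p1@values), 150)
  expect_equal(mapKind(p1), "T1rho")
})

test_that("cross-validation partitions subjects and is deterministic", {
  spec <- tinyPhantomSpec()
  acq <- AcquisitionSpec()
  ids <- sprintf("S%03d", 1:8)
  truths <- lapply(ids, function(id) generatePhantom(
    phantomSpec(matrixSize = c(2, 32, 32), nSubjects = 8, seed = 5), id))
  names(truths) <- ids
  pairs <- lapply(ids, function(id)
    makeSlicePairs(truths[[id]]@t2, truths[[id]]@t1rho, truths[[id]]@labels, id))
  names(pairs) <- ids
  t1 <- lapply(truths, function(tr) tr@t1rho)
  labs <- lapply(truths, function(tr) tr@labels)
  cfg <- trainConfig(maxEpochs = 2, earlyStopPatience = 2, nFolds = 4,
                     batchSize = 4, seed = 10)
  cv <- crossValidate(pairs, t1, labs, tinyUNetSpec(), cfg)
  expect_equal(nrow(cv$folds), 4)
  # every subject appears in exactly one validation fold
  expect_setequal(names(cv$assignments), ids)
  expect_true(all(table(cv$assignments) == 2))
  cv2 <- crossValidate(pairs, t1, labs, tinyUNetSpec(), cfg)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$folds$cartilageNMSE, cv2$folds$cartilageNMSE)
  expect_error(crossValidate(pairs[1:3], t1, labs, tinyUNetSpec(), cfg),
               "fewer subjects")
})

test_that("hyperparameter search returns the argmin with a sorted leaderboard", {
  ids <- sprintf("S%03d", 1:4)
  spec <- phantomSpec(matrixSize = c(2, 32, 32), nSubjects = 4, seed = 6)
  truths <- lapply(ids, function(id) generatePhantom(spec, id))
  names(truths) <- ids
  pairsOf <- function(sids) unlist(lapply(sids, function(id)
    makeSlicePairs(truths[[id]]@t2, truths[[id]]@t1rho, truths[[id]]@labels,
                   id)), recursive = FALSE)
  cfg <- trainConfig(maxEpochs = 2, earlyStopPatience = 2, batchSize = 4,
                     seed = 17)
  grid <- data.frame(learningRate = c(1e-3, 3e-3))
  hp <- hyperparameterSearch(grid, pairsOf(ids[1:3]), pairsOf(ids[4]),
                             list(S004 = truths$S004@t1rho),
                             list(S004 = truths$S004@labels),
                             tinyUNetSpec(), cfg)
  expect_equal(nrow(hp$leaderboard), 2)
  expect_false(is.unsorted(hp$leaderboard$cartilageNMSE))
  expect_equal(hp$best$cartilageNMSE, min(hp$leaderboard$cartilageNMSE))
  # grid of one returns that config; empty grid rejected
  hp1 <- hyperparameterSearch(grid[1, , drop = FALSE], pairsOf(ids[1:3]),
                              pairsOf(ids[4]),
                              list(S004 = truths$S004@t1rho),
                              list(S004 = truths$S004@labels),
                              tinyUNetSpec(), cfg)
  expect_equal(hp1$best$learningRate, 1e-3)
  expect_error(hyperparameterSearch(grid[0, , drop = FALSE], pairsOf(ids[1:3]),
                                    pairsOf(ids[4]), list(), list(),
                                    tinyUNetSpec(), cfg),
               "empty")
})
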