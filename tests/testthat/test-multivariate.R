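test_that("pairwise distances are exact and validated", {
  m <- rbind(c(1, 2), c(1, 2))
  expect_equal(unname(pairwiseDistances(m)[1, 2]), 0)
  expect_equal(unname(pairwiseDistances(rbind(c(0, 0), c(3, 4)))[1, 2]), 5)
  withr::with_seed(21, {
    r <- matrix(rnorm(80), 20, 4)
    expect_equal(unname(pairwiseDistances(r)), naiveEuclidean(r),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
  expect_error(pairwiseDistances(rbind(c(1, NA), c(0, 0))), "finite")
  ## Bray-Curtis on positive data: manual 2x2 check
  b <- pairwiseDistances(rbind(c(1, 3), c(3, 5)), metric = "bray")
  expect_equal(unname(b[1, 2]), (2 + 2) / (4 + 8))
})

test_that("ANOSIM: full separation gives R = 1; statistic matches vegan", {
  cl <- separatedClusters(nPer = 4)
  a <- anosimTest(pairwiseDistances(cl$m), cl$groups, seed = 1)
  expect_equal(a@statistic, 1, tolerance = 1e-12)
  expect_true(a@exact)       # C(8,4) relabelings enumerated
  skip_if_not_installed("vegan")
  withr::with_seed(22, {
    m <- matrix(rnorm(60), 15, 4)
    g <- rep(c("a", "b", "c"), each = 5)
    mine <- anosimTest(pairwiseDistances(m), g, nPermutations = 49, seed = 1)
    ref <- vegan::anosim(dist(m), g, permutations = 9)
    expect_equal(mine@statistic, unname(ref$statistic), tolerance = 1e-12)
  })
})

test_that("ANOSIM exact enumeration agrees with Monte-Carlo permutation", {
  withr::with_seed(23, {
    m <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 1.2), 3, 2))
    g <- rep(c("a", "b"), each = 3)
    D <- pairwiseDistances(m)
    ex <- anosimTest(D, g)                       # 20 relabelings, exact
    expect_true(ex@exact)
    expect_equal(ex@n_permutations, 20)
    B <- 4000
    mc <- anosimTest(D, g, nPermutations = B, seed = 9, exactLimit = 1)
    se <- sqrt(ex@p_value * (1 - ex@p_value) / B)
    expect_lt(abs(mc@p_value - ex@p_value), 2 * se + 2 / B)
  })
})

test_that("ANOSIM is invariant under monotone transforms of the distances", {
  withr::with_seed(24, {
    m <- matrix(rnorm(48), 12, 4)
    g <- rep(c("a", "b"), each = 6)
    D <- pairwiseDistances(m)
    r0 <- anosimTest(D, g, nPermutations = 99, seed = 5)
    for (f in list(function(d) d^2, function(d) log1p(d),
                   function(d) 3 * d)) {
      Dt <- f(D)
      expect_equal(anosimTest(Dt, g, nPermutations = 99, seed = 5)@statistic,
                   r0@statistic, tolerance = 1e-12)
    }
  })
})

test_that("ANOSIM under the null: R near zero, seed-reproducible p", {
  withr::with_seed(25, {
    rejections <- 0L
    for (i in 1:40) {
      m <- matrix(rnorm(48), 12, 4)
      g <- sample(rep(c("a", "b"), each = 6))
      a <- anosimTest(pairwiseDistances(m), g, nPermutations = 99,
                      seed = i, exactLimit = 1)
      rejections <- rejections + (a@p_value < 0.05)
    }
    expect_lte(rejections, 8)  # ~2 expected at the 5% level
  })
  ## identical seed reproduces the permutation p exactly
  cl <- separatedClusters(nPer = 6, gap = 0.5)
  D <- pairwiseDistances(cl$m)
  p1 <- anosimTest(D, cl$groups, nPermutations = 199, seed = 7,
                   exactLimit = 1)@p_value
  p2 <- anosimTest(D, cl$groups, nPermutations = 199, seed = 7,
                   exactLimit = 1)@p_value
  expect_identical(p1, p2)
  expect_error(anosimTest(D, c("a", rep("b", 11)), seed = 1), "singleton")
})

test_that("PCA: explained variance, collinear limit and reconstruction", {
  t <- seq(-3, 3, length.out = 40)
  line <- cbind(2 * t, -t)                 # exactly rank 1
  p <- pcaFit(line, scale = FALSE)
  expect_equal(p$explained[1], 1)
  withr::with_seed(26, {
    m <- matrix(rnorm(200), 50, 4)
    p2 <- pcaFit(m)
    expect_equal(sum(p2$explained), 1)
    expect_equal(order(p2$sdev, decreasing = TRUE), 1:4)
    ## reconstruction from all PCs reproduces the data
    rec <- p2$scores %*% t(p2$loadings)
    rec <- sweep(rec, 2, p2$scale, "*")
    rec <- sweep(rec, 2, p2$center, "+")
    expect_equal(unname(rec), unname(m), tolerance = 1e-10)
    ## total variance conserved on the unscaled fit
    p3 <- pcaFit(m, scale = FALSE)
    expect_equal(sum(p3$sdev^2), sum(apply(m, 2, var)), tolerance = 1e-10)
  })
})

test_that("ripeness staging follows the ellipse-overlap rule", {
  withr::with_seed(27, {
    base <- matrix(rnorm(60, sd = 0.3), 30, 2)
    ## all days share one cloud: everything overlaps the cracking day
    scoresSame <- do.call(rbind, replicate(7, base, simplify = FALSE))
    day <- rep(1:7, each = 30)
    stSame <- assignRipenessStages(scoresSame, day, crackingDay = 4)
    expect_true(all(stSame$stage == "ripened"))

    ## clouds spaced far beyond their spread: before x3, ripened x1, after x3
    scoresFar <- scoresSame + cbind(50 * day, 0)
    stFar <- assignRipenessStages(scoresFar, day, crackingDay = 4)
    expect_equal(stFar$stage, c(rep("before_ripening", 3), "ripened",
                                rep("after_ripening", 3)))
    expect_equal(stFar$overlaps_cracking, c(rep(FALSE, 3), TRUE,
                                            rep(FALSE, 3)))

    ## a day with < 3 readings is unassigned with a warning
    keep <- setdiff(seq_along(day), which(day == 2)[-(1:2)])
    expect_warning(
      stNA <- assignRipenessStages(scoresFar[keep, ], day[keep], 4),
      "unassigned")
    expect_equal(stNA$stage[stNA$day == 2], "unassigned")
  })
})

test_that("LDA axes match the closed-form Fisher direction and MASS", {
  withr::with_seed(28, {
    for (i in 1:20) {
      p <- sample(3:6, 1)
      n <- sample(20:40, 1)
      m <- matrix(rnorm(2 * n * p), 2 * n, p)
      m[seq_len(n), ] <- m[seq_len(n), ] +
        matrix(runif(p, -2, 2), n, p, byrow = TRUE)
      g <- rep(c("a", "b"), each = n)
      fit <- ldaFit(m, g)
      expect_equal(ncol(fit@scaling), 1L)   # two classes -> one axis
      expect_gt(cosineSim(fit@scaling[, 1], fisherDirection(m, g)), 0.999)
    }
  })
  skip_if_not_installed("MASS")
  withr::with_seed(29, {
    m <- matrix(rnorm(240), 60, 4)
    m[1:20, 1] <- m[1:20, 1] + 3; m[21:40, 2] <- m[21:40, 2] - 3
    g <- rep(c("a", "b", "c"), each = 20)
    fit <- ldaFit(m, g)
    ref <- MASS::lda(m, g)
    for (k in 1:2)
      expect_gt(cosineSim(fit@scaling[, k], ref$scaling[, k]), 0.999)
  })
})

test_that("LDA classification: separable limit, scale invariance, canonical sign", {
  withr::with_seed(30, {
    m <- rbind(matrix(rnorm(60), 20, 3),
               matrix(rnorm(60, 8), 20, 3),
               matrix(rnorm(60, -8), 20, 3))
    g <- rep(c("a", "b", "c"), each = 20)
    fit <- ldaFit(m, g)
    expect_equal(as.character(ldaPredict(fit, m)), g)  # 100% training acc
    ## largest-magnitude coefficient positive on every axis
    for (k in seq_len(ncol(fit@scaling))) {
      a <- fit@scaling[, k]
      expect_gt(a[which.max(abs(a))], 0)
    }
    ## affine rescaling of one channel leaves predicted labels unchanged
    m2 <- m; m2[, 2] <- m2[, 2] * 10
    fit2 <- ldaFit(m2, g)
    test <- matrix(rnorm(30, 4), 10, 3)
    test2 <- test; test2[, 2] <- test2[, 2] * 10
    expect_identical(ldaPredict(fit2, test2), ldaPredict(fit, test))
  })
  ## ridge fallback engages on singular within-class covariance
  withr::with_seed(31, {
    m <- matrix(rnorm(40), 20, 2)
    m <- cbind(m, m[, 1] + m[, 2])          # exactly collinear channel
    g <- rep(c("a", "b"), each = 10)
    expect_message(fit <- ldaFit(m, g), "ridge")
    expect_error(ldaFit(m, g, ridge = FALSE), "singular")
  })
})

test_that("externally supplied discriminant functions project as stored", {
  scaling <- cbind(
    Axis1 = c(GM102B = -0.10737, GM302B = 0.23079, GM502B = -0.19401,
              GM702B = -0.0029751),
    Axis2 = c(GM102B = 0.010277, GM302B = 0.0058381, GM502B = -0.0067202,
              GM702B = 0.039215))
  model <- ldaModel(scaling)
  unit <- matrix(c(0, 1, 0, 0), 1,
                 dimnames = list(NULL, rownames(scaling)))
  sc <- ldaPredict(model, unit, type = "scores")
  expect_equal(unname(sc[1, "Axis1"]), 0.23079)
  expect_equal(unname(sc[1, "Axis2"]), 0.0058381)
  expect_error(ldaPredict(model, matrix(1, 1, 2)), "channels")
  expect_error(ldaPredict(model, unit), "centers")
})

test_that("confusion matrix: orientation, conservation and per-class accuracy", {
  ## perfect prediction: diagonal counts, 100% accuracy
  g <- rep(c("a", "b"), c(4, 6))
  cf <- classConfusion(g, g)
  expect_true(all(cf@counts[row(cf@counts) != col(cf@counts)] == 0))
  expect_equal(unname(cf@accuracy), c(100, 100))
  ## n conserved
  withr::with_seed(32, {
    true <- sample(c("a", "b", "c"), 50, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 50, replace = TRUE)
    cf2 <- classConfusion(true, pred)
    expect_equal(sum(cf2@counts), 50)
    expect_equal(as.numeric(colSums(cf2@counts)),
                 as.numeric(table(true)[colnames(cf2@counts)]))
  })
  ## a class absent from the test truth keeps its row with zero totals
  lv <- c("air", "durian", "mealybug")
  cf3 <- classConfusion(rep(c("durian", "mealybug"), each = 3),
                        rep(c("durian", "mealybug"), 3), levels = lv)
  expect_equal(unname(cf3@counts["air", ]), c(0L, 0L, 0L))
  expect_true(is.na(cf3@accuracy["air"]))
})
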