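# Seeded best-first region growing

test_that("incremental mean update follows the closed form", {
  expect_equal(updateMean(0.5, 4, 0.7), 0.54)
  expect_equal(updateMean(0.3, 7, 0.3), 0.3)        # fixed point
  expect_error(updateMean(0.5, 0, 0.7), "size")
  # a chain of updates reproduces the batch mean
  set.seed(5)
  vals <- runif(30)
  mu <- vals[1]
  for (i in 2:30) {
    mu <- updateMean(mu, i - 1, vals[i])
    expect_equal(mu, mean(vals[seq_len(i)]), tolerance = 1e-12)
  }
})

test_that("growth floods a constant image and respects zero tolerance", {
  img <- matrix(0.4, 7, 9)
  expect_true(all(regionGrow(img, c(4, 5), maxdis = 0.01)))
  # maxdis = 0: exactly the seed's equal-valued connected component
  img2 <- matrix(0.2, 8, 8)
  img2[3:5, 3:5] <- 0.8
  img2[7, 7] <- 0.8                      # equal value but not connected
  g <- regionGrow(img2, c(4, 4), maxdis = 0)
  expect_equal(sum(g), 9)
  expect_true(all(g[3:5, 3:5]))
  expect_error(regionGrow(img2, matrix(numeric(0), ncol = 2), maxdis = 0.1),
               "seed")
  expect_error(regionGrow(img2, c(1, 99), maxdis = 0.1), "outside")
})

test_that("growth matches the exhaustive best-first oracle on random images", {
  set.seed(91)
  for (i in 1:20) {
    img <- matrix(runif(64), 8, 8)
    nSeeds <- sample(1:2, 1)
    seeds <- cbind(sample(8, nSeeds, replace = TRUE),
                   sample(8, nSeeds, replace = TRUE))
    maxdis <- sample(c(0.05, 0.1), 1)
    mine <- regionGrow(img, seeds, maxdis = maxdis, trace = TRUE)
    orc <- rgOracle(img, seeds, maxdis = maxdis)
    expect_identical(as.vector(mine), as.vector(orc$region))
    expect_equal(attr(mine, "means"), orc$means, tolerance = 1e-12)
  }
})

test_that("running mean equals the batch mean at every acceptance", {
  set.seed(13)
  img <- matrix(runif(100), 10, 10)
  g <- regionGrow(img, c(5, 5), maxdis = 0.2, trace = TRUE)
  ord <- attr(g, "order")
  mns <- attr(g, "means")
  for (k in seq_len(nrow(ord)))
    expect_equal(mns[k], mean(img[ord[seq_len(k), , drop = FALSE]]),
                 tolerance = 1e-12)
})

test_that("region is monotone in maxdis and contains its seeds", {
  set.seed(23)
  for (i in 1:10) {
    img <- matrix(runif(64), 8, 8)
    seed <- c(sample(8, 1), sample(8, 1))
    g1 <- regionGrow(img, seed, maxdis = 0.05)
    g2 <- regionGrow(img, seed, maxdis = 0.1)
    expect_true(g1[seed[1], seed[2]])
    expect_false(any(g1 & !g2))          # larger threshold: superset
  }
})

test_that("automatic seeding lands inside the nucleus", {
  ph <- generatePhantom(phantomSpec(blurSigma = 0, noiseSd = 0))
  crop <- kmeansCrop(phantomImage(ph), ivdContour(ph), seed = 3)
  sd <- proposeSeed(crop$image, crop$discMask, seed = 3)
  bb <- crop$bbox
  npTrue <- npMask(ph)[bb[1]:bb[2], bb[3]:bb[4]]
  expect_true(npTrue[sd[1], sd[2]])
  # all-dark disc: no bright class to propose from
  expect_error(proposeSeed(matrix(0.2, 10, 10), matrix(TRUE, 10, 10)),
               "manual seed")
})

test_that("growth from the proposed seed recovers the noisy nucleus", {
  ph <- generatePhantom(phantomSpec(seed = 77))   # blur 1, noise 0.02
  img <- normalizeIntensity(phantomImage(ph))
  crop <- kmeansCrop(img, ivdContour(ph), seed = 8)
  sd <- proposeSeed(crop$image, crop$discMask, seed = 8)
  g <- regionGrow(crop$image, sd, maxdis = 0.06, domain = crop$discMask)
  g <- morphoCleanup(g, 2)
  bb <- crop$bbox
  npTrue <- npMask(ph)[bb[1]:bb[2], bb[3]:bb[4]]
  expect_gte(diceCoefficient(g, npTrue), 0.85)
})

test_that("morphological cleanup stabilizes solid shapes and fills holes", {
  dsk <- diskMask(6)
  expect_identical(morphoCleanup(dsk, 2), dsk)
  holed <- dsk; holed[9, 9] <- FALSE
  expect_identical(morphoCleanup(holed, 1), dsk)
  expect_error(morphoCleanup(matrix(FALSE, 4, 4), 1), "segmentation failure")
})

test_that("morphology wrappers agree with the set-algebra oracle", {
  set.seed(33)
  for (i in 1:8) {
    m <- matrix(runif(144) < 0.5, 12, 12)
    r <- sample(1:2, 1)
    expect_identical(binaryErode(m, r), erodeOracle(m, r))
    expect_identical(binaryDilate(m, r), dilateOracle(m, r))
    expect_identical(binaryOpen(m, r), openOracle(m, r))
    expect_identical(binaryClose(m, r), closeOracle(m, r))
  }
})
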