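# Fuzzy C-means: primitives, solver, NP cluster selection, cleanup

test_that("membership initialization is row-normalized and deterministic", {
  U <- initMembership(40, 3, seed = 9)
  expect_equal(rowSums(U), rep(1, 40), tolerance = 1e-12)
  expect_identical(U, initMembership(40, 3, seed = 9))
  expect_error(initMembership(10, 1), "at least 2")
  expect_error(initMembership(3, 3), "more objects")
})

test_that("centroid update reduces to means for hard memberships", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  U <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(updateCentroids(U, x, m = 2), c(0.15, 0.85))
  # uniform memberships collapse both centroids onto the global mean
  U5 <- matrix(0.5, 2, 2)
  expect_equal(updateCentroids(U5, c(0.2, 0.8), m = 2), c(0.5, 0.5))
  expect_error(updateCentroids(rbind(c(1, 0), c(1, 0)), c(1, 2), m = 2),
               "empty fuzzy cluster")
})

test_that("centroid update matches the naive double-loop evaluation", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:20, 1); cc <- sample(2:4, 1)
    U <- matrix(runif(n * cc), n, cc); U <- U / rowSums(U)
    x <- runif(n); m <- runif(1, 1.3, 3)
    naive <- vapply(seq_len(cc), function(k)
      sum(U[, k]^m * x) / sum(U[, k]^m), 0)
    expect_equal(updateCentroids(U, x, m), naive, tolerance = 1e-12)
  }
})

test_that("membership update follows the closed form", {
  expect_equal(updateMembership(0.5, c(0.3, 0.7), m = 2)[1, ], c(0.5, 0.5))
  expect_equal(updateMembership(0.3, c(0.3, 0.9), m = 2)[1, ], c(1, 0))
  # hand-evaluated: x = 0, centers 0.1 and 0.4, m = 2 -> (16/17, 1/17)
  expect_equal(updateMembership(0, c(0.1, 0.4), m = 2)[1, ],
               c(16 / 17, 1 / 17), tolerance = 1e-12)
})

test_that("objective matches the naive triple loop and its zero cases", {
  expect_equal(fcmObjective(rbind(c(1, 0)), c(0.5, 1.0), 0.5, m = 2), 0)
  x <- c(0.1, 0.9); U <- rbind(c(1, 0), c(0, 1))
  expect_equal(fcmObjective(U, c(0.1, 0.9), x, m = 2), 0)
  set.seed(31)
  for (i in 1:8) {
    n <- sample(4:15, 1); cc <- sample(2:3, 1)
    U <- matrix(runif(n * cc), n, cc); U <- U / rowSums(U)
    x <- runif(n); ctr <- runif(cc); m <- runif(1, 1.5, 3)
    naive <- 0
    for (k in seq_len(cc)) for (j in seq_len(n))
      naive <- naive + U[j, k]^m * (ctr[k] - x[j])^2
    expect_equal(fcmObjective(U, ctr, x, m), naive, tolerance = 1e-12)
  }
})

test_that("the solver separates well-separated data and is deterministic", {
  img <- matrix(c(rep(0.2, 30), rep(0.8, 34)), 8, 8)
  p <- fcmCluster(img, c = 2, m = 2, seed = 4)
  expect_equal(sort(clusterCenters(p)), c(0.2, 0.8), tolerance = 1e-6)
  expect_gte(min(apply(membership(p), 1, max)), 0.99)
  expect_true(p@converged)
  p2 <- fcmCluster(img, c = 2, m = 2, seed = 4)
  expect_identical(membership(p), membership(p2))
  # hardened FCM equals the K-means partition on a noiseless two-class image
  hard <- max.col(membership(p), ties.method = "first")
  expect_true(all(tapply(as.vector(img), hard, function(v)
    length(unique(v))) == 1))
})

test_that("solver matches the naive FCM oracle and J is monotone", {
  set.seed(41)
  for (i in 1:6) {
    n <- sample(10:30, 1); cc <- sample(2:3, 1)
    x <- runif(n); sd <- sample.int(1e5, 1)
    p <- fcmCluster(x, c = cc, m = 2, tol = 1e-7, maxIter = 60, seed = sd)
    o <- naiveFcm(x, cc, m = 2, tol = 1e-7, maxIter = 60, seed = sd)
    expect_equal(p@objective, o$J, tolerance = 1e-8)
    expect_equal(clusterCenters(p), o$centers, tolerance = 1e-8)
    expect_true(all(diff(objectiveTrace(p)) <= 1e-12))
    expect_equal(rowSums(membership(p)), rep(1, n), tolerance = 1e-9)
  }
})

test_that("clustering is invariant to data order up to label permutation", {
  x <- c(rnorm(25, 0.2, 0.02), rnorm(25, 0.5, 0.02), rnorm(25, 0.85, 0.02))
  p1 <- fcmCluster(x, c = 3, seed = 2)
  set.seed(17); perm <- sample(length(x))
  p2 <- fcmCluster(x[perm], c = 3, seed = 8)
  expect_equal(sort(clusterCenters(p1)), sort(clusterCenters(p2)),
               tolerance = 1e-4)
})

test_that("NP cluster selection picks the brightest cluster with documented ties", {
  ph <- generatePhantom(phantomSpec(blurSigma = 0, noiseSd = 0))
  crop <- kmeansCrop(phantomImage(ph), ivdContour(ph), seed = 2)
  p <- fcmCluster(crop$image, c = 3, seed = 2)
  sel <- selectNpCluster(p, crop$discMask)
  bb <- crop$bbox
  expect_identical(sel, npMask(ph)[bb[1]:bb[2], bb[3]:bb[4]])
  # all-equal centroids: tie resolves to the first cluster
  fake <- new("FuzzyPartition",
              membership = matrix(1 / 2, 4, 2), centers = c(0.5, 0.5),
              objective = 0, objectiveTrace = 0, nIter = 1L,
              converged = TRUE, m = 2)
  msk <- matrix(TRUE, 2, 2)
  sel2 <- selectNpCluster(fake, msk)
  expect_true(all(sel2))          # every pixel tied -> cluster 1 selected
})

test_that("interference removal opens away specks and keeps the main blob", {
  m <- matrix(FALSE, 20, 20)
  m[5:14, 5:14] <- TRUE
  m[2, 2] <- m[18, 3] <- m[3, 18] <- TRUE
  cleaned <- removeInterference(m, radius = 1)
  expect_false(cleaned[2, 2] || cleaned[18, 3] || cleaned[3, 18])
  expect_true(all(cleaned[6:13, 6:13]))
  # opening is idempotent
  expect_identical(binaryOpen(cleaned, 1), cleaned)
  expect_error(removeInterference(matrix(FALSE, 5, 5) | FALSE, radius = 1),
               "segmentation failure")
})
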