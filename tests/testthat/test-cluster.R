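# smoothness estimation, cluster labeling, Monte-Carlo extent threshold
# and conjunction analysis

test_that("smoothness estimation recovers a known smoothing kernel", {
  set.seed(21)
  dims <- c(24L, 24L, 24L)
  vox <- 3.5
  target <- 8
  # residual-like series: independent volumes smoothed with a known kernel
  arr <- array(rnorm(prod(dims) * 12), c(dims, 12L))
  sm <- smoothVolume(arr, target, vox)
  est <- estimateSmoothness(sm, voxelSize = vox)
  expect_true(all(abs(est$fwhm - target) / target < 0.15))
  # scale invariance
  est2 <- estimateSmoothness(sm * 7.3, voxelSize = vox)
  expect_equal(est$fwhm, est2$fwhm, tolerance = 1e-10)
  # white noise: flagged as rougher than any smoothed field, with the
  # FWHM pinned at the voxel size
  w <- capture_warnings(estW <- estimateSmoothness(arr, voxelSize = vox))
  expect_true(any(grepl("rougher than white noise", w)))
  expect_true(all(estW$fwhm <= 1.5 * vox))
  # constant image: flagged error path
  expect_error(estimateSmoothness(array(1, c(4, 4, 4, 5))),
               "no variance")
})

test_that("cluster labeling matches the flood-fill oracle", {
  # two face-adjacent voxels form one cluster under every connectivity
  bin <- array(FALSE, c(4, 4, 4))
  bin[2, 2, 2] <- bin[3, 2, 2] <- TRUE
  for (conn in c(6L, 18L, 26L)) {
    lc <- labelClusters(bin, conn)
    expect_identical(lc$table$size, 2L)
  }
  # empty map
  lc0 <- labelClusters(array(FALSE, c(3, 3, 3)))
  expect_identical(nrow(lc0$table), 0L)
  # hand-drawn pattern with a corner-diagonal bridge: connected only
  # under 26-connectivity
  pat <- array(FALSE, c(5, 5, 5))
  pat[1:2, 1:2, 1:2] <- TRUE
  pat[3:4, 3:4, 3:4] <- TRUE
  expect_identical(nrow(labelClusters(pat, 26L)$table), 1L)
  expect_identical(nrow(labelClusters(pat, 6L)$table), 2L)
  expect_identical(sort(labelClusters(pat, 6L)$table$size),
                   sort(oracleClusterSizes(pat, 6)))
  # random volumes against the oracle for each connectivity
  set.seed(22)
  for (i in 1:12) {
    rb <- array(runif(1000) < 0.2, c(10, 10, 10))
    for (conn in c(6L, 18L, 26L)) {
      got <- labelClusters(rb, conn)$table$size
      want <- oracleClusterSizes(rb, conn)
      expect_identical(sort(got), sort(as.integer(want)))
      expect_identical(sum(got), sum(rb))
    }
  }
})

test_that("cluster tables report peaks in world coordinates", {
  bin <- array(FALSE, c(5, 5, 5))
  bin[2:3, 2, 2] <- TRUE
  stat <- array(0, c(5, 5, 5))
  stat[3, 2, 2] <- 4.2
  affine <- diag(c(2, 2, 2, 1))
  tab <- labelClusters(bin, 26L, statMap = stat, affine = affine)$table
  expect_equal(tab$peak_stat, 4.2)
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z),
               c((3 - 1) * 2, (2 - 1) * 2, (2 - 1) * 2))
})

test_that("the extent simulation is deterministic and degenerates sanely", {
  sm <- structure(list(fwhm = rep(7, 3), voxelSize = rep(3.5, 3)),
                  class = "SmoothnessEstimate")
  e1 <- simulateExtentThreshold(c(20L, 20L, 20L), smoothness = sm,
                                voxelP = 1e-9, nIter = 100L, seed = 9L)
  # virtually no suprathreshold voxels at an extreme threshold
  expect_identical(extentK(e1), 1L)
  e2 <- simulateExtentThreshold(c(20L, 20L, 20L), smoothness = sm,
                                voxelP = 0.005, nIter = 150L, seed = 10L)
  e3 <- simulateExtentThreshold(c(20L, 20L, 20L), smoothness = sm,
                                voxelP = 0.005, nIter = 150L, seed = 10L)
  expect_identical(e2@nullMax, e3@nullMax)
  expect_identical(extentK(e2), extentK(e3))
  expect_error(simulateExtentThreshold(c(20L, 20L, 20L),
                                       smoothness = sm, nIter = 50L),
               "100")
  expect_warning(simulateExtentThreshold(c(4L, 4L, 4L), smoothness = sm,
                                         voxelP = 0.01, nIter = 100L,
                                         seed = 1L), "unstable")
})

test_that("the extent threshold k shrinks as the voxel threshold tightens", {
  sm <- structure(list(fwhm = rep(7, 3), voxelSize = rep(3.5, 3)),
                  class = "SmoothnessEstimate")
  ks <- vapply(c(0.01, 0.005, 0.001), function(p)
    extentK(simulateExtentThreshold(c(16L, 16L, 16L), smoothness = sm,
                                    voxelP = p, nIter = 200L,
                                    seed = 30L)), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("cluster-extent application keeps clusters of size >= k inclusively", {
  dims <- c(10L, 10L, 10L)
  tmap <- array(0, dims)
  tmap[2:4, 2:4, 2] <- 10   # 9-voxel cluster
  tmap[8, 8, 8] <- 10       # singleton
  g <- new("GroupStatMap", t = tmap, df = 11L, covariate = "c",
           affine = diag(4), voxelSize = rep(1, 3))
  ext <- new("ExtentThreshold", covariate = "c", voxelP = 0.005,
             nullMax = c(rep(1L, 90), rep(8L, 6), rep(9L, 4)), k = 9L,
             alpha = 0.05, seed = 1L, connectivity = 26L)
  res <- applyClusterThreshold(g, ext)
  expect_identical(res$clusters$size, 9L)
  expect_identical(sum(res$map), 9L)
  # a cluster exactly at k survives (inclusive threshold); smaller do not
  expect_false(res$map[8, 8, 8])
  expect_error(applyClusterThreshold(g, ext, connectivity = 6L),
               "match")
})

test_that("extent thresholds control family-wise error on fresh null fields", {
  sm <- structure(list(fwhm = rep(7, 3), voxelSize = rep(3.5, 3)),
                  class = "SmoothnessEstimate")
  dims <- c(16L, 16L, 16L)
  ext <- simulateExtentThreshold(dims, smoothness = sm, voxelP = 0.005,
                                 nIter = 400L, seed = 77L)
  set.seed(78)
  zCrit <- qnorm(1 - 0.005)
  hits <- 0L
  nFresh <- 200L
  for (i in seq_len(nFresh)) {
    x <- smoothVolume(array(rnorm(prod(dims)), dims), sm$fwhm,
                      sm$voxelSize)
    x <- (x - mean(x)) / sd(x)
    bin <- x > zCrit
    if (any(bin) &&
        max(labelClusters(bin, 26L)$table$size) >= extentK(ext))
      hits <- hits + 1L
  }
  expect_gte(hits / nFresh, 0.02)
  expect_lte(hits / nFresh, 0.10)
})

test_that("conjunction is the exact voxelwise intersection", {
  dims <- c(6L, 6L, 6L)
  set.seed(23)
  m1 <- array(runif(prod(dims)) < 0.4, dims)
  m2 <- array(runif(prod(dims)) < 0.4, dims)
  m3 <- array(runif(prod(dims)) < 0.4, dims)
  # idempotence, commutativity, associativity
  expect_identical(conjunction(list(m1, m1)), m1)
  expect_identical(conjunction(list(m1, m2)), conjunction(list(m2, m1)))
  expect_identical(conjunction(list(conjunction(list(m1, m2)), m3)),
                   conjunction(list(m1, conjunction(list(m2, m3)))))
  # oracle: set intersection of voxel indices
  want <- intersect(intersect(which(m1), which(m2)), which(m3))
  got <- which(conjunction(list(m1, m2, m3)))
  expect_identical(got, want)
  # disjoint maps give an empty conjunction
  a <- array(FALSE, dims); a[1, 1, 1] <- TRUE
  b <- array(FALSE, dims); b[6, 6, 6] <- TRUE
  expect_false(any(conjunction(list(a, b))))
  expect_error(conjunction(list(m1, array(TRUE, c(2, 2, 2)))), "shape")
})
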