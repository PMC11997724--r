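test_that("world-to-voxel mapping rounds to the nearest voxel centre", {
  g <- voxelGrid(c(10, 10, 10))
  r <- worldToVoxel(matrix(c(2.4, 0, 0), 1), g)
  expect_equal(r$index[1, ], c(2L, 0L, 0L))
  expect_true(r$inGrid)

  # 2 mm spacing: world 3.0 -> continuous index 1.5 -> 2 under
  # round-half-away-from-zero
  g2 <- voxelGrid(c(10, 10, 10), spacing = 2)
  r2 <- worldToVoxel(matrix(c(3, 0, 0), 1), g2)
  expect_equal(r2$index[1, 1], 2L)

  r3 <- worldToVoxel(matrix(c(-5, 0, 0), 1), g)
  expect_false(r3$inGrid)

  expect_error(worldToVoxel(matrix(c(NA, 0, 0), 1), g), "non-finite")
})

test_that("voxelization counts voxels traversed by straight segments", {
  g <- voxelGrid(c(32, 32, 32))
  seg <- matrix(c(5, 5, 5, 15, 5, 5), ncol = 3, byrow = TRUE)
  v <- voxelizeStreamlines(list(seg), g)
  expect_equal(length(v$voxels), 11L)  # centres 5..15 inclusive
  expect_equal(v$volume, 11)

  # duplicated streamline: identical union
  v2 <- voxelizeStreamlines(list(seg, seg), g)
  expect_identical(v$voxels, v2$voxels)

  # halving the resampling step leaves the voxel set unchanged
  v3 <- voxelizeStreamlines(list(seg), g, step = 0.25)
  expect_identical(v$voxels, v3$voxels)

  expect_error(
    voxelizeStreamlines(list(matrix(c(-9, -9, -9, -8, -8, -8), ncol = 3,
                                    byrow = TRUE)), g),
    "outside the grid")
})

test_that("streamline filtering respects lesion membership exactly", {
  set.seed(11)
  b <- randomBundle(6, extent = 20)
  shp <- c(24, 24, 24)
  emptyMask <- lesionMask(array(0L, shp))
  fullMask <- lesionMask(array(1L, shp))
  fe <- filterInjured(b, emptyMask)
  expect_false(any(fe$isInjured))
  expect_null(fe$injured)
  ff <- filterInjured(b, fullMask)
  expect_true(all(ff$isInjured))
  expect_null(ff$spared)

  # mask exactly the voxels of streamline 3: only #3 injured
  g <- voxelGrid(shp)
  ids3 <- voxelizeStreamlines(list(streamlines(b)[[3]]), g)$voxels
  arr <- array(0L, shp); arr[ids3] <- 1L
  # drop voxels shared with other streamlines so the fixture is selective
  others <- voxelizeStreamlines(streamlines(b)[-3], g)$voxels
  arr[intersect(ids3, others)] <- 0L
  if (sum(arr) > 0) {
    f3 <- filterInjured(b, lesionMask(arr))
    expect_true(f3$isInjured[3])
    expect_false(any(f3$isInjured[-3]))
  }

  # injured + spared restore the bundle in order
  expect_equal(sum(ff$isInjured) + sum(!ff$isInjured),
               length(streamlines(b)))
})

test_that("tract burden hits the 0, 1 and half-coverage limits", {
  set.seed(21)
  L <- randomBundle(5, extent = 18, name = "T_left")
  R <- randomBundle(5, extent = 18, name = "T_right")
  shp <- c(20, 20, 20)
  g <- voxelGrid(shp)

  b0 <- tractBurden(L, R, lesionMask(array(0L, shp)))
  expect_equal(b0$burden, 0)
  expect_equal(b0$total_lesion_volume, 0)

  b1 <- tractBurden(L, R, lesionMask(array(1L, shp)))
  expect_equal(b1$burden, 1)

  # lesion covering the voxels of a subset of streamlines gives the
  # brute-force per-voxel ratio
  idsL <- lapply(streamlines(L), function(s) voxelizeStreamlines(list(s), g)$voxels)
  idsR <- lapply(streamlines(R), function(s) voxelizeStreamlines(list(s), g)$voxels)
  lesion <- unique(c(idsL[[1]], idsL[[2]], idsR[[1]]))
  arr <- array(0L, shp); arr[lesion] <- 1L
  res <- tractBurden(L, R, lesionMask(arr))
  injL <- unique(unlist(idsL[vapply(idsL, function(v) any(v %in% lesion), logical(1))]))
  injR <- unique(unlist(idsR[vapply(idsR, function(v) any(v %in% lesion), logical(1))]))
  expect_equal(res$burden,
               ((length(injL) + length(injR)) / 2) /
                 ((length(unique(unlist(idsL))) + length(unique(unlist(idsR)))) / 2))
  expect_error(
    tractBurden(L, R, lesionMask(array(0L, c(2, 2, 2)))),
    "share a world frame|outside the grid")
})

test_that("total lesion volume scales with voxel volume", {
  arr <- array(0L, c(10, 10, 10)); arr[sample(1000, 37)] <- 1L
  m8 <- lesionMask(arr, affine = diag(c(2, 2, 2, 1)))
  expect_equal(totalLesionVolume(m8), 296)
  expect_equal(totalLesionVolume(lesionMask(array(0L, c(5, 5, 5)))), 0)
})

test_that("burden is translation-equivariant", {
  set.seed(31)
  L <- randomBundle(4, extent = 18, name = "T_left")
  R <- randomBundle(4, extent = 18, name = "T_right")
  shp <- c(20, 20, 20)
  arr <- array(as.integer(runif(prod(shp)) < 0.05), shp)
  base <- tractBurden(L, R, lesionMask(arr))

  shift <- c(7.25, -3.5, 11)
  A2 <- diag(4); A2[1:3, 4] <- shift
  L2 <- tractBundle("T_left", lapply(streamlines(L), function(s)
    sweep(s, 2, shift, "+")))
  R2 <- tractBundle("T_right", lapply(streamlines(R), function(s)
    sweep(s, 2, shift, "+")))
  shifted <- tractBurden(L2, R2, lesionMask(arr, affine = A2))
  expect_equal(shifted$burden, base$burden, tolerance = 1e-12)
  expect_equal(shifted$injured_vol_l, base$injured_vol_l)
})

test_that("injured voxel set is a subset of the canonical set, so burden <= 1", {
  set.seed(41)
  for (rep in 1:10) {
    b <- randomBundle(4, extent = 15)
    shp <- c(16, 16, 16)
    mask <- randomMask(shp, frac = runif(1, 0, 0.3))
    g <- voxelGrid(shp)
    can <- voxelizeStreamlines(b, g)
    f <- filterInjured(b, mask)
    if (!is.null(f$injured)) {
      inj <- voxelizeStreamlines(f$injured, g)
      expect_true(all(inj$voxels %in% can$voxels))
      expect_lte(inj$volume, can$volume)
    }
  }
})

test_that("adding lesion voxels never decreases burden", {
  set.seed(51)
  L <- randomBundle(4, extent = 15, name = "T_left")
  R <- randomBundle(4, extent = 15, name = "T_right")
  shp <- c(16, 16, 16)
  arr <- array(0L, shp)
  prev <- 0
  for (stepi in 1:8) {
    arr[sample(prod(shp), 150)] <- 1L
    cur <- tractBurden(L, R, lesionMask(arr))$burden
    expect_gte(cur, prev)
    prev <- cur
  }
})
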