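test_that("thresholding splits phases and matches generator ground truth", {
  st <- grayscaleStack(array(50, c(4, 4, 4)))
  expect_equal(porosityFraction(binarize(st, 97)), 100)   # all pore
  two <- grayscaleStack(array(c(40, 200), c(4, 4, 4)))
  vox <- binarize(two, 97)
  expect_equal(porosityFraction(vox), 50)
  # blurred noisy render binarized at the generator midpoint agrees >= 99%
  v <- genVolume(shape = c(48L, 48L, 48L), targetPorosity = 46, seed = 2)
  seg <- binarize(v$stack, threshold = 110)
  agree <- mean(voxelData(seg) == voxelData(v$truth))
  expect_gte(agree, 0.99)
  expect_error(binarize(two, 400), "255")
})

test_that("porosity fraction counts voxels and complements to 100", {
  expect_equal(porosityFraction(voxelVolume(array(1L, c(3, 3, 3)))), 100)
  checker <- array(as.integer((slice.index(array(0, c(4, 4, 4)), 1) +
                                 slice.index(array(0, c(4, 4, 4)), 2) +
                                 slice.index(array(0, c(4, 4, 4)), 3)) %% 2),
                   c(4, 4, 4))
  expect_equal(porosityFraction(voxelVolume(checker)), 50)
  v <- genVolume(shape = c(64L, 64L, 64L), targetPorosity = 46, seed = 4)
  expect_equal(porosityFraction(v$truth), 46, tolerance = 0.005)
  inv <- voxelVolume(1L - voxelData(v$truth))
  expect_equal(porosityFraction(v$truth) + porosityFraction(inv), 100)
})

test_that("connectivity labels pore components and detects percolation", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:8, 2:3, 2:3] <- 1L                    # single rectangular pore
  c1 <- connectivity(voxelVolume(arr))
  expect_equal(c1$nComponents, 1L)
  expect_equal(c1$largestComponentFraction, 100)
  # two disjoint pores of 70 and 30 voxels -> 70%
  arr2 <- array(0L, c(12, 12, 12))
  arr2[2:8, 2:6, 2:3] <- 1L                   # 7*5*2 = 70 voxels
  arr2[10:12, 8:12, 11:12] <- 1L              # 3*5*2 = 30 voxels
  c2 <- connectivity(voxelVolume(arr2))
  expect_equal(c2$nComponents, 2L)
  expect_equal(c2$largestComponentFraction, 70)
  # percolated GRF at 50%: largest component holds nearly all pore space
  v <- genVolume(shape = c(96L, 96L, 96L), targetPorosity = 50,
                 correlationLength = 6, seed = 6)
  c3 <- connectivity(v$truth)
  expect_gt(c3$largestComponentFraction, 99)
  expect_true(c3$faceSpanning)
  c4 <- connectivity(v$truth, faceSpanningRule = TRUE)
  expect_gt(c4$spanningFraction, 99)
  expect_error(connectivity(voxelVolume(array(0L, c(3, 3, 3)))), "no pore")
})

test_that("connectivity is invariant under axis permutation and reflection", {
  v <- genVolume(shape = c(32L, 32L, 32L), targetPorosity = 50,
                 correlationLength = 4, seed = 8)
  base <- connectivity(v$truth)$largestComponentFraction
  arr <- voxelData(v$truth)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(connectivity(voxelVolume(aperm(arr,
                                                perm)))$largestComponentFraction,
                 base)
  }
  refl <- arr[dim(arr)[1]:1, , ]
  expect_equal(connectivity(voxelVolume(refl))$largestComponentFraction,
               base)
})

test_that("local thickness reproduces slabs and digitized spheres", {
  # solid slab of 11 voxels: interior thickness 11 * voxel size
  arr <- array(1L, c(30, 30, 30)); arr[, , 10:20] <- 0L
  tm <- localThickness(voxelVolume(arr, voxelSize = c(2, 2, 2)), "solid")
  expect_equal(tm@thickness[15, 15, 15], 11 * 2)
  expect_equal(maxThickness(tm), 11 * 2)
  # digitized ball of radius 8: max thickness 2r within one voxel
  ball <- digitizedBall(41, 8)
  tb <- localThickness(voxelVolume(ball), "pore")
  expect_lt(abs(maxThickness(tb) - 16), 1)
  expect_error(localThickness(voxelVolume(array(1L, c(3, 3, 3))), "solid"),
               "empty")
})

test_that("local thickness equals the brute-force inscribed-sphere oracle", {
  set.seed(42)
  shapes <- list(c(16L, 16L, 16L), c(20L, 14L, 12L), c(20L, 20L, 20L))
  for (d in shapes) {
    field <- array(rnorm(prod(d)), d)
    sm <- gaussianBlurRef(field, 1.5)
    mask <- sm <= quantile(sm, 0.5)
    arr <- array(as.integer(mask), d)
    tm <- localThickness(voxelVolume(arr), "pore")
    oracle <- bruteLocalThickness(array(mask, d))
    expect_equal(tm@thickness, oracle, tolerance = 1e-9)
  }
})

test_that("local thickness is monotone under phase dilation", {
  set.seed(13)
  d <- c(18L, 18L, 18L)
  arr <- array(as.integer(runif(prod(d)) < 0.4), d)
  arr[c(1, d[1]), , ] <- 0L; arr[, c(1, d[2]), ] <- 0L
  arr[, , c(1, d[3])] <- 0L
  tm1 <- localThickness(voxelVolume(arr), "pore")
  # 6-neighborhood dilation
  dil <- arr
  dil[-1, , ] <- pmax(dil[-1, , ], arr[-d[1], , ])
  dil[-d[1], , ] <- pmax(dil[-d[1], , ], arr[-1, , ])
  dil[, -1, ] <- pmax(dil[, -1, ], arr[, -d[2], ])
  dil[, -d[2], ] <- pmax(dil[, -d[2], ], arr[, -1, ])
  dil[, , -1] <- pmax(dil[, , -1], arr[, , -d[3]])
  dil[, , -d[3]] <- pmax(dil[, , -d[3]], arr[, , -1])
  tm2 <- localThickness(voxelVolume(dil), "pore")
  expect_true(all(tm2@thickness >= tm1@thickness - 1e-9))
})

test_that("anisotropic voxels are resampled before thickness analysis", {
  arr <- array(1L, c(24, 24, 24)); arr[, , 9:16] <- 0L  # 8-voxel slab in z
  # z spacing twice x/y: slab is physically 16 units thick
  tm <- localThickness(voxelVolume(arr, voxelSize = c(1, 1, 2)), "solid")
  expect_equal(tm@voxelSize, 1)
  expect_equal(maxThickness(tm), 16, tolerance = 1)
})

test_that("structure comparison orders thickness by correlation length", {
  arrA <- array(1L, c(24, 24, 24)); arrA[, , 9:16] <- 0L   # 8-voxel slab
  arrB <- array(1L, c(24, 24, 24)); arrB[, , 7:18] <- 0L   # 12-voxel slab
  tA <- localThickness(voxelVolume(arrA), "solid")
  tB <- localThickness(voxelVolume(arrB), "solid")
  rep_ <- compareStructures(tB, tA)
  expect_equal(rep_$meanDifference,
               mean(tB@thickness[tB@thickness > 0]) -
                 mean(tA@thickness[tA@thickness > 0]))
  id <- compareStructures(tA, tA)
  expect_equal(id$meanDifference, 0)
  # coarser pore structure -> larger mean pore thickness
  vA <- genVolume(shape = c(48L, 48L, 48L), targetPorosity = 50,
                  correlationLength = 3, seed = 21)
  vB <- genVolume(shape = c(48L, 48L, 48L), targetPorosity = 50,
                  correlationLength = 6, seed = 21)
  mA <- localThickness(vA$truth, "pore")
  mB <- localThickness(vB$truth, "pore")
  expect_gt(meanThickness(mB), meanThickness(mA))
  expect_error(compareStructures(mA, localThickness(vA$truth, "solid")),
               "different phases")
})

test_that("TIFF stack round-trips grayscale and label volumes", {
  v <- genVolume(shape = c(16L, 16L, 8L), targetPorosity = 40,
                 correlationLength = 3, seed = 31,
                 voxelSize = c(2.7, 3.4, 3.0))
  tf <- tempfile(fileext = ".tif")
  writeVoxelTiff(v$stack, tf)
  back <- readVoxelTiff(tf)
  expect_s4_class(back, "GrayscaleStack")
  expect_equal(voxelData(back), voxelData(v$stack), tolerance = 0.51)
  expect_equal(voxelSize(back), c(2.7, 3.4, 3.0))
  tf2 <- tempfile(fileext = ".tif")
  writeVoxelTiff(v$truth, tf2)
  back2 <- readVoxelTiff(tf2)
  expect_s4_class(back2, "VoxelVolume")
  expect_equal(voxelData(back2), voxelData(v$truth))
})
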