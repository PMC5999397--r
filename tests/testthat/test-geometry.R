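test_that("z profile is flat for uniform volumes and zero for empty ones", {
  v <- TomoVolume(array(0.7, c(8, 8, 16)), 16)
  expect_equal(zProfile(v), rep(0.7, 16))
  v0 <- TomoVolume(array(0, c(8, 8, 16)), 16)
  expect_equal(zProfile(v0), rep(0, 16))
  expect_error(zProfile(v, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("z profile locates a slab's boundaries to within one slice", {
  cfg <- smallFlatConfig(thickness = 30)
  ph <- makePhantom(cfg)
  prof <- zProfile(ph$volume)
  b <- iceProfiler:::.slabBounds(prof) * voxelSizeNm(ph$volume)
  z0 <- cfg@volumeShape[3] * cfg@voxelSize / 10 / 2
  expect_lt(abs(b[1] - (z0 - 15)), voxelSizeNm(ph$volume))
  expect_lt(abs(b[2] - (z0 + 15)), voxelSizeNm(ph$volume))
})

test_that("surface fitting recovers planes exactly and flags degeneracy", {
  p <- cbind(x = c(0, 1, 0), y = c(0, 0, 1), z = c(10, 10, 10))
  s <- fitSurface(p)
  expect_equal(c(s@a, s@b, s@c), c(0, 0, 10), tolerance = 1e-12)
  expect_equal(s@fitResidual, 0)
  set.seed(3)
  x <- seq(0, 100, by = 5)
  p2 <- cbind(x = x, y = runif(length(x), 0, 50),
              z = x * tan(5 * pi / 180))
  s2 <- fitSurface(p2)
  expect_equal(s2@a, tan(5 * pi / 180), tolerance = 1e-6)
  expect_error(fitSurface(cbind(x = c(0, 1, 2), y = c(0, 1, 2),
                                z = c(0, 0, 1))),
               "degenerate")
})

test_that("noisy plane coefficients are recovered within 3 standard errors", {
  # Monte-Carlo regression oracle: sigma = 2 nm, 100 points
  set.seed(42)
  n <- 100
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  a <- tan(6 * pi / 180); b <- -tan(3 * pi / 180); c0 <- 55
  reps <- replicate(40, {
    z <- a * x + b * y + c0 + rnorm(n, 0, 2)
    s <- fitSurface(cbind(x, y, z))
    c(s@a, s@b, s@c)
  })
  se <- apply(reps, 1, sd)
  bias <- rowMeans(reps) - c(a, b, c0)
  expect_true(all(abs(bias) < 3 * se / sqrt(40) + 3 * se))
  s1 <- fitSurface(cbind(x, y, a * x + b * y + c0 + rnorm(n, 0, 2)))
  expect_true(abs(s1@a - a) < 3 * se[1] && abs(s1@b - b) < 3 * se[2])
})

test_that("surface tilt follows the normal-vector arithmetic", {
  mk <- function(a, b) new("InterfaceSurface", side = "bottom", a = a, b = b,
                           c = 50, order = 1L, fitResidual = 0,
                           locator = "analytic", supportPoints = 3L)
  expect_equal(surfaceTilt(mk(0, 0)), 0)
  expect_equal(surfaceTilt(mk(tan(10 * pi / 180), 0)), 10, tolerance = 1e-9)
  t3 <- tan(3 * pi / 180); t4 <- tan(4 * pi / 180)
  expect_equal(surfaceTilt(mk(t3, t4)),
               acos(1 / sqrt(1 + t3^2 + t4^2)) * 180 / pi,
               tolerance = 1e-12)
})

test_that("gradient strategy matches analytic surfaces on noiseless input", {
  cfg <- quickConfig(seed = 21L, noiseSigma = 0)
  ph <- makePhantom(cfg)
  mask <- holeMaskFor(ph$volume, cfg@holeRadius)
  su <- locateInterfaces(ph$volume, "gradient", mask = mask)
  s <- truthSurfaces(ph$truth)
  vs <- voxelSizeNm(ph$volume)
  gx <- seq(25, 205, by = 5)
  inm <- outer((gx - 115.2)^2, (gx - 115.2)^2, "+") <= cfg@holeRadius^2
  for (side in c("bottom", "top")) {
    err <- surfaceHeight(su[[side]], gx, gx, grid = TRUE) -
      surfaceHeight(s[[side]], gx, gx, grid = TRUE)
    expect_lt(max(abs(err[inm])), vs)  # within one voxel everywhere in mask
  }
})

test_that("contamination strategy anchors surfaces within a few nm", {
  cfg <- quickConfig(seed = 11L, nParticles = 0L, contaminationDensity = 250,
                     noiseSigma = 0.15,
                     bottomProfile = flatProfile(50),
                     topProfile = flatProfile(50))
  ph <- makePhantom(cfg)
  su <- locateInterfaces(ph$volume, "contamination")
  s <- truthSurfaces(ph$truth)
  gx <- seq(40, 190, by = 10)
  for (side in c("bottom", "top")) {
    err <- surfaceHeight(su[[side]], gx, rep(115.2, length(gx))) -
      surfaceHeight(s[[side]], gx, rep(115.2, length(gx)))
    expect_lt(max(abs(err)), 5)
  }
  expect_identical(su$bottom@locator, "contamination")
  # too few blobs is an explicit error
  cfg2 <- quickConfig(seed = 11L, nParticles = 0L, contaminationDensity = 10,
                      noiseSigma = 0)
  expect_error(locateInterfaces(makePhantom(cfg2)$volume, "contamination"),
               "contamination blobs")
})

test_that("particle-layer strategy places surfaces at the hinted offset", {
  cfg <- quickConfig(seed = 12L, noiseSigma = 0.2, layerOffset = 5)
  ph <- makePhantom(cfg)
  su <- locateInterfaces(ph$volume, "particle_layer", hint = 5)
  s <- truthSurfaces(ph$truth)
  gx <- seq(60, 170, by = 10)
  for (side in c("bottom", "top")) {
    err <- surfaceHeight(su[[side]], gx, rep(115.2, length(gx))) -
      surfaceHeight(s[[side]], gx, rep(115.2, length(gx)))
    expect_lt(max(abs(err)), 5)
  }
  expect_error(locateInterfaces(ph$volume, "particle_layer"),
               "hint")
})

test_that("thickness statistics: flat, concave, and C4 classification", {
  # parallel flat surfaces 30 nm apart
  mkFlat <- function(z, side) new("InterfaceSurface", side = side, a = 0,
                                  b = 0, c = z, x0 = 300, y0 = 300,
                                  order = 1L, fitResidual = 0,
                                  locator = "analytic", supportPoints = 0L)
  g <- thicknessStats(mkFlat(40, "bottom"), mkFlat(70, "top"),
                      holeRadius = 300, holeCenter = c(300, 300),
                      particleMinorAxis = 10)
  expect_equal(g@tCenterMin, 30)
  expect_equal(g@tEdgeMin, 30)
  expect_identical(c(g@curvatureBottom, g@curvatureTop), c("C2", "C2"))
  # concave 30 nm centre / 100 nm edge, 10 nm particle: C3/C3
  g3 <- canonicalHoleGeometry(center = 30, edge = 100, particle = 10)
  expect_identical(c(g3@curvatureBottom, g3@curvatureTop), c("C3", "C3"))
  expect_lt(abs(g3@tCenterMin - 30), 5)
  # 8 nm centre with a 15 nm particle: C4
  g4 <- canonicalHoleGeometry(center = 8, edge = 100, particle = 15)
  expect_identical(g4@curvatureBottom, "C4")
  # crossing surfaces: degenerate, zero thickness, no exception
  gx <- thicknessStats(mkFlat(70, "bottom"), mkFlat(40, "top"),
                       holeRadius = 300, holeCenter = c(300, 300),
                       particleMinorAxis = 10)
  expect_true(gx@degenerate)
  expect_equal(gx@tCenterMin, 0)
})

test_that("thickness is invariant under 90-degree rotation about z", {
  cfg <- quickConfig(seed = 23L, interfaceTilt = 6)
  ph <- makePhantom(cfg)
  mask <- holeMaskFor(ph$volume, cfg@holeRadius)
  vs <- voxelSizeNm(ph$volume)
  measure <- function(vol, mask) {
    su <- locateInterfaces(vol, "gradient", mask = mask)
    g <- thicknessStats(su$bottom, su$top, cfg@holeRadius,
                        holeCenter = c(115.2, 115.2), particleMinorAxis = 10)
    c(g@tCenterMin, g@tEdgeMin, g@tiltBottom)
  }
  m1 <- measure(ph$volume, mask)
  arr <- densities(ph$volume)
  rot <- aperm(arr, c(2, 1, 3))[, dim(arr)[1]:1, ]  # 90 deg about z
  m2 <- measure(TomoVolume(rot, voxelSize(ph$volume)), mask)
  expect_lt(max(abs(m1[1:2] - m2[1:2])), vs)
  expect_lt(abs(m1[3] - m2[3]), 0.5)
})

test_that("inflating the surfaces apart shifts every thickness by delta", {
  g <- canonicalHoleGeometry()
  cfg <- phantomConfig(volumeShape = c(32L, 32L, 32L),
                       voxelSize = 10 * 2 * 600 * 1.1 / 32, holeRadius = 600,
                       bottomProfile = list(class = "C3", center = 15, edge = 50),
                       topProfile = list(class = "C3", center = 15, edge = 50),
                       interfaceTilt = 4, nParticles = 0L, noiseSigma = 0)
  s <- truthSurfaces(makePhantom(cfg)$truth)
  delta <- 12
  s$bottom@c <- s$bottom@c - delta / 2
  s$top@c <- s$top@c + delta / 2
  g2 <- thicknessStats(s$bottom, s$top, 600, particleMinorAxis = 10,
                       gridStep = 10)
  expect_equal(g2@thicknessMap, g@thicknessMap + delta, tolerance = 1e-9)
})

test_that("binning reduces each axis by the factor and averages blocks", {
  arr <- array(seq_len(8 * 8 * 8), c(8, 8, 8))
  v <- TomoVolume(arr, 4)
  b <- binVolume(v, 4L)
  expect_identical(dim(b), c(2L, 2L, 2L))
  expect_equal(voxelSize(b), 16)
  expect_equal(densities(b)[1, 1, 1], mean(arr[1:4, 1:4, 1:4]))
})
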