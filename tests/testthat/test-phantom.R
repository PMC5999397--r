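test_that("flat parallel interfaces give a constant thickness map", {
  cfg <- smallFlatConfig(thickness = 30)
  ph <- makePhantom(cfg)
  mask <- holeMaskFor(ph$volume, cfg@holeRadius)
  expect_equal(max(abs(ph$truth@thicknessMap[mask] - 30)), 0)
})

test_that("requested adsorbed count is realized exactly in the truth", {
  cfg <- quickConfig(seed = 3L, nParticles = 200L, adsorbedFraction = 0.9,
                     noiseSigma = 0)
  ph <- makePhantom(cfg)
  expect_identical(sum(ph$truth@particles$adsorbed), 180L)
  expect_equal(ph$truth@realizedAdsorbedFraction, 0.9)
  # adsorbed-fraction realization differs from the request by rounding only
  for (f in c(0.31, 0.57)) {
    cfg2 <- quickConfig(seed = 4L, nParticles = 101L, adsorbedFraction = f,
                        noiseSigma = 0)
    tr <- makePhantom(cfg2)$truth
    expect_lte(abs(tr@realizedAdsorbedFraction - f), 1 / 101)
  }
})

test_that("configured plane tilt appears exactly in the truth surfaces", {
  cfg <- quickConfig(seed = 2L, interfaceTilt = 10, nParticles = 0L,
                     topProfile = flatProfile(60), bottomProfile = flatProfile(60),
                     noiseSigma = 0)
  s <- truthSurfaces(makePhantom(cfg)$truth)
  expect_equal(surfaceTilt(s$bottom), 10, tolerance = 1e-9)
  expect_equal(surfaceTilt(s$top), 10, tolerance = 1e-9)
})

test_that("generation is deterministic in (config, seed)", {
  cfg <- quickConfig(seed = 9L, nParticles = 40L, noiseSigma = 0.2,
                     contaminationDensity = 100, fragmentDensity = 50)
  a <- makePhantom(cfg)
  b <- makePhantom(cfg)
  expect_identical(densities(a$volume), densities(b$volume))
  expect_identical(a$truth@particles, b$truth@particles)
})

test_that("adsorbed particles sit at the layer offset; free ones keep clear", {
  cfg <- quickConfig(seed = 5L, nParticles = 150L, adsorbedFraction = 0.8,
                     layerOffset = 5, noiseSigma = 0)
  tr <- makePhantom(cfg)$truth
  p <- tr@particles
  sb <- tr@surfaces$bottom; st <- tr@surfaces$top
  zb <- iceProfiler:::.surfaceZ(sb, p$x, p$y)
  zt <- iceProfiler:::.surfaceZ(st, p$x, p$y)
  ads <- p$adsorbed
  offs <- ifelse(p$side == "bottom", p$z - zb, zt - p$z)
  expect_lte(max(abs(offs[ads] - 5)), cfg@voxelSize / 10)
  # non-adsorbed: at least one particle radius from each surface
  expect_true(all(p$z[!ads] - zb[!ads] >= p$diameter[!ads] / 2 - 1e-9))
  expect_true(all(zt[!ads] - p$z[!ads] >= p$diameter[!ads] / 2 - 1e-9))
  # all centres strictly between the surfaces
  expect_true(all(p$z > zb & p$z < zt))
})

test_that("particle mass is additive: total added density scales with n", {
  base <- smallFlatConfig(thickness = 40, nParticles = 0L)
  ph0 <- makePhantom(base)
  cfgN <- smallFlatConfig(thickness = 40, nParticles = 25L)
  phN <- makePhantom(cfgN)
  added <- sum(densities(phN$volume)) - sum(densities(ph0$volume))
  # one reference particle rendered in the same geometry
  cfg1 <- smallFlatConfig(thickness = 40, nParticles = 1L, seed = 2L)
  ph1 <- makePhantom(cfg1)
  one <- sum(densities(ph1$volume)) - sum(densities(ph0$volume))
  expect_lt(abs(added - 25 * one) / abs(25 * one), 0.001)
})

test_that("C1 and C3 profiles are distinguishable in the thickness map", {
  convex <- list(class = "C1", center = 50, edge = 15)
  concave <- list(class = "C3", center = 15, edge = 50)
  cfg1 <- quickConfig(seed = 1L, bottomProfile = convex, topProfile = convex,
                      nParticles = 0L, noiseSigma = 0)
  cfg3 <- quickConfig(seed = 1L, bottomProfile = concave,
                      topProfile = concave, nParticles = 0L, noiseSigma = 0)
  t1 <- makePhantom(cfg1)$truth; t3 <- makePhantom(cfg3)$truth
  ctr <- function(tr) tr@thicknessMap[72, 72]
  edg <- function(tr) tr@thicknessMap[72, 10]
  expect_gte(ctr(t1) - edg(t1), 2 * (50 - 15) - 0.5)
  expect_lte(ctr(t3) - edg(t3), -2 * (50 - 15) + 0.5)
})

test_that("C4 configs exclude whole particles from the thin centre", {
  c4 <- list(class = "C4", center = 3, edge = 50)
  cfg <- quickConfig(seed = 6L, bottomProfile = c4, topProfile = c4,
                     particleDiameter = 15, nParticles = 60L,
                     adsorbedFraction = 1, noiseSigma = 0)
  tr <- makePhantom(cfg)$truth
  p <- tr@particles
  thickAt <- iceProfiler:::.surfaceZ(tr@surfaces$top, p$x, p$y) -
    iceProfiler:::.surfaceZ(tr@surfaces$bottom, p$x, p$y)
  expect_true(all(thickAt >= 15))
  expect_identical(tr@taxonomy$curvature[["bottom"]], "C4")
})

test_that("infeasible configurations are rejected with the violated bound", {
  expect_error(quickConfig(nParticles = 4000L, saturationCap = 20),
               "saturation cap")
  expect_error(quickConfig(holeRadius = 500), "field of view")
  expect_error(quickConfig(bottomProfile = list(class = "C1", center = 10,
                                                edge = 40)),
               "inconsistent with curvature class")
})

test_that("orientation sampling: unit norm, degenerate and uniform limits", {
  v <- sampleOrientations(list(type = "uniform"), 5000, seed = 11)
  expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-9)
  # uniform: small mean resultant length
  expect_lt(sqrt(sum(colSums(v)^2)) / nrow(v), 0.05)
  # concentrated single mode collapses onto the mode direction
  m <- sampleOrientations(list(type = "modes",
                               directions = rbind(c(0, 1, 0)),
                               kappa = 1e8), 200, seed = 12)
  expect_lt(max(abs(sweep(m, 2, c(0, 1, 0)))), 1e-3)
  expect_error(sampleOrientations(list(type = "modes", kappa = 5), 10),
               "empty mode list")
})

test_that("two antipodal high-concentration modes cluster as two modes", {
  v <- sampleOrientations(list(type = "modes",
                               directions = rbind(c(0, 0, 1), c(0, 0, -1)),
                               kappa = 300), 200, seed = 13)
  o <- orientationDispersion(v)
  expect_identical(o@modeCount, 2L)
})

test_that("ground truth round-trips losslessly through JSON", {
  cfg <- smallFlatConfig(thickness = 35, nParticles = 20L, seed = 8L)
  tr <- makePhantom(cfg)$truth
  f <- tempfile(fileext = ".json")
  writeGroundTruth(tr, f)
  tr2 <- readGroundTruth(f)
  expect_equal(tr2@particles$x, tr@particles$x)
  expect_equal(tr2@particles$adsorbed, tr@particles$adsorbed)
  expect_identical(nrow(tr2@particles), 20L)
  expect_equal(tr2@surfaces$bottom$z0, tr@surfaces$bottom$z0)
  expect_identical(tr2@taxonomy$curvature, tr@taxonomy$curvature)
  # empty particle list still round-trips
  tr0 <- makePhantom(smallFlatConfig(nParticles = 0L))$truth
  f0 <- tempfile(fileext = ".json")
  writeGroundTruth(tr0, f0)
  expect_identical(nrow(readGroundTruth(f0)@particles), 0L)
  # particle CSV carries the documented columns
  fc <- tempfile(fileext = ".csv")
  writeParticleCSV(tr, fc)
  tab <- read.csv(fc)
  expect_identical(nrow(tab), 20L)
  expect_true(all(c("x_nm", "y_nm", "z_nm", "vx", "vy", "vz", "adsorbed",
                    "side", "layer") %in% names(tab)))
})

test_that("the missing-wedge filter zeroes the wedge and nothing else", {
  cfg <- smallFlatConfig(thickness = 30, nParticles = 3L,
                         missingWedge = TRUE, wedgeTiltRange = 45)
  ph <- makePhantom(cfg)
  ft <- fft(densities(ph$volume))
  d <- dim(ft)
  ky <- iceProfiler:::.freqAxis(d[2], 1)
  kz <- iceProfiler:::.freqAxis(d[3], 1)
  KY <- matrix(rep(abs(ky), times = d[3]), d[2], d[3])
  KZ <- matrix(rep(abs(kz), each = d[2]), d[2], d[3])
  wedge <- KZ > tan(45 * pi / 180) * KY + 1e-12
  for (i in c(1L, 5L, d[1])) {
    expect_lt(max(Mod(ft[i, , ][wedge])), 1e-6)
  }
  expect_gt(max(Mod(ft[1, , ][!wedge])), 1e-6)
})
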