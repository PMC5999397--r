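test_that("a single centred sphere is detected once, at its centre", {
  cfg <- smallFlatConfig(thickness = 40, nParticles = 1L, seed = 2L)
  ph <- makePhantom(cfg)
  det <- detectParticles(ph$volume, 10)
  expect_identical(nrow(det), 1L)
  tr <- ph$truth@particles
  vs <- voxelSizeNm(ph$volume)
  expect_lt(sqrt((det$x - tr$x)^2 + (det$y - tr$y)^2 + (det$z - tr$z)^2), vs)
})

test_that("detection achieves >= 0.9 recall and precision at SNR 3", {
  cfg <- quickConfig(seed = 31L, nParticles = 100L, noiseSigma = 1 / 3)
  ph <- makePhantom(cfg)
  det <- detectParticles(ph$volume, 10)
  tr <- ph$truth@particles
  matchR <- 5  # half a diameter
  dmat <- outer(tr$x, det$x, "-")^2 + outer(tr$y, det$y, "-")^2 +
    outer(tr$z, det$z, "-")^2
  recall <- mean(apply(dmat, 1, min) < matchR^2)
  precision <- mean(apply(dmat, 2, min) < matchR^2)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("a noise-only volume yields almost no false detections", {
  # null phantom: ice slab, no particles, realistic noise
  cfg <- quickConfig(seed = 32L, nParticles = 0L, noiseSigma = 1 / 3)
  ph <- makePhantom(cfg)
  det <- detectParticles(ph$volume, 10)
  vol_nm3 <- prod(dim(ph$volume)) * voxelSizeNm(ph$volume)^3
  expect_lte(nrow(det), 2 * vol_nm3 / 500^3 + 2)
  # scale outside the sampling limit raises
  expect_error(detectParticles(ph$volume, 2.5), "Nyquist")
})

test_that("layer assignment partitions particles and recovers the truth", {
  cfg <- quickConfig(seed = 33L, adsorbedFraction = 0.9, layerOffset = 5,
                     noiseSigma = 0.25)
  ph <- makePhantom(cfg)
  mask <- holeMaskFor(ph$volume, cfg@holeRadius)
  su <- locateInterfaces(ph$volume, "gradient", mask = mask)
  det <- detectParticles(ph$volume, 10)
  asg <- assignToLayers(det, su$bottom, su$top, cutoff = 10, diameter = 10,
                        holeArea = pi * cfg@holeRadius^2)
  p <- asg$particles
  # partition: every particle in exactly one of bottom/top/none
  expect_true(all(p$side %in% c("bottom", "top", "none")))
  expect_true(all((p$side == "none") == !p$adsorbed))
  expect_true(all(is.na(p$layer[!p$adsorbed])))
  f <- adsorbedFraction(p)
  expect_gte(f, 0.85); expect_lte(f, 0.95)
  expect_identical(nrow(asg$layers), 2L)
})

test_that("mid-ice centroids far from both surfaces form no layers", {
  mkFlat <- function(z, side) new("InterfaceSurface", side = side, a = 0,
                                  b = 0, c = z, order = 1L, fitResidual = 0,
                                  locator = "analytic", supportPoints = 0L)
  cen <- data.frame(x = runif(20, 0, 200), y = runif(20, 0, 200), z = 60)
  asg <- assignToLayers(cen, mkFlat(10, "bottom"), mkFlat(110, "top"),
                        cutoff = 10)
  expect_identical(nrow(asg$layers), 0L)
  expect_true(all(!asg$particles$adsorbed))
  expect_identical(layerCountToken(asg$particles), "0")
  expect_error(assignToLayers(cen, mkFlat(110, "bottom"), mkFlat(10, "top")),
               "cross")
})

test_that("layer tokens follow the survey vocabulary, including 2+ and 1-2", {
  mk <- function(sides) data.frame(adsorbed = sides != "none", side = sides,
                                   layer = c(bottom = 1L, top = 2L,
                                             none = NA_integer_)[sides])
  two <- mk(rep(c("bottom", "top"), each = 20))
  expect_identical(layerCountToken(two), "2")
  twoPlus <- mk(c(rep(c("bottom", "top"), each = 20), rep("none", 5)))
  expect_identical(layerCountToken(twoPlus), "2+")
  # sub-regions disagreeing give the 1-2 token
  p <- mk(c(rep("bottom", 10), rep(c("bottom", "top"), each = 10)))
  regions <- factor(c(rep("center", 10), rep("edge", 20)))
  expect_identical(layerCountToken(p, regions), "1-2")
})

test_that("adsorbed fraction is the exact count ratio and cutoff-monotone", {
  p <- data.frame(adsorbed = c(rep(TRUE, 9), FALSE))
  expect_identical(adsorbedFraction(p), 0.9)
  expect_identical(adsorbedFraction(data.frame(adsorbed = rep(TRUE, 7))), 1)
  expect_error(adsorbedFraction(data.frame(adsorbed = logical(0))), "empty")
  # monotone in the cutoff
  mkFlat <- function(z, side) new("InterfaceSurface", side = side, a = 0,
                                  b = 0, c = z, order = 1L, fitResidual = 0,
                                  locator = "analytic", supportPoints = 0L)
  set.seed(7)
  cen <- data.frame(x = runif(60, 0, 200), y = runif(60, 0, 200),
                    z = runif(60, 12, 98))
  fr <- vapply(c(5, 10, 20, 40), function(cut) {
    adsorbedFraction(assignToLayers(cen, mkFlat(10, "bottom"),
                                    mkFlat(100, "top"),
                                    cutoff = cut)$particles)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("layer tilt recovers configured tilts within the 1-degree error", {
  for (tilt in c(6, 16)) {
    cfg <- quickConfig(seed = 40L + tilt, interfaceTilt = tilt,
                       bottomProfile = flatProfile(70),
                       topProfile = flatProfile(70),
                       adsorbedFraction = 1, layerSplit = 1,
                       nParticles = 120L, noiseSigma = 0.25)
    ph <- makePhantom(cfg)
    det <- detectParticles(ph$volume, 10)
    expect_lt(abs(layerTilt(det) - tilt), 1)
  }
  # coplanar layer at constant z
  flat <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100), z = 50)
  expect_equal(layerTilt(flat), 0, tolerance = 1e-9)
})

test_that("layer saturation matches hexagonal-packing constructions", {
  expect_identical(layerSaturation(0, 10, 1e5), 0)
  # hexagonally packed disc centres at spacing = diameter
  d <- 10
  pts <- NULL
  for (row in 0:19) {
    y <- row * d * sqrt(3) / 2
    xs <- seq(0, 19 * d, by = d) + (row %% 2) * d / 2
    pts <- rbind(pts, cbind(xs, y))
  }
  area <- (19 * d + d) * (19 * d * sqrt(3) / 2 + d * sqrt(3) / 2)
  sat <- layerSaturation(nrow(pts), d, area)
  expect_gt(sat, 98); expect_lte(sat, 100)
  satHalf <- layerSaturation(nrow(pts) / 2, d, area)
  expect_equal(satHalf, sat / 2, tolerance = 0.04)
  expect_error(layerSaturation(5, 10, 0), "area")
})

test_that("projection overlap matches the all-pairs brute force exactly", {
  expect_equal(projectionOverlap(data.frame(x = c(0, 0), y = c(0, 0),
                                            z = c(0, 50)), 10)$overlapFraction,
               1)
  two <- projectionOverlap(data.frame(x = c(0, 30), y = c(0, 0),
                                      z = c(0, 0)), 10)
  expect_equal(two$overlapFraction, 0)
  expect_identical(two$uniqueCount, 2L)
  # random bilayer against the O(n^2) oracle
  set.seed(99)
  for (n in c(50, 300, 500)) {
    p <- data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400),
                    z = runif(n, 0, 80))
    got <- projectionOverlap(p, 12)
    bf <- vapply(seq_len(n), function(i)
      any(sqrt((p$x[-i] - p$x[i])^2 + (p$y[-i] - p$y[i])^2) < 12),
      logical(1))
    expect_identical(got$overlapped, bf)
    expect_identical(got$uniqueCount, sum(!bf))
  }
})

test_that("behavior classification maps adsorption and orientation to B codes", {
  expect_identical(classifyBehavior(FALSE), "B1")
  uni <- orientationDispersion(sampleOrientations(list(type = "uniform"),
                                                  200, seed = 51))
  expect_identical(classifyBehavior(TRUE, uni, 200L), "B2")
  two <- orientationDispersion(sampleOrientations(
    list(type = "modes", directions = rbind(c(0, 0, 1), c(1, 0, 0)),
         kappa = 200), 200, seed = 52))
  expect_identical(classifyBehavior(TRUE, two, 200L), "B3")
  expect_identical(classifyBehavior(TRUE, uni, 3L), "unknown")
  expect_identical(classifyBehavior(TRUE, fragmentsAnnotation = "B4"), "B4")
})
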