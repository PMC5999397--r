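# Shared fixtures: small, fast phantom configurations and truth-based
# surface pairs used across the suite.

flatProfile <- function(t = 25) list(class = "C2", center = t / 2, edge = t / 2)

# a modest phantom: 144^3-class field at bin-4 voxel size (16 A)
quickConfig <- function(seed = 1L, ...) {
  phantomConfig(seed = as.integer(seed), ...)
}

# small flat phantom for cheap unit tests
smallFlatConfig <- function(seed = 1L, thickness = 30, nParticles = 0L, ...) {
  phantomConfig(volumeShape = c(64L, 64L, 48L), voxelSize = 16,
                holeRadius = 45,
                bottomProfile = flatProfile(thickness),
                topProfile = flatProfile(thickness),
                interfaceTilt = 0, nParticles = as.integer(nParticles),
                noiseSigma = 0, seed = as.integer(seed), ...)
}

truthSurfaces <- function(truth) {
  list(bottom = analyticInterface(truth@surfaces$bottom),
       top = analyticInterface(truth@surfaces$top))
}

holeMaskFor <- function(vol, holeRadius) {
  d <- dim(vol)
  vs <- voxelSizeNm(vol)
  xs <- (seq_len(d[1]) - 0.5) * vs
  ys <- (seq_len(d[2]) - 0.5) * vs
  sqrt(outer((xs - d[1] * vs / 2)^2, (ys - d[2] * vs / 2)^2, "+")) <= holeRadius
}

surveyRecords <- function() {
  loadSurvey(system.file("extdata", package = "iceProfiler"))
}

# analytic thin-centre / thick-edge hole geometry at realistic hole size
canonicalHoleGeometry <- function(R = 600, center = 30, edge = 100,
                                  tilt = 4, particle = 10) {
  cfg <- phantomConfig(volumeShape = c(32L, 32L, 32L),
                       voxelSize = 10 * 2 * R * 1.1 / 32, holeRadius = R,
                       bottomProfile = list(class = "C3", center = center / 2,
                                            edge = edge / 2),
                       topProfile = list(class = "C3", center = center / 2,
                                         edge = edge / 2),
                       interfaceTilt = tilt, nParticles = 0L, noiseSigma = 0)
  ph <- makePhantom(cfg)
  s <- truthSurfaces(ph$truth)
  thicknessStats(s$bottom, s$top, R, particleMinorAxis = particle,
                 gridStep = 10)
}
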