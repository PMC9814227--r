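test_that("fluid bilayer composition and leaflet bookkeeping are exact", {
  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0.1, seed = 1)
  sp <- lipidSpecies(syn$frame)
  expect_equal(sum(sp == "PIP2_160"), 90)
  expect_equal(sum(sp == "POPC"), 810)
  expect_equal(unname(table(leaflets(syn$frame))[c("lower", "upper")]),
               c(450L, 450L), ignore_attr = TRUE)
  expect_error(buildFluidBilayer(nLipids = 101), "even")
  expect_error(buildFluidBilayer(areaPerLipid = 0.1), "geometry")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- buildFluidBilayer(nLipids = 60, pip2Fraction = 0.2, seed = 33)
  b <- buildFluidBilayer(nLipids = 60, pip2Fraction = 0.2, seed = 33)
  c <- buildFluidBilayer(nLipids = 60, pip2Fraction = 0.2, seed = 34)
  expect_identical(beads(a$frame), beads(b$frame))
  expect_false(identical(beads(a$frame), beads(c$frame)))
  d1 <- simulateDecay(c(0.5, 0.5), c(2, 6), nPhotons = 1e4, seed = 5)
  d2 <- simulateDecay(c(0.5, 0.5), c(2, 6), nPhotons = 1e4, seed = 5)
  expect_identical(d1$hist@counts, d2$hist@counts)
})

test_that("chain disorder limits give planted order parameters", {
  syn0 <- buildFluidBilayer(nLipids = 60, pip2Fraction = 0,
                            chainDisorder = 0, seed = 2)
  b <- beads(syn0$frame)
  chain_beads <- c("C1A", "D2A", "C3A", "C4A")
  for (lp in unique(b$lipid)[1:10]) {
    sub <- b[b$lipid == lp & b$bead %in% chain_beads, ]
    expect_true(all(abs(diff(sub$x)) < 1e-12))
    expect_true(all(abs(diff(sub$y)) < 1e-12))
  }
  ## disorder 1: first-bond S ~ 0 within 3 SE over ~1e4 chains
  syn1 <- buildFluidBilayer(nLipids = 5000, pip2Fraction = 0,
                            chainDisorder = 1, seed = 3)
  op <- orderProfile(syn1$frame, "POPC")
  expect_lt(abs(op@S[1]), 3 * op@se[1])
})

test_that("planted clusters honor spacing and record a full partition", {
  syn <- buildFluidBilayer(nLipids = 600, pip2Fraction = 0.15, seed = 4)
  pc <- plantClusters(syn$frame, c(90), intraSpacing = 0.5, minGap = 2,
                      seed = 5)
  expect_length(pc$truth$plantedPartition, 1)
  expect_setequal(pc$truth$plantedPartition[[1]], syn$truth$pip2Lipids)

  big <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0.1, seed = 4)
  singles <- plantClusters(big$frame, rep(1, 90), intraSpacing = 0.5,
                           minGap = 0.7, seed = 6)
  expect_length(singles$truth$plantedPartition, 90)
  part <- detectClusters(singles$frame, "PIP2", cutoff = 0.6)
  expect_equal(averageClusterSize(part), 1.0)

  expect_error(plantClusters(syn$frame, c(10, 10)), "sum to")
  tiny <- buildFluidBilayer(nLipids = 60, pip2Fraction = 0.5, seed = 7)
  expect_error(
    plantClusters(tiny$frame, c(15, 15), minGap = 6, seed = 8),
    "packing")
})

test_that("gel patch plants lattice membership and height offset", {
  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0, seed = 9)
  gel <- buildGelPatch(syn$frame, 127, thicknessIncrease = 1.0, seed = 10)
  expect_equal(gel$truth$interiorCount, 91)
  expect_equal(nrow(gel$truth$gelMembership), 127)
  b <- beads(gel$frame)
  po4 <- b[b$bead == "PO4" &
             leaflets(gel$frame)[as.character(b$lipid)] == "upper", ]
  isgel <- po4$lipid %in% gel$truth$gelLipids
  expect_equal(mean(po4$z[isgel]) - mean(po4$z[!isgel]), 1.0,
               tolerance = 0.05)
  expect_error(buildGelPatch(syn$frame, 127, latticeSpacing = 0),
               "positive")
  ## huge spacing: patch must fit the box
  expect_error(buildGelPatch(syn$frame, 127, latticeSpacing = 5), "fit")
})

test_that("undulated bilayer records the analytic curvature field", {
  flat <- buildUndulatedBilayer(nLipids = 100, amplitude = 0,
                                wavelength = 5, seed = 11)
  expect_equal(flat$truth$analyticH(seq(0, 5, 0.5)), rep(0, 11))
  und <- buildUndulatedBilayer(nLipids = 1800, amplitude = 1,
                               wavelength = 24, seed = 12)
  H <- und$truth$analyticH
  ## crest: H = -A (2 pi / L)^2 / 2
  expect_equal(H(24 / 4), -1 * (2 * pi / 24)^2 / 2, tolerance = 1e-12)
  ## for A = 1, L = 25 the crest value is -0.0316 nm^-1
  k25 <- 2 * pi / 25
  expect_equal(-1 * k25^2 / 2, -0.0316, tolerance = 1e-3)
  ## antisymmetry: integrates to zero over one period
  xg <- seq(0, 24, length.out = 4801)[-4801]
  expect_lt(abs(mean(H(xg))), 1e-12)
})

test_that("asymmetric bilayer balances leaflet areas and composition", {
  asy <- buildAsymmetricBilayer(nLipidsUpper = 450,
                                pip2FractionLower = 0.1, seed = 13)
  sp <- lipidSpecies(asy$frame)
  lf <- leaflets(asy$frame)
  expect_equal(sum(sp[lf == "upper"] != "POPC"), 0)
  expect_equal(sum(sp[lf == "lower"] == "PIP2_160"), 45)
  expect_lt(abs(asy$truth$areaUpper - asy$truth$areaLower) /
              asy$truth$areaUpper, 0.01)
  ## distinct per-species areas still balance within 1%
  asy2 <- buildAsymmetricBilayer(nLipidsUpper = 450,
                                 pip2FractionLower = 0.1,
                                 pip2AreaPerLipid = 0.9, seed = 14)
  expect_lt(abs(asy2$truth$areaUpper - asy2$truth$areaLower) /
              asy2$truth$areaUpper, 0.01)
})

test_that("generated frames pass the data-model invariants", {
  for (seed in 1:3) {
    syn <- buildFluidBilayer(nLipids = 100, pip2Fraction = 0.2, seed = seed)
    expect_true(validObject(syn$frame))
    lf <- leaflets(syn$frame)
    expect_setequal(unique(lf), c("upper", "lower"))
    b <- beads(syn$frame)
    box <- boxDims(syn$frame)
    ## lipids contiguous: consecutive beads of one lipid stay bonded
    ## (no lipid split across periodic images after wrapping)
    for (lp in unique(b$lipid)[1:5]) {
      sub <- b[b$lipid == lp, ]
      ## a lipid split across images would show a jump of ~ box length
      step <- sqrt(diff(sub$x)^2 + diff(sub$y)^2 + diff(sub$z)^2)
      expect_lt(max(step), min(box) / 2)
    }
  }
})

test_that("decay simulator matches the single-exponential closed form", {
  sim <- simulateDecay(1, 5, nPhotons = 1e5, nChannels = 512,
                       channelWidth = 0.05, noiseless = TRUE)
  lc <- log(sim$hist@counts)
  expect_equal(diff(lc), rep(-0.05 / 5, 511), tolerance = 1e-9)
  expect_warning(simulateDecay(1, 50, nChannels = 256,
                               channelWidth = 0.05, seed = 1),
                 "truncated")
  expect_error(simulateDecay(c(0.5, 0.6), c(1, 5)), "normalized")
})

test_that("decay counts are Poisson-dispersed", {
  sim <- simulateDecay(c(0.6, 0.4), c(1, 10), nPhotons = 1e6, seed = 15)
  exp_counts <- simulateDecay(c(0.6, 0.4), c(1, 10), nPhotons = 1e6,
                              noiseless = TRUE)$hist@counts
  keep <- exp_counts > 5
  z <- (sim$hist@counts[keep] - exp_counts[keep]) / sqrt(exp_counts[keep])
  expect_equal(var(z), 1, tolerance = 0.1)
})

test_that("polarized-intensity generator inverts the anisotropy formula", {
  iso <- simulatePolarizedIntensities(0, G = 1)
  expect_equal(iso@IVV, iso@IVH)
  pol <- simulatePolarizedIntensities(1, G = 1)
  expect_equal(pol@IVH, 0)
  expect_error(simulatePolarizedIntensities(1.2), "range")
  for (r in seq(-0.5, 1, by = 0.25))
    for (G in c(0.5, 1, 1.8)) {
      I <- simulatePolarizedIntensities(r, G = G)
      expect_equal(gFactor(I), G, tolerance = 1e-12)
      expect_lt(abs(steadyStateAnisotropy(I) - r), 1e-12)
    }
})

test_that("thermal profile generator plants the logistic midpoint", {
  tp <- simulateThermalProfile(rLow = 0.05, rHigh = 0.25, Tm = 45,
                               width = 3, temperatures = seq(21, 69, 4),
                               noiseSD = 0, seed = 1)
  r45 <- tp$profile$r[tp$profile$temperature == 45]
  expect_equal(r45, (0.05 + 0.25) / 2, tolerance = 1e-12)
  expect_equal(tp$profile$r[tp$profile$temperature == 69], 0.05,
               tolerance = 1e-2)
  expect_error(simulateThermalProfile(temperatures = c(20, 30, 40)),
               "6 temperature")
})
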