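test_that("bond S-value reproduces the closed-form limits", {
  expect_equal(bondSValue(matrix(c(0, 0, 1), 1)), 1.0, tolerance = 1e-12)
  expect_equal(bondSValue(matrix(c(0, 0, -2.5), 1)), 1.0, tolerance = 1e-12)
  expect_equal(bondSValue(matrix(c(1, 0, 0), 1)), -0.5, tolerance = 1e-12)
  ## magic angle: cos^2 = 1/3
  v <- c(sqrt(2 / 3), 0, sqrt(1 / 3))
  expect_equal(bondSValue(matrix(v, 1)), 0, tolerance = 1e-12)
  expect_error(bondSValue(matrix(0, 1, 3)), "zero-length")
  ## rotation about the normal leaves S unchanged
  set.seed(1)
  vv <- matrix(rnorm(300), 100, 3)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(bondSValue(vv %*% R), bondSValue(vv), tolerance = 1e-12)
})

test_that("isotropic bonds give S near zero at the Monte-Carlo SE", {
  set.seed(2)
  n <- 1e5
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  vv <- cbind(s * cos(phi), s * sin(phi), z)
  ## exact sampling variance of (3cos^2-1)/2 under isotropy is 1/5
  se <- sqrt(0.2 / n)
  expect_lt(abs(bondSValue(vv)), 3 * se)
})

test_that("order profiles recover planted chain order, leaflet-symmetric", {
  syn0 <- buildFluidBilayer(nLipids = 80, pip2Fraction = 0.2,
                            chainDisorder = 0, seed = 3)
  op <- orderProfile(syn0$frame, "POPC")
  expect_equal(op@S, rep(1, 3), tolerance = 1e-12)
  opP <- orderProfile(syn0$frame, "PIP2")
  expect_equal(opP@S, rep(1, 3), tolerance = 1e-12)

  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0,
                           chainDisorder = 0.5, seed = 4)
  up <- orderProfile(syn$frame, "POPC", leaflet = "upper")
  lo <- orderProfile(syn$frame, "POPC", leaflet = "lower")
  expect_true(all(abs(up@S - lo@S) < 3 * sqrt(up@se^2 + lo@se^2)))
})

test_that("distance-resolved order recovers a planted ordered shell", {
  syn <- buildFluidBilayer(nLipids = 600, pip2Fraction = 0.15,
                           chainDisorder = 0.8, seed = 5)
  pc <- plantClusters(syn$frame, c(45, 45), intraSpacing = 0.5,
                      minGap = 3, seed = 6)
  fr <- pc$frame
  ## straighten every POPC lipid within 1 nm of a PI(4,5)P2 molecule
  sp <- lipidSpecies(fr)
  popc <- as.integer(names(sp)[sp == "POPC"])
  d <- PIPNano:::probeReferenceDistances(
    fr, popc, as.integer(names(sp)[sp != "POPC"]), boxDims(fr))
  fr <- straightenChains(fr, popc[d < 1])
  dro <- distanceResolvedOrder(fr, "POPC", "PIP2", binWidth = 0.2,
                               maxDistance = 3)
  first_occupied <- which(dro@counts > 0)[1]
  expect_equal(dro@S[first_occupied], 1.0, tolerance = 1e-9)
  far <- which(dro@breaks[-length(dro@breaks)] >= 1.2 & dro@counts > 0)
  expect_true(all(dro@S[far] < 0.3))
  ## empty bins are NA, not zero
  expect_true(all(is.na(dro@S[dro@counts == 0])))
})

test_that("pooling all distance bins reproduces the unconditioned S", {
  syn <- buildFluidBilayer(nLipids = 300, pip2Fraction = 0.2,
                           chainDisorder = 0.6, seed = 7)
  box <- boxDims(syn$frame)
  maxd <- sqrt(2) * box[1] / 2 + 0.1
  dro <- distanceResolvedOrder(syn$frame, "POPC", "PIP2",
                               binWidth = maxd, maxDistance = maxd)
  expect_equal(sum(dro@counts),
               sum(lipidSpecies(syn$frame) == "POPC"))
  op <- orderProfile(syn$frame, "POPC")
  expect_equal(dro@S[1], op@S[1], tolerance = 1e-12)
  expect_error(distanceResolvedOrder(syn$frame, "POPC", "CHOL"),
               "empty reference")
})

test_that("hexagonal disc classification matches lattice combinatorics", {
  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0, seed = 8)
  gel <- buildGelPatch(syn$frame, 127, seed = 9)
  hx <- hexagonality(gel$frame, leaflet = "upper")
  expect_equal(hx@nHexagonal, 91L)
  ## isolated chains (one lipid per leaflet): nothing hexagonal
  lone <- buildFluidBilayer(nLipids = 2, pip2Fraction = 0, seed = 99)
  expect_equal(hexagonality(lone$frame)@nHexagonal, 0L)
})

test_that("hexagonality is invariant under in-plane lattice rotation", {
  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0, seed = 10)
  gel <- buildGelPatch(syn$frame, 127, seed = 11)
  base <- hexagonality(gel$frame, leaflet = "upper")@nHexagonal
  for (ang in c(17, 45)) {
    rot <- rotateFrameXY(gel$frame, ang)
    expect_equal(hexagonality(rot, leaflet = "upper")@nHexagonal, base)
  }
})

test_that("hexagonal count is monotone in the angular tolerance and zero
           for fluid or overstretched lattices", {
  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0, seed = 12)
  gel <- buildGelPatch(syn$frame, 127, seed = 13)
  counts <- vapply(c(2, 8, 15, 25), function(tol)
    hexagonality(gel$frame, leaflet = "upper",
                 angleTolerance = tol)@nHexagonal, integer(1))
  expect_true(all(diff(counts) >= 0))
  ## fluid packing at 0.64 nm^2 per lipid: essentially no hexagonal chains
  fl <- hexagonality(syn$frame)
  expect_lt(fl@fraction, 0.05)
  ## lattice spacing far beyond the neighbor cutoff: no contacts
  wide <- buildGelPatch(syn$frame, 127, latticeSpacing = 1.0, seed = 14)
  hw <- hexagonality(wide$frame, leaflet = "upper")
  expect_equal(hw@nHexagonal, 0L)
})

test_that("hexagonality-versus-temperature reports the planted trend", {
  syn <- buildFluidBilayer(nLipids = 900, pip2Fraction = 0, seed = 15)
  sizes <- c(127, 91, 61, 37)
  frames <- lapply(seq_along(sizes), function(i)
    buildGelPatch(syn$frame, sizes[i], seed = 15 + i)$frame)
  tab <- hexagonalityVsTemperature(frames, c(280, 290, 300, 310),
                                   leaflet = "upper")
  expect_true(all(diff(tab$n_hexagonal) < 0))
  expect_equal(attr(tab, "spearman"), -1)
  same <- hexagonalityVsTemperature(list(frames[[1]], frames[[1]]),
                                    c(280, 300), leaflet = "upper")
  expect_equal(same$fraction[1], same$fraction[2])
  expect_error(hexagonalityVsTemperature(frames[1], 280), "2 distinct")
  expect_warning(
    hexagonalityVsTemperature(frames[c(1, 1, 2)], c(280, 280, 300),
                              leaflet = "upper"),
    "duplicate")
})
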