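test_that("height fields recover flat and undulated planted surfaces", {
  syn <- buildFluidBilayer(nLipids = 400, pip2Fraction = 0, seed = 21)
  hf <- buildHeightField(syn$frame, "upper", spacing = 1)
  v <- fieldValues(hf)
  z0 <- mean(v[hf@mask])
  expect_lt(max(abs(v[hf@mask] - z0)), 0.2)

  und <- buildUndulatedBilayer(nLipids = 1800, amplitude = 1,
                               wavelength = 24, seed = 22)
  hu <- buildHeightField(und$frame, "upper", spacing = 1)
  vu <- fieldValues(hu)
  xs <- (seq_len(nrow(vu)) - 0.5) * hu@spacing[1]
  pred <- outer(1 * sin(2 * pi * xs / 24), rep(1, ncol(vu)))
  resid <- (vu - mean(vu[hu@mask], na.rm = TRUE) - pred)[hu@mask]
  expect_lt(sqrt(mean(resid^2)), 0.1)

  ## degenerate single-cell grid: height = leaflet mean z
  big <- buildHeightField(syn$frame, "upper", spacing = 100)
  b <- beads(syn$frame)
  po4 <- b[b$bead == "PO4" &
             leaflets(syn$frame)[as.character(b$lipid)] == "upper", ]
  expect_equal(dim(fieldValues(big)), c(1L, 1L))
  expect_equal(fieldValues(big)[1, 1], mean(po4$z), tolerance = 1e-12)
  expect_warning(buildHeightField(syn$frame, "upper", spacing = 0.2),
                 "oversampling")
})

test_that("curvature of tilted planes vanishes and z-reflection flips sign", {
  nx <- 24; ny <- 24
  xs <- (seq_len(nx) - 0.5); ys <- (seq_len(ny) - 0.5)
  plane <- outer(xs, ys, function(x, y) 5 + 0.3 * x - 0.2 * y)
  hf <- new("HeightField", values = plane,
            mask = matrix(TRUE, nx, ny), spacing = c(1, 1),
            origin = c(0, 0), what = "height:test")
  ## tilted plane is periodic-discontinuous at the seam; evaluate interior
  cf <- meanCurvatureField(hf, fitRadius = 2.2)
  inner <- fieldValues(cf)[5:20, 5:20]
  expect_lt(max(abs(inner)), 1e-6)
  ## flat plane, all cells
  flat <- new("HeightField", values = matrix(3.3, nx, ny),
              mask = matrix(TRUE, nx, ny), spacing = c(1, 1),
              origin = c(0, 0), what = "height:test")
  expect_lt(max(abs(fieldValues(meanCurvatureField(flat))), na.rm = TRUE),
            1e-8)
  ## rigid z-shift leaves H unchanged; z-reflection flips its sign
  und <- buildUndulatedBilayer(nLipids = 1800, amplitude = 1,
                               wavelength = 24, seed = 23)
  hu <- buildHeightField(und$frame, "upper", spacing = 1)
  H1 <- fieldValues(meanCurvatureField(hu))
  hshift <- hu; hshift@values <- hu@values + 4.2
  expect_equal(fieldValues(meanCurvatureField(hshift)), H1,
               tolerance = 1e-9)
  hrefl <- hu; hrefl@values <- -hu@values
  expect_equal(fieldValues(meanCurvatureField(hrefl)), -H1,
               tolerance = 1e-9)
})

test_that("curvature recovers the analytic sinusoid and sphere values", {
  und <- buildUndulatedBilayer(nLipids = 1952, areaPerLipid = 625 / 976,
                               amplitude = 1, wavelength = 25, seed = 24)
  expect_equal(boxDims(und$frame)[1], 25, tolerance = 1e-9)
  hu <- buildHeightField(und$frame, "upper", spacing = 1)
  cf <- meanCurvatureField(hu, fitRadius = 2.5)
  v <- fieldValues(cf)
  xs <- (seq_len(nrow(v)) - 0.5) * cf@spacing[1]
  crest <- abs(sin(2 * pi * xs / 25) - 1) < 0.05
  Hcrest <- mean(v[crest, ], na.rm = TRUE)
  expect_equal(Hcrest, -0.0316, tolerance = 0.05)

  cap <- sphereCapFrame(R = 10, rhoMax = 5)
  hc <- buildHeightField(cap, "upper", spacing = 0.5)
  cc <- meanCurvatureField(hc, fitRadius = 1.6)
  ctr <- round(dim(fieldValues(cc)) / 2)
  Hc <- fieldValues(cc)[ctr[1] + (-1:1), ctr[2] + (-1:1)]
  expect_equal(mean(Hc, na.rm = TRUE), 0.1, tolerance = 0.05)
})

test_that("thickness maps recover planted offsets and cancel undulations", {
  syn <- buildFluidBilayer(nLipids = 400, pip2Fraction = 0, seed = 25)
  tmap <- thicknessMap(syn$frame, spacing = 1.5)
  v <- fieldValues(tmap)
  expect_equal(mean(v[tmap@mask]), 4.0, tolerance = 0.05)

  gel <- buildGelPatch(buildFluidBilayer(nLipids = 900, pip2Fraction = 0,
                                         seed = 26)$frame,
                       127, thicknessIncrease = 1.0, seed = 27)
  tg <- thicknessMap(gel$frame, spacing = 1.5)
  vg <- fieldValues(tg)
  box <- boxDims(gel$frame)
  xs <- (seq_len(nrow(vg)) - 0.5) * tg@spacing[1]
  ys <- (seq_len(ncol(vg)) - 0.5) * tg@spacing[2]
  d2c <- outer((xs - box[1] / 2)^2, (ys - box[2] / 2)^2, "+")
  patch <- d2c < (gel$truth$patchRadius - 1)^2 & tg@mask
  backg <- d2c > (gel$truth$patchRadius + 2)^2 & tg@mask
  expect_equal(mean(vg[patch]) - mean(vg[backg]), 1.0, tolerance = 0.15)
  sph <- attr(tg, "speciesHeights")
  expect_true(is.data.frame(sph) && nrow(sph) >= 2)

  und <- buildUndulatedBilayer(nLipids = 1800, amplitude = 1.5,
                               wavelength = 24, seed = 28)
  tu <- thicknessMap(und$frame, spacing = 1.5)
  vu <- fieldValues(tu)[tu@mask]
  expect_lt(sd(vu), 0.15)
  expect_equal(mean(vu), 4.0, tolerance = 0.05)
})

test_that("registration coefficient separates registered, anti-registered
           and independent leaflet patterns", {
  ## identical patterns in both leaflets: +1
  set.seed(31)
  pts <- cbind(runif(40, 0, 20), runif(40, 0, 20))
  same <- registrationCoefficient(patternFrame(pts, pts), spacing = 2)
  expect_equal(same@coefficient, 1.0, tolerance = 1e-12)

  ## complementary half-box occupancy: negative
  left <- cbind(runif(60, 0, 9), runif(60, 0, 20))
  right <- cbind(runif(60, 10, 19), runif(60, 0, 20))
  anti <- registrationCoefficient(patternFrame(left, right), spacing = 2)
  expect_lt(anti@coefficient, 0)

  ## independently seeded patterns: mean near zero
  coefs <- vapply(1:50, function(s) {
    set.seed(100 + s)
    up <- cbind(runif(30, 0, 20), runif(30, 0, 20))
    lo <- cbind(runif(30, 0, 20), runif(30, 0, 20))
    registrationCoefficient(patternFrame(up, lo), spacing = 2)@coefficient
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(length(coefs)))

  ## symmetry under leaflet exchange
  fr <- patternFrame(left, right)
  swap <- patternFrame(right, left)
  expect_equal(registrationCoefficient(swap, spacing = 2)@coefficient,
               anti@coefficient, tolerance = 1e-12)

  ## species in one leaflet only: explicit error
  asy <- buildAsymmetricBilayer(seed = 32)
  expect_error(registrationCoefficient(asy$frame, "PIP2"),
               "one leaflet")
})
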