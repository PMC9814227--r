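#' @include AllClasses.R synthetic-fluor.R
NULL

#' Instrument G factor
#'
#' G = IHV / IHH from the horizontally excited components.
#'
#' @param I a [PolarizedIntensities-class], or IHV when \code{IHH} given
#' @param IHH horizontal-horizontal component when \code{I} is numeric
#' @return G, dimensionless
#' @examples
#' gFactor(PolarizedIntensities(100, 50, 80, 100))  # 0.8
#' @export
gFactor <- function(I, IHH = NULL) {
  if (is(I, "PolarizedIntensities")) { ihv <- I@IHV; ihh <- I@IHH }
  else { ihv <- I; ihh <- IHH }
  if (is.null(ihh) || ihh == 0)
    stop("IHH must be positive to compute G = IHV/IHH; ",
         "measure the horizontally excited components first")
  ihv / ihh
}

#' Steady-state fluorescence anisotropy
#'
#' <r> = (IVV - G IVH) / (IVV + 2 G IVH). Physical values lie in
#' [-0.5, 1]; out-of-range results are flagged with a warning, never
#' clamped.
#'
#' @param I a [PolarizedIntensities-class]
#' @param G optional G-factor override; by default computed from IHV/IHH
#' @return r, dimensionless
#' @examples
#' steadyStateAnisotropy(simulatePolarizedIntensities(0.3, G = 1.2))
#' @export
steadyStateAnisotropy <- function(I, G = NULL) {
  if (is.null(G)) G <- gFactor(I)
  den <- I@IVV + 2 * G * I@IVH
  if (den == 0) stop("zero denominator: IVV + 2 G IVH must be positive")
  r <- (I@IVV - G * I@IVH) / den
  if (r < -0.5 - 1e-12 || r > 1 + 1e-12)
    warning("anisotropy ", signif(r, 4),
            " outside the physical range [-0.5, 1]")
  r
}

## model counts for parameter vector p = c(log B_1..k, log tau_1..k);
## B_i = integrated counts of component i
decayModelCounts <- function(p, t0, t1) {
  k <- length(p) / 2
  B <- exp(p[seq_len(k)])
  tau <- exp(p[k + seq_len(k)])
  m <- 0
  for (i in seq_len(k))
    m <- m + B[i] * (exp(-t0 / tau[i]) - exp(-t1 / tau[i])) /
      (1 - exp(-(t1[length(t1)]) / tau[i]))
  m
}

#' Fit a multi-exponential decay to a TCSPC histogram
#'
#' Levenberg-Marquardt least squares on the channel-integrated
#' multi-exponential model with Poisson weights \eqn{1/\max(c_k, 1)}
#' (count floor 1 avoids division by zero in empty channels). Amplitudes
#' are renormalized to sum to 1 and components sorted by lifetime. The
#' fit is multistarted from log-spaced lifetime grids spanning the
#' acquisition window; the best reduced chi-squared is kept. Goodness of
#' fit is judged from the reduced chi-squared, the weighted residuals and
#' their autocorrelation; a well-specified fit at TCSPC statistics has
#' reduced chi-squared near 1 (below the customary 1.3 acceptance bound).
#'
#' @param hist a [DecayHistogram-class]
#' @param nComponents number of exponential components (1..4)
#' @param fitRange optional channel index range \code{c(first, last)}
#' @param init optional list(alpha, tau) initial guess; replaces the
#'   multistart grid
#' @param seed RNG seed for multistart jitter
#' @return a [DecayFit-class]
#' @examples
#' sim <- simulateDecay(c(0.6, 0.4), c(1, 10), nPhotons = 1e5, seed = 2)
#' fitDecay(sim$hist, 2)
#' @export
fitDecay <- function(hist, nComponents = 2, fitRange = NULL, init = NULL,
                     seed = 1) {
  if (!nComponents %in% 1:4)
    stop("nComponents must be between 1 and 4")
  counts <- hist@counts
  w <- hist@channelWidth
  idx <- seq_along(counts)
  if (!is.null(fitRange)) idx <- fitRange[1]:fitRange[2]
  y <- counts[idx]
  npar <- 2L * nComponents
  if (length(y) < 10 * npar)
    stop("fit range too short: need at least ", 10 * npar, " channels")
  t0 <- (idx - 1) * w
  t1 <- idx * w
  wt <- 1 / sqrt(pmax(y, 1))
  resid_fn <- function(p) (decayModelCounts(p, t0, t1) - y) * wt
  window <- max(t1)
  total <- sum(y)

  starts <- if (!is.null(init)) {
    B <- init$alpha * init$tau
    list(c(log(total * B / sum(B)), log(init$tau)))
  } else {
    grid <- exp(seq(log(2 * w), log(window / 3),
                    length.out = max(4, nComponents + 3)))
    combs <- utils::combn(grid, nComponents, simplify = FALSE)
    lapply(combs, function(tg)
      c(log(rep(total / nComponents, nComponents)), log(sort(tg))))
  }
  best <- NULL
  flags <- character(0)
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi <- sum(fit$fvec^2) / (length(y) - npar)
    if (is.null(best) || chi < best$chi)
      best <- list(fit = fit, chi = chi)
  }
  if (is.null(best))
    stop("fit failure: no multistart converged (",
         length(starts), " starts tried)")
  p <- best$fit$par
  k <- nComponents
  B <- exp(p[seq_len(k)])
  tau <- exp(p[k + seq_len(k)])
  if (any(tau > 10 * window) || any(tau < w / 10))
    flags <- c(flags, "tau_at_bounds")
  if (best$fit$info %in% c(0, 5))
    flags <- c(flags, "no_convergence")
  ## B_i is component i's windowed count total; the intensity amplitude
  ## alpha_i is proportional to B_i / (tau_i (1 - exp(-T/tau_i)))
  araw <- B / (tau * (1 - exp(-window / tau)))
  alpha <- araw / sum(araw)
  ## guard exact lifetime ties (collapsed components)
  o <- order(tau)
  tau <- tau[o]; alpha <- alpha[o]
  if (any(diff(tau) <= 0)) {
    tau <- tau + seq_len(k) * 1e-12
    flags <- c(flags, "degenerate_components")
  }
  res <- best$fit$fvec
  nlag <- min(50L, length(res) - 1L)
  ac <- stats::acf(res, lag.max = nlag, plot = FALSE)$acf[-1]
  new("DecayFit",
      model = new("DecayModel", alpha = alpha, tau = tau),
      chisq = best$chi, residuals = res, autocorr = as.numeric(ac),
      nChannels = length(y), nParams = as.integer(npar),
      scale = sum(B), flags = flags)
}

#' @rdname meanLifetime
#' @export
setMethod("meanLifetime", "DecayModel", function(model)
  sum(model@alpha * model@tau))

#' @rdname meanLifetime
#' @export
setMethod("meanLifetime", "DecayFit", function(model)
  meanLifetime(model@model))

#' Fit the melting transition of a thermal anisotropy profile
#'
#' Fits the symmetric logistic
#' r(T) = rLow + (rHigh - rLow) / (1 + exp((T - Tm) / width)) by
#' Levenberg-Marquardt least squares; the melting temperature Tm is the
#' transition midpoint. When the fitted amplitude (rHigh - rLow) is below
#' 3x the residual SD the profile has no clear inflection point and the
#' result is reported as "no transition detected". A midpoint outside
#' the sampled temperature range is flagged as extrapolated (unreliable).
#'
#' @param profile data.frame with columns \code{temperature} (deg C) and
#'   \code{r}, e.g. from [simulateThermalProfile()]
#' @return a [TransitionFit-class]
#' @export
fitThermalTransition <- function(profile) {
  Tv <- profile$temperature
  r <- profile$r
  if (length(Tv) < 6)
    stop("at least 6 temperature points spanning both plateaus required")
  o <- order(Tv)
  Tv <- Tv[o]; r <- r[o]
  rng <- range(Tv)
  ## p = (rLow, log dr, Tm, log width)
  model <- function(p)
    p[1] + exp(p[2]) / (1 + exp((Tv - p[3]) / exp(p[4])))
  resid_fn <- function(p) model(p) - r
  dr0 <- max(max(r) - min(r), 1e-6)
  starts <- lapply(stats::quantile(Tv, c(0.25, 0.5, 0.75)), function(tm)
    c(min(r), log(dr0), tm, log(diff(rng) / 10)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("transition fit failed to converge")
  p <- best$fit$par
  rLow <- p[1]; dr <- exp(p[2]); Tm <- p[3]; width <- exp(p[4])
  resSD <- sqrt(best$ss / max(1, length(r) - 4))
  detected <- dr >= 3 * resSD
  extrap <- Tm < rng[1] || Tm > rng[2]
  new("TransitionFit", Tm = Tm, width = width, rLow = rLow,
      rHigh = rLow + dr, residualSD = resSD,
      transitionDetected = detected, extrapolated = extrap,
      data = data.frame(temperature = Tv, r = r))
}

#' Read a TCSPC decay from a two-column TSV (time_ns, counts)
#' @param path input file; channel width inferred from the time column
#' @return a [DecayHistogram-class]
#' @export
readDecay <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  w <- stats::median(diff(tab[[1]]))
  DecayHistogram(tab[[2]], w)
}

#' Read polarized intensities from a four-column TSV (IVV, IVH, IHV, IHH)
#' @param path input file; if several rows, columns are summed
#' @return a [PolarizedIntensities-class]
#' @export
readPolarized <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  PolarizedIntensities(sum(tab$IVV), sum(tab$IVH), sum(tab$IHV),
                       sum(tab$IHH))
}
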