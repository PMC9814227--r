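#' @include AllClasses.R synthetic-bilayer.R
NULL

#' Construct a DecayHistogram
#' @param counts counts per channel
#' @param channelWidth channel width in ns
#' @return a [DecayHistogram-class]
#' @export
DecayHistogram <- function(counts, channelWidth) {
  new("DecayHistogram", counts = as.numeric(counts),
      channelWidth = channelWidth)
}

#' Construct a DecayModel
#' @param alpha normalized amplitudes (must sum to 1)
#' @param tau lifetimes in ns
#' @return a [DecayModel-class] with components sorted by lifetime
#' @export
DecayModel <- function(alpha, tau) {
  o <- order(tau)
  new("DecayModel", alpha = as.numeric(alpha[o]), tau = as.numeric(tau[o]))
}

#' Construct a PolarizedIntensities object
#' @param IVV,IVH,IHV,IHH the four polarized components
#' @return a [PolarizedIntensities-class]
#' @export
PolarizedIntensities <- function(IVV, IVH, IHV, IHH) {
  new("PolarizedIntensities", IVV = IVV, IVH = IVH, IHV = IHV, IHH = IHH)
}

## Channel-integrated expected counts of a multi-exponential decay.
## Total over the window normalized to nPhotons.
decayExpectedCounts <- function(alpha, tau, nChannels, channelWidth,
                                nPhotons) {
  t0 <- (seq_len(nChannels) - 1) * channelWidth
  t1 <- t0 + channelWidth
  per <- matrix(0, nChannels, length(tau))
  for (i in seq_along(tau))
    per[, i] <- alpha[i] * tau[i] * (exp(-t0 / tau[i]) - exp(-t1 / tau[i]))
  e <- rowSums(per)
  e * (nPhotons / sum(e))
}

#' Simulate a TCSPC decay histogram
#'
#' Expected counts per channel are proportional to the integral of
#' \eqn{i(t) = \sum_i \alpha_i e^{-t/\tau_i}} over the channel (delta
#' excitation, no instrument response); observed counts are Poisson draws
#' normalized so the expected total equals \code{nPhotons}.
#'
#' @param alpha normalized amplitudes (sum to 1)
#' @param tau lifetimes in ns (positive)
#' @param nPhotons expected total photon count
#' @param nChannels number of channels
#' @param channelWidth channel width in ns
#' @param seed RNG seed
#' @param noiseless if TRUE, return the expected (non-integer) counts
#' @return list(hist = [DecayHistogram-class], truth); \code{truth} records
#'   the planted components and seed, plus a \code{truncated} flag when the
#'   acquisition window is shorter than 3x the longest lifetime
#' @examples
#' sim <- simulateDecay(c(0.6, 0.4), c(1, 10), nPhotons = 1e5, seed = 1)
#' sim$hist
#' @export
simulateDecay <- function(alpha, tau, nPhotons = 1e6, nChannels = 4096,
                          channelWidth = 0.0122, seed = 1,
                          noiseless = FALSE) {
  if (abs(sum(alpha) - 1) > 1e-6)
    stop("amplitudes must be normalized (sum to 1)")
  if (any(tau <= 0)) stop("lifetimes must be positive")
  window <- nChannels * channelWidth
  truncated <- window < 3 * max(tau)
  if (truncated)
    warning("acquisition window (", signif(window, 4),
            " ns) is shorter than 3x the longest lifetime; decay truncated")
  e <- decayExpectedCounts(alpha, tau, nChannels, channelWidth, nPhotons)
  counts <- if (noiseless) e else withSeed(seed, stats::rpois(length(e), e))
  list(hist = DecayHistogram(counts, channelWidth),
       truth = list(alpha = alpha, tau = tau, seed = seed,
                    nPhotons = nPhotons, truncated = truncated))
}

#' Polarized intensities realizing a given anisotropy and G factor
#'
#' Inverts the steady-state anisotropy definition: returns components such
#' that [steadyStateAnisotropy()] recovers \code{rTrue} exactly and
#' IHV / IHH equals \code{G}.
#'
#' @param rTrue target anisotropy, in the physical range [-0.5, 1]
#' @param totalIntensity IVV + 2 G IVH (counts)
#' @param G instrument correction factor (> 0)
#' @return a [PolarizedIntensities-class]
#' @export
simulatePolarizedIntensities <- function(rTrue, totalIntensity = 3e5,
                                         G = 1) {
  if (rTrue < -0.5 || rTrue > 1)
    stop("anisotropy outside the physical range [-0.5, 1]")
  if (G <= 0) stop("G must be positive")
  IVV <- totalIntensity * (1 + 2 * rTrue) / 3
  IVH <- totalIntensity * (1 - rTrue) / 3 / G
  IHH <- totalIntensity / 4
  PolarizedIntensities(IVV = IVV, IVH = IVH, IHV = G * IHH, IHH = IHH)
}

#' Simulate a thermal anisotropy profile with a planted melting midpoint
#'
#' r(T) = rLow + (rHigh - rLow) / (1 + exp((T - Tm) / width)) plus
#' Gaussian noise: high anisotropy (gel) at low temperature decaying to
#' the fluid plateau, with midpoint Tm.
#'
#' @param rLow,rHigh fluid and gel plateau anisotropies (rHigh > rLow)
#' @param Tm planted midpoint, degrees C
#' @param width transition width, degrees C (> 0)
#' @param temperatures sampled temperatures (>= 6 points)
#' @param noiseSD Gaussian noise SD on r
#' @param seed RNG seed
#' @return list(profile = data.frame(temperature, r), truth)
#' @export
simulateThermalProfile <- function(rLow = 0.05, rHigh = 0.25, Tm = 45,
                                   width = 3,
                                   temperatures = seq(20, 70, by = 2),
                                   noiseSD = 0.002, seed = 1) {
  if (rHigh <= rLow) stop("rHigh must exceed rLow")
  if (width <= 0) stop("width must be positive")
  if (length(temperatures) < 6)
    stop("insufficient sampling: at least 6 temperature points required")
  r0 <- rLow + (rHigh - rLow) / (1 + exp((temperatures - Tm) / width))
  r <- if (noiseSD > 0)
    withSeed(seed, r0 + stats::rnorm(length(r0), 0, noiseSD))
  else r0
  list(profile = data.frame(temperature = temperatures, r = r),
       truth = list(Tm = Tm, width = width, rLow = rLow, rHigh = rHigh,
                    seed = seed))
}
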