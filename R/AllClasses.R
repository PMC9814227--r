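#' @import methods
NULL

## ---------------------------------------------------------------------------
## Membrane data model
## ---------------------------------------------------------------------------

#' MembraneFrame: one coarse-grained membrane snapshot
#'
#' A single coarse-grained (Martini-style) membrane configuration: an
#' orthorhombic box plus beads grouped into lipids, together with the
#' per-species bead topology and optional leaflet labels.
#'
#' @slot box numeric(3), box lengths \code{c(Lx, Ly, Lz)} in nm; strictly
#'   positive (orthorhombic boxes only).
#' @slot beads \code{data.frame} with one row per bead and columns
#'   \code{bead} (bead name, e.g. \code{"PO4"}), \code{lipid} (integer lipid
#'   index), \code{species} (species name), and coordinates \code{x,y,z} in nm.
#' @slot topology named list of lipid topologies (see [defaultTopology()]);
#'   every species appearing in \code{beads} must resolve here.
#' @slot leaflet character vector, one label per lipid (names are lipid
#'   indices), each \code{"upper"}, \code{"lower"} or \code{"unassigned"}.
#' @slot time numeric scalar, frame time in ps.
#'
#' @seealso [loadFrames()], [assignLeaflets()], [buildFluidBilayer()]
#' @export
setClass("MembraneFrame",
  representation(box = "numeric", beads = "data.frame", topology = "list",
                 leaflet = "character", time = "numeric"))

setValidity("MembraneFrame", function(object) {
  msg <- character()
  if (length(object@box) != 3 || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    msg <- c(msg, "box must be three strictly positive finite lengths (nm)")
  need <- c("bead", "lipid", "species", "x", "y", "z")
  if (!all(need %in% names(object@beads)))
    msg <- c(msg, paste("beads needs columns:", paste(need, collapse = ", ")))
  else {
    if (any(!is.finite(object@beads$x)) || any(!is.finite(object@beads$y)) ||
        any(!is.finite(object@beads$z)))
      msg <- c(msg, "bead positions must be finite")
    sp <- unique(object@beads$species)
    unknown <- setdiff(sp, names(object@topology))
    if (length(unknown))
      msg <- c(msg, paste0("species without topology: ",
                           paste(unknown, collapse = ", ")))
    lip <- unique(object@beads$lipid)
    if (length(object@leaflet) &&
        !all(object@leaflet %in% c("upper", "lower", "unassigned")))
      msg <- c(msg, "leaflet labels must be upper/lower/unassigned")
    if (length(object@leaflet) && length(object@leaflet) != length(lip))
      msg <- c(msg, "leaflet must have one label per lipid")
  }
  if (length(msg)) msg else TRUE
})

#' MembraneTrajectory: ordered frames sharing one topology
#'
#' @slot frames list of [MembraneFrame-class] objects with monotonically
#'   increasing time.
#' @slot topology the shared topology map.
#' @export
setClass("MembraneTrajectory",
  representation(frames = "list", topology = "list"))

setValidity("MembraneTrajectory", function(object) {
  if (!length(object@frames)) return("trajectory must contain >= 1 frame")
  if (!all(vapply(object@frames, is, logical(1), "MembraneFrame")))
    return("all frames must be MembraneFrame objects")
  tm <- vapply(object@frames, function(f) f@time, numeric(1))
  if (length(tm) > 1 && any(diff(tm) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## Cluster analysis
## ---------------------------------------------------------------------------

#' ClusterPartition: disjoint lipid clusters of one species in one frame
#'
#' @slot clusters list of integer vectors; disjoint lipid-index sets whose
#'   union is exactly the selected species' lipid set.
#' @slot species selected species name (prefix match allowed on input).
#' @slot time frame time in ps.
#' @slot cutoff contact cutoff in nm.
#' @slot beadSelection \code{"headgroup"} or \code{"all"}.
#' @slot inPlane logical; whether adjacency used in-plane (x,y) distances.
#' @export
setClass("ClusterPartition",
  representation(clusters = "list", species = "character", time = "numeric",
                 cutoff = "numeric", beadSelection = "character",
                 inPlane = "logical"))

setValidity("ClusterPartition", function(object) {
  all_ids <- unlist(object@clusters)
  if (anyDuplicated(all_ids)) return("clusters must be disjoint")
  if (length(object@cutoff) != 1 || object@cutoff <= 0)
    return("cutoff must be a positive scalar")
  TRUE
})

#' ClusterSizeSeries: per-frame cluster statistics over a trajectory
#'
#' @slot series \code{data.frame} with columns \code{time_ps},
#'   \code{n_clusters}, \code{mean_size}, \code{mass_mean_size},
#'   \code{largest_size}, \code{n_lipids}.
#' @slot weighting headline weighting used for \code{mean_size}
#'   (\code{"number"} or \code{"mass"}).
#' @export
setClass("ClusterSizeSeries",
  representation(series = "data.frame", weighting = "character"))

## ---------------------------------------------------------------------------
## Order analysis
## ---------------------------------------------------------------------------

#' OrderProfile: per-bond S-values along an acyl chain
#'
#' Bond \code{k} joins chain beads \code{k} and \code{k+1} counted from the
#' glycerol end. S is the second-Legendre order parameter of the bond
#' relative to the leaflet normal: 1 parallel, -0.5 in-plane, 0 isotropic.
#'
#' @slot species,chain species name and chain id ("A", "B", or "all").
#' @slot S numeric per-bond S values, each in [-0.5, 1].
#' @slot se per-bond standard errors.
#' @slot n per-bond sample counts.
#' @export
setClass("OrderProfile",
  representation(species = "character", chain = "character", S = "numeric",
                 se = "numeric", n = "integer"))

setValidity("OrderProfile", function(object) {
  if (any(object@S < -0.5 - 1e-9 | object@S > 1 + 1e-9, na.rm = TRUE))
    return("S values must lie in [-0.5, 1]")
  TRUE
})

#' DistanceResolvedOrder: probe-species first-bond order vs distance to the
#' nearest reference-species molecule
#'
#' @slot breaks bin edges in nm (contiguous, half-open \code{[lo, hi)}).
#' @slot S per-bin mean first-bond S (NA where the bin is empty).
#' @slot counts per-bin number of probe lipids sampled.
#' @slot probe,reference species names.
#' @export
setClass("DistanceResolvedOrder",
  representation(breaks = "numeric", S = "numeric", counts = "integer",
                 probe = "character", reference = "character"))

#' HexagonalityResult: chains sitting on a local six-fold lattice
#'
#' @slot nTotal,nHexagonal chain counts.
#' @slot fraction nHexagonal / nTotal.
#' @slot hexChains integer indices (into the analyzed chain list) classified
#'   hexagonal.
#' @slot parameters named list: neighborCutoff (nm), angleTolerance (deg),
#'   minNeighbors.
#' @export
setClass("HexagonalityResult",
  representation(nTotal = "integer", nHexagonal = "integer",
                 fraction = "numeric", hexChains = "integer",
                 parameters = "list"))

setValidity("HexagonalityResult", function(object) {
  if (object@nHexagonal < 0 || object@nHexagonal > object@nTotal)
    return("0 <= nHexagonal <= nTotal required")
  TRUE
})

## ---------------------------------------------------------------------------
## Surface analysis
## ---------------------------------------------------------------------------

#' HeightField: gridded surface heights (or thicknesses)
#'
#' @slot values numeric matrix (nx by ny) of cell values in nm; \code{NA}
#'   where masked.
#' @slot mask logical matrix; TRUE where >= 1 bead contributed.
#' @slot spacing numeric(2), actual cell size (nm) in x and y.
#' @slot origin numeric(2), lower-left corner of cell (1,1).
#' @slot what free-text label of the gridded quantity.
#' @export
setClass("HeightField",
  representation(values = "matrix", mask = "matrix", spacing = "numeric",
                 origin = "numeric", what = "character"))

setValidity("HeightField", function(object) {
  if (any(object@spacing <= 0)) return("grid spacing must be positive")
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (any(is.finite(object@values[!object@mask])))
    return("masked cells must not carry values")
  TRUE
})

#' CurvatureField: local mean curvature H (1/nm) on a grid
#'
#' Sign convention: H takes the sign of the local height Laplacian, so a
#' crest bulging toward +z has H < 0 and a valley has H > 0.
#' @export
setClass("CurvatureField", contains = "HeightField")

#' RegistrationResult: inter-leaflet registration of a species
#'
#' @slot coefficient Pearson correlation of the two leaflets' binary
#'   occupancy fields; +1 registered, 0 independent, -1 anti-registered.
#' @slot spacing grid spacing (nm).
#' @slot upper,lower the per-leaflet occupancy fields.
#' @export
setClass("RegistrationResult",
  representation(coefficient = "numeric", spacing = "numeric",
                 upper = "matrix", lower = "matrix"))

setValidity("RegistrationResult", function(object) {
  if (is.finite(object@coefficient) &&
      (object@coefficient < -1 - 1e-9 || object@coefficient > 1 + 1e-9))
    return("coefficient must lie in [-1, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Fluorescence analysis
## ---------------------------------------------------------------------------

#' PolarizedIntensities: the four polarized steady-state components
#'
#' Background-subtracted intensities I_VV, I_VH (vertical excitation) and
#' I_HV, I_HH (horizontal excitation, used for the G factor).
#'
#' @slot IVV,IVH,IHV,IHH non-negative intensities (counts).
#' @export
setClass("PolarizedIntensities",
  representation(IVV = "numeric", IVH = "numeric", IHV = "numeric",
                 IHH = "numeric"))

setValidity("PolarizedIntensities", function(object) {
  v <- c(object@IVV, object@IVH, object@IHV, object@IHH)
  if (length(v) != 4 || any(!is.finite(v)) || any(v < 0))
    return("all four intensities must be finite and non-negative")
  TRUE
})

#' DecayHistogram: TCSPC photon counts per channel
#'
#' @slot counts non-negative counts per channel (integral unless generated
#'   in noiseless mode).
#' @slot channelWidth channel width in ns.
#' @export
setClass("DecayHistogram",
  representation(counts = "numeric", channelWidth = "numeric"))

setValidity("DecayHistogram", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@channelWidth) != 1 || object@channelWidth <= 0)
    return("channelWidth must be a positive scalar (ns)")
  TRUE
})

#' DecayModel: multi-exponential intensity decay
#'
#' i(t) = sum_i alpha_i exp(-t / tau_i) with normalized amplitudes.
#'
#' @slot alpha normalized amplitudes, sum to 1.
#' @slot tau lifetimes in ns, strictly increasing.
#' @export
setClass("DecayModel", representation(alpha = "numeric", tau = "numeric"))

setValidity("DecayModel", function(object) {
  if (length(object@alpha) != length(object@tau))
    return("alpha and tau must have equal length")
  if (abs(sum(object@alpha) - 1) > 1e-9)
    return("amplitudes must sum to 1 (within 1e-9)")
  if (any(object@tau <= 0)) return("lifetimes must be positive")
  if (is.unsorted(object@tau, strictly = TRUE))
    return("lifetimes must be strictly increasing")
  TRUE
})

#' DecayFit: fitted decay model plus goodness-of-fit diagnostics
#'
#' @slot model the fitted [DecayModel-class].
#' @slot chisq reduced chi-squared (Poisson-weighted SSR / dof).
#' @slot residuals weighted residuals per fitted channel.
#' @slot autocorr residual autocorrelation at lags 1..K.
#' @slot nChannels,nParams fit size bookkeeping.
#' @slot scale fitted total-intensity scale (counts).
#' @slot flags character flags ("tau_at_bounds", "no_convergence", ...).
#' @export
setClass("DecayFit",
  representation(model = "DecayModel", chisq = "numeric",
                 residuals = "numeric", autocorr = "numeric",
                 nChannels = "integer", nParams = "integer",
                 scale = "numeric", flags = "character"))

#' TransitionFit: logistic melting-transition fit of an anisotropy scan
#'
#' r(T) = rLow + (rHigh - rLow) / (1 + exp((T - Tm)/width)); Tm is the
#' midpoint of the transition.
#'
#' @slot Tm,width fitted midpoint and width in degrees C.
#' @slot rLow,rHigh plateau anisotropies (rHigh > rLow).
#' @slot residualSD residual standard deviation.
#' @slot transitionDetected FALSE when the fitted amplitude is below 3x the
#'   residual SD ("no transition detected").
#' @slot extrapolated TRUE when Tm falls outside the sampled range (result
#'   unreliable).
#' @slot data the (T, r) pairs used.
#' @export
setClass("TransitionFit",
  representation(Tm = "numeric", width = "numeric", rLow = "numeric",
                 rHigh = "numeric", residualSD = "numeric",
                 transitionDetected = "logical", extrapolated = "logical",
                 data = "data.frame"))
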