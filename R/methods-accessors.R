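#' @include AllGenerics.R
NULL

#' @rdname nLipids
#' @export
setMethod("nLipids", "MembraneFrame", function(x)
  length(unique(x@beads$lipid)))

#' @rdname lipidSpecies
#' @export
setMethod("lipidSpecies", "MembraneFrame", function(x) {
  first <- !duplicated(x@beads$lipid)
  sp <- x@beads$species[first]
  names(sp) <- x@beads$lipid[first]
  sp
})

#' @rdname leaflets
#' @export
setMethod("leaflets", "MembraneFrame", function(x) x@leaflet)

#' @rdname boxDims
#' @export
setMethod("boxDims", "MembraneFrame", function(x) x@box)

#' @rdname beads
#' @export
setMethod("beads", "MembraneFrame", function(x) x@beads)

#' @rdname frameTime
#' @export
setMethod("frameTime", "MembraneFrame", function(x) x@time)

#' @rdname frames
#' @export
setMethod("frames", "MembraneTrajectory", function(x) x@frames)

#' @rdname nFrames
#' @export
setMethod("nFrames", "MembraneTrajectory", function(x) length(x@frames))

#' @export
setMethod("length", "MembraneTrajectory", function(x) length(x@frames))

#' Extract one frame from a trajectory
#' @param x a [MembraneTrajectory-class]
#' @param i frame index
#' @export
setMethod("[[", "MembraneTrajectory", function(x, i) x@frames[[i]])

#' @rdname clusters
#' @export
setMethod("clusters", "ClusterPartition", function(x) x@clusters)

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterPartition", function(x)
  vapply(x@clusters, length, integer(1)))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "HeightField", function(x) x@values)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "MembraneFrame", function(object) {
  sp <- table(lipidSpecies(object))
  lf <- table(factor(object@leaflet, c("upper", "lower", "unassigned")))
  cat(sprintf("MembraneFrame: %d lipids, %d beads, box %.2f x %.2f x %.2f nm, t = %g ps\n",
              nLipids(object), nrow(object@beads),
              object@box[1], object@box[2], object@box[3], object@time))
  cat("  species:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  cat("  leaflets:", paste(sprintf("%s=%d", names(lf), lf), collapse = ", "), "\n")
})

setMethod("show", "MembraneTrajectory", function(object) {
  tm <- vapply(object@frames, frameTime, numeric(1))
  cat(sprintf("MembraneTrajectory: %d frame(s), t = %g..%g ps, %d lipids\n",
              length(object@frames), min(tm), max(tm),
              nLipids(object@frames[[1]])))
})

setMethod("show", "ClusterPartition", function(object) {
  sz <- clusterSizes(object)
  cat(sprintf("ClusterPartition (%s): %d lipids in %d cluster(s); cutoff %.2f nm (%s beads, %s)\n",
              object@species, sum(sz), length(sz), object@cutoff,
              object@beadSelection,
              if (object@inPlane) "in-plane" else "3D"))
  if (length(sz))
    cat(sprintf("  sizes: largest %d, number-avg %.2f, mass-avg %.2f\n",
                max(sz), mean(sz), sum(sz^2) / sum(sz)))
})

setMethod("show", "HeightField", function(object) {
  cat(sprintf("%s [%s]: %d x %d grid, spacing %.2f x %.2f nm, %d/%d cells occupied\n",
              class(object), object@what, nrow(object@values),
              ncol(object@values), object@spacing[1], object@spacing[2],
              sum(object@mask), length(object@mask)))
  v <- object@values[object@mask]
  if (length(v))
    cat(sprintf("  value range: [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "HexagonalityResult", function(object) {
  cat(sprintf("HexagonalityResult: %d / %d chains hexagonal (fraction %.3f)\n",
              object@nHexagonal, object@nTotal, object@fraction))
  p <- object@parameters
  cat(sprintf("  neighborCutoff %.2f nm, angleTolerance %.0f deg, minNeighbors %d\n",
              p$neighborCutoff, p$angleTolerance, p$minNeighbors))
})

setMethod("show", "OrderProfile", function(object) {
  cat(sprintf("OrderProfile: %s chain %s, %d bond(s)\n",
              object@species, object@chain, length(object@S)))
  for (k in seq_along(object@S))
    cat(sprintf("  bond %d: S = %+.4f +/- %.4f (n = %d)\n",
                k, object@S[k], object@se[k], object@n[k]))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: coefficient %+.4f (spacing %.2f nm; +1 registered, 0 independent, -1 anti-registered)\n",
              object@coefficient, object@spacing))
})

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d channels x %.4g ns (window %.4g ns), %d counts\n",
              length(object@counts), object@channelWidth,
              length(object@counts) * object@channelWidth,
              round(sum(object@counts))))
})

setMethod("show", "DecayModel", function(object) {
  cat("DecayModel:\n")
  for (i in seq_along(object@tau))
    cat(sprintf("  component %d: alpha = %.4f, tau = %.4g ns\n",
                i, object@alpha[i], object@tau[i]))
  cat(sprintf("  amplitude-weighted mean lifetime: %.4g ns\n",
              meanLifetime(object)))
})

setMethod("show", "DecayFit", function(object) {
  show(object@model)
  cat(sprintf("  reduced chi-squared = %.4f (%d channels, %d parameters)\n",
              object@chisq, object@nChannels, object@nParams))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TransitionFit", function(object) {
  if (!object@transitionDetected) {
    cat("TransitionFit: no transition detected\n")
  } else {
    cat(sprintf("TransitionFit: Tm = %.2f C (width %.2f C), r: %.4f -> %.4f%s\n",
                object@Tm, object@width, object@rLow, object@rHigh,
                if (object@extrapolated) " [extrapolated, unreliable]" else ""))
  }
})
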