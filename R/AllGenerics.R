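#' @include AllClasses.R
NULL

#' Number of lipids in a frame
#' @param x a [MembraneFrame-class]
#' @return integer lipid count
#' @export
setGeneric("nLipids", function(x) standardGeneric("nLipids"))

#' Lipid species vector
#' @param x a [MembraneFrame-class]
#' @return named character vector, one species per lipid (names are lipid
#'   indices)
#' @export
setGeneric("lipidSpecies", function(x) standardGeneric("lipidSpecies"))

#' Leaflet labels
#' @param x a [MembraneFrame-class]
#' @return character vector of per-lipid leaflet labels
#' @export
setGeneric("leaflets", function(x) standardGeneric("leaflets"))

#' Box dimensions
#' @param x a [MembraneFrame-class]
#' @return numeric(3) box lengths in nm
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Bead table
#' @param x a [MembraneFrame-class]
#' @return the bead \code{data.frame}
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))

#' Frame time (ps)
#' @param x a [MembraneFrame-class]
#' @return numeric time in ps
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' Frames of a trajectory
#' @param x a [MembraneTrajectory-class]
#' @return list of [MembraneFrame-class] objects
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Number of frames
#' @param x a [MembraneTrajectory-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Cluster membership sets
#' @param x a [ClusterPartition-class]
#' @return list of integer vectors of lipid indices
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' Cluster sizes
#' @param x a [ClusterPartition-class]
#' @return integer vector of cluster sizes
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' Grid values of a field
#' @param x a [HeightField-class] or [CurvatureField-class]
#' @return numeric matrix of cell values (NA where masked)
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Amplitude-weighted mean fluorescence lifetime
#'
#' tau_bar = sum_i alpha_i * tau_i over the decay components.
#'
#' @param model a [DecayModel-class] or [DecayFit-class]
#' @return tau_bar in ns
#' @examples
#' meanLifetime(DecayModel(alpha = c(0.6, 0.4), tau = c(1, 10)))  # 4.6 ns
#' @export
setGeneric("meanLifetime", function(model) standardGeneric("meanLifetime"))
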