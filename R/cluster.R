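#' @include geometry.R topology.R
NULL

#' Detect lipid clusters under periodic boundaries
#'
#' Two lipids of the selected species are adjacent iff any pair of their
#' selected beads lies within \code{cutoff} under the minimum-image
#' convention (in-plane x,y distances by default: clusters are
#' leaflet-lateral objects). Clusters are the connected components of this
#' adjacency graph; monomers count as clusters of size 1. Cation beads
#' never enter the adjacency definition: clustering is purely lipid-lipid.
#'
#' @param frame a [MembraneFrame-class]
#' @param species species selector; \code{"PIP2"} matches every PI(4,5)P2
#'   variant by prefix
#' @param cutoff contact cutoff in nm (default 0.6, just beyond the
#'   Martini first-neighbor shell)
#' @param beadSelection \code{"headgroup"} (headgroup + phosphodiester
#'   beads, the default) or \code{"all"}
#' @param inPlane use in-plane (x,y) distances (default TRUE)
#' @return a [ClusterPartition-class]
#' @examples
#' syn <- buildFluidBilayer(nLipids = 100, pip2Fraction = 0.2, seed = 7)
#' detectClusters(syn$frame, "PIP2", cutoff = 0.6)
#' @export
detectClusters <- function(frame, species = "PIP2", cutoff = 0.6,
                           beadSelection = c("headgroup", "all"),
                           inPlane = TRUE) {
  beadSelection <- match.arg(beadSelection)
  if (cutoff <= 0) stop("cutoff must be positive")
  sp <- lipidSpecies(frame)
  ids <- as.integer(names(sp)[speciesMatches(sp, species)])
  if (!length(ids))
    stop("empty selection: species '", species, "' not present in frame")
  b <- frame@beads
  keep <- logical(nrow(b))
  for (s in unique(sp[as.character(ids)])) {
    sel <- selectionBeads(frame@topology[[s]], beadSelection)
    keep <- keep | (b$species == s & b$bead %in% sel)
  }
  keep <- keep & b$lipid %in% ids
  bb <- b[keep, ]
  box <- frame@box
  co <- if (inPlane) cbind(bb$x, bb$y) else cbind(bb$x, bb$y, bb$z)
  d2 <- pbcDist2(co, co, box[seq_len(ncol(co))])
  adj <- d2 <= cutoff^2
  ## bead adjacency -> lipid adjacency edges
  hit <- which(adj & upper.tri(adj), arr.ind = TRUE)
  lp <- bb$lipid
  edges <- unique(cbind(pmin(lp[hit[, 1]], lp[hit[, 2]]),
                        pmax(lp[hit[, 1]], lp[hit[, 2]])))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]),
               to = as.character(edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  memb <- split(as.integer(names(comp$membership)), comp$membership)
  memb <- lapply(memb, sort)
  names(memb) <- NULL
  new("ClusterPartition", clusters = memb, species = species,
      time = frame@time, cutoff = cutoff, beadSelection = beadSelection,
      inPlane = inPlane)
}

#' Average cluster size
#'
#' Number weighting: (sum of sizes) / (number of clusters), monomers
#' included. Mass weighting: (sum of squared sizes) / (sum of sizes).
#' Which of the two a given study reports must be labeled; both are
#' provided.
#'
#' @param partition a [ClusterPartition-class]
#' @param weighting \code{"number"} (default) or \code{"mass"}
#' @return average cluster size in lipids
#' @examples
#' # sizes {10, 10, 80}: number-average 33.33, mass-average 66
#' @export
averageClusterSize <- function(partition,
                               weighting = c("number", "mass")) {
  weighting <- match.arg(weighting)
  sz <- clusterSizes(partition)
  if (!length(sz))
    stop("undefined average: partition contains no clusters")
  if (weighting == "number") sum(sz) / length(sz)
  else sum(sz^2) / sum(sz)
}

#' Cluster-size time series over a trajectory
#'
#' Runs [detectClusters()] frame by frame and tabulates the average
#' cluster size over time; the size-conservation invariant (cluster sizes
#' sum to the species count) is checked every frame.
#'
#' @param traj a [MembraneTrajectory-class]
#' @param species,cutoff,beadSelection,inPlane passed to [detectClusters()]
#' @param weighting headline average, \code{"number"} or \code{"mass"}
#' @return a [ClusterSizeSeries-class]; its \code{series} data.frame has
#'   columns time_ps, n_clusters, mean_size, mass_mean_size, largest_size,
#'   n_lipids
#' @export
clusterTimeseries <- function(traj, species = "PIP2", cutoff = 0.6,
                              beadSelection = "headgroup", inPlane = TRUE,
                              weighting = c("number", "mass")) {
  weighting <- match.arg(weighting)
  if (!nFrames(traj)) stop("trajectory has no frames")
  rows <- lapply(seq_len(nFrames(traj)), function(i) {
    part <- tryCatch(
      detectClusters(traj[[i]], species, cutoff, beadSelection, inPlane),
      error = function(e)
        stop("frame ", i, ": ", conditionMessage(e), call. = FALSE))
    sz <- clusterSizes(part)
    nsp <- sum(speciesMatches(lipidSpecies(traj[[i]]), species))
    if (sum(sz) != nsp)
      stop("frame ", i, ": cluster sizes sum to ", sum(sz),
           " but the frame has ", nsp, " ", species, " lipids")
    data.frame(time_ps = frameTime(traj[[i]]), n_clusters = length(sz),
               mean_size = averageClusterSize(part, "number"),
               mass_mean_size = averageClusterSize(part, "mass"),
               largest_size = max(sz), n_lipids = sum(sz))
  })
  new("ClusterSizeSeries", series = do.call(rbind, rows),
      weighting = weighting)
}
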