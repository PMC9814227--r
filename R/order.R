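#' @include geometry.R topology.R
NULL

#' Second-Legendre S-value of a set of bond vectors
#'
#' S = (3 <cos^2 theta> - 1) / 2 with theta the angle between each bond
#' and the membrane normal: 1 for bonds parallel to the normal, -0.5 for
#' in-plane bonds, 0 for an isotropic sample (cos^2 theta = 1/3 at the
#' magic angle).
#'
#' @param bondVectors n x 3 matrix of bond vectors (any non-zero lengths)
#' @param normal unit normal (default +z); only its axis matters since
#'   cos^2 is sign-invariant
#' @return S, dimensionless, in [-0.5, 1]
#' @examples
#' bondSValue(matrix(c(0, 0, 1), 1))    #  1
#' bondSValue(matrix(c(1, 0, 0), 1))    # -0.5
#' @export
bondSValue <- function(bondVectors, normal = c(0, 0, 1)) {
  bondVectors <- rbind(bondVectors)
  len2 <- rowSums(bondVectors^2)
  if (!nrow(bondVectors) || any(len2 == 0))
    stop("geometry error: zero-length bond vector")
  normal <- normal / sqrt(sum(normal^2))
  c2 <- (bondVectors %*% normal)^2 / len2
  mean((3 * c2 - 1) / 2)
}

## Per-bond samples of (3cos^2-1)/2 for one species/chain over frames.
## Returns list(per bond index) of numeric sample vectors.
collectBondSamples <- function(frames, topology, species, chain, leaflet) {
  out <- list()
  for (fr in frames) {
    sp <- lipidSpecies(fr)
    ids <- as.integer(names(sp)[speciesMatches(sp, species)])
    if (!is.null(leaflet))
      ids <- ids[fr@leaflet[as.character(ids)] == leaflet]
    if (!length(ids)) next
    b <- fr@beads
    spname <- unique(sp[as.character(ids)])
    for (s in spname) {
      top <- topology[[s]]
      chains <- if (identical(chain, "all")) top$chains
                else top$chains[chain]
      if (any(vapply(chains, is.null, logical(1))))
        stop("chain '", chain, "' not defined for species ", s)
      sids <- ids[sp[as.character(ids)] == s]
      bs <- b[b$lipid %in% sids, ]
      for (ch in chains) {
        if (length(ch) < 2)
          stop("topology error: chain must have at least 2 beads")
        for (k in seq_len(length(ch) - 1)) {
          b0 <- bs[bs$bead == ch[k], ]
          b1 <- bs[bs$bead == ch[k + 1], ]
          b1 <- b1[match(b0$lipid, b1$lipid), ]
          dz <- pbcDelta(b1$z - b0$z, fr@box[3])
          dx <- pbcDelta(b1$x - b0$x, fr@box[1])
          dy <- pbcDelta(b1$y - b0$y, fr@box[2])
          c2 <- dz^2 / (dx^2 + dy^2 + dz^2)
          p2 <- (3 * c2 - 1) / 2
          out[[k]] <- c(if (k <= length(out)) out[[k]], p2)
        }
      }
    }
  }
  out
}

#' Acyl-chain order profile
#'
#' Per-bond S-values along the acyl chain(s) of one species, aggregated
#' over lipids and frames. Bond k joins chain beads k and k+1 from the
#' glycerol end. The normal is the z axis with the per-leaflet sign (+z
#' upper, -z lower), so profiles are leaflet-symmetric.
#'
#' @param traj a [MembraneTrajectory-class] or single [MembraneFrame-class]
#' @param species species selector (prefix match)
#' @param chain chain id ("A", "B") or "all" to pool both chains
#' @param leaflet optional, restrict to "upper" or "lower"
#' @return an [OrderProfile-class] with per-bond S, standard errors and
#'   sample counts
#' @export
orderProfile <- function(traj, species, chain = "all", leaflet = NULL) {
  if (is(traj, "MembraneFrame"))
    traj <- new("MembraneTrajectory", frames = list(traj),
                topology = traj@topology)
  samples <- collectBondSamples(traj@frames, traj@topology, species,
                                chain, leaflet)
  if (!length(samples)) stop("species '", species, "' yielded no samples")
  S <- vapply(samples, mean, numeric(1))
  se <- vapply(samples, function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
    numeric(1))
  n <- vapply(samples, length, integer(1))
  new("OrderProfile", species = species,
      chain = if (identical(chain, "all")) "all" else chain,
      S = S, se = se, n = n)
}

## In-plane min-image distance from each probe lipid's glycerol-proximal
## bead to the nearest reference-species molecule (min over that
## molecule's beads). Returns named vector per probe lipid.
probeReferenceDistances <- function(fr, probeIds, refIds, box) {
  b <- fr@beads
  gp <- b[b$lipid %in% probeIds & b$bead == "GL1", ]
  gp <- gp[match(probeIds, gp$lipid), ]
  rb <- b[b$lipid %in% refIds, ]
  d2 <- pbcDist2(cbind(gp$x, gp$y), cbind(rb$x, rb$y), box[1:2])
  ## nearest molecule: min over each reference lipid's beads, then min
  dmin <- apply(d2, 1, function(row) min(tapply(row, rb$lipid, min)))
  stats::setNames(sqrt(dmin), probeIds)
}

#' Probe-lipid first-bond order versus distance to the nearest PI(4,5)P2
#'
#' Each probe lipid is assigned the in-plane minimum-image distance from
#' its glycerol-proximal bead (GL1) to the nearest reference-species
#' molecule in the same leaflet (minimum over that molecule's beads); the
#' S-value of the probe's first acyl-chain bonds is averaged per distance
#' bin. Empty bins are reported as NA (missing), not zero.
#'
#' @param traj a [MembraneTrajectory-class] or [MembraneFrame-class]
#' @param probeSpecies probe species (default POPC)
#' @param referenceSpecies reference species selector (default all
#'   PI(4,5)P2)
#' @param binWidth bin width in nm
#' @param maxDistance largest distance analyzed, nm; probes farther from
#'   any reference molecule are not sampled
#' @return a [DistanceResolvedOrder-class]
#' @export
distanceResolvedOrder <- function(traj, probeSpecies = "POPC",
                                  referenceSpecies = "PIP2",
                                  binWidth = 0.2, maxDistance = 3.0) {
  if (is(traj, "MembraneFrame"))
    traj <- new("MembraneTrajectory", frames = list(traj),
                topology = traj@topology)
  breaks <- seq(0, maxDistance, by = binWidth)
  if (breaks[length(breaks)] < maxDistance)
    breaks <- c(breaks, maxDistance)
  nb <- length(breaks) - 1
  acc <- vector("list", nb)
  counts <- integer(nb)
  anyRef <- FALSE
  for (fr in traj@frames) {
    sp <- lipidSpecies(fr)
    refIdsAll <- as.integer(names(sp)[speciesMatches(sp, referenceSpecies)])
    probeAll <- as.integer(names(sp)[speciesMatches(sp, probeSpecies)])
    if (length(refIdsAll)) anyRef <- TRUE else next
    leafsets <- if (all(fr@leaflet == "unassigned")) list(probeAll)
    else {
      lv <- unique(fr@leaflet[as.character(refIdsAll)])
      lapply(lv, function(l)
        probeAll[fr@leaflet[as.character(probeAll)] == l])
    }
    for (probeIds in leafsets) {
      if (!length(probeIds)) next
      refIds <- refIdsAll
      if (!all(fr@leaflet == "unassigned")) {
        l <- fr@leaflet[as.character(probeIds[1])]
        refIds <- refIdsAll[fr@leaflet[as.character(refIdsAll)] == l]
      }
      if (!length(refIds)) next
      d <- probeReferenceDistances(fr, probeIds, refIds, fr@box)
      bin <- stats::setNames(
        findInterval(d, breaks, rightmost.closed = FALSE), names(d))
      keep <- bin >= 1 & bin <= nb & d < maxDistance
      if (!any(keep)) next
      ## first-bond P2 samples per probe lipid (both chains)
      b <- fr@beads
      for (s in unique(sp[as.character(probeIds)])) {
        top <- traj@topology[[s]]
        pids <- probeIds[sp[as.character(probeIds)] == s & keep]
        if (!length(pids)) next
        bs <- b[b$lipid %in% pids, ]
        for (ch in top$chains) {
          b0 <- bs[bs$bead == ch[1], ]; b1 <- bs[bs$bead == ch[2], ]
          b1 <- b1[match(b0$lipid, b1$lipid), ]
          dz <- pbcDelta(b1$z - b0$z, fr@box[3])
          dx <- pbcDelta(b1$x - b0$x, fr@box[1])
          dy <- pbcDelta(b1$y - b0$y, fr@box[2])
          p2 <- (3 * dz^2 / (dx^2 + dy^2 + dz^2) - 1) / 2
          bb <- bin[as.character(b0$lipid)]
          for (j in seq_along(p2))
            acc[[bb[j]]] <- c(acc[[bb[j]]], p2[j])
        }
        counts_tab <- table(bin[as.character(pids)])
        ix <- as.integer(names(counts_tab))
        counts[ix] <- counts[ix] + as.integer(counts_tab)
      }
    }
  }
  if (!anyRef)
    stop("empty reference: species '", referenceSpecies,
         "' absent from all frames")
  S <- vapply(acc, function(x) if (length(x)) mean(x) else NA_real_,
              numeric(1))
  new("DistanceResolvedOrder", breaks = breaks, S = S, counts = counts,
      probe = probeSpecies, reference = referenceSpecies)
}

## In-plane chain centroids of a frame; returns list(xy matrix, lipid,
## chain label, species)
chainCentroids <- function(frame, species = "all", leaflet = NULL) {
  b <- frame@beads
  sp <- lipidSpecies(frame)
  ids <- as.integer(names(sp))
  if (!identical(species, "all"))
    ids <- ids[speciesMatches(sp, species)]
  if (!is.null(leaflet))
    ids <- ids[frame@leaflet[as.character(ids)] == leaflet]
  xs <- numeric(0); ys <- numeric(0)
  lp <- integer(0); chl <- character(0)
  for (s in unique(sp[as.character(ids)])) {
    top <- frame@topology[[s]]
    sids <- ids[sp[as.character(ids)] == s]
    bs <- b[b$lipid %in% sids, ]
    for (cn in names(top$chains)) {
      ch <- top$chains[[cn]]
      sub <- bs[bs$bead %in% ch, ]
      for (l in sids) {
        rows <- sub[sub$lipid == l, ]
        cxy <- unwrappedCentroidXY(rows$x, rows$y, frame@box)
        xs <- c(xs, cxy[1]); ys <- c(ys, cxy[2])
        lp <- c(lp, l); chl <- c(chl, cn)
      }
    }
  }
  list(xy = cbind(xs, ys), lipid = lp, chain = chl)
}

#' Hexagonal acyl-chain lattice detection
#'
#' Each acyl chain is reduced to its in-plane centroid. A chain is
#' classified hexagonal iff it has at least \code{minNeighbors} centroids
#' within \code{neighborCutoff} and the six nearest of these, sorted by
#' azimuth, show consecutive angular gaps of 60 degrees within
#' \code{angleTolerance}. Highly ordered hexagonal chain lattices are the
#' hallmark of gel-phase packing.
#'
#' @param frame a [MembraneFrame-class]
#' @param species chain selection by species ("all" for every lipid)
#' @param leaflet optional leaflet restriction
#' @param neighborCutoff centroid neighbor cutoff, nm (default 0.55,
#'   between the 0.48 nm gel lattice constant and the ~0.8 nm fluid
#'   spacing)
#' @param angleTolerance allowed deviation from 60-degree gaps, degrees
#' @param minNeighbors minimum in-lattice neighbor count (default 6)
#' @return a [HexagonalityResult-class]
#' @export
hexagonality <- function(frame, species = "all", leaflet = NULL,
                         neighborCutoff = 0.55, angleTolerance = 15,
                         minNeighbors = 6L) {
  cc <- chainCentroids(frame, species, leaflet)
  n <- nrow(cc$xy)
  if (!n) stop("no chains in selection")
  box <- frame@box
  hex <- logical(n)
  d2 <- pbcDist2(cc$xy, cc$xy, box[1:2])
  diag(d2) <- Inf
  cut2 <- neighborCutoff^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= cut2)
    if (length(nb) < minNeighbors) next
    six <- nb[order(d2[i, nb])][1:6]
    dx <- pbcDelta(cc$xy[six, 1] - cc$xy[i, 1], box[1])
    dy <- pbcDelta(cc$xy[six, 2] - cc$xy[i, 2], box[2])
    az <- sort(atan2(dy, dx))
    gaps <- c(diff(az), 2 * pi - (az[6] - az[1])) * 180 / pi
    hex[i] <- all(abs(gaps - 60) <= angleTolerance)
  }
  new("HexagonalityResult", nTotal = n, nHexagonal = sum(hex),
      fraction = sum(hex) / n, hexChains = which(hex),
      parameters = list(neighborCutoff = neighborCutoff,
                        angleTolerance = angleTolerance,
                        minNeighbors = as.integer(minNeighbors)))
}

#' Hexagonality versus temperature
#'
#' Hexagonality per temperature-labeled frame plus a descriptive
#' monotone-trend statistic (Spearman rank correlation of the hexagonal
#' fraction with temperature).
#'
#' @param framesList list of [MembraneFrame-class] objects
#' @param temperatures numeric label per frame (>= 2 distinct labels;
#'   duplicate labels are averaged with a warning)
#' @param ... passed to [hexagonality()]
#' @return data.frame(temperature, n_total, n_hexagonal, fraction) with
#'   attribute \code{spearman}
#' @export
hexagonalityVsTemperature <- function(framesList, temperatures, ...) {
  if (length(framesList) != length(temperatures))
    stop("one temperature label per frame required")
  if (length(unique(temperatures)) < 2)
    stop("at least 2 distinct temperature labels required")
  res <- lapply(framesList, hexagonality, ...)
  tab <- data.frame(temperature = temperatures,
                    n_total = vapply(res, function(r) r@nTotal, integer(1)),
                    n_hexagonal = vapply(res, function(r) r@nHexagonal,
                                         integer(1)),
                    fraction = vapply(res, function(r) r@fraction,
                                      numeric(1)))
  if (anyDuplicated(temperatures)) {
    warning("duplicate temperature labels merged (averaged)")
    tab <- stats::aggregate(tab[-1], list(temperature = tab$temperature),
                            mean)
  }
  tab <- tab[order(tab$temperature), ]
  rho <- suppressWarnings(
    stats::cor(tab$temperature, tab$fraction, method = "spearman"))
  attr(tab, "spearman") <- rho
  tab
}
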