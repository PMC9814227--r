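#' @include synthetic-bilayer.R
NULL

## n points of a triangular-lattice (hexagonally packed) spiral around the
## origin, nearest-neighbor distance = spacing. Points come out in ring
## order, so consecutive points are lattice neighbors.
hexSpiral <- function(n, spacing) {
  ang <- (0:5) * pi / 3
  D <- cbind(cos(ang), sin(ang)) * spacing
  pts <- matrix(0, nrow = 1, ncol = 2)
  r <- 1L
  while (nrow(pts) < n) {
    p <- r * D[5, ]  # ring corner
    for (k in 1:6) {
      for (j in seq_len(r)) {
        pts <- rbind(pts, p)
        p <- p + D[k, ]
      }
    }
    r <- r + 1L
  }
  pts[seq_len(n), , drop = FALSE]
}

## indices of spiral points with all 6 lattice neighbors present
hexInterior <- function(pts, spacing) {
  d2 <- as.matrix(stats::dist(pts))^2
  nn <- rowSums(d2 > 1e-12 & d2 < (1.1 * spacing)^2)
  which(nn >= 6)
}

#' Relocate PI(4,5)P2 lipids into planted clusters
#'
#' Moves the frame's PI(4,5)P2 lipids (in-plane, keeping each lipid's
#' leaflet and internal geometry) into compact hexagonally packed disks:
#' nearest-neighbor spacing at most \code{intraSpacing} inside each disk
#' and at least \code{minGap} between bead positions of different disks.
#' Clusters are in-plane objects: a disk may contain lipids from both
#' leaflets, consistent with in-plane cluster detection. The planted
#' partition is recorded as ground truth and is exactly recoverable by
#' [detectClusters()] at any cutoff between \code{intraSpacing} and
#' \code{minGap}.
#'
#' @param frame a [MembraneFrame-class]
#' @param clusterSizes integer cluster sizes; must sum to the frame's
#'   PI(4,5)P2 count
#' @param intraSpacing nearest-neighbor spacing inside a cluster, nm
#' @param minGap minimum bead-bead gap between clusters, nm (must exceed
#'   the intended detection cutoff)
#' @param species species selector (prefix match; default all PI(4,5)P2)
#' @param seed RNG seed
#' @return list(frame, truth); \code{truth$plantedPartition} is the list
#'   of lipid-index sets
#' @export
plantClusters <- function(frame, clusterSizes, intraSpacing = 0.5,
                          minGap = 2.0, species = "PIP2", seed = 1) {
  sp <- lipidSpecies(frame)
  ids <- as.integer(names(sp)[speciesMatches(sp, species)])
  if (!length(ids)) stop("no ", species, " lipids in frame")
  if (sum(clusterSizes) != length(ids))
    stop("clusterSizes sum to ", sum(clusterSizes), " but the frame has ",
         length(ids), " ", species, " lipids")
  if (any(clusterSizes < 1)) stop("cluster sizes must be >= 1")
  box <- frame@box
  withSeed(seed, {
    s <- 0.95 * intraSpacing
    disks <- lapply(clusterSizes, hexSpiral, spacing = s)
    radii <- vapply(disks, function(d)
      if (nrow(d) > 1) max(sqrt(rowSums(d^2))) else 0, numeric(1))
    ## margin: headgroup beads spread ~0.15 nm around each anchor site
    margin <- minGap + 0.4
    centers <- matrix(NA_real_, length(disks), 2)
    for (i in seq_along(disks)) {
      ok <- FALSE
      for (try in seq_len(5000)) {
        c_i <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]))
        if (i == 1) { ok <- TRUE } else {
          prev <- centers[seq_len(i - 1), , drop = FALSE]
          d <- sqrt(pbcDist2(matrix(c_i, 1), prev, box[1:2]))
          ok <- all(d >= radii[i] + radii[seq_len(i - 1)] + margin)
        }
        if (ok) { centers[i, ] <- c_i; break }
      }
      if (!ok)
        stop("packing error: box too small to honor minGap = ", minGap,
             " nm for the requested cluster sizes")
    }
    ids <- sample(ids)  # random assignment of lipids to clusters
    partition <- vector("list", length(clusterSizes))
    b <- frame@beads
    ## current PO4 anchor of each lipid
    pos <- 0L
    for (i in seq_along(clusterSizes)) {
      members <- ids[pos + seq_len(clusterSizes[i])]
      pos <- pos + clusterSizes[i]
      partition[[i]] <- sort(members)
      sites <- sweep(disks[[i]], 2, centers[i, ], "+")
      for (j in seq_along(members)) {
        rows <- b$lipid == members[j]
        anchor <- b[rows & b$bead ==
                      frame@topology[[b$species[which(rows)[1]]]]$phosphodiester, ]
        shift <- c(sites[j, 1] - anchor$x[1], sites[j, 2] - anchor$y[1])
        b$x[rows] <- b$x[rows] + shift[1]
        b$y[rows] <- b$y[rows] + shift[2]
      }
    }
    frame@beads <- b
    frame <- wrapFrame(frame)
    list(frame = frame,
         truth = list(seed = seed, plantedPartition = partition,
                      centers = centers))
  })
}

#' Plant a hexagonally packed gel patch
#'
#' Rebuilds a contiguous triangular lattice of straight, fully extended
#' acyl chains at the given spacing in one leaflet, raised by
#' \code{thicknessIncrease} relative to the fluid background (emulating the
#' roughly 1 nm lipid-height offset of gel versus fluid phase). Lipids
#' closest to the patch center are converted; each contributes its two
#' chains to adjacent lattice sites. A moat around the patch is cleared of
#' fluid chains so that lattice-boundary classification is deterministic.
#'
#' @param frame a [MembraneFrame-class] with assigned leaflets
#' @param patchChainCount number of chains in the patch (127 gives a
#'   6-ring hexagonal disc with 91 interior chains)
#' @param latticeSpacing gel lattice constant per chain, nm (default 0.48)
#' @param thicknessIncrease height offset of the gel patch, nm
#' @param leaflet which leaflet carries the patch
#' @param seed RNG seed (moat relocations)
#' @return list(frame, truth); truth records the gel chain membership
#'   (\code{data.frame(lipid, chain)}), the lattice sites, and the number
#'   of interior sites
#' @export
buildGelPatch <- function(frame, patchChainCount = 127,
                          latticeSpacing = 0.48, thicknessIncrease = 1.0,
                          leaflet = "upper", seed = 1) {
  if (latticeSpacing <= 0) stop("latticeSpacing must be positive")
  box <- frame@box
  center <- box[1:2] / 2
  sites <- sweep(hexSpiral(patchChainCount, latticeSpacing), 2, center, "+")
  patchRadius <- max(sqrt(rowSums(sweep(sites, 2, center)^2))) +
    0.5 * latticeSpacing
  if (2 * (patchRadius + 1.6) > min(box[1:2]))
    stop("patch does not fit in the box with its moat")
  withSeed(seed, {
    b <- frame@beads
    lab <- frame@leaflet
    inLeaf <- as.integer(names(lab)[lab == leaflet])
    if (!length(inLeaf)) stop("no lipids in leaflet '", leaflet, "'")
    ## PO4 anchors of leaflet lipids
    phos <- vapply(frame@topology[b$species], function(t) t$phosphodiester,
                   character(1))
    po4 <- b[b$bead == phos & b$lipid %in% inLeaf, ]
    po4 <- po4[!duplicated(po4$lipid), ]
    z0f <- mean(po4$z)
    dc <- sqrt(pbcDist2(cbind(po4$x, po4$y), matrix(center, 1), box[1:2]))
    ord <- order(dc)
    nGel <- ceiling(patchChainCount / 2)
    gelLipids <- po4$lipid[ord[seq_len(nGel)]]
    up <- if (leaflet == "upper") +1 else -1

    ## rebuild each gel lipid: chains vertical on their sites
    siteOf <- function(k) if (k <= patchChainCount) sites[k, ] else NULL
    gelChains <- NULL
    for (j in seq_along(gelLipids)) {
      lp <- gelLipids[j]
      rows <- which(b$lipid == lp)
      top <- frame@topology[[b$species[rows[1]]]]
      sA <- siteOf(2 * j - 1)
      sB <- siteOf(2 * j)
      farB <- is.null(sB)
      if (farB) {
        ## unpaired partner chain: park it outside the moat, fluid height
        repeat {
          cand <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]))
          if (sqrt(pbcDist2(matrix(cand, 1), matrix(center, 1),
                            box[1:2])) > patchRadius + 1.6) break
        }
        sB <- cand
      }
      zP <- z0f + thicknessIncrease + stats::runif(1, -0.02, 0.02)
      zB0 <- if (farB) z0f else zP
      anchor <- (sA + sB) / 2
      newpos <- buildLipidBeads(top, anchor, zP, inward = -up, disorder = 0)
      ## override chain + glycerol lateral positions onto the lattice sites
      for (ci in seq_along(top$chains)) {
        s_ci <- if (ci == 1) sA else sB
        z_ci <- if (ci == 1) zP else zB0
        gl <- paste0("GL", min(ci, 2))
        gi <- which(newpos$bead == gl)
        newpos$x[gi] <- s_ci[1]; newpos$y[gi] <- s_ci[2]
        newpos$z[gi] <- z_ci - up * 0.32
        for (k in seq_along(top$chains[[ci]])) {
          bi <- which(newpos$bead == top$chains[[ci]][k])
          newpos$x[bi] <- s_ci[1]; newpos$y[bi] <- s_ci[2]
          newpos$z[bi] <- z_ci - up * (0.32 + k * MARTINI_BOND)
        }
      }
      ## PO4/head follow chain A's z
      b$x[rows] <- newpos$x[match(b$bead[rows], newpos$bead)]
      b$y[rows] <- newpos$y[match(b$bead[rows], newpos$bead)]
      b$z[rows] <- newpos$z[match(b$bead[rows], newpos$bead)]
      keep <- names(top$chains)
      if (farB) keep <- keep[1]
      gelChains <- rbind(gelChains,
                         data.frame(lipid = lp, chain = keep))
    }
    ## moat: push fluid lipids of this leaflet out of the patch surround
    fluid <- setdiff(inLeaf, gelLipids)
    for (lp in fluid) {
      rows <- which(b$lipid == lp)
      d <- min(sqrt(pbcDist2(cbind(b$x[rows], b$y[rows]),
                             matrix(center, 1), box[1:2])))
      if (d < patchRadius + 1.2) {
        repeat {
          cand <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]))
          if (sqrt(pbcDist2(matrix(cand, 1), matrix(center, 1),
                            box[1:2])) > patchRadius + 1.6) break
        }
        b$x[rows] <- b$x[rows] - b$x[rows[1]] + cand[1]
        b$y[rows] <- b$y[rows] - b$y[rows[1]] + cand[2]
      }
    }
    frame@beads <- b
    frame <- wrapFrame(frame)
    truth <- list(seed = seed, gelMembership = gelChains, sites = sites,
                  interiorCount = length(hexInterior(sites, latticeSpacing)),
                  thicknessIncrease = thicknessIncrease,
                  gelLipids = gelLipids, patchRadius = patchRadius)
    list(frame = frame, truth = truth)
  })
}
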