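#' @include io.R geometry.R
NULL

## Run expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  force(expr)
}

MARTINI_BOND <- 0.47  # CG bond length, nm

## Random unit vector(s); n x 3 matrix.
randomUnitVectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

## Bond directions for one chain: interpolation between the leaflet-inward
## axis (disorder 0) and isotropic random directions (disorder 1).
chainBondDirs <- function(nbonds, disorder, inward) {
  base <- matrix(rep(c(0, 0, inward), each = nbonds), nbonds, 3)
  if (disorder <= 0) return(base)
  u <- randomUnitVectors(nbonds)
  v <- (1 - disorder) * base + disorder * u
  v / sqrt(rowSums(v^2))
}

## Bead scaffold for one lipid. site: in-plane anchor (PO4 position);
## z0: PO4 height; inward: -1 upper leaflet, +1 lower (chains descend
## toward the midplane). Returns a matrix-ready list.
buildLipidBeads <- function(top, site, z0, inward, disorder) {
  up <- -inward  # away from midplane
  nm <- character(0); xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
  addBead <- function(name, x, y, z) {
    nm <<- c(nm, name); xs <<- c(xs, x); ys <<- c(ys, y); zs <<- c(zs, z)
  }
  ## headgroup stack above PO4, small in-plane offsets
  hg <- top$headgroup
  hgoff <- cbind(0.12 * cos(2 * pi * seq_along(hg) / max(1, length(hg))),
                 0.12 * sin(2 * pi * seq_along(hg) / max(1, length(hg))))
  for (i in seq_along(hg))
    addBead(hg[i], site[1] + hgoff[i, 1], site[2] + hgoff[i, 2],
            z0 + up * (0.30 + 0.12 * i))
  addBead(top$phosphodiester, site[1], site[2], z0)
  glx <- c(-0.12, 0.12)
  addBead("GL1", site[1] + glx[1], site[2], z0 - up * 0.30)
  addBead("GL2", site[1] + glx[2], site[2], z0 - up * 0.32)
  for (ci in seq_along(top$chains)) {
    chain <- top$chains[[ci]]
    start <- c(site[1] + glx[min(ci, 2)], site[2], z0 - up * 0.32)
    dirs <- chainBondDirs(length(chain), disorder, inward)
    pos <- start
    for (k in seq_along(chain)) {
      pos <- pos + MARTINI_BOND * dirs[k, ]
      addBead(chain[k], pos[1], pos[2], pos[3])
    }
  }
  list(bead = nm, x = xs, y = ys, z = zs)
}

## Assemble a frame from per-lipid scaffolds.
assembleFrame <- function(lipids, species, leaflet, box, topology, time = 0) {
  nb <- vapply(lipids, function(l) length(l$bead), integer(1))
  beads <- data.frame(
    bead = unlist(lapply(lipids, `[[`, "bead")),
    lipid = rep(seq_along(lipids), nb),
    species = rep(species, nb),
    x = unlist(lapply(lipids, `[[`, "x")),
    y = unlist(lapply(lipids, `[[`, "y")),
    z = unlist(lapply(lipids, `[[`, "z")),
    stringsAsFactors = FALSE)
  names(leaflet) <- seq_along(lipids)
  fr <- newFrame(box, beads, topology, time = time, leaflet = leaflet)
  wrapFrame(fr)
}

## Jittered lattice sites for one leaflet: nSites sites on an nx x ny grid.
leafletSites <- function(nSites, Lx, Ly, jitterFrac = 0.06) {
  nx <- ceiling(sqrt(nSites * Lx / Ly))
  ny <- ceiling(nSites / nx)
  ax <- Lx / nx; ay <- Ly / ny
  g <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  g <- g[seq_len(nSites), ]
  cbind(g$ix * ax + stats::runif(nSites, -jitterFrac, jitterFrac) * ax,
        g$iy * ay + stats::runif(nSites, -jitterFrac, jitterFrac) * ay)
}

#' Generate a fluid bilayer with dispersed PI(4,5)P2
#'
#' Builds two mirrored leaflets on jittered lattices at the given area per
#' lipid, with acyl chains grown bead by bead toward the midplane under
#' angular noise scaled by \code{chainDisorder} (0: all bonds parallel to
#' the normal; 1: isotropic bond directions). Species are assigned at
#' random lattice sites at the requested PI(4,5)P2 fraction, split evenly
#' between leaflets, with no planted clusters.
#'
#' @param nLipids total lipid count (even)
#' @param pip2Fraction PI(4,5)P2 mole fraction in [0, 1]
#' @param pip2Species which PI(4,5)P2 variant to use
#' @param areaPerLipid area per lipid in nm^2 (default 0.64, fluid
#'   POPC-like)
#' @param chainDisorder chain angular-noise level in [0, 1]
#' @param boxZ box height in nm
#' @param leafletOffset PO4 plane distance from the midplane, nm
#' @param seed RNG seed; identical seeds give identical output
#' @return list with elements \code{frame} (a [MembraneFrame-class] with
#'   planted leaflet labels) and \code{truth} (seed, PI(4,5)P2 lipid ids,
#'   planted leaflet labels)
#' @examples
#' syn <- buildFluidBilayer(nLipids = 100, pip2Fraction = 0.1, seed = 1)
#' table(lipidSpecies(syn$frame))
#' @export
buildFluidBilayer <- function(nLipids = 900, pip2Fraction = 0.1,
                              pip2Species = "PIP2_160",
                              areaPerLipid = 0.64, chainDisorder = 0.3,
                              boxZ = 10, leafletOffset = 2.0, seed = 1) {
  stopifnot(pip2Fraction >= 0, pip2Fraction <= 1)
  if (nLipids %% 2 != 0) stop("nLipids must be even (two equal leaflets)")
  if (areaPerLipid < 0.3)
    stop("geometry error: area per lipid ", areaPerLipid,
         " nm^2 is too small for a non-overlapping lattice")
  topology <- defaultTopology()
  if (!pip2Species %in% names(topology))
    stop("unknown PI(4,5)P2 species: ", pip2Species)
  withSeed(seed, {
    per <- nLipids %/% 2L
    L <- sqrt(per * areaPerLipid)
    Lx <- Ly <- L
    nPip <- round(nLipids * pip2Fraction)
    nUp <- nPip %/% 2L
    nLo <- nPip - nUp
    sitesUp <- leafletSites(per, Lx, Ly)
    sitesLo <- leafletSites(per, Lx, Ly)
    spUp <- rep("POPC", per); spUp[sample.int(per, nUp)] <- pip2Species
    spLo <- rep("POPC", per); spLo[sample.int(per, nLo)] <- pip2Species
    z0 <- boxZ / 2
    lipids <- vector("list", nLipids)
    species <- c(spUp, spLo)
    leaflet <- rep(c("upper", "lower"), c(per, per))
    for (i in seq_len(per)) {
      lipids[[i]] <- buildLipidBeads(topology[[spUp[i]]], sitesUp[i, ],
        z0 + leafletOffset + stats::runif(1, -0.05, 0.05), inward = -1,
        disorder = chainDisorder)
      lipids[[per + i]] <- buildLipidBeads(topology[[spLo[i]]], sitesLo[i, ],
        z0 - leafletOffset + stats::runif(1, -0.05, 0.05), inward = +1,
        disorder = chainDisorder)
    }
    frame <- assembleFrame(lipids, species, leaflet, c(Lx, Ly, boxZ),
                           topology)
    truth <- list(seed = seed,
                  pip2Lipids = which(species == pip2Species),
                  plantedLeaflet = leaflet)
    list(frame = frame, truth = truth)
  })
}

#' Generate an asymmetric bilayer (PI(4,5)P2 in the lower leaflet only)
#'
#' As [buildFluidBilayer()], but with per-leaflet composition: the upper
#' leaflet is pure POPC and the lower leaflet carries the given PI(4,5)P2
#' fraction. The lower-leaflet lipid count is chosen so the two leaflet
#' areas (per-species area per lipid times count) match.
#'
#' @param nLipidsUpper upper-leaflet lipid count
#' @param pip2FractionLower PI(4,5)P2 fraction in the lower leaflet
#' @param pip2AreaPerLipid area per PI(4,5)P2 lipid in nm^2 (default: same
#'   as POPC, matching CG chain counts)
#' @inheritParams buildFluidBilayer
#' @return list(frame, truth); truth records the per-leaflet areas
#' @export
buildAsymmetricBilayer <- function(nLipidsUpper = 450,
                                   pip2FractionLower = 0.1,
                                   pip2Species = "PIP2_160",
                                   areaPerLipid = 0.64,
                                   pip2AreaPerLipid = areaPerLipid,
                                   chainDisorder = 0.3, boxZ = 10,
                                   leafletOffset = 2.0, seed = 1) {
  stopifnot(pip2FractionLower >= 0, pip2FractionLower <= 1)
  topology <- defaultTopology()
  withSeed(seed, {
    areaUpper <- nLipidsUpper * areaPerLipid
    f <- pip2FractionLower
    nLower <- round(areaUpper /
                      (f * pip2AreaPerLipid + (1 - f) * areaPerLipid))
    nPip <- round(f * nLower)
    areaLower <- nPip * pip2AreaPerLipid +
      (nLower - nPip) * areaPerLipid
    Lx <- Ly <- sqrt(areaUpper)
    sitesUp <- leafletSites(nLipidsUpper, Lx, Ly)
    sitesLo <- leafletSites(nLower, Lx, Ly)
    spUp <- rep("POPC", nLipidsUpper)
    spLo <- rep("POPC", nLower); spLo[sample.int(nLower, nPip)] <- pip2Species
    z0 <- boxZ / 2
    lipids <- vector("list", nLipidsUpper + nLower)
    for (i in seq_len(nLipidsUpper))
      lipids[[i]] <- buildLipidBeads(topology[[spUp[i]]], sitesUp[i, ],
        z0 + leafletOffset + stats::runif(1, -0.05, 0.05), -1, chainDisorder)
    for (i in seq_len(nLower))
      lipids[[nLipidsUpper + i]] <- buildLipidBeads(topology[[spLo[i]]],
        sitesLo[i, ], z0 - leafletOffset + stats::runif(1, -0.05, 0.05),
        +1, chainDisorder)
    frame <- assembleFrame(lipids, c(spUp, spLo),
                           rep(c("upper", "lower"), c(nLipidsUpper, nLower)),
                           c(Lx, Ly, boxZ), topology)
    truth <- list(seed = seed, areaUpper = areaUpper, areaLower = areaLower,
                  nLower = nLower,
                  pip2Lipids = nLipidsUpper + which(spLo == pip2Species))
    list(frame = frame, truth = truth)
  })
}

#' Generate an undulated bilayer with analytic mean curvature
#'
#' Builds a fluid bilayer and displaces both leaflets by
#' \code{z <- z + A * sin(2*pi*x / L)}. The ground truth records the
#' analytic mean-curvature field of the displaced mid-surface,
#' \deqn{H(x) = -\frac{A (2\pi/L)^2 \sin(2\pi x/L)}
#'   {2\,(1 + (A (2\pi/L) \cos(2\pi x/L))^2)^{3/2}},}
#' i.e. the Monge-patch convention in which a crest (bulging toward +z)
#' has negative H.
#'
#' @param amplitude undulation amplitude A in nm (must be < boxZ / 4)
#' @param wavelength undulation wavelength L in nm (must fit in the box)
#' @inheritParams buildFluidBilayer
#' @return list(frame, truth); \code{truth$analyticH} is a function of x
#'   (nm) returning H in 1/nm
#' @export
buildUndulatedBilayer <- function(nLipids = 900, amplitude = 1,
                                  wavelength = 25, pip2Fraction = 0,
                                  chainDisorder = 0.3, areaPerLipid = 0.64,
                                  boxZ = 14, seed = 1) {
  base <- buildFluidBilayer(nLipids = nLipids, pip2Fraction = pip2Fraction,
                            areaPerLipid = areaPerLipid,
                            chainDisorder = chainDisorder, boxZ = boxZ,
                            seed = seed)
  frame <- base$frame
  if (wavelength > frame@box[1])
    stop("wavelength ", wavelength, " nm exceeds the box length ",
         signif(frame@box[1], 4), " nm")
  if (amplitude >= frame@box[3] / 4)
    stop("amplitude must be below a quarter of the box height")
  k <- 2 * pi / wavelength
  frame@beads$z <- frame@beads$z + amplitude * sin(k * frame@beads$x)
  analyticH <- function(x, y = NULL) {
    -(amplitude * k^2 * sin(k * x)) /
      (2 * (1 + (amplitude * k * cos(k * x))^2)^1.5)
  }
  truth <- base$truth
  truth$amplitude <- amplitude
  truth$wavelength <- wavelength
  truth$analyticH <- analyticH
  list(frame = frame, truth = truth)
}
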