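#' @include geometry.R
NULL

#' Assign lipids to leaflets
#'
#' Splits lipids into upper and lower leaflets by the z position of one
#' reference bead per lipid (default: the phosphodiester bead, \code{PO4},
#' which every species in scope carries) relative to a grid-local midplane.
#' The midplane is the per-cell mean reference-bead z over a coarse
#' in-plane grid, which reduces to the global midplane for flat membranes
#' and follows the mid-surface for undulated ones; cells with too few beads
#' fall back to the global mean. Assignment is invariant to rigid
#' z-translation of the whole frame.
#'
#' @param frame a [MembraneFrame-class]
#' @param referenceBead reference bead name; by default each species'
#'   phosphodiester bead
#' @param cellSize in-plane midplane grid cell size in nm
#' @return the frame with \code{leaflet} labels set
#' @section Errors: if either leaflet ends up empty, or the two groups'
#'   mean |z - midplane| separation is below 1 nm (all reference beads
#'   within about one thermal width of the midplane), the geometry is
#'   degenerate (e.g. a monolayer) and an error is raised.
#' @export
assignLeaflets <- function(frame, referenceBead = NULL, cellSize = 4) {
  b <- frame@beads
  sp <- b$species
  refname <- if (is.null(referenceBead))
    vapply(frame@topology[sp], function(t) t$phosphodiester, character(1))
  else rep(referenceBead, nrow(b))
  ref <- b[b$bead == refname, , drop = FALSE]
  lip <- unique(b$lipid)
  if (!all(lip %in% ref$lipid))
    stop("reference bead missing for ",
         sum(!(lip %in% ref$lipid)), " lipid(s)")
  ref <- ref[!duplicated(ref$lipid), ]
  ref <- ref[match(lip, ref$lipid), ]

  nx <- max(1L, floor(frame@box[1] / cellSize))
  ny <- max(1L, floor(frame@box[2] / cellSize))
  ix <- floor(wrapCoord(ref$x, frame@box[1]) / frame@box[1] * nx) + 1L
  iy <- floor(wrapCoord(ref$y, frame@box[2]) / frame@box[2] * ny) + 1L
  cell <- (iy - 1L) * nx + ix
  mid_global <- mean(ref$z)
  mids <- tapply(ref$z, cell, mean)
  ncell <- tapply(ref$z, cell, length)
  mids[ncell < 4] <- mid_global
  dz <- as.numeric(ref$z - mids[as.character(cell)])

  upper <- dz > 0
  if (!any(upper) || all(upper))
    stop("degenerate geometry: all reference beads on one side of the ",
         "midplane (monolayer?)")
  sep <- mean(dz[upper]) - mean(dz[!upper])
  if (sep < 1)
    stop("degenerate geometry: leaflet separation ", signif(sep, 3),
         " nm is below 1 nm; reference beads lie within one thermal ",
         "width of the midplane")
  lab <- ifelse(upper, "upper", "lower")
  names(lab) <- lip
  frame@leaflet <- lab
  frame
}

## per-lipid leaflet label pulled onto bead rows
beadLeaflet <- function(frame) {
  frame@leaflet[as.character(frame@beads$lipid)]
}
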