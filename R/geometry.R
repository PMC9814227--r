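#' @include AllClasses.R
NULL

## Minimum-image displacement for one axis: dx - L * round(dx / L).
## For an orthorhombic box this per-axis form equals the minimum over all
## periodic images.
pbcDelta <- function(dx, L) dx - L * round(dx / L)

#' Minimum-image distance under periodic boundaries
#'
#' Euclidean distance between two points under the minimum-image convention
#' in an orthorhombic box. With \code{inPlane = TRUE} only the x and y
#' components contribute (leaflet-lateral distance).
#'
#' @param p,q numeric(3) positions in nm
#' @param box numeric(3) box lengths in nm
#' @param inPlane logical; drop the z component
#' @return distance in nm
#' @examples
#' minimumImageDistance(c(1, 0, 0), c(9, 0, 0), c(10, 10, 10))  # 2
#' @export
minimumImageDistance <- function(p, q, box, inPlane = FALSE) {
  stopifnot(length(box) == 3, all(box > 0))
  d <- pbcDelta(p - q, box)
  if (inPlane) d <- d[1:2]
  sqrt(sum(d^2))
}

## Squared minimum-image distances between two coordinate sets.
## a: n x k matrix, b: m x k matrix, box: length-k box lengths
## (k = 2 for in-plane, 3 otherwise). Returns n x m matrix.
pbcDist2 <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in seq_len(ncol(a))) {
    dk <- pbcDelta(outer(a[, k], b[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

## Wrap coordinates into [0, L).
wrapCoord <- function(x, L) x - L * floor(x / L)

#' Wrap all beads of a frame into the primary box image
#'
#' Lipids are kept whole: each lipid is wrapped rigidly by the image shift
#' of its first bead, so no lipid is split across box images.
#'
#' @param frame a [MembraneFrame-class]
#' @return the frame with wrapped coordinates
#' @export
wrapFrame <- function(frame) {
  b <- frame@beads
  first <- !duplicated(b$lipid)
  ref <- b[first, c("lipid", "x", "y", "z")]
  shift <- data.frame(
    lipid = ref$lipid,
    sx = wrapCoord(ref$x, frame@box[1]) - ref$x,
    sy = wrapCoord(ref$y, frame@box[2]) - ref$y,
    sz = wrapCoord(ref$z, frame@box[3]) - ref$z)
  idx <- match(b$lipid, shift$lipid)
  b$x <- b$x + shift$sx[idx]
  b$y <- b$y + shift$sy[idx]
  b$z <- b$z + shift$sz[idx]
  frame@beads <- b
  frame
}

## Coordinates (n x 3 matrix) of selected bead rows.
beadCoords <- function(bdf) cbind(x = bdf$x, y = bdf$y, z = bdf$z)

## In-plane centroid of a bead set, unwrapped relative to the first bead so
## that chains straddling the boundary centre correctly; returned wrapped.
unwrappedCentroidXY <- function(x, y, box) {
  x <- x[1] + c(0, cumsum(pbcDelta(diff(x), box[1])))
  y <- y[1] + c(0, cumsum(pbcDelta(diff(y), box[2])))
  c(wrapCoord(mean(x), box[1]), wrapCoord(mean(y), box[2]))
}
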