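#' @include geometry.R leaflets.R
NULL

## cell index helpers for a periodic grid
gridIndex <- function(x, L, n) floor(wrapCoord(x, L) / L * n) + 1L

#' Gridded leaflet surface heights
#'
#' Bins one reference bead per lipid onto a periodic in-plane grid; each
#' cell's height is the mean z of its contributing beads. Cells with no
#' contributing bead are masked.
#'
#' @param frame a [MembraneFrame-class] with assigned leaflets
#' @param leaflet "upper" or "lower"
#' @param bead reference bead name (default: per-species phosphodiester)
#' @param spacing requested grid spacing in nm (actual spacing divides the
#'   box evenly)
#' @return a [HeightField-class]
#' @export
buildHeightField <- function(frame, leaflet, bead = NULL, spacing = 1.0) {
  if (all(frame@leaflet == "unassigned"))
    stop("leaflets not assigned; run assignLeaflets() first")
  b <- frame@beads
  refname <- if (is.null(bead))
    vapply(frame@topology[b$species], function(t) t$phosphodiester,
           character(1))
  else rep(bead, nrow(b))
  keep <- b$bead == refname &
    frame@leaflet[as.character(b$lipid)] == leaflet
  bb <- b[keep, ]
  if (!nrow(bb)) stop("no reference beads in leaflet '", leaflet, "'")
  if (spacing < 0.4)
    warning("grid spacing ", spacing,
            " nm is below half the typical bead spacing (oversampling)")
  box <- frame@box
  nx <- max(1L, round(box[1] / spacing))
  ny <- max(1L, round(box[2] / spacing))
  sx <- box[1] / nx; sy <- box[2] / ny
  ix <- gridIndex(bb$x, box[1], nx)
  iy <- gridIndex(bb$y, box[2], ny)
  cell <- (iy - 1L) * nx + ix
  vals <- matrix(NA_real_, nx, ny)
  agg <- tapply(bb$z, cell, mean)
  vals[as.integer(names(agg))] <- agg
  mask <- !is.na(vals)
  new("HeightField", values = vals, mask = mask, spacing = c(sx, sy),
      origin = c(0, 0), what = paste0("height:", leaflet))
}

#' Local mean curvature of a gridded surface
#'
#' Fits a local quadratic Monge patch
#' \eqn{z = a x^2 + b y^2 + c xy + d x + e y + f} by least squares to the
#' occupied cells within \code{fitRadius} of each cell (periodic), and
#' evaluates the mean curvature with the full first-fundamental-form
#' correction
#' \deqn{H = \frac{a (1 + e^2) + b (1 + d^2) - c d e}
#'   {(1 + d^2 + e^2)^{3/2}},}
#' which is exact for tilted planes (H = 0 for any plane). Sign
#' convention: H carries the sign of the height Laplacian, so crests
#' (bulging toward +z) are negative and valleys positive. Cells with
#' fewer than 6 occupied neighbors, rank-deficient fits, or |H| beyond
#' the 1/(2 spacing) sanity bound are masked.
#'
#' @param height a [HeightField-class]
#' @param fitRadius neighborhood radius in nm (default 2.5)
#' @return a [CurvatureField-class]
#' @export
meanCurvatureField <- function(height, fitRadius = 2.5) {
  v <- height@values
  nx <- nrow(v); ny <- ncol(v)
  sx <- height@spacing[1]; sy <- height@spacing[2]
  Lx <- nx * sx; Ly <- ny * sy
  occ <- which(height@mask, arr.ind = TRUE)
  cxo <- (occ[, 1] - 0.5) * sx
  cyo <- (occ[, 2] - 0.5) * sy
  zo <- v[height@mask]
  H <- matrix(NA_real_, nx, ny)
  bound <- 1 / (2 * min(sx, sy))
  for (idx in seq_len(nrow(occ))) {
    x0 <- cxo[idx]; y0 <- cyo[idx]
    dx <- pbcDelta(cxo - x0, Lx)
    dy <- pbcDelta(cyo - y0, Ly)
    sel <- dx^2 + dy^2 <= fitRadius^2
    if (sum(sel) < 6) next
    X <- cbind(dx[sel]^2, dy[sel]^2, dx[sel] * dy[sel], dx[sel], dy[sel], 1)
    qrX <- qr(X)
    if (qrX$rank < 6) next
    cf <- qr.coef(qrX, zo[sel])
    a <- cf[1]; bq <- cf[2]; cc <- cf[3]; d <- cf[4]; e <- cf[5]
    h <- (a * (1 + e^2) + bq * (1 + d^2) - cc * d * e) /
      (1 + d^2 + e^2)^1.5
    if (is.finite(h) && abs(h) <= bound) H[occ[idx, 1], occ[idx, 2]] <- h
  }
  new("CurvatureField", values = H, mask = !is.na(H),
      spacing = height@spacing, origin = height@origin,
      what = sub("height", "meanCurvature", height@what))
}

#' Bilayer thickness map
#'
#' Per-cell upper-leaflet height minus lower-leaflet height (phosphate
#' to phosphate). Cells occupied in only one leaflet are masked. The
#' returned field carries per-species, per-leaflet mean reference-bead
#' heights as attribute \code{"speciesHeights"}.
#'
#' @param frame a [MembraneFrame-class] with assigned leaflets
#' @param spacing grid spacing in nm
#' @param bead reference bead (default: phosphodiester)
#' @return a [HeightField-class] of thickness values
#' @export
thicknessMap <- function(frame, spacing = 1.0, bead = NULL) {
  up <- buildHeightField(frame, "upper", bead, spacing)
  lo <- buildHeightField(frame, "lower", bead, spacing)
  mask <- up@mask & lo@mask
  vals <- up@values - lo@values
  vals[!mask] <- NA_real_
  b <- frame@beads
  refname <- if (is.null(bead))
    vapply(frame@topology[b$species], function(t) t$phosphodiester,
           character(1))
  else rep(bead, nrow(b))
  ref <- b[b$bead == refname, ]
  sph <- stats::aggregate(
    z ~ species + leaflet,
    data = data.frame(z = ref$z, species = ref$species,
                      leaflet = frame@leaflet[as.character(ref$lipid)]),
    FUN = mean)
  out <- new("HeightField", values = vals, mask = mask,
             spacing = up@spacing, origin = up@origin, what = "thickness")
  attr(out, "speciesHeights") <- sph
  out
}

#' Inter-leaflet registration coefficient of a species
#'
#' Grids each leaflet's species positions (phosphodiester beads) into a
#' binary occupancy field and returns the Pearson correlation of the two
#' fields over all cells: +1 for registered domains, 0 for independent
#' placement, -1 for anti-registered (decoupled) domains. Symmetric under
#' leaflet exchange.
#'
#' @param frame a [MembraneFrame-class] with assigned leaflets
#' @param species species selector (default all PI(4,5)P2)
#' @param spacing occupancy grid spacing in nm
#' @return a [RegistrationResult-class]
#' @export
registrationCoefficient <- function(frame, species = "PIP2",
                                    spacing = 2.0) {
  if (all(frame@leaflet == "unassigned"))
    stop("leaflets not assigned; run assignLeaflets() first")
  sp <- lipidSpecies(frame)
  ids <- as.integer(names(sp)[speciesMatches(sp, species)])
  if (!length(ids)) stop("species '", species, "' not present in frame")
  lab <- frame@leaflet[as.character(ids)]
  if (!any(lab == "upper") || !any(lab == "lower"))
    stop("registration undefined: species '", species,
         "' present in one leaflet only")
  b <- frame@beads
  refname <- vapply(frame@topology[b$species],
                    function(t) t$phosphodiester, character(1))
  box <- frame@box
  nx <- max(1L, round(box[1] / spacing))
  ny <- max(1L, round(box[2] / spacing))
  occField <- function(which_leaf) {
    sel <- b$lipid %in% ids & b$bead == refname &
      frame@leaflet[as.character(b$lipid)] == which_leaf
    m <- matrix(0, nx, ny)
    ix <- gridIndex(b$x[sel], box[1], nx)
    iy <- gridIndex(b$y[sel], box[2], ny)
    m[cbind(ix, iy)] <- 1
    m
  }
  up <- occField("upper"); lo <- occField("lower")
  coef <- if (stats::sd(up) == 0 || stats::sd(lo) == 0) NA_real_
  else stats::cor(as.vector(up), as.vector(lo))
  new("RegistrationResult", coefficient = coef,
      spacing = box[1] / nx, upper = up, lower = lo)
}
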