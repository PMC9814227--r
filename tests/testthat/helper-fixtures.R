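# Shared fixtures and independent oracles. The brute-force cluster oracle
# deliberately avoids the package's periodic-distance helpers: it
# enumerates explicit periodic images and merges with a hand-rolled
# union-find, so it is an independent check on detectClusters().

# canonical form of a partition (list of integer vectors) for comparison
canonicalPartition <- function(p) {
  p <- lapply(p, function(s) sort(as.integer(s)))
  p <- p[order(vapply(p, min, integer(1)))]
  names(p) <- NULL
  p
}

# O(N^2) union-find cluster oracle over explicit periodic images
bruteForceClusters <- function(frame, species = "PIP2", cutoff = 0.6,
                               inPlane = TRUE) {
  b <- beads(frame)
  sp <- lipidSpecies(frame)
  ids <- as.integer(names(sp)[startsWith(sp, species)])
  topo <- frame@topology
  keep <- rep(FALSE, nrow(b))
  for (s in unique(sp[as.character(ids)])) {
    selb <- c(topo[[s]]$headgroup, topo[[s]]$phosphodiester)
    keep <- keep | (b$species == s & b$bead %in% selb)
  }
  keep <- keep & b$lipid %in% ids
  bb <- b[keep, ]
  box <- boxDims(frame)
  n <- nrow(bb)
  shifts <- expand.grid(sx = -1:1, sy = -1:1,
                        sz = if (inPlane) 0 else -1:1)
  d2min <- matrix(Inf, n, n)
  for (k in seq_len(nrow(shifts))) {
    dx <- outer(bb$x, bb$x + shifts$sx[k] * box[1], "-")
    dy <- outer(bb$y, bb$y + shifts$sy[k] * box[2], "-")
    d2 <- dx^2 + dy^2
    if (!inPlane) {
      dz <- outer(bb$z, bb$z + shifts$sz[k] * box[3], "-")
      d2 <- d2 + dz^2
    }
    d2min <- pmin(d2min, d2)
  }
  # union-find over lipids
  parent <- seq_along(ids)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lipOf <- match(bb$lipid, ids)
  hit <- which(d2min <= cutoff^2, arr.ind = TRUE)
  for (h in seq_len(nrow(hit))) {
    i <- lipOf[hit[h, 1]]; j <- lipOf[hit[h, 2]]
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(ids), findRoot, integer(1))
  canonicalPartition(split(ids, roots))
}

# minimal frame carrying only PO4 beads of PIP2_160 at given in-plane
# positions per leaflet (z = 7 upper, 3 lower); for registration tests
patternFrame <- function(upperXY, lowerXY, box = c(20, 20, 10)) {
  nu <- nrow(upperXY); nl <- nrow(lowerXY)
  beads <- data.frame(
    bead = "PO4",
    lipid = seq_len(nu + nl),
    species = "PIP2_160",
    x = c(upperXY[, 1], lowerXY[, 1]),
    y = c(upperXY[, 2], lowerXY[, 2]),
    z = rep(c(7, 3), c(nu, nl)))
  leaflet <- rep(c("upper", "lower"), c(nu, nl))
  names(leaflet) <- seq_len(nu + nl)
  new("MembraneFrame", box = box, beads = beads,
      topology = defaultTopology(), leaflet = leaflet, time = 0)
}

# rotate all beads in-plane about a center (degrees), wrapping into the box
rotateFrameXY <- function(frame, angleDeg, center = boxDims(frame)[1:2] / 2) {
  th <- angleDeg * pi / 180
  b <- beads(frame)
  dx <- b$x - center[1]; dy <- b$y - center[2]
  b$x <- center[1] + cos(th) * dx - sin(th) * dy
  b$y <- center[2] + sin(th) * dx + cos(th) * dy
  box <- boxDims(frame)
  b$x <- b$x - box[1] * floor(b$x / box[1])
  b$y <- b$y - box[2] * floor(b$y / box[2])
  frame@beads <- b
  frame
}

# straighten the acyl chains of the given lipids (all bonds parallel to
# the leaflet normal), for planted-shell order constructions
straightenChains <- function(frame, lipids) {
  b <- beads(frame)
  lab <- leaflets(frame)
  for (lp in lipids) {
    rows <- which(b$lipid == lp)
    top <- frame@topology[[b$species[rows[1]]]]
    up <- if (lab[as.character(lp)] == "upper") 1 else -1
    for (ci in seq_along(top$chains)) {
      ch <- top$chains[[ci]]
      gl <- paste0("GL", min(ci, 2))
      gi <- rows[b$bead[rows] == gl]
      for (k in seq_along(ch)) {
        bi <- rows[b$bead[rows] == ch[k]]
        b$x[bi] <- b$x[gi]
        b$y[bi] <- b$y[gi]
        b$z[bi] <- b$z[gi] - up * k * 0.47
      }
    }
  }
  frame@beads <- b
  frame
}

# analytic-bowl frame: one PO4 bead per lipid on a spherical bowl cap of
# radius R (concave up, curvature +1/R), surrounded by masked vacuum
sphereCapFrame <- function(R = 10, rhoMax = 5, box = c(20, 20, 20),
                           spacing = 0.5) {
  g <- expand.grid(x = seq(0.25, box[1], by = spacing),
                   y = seq(0.25, box[2], by = spacing))
  dx <- g$x - box[1] / 2; dy <- g$y - box[2] / 2
  rho2 <- dx^2 + dy^2
  g <- g[rho2 <= rhoMax^2, ]
  rho2 <- rho2[rho2 <= rhoMax^2]
  z <- 10 - sqrt(R^2 - rho2) + R
  n <- nrow(g)
  beads <- data.frame(bead = "PO4", lipid = seq_len(n),
                      species = "PIP2_160", x = g$x, y = g$y, z = z)
  leaflet <- rep("upper", n)
  names(leaflet) <- seq_len(n)
  new("MembraneFrame", box = box, beads = beads,
      topology = defaultTopology(), leaflet = leaflet, time = 0)
}
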