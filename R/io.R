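#' @include AllClasses.R topology.R
NULL

## Construct a MembraneFrame with unassigned leaflets.
newFrame <- function(box, beads, topology, time = 0,
                     leaflet = NULL) {
  nl <- length(unique(beads$lipid))
  if (is.null(leaflet)) leaflet <- rep("unassigned", nl)
  names(leaflet) <- unique(beads$lipid)
  new("MembraneFrame", box = as.numeric(box), beads = beads,
      topology = topology, leaflet = leaflet, time = as.numeric(time))
}

## species name <-> 5-char residue alias maps for a topology list
resnameMap <- function(topology) {
  ali <- vapply(topology, function(t)
    if (is.null(t$resname)) substr(t$species, 1, 5) else t$resname,
    character(1))
  names(ali) <- names(topology)
  ali
}

speciesFromResname <- function(res, topology) {
  ali <- resnameMap(topology)
  out <- names(ali)[match(res, ali)]
  direct <- match(res, names(ali))
  out[is.na(out)] <- names(ali)[direct[is.na(out)]]
  out
}

parseGROFrames <- function(lines, path) {
  frames <- list()
  i <- 1L
  nline <- length(lines)
  fidx <- 0L
  while (i <= nline) {
    if (!nzchar(trimws(lines[i])) && i == nline) break
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms <= 0)
      stop("GRO format error in '", path, "' at line ", i + 1L,
           ": expected atom count, got '", trimws(lines[i + 1L]), "'")
    if (i + 1L + natoms + 1L > nline)
      stop("GRO format error in '", path, "': truncated frame at line ", i)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
    resname <- trimws(substr(atom_lines, 6, 10))
    atname <- trimws(substr(atom_lines, 11, 15))
    x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop("GRO format error in '", path, "' at line ", i + 1L + bad[1],
           ": unparseable atom record")
    boxv <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[i + 2L + natoms]), "\\s+")[[1]]))
    if (length(boxv) < 3 || any(is.na(boxv[1:3])))
      stop("GRO format error in '", path, "' at line ", i + 2L + natoms,
           ": unparseable box line")
    if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
      stop("triclinic box in '", path, "' is not supported; ",
           "only orthorhombic boxes are handled")
    fidx <- fidx + 1L
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    tm <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else fidx - 1
    frames[[fidx]] <- list(resid = resid, resname = resname,
                           atname = atname, x = x, y = y, z = z,
                           box = boxv[1:3], time = tm)
    i <- i + 3L + natoms
    while (i <= nline && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames))
    stop("no frames found in '", path, "'")
  frames
}

rawToFrame <- function(raw, topology, path) {
  species <- speciesFromResname(raw$resname, topology)
  if (anyNA(species)) {
    unk <- unique(raw$resname[is.na(species)])
    stop("unknown species in '", path, "': residue name(s) ",
         paste(unk, collapse = ", "),
         " have no topology entry")
  }
  ## lipid index increments whenever the residue id changes (robust to
  ## resid wrap-around)
  newlip <- c(TRUE, diff(raw$resid) != 0)
  lipid <- cumsum(newlip)
  beads <- data.frame(bead = raw$atname, lipid = lipid, species = species,
                      x = raw$x, y = raw$y, z = raw$z,
                      stringsAsFactors = FALSE)
  newFrame(raw$box, beads, topology, time = raw$time)
}

#' Load membrane frames from GRO or PDB coordinate files
#'
#' Reads one or more coarse-grained membrane snapshots. GRO files
#' (fixed-column, nm) may contain several concatenated frames; a directory
#' is read as per-frame GRO files in lexical order. PDB input (ATOM
#' records, Angstrom) is converted to nm on load. Every residue name must
#' resolve in the topology map, either as a species name or its
#' 5-character residue alias.
#'
#' @param path a GRO/PDB file or a directory of GRO files
#' @param topology topology map, see [defaultTopology()]
#' @param frameRange optional integer vector of frame indices to keep
#' @return a [MembraneTrajectory-class]
#' @export
loadFrames <- function(path, topology = defaultTopology(),
                       frameRange = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.gro$", full.names = TRUE))
    if (!length(files)) stop("no .gro files found in directory '", path, "'")
    raws <- unlist(lapply(files, function(f)
      parseGROFrames(readLines(f), f)), recursive = FALSE)
  } else if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    raws <- list(parsePDBFrame(path))
  } else {
    raws <- parseGROFrames(readLines(path), path)
  }
  ## re-sequence times if the files carry none / duplicates
  tm <- vapply(raws, function(r) r$time, numeric(1))
  if (any(duplicated(tm)) || is.unsorted(tm, strictly = TRUE))
    for (k in seq_along(raws)) raws[[k]]$time <- k - 1
  if (!is.null(frameRange)) {
    if (any(frameRange < 1 | frameRange > length(raws)))
      stop("frameRange outside 1..", length(raws))
    raws <- raws[frameRange]
  }
  fr <- lapply(raws, rawToFrame, topology = topology, path = path)
  new("MembraneTrajectory", frames = fr, topology = topology)
}

## Single-model PDB via bio3d; coordinates converted Angstrom -> nm.
parsePDBFrame <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  box <- c(10, 10, 10)
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                       substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(cr[1], 34, 40),
                                         substr(cr[1], 41, 47),
                                         substr(cr[1], 48, 54))))
    if (!anyNA(ang) && any(abs(ang - 90) > 1e-6))
      stop("triclinic box in '", path, "' is not supported")
    if (!anyNA(v)) box <- v / 10
  }
  list(resid = at$resno, resname = at$resid, atname = at$elety,
       x = at$x / 10, y = at$y / 10, z = at$z / 10, box = box, time = 0)
}

#' Write a frame as a GRO-dialect coordinate file
#'
#' Positions are written at GRO precision (0.001 nm), so a
#' write-then-load round trip reproduces coordinates within 1e-3 nm.
#'
#' @param frame a [MembraneFrame-class]
#' @param path output path
#' @param append append as an additional frame (multi-frame GRO)
#' @return invisibly, the path
#' @export
writeFrame <- function(frame, path, append = FALSE) {
  b <- frame@beads
  if (!nrow(b)) stop("refusing to write a frame with zero beads")
  ali <- resnameMap(frame@topology)
  res <- ali[b$species]
  lines <- c(
    sprintf("PIPNano frame t= %g", frame@time),
    sprintf("%5d", nrow(b)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            b$lipid %% 100000L, res, substr(b$bead, 1, 5),
            seq_len(nrow(b)) %% 100000L, b$x, b$y, b$z),
    sprintf("%10.5f%10.5f%10.5f", frame@box[1], frame@box[2], frame@box[3]))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
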