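#' @include AllClasses.R
NULL

## One topology entry is a plain named list; kept light because frames carry
## many of them by reference.
makeTopology <- function(species, resname, headgroup, phosphodiester,
                         chains) {
  if (!length(chains) || any(!vapply(chains, length, integer(1))))
    stop("topology '", species, "': chain lists must be non-empty")
  if (anyDuplicated(unlist(chains)))
    stop("topology '", species, "': no bead may belong to two chains")
  list(species = species, resname = resname, headgroup = headgroup,
       phosphodiester = phosphodiester, chains = chains)
}

#' Built-in Martini-style lipid topologies
#'
#' Bead-name topologies for the species in scope: POPC and three
#' PI(4,5)P2 acyl-chain variants (16:0/16:0, 18:1/18:1, 18:0/20:4).
#' Each entry records the headgroup beads, the phosphodiester bead
#' (\code{PO4}, present in every species and used as the default leaflet
#' reference), the acyl chains as ordered bead lists (glycerol-proximal
#' first), and a 5-character residue alias used in GRO/PDB files.
#'
#' @return named list of topology entries
#' @examples
#' names(defaultTopology())
#' defaultTopology()$POPC$chains
#' @export
defaultTopology <- function() {
  list(
    POPC = makeTopology("POPC", "POPC",
      headgroup = "NC3", phosphodiester = "PO4",
      chains = list(A = c("C1A", "D2A", "C3A", "C4A"),
                    B = c("C1B", "C2B", "C3B", "C4B"))),
    PIP2_160 = makeTopology("PIP2_160", "P160",
      headgroup = c("C1", "C2", "C3", "P4", "P5"), phosphodiester = "PO4",
      chains = list(A = c("C1A", "C2A", "C3A", "C4A"),
                    B = c("C1B", "C2B", "C3B", "C4B"))),
    PIP2_181 = makeTopology("PIP2_181", "P181",
      headgroup = c("C1", "C2", "C3", "P4", "P5"), phosphodiester = "PO4",
      chains = list(A = c("C1A", "D2A", "C3A", "C4A"),
                    B = c("C1B", "D2B", "C3B", "C4B"))),
    PIP2_SAPI = makeTopology("PIP2_SAPI", "PSAP",
      headgroup = c("C1", "C2", "C3", "P4", "P5"), phosphodiester = "PO4",
      chains = list(A = c("D1A", "D2A", "D3A", "D4A", "C5A"),
                    B = c("C1B", "C2B", "C3B", "C4B"))))
}

#' Read a topology map from a YAML config file
#'
#' The file maps species names to bead lists, e.g.
#' \preformatted{
#' POPC:
#'   resname: POPC
#'   headgroup: [NC3]
#'   phosphodiester: PO4
#'   chains:
#'     A: [C1A, D2A, C3A, C4A]
#'     B: [C1B, C2B, C3B, C4B]
#' }
#'
#' @param path path to the YAML file
#' @return named list of topology entries as in [defaultTopology()]
#' @export
readTopology <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(sp) {
    e <- raw[[sp]]
    makeTopology(sp,
                 resname = if (is.null(e$resname)) substr(sp, 1, 5) else e$resname,
                 headgroup = unlist(e$headgroup),
                 phosphodiester = if (is.null(e$phosphodiester)) "PO4" else e$phosphodiester,
                 chains = lapply(e$chains, unlist))
  })
  names(out) <- names(raw)
  out
}

## All bead names of a topology entry, head to tail.
topologyBeads <- function(top) {
  c(top$headgroup, top$phosphodiester, "GL1", "GL2", unlist(top$chains,
    use.names = FALSE))
}

## Bead names used for a contact/bead selection.
selectionBeads <- function(top, selection = c("headgroup", "all")) {
  selection <- match.arg(selection)
  if (selection == "headgroup") c(top$headgroup, top$phosphodiester)
  else topologyBeads(top)
}

## TRUE for species matching `species` exactly or by prefix (so "PIP2"
## selects every PI(4,5)P2 variant).
speciesMatches <- function(sp, species) {
  sp == species | startsWith(sp, paste0(species, "_")) |
    startsWith(sp, species)
}
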