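#' Construct a rigid domain specification
#'
#' @param name unique label.
#' @param beads n x 3 matrix of C-alpha coordinates (A).
#' @param nAnchor,cAnchor bead indices where the preceding (N-side) and
#'   following (C-side) linker attach; default first and last bead.
#' @return a [DomainSpec-class].
#' @export
DomainSpec <- function(name, beads, nAnchor = 1L, cAnchor = nrow(beads)) {
  new("DomainSpec", name = as.character(name), beads = as.matrix(beads),
      nAnchor = as.integer(nAnchor), cAnchor = as.integer(cAnchor))
}

#' Construct a flexible linker specification
#'
#' @param name unique label.
#' @param nResidues number of linker beads (typical cellulosomal dockerin
#'   linkers have 19).
#' @param bondLength virtual C-alpha--C-alpha bond (A), default 3.8
#'   (trans peptide).
#' @return a [LinkerSpec-class].
#' @export
LinkerSpec <- function(name, nResidues, bondLength = 3.8) {
  new("LinkerSpec", name = as.character(name), nResidues = as.integer(nResidues),
      bondLength = bondLength)
}

#' Synthetic spherical-shell domain
#'
#' Places `nBeads` beads quasi-uniformly (Fibonacci lattice) on a sphere of
#' the given radius; anchors default to the two beads closest to the -x and
#' +x poles so that consecutive domains extend away from each other when
#' linkers leave radially.
#'
#' @param name label.
#' @param radius sphere radius (A), default 15.
#' @param nBeads number of beads, default 120.
#' @return a [DomainSpec-class].
#' @export
sphericalShellDomain <- function(name, radius = 15, nBeads = 120L) {
  i <- seq_len(nBeads) - 0.5
  z <- 1 - 2 * i / nBeads
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  beads <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  DomainSpec(name, beads,
             nAnchor = which.min(beads[, 1]), cAnchor = which.max(beads[, 1]))
}

#' Read a rigid domain from a PDB file at one bead per residue
#'
#' Extracts C-alpha positions with \pkg{bio3d}. Every residue that has any
#' atom in the selected range must have a C-alpha, otherwise an error names
#' the offending residue. Residues missing entirely (sequence gaps) are
#' bridged as rigid gaps and reported with a message.
#'
#' @param name label for the domain.
#' @param file PDB file path.
#' @param chain optional chain identifier.
#' @param resRange optional length-2 integer range of residue numbers.
#' @param nAnchor,cAnchor anchor bead indices (default first/last residue).
#' @return a [DomainSpec-class].
#' @export
domainFromPDB <- function(name, file, chain = NULL, resRange = NULL,
                          nAnchor = NULL, cAnchor = NULL) {
  if (!file.exists(file)) stop("structure file not found: ", file)
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain == chain
  if (!is.null(resRange)) keep <- keep & at$resno >= resRange[1] & at$resno <= resRange[2]
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms selected from ", file)
  resnos <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing <- setdiff(resnos, ca$resno)
  if (length(missing) > 0)
    stop(sprintf("missing C-alpha in residue %d of %s", missing[1], file))
  gaps <- which(diff(resnos) > 1)
  if (length(gaps) > 0)
    message(sprintf("domain '%s': %d sequence gap(s) bridged as rigid gaps (after residue %s)",
                    name, length(gaps), paste(resnos[gaps], collapse = ", ")))
  ca <- ca[order(ca$resno), , drop = FALSE]
  beads <- as.matrix(ca[, c("x", "y", "z")])
  rownames(beads) <- NULL
  DomainSpec(name, beads,
             nAnchor = if (is.null(nAnchor)) 1L else nAnchor,
             cAnchor = if (is.null(cAnchor)) nrow(beads) else cAnchor)
}

setMethod("show", "DomainSpec", function(object) {
  cat(sprintf("DomainSpec '%s': %d beads, anchors %d/%d\n", object@name,
              nrow(object@beads), object@nAnchor, object@cAnchor))
})
setMethod("show", "LinkerSpec", function(object) {
  cat(sprintf("LinkerSpec '%s': %d residues, bond %.2f A\n", object@name,
              object@nResidues, object@bondLength))
})
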