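#' Create a Conformation from coordinates
#'
#' @param topology generating [Topology-class].
#' @param coords N x 3 coordinate matrix (A).
#' @param energy optional cached energy (kT at 300 K).
#' @return a [Conformation-class] with rg and dmax filled in.
#' @export
Conformation <- function(topology, coords, energy = NA_real_) {
  m <- conformationMetrics(coords)
  new("Conformation", coords = as.matrix(coords), topology = topology,
      rg = m[["rg"]], dmax = m[["dmax"]], energy = energy)
}

#' Radius of gyration and maximum dimension of a bead set
#'
#' Rg is the root-mean-square bead distance from the centroid with unit bead
#' weights (residue-mass weighting differs by under 2% for typical protein
#' compositions); dmax is the exhaustive maximum pairwise distance.
#'
#' @param x a [Conformation-class] or an N x 3 coordinate matrix.
#' @return named numeric vector `c(rg = , dmax = )` (A).
#' @examples
#' conformationMetrics(rbind(c(0, 0, 0), c(100, 0, 0)))  # rg 50, dmax 100
#' @export
conformationMetrics <- function(x) {
  coords <- if (is(x, "Conformation")) x@coords else as.matrix(x)
  if (nrow(coords) < 1) stop("at least one bead required")
  m <- cpp_rg_dmax(as.numeric(t(coords)), nrow(coords), 1L)
  c(rg = m[1, 1], dmax = m[1, 2])
}

#' @rdname conformationMetrics
#' @export
setGeneric("rgyr", function(x) standardGeneric("rgyr"))
#' @rdname conformationMetrics
#' @export
setGeneric("maxDim", function(x) standardGeneric("maxDim"))

setMethod("rgyr", "Conformation", function(x) x@rg)
setMethod("maxDim", "Conformation", function(x) x@dmax)
setMethod("rgyr", "GuinierResult", function(x) x@rg)
setMethod("rgyr", "PairDistribution", function(x) x@rgPr)
setMethod("maxDim", "PairDistribution", function(x) x@dmax)

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: %d beads, Rg = %.1f A, Dmax = %.1f A\n",
              nrow(object@coords), object@rg, object@dmax))
})

# squared-distance clash test used by builders (the sampler has its own)
hasClash <- function(coords, lay, clashRadius) {
  n <- nrow(coords)
  if (n < 2) return(FALSE)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (nrow(lay$bonds) > 0)
    for (i in seq_len(nrow(lay$bonds))) {
      d[lay$bonds[i, 1], lay$bonds[i, 2]] <- Inf
      d[lay$bonds[i, 2], lay$bonds[i, 1]] <- Inf
    }
  for (mem in lay$unitMembers) if (length(mem) > 1) d[mem, mem] <- Inf
  min(d) < 2 * clashRadius
}

# place one chain's segments into coords; `anchored` gives a segment index
# (within the chain) already placed. Directions leaving a domain are biased
# outward from its centroid to keep placement attempts efficient.
buildChainCoords <- function(coords, lay, ci, startPos = c(0, 0, 0), anchored = NULL) {
  segs <- which(lay$segChain == ci)
  placeDomain <- function(si, anchorBead, target) {
    b <- lay$segObj[[si]]@beads
    shift <- target - b[anchorBead, ]
    coords[lay$offset[si] + seq_len(nrow(b)), ] <<- sweep(b, 2, shift, "+")
  }
  outwardDir <- function(si, anchorGlobal) {
    mem <- lay$offset[si] + seq_len(lay$segN[si])
    ctr <- colMeans(coords[mem, , drop = FALSE])
    v <- coords[anchorGlobal, ] - ctr
    n <- sqrt(sum(v^2))
    u <- if (n > 1e-9) v / n else randUnit()
    w <- u + 0.6 * randUnit()
    w / sqrt(sum(w^2))
  }
  randUnit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  buildForward <- function(from) {
    idx <- segs[segs > from]
    for (si in idx) {
      prev <- segs[which(segs == si) - 1L]
      if (lay$segType[si] == "linker") {
        b <- lay$segObj[[si]]@bondLength
        startBead <- if (length(prev) > 0 && lay$segType[prev] == "domain") {
          anchor <- lay$anchorC[prev]
          dir <- outwardDir(prev, anchor)
          coords[anchor, ] + b * dir
        } else {
          dir <- randUnit()
          startPos
        }
        for (k in seq_len(lay$segN[si]))
          coords[lay$offset[si] + k, ] <<- startBead + (k - 1) * b * dir
      } else {
        if (length(prev) > 0 && lay$segType[prev] == "linker") {
          b <- lay$segObj[[prev]]@bondLength
          lastBead <- coords[lay$offset[prev] + lay$segN[prev], ]
          prevBead <- if (lay$segN[prev] > 1)
            coords[lay$offset[prev] + lay$segN[prev] - 1L, ]
          else lastBead - randUnit() * b
          dir <- lastBead - prevBead
          dir <- dir / sqrt(sum(dir^2))
          placeDomain(si, lay$segObj[[si]]@nAnchor, lastBead + b * dir)
        } else {
          placeDomain(si, lay$segObj[[si]]@nAnchor, startPos)
        }
      }
    }
  }
  buildBackward <- function(from) {
    idx <- rev(segs[segs < from])
    for (si in idx) {
      nxt <- segs[which(segs == si) + 1L]
      if (lay$segType[si] == "linker") {
        b <- lay$segObj[[si]]@bondLength
        anchor <- lay$anchorN[nxt]
        dir <- outwardDir(nxt, anchor)
        endBead <- coords[anchor, ] + b * dir
        for (k in seq_len(lay$segN[si]))
          coords[lay$offset[si] + k, ] <<-
            endBead + (lay$segN[si] - k) * b * dir
      } else {
        b <- lay$segObj[[nxt]]@bondLength
        firstBead <- coords[lay$offset[nxt] + 1L, ]
        secondBead <- if (lay$segN[nxt] > 1) coords[lay$offset[nxt] + 2L, ]
                      else firstBead + randUnit() * b
        dir <- firstBead - secondBead
        dir <- dir / sqrt(sum(dir^2))
        placeDomain(si, lay$segObj[[si]]@cAnchor, firstBead + b * dir)
      }
    }
  }
  if (is.null(anchored)) {
    s1 <- segs[1]
    if (lay$segType[s1] == "domain") {
      b <- lay$segObj[[s1]]@beads
      shift <- startPos - colMeans(b)
      coords[lay$offset[s1] + seq_len(nrow(b)), ] <- sweep(b, 2, shift, "+")
    } else {
      dir <- randUnit()
      bl <- lay$segObj[[s1]]@bondLength
      for (k in seq_len(lay$segN[s1]))
        coords[lay$offset[s1] + k, ] <- startPos + (k - 1) * bl * dir
    }
    buildForward(segs[1])
  } else {
    buildForward(anchored)
    buildBackward(anchored)
  }
  coords
}

#' Deterministic initial conformation of a Topology
#'
#' Linkers are laid out fully extended along randomized (outward-biased)
#' directions at exact bond-length spacing; rigid domains are placed
#' unrotated and rigidly translated to satisfy their anchors. Placement is
#' retried with fresh directions until the structure is free of hard-sphere
#' clashes. Identical seeds give bitwise-identical coordinates.
#'
#' @param topology a [Topology-class].
#' @param seed integer seed.
#' @param clashRadius bead hard-core radius (A); pairs other than bonded or
#'   same-rigid-unit pairs must be at least 2*clashRadius apart.
#' @param maxAttempts placement retries before a packing error.
#' @return a clash-free [Conformation-class].
#' @export
initialConformation <- function(topology, seed = 1L, clashRadius = 1.9,
                                maxAttempts = 10000L) {
  lay <- topologyLayout(topology)
  att <- topology@attachments
  withLocalSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      coords <- matrix(NA_real_, lay$nBeads, 3)
      placed <- logical(length(topology@chains))
      coords <- buildChainCoords(coords, lay, 1L)
      placed[1] <- TRUE
      repeat {
        todo <- NULL
        if (nrow(att) > 0) for (k in seq_len(nrow(att))) {
          ia <- which(lay$segName == att[k, 1]); ib <- which(lay$segName == att[k, 2])
          ca <- lay$segChain[ia]; cb <- lay$segChain[ib]
          if (placed[ca] && !placed[cb]) { todo <- c(ia, ib); break }
          if (placed[cb] && !placed[ca]) { todo <- c(ib, ia); break }
        }
        if (is.null(todo)) break
        ia <- todo[1]; ib <- todo[2]
        memA <- lay$offset[ia] + seq_len(lay$segN[ia])
        ctrA <- colMeans(coords[memA, , drop = FALSE])
        extA <- max(sqrt(rowSums(sweep(coords[memA, , drop = FALSE], 2, ctrA)^2)))
        bB <- lay$segObj[[ib]]@beads
        ctrB0 <- colMeans(bB)
        extB <- max(sqrt(rowSums(sweep(bB, 2, ctrB0)^2)))
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        target <- ctrA + u * (extA + extB + 2 * clashRadius)
        memB <- lay$offset[ib] + seq_len(lay$segN[ib])
        coords[memB, ] <- sweep(bB, 2, target - ctrB0, "+")
        coords <- buildChainCoords(coords, lay, lay$segChain[ib],
                                   anchored = ib)
        placed[lay$segChain[ib]] <- TRUE
      }
      # chains with no attachment to anything placed: offset sideways
      for (ci in which(!placed)) {
        span <- max(abs(coords[!is.na(coords[, 1]), ]), 0) + 50
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        coords <- buildChainCoords(coords, lay, ci, startPos = u * (2 * span))
        placed[ci] <- TRUE
      }
      if (!anyNA(coords) && !hasClash(coords, lay, clashRadius))
        return(Conformation(topology, coords))
    }
    stop("packing error: no clash-free initial conformation after ",
         maxAttempts, " attempts")
  })
}

## ------------------------------------------------------------------ pool ----

#' Number of models in a ConformationPool
#' @param pool a [ConformationPool-class].
#' @return integer count.
#' @export
poolSize <- function(pool) dim(pool@coords)[3]

#' Extract one model from a ConformationPool
#' @param pool a [ConformationPool-class].
#' @param k model index (the chi-square label k).
#' @return a [Conformation-class].
#' @export
getConformation <- function(pool, k) {
  if (k < 1 || k > poolSize(pool)) stop("model index out of range")
  Conformation(pool@topology, pool@coords[, , k],
               energy = pool@meta$energy[k])
}

setMethod("show", "ConformationPool", function(object) {
  k <- poolSize(object)
  cat(sprintf("ConformationPool: %d models, %d beads; Rg %.1f-%.1f A%s\n",
              k, dim(object@coords)[1],
              if (k) min(object@meta$rg) else NA, if (k) max(object@meta$rg) else NA,
              if (length(object@q)) sprintf("; profiles on %d q points", length(object@q)) else ""))
})

# assemble a pool from a flat coords vector in saved-frame order
makePool <- function(topology, coordsFlat, n, k, meta, provenance = list()) {
  arr <- aperm(array(coordsFlat, dim = c(3, n, k)), c(2, 1, 3))
  md <- cpp_rg_dmax(coordsFlat, n, k)
  meta$rg <- md[, 1]
  meta$dmax <- md[, 2]
  meta$k <- seq_len(k)
  new("ConformationPool", topology = topology, coords = arr, meta = meta,
      q = numeric(0), profiles = matrix(0, 0, 0), provenance = provenance)
}

#' Write a pool as multi-model PDB plus a TSV index
#'
#' One pseudo-atom `CA` per bead; the PDB MODEL number is the pool index k.
#' The index file has columns k, replica, sweep, energy, rg, dmax.
#'
#' @param pool a [ConformationPool-class].
#' @param pdbPath,indexPath output paths.
#' @return invisibly, `pdbPath`.
#' @export
writePool <- function(pool, pdbPath, indexPath = sub("\\.pdb$", ".tsv", pdbPath)) {
  lay <- topologyLayout(pool@topology)
  chainLetter <- LETTERS[(lay$segChain[lay$segId] - 1L) %% 26 + 1L]
  con <- file(pdbPath, "w")
  on.exit(close(con))
  n <- lay$nBeads
  for (k in seq_len(poolSize(pool))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    x <- pool@coords[, , k]
    writeLines(sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       seq_len(n), chainLetter, seq_len(n),
                       x[, 1], x[, 2], x[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  utils::write.table(pool@meta[, c("k", "replica", "sweep", "energy", "rg", "dmax")],
                     indexPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(pdbPath)
}

#' Read a pool written by [writePool()]
#'
#' @param topology the generating [Topology-class] (needed to re-attach the
#'   bead bookkeeping).
#' @param pdbPath,indexPath input paths.
#' @return a [ConformationPool-class] (profiles not restored).
#' @export
readPool <- function(topology, pdbPath, indexPath = sub("\\.pdb$", ".tsv", pdbPath)) {
  pdb <- bio3d::read.pdb(pdbPath, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n <- ncol(xyz) / 3
  k <- nrow(xyz)
  flat <- as.numeric(t(xyz))   # frame-major, xyz per bead
  meta <- utils::read.table(indexPath, header = TRUE, sep = "\t")
  makePool(topology, flat, n, k,
           meta[, c("replica", "sweep", "energy")],
           provenance = list(source = pdbPath))
}
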