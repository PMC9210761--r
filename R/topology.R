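#' Build a Topology from chains of domains and linkers
#'
#' @param chains a single chain (list of [DomainSpec-class] /
#'   [LinkerSpec-class] in N-to-C order) or a list of such chains.
#' @param attachments optional 2-column matrix/data.frame of domain-name
#'   pairs from different chains to be held as one rigid unit
#'   (cohesin--dockerin style).
#' @return a validated [Topology-class].
#' @examples
#' d1 <- sphericalShellDomain("D1", radius = 10, nBeads = 40)
#' d2 <- sphericalShellDomain("D2", radius = 10, nBeads = 40)
#' topo <- buildTopology(list(d1, LinkerSpec("L1", 19), d2))
#' mobileDof(topo)
#' @export
buildTopology <- function(chains, attachments = NULL) {
  if (length(chains) > 0 && (is(chains[[1]], "DomainSpec") || is(chains[[1]], "LinkerSpec")))
    chains <- list(chains)
  att <- if (is.null(attachments)) {
    matrix(character(0), 0, 2, dimnames = list(NULL, c("a", "b")))
  } else {
    m <- as.matrix(attachments)
    dimnames(m) <- list(NULL, c("a", "b"))
    m
  }
  # explicit check so the error names the missing domain before validity runs
  domNames <- unlist(lapply(chains, function(ch)
    vapply(Filter(function(s) is(s, "DomainSpec"), ch), function(s) s@name, character(1))))
  for (nm in c(att)) if (!(nm %in% domNames))
    stop("attachment or linker references undefined domain '", nm, "'")
  new("Topology", chains = chains, attachments = att)
}

#' Parse a plain-text topology configuration
#'
#' Recognized directives (one per line, `#` comments allowed):
#' \preformatted{
#' CHAIN
#' DOMAIN name file [chain] [first-last]
#' DOMAIN name sphere:radius:nbeads
#' LINKER name n_residues
#' ATTACH domA domB
#' }
#' `CHAIN` starts a new chain; `DOMAIN` lines may reference a PDB file
#' (relative paths resolved against the config location) or a synthetic
#' spherical-shell directive.
#'
#' @param path config file path.
#' @return a [Topology-class].
#' @export
readTopologyConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  dir <- dirname(path)
  lines <- readLines(path, warn = FALSE)
  chains <- list()
  cur <- list()
  att <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    kw <- toupper(tok[1])
    if (kw == "CHAIN") {
      if (length(cur) > 0) chains[[length(chains) + 1L]] <- cur
      cur <- list()
    } else if (kw == "DOMAIN") {
      if (length(tok) < 3) stop("DOMAIN needs a name and a source: ", ln)
      nm <- tok[2]; src <- tok[3]
      if (grepl("^sphere:", src)) {
        pp <- strsplit(src, ":")[[1]]
        if (length(pp) != 3) stop("synthetic domain directive must be sphere:radius:nbeads")
        dom <- sphericalShellDomain(nm, radius = as.numeric(pp[2]),
                                    nBeads = as.integer(pp[3]))
      } else {
        f <- if (file.exists(src)) src else file.path(dir, src)
        ch <- if (length(tok) >= 4 && !grepl("-", tok[4])) tok[4] else NULL
        rng <- NULL
        for (t in tok[-(1:3)]) if (grepl("^[0-9]+-[0-9]+$", t))
          rng <- as.integer(strsplit(t, "-")[[1]])
        dom <- domainFromPDB(nm, f, chain = ch, resRange = rng)
      }
      cur[[length(cur) + 1L]] <- dom
    } else if (kw == "LINKER") {
      if (length(tok) < 3) stop("LINKER needs a name and a residue count: ", ln)
      cur[[length(cur) + 1L]] <- LinkerSpec(tok[2], as.integer(tok[3]))
    } else if (kw == "ATTACH") {
      if (length(tok) < 3) stop("ATTACH needs two domain names: ", ln)
      att <- rbind(att, tok[2:3])
    } else stop("unknown topology directive: ", tok[1])
  }
  if (length(cur) > 0) chains[[length(chains) + 1L]] <- cur
  buildTopology(chains, attachments = att)
}

# Derived layout shared by the sampler, builders and validity checks:
# global bead bookkeeping, bonded term lists (bonds/angles/torsions over
# linker degrees of freedom), rigid units (attachment-merged domains),
# and the precomputed Monte Carlo move sets.
topologyLayout <- function(topo) {
  chains <- topo@chains
  segType <- character(0); segName <- character(0); segChain <- integer(0)
  segObj <- list()
  for (ci in seq_along(chains)) for (s in chains[[ci]]) {
    segType <- c(segType, if (is(s, "DomainSpec")) "domain" else "linker")
    segName <- c(segName, s@name)
    segChain <- c(segChain, ci)
    segObj[[length(segObj) + 1L]] <- s
  }
  nSeg <- length(segObj)
  segN <- vapply(seq_len(nSeg), function(i)
    if (segType[i] == "domain") nrow(segObj[[i]]@beads) else segObj[[i]]@nResidues,
    integer(1))
  offset <- cumsum(c(0L, segN))[seq_len(nSeg)]
  nBeads <- sum(segN)
  beadSeg <- rep(seq_len(nSeg), segN)
  isLinker <- segType[beadSeg] == "linker"

  # rigid units: one per domain, merged by attachments (union-find)
  uf <- seq_len(nSeg)
  if (nrow(topo@attachments) > 0)
    for (k in seq_len(nrow(topo@attachments))) {
      ia <- which(segName == topo@attachments[k, 1])
      ib <- which(segName == topo@attachments[k, 2])
      ra <- ia; while (uf[ra] != ra) ra <- uf[ra]
      rb <- ib; while (uf[rb] != rb) rb <- uf[rb]
      uf[rb] <- ra
    }
  segUnit <- integer(nSeg)
  roots <- unique(vapply(which(segType == "domain"), function(i) {
    r <- i; while (uf[r] != r) r <- uf[r]; r
  }, integer(1)))
  for (i in which(segType == "domain")) {
    r <- i; while (uf[r] != r) r <- uf[r]
    segUnit[i] <- match(r, roots)
  }
  beadUnit <- ifelse(isLinker, 0L, segUnit[beadSeg])

  anchorN <- function(si) offset[si] + segObj[[si]]@nAnchor
  anchorC <- function(si) offset[si] + segObj[[si]]@cAnchor

  # bonds + bending/torsion paths: per linker, the bead path is
  # [C-anchor of preceding domain] + linker beads + [N-anchor of next domain]
  bonds <- NULL; angles <- NULL; torsions <- NULL
  linkerOfTerm <- list(bond = integer(0), angle = integer(0), torsion = integer(0))
  for (si in which(segType == "linker")) {
    lb <- offset[si] + seq_len(segN[si])
    path <- lb
    ci <- segChain[si]
    pos <- which(vapply(chains[[ci]], function(s) s@name, character(1)) == segName[si])
    segsInChain <- which(segChain == ci)
    if (pos > 1) path <- c(anchorC(segsInChain[pos - 1L]), path)
    if (pos < length(segsInChain)) path <- c(path, anchorN(segsInChain[pos + 1L]))
    if (length(path) >= 2)
      bonds <- rbind(bonds, cbind(path[-length(path)], path[-1]))
    if (length(path) >= 3)
      angles <- rbind(angles, cbind(path[1:(length(path) - 2)],
                                    path[2:(length(path) - 1)],
                                    path[3:length(path)]))
    if (length(path) >= 4)
      torsions <- rbind(torsions, cbind(path[1:(length(path) - 3)],
                                        path[2:(length(path) - 2)],
                                        path[3:(length(path) - 1)],
                                        path[4:length(path)]))
  }
  if (is.null(bonds)) bonds <- matrix(0L, 0, 2)
  if (is.null(angles)) angles <- matrix(0L, 0, 3)
  if (is.null(torsions)) torsions <- matrix(0L, 0, 4)
  mobileDof <- nrow(bonds) + nrow(angles) + nrow(torsions)

  # connectivity graph: backbone bonds + star edges inside each rigid unit
  adj <- vector("list", nBeads)
  addEdge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  if (nrow(bonds) > 0) for (i in seq_len(nrow(bonds))) addEdge(bonds[i, 1], bonds[i, 2])
  unitMembers <- list()
  nUnits <- max(c(0L, beadUnit))
  for (u in seq_len(nUnits)) {
    mem <- which(beadUnit == u)
    unitMembers[[u]] <- mem
    if (length(mem) > 1) for (m in mem[-1]) addEdge(mem[1], m)
  }

  compOf <- integer(nBeads)
  comp <- 0L
  for (s0 in seq_len(nBeads)) if (compOf[s0] == 0L) {
    comp <- comp + 1L
    queue <- s0; compOf[s0] <- comp
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (compOf[w] == 0L) { compOf[w] <- comp; queue <- c(queue, w) }
    }
  }
  components <- split(seq_len(nBeads), compOf)
  names(components) <- NULL

  # pivot moves: cut a backbone bond at a linker-bead end, rotate the far side
  pivotCenter <- integer(0)
  pivotMoved <- list()
  if (nrow(bonds) > 0) for (i in seq_len(nrow(bonds))) {
    for (e in 1:2) {
      ctr <- bonds[i, e]; other <- bonds[i, 3 - e]
      if (!isLinker[ctr]) next
      # component of `other` with this edge removed
      seen <- logical(nBeads)
      seen[other] <- TRUE
      queue <- other
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if ((v == other && w == ctr) || (v == ctr && w == other)) next
          if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
        }
      }
      if (seen[ctr]) next                       # cycle: pivot impossible
      pivotCenter <- c(pivotCenter, ctr)
      pivotMoved[[length(pivotMoved) + 1L]] <- which(seen)
    }
  }

  deg <- lengths(adj)
  crank <- NULL
  for (j in which(isLinker & deg == 2)) {
    nb <- adj[[j]]
    crank <- rbind(crank, c(j, nb[1], nb[2]))
  }
  if (is.null(crank)) crank <- matrix(0L, 0, 3)

  list(nBeads = nBeads, segId = beadSeg, unitId = beadUnit, isLinker = isLinker,
       segType = segType, segName = segName, segChain = segChain,
       segObj = segObj, segN = segN, offset = offset,
       bonds = bonds, angles = angles, torsions = torsions,
       mobileDof = as.integer(mobileDof),
       pivotCenter = as.integer(pivotCenter), pivotMoved = pivotMoved,
       crank = crank, displBeads = as.integer(which(isLinker)),
       components = components, unitMembers = unitMembers,
       anchorN = vapply(seq_len(nSeg), function(i)
         if (segType[i] == "domain") anchorN(i) else NA_integer_, integer(1)),
       anchorC = vapply(seq_len(nSeg), function(i)
         if (segType[i] == "domain") anchorC(i) else NA_integer_, integer(1)))
}

#' Number of flexible degrees of freedom of a Topology
#'
#' Counts the bond, bending-angle and torsion terms associated with the
#' flexible linkers (rigid bodies contribute no internal dof).
#' @param topology a [Topology-class].
#' @return integer count.
#' @export
mobileDof <- function(topology) topologyLayout(topology)$mobileDof

#' Total number of beads in a Topology
#' @param topology a [Topology-class].
#' @return integer count.
#' @export
nBeads <- function(topology) topologyLayout(topology)$nBeads

setMethod("show", "Topology", function(object) {
  lay <- topologyLayout(object)
  cat(sprintf("Topology: %d chain(s), %d beads, %d rigid unit(s), %d mobile dof\n",
              length(object@chains), lay$nBeads, length(lay$unitMembers),
              lay$mobileDof))
})
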