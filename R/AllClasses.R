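#' @import methods
#' @importFrom stats approx integrate optim rnorm runif sd setNames
#' @importFrom utils head read.table tail
#' @useDynLib flexsaxs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------- curves ----

#' ScatteringCurve: a measured or simulated SAXS profile
#'
#' Container for a one-dimensional SAXS curve: the momentum-transfer grid
#' q = 4*pi/lambda * sin(theta) (2*theta being the scattering angle), the
#' scattered intensity I(q) in arbitrary units, and the per-point statistical
#' error sigma(q) in the same units. q is stored internally in 1/Angstrom.
#'
#' @slot q numeric, strictly increasing, non-negative momentum transfer (1/A).
#' @slot intensity numeric, I(q), same length as `q`.
#' @slot sigma numeric, strictly positive errors, same length as `q`.
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric"),
  validity = function(object) {
    n <- length(object@q)
    if (length(object@intensity) != n || length(object@sigma) != n)
      return("q, intensity and sigma must have equal length")
    if (n > 0) {
      if (any(object@q < 0)) return("q must be non-negative")
      if (n > 1 && any(diff(object@q) <= 0)) return("q must be strictly increasing")
      if (any(object@sigma <= 0)) return("sigma must be strictly positive")
      if (any(!is.finite(object@q)) || any(!is.finite(object@intensity)) ||
          any(!is.finite(object@sigma)))
        return("non-finite values in curve")
    }
    TRUE
  }
)

#' GuinierResult: outcome of a Guinier fit
#'
#' @slot rg radius of gyration (A).
#' @slot i0 forward scattering I(0) (intensity units).
#' @slot fitRange integer pair, first and last point index of the fit window.
#' @slot qmaxRg dimensionless product q_last * Rg.
#' @slot residualSd standard deviation of the ln-space fit residuals.
#' @export
setClass("GuinierResult",
  representation(rg = "numeric", i0 = "numeric", fitRange = "integer",
                 qmaxRg = "numeric", residualSd = "numeric"),
  validity = function(object) {
    if (object@rg < 0) return("rg must be >= 0")
    if (object@i0 <= 0) return("i0 must be > 0")
    if (length(object@fitRange) != 2) return("fitRange must be an index pair")
    if (diff(object@fitRange) + 1 < 10) return("fit window must contain >= 10 points")
    TRUE
  }
)

#' PairDistribution: P(r) from an indirect Fourier transform
#'
#' @slot r uniform distance grid from 0 to dmax (A).
#' @slot p P(r) values (arbitrary units); zero at both boundaries.
#' @slot dmax maximum particle dimension (A).
#' @slot rgPr real-space radius of gyration derived from P(r) (A).
#' @slot i0Pr forward scattering implied by P(r): 4*pi * integral P dr.
#' @slot alpha smoothness-regularization weight actually used.
#' @slot chi2 per-point data-fit chi-square of the regularized solution.
#' @export
setClass("PairDistribution",
  representation(r = "numeric", p = "numeric", dmax = "numeric",
                 rgPr = "numeric", i0Pr = "numeric", alpha = "numeric",
                 chi2 = "numeric"),
  validity = function(object) {
    n <- length(object@r)
    if (length(object@p) != n) return("r and p must have equal length")
    if (n < 3) return("grid too small")
    if (abs(object@p[1]) > 1e-12 || abs(object@p[n]) > 1e-12)
      return("P must vanish at r = 0 and r = dmax")
    dr <- diff(object@r)
    if (max(abs(dr - dr[1])) > 1e-8 * dr[1]) return("r grid must be uniform")
    if (object@rgPr < 0) return("rgPr must be >= 0")
    TRUE
  }
)

## --------------------------------------------------------------- cg model ----

#' DomainSpec: a rigid folded domain at one bead per residue
#'
#' Beads are C-alpha positions; internal pairwise distances are immutable
#' (rigid-body contract enforced by the sampler and checked on conformations).
#'
#' @slot name label.
#' @slot beads numeric matrix (n x 3) of bead coordinates (A).
#' @slot nAnchor,cAnchor bead indices where the preceding/following linker
#'   attaches.
#' @export
setClass("DomainSpec",
  representation(name = "character", beads = "matrix",
                 nAnchor = "integer", cAnchor = "integer"),
  validity = function(object) {
    b <- object@beads
    if (!is.numeric(b) || ncol(b) != 3) return("beads must be an n x 3 numeric matrix")
    if (nrow(b) < 3) return("a domain needs >= 3 beads")
    d <- stats::dist(b)
    if (min(d) < 2.0) return("beads closer than 2.0 A inside a domain")
    if (object@nAnchor < 1 || object@nAnchor > nrow(b) ||
        object@cAnchor < 1 || object@cAnchor > nrow(b))
      return("anchor index out of range")
    TRUE
  }
)

#' LinkerSpec: a flexible linker of amino-acid beads
#'
#' @slot name label.
#' @slot nResidues number of linker beads (e.g. 19 for typical dockerin
#'   linkers).
#' @slot bondLength virtual C-alpha--C-alpha bond length (A), default 3.8.
#' @export
setClass("LinkerSpec",
  representation(name = "character", nResidues = "integer",
                 bondLength = "numeric"),
  validity = function(object) {
    if (object@nResidues < 1) return("nResidues must be >= 1")
    if (object@bondLength < 3.6 || object@bondLength > 4.0)
      return("bondLength must lie in [3.6, 4.0] A")
    TRUE
  }
)

#' Topology: domains and linkers forming one or more chains
#'
#' Within a chain, segments strictly alternate between rigid domains and
#' flexible linkers. Domains of *different* chains may be fused into one
#' rigid unit through `attachments` (cohesin--dockerin style complexes).
#'
#' @slot chains list of chains; each chain is a list of [DomainSpec-class] /
#'   [LinkerSpec-class] objects in N-to-C order.
#' @slot attachments character matrix with columns `a`, `b` naming pairs of
#'   domains (from different chains) held as one rigid unit.
#' @export
setClass("Topology",
  representation(chains = "list", attachments = "matrix"),
  validity = function(object) {
    segNames <- character(0)
    domChain <- character(0)
    for (ci in seq_along(object@chains)) {
      ch <- object@chains[[ci]]
      if (length(ch) == 0) return("empty chain")
      types <- vapply(ch, function(s) class(s)[1], character(1))
      if (!all(types %in% c("DomainSpec", "LinkerSpec")))
        return("chain segments must be DomainSpec or LinkerSpec")
      if (length(types) > 1 && any(types[-1] == types[-length(types)]))
        return("segments within a chain must alternate domain/linker")
      nm <- vapply(ch, function(s) s@name, character(1))
      segNames <- c(segNames, nm)
      domChain <- c(domChain, setNames(rep(as.character(ci), sum(types == "DomainSpec")),
                                       nm[types == "DomainSpec"]))
    }
    if (anyDuplicated(segNames)) return("segment names must be unique")
    att <- object@attachments
    if (nrow(att) > 0) {
      for (i in seq_len(nrow(att))) {
        a <- att[i, 1]; b <- att[i, 2]
        if (!(a %in% names(domChain))) return(sprintf("attachment references unknown domain '%s'", a))
        if (!(b %in% names(domChain))) return(sprintf("attachment references unknown domain '%s'", b))
        if (domChain[[a]] == domChain[[b]])
          return("rigid attachment must join domains of different chains")
      }
    }
    TRUE
  }
)

#' Conformation: one full-coordinate realization of a Topology
#'
#' @slot coords numeric matrix (N x 3) of all bead coordinates (A).
#' @slot topology the generating [Topology-class].
#' @slot rg radius of gyration (A, unit bead weights).
#' @slot dmax maximum pairwise bead distance (A).
#' @slot energy cached energy in kT at 300 K (NA when not evaluated).
#' @export
setClass("Conformation",
  representation(coords = "matrix", topology = "Topology",
                 rg = "numeric", dmax = "numeric", energy = "numeric"),
  validity = function(object) {
    lay <- topologyLayout(object@topology)
    if (nrow(object@coords) != lay$nBeads)
      return("coordinate count does not match topology")
    if (ncol(object@coords) != 3) return("coords must be N x 3")
    TRUE
  }
)

#' ConformationPool: indexed set of saved conformations
#'
#' The pool index k is stable and is the model label entering the chi-square
#' comparison against experimental curves. Coordinates are stored as a dense
#' N x 3 x K array; per-model scattering profiles can be cached with
#' [poolProfiles()].
#'
#' @slot topology generating [Topology-class].
#' @slot coords numeric array N x 3 x K.
#' @slot meta data.frame with one row per model: k, replica, sweep, energy,
#'   rg, dmax.
#' @slot q q grid of cached profiles (empty until computed).
#' @slot profiles matrix (length(q) x K) of model intensities I_k(q).
#' @slot provenance list describing how the pool was generated.
#' @export
setClass("ConformationPool",
  representation(topology = "Topology", coords = "array", meta = "data.frame",
                 q = "numeric", profiles = "matrix", provenance = "list"),
  validity = function(object) {
    k <- dim(object@coords)[3]
    if (nrow(object@meta) != k) return("meta rows must match number of models")
    if (length(object@q) > 0 &&
        (nrow(object@profiles) != length(object@q) || ncol(object@profiles) != k))
      return("profiles must be length(q) x nModels")
    TRUE
  }
)

## ---------------------------------------------------------------- sampler ----

#' EnergyModel: coarse-grained potential for flexible linkers
#'
#' Harmonic stretching and bending, a cosine torsion series, and a hard-core
#' excluded volume. Energies are in units of kT at the 300 K reference
#' temperature.
#'
#' @slot kStretch harmonic bond constant (kT/A^2).
#' @slot r0 equilibrium virtual bond length (A).
#' @slot kBend harmonic angle constant (kT/rad^2).
#' @slot theta0 equilibrium virtual bond angle (rad).
#' @slot torsionC,torsionPhase,torsionN cosine-series coefficients (kT),
#'   phases (rad) and multiplicities: sum_n c_n (1 + cos(n*phi - phi_n)).
#' @slot hardRadius bead excluded-volume radius (A); any non-bonded pair of
#'   beads not in the same rigid unit closer than 2*hardRadius is rejected.
#' @slot kAttract optional harmonic attraction between rigid-unit centroids
#'   (kT/A^2); 0 in normal sampling, used for biased compaction.
#' @export
setClass("EnergyModel",
  representation(kStretch = "numeric", r0 = "numeric", kBend = "numeric",
                 theta0 = "numeric", torsionC = "numeric",
                 torsionPhase = "numeric", torsionN = "integer",
                 hardRadius = "numeric", kAttract = "numeric"),
  validity = function(object) {
    if (object@kStretch < 0 || object@kBend < 0 || any(object@torsionC < 0) ||
        object@kAttract < 0)
      return("force constants must be >= 0")
    if (object@hardRadius <= 0) return("hardRadius must be > 0")
    nt <- length(object@torsionC)
    if (length(object@torsionPhase) != nt || length(object@torsionN) != nt)
      return("torsion coefficient/phase/multiplicity lengths differ")
    TRUE
  }
)

#' ReplicaLadder: replica-exchange temperature ladder
#'
#' @slot temperatures strictly increasing temperatures (K); the default is 20
#'   temperatures spanning 300--500 K geometrically.
#' @slot betas reduced inverse temperatures 300/T (energies are in kT at the
#'   300 K reference).
#' @export
setClass("ReplicaLadder",
  representation(temperatures = "numeric", betas = "numeric"),
  validity = function(object) {
    t <- object@temperatures
    if (length(t) < 1) return("at least one temperature required")
    if (any(t <= 0)) return("temperatures must be positive")
    if (length(t) > 1 && any(diff(t) <= 0)) return("temperatures must be strictly increasing")
    if (length(object@betas) != length(t)) return("betas must match temperatures")
    TRUE
  }
)

#' SamplerConfig: Monte Carlo schedule and move amplitudes
#'
#' @slot nSweeps MC sweeps per replica (one sweep = one attempted move per
#'   mobile degree of freedom).
#' @slot saveEvery sweep interval between saved structures.
#' @slot exchangeEvery sweeps between replica-exchange attempts.
#' @slot seed master integer seed.
#' @slot pivotMax,crankMax maximum pivot/crankshaft rotation (rad).
#' @slot displMax maximum single-bead displacement per axis (A).
#' @slot rigidRotMax,rigidTransMax whole-body rotation (rad) / translation (A)
#'   amplitudes.
#' @export
setClass("SamplerConfig",
  representation(nSweeps = "numeric", saveEvery = "numeric",
                 exchangeEvery = "numeric", seed = "integer",
                 pivotMax = "numeric", crankMax = "numeric",
                 displMax = "numeric", rigidRotMax = "numeric",
                 rigidTransMax = "numeric"),
  validity = function(object) {
    if (object@saveEvery < 1) return("saveEvery must be >= 1")
    if (object@nSweeps < 1) return("nSweeps must be >= 1")
    if (object@nSweeps %% object@saveEvery != 0)
      return("nSweeps must be divisible by saveEvery")
    if (object@exchangeEvery < 1) return("exchangeEvery must be >= 1")
    TRUE
  }
)

## ---------------------------------------------------------------- fitting ----

#' FormFactorTable: per-residue effective scattering amplitudes
#'
#' Either a single constant amplitude for every bead (default; the free scale
#' factor of the chi-square fit absorbs the overall amplitude) or a
#' q-dependent amplitude shared by all beads, optionally modulated per bead.
#'
#' @slot perBead numeric amplitude per bead (recycled to length 1 for a
#'   global constant).
#' @slot qShape optional function of q giving a common q-dependent amplitude
#'   factor f(q) with f(0) > 0; identity when NULL.
#' @export
setClass("FormFactorTable",
  representation(perBead = "numeric", qShape = "ANY"),
  validity = function(object) {
    if (any(object@perBead <= 0)) return("amplitudes must be positive")
    if (!is.null(object@qShape) && !is.function(object@qShape))
      return("qShape must be NULL or a function of q")
    TRUE
  }
)

#' FitResult: chi-square fit of model intensities against a curve
#'
#' @slot chi2 reduced chi-square (sum divided by the number of data points).
#' @slot a fitted scale factor.
#' @slot b fitted offset (intensity units; absorbs buffer-subtraction
#'   uncertainty).
#' @slot members model indices of the (possibly single-member) ensemble.
#' @slot weights statistical weights of the members, summing to 1.
#' @export
setClass("FitResult",
  representation(chi2 = "numeric", a = "numeric", b = "numeric",
                 members = "integer", weights = "numeric"),
  validity = function(object) {
    if (object@chi2 < -1e-9) return("chi2 must be >= 0")
    if (length(object@members) != length(object@weights))
      return("members and weights must have equal length")
    if (anyDuplicated(object@members)) return("members must be distinct")
    if (length(object@weights) > 0) {
      if (any(object@weights <= 0)) return("weights must be > 0")
      if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
    }
    TRUE
  }
)

## -------------------------------------------------------------- synthetic ----

#' SyntheticSystem: ground-truth two-state system for validation
#'
#' @slot topology shared [Topology-class] of the reference states.
#' @slot states named list of reference [Conformation-class] objects
#'   (canonically "compact" and "extended").
#' @slot weights true mixture weights (same names, summing to 1).
#' @slot noiseFrac relative Gaussian noise level applied by [simulateCurve()].
#' @slot seed integer master seed the system was built from.
#' @export
setClass("SyntheticSystem",
  representation(topology = "Topology", states = "list", weights = "numeric",
                 noiseFrac = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@states) < 1) return("at least one reference state")
    if (length(object@weights) != length(object@states))
      return("weights must match states")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
      return("weights must be non-negative and sum to 1")
    if (object@noiseFrac < 0) return("noiseFrac must be >= 0")
    ok <- vapply(object@states, function(s) is(s, "Conformation"), logical(1))
    if (!all(ok)) return("states must be Conformation objects")
    TRUE
  }
)
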