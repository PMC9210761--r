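#' Coarse-grained energy model
#'
#' Defaults follow common serial virtual-bond statistics for disordered
#' protein linkers: a stiff virtual C-alpha bond at 3.8 A, a soft bending
#' preference around 2.12 rad, a single weak torsion term, and a hard core
#' of radius 1.9 A. Energies are expressed in kT at 300 K; the sampler's
#' reduced inverse temperature is 300/T.
#'
#' @param kStretch bond constant (kT/A^2), default 100.
#' @param r0 equilibrium bond length (A), default 3.8.
#' @param kBend angle constant (kT/rad^2), default 2.
#' @param theta0 equilibrium angle (rad), default 2.12.
#' @param torsionC,torsionPhase,torsionN torsion series c_n (1 + cos(n*phi -
#'   phi_n)); the default single term (c = 0.5 kT, phase = pi) has its
#'   minimum at the compact cis rotamer, so heating expands the chain.
#' @param hardRadius excluded-volume radius (A), default 1.9; any pair of
#'   beads that is neither bonded nor inside one rigid unit must stay
#'   further apart than 2*hardRadius, else the energy is +Inf.
#' @param kAttract optional rigid-unit centroid pair attraction (kT/A^2),
#'   used only for biased compaction; default 0.
#' @return an [EnergyModel-class].
#' @export
EnergyModel <- function(kStretch = 100, r0 = 3.8, kBend = 2, theta0 = 2.12,
                        torsionC = 0.5, torsionPhase = pi, torsionN = 1L,
                        hardRadius = 1.9, kAttract = 0) {
  new("EnergyModel", kStretch = kStretch, r0 = r0, kBend = kBend,
      theta0 = theta0, torsionC = torsionC, torsionPhase = torsionPhase,
      torsionN = as.integer(torsionN), hardRadius = hardRadius,
      kAttract = kAttract)
}

#' Replica-exchange temperature ladder
#'
#' @param temperatures explicit temperatures (K); if NULL, `n` temperatures
#'   spanning `tmin`--`tmax` geometrically (equal beta ratios). The default
#'   reproduces the 20-replica 300--500 K ladder used for cellulosomal
#'   systems.
#' @param n,tmin,tmax ladder size and range.
#' @return a [ReplicaLadder-class] with reduced betas 300/T.
#' @export
ReplicaLadder <- function(temperatures = NULL, n = 20L, tmin = 300, tmax = 500) {
  if (is.null(temperatures))
    temperatures <- tmin * (tmax / tmin)^(seq(0, 1, length.out = n))
  new("ReplicaLadder", temperatures = temperatures, betas = 300 / temperatures)
}

#' Monte Carlo schedule and move amplitudes
#'
#' @param nSweeps sweeps per replica; must be divisible by `saveEvery`.
#' @param saveEvery sweep interval between saved structures.
#' @param seed master seed (every stream is derived from it).
#' @param exchangeEvery sweeps between replica-swap rounds (alternating
#'   even/odd adjacent pairs), default 10.
#' @param pivotMax,crankMax,displMax,rigidRotMax,rigidTransMax fixed move
#'   amplitudes (rad, rad, A, rad, A).
#' @return a [SamplerConfig-class].
#' @export
SamplerConfig <- function(nSweeps, saveEvery, seed = 1L, exchangeEvery = 10L,
                          pivotMax = 0.5, crankMax = 1.2, displMax = 0.3,
                          rigidRotMax = 0.3, rigidTransMax = 2.0) {
  new("SamplerConfig", nSweeps = as.numeric(nSweeps),
      saveEvery = as.numeric(saveEvery), exchangeEvery = as.numeric(exchangeEvery),
      seed = as.integer(seed), pivotMax = pivotMax, crankMax = crankMax,
      displMax = displMax, rigidRotMax = rigidRotMax,
      rigidTransMax = rigidTransMax)
}

setMethod("show", "ReplicaLadder", function(object) {
  cat(sprintf("ReplicaLadder: %d temperatures, %.0f-%.0f K\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures)))
})
setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf("SamplerConfig: %g sweeps, save every %g, exchange every %g, seed %d\n",
              object@nSweeps, object@saveEvery, object@exchangeEvery, object@seed))
})

# marshal an EnergyModel for the C++ engine
eparList <- function(model) {
  list(ks = model@kStretch, r0 = model@r0, kb = model@kBend, th0 = model@theta0,
       tc = model@torsionC, tphi = model@torsionPhase, tn = model@torsionN,
       hardRadius = model@hardRadius, kattr = model@kAttract)
}

layoutList <- function(lay) {
  list(segId = as.integer(lay$segId), unitId = as.integer(lay$unitId),
       bonds = lay$bonds, angles = lay$angles, torsions = lay$torsions,
       pivotCenter = lay$pivotCenter, pivotMoved = lay$pivotMoved,
       crank = lay$crank, displBeads = lay$displBeads,
       components = lay$components, unitMembers = lay$unitMembers,
       mobileDof = lay$mobileDof)
}

ampsList <- function(config) {
  list(displ = config@displMax, pivot = config@pivotMax, crank = config@crankMax,
       rigidRot = config@rigidRotMax, rigidTrans = config@rigidTransMax)
}

#' Total coarse-grained energy of a conformation
#'
#' Sums harmonic stretching over linker bonds, harmonic bending and the
#' torsion series over linker angles/dihedrals, and returns +Inf (a value,
#' not an error) when any hard-core pair overlaps.
#'
#' @param conf a [Conformation-class].
#' @param model an [EnergyModel-class].
#' @return energy in kT at 300 K (possibly `Inf`).
#' @export
calcEnergy <- function(conf, model = EnergyModel()) {
  lay <- topologyLayout(conf@topology)
  cpp_full_energy(conf@coords, layoutList(lay), eparList(model))
}

#' Run Metropolis Monte Carlo sweeps on a single conformation
#'
#' One sweep attempts one move per mobile degree of freedom, drawing from
#' the move menu (single-bead displacement, pivot of the downstream segment
#' about a linker bead, crankshaft of interior linker beads, whole-body
#' rigid moves). Each move is accepted with probability
#' min(1, exp(-beta * dE)).
#'
#' @param conf starting [Conformation-class] (finite energy required).
#' @param model an [EnergyModel-class].
#' @param nSweeps number of sweeps.
#' @param beta reduced inverse temperature (300 K reference; beta = 300/T).
#' @param seed integer seed.
#' @param saveEvery save a frame every this many sweeps (0 = none).
#' @param config a [SamplerConfig-class] supplying move amplitudes.
#' @return list with `conformation` (updated), `acceptance` (data.frame of
#'   attempts/accepts per move type), `energy` (final), and when frames were
#'   saved, `frames` (N x 3 x nSaved array) and `energies`.
#' @export
mcSweeps <- function(conf, model = EnergyModel(), nSweeps = 1L, beta = 1,
                     seed = 1L, saveEvery = 0L,
                     config = SamplerConfig(nSweeps = 1, saveEvery = 1)) {
  lay <- topologyLayout(conf@topology)
  se <- if (saveEvery > 0) saveEvery else nSweeps
  if (nSweeps %% se != 0) stop("nSweeps must be divisible by saveEvery")
  res <- cpp_remc(conf@coords, layoutList(lay), eparList(model), beta,
                  nSweeps, se, 0, ampsList(config), subSeed(seed, 0))
  n <- lay$nBeads
  newCoords <- res$finalCoords[, 1:3, drop = FALSE]
  acc <- data.frame(move = c("displacement", "pivot", "crankshaft", "rigid"),
                    attempts = as.integer(res$moveAtt),
                    accepts = as.integer(res$moveAcc))
  out <- list(conformation = Conformation(conf@topology, newCoords,
                                          energy = res$finalEnergy[1]),
              acceptance = acc, energy = res$finalEnergy[1])
  if (saveEvery > 0) {
    k <- length(res$energy)
    out$frames <- aperm(array(res$coords, dim = c(3, n, k)), c(2, 1, 3))
    out$energies <- res$energy
  }
  out
}

#' Closed-form saved-model count of a sampling schedule
#'
#' @param nReplicas number of replicas.
#' @param nSweeps MC sweeps per replica.
#' @param saveEvery saving interval in sweeps.
#' @return number of saved models, nReplicas * nSweeps / saveEvery. The
#'   canonical production schedule (20 replicas, 1e7 sweeps, save every 1e3)
#'   yields 2e5 models.
#' @export
scheduleSize <- function(nReplicas, nSweeps, saveEvery) {
  if (nSweeps %% saveEvery != 0) stop("nSweeps must be divisible by saveEvery")
  nReplicas * nSweeps / saveEvery
}

#' Replica-exchange Monte Carlo sampling of a conformational pool
#'
#' Runs `length(ladder@temperatures)` replicas with per-replica random
#' streams derived from the master seed. Every `config@exchangeEvery` sweeps,
#' alternating even/odd adjacent replica pairs attempt a swap accepted with
#' probability min(1, exp((beta_i - beta_j) (E_i - E_j))). Every
#' `config@saveEvery` sweeps each replica saves its structure, so the pool
#' holds nReplicas * nSweeps / saveEvery models; runs are fully reproducible
#' given the seed.
#'
#' @param topology a [Topology-class].
#' @param model an [EnergyModel-class].
#' @param ladder a [ReplicaLadder-class].
#' @param config a [SamplerConfig-class].
#' @param init optional starting [Conformation-class]; by default a
#'   deterministic extended conformation derived from the seed.
#' @return a [ConformationPool-class]; its `meta` also records per-pair
#'   exchange attempts/accepts and per-move acceptance in `provenance`.
#' @export
runREMC <- function(topology, model = EnergyModel(), ladder = ReplicaLadder(),
                    config, init = NULL) {
  stopifnot(is(config, "SamplerConfig"))
  if (config@nSweeps %% config@saveEvery != 0)
    stop("config error: nSweeps not divisible by saveEvery")
  if (is.null(init))
    init <- initialConformation(topology, seed = subSeed(config@seed, 1),
                                clashRadius = model@hardRadius)
  lay <- topologyLayout(topology)
  res <- cpp_remc(init@coords, layoutList(lay), eparList(model), ladder@betas,
                  config@nSweeps, config@saveEvery, config@exchangeEvery,
                  ampsList(config), subSeed(config@seed, 2))
  k <- length(res$energy)
  meta <- data.frame(replica = res$replica, sweep = res$sweep, energy = res$energy)
  prov <- list(nReplicas = length(ladder@betas), nSweeps = config@nSweeps,
               saveEvery = config@saveEvery, seed = config@seed,
               temperatures = ladder@temperatures,
               exchange = data.frame(pair = seq_along(res$exchAtt),
                                     attempts = as.integer(res$exchAtt),
                                     accepts = as.integer(res$exchAcc)),
               moves = data.frame(move = c("displacement", "pivot", "crankshaft", "rigid"),
                                  attempts = as.integer(res$moveAtt),
                                  accepts = as.integer(res$moveAcc)))
  makePool(topology, res$coords, lay$nBeads, k, meta, provenance = prov)
}
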