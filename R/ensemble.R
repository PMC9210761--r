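# chi-square fitting with free scale/offset, single-best-model selection,
# and equal-weight minimal-ensemble search.

# weighted sufficient statistics shared by all fit paths
fitStats <- function(y, s) {
  w <- 1 / s^2
  list(w = w, Sw = sum(w), Sy = sum(w * y), Syy = sum(w * y * y), y = y)
}

# closed-form (a, b, chi2) for one model intensity given precomputed stats
abChi2 <- function(m, st) {
  Sm <- sum(st$w * m); Smm <- sum(st$w * m * m); Smy <- sum(st$w * m * st$y)
  den <- st$Sw * Smm - Sm^2
  if (!is.finite(den) || den <= .Machine$double.eps * st$Sw * Smm)
    stop("degenerate design: model intensities are constant")
  a <- (st$Sw * Smy - Sm * st$Sy) / den
  b <- (Smm * st$Sy - Sm * Smy) / den
  rss <- sum(st$w * (a * m + b - st$y)^2)
  c(a = a, b = b, chi2 = rss / length(m))
}

#' Chi-square fit of a model intensity against an experimental curve
#'
#' Computes chi2 = (1/N_q) * sum_i (a I_model(q_i) + b - I_exp(q_i))^2 /
#' sigma^2(q_i), with the scale factor a and offset b obtained in closed form
#' from the stationarity conditions d(chi2)/da = 0, d(chi2)/db = 0 (weighted
#' two-parameter linear least squares). The offset absorbs buffer-subtraction
#' uncertainty and is unconstrained in sign; a non-positive fitted scale
#' triggers a warning. The sum is divided by N_q (reduced convention).
#'
#' @param modelIntensity numeric vector of model I(q) evaluated on exactly
#'   the curve's q grid (use [interpolateProfile()] first if needed).
#' @param curve a [ScatteringCurve-class].
#' @return a [FitResult-class] (no members for a bare profile fit).
#' @export
chi2Fit <- function(modelIntensity, curve) {
  stopifnot(is(curve, "ScatteringCurve"))
  nq <- nPoints(curve)
  if (nq < 3) stop("need at least 3 data points")
  if (length(modelIntensity) != nq)
    stop("model intensity must be evaluated on the curve's q grid")
  st <- fitStats(curve@intensity, curve@sigma)
  f <- abChi2(modelIntensity, st)
  if (f[["a"]] <= 0) warning("fitted scale factor a <= 0")
  new("FitResult", chi2 = max(0, f[["chi2"]]), a = f[["a"]], b = f[["b"]],
      members = integer(0), weights = numeric(0))
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: chi2 = %.4g, a = %.4g, b = %.4g", object@chi2,
              object@a, object@b))
  if (length(object@members) > 0)
    cat(sprintf("; members [%s], weights [%s]",
                paste(object@members, collapse = ", "),
                paste(sprintf("%.3g", object@weights), collapse = ", ")))
  cat("\n")
})

#' Linear interpolation of a model profile onto an experimental grid
#'
#' The model grid must span the target grid; extrapolation is refused.
#'
#' @param qModel,intensity model profile.
#' @param qTarget target grid.
#' @return intensities on `qTarget`.
#' @export
interpolateProfile <- function(qModel, intensity, qTarget) {
  if (min(qTarget) < min(qModel) || max(qTarget) > max(qModel))
    stop("model q grid does not span the experimental grid (no extrapolation)")
  approx(qModel, intensity, xout = qTarget)$y
}

# pool profiles re-gridded onto the curve's q values
poolProfilesOn <- function(pool, curve) {
  if (length(pool@q) == 0) stop("pool has no cached profiles; run poolProfiles() first")
  if (length(pool@q) == nPoints(curve) && all(pool@q == curve@q))
    return(pool@profiles)
  apply(pool@profiles, 2, function(col)
    interpolateProfile(pool@q, col, curve@q))
}

# vectorized closed-form fits for every column of a profile matrix
allSingleFits <- function(M, st) {
  nq <- nrow(M)
  Sm <- colSums(st$w * M)
  Smm <- colSums(st$w * M * M)
  Smy <- colSums(st$w * M * st$y)
  den <- st$Sw * Smm - Sm^2
  a <- (st$Sw * Smy - Sm * st$Sy) / den
  b <- (Smm * st$Sy - Sm * Smy) / den
  rss <- st$Syy + a^2 * Smm + b^2 * st$Sw + 2 * a * b * Sm -
    2 * a * Smy - 2 * b * st$Sy
  data.frame(a = a, b = b, chi2 = pmax(0, rss) / nq)
}

#' Best single model from a pool
#'
#' Evaluates the closed-form chi-square fit for every model profile and
#' returns the minimizer; ties are broken by the lowest model index.
#'
#' @param pool a [ConformationPool-class] with cached profiles.
#' @param curve a [ScatteringCurve-class].
#' @return a [FitResult-class] with a single member.
#' @export
bestModel <- function(pool, curve) {
  if (poolSize(pool) == 0) stop("empty pool")
  M <- poolProfilesOn(pool, curve)
  st <- fitStats(curve@intensity, curve@sigma)
  fits <- allSingleFits(M, st)
  k <- which(fits$chi2 <= min(fits$chi2))[1]
  new("FitResult", chi2 = fits$chi2[k], a = fits$a[k], b = fits$b[k],
      members = as.integer(k), weights = 1)
}

#' Fit a fixed ensemble of pool members
#'
#' The ensemble intensity is the weighted mean sum_m w_m I_m(q); in `equal`
#' mode w_m = 1/s, in `optimized` mode non-negative weights on the simplex
#' are found by constrained least squares (the free scale factor makes the
#' simplex constraint a normalization, so the solve is a bounded quadratic
#' program in a*w_m and b).
#'
#' @param pool a [ConformationPool-class] with cached profiles.
#' @param curve a [ScatteringCurve-class].
#' @param members model indices.
#' @param weightMode `"equal"` or `"optimized"`.
#' @return a [FitResult-class].
#' @export
ensembleFit <- function(pool, curve, members, weightMode = c("equal", "optimized")) {
  weightMode <- match.arg(weightMode)
  M <- poolProfilesOn(pool, curve)[, members, drop = FALSE]
  st <- fitStats(curve@intensity, curve@sigma)
  if (weightMode == "equal") {
    s <- length(members)
    f <- abChi2(rowMeans(M), st)
    return(new("FitResult", chi2 = max(0, f[["chi2"]]), a = f[["a"]], b = f[["b"]],
               members = as.integer(members), weights = rep(1 / s, s)))
  }
  # optimized: minimize ||sqrt(w).(M c + b - y)||^2, c >= 0, b free;
  # then a = sum(c), w_m = c_m / a
  nq <- nrow(M); s <- ncol(M)
  A <- cbind(M, 1) * sqrt(st$w)
  yw <- curve@intensity * sqrt(st$w)
  H <- crossprod(A); g <- crossprod(A, yw)
  eq <- abChi2(rowMeans(M), st)
  start <- c(rep(max(eq[["a"]], 1e-8) / s, s), eq[["b"]])
  fn <- function(p) as.numeric(p %*% H %*% p) - 2 * sum(g * p)
  gr <- function(p) 2 * as.numeric(H %*% p) - 2 * as.numeric(g)
  res <- optim(start, fn, gr, method = "L-BFGS-B",
               lower = c(rep(0, s), -Inf),
               control = list(maxit = 500L, factr = 1e4,
                              fnscale = max(abs(g), 1)))
  cc <- pmax(res$par[seq_len(s)], 0)
  b <- res$par[s + 1]
  if (sum(cc) <= 0) {  # degenerate: fall back to equal weights
    f <- abChi2(rowMeans(M), st)
    return(new("FitResult", chi2 = max(0, f[["chi2"]]), a = f[["a"]], b = f[["b"]],
               members = as.integer(members), weights = rep(1 / s, s)))
  }
  a <- sum(cc)
  w <- cc / a
  keep <- w > 1e-12
  rss <- sum(st$w * (as.numeric(M %*% cc) + b - curve@intensity)^2)
  new("FitResult", chi2 = max(0, rss / nq), a = a, b = b,
      members = as.integer(members[keep]), weights = w[keep] / sum(w[keep]))
}

# equal-weight pair chi2 for all pairs of a candidate set via the weighted
# Gram matrix; returns the best (u, v, chi2, a, b) with lowest-index ties
bestPairExhaustive <- function(M, st, cand) {
  Mc <- M[, cand, drop = FALSE]
  K <- crossprod(Mc * sqrt(st$w))
  sm <- colSums(st$w * Mc)
  tm <- colSums(st$w * Mc * st$y)
  n <- length(cand); nq <- nrow(M)
  best <- list(chi2 = Inf)
  for (u in seq_len(n - 1)) {
    v <- (u + 1):n
    Smm <- (K[u, u] + 2 * K[u, v] + diag(K)[v]) / 4
    Sm <- (sm[u] + sm[v]) / 2
    Smy <- (tm[u] + tm[v]) / 2
    den <- st$Sw * Smm - Sm^2
    a <- (st$Sw * Smy - Sm * st$Sy) / den
    b <- (Smm * st$Sy - Sm * Smy) / den
    chi2 <- pmax(0, st$Syy + a^2 * Smm + b^2 * st$Sw + 2 * a * b * Sm -
                   2 * a * Smy - 2 * b * st$Sy) / nq
    j <- which.min(chi2)
    if (length(j) && chi2[j] < best$chi2)
      best <- list(chi2 = chi2[j], u = cand[u], v = cand[v[j]],
                   a = a[j], b = b[j])
  }
  best
}

# greedy partner scan: best v completing `fixed` under equal weights
bestAddition <- function(M, st, fixed) {
  nq <- nrow(M); K <- ncol(M)
  s <- length(fixed) + 1
  base <- rowSums(M[, fixed, drop = FALSE])
  mixes <- (base + M) / s          # column v = mixture with model v
  fits <- allSingleFits(mixes, st)
  fits$chi2[fixed] <- Inf
  v <- which(fits$chi2 <= min(fits$chi2))[1]
  list(v = v, chi2 = fits$chi2[v], a = fits$a[v], b = fits$b[v])
}

#' Minimal-ensemble selection
#'
#' For ensemble sizes s = 1..`maxSize`, finds the member set minimizing the
#' chi-square of the weighted mean intensity, and returns the smallest s
#' whose chi2 improves on s-1 by more than `improve` (5% by default, a
#' parsimony rule). The pair search is exhaustive whenever the number of
#' pairs fits the `pairsBudget`, after Rg-stratified pre-clustering of the
#' candidate set when needed; a greedy forward search with `restarts`
#' restarts over the full pool runs alongside and the better result wins.
#' Ties are always broken toward the lowest model index.
#'
#' @param pool a [ConformationPool-class] with cached profiles.
#' @param curve a [ScatteringCurve-class].
#' @param maxSize maximum ensemble size (default 2, the minimal-ensemble
#'   regime where one compact and one extended conformer at equal weights
#'   explain a flexible scaffoldin's curve).
#' @param weightMode `"equal"` (default) or `"optimized"` (weights refit on
#'   the simplex for the shortlisted sets).
#' @param pairsBudget maximum number of pairs evaluated exhaustively; each
#'   pair costs O(1) after the Gram precomputation, so the default covers
#'   pools of ~1000 models. Candidate pre-clustering keeps the best single
#'   fits per Rg stratum; note that on strongly two-state data the true
#'   endpoints can rank poorly as singles, so exhaustive search is
#'   preferred whenever affordable.
#' @param improve fractional chi2 improvement required to accept a larger
#'   ensemble.
#' @param restarts greedy restarts (from the top single models).
#' @return a [FitResult-class].
#' @export
minimalEnsemble <- function(pool, curve, maxSize = 2L,
                            weightMode = c("equal", "optimized"),
                            pairsBudget = 5e5, improve = 0.05, restarts = 10L) {
  weightMode <- match.arg(weightMode)
  K <- poolSize(pool)
  if (maxSize < 1) stop("maxSize must be >= 1")
  if (maxSize > K) stop("maxSize exceeds pool size")
  M <- poolProfilesOn(pool, curve)
  st <- fitStats(curve@intensity, curve@sigma)
  fits1 <- allSingleFits(M, st)
  k1 <- which(fits1$chi2 <= min(fits1$chi2))[1]
  best <- new("FitResult", chi2 = fits1$chi2[k1], a = fits1$a[k1], b = fits1$b[k1],
              members = as.integer(k1), weights = 1)
  if (maxSize == 1) return(best)

  ord <- order(fits1$chi2, seq_len(K))
  # candidate set for the exhaustive pair pass
  targetN <- floor((1 + sqrt(1 + 8 * pairsBudget)) / 2)
  cand <- if (K <= targetN) seq_len(K) else {
    strata <- cut(pool@meta$rg, breaks = 40)
    quota <- max(1L, ceiling(targetN / nlevels(strata)))
    picked <- unlist(lapply(split(seq_len(K), strata), function(idx)
      idx[order(fits1$chi2[idx])][seq_len(min(length(idx), quota))]),
      use.names = FALSE)
    u <- unique(c(ord[seq_len(min(K, 50L))], picked))
    sort(u[order(fits1$chi2[u])][seq_len(min(targetN, length(u)))])
  }
  pair <- bestPairExhaustive(M, st, cand)
  # greedy over the full pool from the top singles
  for (r in seq_len(min(restarts, K))) {
    add <- bestAddition(M, st, ord[r])
    if (add$chi2 < pair$chi2) {
      uv <- sort(c(ord[r], add$v))
      pair <- list(chi2 = add$chi2, u = uv[1], v = uv[2], a = add$a, b = add$b)
    }
  }
  fit2 <- new("FitResult", chi2 = pair$chi2, a = pair$a, b = pair$b,
              members = as.integer(c(pair$u, pair$v)), weights = c(0.5, 0.5))
  if (weightMode == "optimized") {
    fit2 <- ensembleFit(pool, curve, c(pair$u, pair$v), "optimized")
    best <- ensembleFit(pool, curve, best@members, "optimized")
  }
  if (!(fit2@chi2 < (1 - improve) * best@chi2)) return(best)
  best <- fit2
  members <- as.integer(c(pair$u, pair$v))
  s <- 2L
  while (s < maxSize) {
    add <- bestAddition(M, st, members)
    cur <- if (weightMode == "optimized")
      ensembleFit(pool, curve, c(members, add$v), "optimized")
    else
      ensembleFit(pool, curve, c(members, add$v), "equal")
    if (!(cur@chi2 < (1 - improve) * best@chi2)) break
    members <- c(members, add$v)
    best <- cur
    s <- s + 1L
  }
  best
}
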