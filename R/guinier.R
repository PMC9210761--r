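#' Guinier fit of the low-q region
#'
#' Fits the Guinier law I(q) = I(0) exp(-q^2 Rg^2 / 3) by weighted linear
#' regression of ln I on q^2. The fit window starts at the first point; an
#' initial Rg is estimated from the first 10 points and the window is then
#' iterated (refit, truncate to q*Rg <= `qrg_limit`) to a fixed point. Errors
#' are propagated to ln-space to first order (sigma_lnI = sigma/I).
#'
#' @param curve a [ScatteringCurve-class].
#' @param qrg_limit upper limit on q*Rg for the fit window (the conventional
#'   validity bound is roughly 1.1--1.2; default 1.2).
#' @param max_iter maximum window iterations.
#' @return a [GuinierResult-class] with Rg = sqrt(-3*slope) and
#'   I(0) = exp(intercept).
#' @examples
#' q <- seq(0.005, 0.05, length.out = 60)
#' cv <- ScatteringCurve(q, 100 * exp(-q^2 * 900 / 3), rep(1e-3, 60))
#' guinierFit(cv)
#' @export
guinierFit <- function(curve, qrg_limit = 1.2, max_iter = 50L) {
  stopifnot(is(curve, "ScatteringCurve"))
  n <- nPoints(curve)
  if (n < 10) stop("insufficient range: need at least 10 points")
  q <- curve@q; I <- curve@intensity; s <- curve@sigma

  fitWindow <- function(last) {
    idx <- seq_len(last)
    if (any(I[idx] <= 0)) stop("non-positive intensity inside the Guinier window")
    x <- q[idx]^2
    y <- log(I[idx])
    w <- (I[idx] / s[idx])^2          # 1 / sigma_lnI^2
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x * x); sxy <- sum(w * x * y)
    den <- sw * sxx - sx^2
    if (den <= 0) stop("degenerate Guinier design")
    slope <- (sw * sxy - sx * sy) / den
    intercept <- (sy * sxx - sx * sxy) / den
    resid <- y - (intercept + slope * x)
    list(slope = slope, intercept = intercept, resid = resid)
  }

  last <- 10L
  for (it in seq_len(max_iter)) {
    f <- fitWindow(last)
    if (f$slope > 1e-12) {
      # a noise-dominated short window can slope upward; widen and retry --
      # only an upward slope over the full curve is non-Guinier behavior
      if (last < n) { last <- min(n, 2L * last); next }
      stop("non-Guinier behavior: positive slope of ln I vs q^2 (Rg^2 < 0)")
    }
    rg <- sqrt(max(0, -3 * f$slope))
    newLast <- if (rg == 0) n else max(which(q * rg <= qrg_limit), 0L)
    if (newLast < 10L)
      stop("insufficient range: fewer than 10 points satisfy q*Rg <= ", qrg_limit)
    if (newLast == last) break
    last <- as.integer(newLast)
  }
  f <- fitWindow(last)
  rg <- sqrt(max(0, -3 * f$slope))
  new("GuinierResult", rg = rg, i0 = exp(f$intercept),
      fitRange = c(1L, last), qmaxRg = q[last] * rg,
      residualSd = if (length(f$resid) > 2) sd(f$resid) else 0)
}

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf("Guinier fit: Rg = %.2f A, I(0) = %.4g, window %d..%d (qmax*Rg = %.3f)\n",
              object@rg, object@i0, object@fitRange[1], object@fitRange[2],
              object@qmaxRg))
})

#' Kratky and dimensionless Kratky transforms
#'
#' The plain Kratky transform plots q^2 I(q) against q and diagnoses
#' globular versus extended/disordered character. The normalized
#' (dimensionless) form plots (q Rg)^2 I(q)/I(0) against q Rg; for an ideal
#' globular particle it peaks at q Rg = sqrt(3) with height 3/e.
#'
#' @param curve a [ScatteringCurve-class].
#' @param normalized logical; if TRUE a Guinier result must be supplied.
#' @param guinier a [GuinierResult-class] with rg > 0 and i0 > 0 (normalized
#'   form only).
#' @return data.frame with columns `x`, `y`.
#' @export
kratkyTransform <- function(curve, normalized = FALSE, guinier = NULL) {
  stopifnot(is(curve, "ScatteringCurve"))
  if (!normalized)
    return(data.frame(x = curve@q, y = curve@q^2 * curve@intensity))
  if (is.null(guinier) || !is(guinier, "GuinierResult"))
    stop("normalized Kratky transform requires a GuinierResult")
  if (guinier@rg <= 0) stop("normalized Kratky transform requires rg > 0")
  x <- curve@q * guinier@rg
  data.frame(x = x, y = x^2 * curve@intensity / guinier@i0)
}
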