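# shared fixture builders; everything is generated in code

sphereFormFactor2 <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# analytic homogeneous-sphere curve with a SAXS-like error model
sphereCurve <- function(R = 30, qmin = 0.008, qmax = 0.25, n = 120,
                        i0 = 100, noiseFrac = 0.005, seed = NULL) {
  q <- seq(qmin, qmax, length.out = n)
  I <- i0 * sphereFormFactor2(q, R)
  s <- noiseFrac * I * (1 + q / 0.2)
  if (!is.null(seed)) {
    set.seed(seed)
    I <- I + rnorm(n) * s
  }
  ScatteringCurve(q, I, s)
}

# exact Guinier-law curve, optionally with relative Gaussian noise
guinierCurve <- function(rg, i0 = 100, qmax = 1.3 / rg, n = 120,
                         noiseFrac = 0, seed = NULL) {
  q <- seq(qmax / n / 5, qmax, length.out = n)
  I <- i0 * exp(-q^2 * rg^2 / 3)
  s <- if (noiseFrac > 0) noiseFrac * I else 1e-6 * I
  if (noiseFrac > 0 && !is.null(seed)) {
    set.seed(seed)
    I <- I + rnorm(n) * s
  }
  ScatteringCurve(q, I, s)
}

# exact pair-distance density of the uniform ball, support [0, 2R]
ballPairDensity <- function(r, R) {
  x <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[r < 0 | r > 2 * R] <- 0
  p
}

# small domain-linker-domain topology used across sampler tests
tinyTopology <- function(nBeads = 40, radius = 10, linker = 12) {
  buildTopology(list(sphericalShellDomain("dA", radius, nBeads),
                     LinkerSpec("l1", linker),
                     sphericalShellDomain("dB", radius, nBeads)))
}

# cached study-condition two-state system (expensive enough to share)
.fixtures <- new.env()
getTwoState <- function() {
  if (is.null(.fixtures$twoState))
    .fixtures$twoState <- makeTwoStateSystem(nDomains = 2, linkerLengths = 19L,
                                             seed = 42)
  .fixtures$twoState
}

# independent weighted 2-parameter fit via stats::lm (oracle for chi2Fit)
lmChi2 <- function(m, curve) {
  w <- 1 / sigmas(curve)^2
  fit <- stats::lm(intensities(curve) ~ m, weights = w)
  list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
       chi2 = sum(w * residuals(fit)^2) / nPoints(curve))
}

extdata <- function(...) system.file("extdata", ..., package = "flexsaxs")
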