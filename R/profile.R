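#' Per-residue effective scattering amplitudes
#'
#' The default is a constant amplitude of 1 for every bead: the chi-square
#' fit's free scale factor absorbs the overall amplitude, so only the shape
#' of I(q) matters. A per-bead amplitude vector and/or a common q-dependent
#' shape factor can be supplied.
#'
#' @param perBead positive numeric amplitude(s), recycled over beads.
#' @param qShape optional function f(q) (vectorized, f(0) > 0) applied as a
#'   common amplitude factor.
#' @return a [FormFactorTable-class].
#' @export
FormFactorTable <- function(perBead = 1, qShape = NULL) {
  new("FormFactorTable", perBead = as.numeric(perBead), qShape = qShape)
}

# nq x N amplitude matrix for the direct Debye sum
ffMatrix <- function(ff, q, n) {
  per <- rep_len(ff@perBead, n)
  g <- if (is.null(ff@qShape)) rep(1, length(q)) else ff@qShape(q)
  if (any(!is.finite(g)) || g[1] <= 0 && q[1] == 0)
    stop("form factor must be finite with f(0) > 0")
  outer(g, per)
}

#' Debye-formula scattering profile of a conformation
#'
#' Computes the orientationally averaged intensity
#' I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij),
#' with sin(x)/x -> 1 as x -> 0, so that I(0) = (sum_i f_i(0))^2. The exact
#' pair sum is O(N^2) per q point; for large bead counts a distance-histogram
#' approximation (bin width <= 0.1 A, with first- and second-moment
#' corrections per bin) evaluates the same sum over bins.
#'
#' @param conf a [Conformation-class] or an N x 3 coordinate matrix.
#' @param q momentum-transfer grid (1/A), non-negative.
#' @param ff a [FormFactorTable-class].
#' @param method `"auto"` (histogram when N > 1000), `"direct"`, or
#'   `"histogram"`.
#' @param binWidth histogram bin width (A), default 0.05.
#' @return data.frame with columns `q` and `intensity`.
#' @examples
#' two <- rbind(c(0, 0, 0), c(50, 0, 0))
#' debyeProfile(two, q = c(0, 0.1))  # I(0) = 4
#' @export
debyeProfile <- function(conf, q = defaultQGrid(), ff = FormFactorTable(),
                         method = c("auto", "direct", "histogram"),
                         binWidth = 0.05) {
  method <- match.arg(method)
  coords <- if (is(conf, "Conformation")) conf@coords else as.matrix(conf)
  if (nrow(coords) < 1) stop("empty conformation")
  if (any(q < 0)) stop("q must be non-negative")
  if (binWidth > 0.1) stop("histogram bin width must be <= 0.1 A")
  n <- nrow(coords)
  if (method == "auto") method <- if (n > 1000) "histogram" else "direct"
  I <- if (method == "direct") {
    cpp_debye_direct(coords, q, ffMatrix(ff, q, n))
  } else {
    per <- rep_len(ff@perBead, n)
    g <- if (is.null(ff@qShape)) rep(1, length(q)) else ff@qShape(q)
    cpp_debye_hist(coords, q, per, g, binWidth)
  }
  data.frame(q = q, intensity = I)
}

#' Compute and cache model profiles for every pool member
#'
#' @param pool a [ConformationPool-class].
#' @param q momentum-transfer grid (1/A).
#' @param ff a [FormFactorTable-class].
#' @param method,binWidth passed to [debyeProfile()]; pools default to the
#'   histogram path.
#' @return the pool with its `q` and `profiles` slots filled (one column of
#'   I_k(q) per model index k).
#' @export
poolProfiles <- function(pool, q = defaultQGrid(), ff = FormFactorTable(),
                         method = "histogram", binWidth = 0.1) {
  k <- poolSize(pool)
  prof <- matrix(0, length(q), k)
  for (i in seq_len(k))
    prof[, i] <- debyeProfile(pool@coords[, , i], q = q, ff = ff,
                              method = method, binWidth = binWidth)$intensity
  pool@q <- q
  pool@profiles <- prof
  pool
}
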