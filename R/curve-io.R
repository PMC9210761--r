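#' Construct a ScatteringCurve
#'
#' @param q momentum transfer (1/A), strictly increasing, non-negative.
#' @param intensity I(q), arbitrary units.
#' @param sigma per-point statistical errors, strictly positive.
#' @return a [ScatteringCurve-class] object.
#' @examples
#' q <- seq(0.01, 0.3, length.out = 50)
#' ScatteringCurve(q, 100 * exp(-q^2 * 100), rep(0.5, 50))
#' @export
ScatteringCurve <- function(q, intensity, sigma) {
  new("ScatteringCurve", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = as.numeric(sigma))
}

#' @describeIn ScatteringCurve number of points N_q.
#' @param x,object a ScatteringCurve.
#' @export
nPoints <- function(x) length(x@q)

#' Accessors for ScatteringCurve slots
#' @param x a [ScatteringCurve-class].
#' @return numeric vector.
#' @export
qValues <- function(x) x@q

#' @rdname qValues
#' @export
intensities <- function(x) x@intensity

#' @rdname qValues
#' @export
sigmas <- function(x) x@sigma

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d points, q in [%.4g, %.4g] 1/A\n",
              nPoints(object), min(object@q), max(object@q)))
})

setMethod("length", "ScatteringCurve", function(x) length(x@q))

#' Load a SAXS curve from a 3-column ASCII file
#'
#' Reads the standard `.dat` layout: whitespace-separated columns q, I(q),
#' sigma(q). Lines starting with `#` or containing non-numeric tokens in the
#' first three fields are skipped. Units are never auto-guessed: pass
#' `q_units = "inverse-nanometer"` to convert nm^-1 input to the internal
#' 1/A convention (division by 10).
#'
#' @param path file path.
#' @param q_units `"inverse-angstrom"` (default) or `"inverse-nanometer"`.
#' @return a [ScatteringCurve-class].
#' @export
loadCurve <- function(path, q_units = c("inverse-angstrom", "inverse-nanometer")) {
  q_units <- match.arg(q_units)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  rowLine <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) < 3) next
    vals <- suppressWarnings(as.numeric(tok[1:3]))
    if (any(is.na(vals))) next
    rows[[length(rows) + 1L]] <- vals
    rowLine <- c(rowLine, i)
  }
  if (length(rows) < 20)
    stop("malformed input: fewer than 20 usable data rows in ", path)
  m <- do.call(rbind, rows)
  q <- m[, 1]; I <- m[, 2]; s <- m[, 3]
  if (q_units == "inverse-nanometer") q <- q / 10
  bad <- which(s <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive sigma at file line %d (data row %d)",
                 rowLine[bad[1]], bad[1]))
  if (any(diff(q) <= 0)) {
    j <- which(diff(q) <= 0)[1]
    stop(sprintf("q not strictly increasing at data row %d", j + 1L))
  }
  ScatteringCurve(q, I, s)
}

#' Write a SAXS curve as 3-column ASCII
#'
#' Full double precision is used so that a write/reload round trip is exact.
#'
#' @param curve a [ScatteringCurve-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "ScatteringCurve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q[1/A] I(q) sigma(q)", con)
  writeLines(sprintf("%.17g %.17g %.17g", curve@q, curve@intensity, curve@sigma), con)
  invisible(path)
}
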