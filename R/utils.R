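# internal helpers

# run expr with a local RNG state derived from `seed`, restoring the caller's
# state afterwards; all package randomness funnels through this
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic sub-seed derivation (kept below 2^31)
subSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1299721) %% 2147483629
}

sincR <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' Default momentum-transfer grid
#'
#' 101 points spanning 0.005--0.5 1/A, the usable SEC-SAXS range after
#' discarding the lowest-q points.
#' @param n number of points.
#' @param qmin,qmax grid limits (1/A).
#' @return numeric vector of q values.
#' @export
defaultQGrid <- function(n = 101, qmin = 0.005, qmax = 0.5) {
  seq(qmin, qmax, length.out = n)
}
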