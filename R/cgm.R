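#' Hill production propensities of the coarse-grain models
#'
#' SGAA (auto-activation): `X(N) = g2 + g2Star * N^n / (N^n + K)` — monotone
#' non-decreasing in `N`, bounded by `g2 + g2Star` (the activated rate).
#' Toggle switch (repression): `X(N_other) = g5 + g5Star / (N_other^n + K)`
#' — monotone non-increasing, `g5 + g5Star/K` at zero repressor (the basal
#' rate) with asymptote `g5` (the repressed rate).  The cooperativity `n` is
#' fixed to 2 unless overridden.
#'
#' @param N protein count (SGAA: the protein's own count; TS: the other
#'   gene's count).
#' @param params named list/vector: SGAA `g2, g2Star, K, r2` (+ optional
#'   `n`); TS `g5, g5Star, K, r5` (+ optional `n`).
#' @return production propensity in s^-1 (vectorised over `N`).
#' @export
hillProductionSGAA <- function(N, params) {
  p <- as.list(params)
  n <- if (is.null(p$n)) 2 else p$n
  stopifnot(all(N >= 0))
  Nn <- N^n
  p$g2 + ifelse(Nn + p$K > 0, p$g2Star * Nn / (Nn + p$K), 0)
}

#' @rdname hillProductionSGAA
#' @export
hillProductionTS <- function(N, params) {
  p <- as.list(params)
  n <- if (is.null(p$n)) 2 else p$n
  stopifnot(all(N >= 0))
  Nn <- N^n
  if (any(Nn + p$K <= 0))
    stop("Hill repression undefined: N^n + K = 0")
  p$g5 + p$g5Star / (Nn + p$K)
}

#' Coarse-grain-model state spaces
#'
#' Protein-count axes only, no promoter axes: dimension `nmax + 1` (SGAA) or
#' `nmax^2 + 1` (TS), sink included.
#'
#' @param circuit `"sgaa"` or `"ts"`.
#' @param nmax FSP bound per protein axis.
#' @return an [FSPStateSpace-class].
#' @export
cgmSpace <- function(circuit = c("sgaa", "ts"), nmax) {
  circuit <- match.arg(circuit)
  if (circuit == "sgaa") buildStateSpace(c(A = nmax))
  else buildStateSpace(c(A = nmax, B = nmax))
}

#' Coarse-grain-model generator
#'
#' Birth with the Hill propensity, per-capita death.  For the toggle switch
#' each species' birth propensity reads the other species' count
#' (mutual repression); the scheme is A/B exchange symmetric.
#'
#' @param params see [hillProductionSGAA()].
#' @param space a 1-axis (SGAA) or 2-axis (TS) space from [cgmSpace()]
#'   without promoter axes.
#' @return a [GeneratorMatrix-class].
#' @export
cgmGenerator <- function(params, space) {
  if (any(space@axes$kind != "count"))
    stop("CGM spaces have no promoter axes; see cgmSpace()")
  p <- as.list(params)
  if (length(space@axes$name) == 1) {
    stopifnot(identical(space@axes$name, "A"))
    rules <- list(
      list(delta = c(A = 1L),
           propensity = function(s) hillProductionSGAA(s[, "A"], p)),
      list(delta = c(A = -1L),
           propensity = function(s) p$r2 * s[, "A"]))
  } else {
    stopifnot(identical(space@axes$name, c("A", "B")))
    rules <- list(
      list(delta = c(A = 1L),
           propensity = function(s) hillProductionTS(s[, "B"], p)),
      list(delta = c(B = 1L),
           propensity = function(s) hillProductionTS(s[, "A"], p)),
      list(delta = c(A = -1L),
           propensity = function(s) p$r5 * s[, "A"]),
      list(delta = c(B = -1L),
           propensity = function(s) p$r5 * s[, "B"]))
  }
  assembleGenerator(rules, space)
}

#' CGM effective rates
#'
#' SGAA: `peff = g2`, `peffStar = g2 + g2Star` (the saturated Hill rate),
#' `reff = r2`.  TS: `peff = g5 + g5Star/K` (zero-repressor rate),
#' `peffStar = g5` (fully repressed asymptote), `reff = r5`.
#'
#' @param params fitted CGM parameters.
#' @param circuit `"sgaa"` or `"ts"`.
#' @return named vector `peff`, `peffStar`, `reff`.
#' @export
cgmEffectiveRates <- function(params, circuit = c("sgaa", "ts")) {
  circuit <- match.arg(circuit)
  p <- as.list(params)
  if (circuit == "sgaa")
    c(peff = p$g2, peffStar = p$g2 + p$g2Star, reff = p$r2)
  else
    c(peff = p$g5 + p$g5Star / p$K, peffStar = p$g5, reff = p$r5)
}
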