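#' Detailed-model (DM) state spaces
#'
#' The DM keeps the promoter explicit: the SGAA space has one protein axis
#' plus a binary promoter axis (`0` basal, `1` activated); the toggle-switch
#' space has two protein axes plus two binary occupancy flags (`sA`: A bound
#' to its operator, repressing B; `sB`: B bound, repressing A).
#'
#' @param nmax FSP bound: tracked counts `0..nmax-1` per protein axis.
#' @return an [FSPStateSpace-class].
#' @export
sgaaDMSpace <- function(nmax) {
  buildStateSpace(c(A = nmax), c(promoter = 2L))
}

#' @rdname sgaaDMSpace
#' @export
tsDMSpace <- function(nmax) {
  buildStateSpace(c(A = nmax, B = nmax), c(sA = 2L, sB = 2L))
}

#' SGAA detailed-model generator
#'
#' The reduced auto-activation scheme with explicit promoter: production of
#' monomer `A` at `g1` (basal) or `g1Star` (activated), per-capita
#' degradation `r1`, and monomer binding/unbinding of the promoter at
#' `f1*N` / `b1` with the bound monomer removed from (binding) or returned to
#' (unbinding) the free pool.
#'
#' @param params named `g1, g1Star, r1, f1, b1` (s^-1; `f1` per
#'   molecule-second).
#' @param space a space from [sgaaDMSpace()].
#' @return a [GeneratorMatrix-class].
#' @export
sgaaDMGenerator <- function(params, space) {
  p <- as.list(params)
  stopifnot(all(unlist(p) >= 0))
  if (!identical(space@axes$name, c("A", "promoter")))
    stop("space must have axes (A, promoter); see sgaaDMSpace()")
  rules <- list(
    list(delta = c(A = 1L),
         propensity = function(s) ifelse(s[, "promoter"] == 0, p$g1, p$g1Star)),
    list(delta = c(A = -1L),
         propensity = function(s) p$r1 * s[, "A"]),
    list(delta = c(A = -1L, promoter = 1L),
         propensity = function(s) p$f1 * s[, "A"] * (s[, "promoter"] == 0)),
    list(delta = c(A = 1L, promoter = -1L),
         propensity = function(s) p$b1 * (s[, "promoter"] == 1)))
  assembleGenerator(rules, space)
}

#' Toggle-switch detailed-model generator
#'
#' Symmetric mutual repression with monomer-operator binding: `A` is produced
#' at `g4` while `sB = 0` and at `g4Star` while `sB = 1` (B bound), and
#' symmetrically for `B` vs `sA`.  Binding consumes a free monomer
#' (`f4*N`), unbinding (`b4`) returns it; degradation is per-capita at `r4`.
#'
#' @param params named `g4, g4Star, r4, f4, b4` (s^-1).
#' @param space a space from [tsDMSpace()].
#' @return a [GeneratorMatrix-class].
#' @export
tsDMGenerator <- function(params, space) {
  p <- as.list(params)
  stopifnot(all(unlist(p) >= 0))
  if (!identical(space@axes$name, c("A", "B", "sA", "sB")))
    stop("space must have axes (A, B, sA, sB); see tsDMSpace()")
  rules <- list(
    list(delta = c(A = 1L),
         propensity = function(s) ifelse(s[, "sB"] == 0, p$g4, p$g4Star)),
    list(delta = c(B = 1L),
         propensity = function(s) ifelse(s[, "sA"] == 0, p$g4, p$g4Star)),
    list(delta = c(A = -1L),
         propensity = function(s) p$r4 * s[, "A"]),
    list(delta = c(B = -1L),
         propensity = function(s) p$r4 * s[, "B"]),
    list(delta = c(A = -1L, sA = 1L),
         propensity = function(s) p$f4 * s[, "A"] * (s[, "sA"] == 0)),
    list(delta = c(A = 1L, sA = -1L),
         propensity = function(s) p$b4 * (s[, "sA"] == 1)),
    list(delta = c(B = -1L, sB = 1L),
         propensity = function(s) p$f4 * s[, "B"] * (s[, "sB"] == 0)),
    list(delta = c(B = 1L, sB = -1L),
         propensity = function(s) p$b4 * (s[, "sB"] == 1)))
  assembleGenerator(rules, space)
}

#' DM effective rates
#'
#' For the detailed models the effective rates are the fitted rate constants
#' themselves: `peff = g1` (`g4`), `peffStar = g1Star` (`g4Star`),
#' `reff = r1` (`r4`).
#'
#' @param params fitted DM parameters.
#' @param circuit `"sgaa"` or `"ts"`.
#' @return named vector `peff`, `peffStar`, `reff`.
#' @export
dmEffectiveRates <- function(params, circuit = c("sgaa", "ts")) {
  circuit <- match.arg(circuit)
  p <- as.list(params)
  if (circuit == "sgaa")
    c(peff = p$g1, peffStar = p$g1Star, reff = p$r1)
  else
    c(peff = p$g4, peffStar = p$g4Star, reff = p$r4)
}

# Observed-state (protein counts only) transition matrix for a DM.
# The promoter is hidden: each column i weighs the initial promoter
# configuration by its quasi-stationary conditional given the observed
# count(s), and sums the final promoter configurations.  Under stationarity
# this is exactly the marginal count transition probability.
.dmObservedTransition <- function(W, tau) {
  space <- W@space
  P <- propagate(W, tau)
  full <- P@P[-space@sinkIndex, -space@sinkIndex, drop = FALSE]
  states <- stateGrid(space)
  isCount <- space@axes$kind == "count"
  obsCard <- space@axes$cardinality[isCount]
  obsStride <- cumprod(c(1L, obsCard[-length(obsCard)]))
  obsIdx <- as.vector(1L + states[, isCount, drop = FALSE] %*% obsStride)
  nObs <- prod(obsCard)
  # quasi-stationary law over the full space -> conditional promoter weights;
  # vector iteration on the substochastic block (cheap relative to expm, and
  # the m-window propagator already mixes well)
  n <- nrow(full)
  pi <- rep(1 / n, n)
  for (it in 1:1000) {
    v <- full %*% pi
    v <- as.vector(v) / sum(v)
    if (max(abs(v - pi)) < 1e-13) { pi <- v; break }
    pi <- v
  }
  grpMass <- as.vector(rowsum(pi, obsIdx))
  w <- pi / grpMass[obsIdx]
  deg <- !is.finite(w) | grpMass[obsIdx] < 1e-280
  if (any(deg)) {  # counts with no stationary mass: uniform promoter weights
    tab <- tabulate(obsIdx, nObs)
    w[deg] <- 1 / tab[obsIdx[deg]]
  }
  agg <- Matrix::sparseMatrix(i = obsIdx, j = seq_along(obsIdx), x = 1,
                              dims = c(nObs, length(obsIdx)))
  start <- Matrix::sparseMatrix(i = seq_along(obsIdx), j = obsIdx, x = w,
                                dims = c(length(obsIdx), nObs))
  as.matrix(agg %*% full %*% start)
}
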