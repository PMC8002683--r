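#' Maximum Caliber per-frame path distribution (one gene)
#'
#' Given `N` proteins at the start of a frame, the micro-trajectory over the
#' frame is labelled by `lAlpha` productions (0..M) and `lA` survivors
#' (0..N).  Path-entropy maximisation under constraints on mean production,
#' mean survival and the production-abundance correlation gives
#' `P(lAlpha, lA) = Q^-1 * C(N, lA) * exp(hAlpha*lAlpha + hA*lA +
#' KA*lAlpha*lA)`.  Computed with a log-sum-exp shift for numerical safety.
#'
#' @param N current protein count (>= 0).
#' @param params named `hAlpha, hA, KA` (dimensionless Lagrange multipliers)
#'   and `M` (integer production cap, >= 1).
#' @return a [PathDistribution-class]; `probs` has dimensions
#'   `(M+1) x (N+1)` indexed by `(lAlpha, lA)` (0-based labels).
#' @export
pathDistributionSGAA <- function(N, params) {
  p <- as.list(params)
  stopifnot(N >= 0, p$M >= 1, is.finite(p$hAlpha), is.finite(p$hA),
            is.finite(p$KA))
  M <- as.integer(p$M)
  la <- 0:M
  lA <- 0:N
  lw <- outer(la, lA, function(a, s)
    lchoose(N, s) + p$hAlpha * a + p$hA * s + p$KA * a * s)
  mx <- max(lw)
  w <- exp(lw - mx)
  Q <- sum(w)
  if (!is.finite(Q) || Q <= 0) stop("partition function overflowed")
  new("PathDistribution", state = as.integer(N),
      probs = array(w / Q, dim = dim(w)), logQ = mx + log(Q), M = M)
}

#' Maximum Caliber per-frame path distribution (toggle switch)
#'
#' Joint labels `(lAlpha, lA, lBeta, lB)` for productions and survivors of
#' both genes, with degeneracy `C(NA, lA) * C(NB, lB)` and exponent
#' `hAlpha*(lAlpha+lBeta) + hA*(lA+lB) + KAalpha*(lAlpha*lA + lBeta*lB) +
#' KAbeta*(lBeta*lA + lAlpha*lB)`; `KAbeta` carries the cross-gene
#' (repression) coupling.  Exchange-symmetric in the two genes when
#' `NA == NB`.
#'
#' @param NA_,NB_ current protein counts of the two genes.
#' @param params named `hAlpha, hA, KAalpha, KAbeta, M`.
#' @return a [PathDistribution-class]; `probs` has dimensions
#'   `(M+1) x (NA+1) x (M+1) x (NB+1)`.
#' @export
pathDistributionTS <- function(NA_, NB_, params) {
  p <- as.list(params)
  stopifnot(NA_ >= 0, NB_ >= 0, p$M >= 1)
  M <- as.integer(p$M)
  la <- 0:M; lA <- 0:NA_; lb <- 0:M; lB <- 0:NB_
  dims <- c(M + 1L, NA_ + 1L, M + 1L, NB_ + 1L)
  g <- expand.grid(la = la, lA = lA, lb = lb, lB = lB)
  lw <- lchoose(NA_, g$lA) + lchoose(NB_, g$lB) +
    p$hAlpha * (g$la + g$lb) + p$hA * (g$lA + g$lB) +
    p$KAalpha * (g$la * g$lA + g$lb * g$lB) +
    p$KAbeta * (g$lb * g$lA + g$la * g$lB)
  mx <- max(lw)
  w <- exp(lw - mx)
  Q <- sum(w)
  if (!is.finite(Q) || Q <= 0) stop("partition function overflowed")
  new("PathDistribution", state = as.integer(c(NA_, NB_)),
      probs = array(w / Q, dim = dims), logQ = mx + log(Q), M = M)
}

#' Maximum Caliber state spaces
#'
#' Same tracked ranges as the CGM spaces (protein counts only, plus sink).
#'
#' @param circuit `"sgaa"` or `"ts"`.
#' @param nmax FSP bound per protein axis.
#' @return an [FSPStateSpace-class].
#' @export
maxcalSpace <- function(circuit = c("sgaa", "ts"), nmax) {
  cgmSpace(match.arg(circuit), nmax)
}

#' One-frame Maximum Caliber transition matrix (one gene)
#'
#' Entry `(i -> j)` sums the path probabilities with `lAlpha + lA = j`
#' conditioned on `N = i`; targets beyond the tracked range go to the sink.
#' `j > i + M` is impossible (exact zero).
#'
#' @param params named `hAlpha, hA, KA, M`.
#' @param space a 1-axis space from [maxcalSpace()].
#' @return a [PropagatorMatrix-class] with a one-frame horizon.
#' @export
transitionMatrixSGAA <- function(params, space) {
  p <- as.list(params)
  if (nrow(space@axes) != 1 || space@axes$kind != "count")
    stop("space must be the 1-axis MaxCal space")
  nmax <- space@axes$cardinality
  P <- maxcal_transition_sgaa_cpp(p$hAlpha, p$hA, p$KA, as.integer(p$M), nmax)
  new("PropagatorMatrix", P = P, horizon = 1, unit = "frames", space = space)
}

#' One-frame Maximum Caliber transition matrix (toggle switch)
#'
#' Entry `((i,k) -> (j,l))` sums joint path probabilities with
#' `lAlpha + lA = j` and `lBeta + lB = l`.  Cost grows steeply with the
#' tracked range and `M`; intended for the moderate spaces used in
#' inference tests.
#'
#' @param params named `hAlpha, hA, KAalpha, KAbeta, M`.
#' @param space a 2-axis space from [maxcalSpace()].
#' @return a [PropagatorMatrix-class] with a one-frame horizon.
#' @export
transitionMatrixTS <- function(params, space) {
  p <- as.list(params)
  if (nrow(space@axes) != 2 || any(space@axes$kind != "count"))
    stop("space must be the 2-axis MaxCal space")
  nmax <- space@axes$cardinality[1]
  stopifnot(space@axes$cardinality[2] == nmax)
  P <- maxcal_transition_ts_cpp(p$hAlpha, p$hA, p$KAalpha, p$KAbeta,
                                as.integer(p$M), nmax)
  new("PropagatorMatrix", P = P, horizon = 1, unit = "frames", space = space)
}

# strict local maxima of a probability vector over counts 0..n-1;
# returns 0-based locations ordered by decreasing mass
.findModes <- function(p) {
  n <- length(p)
  if (n == 1) return(0L)
  left <- c(Inf, p[-n])   # boundary counts as a mode only via its one neighbour
  right <- c(p[-1], Inf)
  is_mode <- (p > left & p >= right) | (p >= left & p > right)
  is_mode[1] <- p[1] > p[2]
  is_mode[n] <- p[n] > p[n - 1]
  modes <- unname(which(is_mode)) - 1L
  modes[order(p[modes + 1L], decreasing = TRUE)]
}

#' Extract effective rates from a fitted Maximum Caliber model
#'
#' Locates the low (`NL`) and high (`NH`) modes of the stationary count law
#' of the fitted chain, then reads production and degradation off the exact
#' conditional path moments: `peff = <lAlpha>_{NL} / deltaT`,
#' `peffStar = <lAlpha>_{NH} / deltaT` (for the toggle switch the
#' conditioning states are the `(NH, NL)` / `(NL, NH)` joint modes and the
#' roles of `peff`/`peffStar` swap accordingly), and
#' `r(N) = (N - <lA>_N) / (N * deltaT)` averaged over the stationary law
#' excluding `N = 0` (where `r` is undefined), renormalised over `N >= 1`.
#'
#' @param params fitted MaxCal parameters (see [transitionMatrixSGAA()] /
#'   [transitionMatrixTS()]).
#' @param space the MaxCal state space used in the fit.
#' @param deltaT frame interval in seconds.
#' @param circuit `"sgaa"` or `"ts"`.
#' @param modesFrom `"model"` (default): modes of the model's stationary
#'   law; `"data"`: modes of a supplied empirical count histogram.
#' @param dataCounts pooled observed counts, required for
#'   `modesFrom = "data"`.
#' @return named vector `peff, peffStar, reff` with attributes `modes`
#'   (the conditioning states) and `stationary`.
#' @export
maxcalEffectiveRates <- function(params, space, deltaT,
                                 circuit = c("sgaa", "ts"),
                                 modesFrom = c("model", "data"),
                                 dataCounts = NULL) {
  circuit <- match.arg(circuit)
  modesFrom <- match.arg(modesFrom)
  p <- as.list(params)
  nmax <- space@axes$cardinality[1]
  if (circuit == "sgaa") {
    P1 <- transitionMatrixSGAA(p, space)
    peq <- stationaryDistribution(P1, leakTol = Inf)
    marg <- if (modesFrom == "model") peq else
      tabulate(dataCounts + 1L, nmax) / length(dataCounts)
    modes <- .findModes(marg)
    if (length(modes) < 2)
      stop(sprintf(paste0("stationary count law is unimodal (single mode at ",
                          "N=%d): cannot separate low and high expression ",
                          "states"), if (length(modes)) modes[1] else NA))
    two <- sort(modes[1:2])
    NL <- two[1]; NH <- two[2]
    mm <- maxcal_means_sgaa_cpp(p$hAlpha, p$hA, p$KA, as.integer(p$M), nmax)
    lAlphaMean <- mm[1, ]; lAMean <- mm[2, ]
    peff <- lAlphaMean[NL + 1] / deltaT
    peffStar <- lAlphaMean[NH + 1] / deltaT
    Ns <- 1:(nmax - 1)
    rN <- (Ns - lAMean[Ns + 1]) / (Ns * deltaT)
    wts <- peq[Ns + 1] / sum(peq[Ns + 1])
    reff <- sum(wts * rN)
    structure(c(peff = peff, peffStar = peffStar, reff = reff),
              modes = c(NL = NL, NH = NH), stationary = peq)
  } else {
    P1 <- transitionMatrixTS(p, space)
    peq <- stationaryDistribution(P1, leakTol = Inf)
    NAv <- rep(0:(nmax - 1), times = nmax)
    NBv <- rep(0:(nmax - 1), each = nmax)
    margA <- as.vector(rowsum(peq, NAv))
    modes <- .findModes(margA)
    if (length(modes) < 2)
      stop("stationary A-marginal is unimodal: cannot locate the two switch states")
    two <- sort(modes[1:2])
    NL <- two[1]; NH <- two[2]
    mm <- maxcal_means_ts_cpp(p$hAlpha, p$hA, p$KAalpha, p$KAbeta,
                              as.integer(p$M), nmax)
    idxHL <- (NH + nmax * NL) + 1L  # state (A=NH, B=NL): A unrepressed
    idxLH <- (NL + nmax * NH) + 1L  # state (A=NL, B=NH): A repressed
    peff <- mm[1, idxHL] / deltaT
    peffStar <- mm[1, idxLH] / deltaT
    ok <- NAv >= 1
    rA <- (NAv[ok] - mm[2, ok]) / (NAv[ok] * deltaT)
    wts <- peq[ok] / sum(peq[ok])
    reff <- sum(wts * rA)
    structure(c(peff = peff, peffStar = peffStar, reff = reff),
              modes = c(NL = NL, NH = NH), stationary = peq)
  }
}
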