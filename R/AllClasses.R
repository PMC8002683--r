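#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix Matrix
#' @useDynLib CircuitCaliber, .registration = TRUE
NULL

#' Frame-sampled protein-count trajectory
#'
#' A `FrameSeries` holds one uniformly sampled single-cell trajectory: the
#' copy number of each fluorescently tagged protein recorded every `deltaT`
#' seconds.  Only tagged proteins appear here; mRNAs, dimers and promoter
#' states are invisible to the (emulated) measurement.
#'
#' @slot deltaT frame interval in seconds.
#' @slot counts integer matrix, one row per frame, one column per tagged
#'   protein.
#' @slot speciesLabels names of the tagged proteins (e.g. `"A"` or
#'   `c("A", "B")`).
#' @export
setClass("FrameSeries",
  representation(deltaT = "numeric", counts = "matrix",
                 speciesLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@deltaT) != 1L || !is.finite(object@deltaT) ||
        object@deltaT <= 0)
      msg <- c(msg, "deltaT must be a single positive number")
    if (ncol(object@counts) != length(object@speciesLabels))
      msg <- c(msg, "one column per tagged protein required")
    cts <- object@counts
    if (length(cts) && (any(!is.finite(cts)) || any(cts < 0) ||
                        any(cts != round(cts))))
      msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
  })

#' Construct a FrameSeries
#'
#' @param counts integer matrix or vector of protein counts (frames in rows).
#' @param deltaT frame interval in seconds.
#' @param speciesLabels tagged-protein names; defaults to the column names of
#'   `counts` or `"A"`, `"B"`, ... .
#' @return a [FrameSeries-class] object.
#' @export
FrameSeries <- function(counts, deltaT, speciesLabels = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L)
  storage.mode(counts) <- "integer"
  if (is.null(speciesLabels)) {
    speciesLabels <- colnames(counts)
    if (is.null(speciesLabels)) speciesLabels <- c("A", "B")[seq_len(ncol(counts))]
  }
  colnames(counts) <- speciesLabels
  new("FrameSeries", deltaT = as.numeric(deltaT), counts = counts,
      speciesLabels = speciesLabels)
}

#' Stochastic reaction network
#'
#' Species, reactions (mass-action or Hill-type propensities) and an initial
#' state.  Promoter occupancy is represented by indicator species grouped in
#' `promoterGroups`; exactly one indicator per group is active at any time.
#'
#' @slot species ordered character vector of species names.
#' @slot reactions list of reactions as returned by [reaction()].
#' @slot initialState named integer vector over `species`.
#' @slot promoterGroups list of character vectors of mutually exclusive
#'   promoter-indicator species.
#' @slot observed names of the tagged (recorded) proteins.
#' @export
setClass("ReactionNetwork",
  representation(species = "character", reactions = "list",
                 initialState = "integer", promoterGroups = "list",
                 observed = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@initialState), object@species))
      msg <- c(msg, "initialState must be named exactly by species")
    if (any(object@initialState < 0))
      msg <- c(msg, "initial counts must be non-negative")
    for (rx in object@reactions) {
      refd <- c(names(rx$reactants), names(rx$products),
                if (!is.null(rx$hill)) rx$hill$modifier)
      if (!all(refd %in% object@species))
        msg <- c(msg, sprintf("reaction '%s' references unknown species", rx$name))
      if (rx$rate < 0)
        msg <- c(msg, sprintf("reaction '%s' has a negative rate", rx$name))
    }
    for (grp in object@promoterGroups) {
      if (!all(grp %in% object@species))
        msg <- c(msg, "promoter group references unknown species")
      else if (sum(object@initialState[grp]) != 1L)
        msg <- c(msg, "exactly one promoter indicator must be active per group")
    }
    if (!all(object@observed %in% object@species))
      msg <- c(msg, "observed species must be in the species list")
    if (length(msg)) msg else TRUE
  })

#' Define a single reaction
#'
#' @param name short label.
#' @param reactants,products named integer vectors of stoichiometries (may be
#'   empty for pure production / degradation).
#' @param rate rate constant in s^-1 (units depend on reaction order).
#' @param type propensity rule: `"mass_action"`, `"hill_activation"` or
#'   `"hill_repression"`.
#' @param hill for Hill types, `list(modifier=, gBase=, gAmp=, K=, n=)`; the
#'   propensity is then `gBase + gAmp*x^n/(x^n+K)` (activation) or
#'   `gBase + gAmp/(x^n+K)` (repression) with `x` the modifier's count.
#' @param combMult multiplier for the homodimerisation combinatorial factor;
#'   the default `1` uses the exact-SSA convention `fd*N*(N-1)/2`, set `2`
#'   for the `fd*N*(N-1)` convention.
#' @return a list describing the reaction, for [ReactionNetwork()].
#' @export
reaction <- function(name, reactants = integer(), products = integer(), rate,
                     type = c("mass_action", "hill_activation", "hill_repression"),
                     hill = NULL, combMult = 1) {
  type <- match.arg(type)
  if (!is.finite(rate) || rate < 0)
    stop("rate constant must be finite and >= 0 (reaction '", name, "')")
  stopifnot(all(reactants >= 0), all(products >= 0),
            all(reactants == round(reactants)), all(products == round(products)))
  if (type != "mass_action" && is.null(hill))
    stop("Hill-type reactions need a 'hill' parameter list")
  list(name = name, reactants = reactants, products = products, rate = rate,
       type = type, hill = hill, combMult = combMult)
}

#' Construct a ReactionNetwork
#'
#' @param species ordered species names.
#' @param reactions list of [reaction()] objects.
#' @param initialState named integer vector (defaults to all zero).
#' @param promoterGroups list of character vectors of mutually exclusive
#'   promoter indicators.
#' @param observed tagged-protein names to record during simulation.
#' @return a [ReactionNetwork-class] object.
#' @export
ReactionNetwork <- function(species, reactions, initialState = NULL,
                            promoterGroups = list(), observed = character()) {
  if (is.null(initialState)) {
    initialState <- setNames(integer(length(species)), species)
  } else {
    initialState <- initialState[species]
    names(initialState) <- species
    initialState[is.na(initialState)] <- 0L
    storage.mode(initialState) <- "integer"
  }
  new("ReactionNetwork", species = species, reactions = reactions,
      initialState = initialState, promoterGroups = promoterGroups,
      observed = observed)
}

#' Simulation configuration
#'
#' @slot tEnd total simulated time per trajectory (s), including burn-in.
#' @slot deltaT frame interval (s).
#' @slot nTrajectories trajectories per replicate.
#' @slot nReplicates independent replicates.
#' @slot burnIn time discarded before the first recorded frame (s).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(tEnd = "numeric", deltaT = "numeric",
                 nTrajectories = "integer", nReplicates = "integer",
                 burnIn = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@tEnd > object@deltaT && object@deltaT > 0))
      msg <- c(msg, "need tEnd > deltaT > 0")
    if (object@burnIn < 0) msg <- c(msg, "burnIn must be >= 0")
    if (object@burnIn >= object@tEnd) msg <- c(msg, "burnIn must be < tEnd")
    if (object@nTrajectories < 1L || object@nReplicates < 1L)
      msg <- c(msg, "trajectory and replicate counts must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a SimulationConfig
#'
#' @param tEnd total simulated time (s), burn-in included.
#' @param deltaT frame interval (s); 300 s by default.
#' @param nTrajectories,nReplicates ensemble sizes.
#' @param burnIn discarded initial transient (s); 12 h by default.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class] object.
#' @export
SimulationConfig <- function(tEnd, deltaT = 300, nTrajectories = 1L,
                             nReplicates = 1L, burnIn = 12 * 3600, seed = 1L) {
  new("SimulationConfig", tEnd = as.numeric(tEnd), deltaT = as.numeric(deltaT),
      nTrajectories = as.integer(nTrajectories),
      nReplicates = as.integer(nReplicates), burnIn = as.numeric(burnIn),
      seed = as.integer(seed))
}

#' Truncated CME state space with sink
#'
#' Protein-count axes track the range `0..cardinality-1`; promoter axes are
#' discrete flags.  A single absorbing sink state, appended last, aggregates
#' every configuration with any count beyond its tracked range (Finite State
#' Projection truncation).
#'
#' @slot axes data.frame with columns `name`, `cardinality`, `kind`
#'   (`"count"` or `"promoter"`).
#' @slot dim total dimension, `prod(cardinality) + 1`.
#' @slot sinkIndex linear index of the sink (== `dim`).
#' @export
setClass("FSPStateSpace",
  representation(axes = "data.frame", dim = "integer", sinkIndex = "integer"),
  validity = function(object) {
    if (any(object@axes$cardinality < 1L))
      return("axis cardinalities must be >= 1")
    if (object@dim != prod(object@axes$cardinality) + 1L)
      return("dim must equal prod(cardinalities) + 1 (sink)")
    if (object@sinkIndex != object@dim) return("sink must be the last index")
    TRUE
  })

#' CME generator (rate) matrix over a state space
#'
#' Convention: `W[j, i]` is the rate from state `i` to state `j`; diagonal
#' entries hold minus the total outflow, so every column sums to zero.  Flux
#' out of the tracked range is routed to the sink row; the sink column is
#' zero (absorbing).
#'
#' @slot W sparse rate matrix (s^-1 entries).
#' @slot space the [FSPStateSpace-class] the matrix lives on.
#' @export
setClass("GeneratorMatrix",
  representation(W = "Matrix", space = "FSPStateSpace"),
  validity = function(object) {
    if (nrow(object@W) != object@space@dim) return("W dimension mismatch")
    if (nrow(object@W) != ncol(object@W)) return("W must be square")
    TRUE
  })

#' Column-stochastic propagator matrix
#'
#' `P[j, i]` is the probability of reaching state `j` from state `i` over the
#' horizon.  Produced by matrix exponentiation of a generator (continuous
#' time) or as a per-frame Maximum Caliber transition matrix (discrete time).
#'
#' @slot P dense column-stochastic matrix.
#' @slot horizon time propagated, in seconds (continuous) or frames
#'   (discrete; see `unit`).
#' @slot unit `"seconds"` or `"frames"`.
#' @slot space the underlying [FSPStateSpace-class].
#' @export
setClass("PropagatorMatrix",
  representation(P = "matrix", horizon = "numeric", unit = "character",
                 space = "FSPStateSpace"),
  validity = function(object) {
    if (nrow(object@P) != ncol(object@P)) return("P must be square")
    if (nrow(object@P) != object@space@dim) return("P dimension mismatch")
    cs <- colSums(object@P)
    if (any(abs(cs - 1) > 1e-8)) return("columns must sum to 1")
    if (min(object@P) < -1e-12) return("entries must be non-negative")
    TRUE
  })

#' Maximum Caliber per-frame path distribution
#'
#' Probabilities of the per-frame micro-trajectory labels conditioned on the
#' current state: `(l_alpha, l_A)` for one gene, `(l_alpha, l_A, l_beta,
#' l_B)` for the toggle switch.  `l_alpha` counts productions in the frame
#' (0..M) and `l_A` the proteins surviving from the previous frame (0..N).
#'
#' @slot state conditioning protein count(s).
#' @slot probs probability array, dimensions `(M+1, N_A+1)` or
#'   `(M+1, N_A+1, M+1, N_B+1)`.
#' @slot logQ log partition function.
#' @slot M per-frame production cap.
#' @export
setClass("PathDistribution",
  representation(state = "integer", probs = "array", logQ = "numeric",
                 M = "integer"),
  validity = function(object) {
    if (abs(sum(object@probs) - 1) > 1e-12)
      return("path probabilities must sum to 1")
    if (min(object@probs) < 0) return("negative path probability")
    TRUE
  })

#' Pooled m-frame transition counts
#'
#' Transitions are taken between frames `0 -> m, m -> 2m, ...` within each
#' trajectory (non-overlapping windows) and pooled across trajectories.
#'
#' @slot m frames per transition window.
#' @slot deltaT frame interval of the underlying data (s).
#' @slot from,to integer matrices of origin/destination states, one row per
#'   distinct transition (1 column for one gene, 2 for the toggle switch).
#' @slot n observed multiplicity of each distinct transition.
#' @slot nTransitions total number of windows counted.
#' @export
setClass("TransitionCounts",
  representation(m = "integer", deltaT = "numeric", from = "matrix",
                 to = "matrix", n = "integer", nTransitions = "integer"),
  validity = function(object) {
    if (nrow(object@from) != nrow(object@to) ||
        nrow(object@from) != length(object@n))
      return("from/to/n must align")
    if (any(object@n < 0L)) return("multiplicities must be >= 0")
    if (sum(object@n) != object@nTransitions)
      return("nTransitions must equal sum(n)")
    TRUE
  })

#' Result of one maximum-likelihood fit
#'
#' @slot model one of `"dm"`, `"cgm"`, `"maxcal"`.
#' @slot circuit `"sgaa"` or `"ts"`.
#' @slot params fitted parameters (named, s^-1 for rates; Lagrange
#'   multipliers are dimensionless).
#' @slot logLik maximised log-likelihood.
#' @slot effectiveRates named vector `peff`, `peffStar`, `reff` (s^-1).
#' @slot m,nmax,deltaT settings the fit was run with.
#' @slot replicate replicate index.
#' @slot convergence TRUE if the best start converged.
#' @slot diagnostics list: optimiser trace, mode locations, timing
#'   (informational), warnings.
#' @export
setClass("InferenceResult",
  representation(model = "character", circuit = "character",
                 params = "numeric", logLik = "numeric",
                 effectiveRates = "numeric", m = "integer", nmax = "integer",
                 deltaT = "numeric", replicate = "integer",
                 convergence = "logical", diagnostics = "list"),
  validity = function(object) {
    if (!object@model %in% c("dm", "cgm", "maxcal")) return("unknown model")
    if (!object@circuit %in% c("sgaa", "ts")) return("unknown circuit")
    TRUE
  })
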