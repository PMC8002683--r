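#' Default generator rate constants
#'
#' Rate constants of the fine-grained benchmark generators: the single-gene
#' auto-activation (SGAA) circuit with mRNA, monomer, dimer and a two-state
#' promoter, and the symmetric two-gene toggle switch (TS) with a three-state
#' promoter.  All values in s^-1.
#'
#' @param circuit `"sgaa"` or `"ts"`.
#' @return named numeric vector of rate constants.
#' @export
defaultRates <- function(circuit = c("sgaa", "ts")) {
  circuit <- match.arg(circuit)
  if (circuit == "sgaa") {
    c(g = 0.05, d = 0.2, p = 0.02, r = 1.0e-3,
      fd = 5.0e-3, bd = 50.0, fp = 6.0e-3, bp = 3.0e-5, gStar = 0.5)
  } else {
    c(g3 = 0.5, g3Star = 2.5e-3, d3 = 0.5, p3 = 0.02, r3 = 1.0e-3,
      f3 = 3.5e-6, b3 = 2.0e-5)
  }
}

#' True effective rates of a generator
#'
#' The model-independent summaries used to score inference accuracy: basal
#' production `peff`, activated (SGAA) or repressed (TS) production
#' `peffStar`, and per-capita degradation `reff`.  For the fine-grained
#' generators these follow from the steady-state mRNA level: SGAA
#' `peff = p*(g/d)`, `peffStar = p*(gStar/d)`, `reff = r`; TS
#' `peff = p3*(g3/d3)`, `peffStar = p3*(g3Star/d3)`, `reff = r3`.
#'
#' @param circuit `"sgaa"` or `"ts"`.
#' @param params generator rate constants; defaults to [defaultRates()].
#' @return named vector `peff`, `peffStar`, `reff` (s^-1).
#' @export
trueEffectiveRates <- function(circuit = c("sgaa", "ts"),
                               params = defaultRates(circuit)) {
  circuit <- match.arg(circuit)
  if (circuit == "sgaa") {
    c(peff = unname(params["p"] * params["g"] / params["d"]),
      peffStar = unname(params["p"] * params["gStar"] / params["d"]),
      reff = unname(params["r"]))
  } else {
    c(peff = unname(params["p3"] * params["g3"] / params["d3"]),
      peffStar = unname(params["p3"] * params["g3Star"] / params["d3"]),
      reff = unname(params["r3"]))
  }
}

#' Build the SGAA generator network
#'
#' The fine-grained single-gene auto-activation scheme: mRNA `a` transcribed
#' at `g` (basal promoter) or `gStar` (activated promoter), translated to
#' monomer `A`, which dimerises to `A2`; the dimer binds the promoter to
#' activate it.  The promoter-bound dimer is sequestered: binding consumes
#' one free `A2` and unbinding restores it.
#'
#' @param params named rates `g, d, p, r, fd, bd, fp, bp, gStar` (s^-1);
#'   see [defaultRates()].
#' @param halveDimerisation if `TRUE` (default) the homodimerisation
#'   propensity is `fd*N*(N-1)/2` (exact-SSA combinatorial convention);
#'   if `FALSE`, `fd*N*(N-1)`.
#' @return a [ReactionNetwork-class] with species
#'   `a, A, A2, alpha, alphaStar`, observing `A`.
#' @export
buildSGAAGenerator <- function(params = defaultRates("sgaa"),
                               halveDimerisation = TRUE) {
  p <- as.list(params)
  if (any(unlist(p) < 0)) stop("all rate constants must be >= 0")
  if (p$gStar < p$g)
    warning("gStar < g: activation would lower expression")
  rx <- list(
    reaction("transcription_basal", c(alpha = 1L), c(alpha = 1L, a = 1L), p$g),
    reaction("mrna_decay", c(a = 1L), integer(), p$d),
    reaction("translation", c(a = 1L), c(a = 1L, A = 1L), p$p),
    reaction("protein_decay", c(A = 1L), integer(), p$r),
    reaction("dimerisation", c(A = 2L), c(A2 = 1L), p$fd,
             combMult = if (halveDimerisation) 1 else 2),
    reaction("dimer_dissociation", c(A2 = 1L), c(A = 2L), p$bd),
    reaction("promoter_binding", c(alpha = 1L, A2 = 1L), c(alphaStar = 1L), p$fp),
    reaction("promoter_release", c(alphaStar = 1L), c(alpha = 1L, A2 = 1L), p$bp),
    reaction("transcription_active", c(alphaStar = 1L),
             c(alphaStar = 1L, a = 1L), p$gStar))
  ReactionNetwork(
    species = c("a", "A", "A2", "alpha", "alphaStar"),
    reactions = rx,
    initialState = c(alpha = 1L),
    promoterGroups = list(c("alpha", "alphaStar")),
    observed = "A")
}

#' Build the toggle-switch generator network
#'
#' The symmetric two-gene mutual-repression scheme: one promoter with three
#' mutually exclusive states — basal `alpha` (both mRNAs at `g3`), `alphaStar`
#' (monomer `A` bound; mRNA `b` repressed to `g3Star`) and `alphaPrime`
#' (monomer `B` bound; mRNA `a` repressed to `g3Star`).  Bound monomers are
#' sequestered from the free pool.
#'
#' @param params named rates `g3, g3Star, d3, p3, r3, f3, b3` (s^-1);
#'   see [defaultRates()].
#' @return a [ReactionNetwork-class] with species
#'   `a, b, A, B, alpha, alphaStar, alphaPrime`, observing `A` and `B`.
#' @export
buildTSGenerator <- function(params = defaultRates("ts")) {
  p <- as.list(params)
  if (any(unlist(p) < 0)) stop("all rate constants must be >= 0")
  if (p$g3Star > p$g3)
    warning("g3Star > g3: binding would enhance, not repress")
  rx <- list(
    # basal promoter: both genes at full rate
    reaction("transcription_a_basal", c(alpha = 1L), c(alpha = 1L, a = 1L), p$g3),
    reaction("transcription_b_basal", c(alpha = 1L), c(alpha = 1L, b = 1L), p$g3),
    # A bound (alphaStar): a at g3, b repressed
    reaction("transcription_a_Abound", c(alphaStar = 1L),
             c(alphaStar = 1L, a = 1L), p$g3),
    reaction("transcription_b_Abound", c(alphaStar = 1L),
             c(alphaStar = 1L, b = 1L), p$g3Star),
    # B bound (alphaPrime): a repressed, b at g3
    reaction("transcription_a_Bbound", c(alphaPrime = 1L),
             c(alphaPrime = 1L, a = 1L), p$g3Star),
    reaction("transcription_b_Bbound", c(alphaPrime = 1L),
             c(alphaPrime = 1L, b = 1L), p$g3),
    reaction("mrna_a_decay", c(a = 1L), integer(), p$d3),
    reaction("mrna_b_decay", c(b = 1L), integer(), p$d3),
    reaction("translation_A", c(a = 1L), c(a = 1L, A = 1L), p$p3),
    reaction("translation_B", c(b = 1L), c(b = 1L, B = 1L), p$p3),
    reaction("protein_A_decay", c(A = 1L), integer(), p$r3),
    reaction("protein_B_decay", c(B = 1L), integer(), p$r3),
    reaction("A_binding", c(alpha = 1L, A = 1L), c(alphaStar = 1L), p$f3),
    reaction("A_release", c(alphaStar = 1L), c(alpha = 1L, A = 1L), p$b3),
    reaction("B_binding", c(alpha = 1L, B = 1L), c(alphaPrime = 1L), p$f3),
    reaction("B_release", c(alphaPrime = 1L), c(alpha = 1L, B = 1L), p$b3))
  ReactionNetwork(
    species = c("a", "b", "A", "B", "alpha", "alphaStar", "alphaPrime"),
    reactions = rx,
    initialState = c(alpha = 1L),
    promoterGroups = list(c("alpha", "alphaStar", "alphaPrime")),
    observed = c("A", "B"))
}

#' Simple birth-death network
#'
#' Production at constant rate `lambda`, per-capita degradation at `mu`.
#' Its stationary law is Poisson(lambda/mu); used widely as an analytic
#' reference.
#'
#' @param lambda production rate (s^-1).
#' @param mu per-capita degradation rate (s^-1).
#' @param A0 initial count.
#' @return a [ReactionNetwork-class] observing `A`.
#' @export
birthDeathNetwork <- function(lambda, mu, A0 = 0L) {
  ReactionNetwork(
    species = "A",
    reactions = list(
      reaction("birth", integer(), c(A = 1L), lambda),
      reaction("death", c(A = 1L), integer(), mu)),
    initialState = c(A = as.integer(A0)),
    observed = "A")
}

#' Evaluate reaction propensities at a state
#'
#' Mass-action propensities use the combinatorial convention
#' `rate * prod choose(x, nu)` (times `combMult`); Hill reactions evaluate
#' their saturating rate law at the modifier's count.
#'
#' @param network a [ReactionNetwork-class].
#' @param state named integer vector over the network's species.
#' @return named numeric vector of propensities (s^-1), one per reaction.
#' @export
propensities <- function(network, state) {
  state <- state[network@species]
  vapply(network@reactions, function(rx) {
    if (rx$type == "mass_action") {
      a <- rx$rate * rx$combMult
      for (s in names(rx$reactants)) {
        nu <- rx$reactants[[s]]
        a <- a * choose(state[[s]], nu)
      }
      a
    } else {
      x <- state[[rx$hill$modifier]]
      xn <- x^rx$hill$n
      if (rx$type == "hill_activation")
        rx$hill$gBase + if (xn + rx$hill$K > 0) rx$hill$gAmp * xn / (xn + rx$hill$K) else 0
      else {
        if (xn + rx$hill$K <= 0)
          stop("Hill repression propensity undefined: x^n + K = 0")
        rx$hill$gBase + rx$hill$gAmp / (xn + rx$hill$K)
      }
    }
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(network@reactions, `[[`, character(1), "name"))
}

# encode a network for the C++ SSA kernel
.encodeNetwork <- function(network) {
  sp <- network@species
  nr <- length(network@reactions)
  nuIn <- matrix(0L, length(sp), nr, dimnames = list(sp, NULL))
  nuDelta <- nuIn
  rate <- numeric(nr); rtype <- integer(nr); combMult <- rep(1, nr)
  hpar <- matrix(0, 5, nr)
  for (j in seq_len(nr)) {
    rx <- network@reactions[[j]]
    for (s in names(rx$reactants)) {
      nuIn[s, j] <- rx$reactants[[s]]
      nuDelta[s, j] <- nuDelta[s, j] - rx$reactants[[s]]
    }
    for (s in names(rx$products))
      nuDelta[s, j] <- nuDelta[s, j] + rx$products[[s]]
    rate[j] <- rx$rate
    combMult[j] <- rx$combMult
    rtype[j] <- switch(rx$type, mass_action = 0L, hill_activation = 1L,
                       hill_repression = 2L)
    if (rtype[j] > 0L)
      hpar[, j] <- c(match(rx$hill$modifier, sp) - 1L, rx$hill$gBase,
                     rx$hill$gAmp, rx$hill$K, rx$hill$n)
  }
  list(nuIn = nuIn, nuDelta = nuDelta, rate = rate, rtype = rtype,
       combMult = combMult, hpar = hpar,
       recordIdx = match(network@observed, sp) - 1L)
}

#' Simulate a network with the exact Gillespie algorithm
#'
#' Direct-method stochastic simulation: exponentially distributed waiting
#' times with the total propensity, reaction chosen proportionally to its
#' propensity.  The state is recorded at every frame time
#' `burnIn + k*deltaT` (value immediately before/at the frame).  Only the
#' network's observed (tagged) species are recorded.  Reproducible under
#' `set.seed()`; `simulateSSA` seeds from `config@seed`.
#'
#' @param network a [ReactionNetwork-class].
#' @param config a [SimulationConfig-class]; `nTrajectories` trajectories are
#'   returned (replicates are handled by [generateBenchmarkEnsemble()]).
#' @return list of [FrameSeries-class], one per trajectory.
#' @export
simulateSSA <- function(network, config) {
  validObject(network); validObject(config)
  enc <- .encodeNetwork(network)
  set.seed(config@seed)
  lapply(seq_len(config@nTrajectories), function(i) {
    m <- ssa_simulate_cpp(network@initialState, enc$nuIn, enc$nuDelta,
                          enc$rate, enc$rtype, enc$combMult, enc$hpar,
                          config@tEnd, config@deltaT, config@burnIn,
                          enc$recordIdx)
    FrameSeries(m, config@deltaT, network@observed)
  })
}

#' Generate (and optionally write) a benchmark ensemble
#'
#' Simulates `nReplicates` independent sets of `nTrajectories` trajectories
#' from a named circuit at its benchmark rates, optionally writing each
#' replicate to disk as TSV trajectories plus a JSON manifest
#' (see [writeTrajectories()]).
#'
#' @param circuit `"sgaa"` or `"ts"`.
#' @param config a [SimulationConfig-class].
#' @param params generator rates; defaults to [defaultRates()].
#' @param outDir if non-NULL, directory to write replicate subdirectories
#'   `replicate_1, ...` into.
#' @return invisibly, a list with one element per replicate, each a list of
#'   [FrameSeries-class]; attribute `"manifests"` holds written manifests.
#' @export
generateBenchmarkEnsemble <- function(circuit = c("sgaa", "ts"), config,
                                      params = NULL, outDir = NULL) {
  circuit <- match.arg(circuit)
  if (is.null(params)) params <- defaultRates(circuit)
  network <- if (circuit == "sgaa") buildSGAAGenerator(params)
             else buildTSGenerator(params)
  reps <- vector("list", config@nReplicates)
  manifests <- vector("list", config@nReplicates)
  for (r in seq_len(config@nReplicates)) {
    repSeed <- config@seed + (r - 1L) * 10000L
    cfg <- SimulationConfig(config@tEnd, config@deltaT, config@nTrajectories,
                            1L, config@burnIn, repSeed)
    reps[[r]] <- simulateSSA(network, cfg)
    if (!is.null(outDir)) {
      dir <- file.path(outDir, sprintf("replicate_%d", r))
      manifests[[r]] <- writeTrajectories(
        reps[[r]], dir, circuit = circuit, params = params, seed = repSeed)
    }
  }
  attr(reps, "manifests") <- manifests
  invisible(reps)
}
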