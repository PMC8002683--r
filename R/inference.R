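#' Count m-frame transitions
#'
#' Transitions are taken between frames `0 -> m, m -> 2m, ...` within each
#' trajectory (non-overlapping windows — the likelihood factorises over
#' independent windows, sliding windows would double-count), then pooled
#' across trajectories (the likelihood is a product over independent
#' trajectories, so counts add).
#'
#' @param trajectories list of [FrameSeries-class] with a common `deltaT`.
#' @param m window length in frames (>= 1).
#' @return a [TransitionCounts-class]; total windows equal
#'   `sum(floor((nFrames - 1)/m))`.
#' @export
countTransitions <- function(trajectories, m) {
  stopifnot(length(trajectories) >= 1, m >= 1, m == round(m))
  m <- as.integer(m)
  dts <- vapply(trajectories, deltaT, numeric(1))
  if (max(dts) - min(dts) > 1e-9)
    stop("trajectories have mixed frame intervals")
  d <- ncol(counts(trajectories[[1]]))
  fromAll <- toAll <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    cts <- counts(trajectories[[i]])
    if (ncol(cts) != d) stop("trajectories mix one- and two-gene data")
    idx <- seq(1L, nrow(cts), by = m)
    if (length(idx) < 2) next
    fromAll[[i]] <- cts[idx[-length(idx)], , drop = FALSE]
    toAll[[i]] <- cts[idx[-1], , drop = FALSE]
  }
  fromM <- do.call(rbind, fromAll)
  toM <- do.call(rbind, toAll)
  if (is.null(fromM)) stop("no complete m-frame window in the data")
  key <- do.call(paste, c(lapply(seq_len(d), function(j) fromM[, j]),
                          lapply(seq_len(d), function(j) toM[, j]),
                          sep = ","))
  tab <- table(key)
  first <- match(names(tab), key)
  new("TransitionCounts", m = m, deltaT = dts[1],
      from = fromM[first, , drop = FALSE], to = toM[first, , drop = FALSE],
      n = as.integer(tab), nTransitions = as.integer(sum(tab)))
}

#' Choose the transition window m from dwell times
#'
#' Heuristic for the likelihood window: split the pooled counts into two
#' occupancy clusters (2-means), measure the mean dwell time (in frames) of
#' each cluster along every trajectory, and return the geometric mean of the
#' two dwell times, rounded and clamped to `[1, nFrames/10]`.  Windows on the
#' dwell-time scale avoid spurious multi-protein jumps between consecutive
#' frames that the per-frame path model cannot represent.  Degenerate
#' (unimodal/constant) data return `m = 1` with a warning.
#'
#' @param trajectories list of [FrameSeries-class].
#' @param species column to cluster on (default 1; for the toggle switch the
#'   two marginals are exchangeable).
#' @return integer `m` with attribute `diagnostics` (cluster centres, dwell
#'   times).
#' @export
selectM <- function(trajectories, species = 1L) {
  pooled <- unlist(lapply(trajectories, function(t) counts(t)[, species]))
  nf <- min(vapply(trajectories, nFrames, integer(1)))
  mMax <- max(1L, floor(nf / 10))
  if (stats::sd(pooled) < 1e-9) {
    warning("constant data: m = 1")
    return(structure(1L, diagnostics = list(reason = "constant")))
  }
  km <- stats::kmeans(pooled, centers = range(pooled), iter.max = 50)
  ctr <- sort(as.vector(km$centers))
  frac <- min(km$size) / length(pooled)
  if (diff(ctr) < 2 || frac < 0.02) {
    warning("no clear low/high occupancy split: m = 1")
    return(structure(1L, diagnostics = list(centres = ctr, reason = "unimodal")))
  }
  thr <- mean(ctr)
  dwell <- c(low = 0, high = 0); nruns <- c(low = 0, high = 0)
  for (t in trajectories) {
    z <- counts(t)[, species] >= thr
    r <- rle(z)
    dwell["low"] <- dwell["low"] + sum(r$lengths[!r$values])
    nruns["low"] <- nruns["low"] + sum(!r$values)
    dwell["high"] <- dwell["high"] + sum(r$lengths[r$values])
    nruns["high"] <- nruns["high"] + sum(r$values)
  }
  if (any(nruns == 0)) {
    warning("one occupancy state never visited: m = 1")
    return(structure(1L, diagnostics = list(centres = ctr, reason = "one-state")))
  }
  mean_dwell <- dwell / nruns
  m <- as.integer(min(max(1, round(sqrt(prod(mean_dwell)))), mMax))
  structure(m, diagnostics = list(centres = ctr, meanDwellFrames = mean_dwell,
                                  clamp = c(1L, mMax)))
}

#' Choose a kinetic-scale window for exact-propagator models
#'
#' The detailed and coarse-grain models propagate an exact CME over any
#' horizon, so their likelihood is valid at any window; short windows retain
#' the within-state relaxation kinetics that dwell-scale windows average
#' away (the count-transition kernel over windows much longer than the
#' protein lifetime constrains only the stationary law and the slow
#' switching, leaving the overall timescale nearly free).  This returns one
#' mean protein lifetime per window, `m = round(1/(rHat*deltaT))`, clamped
#' to `[1, selectM(trajectories)]`.
#'
#' The per-capita loss rate `rHat` comes from the within-state fluctuation
#' of consecutive-frame differences: for a birth-death process at local
#' equilibrium around mean `Nbar`, `Var(dN) = 2*Nbar*(1 - exp(-r*deltaT))`,
#' so `rHat = -log(1 - Var(dN)/(2*Nbar))/deltaT`, pooled over the low/high
#' occupancy clusters (a plain downward-flux estimate underestimates `r`
#' badly once `deltaT` is a sizable fraction of the lifetime, because
#' births cancel most deaths within a frame).
#'
#' @param trajectories list of [FrameSeries-class].
#' @return integer `m` with attribute `diagnostics` (`rHat` and the clamp).
#' @export
selectKineticM <- function(trajectories) {
  dt <- deltaT(trajectories[[1]])
  x <- unlist(lapply(trajectories, function(t) counts(t)[, 1]))
  thr <- tryCatch({
    km <- stats::kmeans(x, centers = range(x), iter.max = 50)
    mean(km$centers)
  }, error = function(e) stats::median(x) + 0.5)
  num <- 0; den <- 0
  for (t in trajectories) {
    v <- counts(t)[, 1]
    for (cl in list(v < thr, v >= thr)) {
      keep <- cl[-length(cl)] & cl[-1]         # both frames in the cluster
      if (sum(keep) < 10) next
      d <- diff(v)[keep]
      nbar <- mean(v[-length(v)][keep])
      if (nbar < 1) next
      frac <- min(stats::var(d) / (2 * nbar), 0.95)
      num <- num + sum(keep) * (-log(1 - frac) / dt)
      den <- den + sum(keep)
    }
  }
  rHat <- if (den > 0) num / den else 1 / dt
  mUp <- as.integer(suppressWarnings(selectM(trajectories)))
  m <- as.integer(min(max(1, round(1 / (max(rHat, 1e-6) * dt))), mUp))
  structure(m, diagnostics = list(rHat = rHat, clamp = c(1L, mUp)))
}

#' Transition log-likelihood
#'
#' `sum(omega * log P)` over the observed transitions, with model
#' probabilities floored at `1e-300` (a warning counter in the attribute
#' `nFloored` reports transitions the model deems impossible).
#'
#' @param Pobs column-stochastic (or substochastic, sink dropped) matrix of
#'   observed-state transition probabilities, `Pobs[j+1, i+1] = P(i -> j)`
#'   for one gene, joint linear indices for two.
#' @param omega a [TransitionCounts-class].
#' @param nmax tracked range used to linearise two-gene states.
#' @return log-likelihood (scalar) with attribute `nFloored`.
#' @export
logLikelihood <- function(Pobs, omega, nmax = NULL) {
  d <- ncol(omega@from)
  if (d == 1) {
    i <- omega@from[, 1] + 1L
    j <- omega@to[, 1] + 1L
    if (max(omega@from, omega@to) + 1L > nrow(Pobs))
      stop("observed counts exceed the tracked range: raise nmax")
  } else {
    if (is.null(nmax)) nmax <- as.integer(round(sqrt(nrow(Pobs))))
    if (max(omega@from, omega@to) >= nmax)
      stop("observed counts exceed the tracked range: raise nmax")
    i <- omega@from[, 1] + nmax * omega@from[, 2] + 1L
    j <- omega@to[, 1] + nmax * omega@to[, 2] + 1L
  }
  pr <- Pobs[cbind(j, i)]
  nf <- sum(pr < 1e-300)
  structure(sum(omega@n * log(pmax(pr, 1e-300))), nFloored = nf)
}

#' Automatic FSP bound from data
#'
#' `ceil(1.5 * max observed count)`, but at least `max + 20`: comfortably
#' above the largest count seen so that truncation leakage is negligible.
#'
#' @param trajectories list of [FrameSeries-class] (or a
#'   [TransitionCounts-class]).
#' @return integer Nmax.
#' @export
autoNmax <- function(trajectories) {
  mx <- if (is(trajectories, "TransitionCounts"))
    max(trajectories@from, trajectories@to)
  else max(vapply(trajectories, function(t) max(counts(t)), numeric(1)))
  as.integer(max(ceiling(1.5 * mx), mx + 20))
}

# observed-state transition matrix over one m-window for any registered model
.modelTransition <- function(model, circuit, params, nmax, deltaT, m) {
  if (model == "dm") {
    space <- if (circuit == "sgaa") sgaaDMSpace(nmax) else tsDMSpace(nmax)
    W <- if (circuit == "sgaa") sgaaDMGenerator(params, space)
         else tsDMGenerator(params, space)
    .dmObservedTransition(W, m * deltaT)
  } else if (model == "cgm") {
    space <- cgmSpace(circuit, nmax)
    W <- cgmGenerator(params, space)
    P <- propagate(W, m * deltaT)
    P@P[-space@sinkIndex, -space@sinkIndex, drop = FALSE]
  } else {
    space <- maxcalSpace(circuit, nmax)
    P1 <- if (circuit == "sgaa") transitionMatrixSGAA(params, space)
          else transitionMatrixTS(params, space)
    Pm <- matrixPower(P1, m)
    Pm@P[-space@sinkIndex, -space@sinkIndex, drop = FALSE]
  }
}

# parameter names per model/circuit; rates are optimised in log space,
# Lagrange multipliers untransformed
.paramInfo <- function(model, circuit) {
  if (model == "dm") {
    nm <- if (circuit == "sgaa") c("g1", "g1Star", "r1", "f1", "b1")
          else c("g4", "g4Star", "r4", "f4", "b4")
    list(names = nm, logScale = rep(TRUE, 5),
         lo = rep(-18, 5), hi = rep(3, 5))
  } else if (model == "cgm") {
    nm <- if (circuit == "sgaa") c("g2", "g2Star", "K", "r2")
          else c("g5", "g5Star", "K", "r5")
    # K is a count^n scale and may legitimately reach ~1e6
    list(names = nm, logScale = rep(TRUE, 4),
         lo = rep(-18, 4), hi = c(3, 3, 15, 3))
  } else {
    nm <- if (circuit == "sgaa") c("hAlpha", "hA", "KA")
          else c("hAlpha", "hA", "KAalpha", "KAbeta")
    k <- length(nm)
    list(names = nm, logScale = rep(FALSE, k), lo = rep(-60, k),
         hi = rep(60, k))
  }
}

# method-of-moments starting values; when raw trajectories are available the
# per-capita loss rate comes from single-frame downward flux and the
# promoter-switching guesses from threshold-crossing dwell times
.momInit <- function(model, circuit, omega, deltaT, trajectories = NULL) {
  cts <- c(omega@from[, 1], omega@to[, 1])
  wts <- rep(omega@n, 2)
  mu <- stats::weighted.mean(cts, wts)
  km <- tryCatch(stats::kmeans(rep(cts, wts), centers = range(cts)),
                 error = function(e) NULL)
  ctr <- if (is.null(km) || abs(diff(range(cts))) < 2) c(mu * 0.5, mu * 1.5)
         else sort(as.vector(km$centers))
  NL <- max(ctr[1], 0.5); NH <- max(ctr[2], NL + 1)
  dwellSec <- c(low = 20, high = 20) * omega@m * omega@deltaT
  if (!is.null(trajectories)) {
    x <- unlist(lapply(trajectories, function(t) counts(t)[, 1]))
    dx <- unlist(lapply(trajectories, function(t) diff(counts(t)[, 1])))
    rHat <- mean(pmax(-dx, 0)) / max(mean(x), 0.5) / deltaT
    dg <- attr(suppressWarnings(selectM(trajectories)), "diagnostics")
    if (!is.null(dg$meanDwellFrames))
      dwellSec <- dg$meanDwellFrames * deltaT
  } else {
    drop <- pmax(omega@from[, 1] - omega@to[, 1], 0)
    rHat <- stats::weighted.mean(drop, omega@n) /
      max(mu, 0.5) / (omega@m * omega@deltaT)
  }
  rHat <- min(max(rHat, 1e-5), 0.1)
  if (model == "dm") {
    par <- c(NL * rHat, NH * rHat, rHat,
             1 / (dwellSec[["low"]] * NL), 1 / dwellSec[["high"]])
  } else if (model == "cgm") {
    par <- c(NL * rHat, (NH - NL) * rHat, ((NL + NH) / 2)^2, rHat)
  } else {
    # stationary balance: mean production per frame ~= N*(1-sigma);
    # invert the soft-geometric production field at the two cluster centres
    sig <- exp(-rHat * deltaT)
    hA <- log(sig / (1 - sig))
    effAt <- function(N) { mu <- max(N * rHat * deltaT, 0.02); log(mu / (1 + mu)) }
    KA <- (effAt(NH) - effAt(NL)) / (sig * (NH - NL))
    hAlpha <- effAt(NL) - KA * sig * NL
    par <- c(hAlpha, hA, KA)
    if (circuit == "ts") par <- c(par[1:2], 0.5 * KA, -abs(KA))
  }
  info <- .paramInfo(model, circuit)
  stats::setNames(par, info$names)
}

#' Maximise the transition likelihood for a registered model
#'
#' Derivative-free Nelder-Mead over log-transformed rates (Lagrange
#' multipliers are fitted untransformed), with seeded multi-start around a
#' method-of-moments initial guess.  For the Maximum Caliber model the
#' integer cap `M` is selected by an exhaustive grid with the multipliers
#' re-optimised per `M` (warm-started from the previous grid point) and ties
#' broken toward smaller `M`.
#'
#' @param model `"dm"`, `"cgm"` or `"maxcal"`.
#' @param circuit `"sgaa"` or `"ts"`.
#' @param omega a [TransitionCounts-class].
#' @param nmax FSP bound; default [autoNmax()] on the counted states.
#' @param deltaT frame interval (s); default from `omega`.
#' @param nStarts number of optimiser starts (default 5).
#' @param Mgrid integer grid for the MaxCal production cap (default
#'   `1:40`).
#' @param init optional named starting parameters overriding the
#'   method-of-moments guess.
#' @param seed seed for the start jitter.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param replicate replicate index recorded in the result.
#' @return an [InferenceResult-class].
#' @export
maximizeLikelihood <- function(model = c("dm", "cgm", "maxcal"),
                               circuit = c("sgaa", "ts"), omega,
                               nmax = NULL, deltaT = NULL, nStarts = 5L,
                               Mgrid = 1:40, init = NULL, seed = 1L,
                               maxit = NULL, trajectories = NULL,
                               replicate = 1L) {
  model <- match.arg(model); circuit <- match.arg(circuit)
  stopifnot(is(omega, "TransitionCounts"))
  if (is.null(nmax)) nmax <- autoNmax(omega)
  if (is.null(deltaT)) deltaT <- omega@deltaT
  if (is.null(maxit))
    maxit <- switch(model, dm = 1000L, cgm = 800L, maxcal = 400L)
  info <- .paramInfo(model, circuit)
  nCalls <- 0L; tCalls <- 0
  negll <- function(theta, extra = NULL) {
    # keep the simplex inside a sane per-parameter box (log scale for rates)
    if (any(theta < info$lo | theta > info$hi)) return(1e12)
    par <- theta
    par[info$logScale] <- exp(par[info$logScale])
    names(par) <- info$names
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch({
      plist <- c(as.list(par), extra)
      Pobs <- .modelTransition(model, circuit, plist, nmax, deltaT, omega@m)
      -as.numeric(logLikelihood(Pobs, omega, nmax = nmax))
    }, error = function(e) 1e12)
    nCalls <<- nCalls + 1L
    tCalls <<- tCalls + (proc.time()[["elapsed"]] - t0)
    if (!is.finite(val)) 1e12 else val
  }
  toTheta <- function(par) {
    th <- par
    th[info$logScale] <- log(pmax(par[info$logScale], 1e-12))
    pmin(pmax(th, info$lo), info$hi)   # keep starts inside the box
  }
  momPar <- .momInit(model, circuit, omega, deltaT, trajectories)
  basePar <- if (is.null(init)) momPar else {
    out <- momPar; out[names(init)] <- init; out
  }
  set.seed(seed)
  jitterOf <- function(centre) {
    th <- toTheta(centre) + stats::rnorm(length(centre), 0,
                                         ifelse(info$logScale, 0.6, 0.3))
    pmin(pmax(th, info$lo), info$hi)
  }
  runStarts <- function(extra, warm = NULL) {
    best <- NULL
    for (k in seq_len(nStarts)) {
      # start 1: the method-of-moments centre (or the warm start handed in);
      # even k: restart the simplex from the incumbent optimum (a fresh
      # simplex often escapes premature Nelder-Mead collapse); odd k: jitter
      th0 <- if (k == 1) {
        if (is.null(warm)) toTheta(basePar) else warm
      } else if (k %% 2L == 0L && !is.null(best)) best$par
      else jitterOf(basePar)
      opt <- stats::optim(th0, negll, extra = extra, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-8))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    best
  }
  suppressWarnings({
    if (model == "maxcal") {
      bestM <- NULL; warm <- NULL; grid <- sort(unique(as.integer(Mgrid)))
      fullStarts <- nStarts
      for (M in grid) {
        # the first grid point explores with the full multi-start; later
        # points are warm-started from the previous optimum with one restart
        nStarts <- if (is.null(warm)) fullStarts else min(2L, fullStarts)
        opt <- runStarts(extra = list(M = M), warm = warm)
        nStarts <- fullStarts
        warm <- opt$par
        if (is.null(bestM) || opt$value < bestM$value - 1e-9)
          bestM <- c(opt, list(M = M))   # strict improvement: ties keep smaller M
      }
      best <- bestM
      extra <- list(M = best$M)
    } else {
      best <- runStarts(extra = NULL)
      extra <- NULL
    }
  })
  if (best$value >= 1e12)
    stop("no optimiser start produced a finite likelihood; diagnostics: ",
         sprintf("model=%s circuit=%s m=%d nmax=%d", model, circuit,
                 omega@m, nmax))
  par <- best$par
  par[info$logScale] <- exp(par[info$logScale])
  names(par) <- info$names
  fitted <- c(as.list(par), extra)
  er <- suppressWarnings(tryCatch({
    if (model == "dm") dmEffectiveRates(fitted, circuit)
    else if (model == "cgm") cgmEffectiveRates(fitted, circuit)
    else maxcalEffectiveRates(fitted, maxcalSpace(circuit, nmax), deltaT,
                              circuit)
  }, error = function(e) {
    warning("effective-rate extraction failed: ", conditionMessage(e))
    c(peff = NA_real_, peffStar = NA_real_, reff = NA_real_)
  }))
  parOut <- unlist(fitted)
  new("InferenceResult", model = model, circuit = circuit,
      params = parOut, logLik = -best$value,
      effectiveRates = er[c("peff", "peffStar", "reff")],
      m = omega@m, nmax = as.integer(nmax), deltaT = deltaT,
      replicate = as.integer(replicate),
      convergence = best$convergence == 0,
      diagnostics = list(
        optim = best[c("counts", "convergence")],
        momInit = momPar,
        modes = attr(er, "modes"),
        nLikelihoodCalls = nCalls,
        meanCallSeconds = if (nCalls) tCalls / nCalls else NA_real_,
        totalCallSeconds = tCalls))
}

#' Run the replicate benchmark
#'
#' Generates (or accepts) a replicate ensemble from a named circuit, fits the
#' requested models to each replicate's pooled transition counts, extracts
#' effective rates, and aggregates mean and standard deviation across
#' replicates.  Wall-clock per-likelihood-call and total fit times are
#' recorded as informational fields only — they depend on hardware and are
#' never part of any accuracy statement.
#'
#' @param circuit `"sgaa"` or `"ts"`.
#' @param config a [SimulationConfig-class] for data generation (ignored if
#'   `replicates` is supplied).
#' @param models subset of `c("dm", "cgm", "maxcal")`.
#' @param params generator rates; defaults to [defaultRates()].
#' @param replicates optional pre-generated list (one element per replicate,
#'   each a list of [FrameSeries-class]).
#' @param m transition window override; by default the dwell-scale
#'   [selectM()] window is used for the MaxCal fit and the kinetic-scale
#'   [selectKineticM()] window for the DM and CGM fits, per replicate.
#' @param nmax FSP bound; default [autoNmax()] over all replicates.
#' @param Mgrid MaxCal production-cap grid.
#' @param nStarts optimiser starts per fit.
#' @param seed base seed for optimiser starts.
#' @return a `BenchmarkReport` list: `true` rates, per-model `fits`
#'   ([InferenceResult-class] per replicate), aggregated `summary`
#'   data.frame, and `failures`.
#' @export
runBenchmark <- function(circuit = c("sgaa", "ts"), config = NULL,
                         models = c("dm", "cgm", "maxcal"), params = NULL,
                         replicates = NULL, m = NULL, nmax = NULL,
                         Mgrid = 1:40, nStarts = 5L, seed = 1L) {
  circuit <- match.arg(circuit)
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(params)) params <- defaultRates(circuit)
  if (is.null(replicates)) {
    stopifnot(!is.null(config))
    replicates <- generateBenchmarkEnsemble(circuit, config, params)
  }
  if (is.null(nmax)) nmax <- autoNmax(unlist(replicates, recursive = FALSE))
  fits <- stats::setNames(vector("list", length(models)), models)
  failures <- list()
  for (r in seq_along(replicates)) {
    # window policy: dwell-scale windows for the MaxCal path model,
    # one-lifetime windows for the exact-propagator models (DM, CGM),
    # whose likelihood loses the overall timescale at dwell-scale windows
    # (see selectKineticM)
    mDwell <- if (is.null(m)) selectM(replicates[[r]]) else as.integer(m)
    mKin <- if (is.null(m)) selectKineticM(replicates[[r]]) else as.integer(m)
    for (mod in models) {
      mr <- if (mod == "maxcal") mDwell else mKin
      omega <- countTransitions(replicates[[r]], mr)
      res <- tryCatch(
        maximizeLikelihood(mod, circuit, omega, nmax = nmax,
                           nStarts = nStarts, Mgrid = Mgrid,
                           seed = seed + 97L * r,
                           trajectories = replicates[[r]], replicate = r),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[sprintf("%s_rep%d", mod, r)]] <- conditionMessage(res)
      } else {
        fits[[mod]] <- c(fits[[mod]], list(res))
      }
    }
  }
  truth <- trueEffectiveRates(circuit, params)
  summ <- do.call(rbind, lapply(models, function(mod) {
    if (!length(fits[[mod]])) return(NULL)
    er <- do.call(rbind, lapply(fits[[mod]], effectiveRates))
    tm <- vapply(fits[[mod]],
                 function(f) f@diagnostics$meanCallSeconds, numeric(1))
    tt <- vapply(fits[[mod]],
                 function(f) f@diagnostics$totalCallSeconds, numeric(1))
    data.frame(
      method = mod,
      peff = mean(er[, "peff"]),
      peff_sd = if (nrow(er) >= 2) stats::sd(er[, "peff"]) else NA_real_,
      peffStar = mean(er[, "peffStar"]),
      peffStar_sd = if (nrow(er) >= 2) stats::sd(er[, "peffStar"]) else NA_real_,
      reff = mean(er[, "reff"]),
      reff_sd = if (nrow(er) >= 2) stats::sd(er[, "reff"]) else NA_real_,
      unitOpSeconds = mean(tm), totalSeconds = mean(tt))
  }))
  structure(list(circuit = circuit, true = truth, fits = fits,
                 summary = summ, failures = failures,
                 nmax = nmax, nReplicates = length(replicates)),
            class = "BenchmarkReport")
}
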