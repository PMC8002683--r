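#' Build a truncated state space with sink
#'
#' Count axes track `0..Nmax-1`; any transition producing a count `>= Nmax`
#' is routed to a single absorbing sink state appended last.  With one
#' protein axis of cardinality 92 and a binary promoter axis the dimension is
#' `92*2 + 1 = 185`; with two protein axes of 59 and two binary promoter
#' flags, `59*59*2*2 + 1 = 13925`.
#'
#' @param countAxes named integer vector of protein-axis cardinalities
#'   (tracked counts `0..card-1`).
#' @param promoterAxes optional named integer vector of discrete promoter
#'   axes (cardinality = number of promoter states).
#' @param cap refuse state spaces larger than this (default 5e4): the dense
#'   propagator algebra downstream scales cubically.
#' @return an [FSPStateSpace-class].
#' @export
buildStateSpace <- function(countAxes, promoterAxes = NULL, cap = 5e4) {
  stopifnot(length(countAxes) >= 1, all(countAxes >= 1))
  axes <- data.frame(
    name = c(names(countAxes), names(promoterAxes)),
    cardinality = as.integer(c(countAxes, promoterAxes)),
    kind = c(rep("count", length(countAxes)),
             rep("promoter", length(promoterAxes))),
    stringsAsFactors = FALSE)
  d <- prod(axes$cardinality) + 1
  if (d > cap)
    stop(sprintf(paste0("state space dimension %d exceeds cap %d; lower Nmax ",
                        "or raise 'cap' knowingly"), d, cap))
  new("FSPStateSpace", axes = axes, dim = as.integer(d),
      sinkIndex = as.integer(d))
}

# all non-sink states as an integer matrix (one row per state, 0-based values,
# row order == linear index order; first axis varies fastest)
stateGrid <- function(space) {
  g <- do.call(expand.grid, lapply(space@axes$cardinality,
                                   function(k) 0:(k - 1L)))
  names(g) <- space@axes$name
  as.matrix(g)
}

# 1-based linear index of state rows (matrix columns in axis order);
# rows with any count-axis value >= cardinality map to the sink;
# values < 0 or promoter values out of range are an error for the caller.
stateIndex <- function(space, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  card <- space@axes$cardinality
  stride <- cumprod(c(1L, card[-length(card)]))
  idx <- as.vector(1L + states %*% stride)
  over <- rep(FALSE, nrow(states))
  for (j in seq_along(card)) over <- over | states[, j] >= card[j]
  idx[over] <- space@sinkIndex
  idx
}

#' Assemble a CME generator matrix from transition rules
#'
#' Each rule contributes one reaction channel: a state-change vector over the
#' axes and a vectorised propensity function evaluated on all tracked states.
#' Transitions leaving any tracked count range are routed to the sink, which
#' is absorbing; every column of the result sums to zero.
#'
#' @param rules list of `list(delta = , propensity = function(states))`:
#'   `delta` a named integer change per axis, `propensity` returning one
#'   non-negative rate (s^-1) per row of the 0-based state matrix.
#' @param space the [FSPStateSpace-class] to assemble over.
#' @return a [GeneratorMatrix-class].
#' @export
assembleGenerator <- function(rules, space) {
  states <- stateGrid(space)
  nState <- nrow(states)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (rule in rules) {
    delta <- integer(ncol(states))
    names(delta) <- colnames(states)
    delta[names(rule$delta)] <- as.integer(rule$delta)
    if (!all(names(rule$delta) %in% colnames(states)))
      stop("rule references an axis absent from the state space")
    a <- rule$propensity(states)
    if (length(a) != nState) stop("propensity must return one value per state")
    if (any(a < 0) || any(!is.finite(a))) stop("propensities must be finite and >= 0")
    keep <- a > 0
    if (!any(keep)) next
    tgt <- states[keep, , drop = FALSE] +
      matrix(delta, sum(keep), length(delta), byrow = TRUE)
    if (any(tgt < 0))
      stop("a rule with positive propensity leaves the lattice below zero")
    promoBad <- rep(FALSE, nrow(tgt))
    for (j in which(space@axes$kind == "promoter"))
      promoBad <- promoBad | tgt[, j] >= space@axes$cardinality[j]
    if (any(promoBad))
      stop("a rule with positive propensity leaves a promoter axis range")
    ii <- c(ii, stateIndex(space, tgt))
    jj <- c(jj, which(keep))
    xx <- c(xx, a[keep])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(space@dim, space@dim))
  Matrix::diag(W) <- Matrix::diag(W) - Matrix::colSums(W)
  new("GeneratorMatrix", W = W, space = space)
}

#' Propagate a generator over a time interval
#'
#' Computes the column-stochastic propagator `exp(W*tau)` by dense
#' scaling-and-squaring matrix exponentiation.
#'
#' @param W a [GeneratorMatrix-class].
#' @param tau propagation horizon in seconds (>= 0).
#' @return a [PropagatorMatrix-class] over the same space.
#' @export
propagate <- function(W, tau) {
  stopifnot(is(W, "GeneratorMatrix"), tau >= 0)
  if (tau == 0) {
    P <- diag(nrow(W@W))
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(as.matrix(W@W) * tau)))
    if (any(!is.finite(P))) stop("non-finite entries in propagator")
    P[P < 0] <- 0
  }
  new("PropagatorMatrix", P = P, horizon = tau, unit = "seconds",
      space = W@space)
}

#' Raise a propagator to an integer power
#'
#' Exponentiation by repeated squaring; used to turn a one-frame transition
#' matrix into an m-frame one.
#'
#' @param P a [PropagatorMatrix-class].
#' @param m positive integer power.
#' @return a [PropagatorMatrix-class] over `m` times the horizon.
#' @export
matrixPower <- function(P, m) {
  stopifnot(is(P, "PropagatorMatrix"))
  if (length(m) != 1 || m < 1 || m != round(m))
    stop("m must be a positive integer")
  m <- as.integer(m)
  out <- NULL
  base <- P@P
  k <- m
  while (k > 0) {
    if (k %% 2L == 1L) out <- if (is.null(out)) base else base %*% out
    k <- k %/% 2L
    if (k > 0) base <- base %*% base
  }
  out[out < 0] <- 0
  new("PropagatorMatrix", P = out, horizon = P@horizon * m, unit = P@unit,
      space = P@space)
}

#' Stationary distribution over the tracked states
#'
#' The "relative equilibrium" of a truncated chain: the dominant eigenvector
#' of the propagator restricted to non-sink states, renormalised to sum to 1
#' (the sink makes the restriction substochastic, so this is a
#' quasi-stationary law).  Small systems use a dense eigendecomposition;
#' large ones, or a too-small spectral gap, fall back to repeated squaring of
#' the restricted propagator (power iteration).
#'
#' @param x a [PropagatorMatrix-class], or a [GeneratorMatrix-class] (then a
#'   propagator over `tau` is formed first).
#' @param tau horizon used when `x` is a generator; default `1/max|diag(W)|`
#'   scaled to 10 expected events.
#' @param leakTol warn when the per-step probability flux into the sink under
#'   the stationary law exceeds this (FSP truncation too tight).
#' @param method `"auto"`, `"eigen"` or `"power"`.
#' @return named probability vector over the non-sink states; attributes
#'   `leakage` (per-step sink flux) and `method`.
#' @export
stationaryDistribution <- function(x, tau = NULL, leakTol = 1e-6,
                                   method = c("auto", "eigen", "power")) {
  method <- match.arg(method)
  if (is(x, "GeneratorMatrix")) {
    if (is.null(tau)) {
      mx <- max(abs(Matrix::diag(x@W)))
      tau <- if (mx > 0) 10 / mx else 1
    }
    x <- propagate(x, tau)
  }
  stopifnot(is(x, "PropagatorMatrix"))
  A <- x@P[-x@space@sinkIndex, -x@space@sinkIndex, drop = FALSE]
  n <- nrow(A)
  used <- method
  v <- NULL
  if (method %in% c("auto", "eigen") && n <= 1500) {
    eg <- eigen(A)
    ord <- order(Mod(eg$values), decreasing = TRUE)
    gap <- if (n > 1) Mod(eg$values[ord[1]]) - Mod(eg$values[ord[2]]) else 1
    vec <- Re(eg$vectors[, ord[1]])
    if (sum(vec) < 0) vec <- -vec
    if (gap > 1e-12 && all(vec > -1e-8 * max(abs(vec)))) {
      vec[vec < 0] <- 0
      v <- vec / sum(vec)
      used <- "eigen"
    } else if (method == "eigen") {
      warning("degenerate leading eigenpair; falling back to power iteration")
    }
  }
  if (is.null(v)) {
    B <- A
    v <- rep(1 / n, n)
    for (k in 1:60) {
      B <- B %*% B
      s <- max(B)
      if (!is.finite(s) || s <= 0)
        stop("chain has no mass on tracked states")
      B <- B / s
      vNew <- rowSums(B)
      tot <- sum(vNew)
      if (!is.finite(tot) || tot <= 0)
        stop("chain has no mass on tracked states")
      vNew <- vNew / tot
      if (max(abs(vNew - v)) < 1e-13) { v <- vNew; break }
      v <- vNew
    }
    used <- "power"
  }
  leak <- sum((1 - colSums(A)) * v)
  if (leak > leakTol)
    warning(sprintf("stationary sink leakage %.3g per step exceeds %g: raise Nmax",
                    leak, leakTol))
  lbl <- if (sum(x@space@axes$kind == "count") == nrow(x@space@axes) &&
             nrow(x@space@axes) == 1) as.character(0:(n - 1)) else NULL
  structure(stats::setNames(v, lbl), leakage = leak, method = used)
}
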