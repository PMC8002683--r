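mkSeries <- function(x, dt = 300) FrameSeries(as.integer(x), dt)

test_that("transition counting uses non-overlapping windows and pools", {
  om <- countTransitions(list(mkSeries(c(3, 3, 3, 3))), 1)
  expect_equal(om@nTransitions, 3L)
  expect_equal(unname(cbind(om@from, om@to, om@n)),
               matrix(c(3L, 3L, 3L), 1))
  om2 <- countTransitions(list(mkSeries(0:4)), 2)
  expect_equal(om2@nTransitions, 2L)
  expect_setequal(paste(om2@from, om2@to), c("0 2", "2 4"))
  # pooled across trajectories, order-invariant
  a <- list(mkSeries(c(1, 2, 1, 2, 1)), mkSeries(c(5, 5, 5, 5, 5)))
  oA <- countTransitions(a, 2)
  oB <- countTransitions(rev(a), 2)
  expect_equal(oA@nTransitions, 4L)
  keyA <- order(paste(oA@from, oA@to))
  keyB <- order(paste(oB@from, oB@to))
  expect_equal(cbind(oA@from, oA@to, oA@n)[keyA, ],
               cbind(oB@from, oB@to, oB@n)[keyB, ])
  expect_error(countTransitions(list(mkSeries(1:3, 300),
                                     mkSeries(1:3, 200)), 1), "mixed")
})

test_that("window totals follow the floor((T-1)/m) bookkeeping", {
  trs <- replicate(10, mkSeries(rep(0:1, length.out = 2017)),
                   simplify = FALSE)
  om <- countTransitions(trs, 16)
  expect_equal(om@nTransitions, 10L * 126L)
})

test_that("selectM finds the dwell scale of a square wave and degenerates
          gracefully", {
  sq <- makeFixture("square_wave", dwell = 50L)
  m <- selectM(sq)
  expect_equal(as.integer(m), 50L)
  expect_warning(mc <- selectM(list(mkSeries(rep(7, 400)))), "m = 1")
  expect_equal(as.integer(mc), 1L)
})

test_that("log-likelihood arithmetic and the multinomial MLE identity hold", {
  P <- matrix(c(0.5, 0.25, 0.25, 0.2, 0.6, 0.2, 0.1, 0.1, 0.8), 3)
  om <- new("TransitionCounts", m = 1L, deltaT = 300,
            from = matrix(c(0L, 0L), 2), to = matrix(c(0L, 1L), 2),
            n = c(2L, 1L), nTransitions = 3L)
  expect_equal(as.numeric(logLikelihood(P, om)), 2 * log(0.5) + log(0.25))
  omUnit <- new("TransitionCounts", m = 1L, deltaT = 300,
                from = matrix(0L), to = matrix(0L), n = 1L,
                nTransitions = 1L)
  expect_equal(as.numeric(logLikelihood(diag(3), omUnit)), 0)
  # empirical frequencies maximise sum omega * log P over stochastic P
  set.seed(8)
  for (k in 1:10) {
    n <- matrix(rpois(9, 4), 3)
    omK <- new("TransitionCounts", m = 1L, deltaT = 1,
               from = matrix(rep(0:2, each = 3), ncol = 1),
               to = matrix(rep(0:2, times = 3), ncol = 1),
               n = as.vector(t(n)), nTransitions = sum(n))
    Pmle <- t(apply(n, 1, function(r) r / sum(r)))  # rows: from-state
    llAt <- function(P) as.numeric(logLikelihood(t(P), omK))
    best <- llAt(Pmle)
    for (j in 1:20) {
      Prand <- t(apply(matrix(rexp(9), 3), 1, function(r) r / sum(r)))
      expect_lte(llAt(Prand), best + 1e-9)
    }
  }
})

test_that("observations beyond the tracked range are refused", {
  om <- new("TransitionCounts", m = 1L, deltaT = 300,
            from = matrix(10L), to = matrix(2L), n = 1L, nTransitions = 1L)
  expect_error(logLikelihood(diag(5), om), "raise nmax")
  expect_equal(autoNmax(om), 30L)   # max(ceil(1.5*10), 10+20)
  expect_equal(autoNmax(list(mkSeries(c(0, 100)))), 150L)
})

test_that("CGM fit recovers a known birth-death law from its own data", {
  lambda <- 0.02; mu <- 0.002
  cfg <- SimulationConfig(tEnd = 4e5, deltaT = 300, nTrajectories = 10,
                          burnIn = 2e4, seed = 21)
  trs <- simulateSSA(birthDeathNetwork(lambda, mu), cfg)
  om <- countTransitions(trs, 1)
  fit <- maximizeLikelihood("cgm", "sgaa", om, seed = 2,
                            init = c(g2Star = 1e-9), trajectories = trs)
  expect_true(fit@convergence)
  expect_lt(abs(fit@params[["g2"]] - lambda) / lambda, 0.05)
  expect_lt(abs(fit@params[["r2"]] - mu) / mu, 0.05)
})

test_that("likelihood permutation invariance carries through a fit", {
  trs <- makeFixture("tiny_sgaa", seed = 5)
  om1 <- countTransitions(trs, 8)
  om2 <- countTransitions(rev(trs), 8)
  f1 <- maximizeLikelihood("cgm", "sgaa", om1, seed = 9, nStarts = 2L)
  f2 <- maximizeLikelihood("cgm", "sgaa", om2, seed = 9, nStarts = 2L)
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-10)
  expect_equal(f1@params, f2@params, tolerance = 1e-8)
})

test_that("the MaxCal m-step propagator shares the one-step code path", {
  par <- list(hAlpha = -0.5, hA = 1, KA = 0.03, M = 5)
  sp <- maxcalSpace("sgaa", 30)
  P1 <- transitionMatrixSGAA(par, sp)
  P4 <- matrixPower(P1, 4)
  expect_identical(P4@P, ((P1@P %*% P1@P) %*% (P1@P %*% P1@P)))
})

test_that("fits converge toward truth as data volume grows", {
  # CGM fitted to data from its own Hill scheme at three data sizes;
  # median total relative parameter error over 5 seeds must decrease
  pc <- list(g2 = 0.004, g2Star = 0.03, K = 64, r2 = 0.002)
  netc <- ReactionNetwork("A",
    list(reaction("birth", integer(), c(A = 1L), 1, type = "hill_activation",
                  hill = list(modifier = "A", gBase = pc$g2, gAmp = pc$g2Star,
                              K = pc$K, n = 2)),
         reaction("death", c(A = 1L), integer(), pc$r2)),
    observed = "A")
  relErr <- function(nTraj, seed) {
    cfg <- SimulationConfig(tEnd = 2e5, deltaT = 300, nTrajectories = nTraj,
                            burnIn = 2e4, seed = seed)
    trs <- simulateSSA(netc, cfg)
    fit <- maximizeLikelihood("cgm", "sgaa", om <- countTransitions(trs, 1),
                              seed = seed, nStarts = 3L, trajectories = trs)
    sum(abs(unlist(fit@params[names(pc)]) - unlist(pc)) / unlist(pc))
  }
  med <- vapply(c(2, 16, 128), function(n)
    median(vapply(1:5, function(s) relErr(n, 100 + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) < 0))
})
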