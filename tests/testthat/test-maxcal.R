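test_that("path distribution normalises and matches hand-computable cases", {
  # all multipliers zero: Q = (M+1) * 2^N, probabilities binomial in lA
  pd <- pathDistributionSGAA(3, list(hAlpha = 0, hA = 0, KA = 0, M = 1))
  expect_equal(exp(pd@logQ), 16)
  expect_equal(pd@probs[1, ], choose(3, 0:3) / 16)
  expect_equal(sum(pd@probs), 1)
  # N = 0: survivors forced to zero, production weights ~ exp(hAlpha*la)
  pd0 <- pathDistributionSGAA(0, list(hAlpha = 0.7, hA = -1, KA = 5, M = 3))
  expect_equal(dim(pd0@probs), c(4L, 1L))
  expect_equal(as.vector(pd0@probs),
               exp(0.7 * (0:3)) / sum(exp(0.7 * (0:3))))
  # generic case against exhaustive enumeration
  pd2 <- pathDistributionSGAA(2, list(hAlpha = 0.5, hA = -0.2, KA = 0.1,
                                      M = 1))
  g <- expand.grid(la = 0:1, lA = 0:2)
  w <- choose(2, g$lA) * exp(0.5 * g$la - 0.2 * g$lA + 0.1 * g$la * g$lA)
  expect_lt(max(abs(as.vector(pd2@probs) - w / sum(w))), 1e-12)
})

test_that("toggle path distribution factorises when the couplings vanish", {
  par <- list(hAlpha = 0.3, hA = -0.4, KAalpha = 0, KAbeta = 0, M = 2)
  joint <- pathDistributionTS(2, 3, par)@probs
  margA <- apply(joint, c(1, 2), sum)
  margB <- apply(joint, c(3, 4), sum)
  expect_lt(max(abs(joint - outer(margA, margB))), 1e-12)
  # NA=NB=1, M=1 generic case against 16-term enumeration
  par2 <- list(hAlpha = 0.2, hA = 0.5, KAalpha = -0.3, KAbeta = 0.7, M = 1)
  joint2 <- pathDistributionTS(1, 1, par2)@probs
  g <- expand.grid(la = 0:1, lA = 0:1, lb = 0:1, lB = 0:1)
  w <- exp(0.2 * (g$la + g$lb) + 0.5 * (g$lA + g$lB) -
             0.3 * (g$la * g$lA + g$lb * g$lB) +
             0.7 * (g$lb * g$lA + g$la * g$lB))
  expect_lt(max(abs(as.vector(joint2) - w / sum(w))), 1e-12)
  expect_equal(sum(joint2), 1)
})

test_that("repressive cross-coupling lowers the partner's production", {
  base <- list(hAlpha = 0, hA = 0, KAalpha = 0, KAbeta = 0, M = 3)
  rep_ <- modifyList(base, list(KAbeta = -0.5))
  mB <- function(par) {
    pr <- pathDistributionTS(8, 2, par)@probs
    sum(sweep(pr, 3, 0:par$M, "*"))  # <lBeta> with NA large
  }
  expect_lt(mB(rep_), mB(base))
})

test_that("transition matrices match brute-force enumeration over draws", {
  set.seed(101)
  for (k in 1:25) {
    h <- rnorm(3); nmax <- sample(2:6, 1); M <- sample(1:3, 1)
    P <- transitionMatrixSGAA(list(hAlpha = h[1], hA = h[2], KA = h[3],
                                   M = M), maxcalSpace("sgaa", nmax))@P
    expect_lt(max(abs(P - bruteForceTransitionSGAA(h[1], h[2], h[3], M,
                                                   nmax))), 1e-10)
  }
  for (k in 1:10) {
    h <- rnorm(4, 0, 0.8); nmax <- sample(2:5, 1); M <- sample(1:3, 1)
    P <- transitionMatrixTS(list(hAlpha = h[1], hA = h[2], KAalpha = h[3],
                                 KAbeta = h[4], M = M),
                            maxcalSpace("ts", nmax))@P
    expect_lt(max(abs(P - bruteForceTransitionTS(h[1], h[2], h[3], h[4], M,
                                                 nmax))), 1e-10)
  }
})

test_that("transition matrix respects reachability and suppression limits", {
  par <- list(hAlpha = 0.2, hA = 0.4, KA = 0.05, M = 3)
  P <- transitionMatrixSGAA(par, maxcalSpace("sgaa", 12))@P
  # from 0 only 0..M reachable; j > i + M impossible
  expect_equal(sum(P[5:13, 1]), 0)
  for (i in 0:8) expect_equal(sum(P[(i + par$M + 2):13, i + 1]), 0)
  # strongly suppressed production: nothing moves up
  Pdown <- transitionMatrixSGAA(modifyList(par, list(hAlpha = -30)),
                                maxcalSpace("sgaa", 12))@P
  for (i in 1:11) expect_lt(sum(Pdown[(i + 2):13, i + 1]), 1e-10)
})

test_that("one-step matrix matches a Monte Carlo path-sampling oracle", {
  par <- list(hAlpha = -0.4, hA = 0.9, KA = 0.02, M = 4)
  i <- 5
  pd <- pathDistributionSGAA(i, par)
  set.seed(7)
  n <- 1e6
  draw <- sample(length(pd@probs), n, replace = TRUE,
                 prob = as.vector(pd@probs))
  la <- (draw - 1) %% (par$M + 1)
  lA <- (draw - 1) %/% (par$M + 1)
  j <- la + lA
  P <- transitionMatrixSGAA(par, maxcalSpace("sgaa", 12))@P
  for (jj in 0:9) {
    phat <- mean(j == jj)
    se <- sqrt(max(phat * (1 - phat), 1e-12) / n)
    expect_lt(abs(phat - P[jj + 1, i + 1]), 4 * se + 1e-9)
  }
})

test_that("production multiplier and coupling act monotonically", {
  sp <- maxcalSpace("sgaa", 20)
  meanUp <- function(h, KA, i) {
    mm <- CircuitCaliber:::maxcal_means_sgaa_cpp(h, 0.5, KA, 5L, 20L)
    mm[1, i + 1]
  }
  hs <- seq(-1, 1, by = 0.5)
  for (i in c(2, 10)) {
    vals <- vapply(hs, meanUp, numeric(1), KA = 0.05, i = i)
    expect_true(all(diff(vals) > 0))
  }
  # KA raises production more at larger N
  gain <- function(i) meanUp(-0.5, 0.08, i) - meanUp(-0.5, 0, i)
  expect_gt(gain(15), gain(3))
})

test_that("MaxCal chain with positive coupling can be bistable and yields rates", {
  par <- list(hAlpha = -2.0, hA = 2.5, KA = 0.045, M = 8)
  sp <- maxcalSpace("sgaa", 120)
  er <- maxcalEffectiveRates(par, sp, 300, "sgaa")
  modes <- attr(er, "modes")
  expect_length(modes, 2)
  expect_gt(modes[["NH"]], modes[["NL"]])
  expect_gt(er[["peffStar"]], er[["peff"]])
  expect_gt(er[["reff"]], 0)
})

test_that("decoupled constraints give state-independent production", {
  # KA = 0: <lAlpha>_N identical for every N, so peff would equal peff*
  mm <- CircuitCaliber:::maxcal_means_sgaa_cpp(-0.7, 0.9, 0, 6L, 30L)
  expect_lt(max(mm[1, ]) - min(mm[1, ]), 1e-12)
})

test_that("pure-survival limit reproduces the binomial death rate", {
  # hAlpha -> -infinity: no production; survivors are Binomial(N, sigma)
  # with sigma = e^hA/(1+e^hA), so r(N) = (1-sigma)/dt for every N
  hA <- 0.8; dt <- 300
  sigma <- exp(hA) / (1 + exp(hA))
  mm <- CircuitCaliber:::maxcal_means_sgaa_cpp(-30, hA, 0, 3L, 25L)
  Ns <- 1:24
  rN <- (Ns - mm[2, Ns + 1]) / (Ns * dt)
  expect_lt(max(abs(rN - (1 - sigma) / dt)), 1e-12)
  expect_lt(max(mm[1, ]), 1e-10)   # and essentially no production
})

test_that("TS transition matrix is symmetric and factorises when decoupled", {
  nmax <- 4
  sp <- maxcalSpace("ts", nmax)
  par <- list(hAlpha = 0.3, hA = -0.2, KAalpha = 0.1, KAbeta = -0.4, M = 2)
  P <- transitionMatrixTS(par, sp)@P
  iv <- rep(0:(nmax - 1), times = nmax); kv <- rep(0:(nmax - 1), each = nmax)
  perm <- c(kv + nmax * iv + 1L, nmax^2 + 1L)
  expect_lt(max(abs(P - P[perm, perm])), 1e-12)
  # KAbeta = 0 -> kronecker product of two one-gene matrices
  par0 <- modifyList(par, list(KAbeta = 0))
  PT <- transitionMatrixTS(par0, sp)@P
  PS <- transitionMatrixSGAA(list(hAlpha = 0.3, hA = -0.2, KA = 0.1, M = 2),
                             maxcalSpace("sgaa", nmax))@P
  A <- PS[1:nmax, 1:nmax]
  expect_lt(max(abs(PT[1:nmax^2, 1:nmax^2] - kronecker(A, A))), 1e-12)
})
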