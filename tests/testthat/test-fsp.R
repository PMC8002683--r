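test_that("state-space dimensions follow the truncation convention", {
  expect_equal(spaceDim(buildStateSpace(c(A = 92), c(promoter = 2))), 185L)
  expect_equal(spaceDim(buildStateSpace(c(A = 92))), 93L)
  expect_equal(spaceDim(buildStateSpace(c(A = 1))), 2L)
  expect_equal(spaceDim(buildStateSpace(c(A = 59, B = 59),
                                        c(sA = 2, sB = 2))), 13925L)
  expect_equal(spaceDim(buildStateSpace(c(A = 59, B = 59))), 3482L)
  expect_error(buildStateSpace(c(A = 300, B = 300)), "cap")
})

test_that("hand-assembled small birth-death generator matches", {
  W <- as.matrix(birthDeathGeneratorMatrix(0.4, 0.1, 3)@W)
  expect_equal(dim(W), c(4L, 4L))        # counts 0..2 + sink
  expect_equal(W[2, 1], 0.4)             # birth 0 -> 1
  expect_equal(W[1, 2], 0.1)             # death 1 -> 0
  expect_equal(W[4, 3], 0.4)             # birth 2 -> sink
  expect_equal(colSums(W), rep(0, 4))
  # all rates zero -> zero matrix
  W0 <- as.matrix(birthDeathGeneratorMatrix(0, 0, 3)@W)
  expect_equal(W0, matrix(0, 4, 4))
})

test_that("SGAA DM generator reproduces the CME gain/loss pairs statewise", {
  # independent right-hand side of the detailed CME, evaluated at random
  # states; promoter 0 = basal, 1 = activated
  p <- list(g1 = 0.004, g1Star = 0.06, r1 = 0.002, f1 = 3e-5, b1 = 2e-4)
  nmax <- 20
  sp <- sgaaDMSpace(nmax)
  W <- as.matrix(sgaaDMGenerator(p, sp)@W)
  idx <- function(N, a) 1L + N + nmax * a
  set.seed(42)
  for (k in 1:20) {
    N <- sample(0:(nmax - 2), 1); a <- sample(0:1, 1)
    j <- idx(N, a)
    prodRate <- if (a == 0) p$g1 else p$g1Star
    # outflow: production + degradation + binding (basal) / unbinding (act.)
    out <- prodRate + p$r1 * N +
      if (a == 0) p$f1 * N else p$b1
    expect_equal(W[j, j], -out)
    expect_equal(W[idx(N + 1, a), j], prodRate)
    if (N > 0) expect_equal(W[idx(N - 1, a), j], p$r1 * N)
    if (a == 0 && N > 0) expect_equal(W[idx(N - 1, 1), j], p$f1 * N)
    if (a == 1) expect_equal(W[idx(N + 1, 0), j], p$b1)
  }
  # spec'd outflow example: at (NA = 5, basal): g1 + 5 r1 + 5 f1
  expect_equal(-W[idx(5, 0), idx(5, 0)], p$g1 + 5 * p$r1 + 5 * p$f1)
})

test_that("propagator matches the 2-state closed form and a Taylor oracle", {
  k <- 0.3
  sp2 <- buildStateSpace(c(x = 1), c(s = 2))
  W <- assembleGenerator(list(
    list(delta = c(s = 1L), propensity = function(st) k * (st[, "s"] == 0)),
    list(delta = c(s = -1L), propensity = function(st) k * (st[, "s"] == 1))),
    sp2)
  for (tau in c(0.5, 2, 10)) {
    stay <- (1 + exp(-2 * k * tau)) / 2
    expect_lt(abs(propagate(W, tau)@P[1, 1] - stay), 1e-8)
  }
  expect_equal(propagate(W, 0)@P, diag(3))
  set.seed(1)
  for (k in 1:5) {
    A <- randomGenerator(10)
    P <- propagate(asGenerator(A), 0.3)@P
    expect_lt(max(abs(P - taylorExpm(A * 0.3))), 1e-8)
  }
})

test_that("matrix power agrees with naive products and the semigroup", {
  set.seed(2)
  A <- randomGenerator(8, 0.5)
  P1 <- propagate(asGenerator(A), 0.4)
  expect_identical(matrixPower(P1, 1)@P, P1@P)
  naive <- P1@P %*% P1@P %*% P1@P %*% P1@P
  expect_lt(max(abs(matrixPower(P1, 4)@P - naive)), 1e-12)
  expect_lt(max(abs(matrixPower(P1, 6)@P - propagate(asGenerator(A), 2.4)@P)),
            1e-8)
  expect_error(matrixPower(P1, 0), "positive")
  # semigroup in continuous time
  Pa <- propagate(asGenerator(A), 0.7)@P
  Pb <- propagate(asGenerator(A), 1.1)@P
  expect_lt(max(abs(Pa %*% Pb - propagate(asGenerator(A), 1.8)@P)), 1e-8)
})

test_that("column sums are conserved and sink mass is monotone in tau", {
  set.seed(3)
  W <- birthDeathGeneratorMatrix(1, 0.2, 8)
  expect_lt(max(abs(Matrix::colSums(W@W))), 1e-12)
  sink <- vapply(c(1, 2, 5, 10, 20),
                 function(tau) propagate(W, tau)@P[9, 1], numeric(1))
  expect_lt(max(abs(colSums(propagate(W, 5)@P) - 1)), 1e-10)
  expect_true(all(diff(sink) >= -1e-12))
})

test_that("stationary law of linear birth-death is Poisson", {
  W <- birthDeathGeneratorMatrix(1, 0.1, 60)
  for (method in c("eigen", "power")) {
    pi <- stationaryDistribution(propagate(W, 5), method = method)
    ref <- dpois(0:59, 10); ref <- ref / sum(ref)
    expect_lt(0.5 * sum(abs(pi - ref)), 1e-4)
  }
  expect_lt(attr(stationaryDistribution(propagate(W, 5)), "leakage"), 1e-10)
})

test_that("an absorbing state collects all stationary mass", {
  sp <- buildStateSpace(c(A = 5))
  W <- assembleGenerator(list(
    list(delta = c(A = -1L), propensity = function(s) 0.3 * s[, "A"])), sp)
  pi <- stationaryDistribution(propagate(W, 10), method = "power")
  expect_equal(unname(pi[1]), 1, tolerance = 1e-9)
})

test_that("excessive sink leakage triggers the FSP warning", {
  # Nmax far below the stationary mean -> strong leakage
  W <- birthDeathGeneratorMatrix(1, 0.1, 5)
  expect_warning(stationaryDistribution(propagate(W, 10)), "leakage")
})
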