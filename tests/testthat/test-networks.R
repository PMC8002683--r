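test_that("SGAA generator propensities match hand-evaluated mass action", {
  net <- buildSGAAGenerator()
  a <- propensities(net, c(a = 2L, A = 10L, A2 = 0L, alpha = 1L,
                           alphaStar = 0L))
  expect_equal(a[["transcription_basal"]], 0.05)     # g * alpha
  expect_equal(a[["translation"]], 0.04)             # p * a = 0.02*2
  expect_equal(a[["dimerisation"]], 0.225)           # fd * 10*9/2
  expect_equal(a[["promoter_binding"]], 0)           # no free dimer
  expect_equal(a[["transcription_active"]], 0)       # promoter basal
  # alternative homodimerisation convention doubles that one propensity
  net2 <- buildSGAAGenerator(halveDimerisation = FALSE)
  a2 <- propensities(net2, c(a = 2L, A = 10L, A2 = 0L, alpha = 1L,
                             alphaStar = 0L))
  expect_equal(a2[["dimerisation"]], 0.45)
  expect_equal(a2[["translation"]], a[["translation"]])
})

test_that("basal SGAA summaries reproduce the true effective rates", {
  p <- defaultRates("sgaa")
  expect_equal(unname(p["g"] / p["d"]), 0.25)        # mean basal mRNA
  tr <- trueEffectiveRates("sgaa")
  expect_equal(tr[["peff"]], 5.0e-3)
  expect_equal(tr[["peffStar"]], 50e-3)
  expect_equal(tr[["reff"]], 1.0e-3)
})

test_that("TS generator is A/B symmetric with exclusive monomer binding", {
  net <- buildTSGenerator()
  a <- propensities(net, c(a = 0L, b = 0L, A = 30L, B = 0L, alpha = 1L,
                           alphaStar = 0L, alphaPrime = 0L))
  expect_equal(a[["A_binding"]], defaultRates("ts")[["f3"]] * 30)
  expect_equal(a[["B_binding"]], 0)
  # with A bound, B cannot bind (promoter states exclusive)
  aStar <- propensities(net, c(a = 0L, b = 0L, A = 0L, B = 30L, alpha = 0L,
                               alphaStar = 1L, alphaPrime = 0L))
  expect_equal(aStar[["B_binding"]], 0)
  expect_equal(aStar[["transcription_b_Abound"]],
               defaultRates("ts")[["g3Star"]])
  expect_equal(trueEffectiveRates("ts")[["peff"]], 20e-3)
  expect_equal(trueEffectiveRates("ts")[["peffStar"]], 0.1e-3)
})

test_that("rate validation rejects negatives and warns on odd activation", {
  p <- defaultRates("sgaa"); p["d"] <- -1
  expect_error(buildSGAAGenerator(p), ">= 0")
  p <- defaultRates("sgaa"); p["gStar"] <- p[["g"]] / 2
  expect_warning(buildSGAAGenerator(p), "gStar")
  p <- defaultRates("ts"); p["g3Star"] <- 1
  expect_warning(buildTSGenerator(p), "repress")
})

test_that("a network with no possible reactions yields a constant series", {
  net <- ReactionNetwork("A", list(reaction("death", c(A = 1L), integer(),
                                            0.5)),
                         initialState = c(A = 0L), observed = "A")
  # start at 0: the only reaction has zero propensity forever
  tr <- simulateSSA(net, SimulationConfig(tEnd = 3000, deltaT = 300,
                                          burnIn = 0, seed = 1))[[1]]
  expect_equal(as.vector(counts(tr)), rep(0L, 11))
  net7 <- ReactionNetwork("A", list(), initialState = c(A = 7L),
                          observed = "A")
  tr7 <- simulateSSA(net7, SimulationConfig(tEnd = 3000, deltaT = 300,
                                            burnIn = 0, seed = 1))[[1]]
  expect_equal(as.vector(counts(tr7)), rep(7L, 11))
})

test_that("pure death ensemble mean matches the closed form", {
  net <- ReactionNetwork("A", list(reaction("death", c(A = 1L), integer(),
                                            0.001)),
                         initialState = c(A = 100L), observed = "A")
  cfg <- SimulationConfig(tEnd = 1000, deltaT = 500, nTrajectories = 1000,
                          burnIn = 0, seed = 2)
  fin <- vapply(simulateSSA(net, cfg), function(t) counts(t)[3, 1],
                integer(1))
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 100 * exp(-1)), 3 * se)
})

test_that("seed determinism: identical config gives identical trajectories", {
  cfg <- SimulationConfig(tEnd = 6 * 3600, deltaT = 300, nTrajectories = 3,
                          burnIn = 3600, seed = 77)
  a <- simulateSSA(buildSGAAGenerator(), cfg)
  b <- simulateSSA(buildSGAAGenerator(), cfg)
  for (i in seq_along(a)) expect_identical(counts(a[[i]]), counts(b[[i]]))
})

test_that("birth-death frame histogram is Poisson at stationarity", {
  # frames 5 relaxation times apart: effectively independent draws
  net <- birthDeathNetwork(1, 0.1)
  cfg <- SimulationConfig(tEnd = 5e5 + 500, deltaT = 50, nTrajectories = 10,
                          burnIn = 500, seed = 3)
  x <- unlist(lapply(simulateSSA(net, cfg), function(t) counts(t)[, 1]))
  expect_gte(length(x), 1e5)
  brk <- c(0:20, Inf)
  obs <- table(cut(x, breaks = c(-1, brk)))
  pr <- diff(c(0, ppois(c(0:20), 10), 1))
  keep <- pr * length(x) >= 5
  chi <- suppressWarnings(chisq.test(as.vector(obs)[keep],
                                     p = pr[keep] / sum(pr[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("SGAA benchmark trajectories switch between low and high states", {
  cfg <- SimulationConfig(tEnd = 48 * 3600 + 12 * 3600, deltaT = 300,
                          nTrajectories = 10, burnIn = 12 * 3600, seed = 11)
  x <- unlist(lapply(simulateSSA(buildSGAAGenerator(), cfg),
                     function(t) counts(t)[, 1]))
  expect_gt(mean(x < 15), 0.05)   # low state visited
  expect_gt(mean(x > 30), 0.05)   # high state visited
  expect_lt(mean(x > 15 & x < 30), mean(x <= 15))  # trough between modes
})

test_that("toggle-switch trajectories anticorrelate A and B", {
  cfg <- SimulationConfig(tEnd = 96 * 3600 + 12 * 3600, deltaT = 300,
                          nTrajectories = 3, burnIn = 12 * 3600, seed = 13)
  trs <- simulateSSA(buildTSGenerator(), cfg)
  cc <- cor(do.call(rbind, lapply(trs, counts)))
  expect_lt(cc["A", "B"], 0)
})

test_that("promoter indicators stay mutually exclusive along a trajectory", {
  # record the indicators themselves and check the conservation law
  net <- buildSGAAGenerator()
  net@observed <- c("alpha", "alphaStar")
  cfg <- SimulationConfig(tEnd = 24 * 3600, deltaT = 300, burnIn = 0,
                          seed = 5)
  cts <- counts(simulateSSA(net, cfg)[[1]])
  expect_true(all(rowSums(cts) == 1))
  netT <- buildTSGenerator()
  netT@observed <- c("alpha", "alphaStar", "alphaPrime")
  ctsT <- counts(simulateSSA(netT, cfg)[[1]])
  expect_true(all(rowSums(ctsT) == 1))
})

test_that("switched-off feedback reduces SGAA to a birth-death cascade", {
  p <- defaultRates("sgaa"); p["fd"] <- 0; p["fp"] <- 0
  net <- buildSGAAGenerator(p)
  cfg <- SimulationConfig(tEnd = 2e5, deltaT = 100, nTrajectories = 5,
                          burnIn = 2e4, seed = 19)
  x <- unlist(lapply(simulateSSA(net, cfg), function(t) counts(t)[, 1]))
  # stationary mean of the two-stage cascade: p*g/(d*r) = 5
  expect_lt(abs(mean(x) - 5), 0.5)
})

test_that("benchmark ensemble writes files plus manifest, deterministically", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- SimulationConfig(tEnd = 6 * 3600, deltaT = 300, nTrajectories = 3,
                          nReplicates = 2, burnIn = 3600, seed = 31)
  generateBenchmarkEnsemble("sgaa", cfg, outDir = dir1)
  generateBenchmarkEnsemble("sgaa", cfg, outDir = dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_length(grep("trajectory_.*tsv", f1), 6)
  expect_length(grep("manifest", f1), 2)
  for (f in grep("tsv", f1, value = TRUE))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
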