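test_that("design-mode genotype assignment expands exact counts", {
  d <- canonicalDesign("pure", gSize = 100, replicates = 2)
  ind <- assignGenotypes(design = d)
  expect_equal(nrow(ind), 800)
  g1 <- ind[ind$group == 1 & ind$replicate == 1, ]
  expect_equal(sum(g1$role == "seeder" & g1$genotype == "AA"), 47)
  expect_equal(sum(g1$role == "contact"), 53)
})

test_that("HWE genotype assignment has the right frequencies", {
  set.seed(42)
  g <- assignGenotypes(p = 0.5, n = 1e5)
  expect_lt(abs(mean(g == "AB") - 0.5), 0.005)  # 3 sigma ~ 0.0047
  expect_true(all(assignGenotypes(p = 1, n = 100) == "AA"))
  expect_error(assignGenotypes(p = 1.5, n = 10), "p must lie")
})

test_that("trait construction follows the SNP + fixed + residual model", {
  p0 <- epidemicParams(beta = 1)
  tr <- drawTraits(p0, c("AB", "AA", "BB"))
  expect_equal(tr$g, c(0, 0, 0))
  expect_equal(tr$f, c(0, 0, 0))

  pA <- epidemicParams(beta = 1, aG = 0.5, aR = -0.2, deltaG = 1)
  tr <- drawTraits(pA, c("AA", "AB", "BB"))
  expect_equal(tr$g, c(0.5, 0.5, -0.5))
  expect_equal(tr$r, c(-0.2, 0, 0.2))

  # residual correlation between susceptibility and infectivity
  Sig <- matrix(c(1, 0.3, 0, 0.3, 1, 0, 0, 0, 1), 3, 3)
  pS <- epidemicParams(beta = 1, Sigma = Sig)
  set.seed(1)
  tr <- drawTraits(pS, rep("AB", 2e4))
  expect_lt(abs(cor(tr$g, tr$f) - 0.3), 0.03)

  # fixed effects enter through X b
  X <- matrix(c(1, 0), 2, 1)
  pX <- epidemicParams(beta = 1, X = X, bG = 0.7)
  tr <- drawTraits(pX, c("AB", "AB"))
  expect_equal(tr$g, c(0.7, 0))
})

test_that("zero transmission leaves all contacts uninfected", {
  p <- epidemicParams(beta = 0, gamma = 1, k = 2)
  set.seed(3)
  sim <- simulateGroup(baselineTraits(5, 45), p)
  expect_equal(sum(!is.na(sim$t_inf)), 5)
  expect_true(all(sim$t_inf[sim$role == "seeder"] == 0))
  expect_true(all(!is.na(sim$t_rec[sim$role == "seeder"])))
})

test_that("recovery durations follow the gamma recoverability model", {
  # all seeders, genotype AA with a_r = 0.5: mean duration 1/(gamma e^0.5)
  set.seed(4)
  p <- epidemicParams(beta = 0, gamma = 1, k = 4, aR = 0.5)
  tr <- drawTraits(p, rep("AA", 4000))
  tr$role <- "seeder"
  sim <- simulateGroup(tr, p)
  dur <- sim$t_rec - sim$t_inf
  expect_lt(abs(mean(dur) - exp(-0.5)), 0.02)
  # dispersion shrinks as 1/sqrt(k)
  expect_lt(abs(sd(dur) - exp(-0.5) / sqrt(4)), 0.02)
})

test_that("event tables are reproducible and internally consistent", {
  d <- canonicalDesign("mixed", gSize = 60, replicates = 2)
  p <- smallEffectParams(r0 = 4, gSize = 60, a = 0.3, k = 2)
  ev1 <- simulateExperiment(d, p, seed = 11)
  ev2 <- simulateExperiment(d, p, seed = 11)
  ev3 <- simulateExperiment(d, p, seed = 12)
  expect_identical(ev1, ev2)
  expect_false(identical(ev1, ev3))

  # seeders start at 0; recovery strictly after infection; roles conserved
  expect_true(all(ev1$t_inf[ev1$role == "seeder"] == 0))
  inf <- !is.na(ev1$t_inf)
  expect_true(all(ev1$t_rec[inf] > ev1$t_inf[inf]))
  expect_true(all(is.na(ev1$t_rec[!inf])))
  expect_equal(nrow(ev1), 240)
  expect_equal(anyDuplicated(ev1$id), 0)
})

test_that("S + I + R bookkeeping holds at every event", {
  d <- canonicalDesign("single", gSize = 80)
  p <- smallEffectParams(r0 = 3, gSize = 80, a = 0)
  ev <- simulateExperiment(d, p, seed = 5)
  times <- sort(c(ev$t_inf, ev$t_rec))
  times <- times[is.finite(times)]
  for (t in unique(times)) {
    S <- sum(is.na(ev$t_inf) | ev$t_inf > t)
    I <- sum(!is.na(ev$t_inf) & ev$t_inf <= t & ev$t_rec > t)
    R <- sum(!is.na(ev$t_rec) & ev$t_rec <= t)
    expect_equal(S + I + R, 80)
  }
})

test_that("final-size solver matches known fixed points", {
  expect_equal(finalSizePhi(0, 0.1), 0)
  expect_gt(finalSizePhi(30, 0.1), 0.999)
  expect_equal(finalSizePhi(2, 1e-9), 0.7968, tolerance = 1e-4)
  # phi solves its own fixed-point equation
  for (r0 in c(1.5, 2, 6)) {
    for (h0 in c(0.05, 0.3)) {
      phi <- finalSizePhi(r0, h0)
      expect_equal(phi, 1 - exp(-r0 * (h0 + (1 - h0) * phi)),
                   tolerance = 1e-9)
    }
  }
})

test_that("empirical final size approaches the deterministic fixed point", {
  set.seed(6)
  p <- epidemicParams(beta = betaFromR0(2, 300), gamma = 1, k = 1)
  fr <- replicate(25, {
    s <- simulateGroup(baselineTraits(6, 294), p)
    mean(!is.na(s$t_inf[s$role == "contact"]))
  })
  fr <- fr[fr >= 0.1]  # condition on non-extinction
  expect_lt(abs(mean(fr) - finalSizePhi(2, 0.02)), 0.05)
})

test_that("extinction probabilities follow the branching approximation", {
  expect_equal(extinctionProbability(0.8, 3), 1)
  expect_equal(extinctionProbability(2, 3), 0.125)
  mc <- extinctionProbability(4, 1, "monte_carlo", gSize = 200,
                              nRuns = 500, seed = 7)
  expect_lt(abs(mc - 0.25), 0.07)
})

test_that("susceptibility effects produce the exponential-link hazard ratio", {
  # independent oracle: Cox PH on time-to-infection. All susceptibles in one
  # group share the same exposure process, so the AA vs BB hazard ratio is
  # exp(g_AA - g_BB) = exp(2 a_g) = e at a_g = 0.5.
  set.seed(8)
  p <- epidemicParams(beta = betaFromR0(5, 1200), gamma = 1, k = 1, aG = 0.5)
  tr <- drawTraits(p, c(rep("AA", 20), rep("AA", 590), rep("BB", 590)))
  tr$role <- rep(c("seeder", "contact"), c(20, 1180))
  sim <- simulateGroup(tr, p)
  cont <- sim[sim$role == "contact", ]
  tEnd <- max(sim$t_rec, na.rm = TRUE)
  time <- ifelse(is.na(cont$t_inf), tEnd, cont$t_inf)
  status <- as.integer(!is.na(cont$t_inf))
  fit <- survival::coxph(survival::Surv(time, status) ~ I(genotype == "AA"),
                         data = cont)
  expect_lt(abs(unname(coef(fit)) - 1), 0.2)
})

test_that("event tables round-trip through CSV with metadata sidecar", {
  d <- canonicalDesign("single", gSize = 40)
  p <- smallEffectParams(r0 = 3, gSize = 40)
  ev <- simulateExperiment(d, p, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEvents(ev, path, params = p, seed = 9)
  back <- readEvents(path)
  expect_equal(back$t_inf, ev$t_inf)
  expect_equal(back$genotype, ev$genotype)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 9)
  expect_equal(meta$params$k, p@k)
})
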