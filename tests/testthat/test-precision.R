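# Expected values below were derived by hand: direct evaluation of the W/Y
# contrasts and the 2x2 information matrix on small compositions.

test_that("W and Y vanish for single groups and matched compositions", {
  sm <- summarizeDesign(oneGroupDesign(90, 0, 10), phi = 1)
  wy <- computeWY(sm)
  expect_equal(unname(wy["W"]), 0)

  # chi_seed == chi_cont in every group
  d <- experimentDesign(list(
    groupDesign(gc3(AA = 9, BB = 1), gc3(AA = 45, BB = 5)),
    groupDesign(gc3(AA = 1, BB = 9), gc3(AA = 5, BB = 45))))
  wy <- computeWY(summarizeDesign(d, phi = 1))
  expect_equal(unname(wy), c(0, 0))
})

test_that("W and Y on the pure design match the hand-derived values", {
  # <(chi_c)(chi_s - chi_c)> = -1 and <(chi_s - chi_c)^2> = 2 over the four
  # (seed, cont) combos, so W = log(h) and Y = 2(1 - h)
  sm <- summarizeDesign(canonicalDesign("pure", 100), phi = 1)
  wy <- computeWY(sm)
  expect_equal(unname(wy["W"]), log(0.47), tolerance = 1e-12)
  expect_equal(unname(wy["Y"]), 2 * 0.53, tolerance = 1e-12)
})

test_that("Fisher information matrix matches its printed structure", {
  sm <- summarizeDesign(oneGroupDesign(90, 0, 10, nSeed = 15), phi = 0.7)
  M <- fisherInfoGF(sm)@M
  expect_equal(M[1, 2], M[2, 1])
  expect_equal(M["a_g", "a_g"], 0.7 * 100 * (1 - 0.8^2))

  sm <- summarizeDesign(canonicalDesign("pure", 100), phi = 1)
  fi <- fisherInfoGF(sm)
  expect_equal(fi@M["a_f", "a_f"],
               4 * (53 * 1 + 47 * (2 * fi@W + fi@Y)))
})

test_that("SNP-effect SDs reproduce the reference coefficients", {
  smPure <- summarizeDesign(canonicalDesign("pure", 100), phi = 1)
  coefPure <- sdSnpEffects(smPure) * sqrt(400)
  expect_equal(round(unname(coefPure), 2), c(1.52, 1.96, 1.00))

  smMixed <- summarizeDesign(mixedLimitDesign(), phi = 1)
  coefMixed <- sdSnpEffects(smMixed) * sqrt(2)
  expect_equal(unname(coefMixed["aG"]), sqrt(2), tolerance = 1e-6)
  expect_equal(unname(coefMixed["aF"]), 2, tolerance = 1e-6)
  expect_equal(unname(coefMixed["aR"]), 1, tolerance = 1e-6)
})

test_that("designs with no genotype variation cannot estimate a_r", {
  d <- experimentDesign(groupDesign(gc3(AA = 10), gc3(AA = 90)))
  classes <- character()
  sds <- withCallingHandlers(
    sdSnpEffects(summarizeDesign(d, phi = 1)),
    warning = function(w) {
      classes <<- c(classes, class(w)[1])
      invokeRestart("muffleWarning")
    })
  expect_equal(unname(sds["aR"]), Inf)
  expect_true("sirdesign_degenerate" %in% classes)
})

test_that("dominance SDs follow the homozygosity formulas", {
  # all-homozygote contacts: no information about dominance
  smPure <- summarizeDesign(canonicalDesign("pure", 100), phi = 1)
  dm <- suppressWarnings(sdDominance(smPure, aG = 1, aF = 1, aR = 1))
  expect_equal(unname(dm["dG"]), Inf)

  smDom <- summarizeDesign(canonicalDesign("pure_dominance", 100), phi = 1)
  dm1 <- sdDominance(smDom, aG = 1, aF = 1, aR = 1)
  expect_equal(unname(dm1["dG"]) * sqrt(900), 1 / sqrt(0.53 * 2 / 9),
               tolerance = 1e-12)
  # 1/|a| scaling
  dm2 <- sdDominance(smDom, aG = 2, aF = 0.5, aR = 4)
  expect_equal(unname(dm2["dG"]), unname(dm1["dG"]) / 2)
  expect_equal(unname(dm2["dF"]), unname(dm1["dF"]) * 2)
  expect_equal(unname(dm2["dR"]), unname(dm1["dR"]) / 4)
  # zero additive effect: dominance unidentifiable
  expect_equal(unname(suppressWarnings(
    sdDominance(smDom, 0, 1, 1))["dG"]), Inf)
})

test_that("closed forms evaluate as printed and degenerate to +Inf", {
  expect_equal(round(sdClosedForm("single", h = 0.15, chiSeed = -1,
                                  chiCont = 0.8, nTotal = 1), 2), 3.09)
  expect_equal(sdClosedForm("single", h = 0.15, chiSeed = 0.8,
                            chiCont = 0.8), Inf)
  expect_equal(sdClosedForm("mixed", chiCont = 1 / sqrt(2)), 2)
  expect_equal(sdClosedForm("mixed", chiCont = 0), Inf)
  expect_equal(sdClosedForm("mixed", chiCont = 1), Inf)
})

test_that("general pipeline agrees with the closed forms (oracle check)", {
  # single group, arbitrary compositions (heterozygotes included)
  for (cont in list(c(80, 0, 20), c(60, 25, 15), c(50, 0, 50))) {
    for (ns in c(10, 33)) {
      d <- experimentDesign(groupDesign(gc3(BB = ns),
                                        gc3(cont[1], cont[2], cont[3])))
      sm <- summarizeDesign(d, phi = 1)
      pg <- groupTable(sm)
      want <- sdClosedForm("single", h = seederFraction(sm),
                          chiSeed = -1, chiCont = pg$chiCont,
                          nTotal = nTotal(sm))
      got <- unname(sdSnpEffects(sm)["aF"])
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
  # pure design across seeder fractions
  for (s in c(0.2, 0.47, 0.8)) {
    sm <- summarizeDesign(pureFracDesign(s), phi = 1)
    expect_equal(unname(sdSnpEffects(sm)["aF"]),
                 sdClosedForm("pure", h = s, nTotal = 4), tolerance = 1e-6)
  }
  # mixed design in the negligible-seeder limit, across contact mixes
  for (chi in c(0.4, 1 / sqrt(2), 0.9)) {
    sm <- summarizeDesign(mixedLimitDesign(chi), phi = 1)
    expect_equal(unname(sdSnpEffects(sm)["aF"]),
                 sdClosedForm("mixed", chiCont = chi, nTotal = 2),
                 tolerance = 1e-6)
  }
})

test_that("SD scaling laws hold exactly", {
  base <- summarizeDesign(canonicalDesign("pure", 100), phi = 0.9)
  sds1 <- sdSnpEffects(base, k = 1)
  # replication: m^{-1/2}
  for (m in c(2, 5)) {
    smM <- summarizeDesign(canonicalDesign("pure", 100, replicates = m),
                           phi = 0.9)
    expect_equal(sdSnpEffects(smM, k = 1), sds1 / sqrt(m))
  }
  # recoverability: k^{-1/2}
  for (k in c(0.5, 4)) {
    sdsK <- sdSnpEffects(base, k = k)
    expect_equal(unname(sdsK["aR"]), unname(sds1["aR"]) / sqrt(k))
    expect_equal(sdsK[c("aG", "aF")], sds1[c("aG", "aF")])
  }
})

test_that("higher phi never worsens any SD", {
  for (nm in c("single", "pure", "mixed")) {
    d <- canonicalDesign(nm, 100)
    phis <- seq(0.2, 1, by = 0.1)
    sds <- t(vapply(phis, function(p)
      suppressWarnings(sdSnpEffects(summarizeDesign(d, phi = p))),
      numeric(3)))
    expect_true(all(diff(sds[, "aG"]) <= 1e-10))
    expect_true(all(diff(sds[, "aF"]) <= 1e-10))
    expect_true(all(diff(sds[, "aR"]) <= 1e-10))
  }
})

test_that("HWE (GWAS) SDs match direct substitution", {
  got <- gwasSd(p = 0.5, nTotal = 1, nGroup = 1, gSize = 2, k = 1)
  expect_equal(unname(got["aG"]), 1 / sqrt(0.5))
  expect_equal(unname(got["aR"]), 1 / sqrt(0.5))
  expect_equal(unname(got["aF"]), 1 / sqrt(0.5 * (2 - 1 / (2 - 1)) * 1))
  # boundary allele frequencies carry no information
  expect_true(all(gwasSd(1, 100, 10, 10) == Inf))
  expect_true(all(gwasSd(0, 100, 10, 10) == Inf))
})

test_that("coefficient table reports the reference designs at 2 dp", {
  tab <- table3Report()
  rownames(tab) <- tab$design
  expect_equal(tab["pure", c("aG", "aF", "aR")],
               data.frame(aG = 1.52, aF = 1.96, aR = 1, row.names = "pure"))
  expect_equal(tab["mixed", "aF"], 2)
  expect_equal(tab["mixed", "aG"], 1.41)
  expect_equal(tab["single", "aF"], 3.09)
  expect_equal(tab["pure_dominance", c("aF", "dG", "dF")],
               data.frame(aF = 2.4, dG = 2.91, dF = 3.76,
                          row.names = "pure_dominance"))
  # no-dominance designs cannot report dominance SDs
  expect_true(all(is.infinite(unlist(tab["pure", c("dG", "dF", "dR")]))))
  # the k used for scaling cancels in the reported coefficients
  expect_equal(table3Report(k = 4), table3Report())
})

test_that("precisionReport accepts phi or r0 but not both", {
  d <- canonicalDesign("pure", 100)
  expect_error(precisionReport(d), "exactly one")
  expect_error(precisionReport(d, phi = 1, r0 = 2), "exactly one")
  repPhi <- precisionReport(d, phi = 1)
  expect_s4_class(repPhi, "PrecisionReport")
  # large r0 drives phi -> 1, recovering the phi = 1 report
  repR0 <- precisionReport(d, r0 = 50)
  expect_equal(repR0@sd, repPhi@sd, tolerance = 1e-4)
  withDom <- suppressWarnings(
    precisionReport(d, phi = 1, aG = 0.4, aF = 0.4, aR = 0.4))
  expect_named(withDom@sd, c("aG", "aF", "aR", "dG", "dF", "dR"))
})
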