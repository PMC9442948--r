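## Analytic precision engine.
##
## All standard deviations come from the Fisher information of the
## complete-data epidemic likelihood in the small-effect regime. The
## susceptibility/infectivity SDs are the square roots of the diagonal of the
## inverse of the 2x2 information matrix M (equivalently the reciprocal
## square roots of the Schur complements of M), which is how the published
## closed forms for the reference designs arise as special cases.

degenerateWarn <- function(what) {
  warning(warningCondition(
    paste0("non-positive information for ", what,
           ": returning +Inf (design degenerate or small-effect ",
           "approximation broken)"),
    class = c("sirdesign_degenerate", "warning")))
}

sdFromInfo <- function(info, what, warn = TRUE) {
  if (is.na(info) || info <= 1e-12) {
    if (warn) degenerateWarn(what)
    return(Inf)
  }
  1 / sqrt(info)
}

## contrast averages for W/Y; `seed` and `cont` are per-group columns
WYterms <- function(sm, seedCol, contCol) {
  pg <- sm@perGroup
  w <- if (length(unique(pg$nCont)) == 1L) rep(1, nrow(pg)) else pg$nCont
  s <- pg[[seedCol]]; co <- pg[[contCol]]
  m <- wmean(co, w)
  h <- sm@h
  phiNc <- sm@phi * sm@nCont
  if (h >= 1 || phiNc <= 0)  # no contact infections: seeder terms vanish
    return(c(W = 0, Y = 0))
  W <- -log(h) * wmean((co - m) * (s - co), w)
  Y <- (1 - h) * wmean((s - co)^2, w) -
    (sm@nSeed / phiNc) * log(h)^2 * wmean(s - co, w)^2
  c(W = W, Y = Y)
}

#' Seeder-contrast information intermediates W and Y
#'
#' The scalars \eqn{W = -\log(h)\langle(\chi_{cont}-\langle\chi_{cont}\rangle)
#' (\chi_{seed}-\chi_{cont})\rangle} and
#' \eqn{Y = (1-h)\langle(\chi_{seed}-\chi_{cont})^2\rangle -
#' (N_{seed}/\phi N_{cont})\log^2(h)\langle\chi_{seed}-\chi_{cont}\rangle^2}
#' quantify the information about infectivity carried by the genotype
#' contrast between seeders and contacts early in each epidemic.
#'
#' @param summary a [DesignSummary-class]
#' @return named numeric vector c(W, Y)
#' @export
computeWY <- function(summary) {
  stopifnot(is(summary, "DesignSummary"))
  if (summary@h <= 0)
    stop("degenerate design: h = 0 (log divergence)", call. = FALSE)
  WYterms(summary, "chiSeed", "chiCont")
}

#' Fisher information matrix for the susceptibility/infectivity SNP effects
#'
#' Builds the 2x2 information matrix for (a_g, a_f) as the sum of a
#' contact-infection term (scaling with the expected number of infected
#' contacts, N_group * phi * N_cont) and a seeder term (scaling with
#' N_group * N_seed) built from the W/Y contrasts. Also carries the
#' homozygosity-based analogues WH/YH used for the infectivity dominance
#' factor.
#'
#' @param summary a [DesignSummary-class]
#' @return a [FisherInfo-class]
#' @export
fisherInfoGF <- function(summary) {
  stopifnot(is(summary, "DesignSummary"))
  wy <- computeWY(summary)
  wyH <- WYterms(summary, "HSeed", "HCont")
  av <- summary@averages
  A <- summary@nGroup * summary@phi * summary@nCont
  B <- summary@nGroup * summary@nSeed
  M <- A * matrix(c(av["HCont"] - av["chiCont"]^2, av["varChiCont"],
                    av["varChiCont"], av["varChiCont"]), 2, 2) +
       B * matrix(c(0, wy["W"], wy["W"], 2 * wy["W"] + wy["Y"]), 2, 2)
  dimnames(M) <- list(c("a_g", "a_f"), c("a_g", "a_f"))
  new("FisherInfo", M = M, W = unname(wy["W"]), Y = unname(wy["Y"]),
      WH = unname(wyH["W"]), YH = unname(wyH["Y"]))
}

setMethod("show", "FisherInfo", function(object) {
  cat("FisherInfo for (a_g, a_f):\n")
  print(object@M)
  cat(sprintf("W = %.6g, Y = %.6g (WH = %.6g, YH = %.6g)\n",
              object@W, object@Y, object@WH, object@YH))
})

#' Analytic SDs of the SNP effects a_g, a_f, a_r
#'
#' Susceptibility and infectivity SDs are obtained by inverting the Fisher
#' information matrix of [fisherInfoGF()]; the recoverability SD is
#' \eqn{1/\sqrt{k N_{group}(N_{seed}+\phi N_{cont})(\bar H - \bar\chi^2)}}.
#' A non-positive information (non-identifiable or pathological design) maps
#' to +Inf with a warning of class "sirdesign_degenerate", never an error, so
#' optimisers can traverse bad regions.
#'
#' @param summary a [DesignSummary-class]
#' @param k gamma shape of the infectious-duration distribution
#' @return named numeric c(aG, aF, aR) of posterior SDs
#' @examples
#' sm <- summarizeDesign(canonicalDesign("pure", 100), phi = 1)
#' sdSnpEffects(sm) * sqrt(nTotal(sm))
#' @export
sdSnpEffects <- function(summary, k = 1) {
  stopifnot(is(summary, "DesignSummary"), k > 0)
  M <- fisherInfoGF(summary)@M
  tol <- 1e-12 * max(1, abs(M[1, 1]), abs(M[2, 2]))
  infoG <- if (M[2, 2] > tol) M[1, 1] - M[1, 2]^2 / M[2, 2] else M[1, 1]
  infoF <- if (M[1, 1] > tol) M[2, 2] - M[1, 2]^2 / M[1, 1] else M[2, 2]
  av <- summary@averages
  infoR <- k * summary@nGroup * (summary@nSeed + summary@phi * summary@nCont) *
    (av["HBar"] - av["chiBar"]^2)
  c(aG = sdFromInfo(infoG, "a_g"),
    aF = sdFromInfo(infoF, "a_f"),
    aR = sdFromInfo(unname(infoR), "a_r"))
}

#' Analytic SDs of the dominance factors
#'
#' The dominance SDs scale as 1/|a| in the corresponding additive effect and
#' replace the homozygote-balance contrasts by homozygosity contrasts:
#' \eqn{SD(\Delta_g) = 1/(|a_g|\sqrt{N_{group}\phi N_{cont}
#' (\langle H_{cont}\rangle - \langle H_{cont}\rangle^2)})}, the infectivity
#' analogue uses Var(H_cont) with the WH/YH seeder contrasts, and
#' \eqn{SD(\Delta_r) = 1/(|a_r|\sqrt{k N_{group}(N_{seed}+\phi N_{cont})
#' (\bar H - \bar H^2)})}. A zero additive effect makes the dominance factor
#' unidentifiable (+Inf).
#'
#' @param summary a [DesignSummary-class]
#' @param aG,aF,aR additive SNP effect sizes
#' @param k gamma shape of the infectious-duration distribution
#' @return named numeric c(dG, dF, dR)
#' @export
sdDominance <- function(summary, aG, aF, aR, k = 1) {
  stopifnot(is(summary, "DesignSummary"), k > 0)
  fi <- fisherInfoGF(summary)
  av <- summary@averages
  A <- summary@nGroup * summary@phi * summary@nCont
  B <- summary@nGroup * summary@nSeed
  infoDg <- A * (av["HCont"] - av["HCont"]^2)
  infoDf <- A * av["varHCont"] + B * (2 * fi@WH + fi@YH)
  infoDr <- k * summary@nGroup * (summary@nSeed + summary@phi * summary@nCont) *
    (av["HBar"] - av["HBar"]^2)
  scale1 <- function(a, info, what) {
    if (a == 0) return(Inf)
    sdFromInfo(unname(info), what) / abs(a)
  }
  c(dG = scale1(aG, infoDg, "Delta_g"),
    dF = scale1(aF, infoDf, "Delta_f"),
    dR = scale1(aR, infoDr, "Delta_r"))
}

#' Closed-form infectivity SD for the three reference design families
#'
#' Evaluates the printed design-specific formulas (phi = 1 is baked into the
#' single/pure forms; the mixed form is the negligible-seeder limit):
#' \describe{
#'   \item{single}{\eqn{1/\sqrt{N(h(1-h) - \frac{h^2}{1-h}\log^2 h)
#'     (\chi_{seed}-\chi_{cont})^2}}}
#'   \item{pure}{\eqn{1/\sqrt{N(2h(1-h) - \frac{h^2}{1-h}\log^2 h)}}}
#'   \item{mixed}{\eqn{1/\sqrt{N(1-\chi_{cont,1}^2)\chi_{cont,1}^2}} with
#'     group 2 at \eqn{-\chi_{cont,1}}}
#' }
#'
#' @param designType "single", "pure" or "mixed"
#' @param h seeder fraction (N_seed/G_size under phi = 1); single/pure only
#' @param chiSeed,chiCont homozygote balances (chiCont is the group-1 value
#'   for the mixed design)
#' @param nTotal total number of individuals
#' @return the SD of a_f (+Inf when degenerate)
#' @examples
#' sdClosedForm("single", h = 0.15, chiSeed = -1, chiCont = 0.8, nTotal = 1)
#' @export
sdClosedForm <- function(designType = c("single", "pure", "mixed"),
                         h = NULL, chiSeed = NULL, chiCont = NULL,
                         nTotal = 1) {
  designType <- match.arg(designType)
  if (designType %in% c("single", "pure")) {
    stopifnot(!is.null(h), h > 0, h < 1)
    base <- h * (1 - h) - h^2 / (1 - h) * log(h)^2
  }
  info <- switch(designType,
    single = nTotal * base * (chiSeed - chiCont)^2,
    pure = nTotal * (base + h * (1 - h)),
    mixed = nTotal * (1 - chiCont^2) * chiCont^2)
  sdFromInfo(info, "a_f", warn = FALSE)
}

#' SNP-effect SDs for a Hardy-Weinberg population (GWAS setting)
#'
#' When genotypes are allocated randomly at allele frequency p under
#' Hardy-Weinberg equilibrium (rather than controlled by the experimenter),
#' the SDs become
#' \eqn{SD(a_g) = 1/\sqrt{2p(1-p)N_{total}}},
#' \eqn{SD(a_f) = 1/\sqrt{2p(1-p)(2 - 1/(G_{size}-1))N_{group}}},
#' \eqn{SD(a_r) = 1/\sqrt{2p(1-p)k N_{total}}}.
#' The infectivity SD scales with the number of groups, not individuals:
#' many small groups beat few large ones for a_f.
#'
#' @param p frequency of the A allele, in (0, 1); the boundary gives +Inf
#' @param nTotal total number of individuals
#' @param nGroup number of contact groups
#' @param gSize individuals per group (>= 2)
#' @param k gamma shape of the infectious-duration distribution
#' @return named numeric c(aG, aF, aR)
#' @export
gwasSd <- function(p, nTotal, nGroup, gSize, k = 1) {
  stopifnot(p >= 0, p <= 1, gSize >= 2, k > 0)
  het <- 2 * p * (1 - p)
  c(aG = sdFromInfo(het * nTotal, "a_g", warn = FALSE),
    aF = sdFromInfo(het * (2 - 1 / (gSize - 1)) * nGroup, "a_f", warn = FALSE),
    aR = sdFromInfo(het * k * nTotal, "a_r", warn = FALSE))
}

## idealised (proportion-space) compositions of the five reference designs,
## with exact target proportions and, for the mixed families, a negligible
## seeder fraction. Used for reporting SD coefficients.
idealDesign <- function(name, seederEps = 1e-9) {
  g <- function(s, co) groupDesign(setNames(s, GENOTYPES),
                                   setNames(co, GENOTYPES))
  pAA <- (1 + 1 / sqrt(2)) / 2
  pD <- (0.9 + 1 / sqrt(2)) / 2 # mixed-dominance AA share (chi = 1/sqrt 2, 10% AB)
  switch(name,
    single = experimentDesign(list(
      g(c(0, 0, 0.15), 0.85 * c(0.9, 0, 0.1)))),
    pure = experimentDesign(list(
      g(c(0.47, 0, 0), c(0.53, 0, 0)), g(c(0.47, 0, 0), c(0, 0, 0.53)),
      g(c(0, 0, 0.47), c(0.53, 0, 0)), g(c(0, 0, 0.47), c(0, 0, 0.53)))),
    pure_dominance = experimentDesign(unlist(lapply(1:3, function(i)
      lapply(1:3, function(j) {
        s <- co <- c(0, 0, 0); s[i] <- 0.47; co[j] <- 0.53
        g(s, co)
      })), recursive = FALSE)),
    mixed = experimentDesign(list(
      g(c(seederEps, 0, 0), (1 - seederEps) * c(pAA, 0, 1 - pAA)),
      g(c(seederEps, 0, 0), (1 - seederEps) * c(1 - pAA, 0, pAA)))),
    mixed_dominance = experimentDesign(list(
      g(c(seederEps, 0, 0), (1 - seederEps) * c(pD, 0.1, 0.9 - pD)),
      g(c(seederEps, 0, 0), (1 - seederEps) * c(0.1, 0.8, 0.1)),
      g(c(seederEps, 0, 0), (1 - seederEps) * c(0.9 - pD, 0.1, pD)))))
}

#' SD coefficients for the five reference designs
#'
#' Evaluates the general analytic pipeline on the idealised compositions of
#' the five reference designs (phi = 1; the mixed designs in their
#' negligible-seeder limit; the dominance designs at their exact optimum
#' compositions) and reports each SD as a coefficient: of
#' \eqn{1/\sqrt{N_{total}}} for a_g and a_f, of \eqn{1/\sqrt{k N_{total}}}
#' for a_r, of \eqn{1/(|a|\sqrt{N_{total}})} for the dominance factors
#' (\eqn{1/(|a_r|\sqrt{k N_{total}})} for dR). Coefficients are rounded to
#' two decimal places.
#'
#' @param k gamma shape used for the a_r scaling (the coefficient itself is
#'   k-free by construction)
#' @return data.frame with one row per design
#' @export
table3Report <- function(k = 1) {
  designs <- c("single", "pure", "pure_dominance", "mixed", "mixed_dominance")
  rows <- lapply(designs, function(nm) {
    d <- idealDesign(nm)
    sm <- summarizeDesign(d, phi = 1)
    sc <- sqrt(nTotal(d))
    a <- suppressWarnings(sdSnpEffects(sm, k = k))
    dm <- suppressWarnings(sdDominance(sm, aG = 1, aF = 1, aR = 1, k = k))
    data.frame(design = nm,
               aG = round(a["aG"] * sc, 2), aF = round(a["aF"] * sc, 2),
               aR = round(a["aR"] * sqrt(k) * sc, 2),
               dG = round(dm["dG"] * sc, 2), dF = round(dm["dF"] * sc, 2),
               dR = round(dm["dR"] * sqrt(k) * sc, 2), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Analytic precision report for an arbitrary design
#'
#' The calculator surface: takes a design plus phi (or R0, converted through
#' the final-size relation with the design's own seeder fraction) and the
#' recovery shape k, and returns the posterior SDs of the SNP effects, plus
#' the dominance factors when effect sizes are supplied.
#'
#' @param design an [ExperimentDesign-class]
#' @param phi fraction of contacts expected to become infected (exactly one
#'   of phi and r0 must be given)
#' @param r0 basic reproduction number (beta * G_size / gamma at baseline)
#' @param k gamma shape of the infectious-duration distribution
#' @param aG,aF,aR optional SNP effect sizes enabling dominance SDs
#' @param dominantAllele complete-dominance recoding passed to
#'   [summarizeDesign()]
#' @return a [PrecisionReport-class]
#' @export
precisionReport <- function(design, phi = NULL, r0 = NULL, k = 1,
                            aG = NULL, aF = NULL, aR = NULL,
                            dominantAllele = "none") {
  if (is.null(phi) == is.null(r0))
    stop("supply exactly one of phi and r0", call. = FALSE)
  if (!is.null(r0)) {
    gsz <- vapply(design@groups, function(g) sum(g@seeders) + sum(g@contacts),
                  0)
    ns <- vapply(design@groups, function(g) sum(g@seeders), 0)
    phi <- finalSizePhi(r0, h0 = mean(ns / gsz))
  }
  sm <- summarizeDesign(design, phi = phi, dominantAllele = dominantAllele)
  sds <- sdSnpEffects(sm, k = k)
  if (!is.null(aG) && !is.null(aF) && !is.null(aR))
    sds <- c(sds, sdDominance(sm, aG, aF, aR, k = k))
  new("PrecisionReport", sd = sds, method = "analytic_general",
      nTotal = nTotal(design))
}

setMethod("show", "PrecisionReport", function(object) {
  cat(sprintf("PrecisionReport (%s), N_total = %g\n",
              object@method, object@nTotal))
  sds <- object@sd
  for (nm in names(sds))
    cat(sprintf("  SD(%s) = %.4g  [coefficient %.2f / sqrt(N_total)]\n",
                nm, sds[nm], sds[nm] * sqrt(object@nTotal)))
})
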