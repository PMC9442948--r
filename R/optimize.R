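## Numerical optimisation of design parameters against the analytic SDs.
## All objectives are smooth scalar functions, so bounded golden-section /
## Brent search (stats::optimize) is sufficient; no stochastic optimiser.

## parametric proportion-space designs (group totals normalised to 1)
idealSingleFrac <- function(s, chiSeed = -1, chiCont = 0.8) {
  role <- function(tot, chi) setNames(tot * c((1 + chi) / 2, 0, (1 - chi) / 2),
                                      GENOTYPES)
  experimentDesign(list(groupDesign(role(s, chiSeed), role(1 - s, chiCont))))
}

idealPureFrac <- function(s) {
  experimentDesign(lapply(list(c(1, 1), c(1, 3), c(3, 1), c(3, 3)),
    function(cm) {
      sd <- co <- setNames(numeric(3), GENOTYPES)
      sd[cm[1]] <- s; co[cm[2]] <- 1 - s
      groupDesign(sd, co)
    }))
}

idealMixedFrac <- function(s, chi = 1 / sqrt(2)) {
  role <- function(tot, x) setNames(tot * c((1 + x) / 2, 0, (1 - x) / 2),
                                    GENOTYPES)
  experimentDesign(list(
    groupDesign(setNames(c(s, 0, 0), GENOTYPES), role(1 - s, chi)),
    groupDesign(setNames(c(s, 0, 0), GENOTYPES), role(1 - s, -chi))))
}

#' Optimal seeder fraction for a design family
#'
#' Minimises the analytic SD of the infectivity SNP effect a_f over the
#' seeder fraction. At phi = 1 the single/pure closed forms are minimised
#' over h in (0.01, 0.99) by bounded scalar search; for phi < 1 the general
#' pipeline is minimised over the per-group seeder fraction (and the
#' corresponding h is reported). For the mixed family the SD is monotone
#' decreasing in the number of seeders, so the reported optimum sits at the
#' smallest seeder fraction allowed (`minSeedFraction`, default 0.03,
#' i.e. about 3 seeders per group of 100 — enough to make epidemic extinction
#' unlikely).
#'
#' @param designType "single", "pure" or "mixed"
#' @param nTotal total number of individuals (scales the reported SD only;
#'   the argmin is invariant)
#' @param phi fraction of contacts that become infected
#' @param r0 alternative to phi: basic reproduction number, from which the
#'   final-size phi is recomputed for every candidate seeder fraction
#' @param minSeedFraction smallest admissible seeder fraction (mixed family)
#' @return list with elements `par` (h and/or seeder fraction), `sd`
#'   (achieved SD of a_f), `objective` tag, and a search `trace`
#' @examples
#' optimizeSeederFraction("pure")$par
#' @export
optimizeSeederFraction <- function(designType = c("single", "pure", "mixed"),
                                   nTotal = 1, phi = 1, r0 = NULL,
                                   minSeedFraction = 0.03) {
  designType <- match.arg(designType)
  stopifnot(nTotal >= 1)
  phiAt <- function(s) if (is.null(r0)) phi else finalSizePhi(r0, s)
  lower <- 0.01; upper <- 0.99
  if (designType == "mixed") {
    obj <- function(s) suppressWarnings(sdSnpEffects(
      summarizeDesign(idealMixedFrac(s), phi = phiAt(s)))["aF"]) / sqrt(nTotal)
    grid <- seq(minSeedFraction, 0.5, length.out = 40)
    trace <- data.frame(s = grid, sd = vapply(grid, obj, 0))
    sStar <- minSeedFraction
    return(list(designType = designType, objective = "min_sd_af",
                par = c(s = sStar, h = sStar / (sStar + phi * (1 - sStar))),
                sd = obj(sStar), monotone = all(diff(trace$sd) >= 0),
                trace = trace))
  }
  if (is.null(r0) && phi == 1) {
    obj <- function(h) sdClosedForm(designType, h = h, chiSeed = -1,
                                    chiCont = 0.8, nTotal = nTotal)
    opt <- optimize(obj, c(lower, upper), tol = 1e-6)
    hStar <- opt$minimum
    sStar <- hStar
  } else {
    build <- if (designType == "pure") idealPureFrac else idealSingleFrac
    obj <- function(s) suppressWarnings(sdSnpEffects(
      summarizeDesign(build(s), phi = phiAt(s)))["aF"]) / sqrt(nTotal)
    opt <- optimize(obj, c(lower, upper), tol = 1e-6)
    sStar <- opt$minimum
    hStar <- sStar / (sStar + phiAt(sStar) * (1 - sStar))
  }
  grid <- seq(lower, upper, length.out = 50)
  list(designType = designType, objective = "min_sd_af",
       par = c(s = sStar, h = hStar), sd = unname(obj(sStar)),
       trace = data.frame(s = grid, sd = vapply(grid, obj, 0)))
}

#' Optimal contact genotype composition
#'
#' \describe{
#'   \item{mixed}{minimises the closed-form a_f SD over the group-1
#'     homozygote balance chi in (0, 1); the optimum is chi = 1/sqrt(2),
#'     i.e. about an 85\%/15\% AA/BB split (group 2 mirrored).}
#'   \item{single}{the a_f SD is minimised at chi_cont = 1 where the a_g SD
#'     diverges; returns the trade-off curve, the conventional compromise
#'     chi_cont = 0.8 (flagged heuristic) and the equal-precision point where
#'     SD(a_g) = SD(a_f).}
#'   \item{mixed_dominance}{grid search over the heterozygote share and
#'     homozygote balance of the three cyclically permuted contact mixtures,
#'     minimising the SD of the infectivity dominance factor; the 80/10/10
#'     blueprint is included in the candidate set.}
#' }
#'
#' @param designType "mixed", "single" or "mixed_dominance"
#' @param h seeder fraction used for the single-group trade-off
#' @return list with the argmin composition, achieved SDs and search trace
#' @export
optimizeContactMix <- function(designType = c("mixed", "single",
                                              "mixed_dominance"),
                               h = 0.15) {
  designType <- match.arg(designType)
  if (designType == "mixed") {
    obj <- function(chi) sdClosedForm("mixed", chiCont = chi, nTotal = 1)
    opt <- optimize(obj, c(1e-6, 1 - 1e-6), tol = 1e-9)
    chi <- opt$minimum
    grid <- seq(0.05, 0.95, length.out = 50)
    return(list(designType = designType, objective = "min_sd_af",
                par = c(chiCont = chi),
                contacts = c(AA = (1 + chi) / 2, AB = 0, BB = (1 - chi) / 2),
                sd = obj(chi),
                trace = data.frame(chi = grid, sd = vapply(grid, obj, 0))))
  }
  if (designType == "single") {
    sdAg <- function(chi) 1 / sqrt(pmax((1 - h) * (1 - chi^2), 0))
    sdAf <- function(chi) sdClosedForm("single", h = h, chiSeed = -1,
                                       chiCont = chi, nTotal = 1)
    gap <- function(chi) sdAg(chi) - sdAf(chi)
    eq <- uniroot(gap, c(0.5, 1 - 1e-9), tol = 1e-9)$root
    grid <- seq(0, 0.99, length.out = 100)
    return(list(designType = designType,
                objective = "min_sd_af_subject_to_ag",
                par = c(chiCont = 0.8), heuristic = TRUE,
                equalPrecision = c(chiCont = eq),
                sd = c(aG = sdAg(0.8), aF = sdAf(0.8)),
                trace = data.frame(chi = grid, sdAg = sdAg(grid),
                                   sdAf = vapply(grid, sdAf, 0))))
  }
  ## mixed_dominance: cyclic 3-group mixtures parameterised by the
  ## heterozygote share pAB and homozygote balance chi of group 1
  cand <- expand.grid(pAB = seq(0.05, 0.45, by = 0.05),
                      chi = seq(0.3, 0.9, by = 0.05))
  cand <- cand[cand$chi <= 1 - cand$pAB, ]
  cand <- rbind(cand, data.frame(pAB = 0.1, chi = 0.7)) # 80/10/10 blueprint
  evalOne <- function(pAB, chi) {
    p <- c((1 - pAB + chi) / 2, pAB, (1 - pAB - chi) / 2)
    eps <- 1e-9
    des <- experimentDesign(lapply(
      list(p, p[c(3, 1, 2)], p[c(2, 3, 1)]),
      function(pp) groupDesign(setNames(c(eps, 0, 0), GENOTYPES),
                               setNames((1 - eps) * pp, GENOTYPES))))
    sm <- summarizeDesign(des, phi = 1)
    suppressWarnings(sdDominance(sm, 1, 1, 1)["dF"])
  }
  cand$sdDf <- mapply(evalOne, cand$pAB, cand$chi)
  best <- cand[which.min(cand$sdDf), ]
  list(designType = designType, objective = "min_sd_dominance",
       par = c(pAB = best$pAB, chi = best$chi),
       contacts = c(AA = (1 - best$pAB + best$chi) / 2, AB = best$pAB,
                    BB = (1 - best$pAB - best$chi) / 2),
       sd = best$sdDf, blueprint = c(AA = 0.8, AB = 0.1, BB = 0.1),
       trace = cand)
}

#' Compare designs by analytic precision
#'
#' Evaluates the precision engine on each design and reports the SDs, the
#' pairwise a_f SD ratios, and their squares (the relative sample sizes
#' needed for equal precision).
#'
#' @param designs named list of [ExperimentDesign-class] objects
#' @param phi fraction of contacts that become infected
#' @param k gamma shape of the infectious-duration distribution
#' @return list with a per-design `table`, the a_f SD `ratios` matrix and
#'   the `sampleSizeRatios` matrix (squared ratios)
#' @export
compareDesigns <- function(designs, phi = 1, k = 1) {
  stopifnot(is.list(designs), length(designs) >= 1)
  if (is.null(names(designs)))
    names(designs) <- paste0("design", seq_along(designs))
  nt <- vapply(designs, nTotal, 0)
  if (length(unique(round(nt, 6))) > 1L)
    warning("designs do not share N_total; SD ratios mix sample sizes")
  tab <- do.call(rbind, lapply(names(designs), function(nm) {
    sm <- summarizeDesign(designs[[nm]], phi = phi)
    sds <- suppressWarnings(sdSnpEffects(sm, k = k))
    data.frame(design = nm, nTotal = nTotal(designs[[nm]]),
               sdAg = sds["aG"], sdAf = sds["aF"], sdAr = sds["aR"],
               row.names = NULL)
  }))
  ratios <- outer(tab$sdAf, tab$sdAf, "/")
  dimnames(ratios) <- list(tab$design, tab$design)
  tab <- tab[order(tab$sdAf), ]
  list(table = tab, ratios = ratios, sampleSizeRatios = ratios^2)
}
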