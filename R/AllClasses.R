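#' @import methods
#' @importFrom stats optim optimize uniroot rexp rgamma rnorm runif rmultinom
#'   dgamma setNames var sd quantile optimHess
#' @importFrom utils read.csv write.csv modifyList
NULL

GENOTYPES <- c("AA", "AB", "BB")

## genotype count vectors are plain named numerics c(AA=, AB=, BB=).
## Counts are allowed to be non-integer so that designs can be analysed in
## proportion space (e.g. exact optimum compositions, seeder -> 0 limits);
## canonicalDesign() always returns integer realisations.
checkGenotypeCounts <- function(x, what = "genotype counts") {
  if (!is.numeric(x) || length(x) != 3L || !identical(names(x), GENOTYPES))
    return(sprintf("%s must be a numeric vector with names AA, AB, BB", what))
  if (anyNA(x) || any(x < 0))
    return(sprintf("%s must be non-negative and non-missing", what))
  TRUE
}

#' Class for the composition of one contact group
#'
#' A contact group is described by the SNP genotype counts of its seeders
#' (individuals infected at time 0) and its contacts (initially susceptible
#' individuals). Counts may be non-integer, which is useful when working with
#' idealised compositions in proportion space.
#'
#' @slot seeders named numeric vector of genotype counts (AA, AB, BB)
#' @slot contacts named numeric vector of genotype counts (AA, AB, BB)
#' @export
setClass("GroupDesign",
  representation(seeders = "numeric", contacts = "numeric"),
  validity = function(object) {
    msg <- character()
    for (role in c("seeders", "contacts")) {
      chk <- checkGenotypeCounts(slot(object, role), role)
      if (!isTRUE(chk)) msg <- c(msg, chk)
    }
    if (length(msg)) return(msg)
    if (sum(object@seeders) <= 0)
      return("invalid design: each group needs at least one seeder")
    TRUE
  })

#' Class for a transmission-experiment design
#'
#' An ordered list of contact groups plus a replication count. Replication
#' repeats the whole block of groups; it multiplies the total group number but
#' leaves per-group compositions (and hence all genotype summaries) unchanged.
#'
#' @slot groups list of [GroupDesign-class] objects
#' @slot replicates number of times the block of groups is replicated
#' @export
setClass("ExperimentDesign",
  representation(groups = "list", replicates = "numeric"),
  validity = function(object) {
    if (!length(object@groups))
      return("invalid design: at least one group is required")
    if (!all(vapply(object@groups, is, TRUE, "GroupDesign")))
      return("groups must be a list of GroupDesign objects")
    if (length(object@replicates) != 1L || is.na(object@replicates) ||
        object@replicates < 1 || object@replicates != round(object@replicates))
      return("replicates must be a single integer >= 1")
    TRUE
  })

#' Class for derived genotype-composition summaries of a design
#'
#' Holds the per-group homozygosity H and homozygote balance chi for seeders
#' and contacts, their across-group averages and variances, the seeder
#' fraction h of the final infected population, and the infected-population
#' averages used by the recoverability formulas. All analytic precision
#' formulas consume this object.
#'
#' @slot perGroup data.frame with one row per distinct group (nSeed, nCont,
#'   HSeed, chiSeed, HCont, chiCont)
#' @slot phi assumed fraction of contacts that ultimately become infected
#' @slot h seeder fraction of the final infected population,
#'   \eqn{h = N_{seed}/(N_{seed} + \phi N_{cont})}
#' @slot nGroup total number of contact groups (distinct groups x replicates)
#' @slot nSeed,nCont per-group seeder/contact counts (means across groups)
#' @slot nTotal total number of individuals over all groups and replicates
#' @slot averages named numeric vector: HCont, chiCont, HSeed, chiSeed
#'   (across-group averages), varChiCont, varHCont (population variances
#'   across distinct groups), HBar, chiBar (infected-population averages)
#' @export
setClass("DesignSummary",
  representation(perGroup = "data.frame", phi = "numeric", h = "numeric",
                 nGroup = "numeric", nSeed = "numeric", nCont = "numeric",
                 nTotal = "numeric", averages = "numeric"))

#' Class for the susceptibility/infectivity Fisher information
#'
#' The 2x2 information matrix for the SNP effects (a_g, a_f) together with the
#' scalar intermediates W and Y (and their homozygosity-based analogues WH and
#' YH used for the infectivity dominance factor).
#'
#' @slot M symmetric 2x2 matrix, rows/columns named a_g, a_f
#' @slot W,Y scalar intermediates built from homozygote-balance contrasts
#' @slot WH,YH the same contrasts with homozygosity H in place of chi
#' @export
setClass("FisherInfo",
  representation(M = "matrix", W = "numeric", Y = "numeric",
                 WH = "numeric", YH = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@M), c(2L, 2L))) return("M must be 2x2")
    if (abs(object@M[1, 2] - object@M[2, 1]) > 1e-8 * (1 + max(abs(object@M))))
      return("M must be symmetric")
    TRUE
  })

#' Class for epidemic simulation parameters
#'
#' Parameters of the genetic-epidemiological SIR model: baseline transmission
#' and recovery rates, the gamma shape of infectious durations, SNP additive
#' and dominance effects on the three host traits, the group-effect standard
#' deviation, the residual trait covariance, and optional fixed effects.
#'
#' @slot beta baseline transmission rate (per pair per unit time; the basic
#'   reproduction number at baseline traits is R0 = beta * G_size / gamma)
#' @slot gamma population average recovery rate (1/mean infectious period)
#' @slot k gamma shape of the infectious-duration distribution
#' @slot aG,aF,aR SNP effects: half the log-scale trait difference between the
#'   AA and BB homozygotes for susceptibility, infectivity, recoverability
#' @slot deltaG,deltaF,deltaR scaled dominance factors in [-1, 1]
#' @slot sigmaG standard deviation of the normal group effects
#' @slot Sigma 3x3 residual covariance of the per-individual (g, f, r) traits
#' @slot X design matrix for fixed effects (0-column matrix when absent)
#' @slot bG,bF,bR fixed-effect coefficient vectors sharing X
#' @export
setClass("EpidemicParams",
  representation(beta = "numeric", gamma = "numeric", k = "numeric",
                 aG = "numeric", aF = "numeric", aR = "numeric",
                 deltaG = "numeric", deltaF = "numeric", deltaR = "numeric",
                 sigmaG = "numeric", Sigma = "matrix",
                 X = "matrix", bG = "numeric", bF = "numeric", bR = "numeric"),
  validity = function(object) {
    if (object@beta < 0) return("beta must be >= 0")
    if (object@gamma <= 0 || object@k <= 0) return("gamma and k must be > 0")
    for (d in c(object@deltaG, object@deltaF, object@deltaR))
      if (abs(d) > 1) return("dominance factors must lie in [-1, 1]")
    if (object@sigmaG < 0) return("sigmaG must be >= 0")
    S <- object@Sigma
    if (!identical(dim(S), c(3L, 3L)) || max(abs(S - t(S))) > 1e-8)
      return("Sigma must be a symmetric 3x3 matrix")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return("Sigma must be positive semi-definite")
    TRUE
  })

#' Class for an analytic (or simulation-based) precision report
#'
#' Posterior standard deviations for the SNP effects and, when effect sizes
#' are supplied, the dominance factors. +Inf means "not estimable from this
#' design".
#'
#' @slot sd named numeric vector (aG, aF, aR and optionally dG, dF, dR)
#' @slot method one of "analytic_general", "analytic_closed_form", "simulation"
#' @slot nTotal total number of individuals the SDs refer to
#' @export
setClass("PrecisionReport",
  representation(sd = "numeric", method = "character", nTotal = "numeric"),
  validity = function(object) {
    if (any(object@sd <= 0, na.rm = TRUE))
      return("all reported SDs must be positive (+Inf allowed)")
    TRUE
  })

#' Class for a maximum-likelihood fit of the transmission model
#'
#' @slot estimate named numeric vector of point estimates (natural scale)
#' @slot se named numeric vector of standard errors (log scale for the
#'   positive parameters beta, gamma, k; +Inf for non-identified directions)
#' @slot vcov approximate covariance of the estimated parameters (inverse
#'   observed information, pseudo-inverted when singular)
#' @slot logLik log-likelihood at the optimum
#' @slot convergence optim convergence code (0 = success)
#' @slot gradient numeric gradient at the optimum (estimation scale)
#' @slot nEvents number of contact infections in the fitted data
#' @export
setClass("SIRFit",
  representation(estimate = "numeric", se = "numeric", vcov = "matrix",
                 logLik = "numeric", convergence = "numeric",
                 gradient = "numeric", nEvents = "numeric"))
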