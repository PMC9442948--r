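#' Construct epidemic simulation parameters
#'
#' @param beta baseline transmission rate per susceptible-infected pair per
#'   unit time (R0 = beta * G_size / gamma at baseline traits)
#' @param gamma population average recovery rate; gamma = 1 defines the time
#'   unit (mean baseline infectious period 1)
#' @param k gamma shape of the infectious-duration distribution
#' @param aG,aF,aR SNP effects on susceptibility, infectivity, recoverability
#' @param deltaG,deltaF,deltaR scaled dominance factors in [-1, 1]
#' @param sigmaG standard deviation of the normal group effects
#' @param Sigma 3x3 residual covariance of per-individual (g, f, r) traits
#' @param X optional fixed-effect design matrix (one row per individual when
#'   used with [drawTraits()])
#' @param bG,bF,bR fixed-effect coefficients (one per column of X)
#' @return an [EpidemicParams-class]
#' @examples
#' epidemicParams(beta = 0.05, gamma = 1, k = 3, aG = 0.5)
#' @export
epidemicParams <- function(beta, gamma = 1, k = 1,
                           aG = 0, aF = 0, aR = 0,
                           deltaG = 0, deltaF = 0, deltaR = 0,
                           sigmaG = 0, Sigma = matrix(0, 3, 3),
                           X = NULL, bG = numeric(), bF = numeric(),
                           bR = numeric()) {
  if (is.null(X)) X <- matrix(0, 0, max(length(bG), length(bF), length(bR)))
  new("EpidemicParams", beta = beta, gamma = gamma, k = k,
      aG = aG, aF = aF, aR = aR,
      deltaG = deltaG, deltaF = deltaF, deltaR = deltaR,
      sigmaG = sigmaG, Sigma = Sigma, X = X,
      bG = as.numeric(bG), bF = as.numeric(bF), bR = as.numeric(bR))
}

#' Transmission rate matching a target basic reproduction number
#'
#' Uses the convention R0 = beta * G_size / gamma at baseline traits (the
#' transmission term is density dependent: the per-susceptible hazard sums
#' the infectivities of all infected groupmates without dividing by group
#' size).
#'
#' @param r0 target basic reproduction number
#' @param gSize group size
#' @param gamma recovery rate
#' @export
betaFromR0 <- function(r0, gSize, gamma = 1) r0 * gamma / gSize

setMethod("show", "EpidemicParams", function(object) {
  cat(sprintf("EpidemicParams: beta = %g, gamma = %g, k = %g\n",
              object@beta, object@gamma, object@k))
  cat(sprintf("  SNP effects a = (%g, %g, %g), dominance = (%g, %g, %g)\n",
              object@aG, object@aF, object@aR,
              object@deltaG, object@deltaF, object@deltaR))
  cat(sprintf("  sigmaG = %g, residual Sigma %s\n", object@sigmaG,
              if (all(object@Sigma == 0)) "= 0" else "supplied"))
})

#' Assign SNP genotypes to individuals
#'
#' Design mode (`design` supplied) expands the exact genotype counts of every
#' group, role by role, into one row per individual (deterministic). HWE mode
#' (`p` and `n` supplied) draws i.i.d. genotypes with Hardy-Weinberg
#' probabilities (p^2, 2p(1-p), (1-p)^2) — the genome-wide association
#' setting where composition cannot be controlled.
#'
#' @param design an [ExperimentDesign-class] (design mode)
#' @param p frequency of the A allele in [0, 1] (HWE mode)
#' @param n number of individuals (HWE mode)
#' @return design mode: data.frame(group, replicate, role, genotype);
#'   HWE mode: character vector of genotypes
#' @export
assignGenotypes <- function(design = NULL, p = NULL, n = NULL) {
  if (!is.null(design)) {
    stopifnot(is(design, "ExperimentDesign"))
    one <- do.call(rbind, lapply(seq_along(design@groups), function(i) {
      g <- design@groups[[i]]
      cnt <- function(x) {
        xi <- round(x)
        if (max(abs(x - xi)) > 1e-8)
          stop("design mode needs integer genotype counts", call. = FALSE)
        xi
      }
      s <- cnt(g@seeders); co <- cnt(g@contacts)
      data.frame(group = i,
                 role = rep(c("seeder", "contact"), c(sum(s), sum(co))),
                 genotype = c(rep(GENOTYPES, s), rep(GENOTYPES, co)))
    }))
    out <- do.call(rbind, lapply(seq_len(design@replicates), function(r)
      cbind(one[1], replicate = r, one[2:3])))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(!is.null(p), !is.null(n))
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  sample(GENOTYPES, n, replace = TRUE,
         prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
}

#' Draw individual trait deviations
#'
#' Builds the per-individual log-scale deviations (g, f, r) as the sum of the
#' SNP contribution ([genotypeEffect()]), the fixed-effect contribution X b,
#' and multivariate-normal residuals with covariance Sigma (independent
#' across individuals, correlated across the three traits).
#'
#' @param params an [EpidemicParams-class]
#' @param genotypes character vector of genotypes (one per individual)
#' @return data.frame(genotype, g, f, r)
#' @export
drawTraits <- function(params, genotypes) {
  stopifnot(is(params, "EpidemicParams"))
  n <- length(genotypes)
  g <- genotypeEffect(genotypes, params@aG, params@deltaG)
  f <- genotypeEffect(genotypes, params@aF, params@deltaF)
  r <- genotypeEffect(genotypes, params@aR, params@deltaR)
  if (nrow(params@X) > 0) {
    if (nrow(params@X) != n)
      stop("X must have one row per individual", call. = FALSE)
    if (length(params@bG)) g <- g + drop(params@X %*% params@bG)
    if (length(params@bF)) f <- f + drop(params@X %*% params@bF)
    if (length(params@bR)) r <- r + drop(params@X %*% params@bR)
  }
  if (any(params@Sigma != 0)) {
    eps <- MASS::mvrnorm(n, mu = numeric(3), Sigma = params@Sigma)
    g <- g + eps[, 1]; f <- f + eps[, 2]; r <- r + eps[, 3]
  }
  data.frame(genotype = genotypes, g = g, f = f, r = r)
}

#' Simulate one contact-group epidemic
#'
#' Exact continuous-time simulation of the SIR model with individual trait
#' variation. Each susceptible j is infected with hazard
#' \eqn{\lambda_j = \beta e^{G_z} e^{g_j} \sum_{i \in I} e^{f_i}}; hazards
#' are piecewise constant between events, so the next infection comes from
#' an exponential race (re-drawn after every event) against the scheduled
#' recoveries. Infectious durations are drawn at infection from a gamma
#' distribution with shape k and mean \eqn{(\gamma e^{r_j})^{-1}}. Seeders
#' start infected at t = 0. The epidemic runs until no infected individuals
#' remain (no censoring).
#'
#' @param traits data.frame with columns role ("seeder"/"contact"),
#'   genotype, g, f, r (one row per individual, as from [drawTraits()])
#' @param params an [EpidemicParams-class]
#' @param groupEffect the realised group effect G_z (log-scale)
#' @return `traits` with columns t_inf (0 for seeders, NA if never
#'   infected) and t_rec appended
#' @export
simulateGroup <- function(traits, params, groupEffect = 0) {
  n <- nrow(traits)
  if (!any(traits$role == "seeder"))
    stop("at least one seeder is required", call. = FALSE)
  wS <- exp(traits$g)              # susceptibility weights
  wI <- exp(traits$f)              # infectivity contributions
  rateRec <- params@gamma * exp(traits$r)
  betaG <- params@beta * exp(groupEffect)

  tInf <- rep(NA_real_, n); tRec <- rep(NA_real_, n)
  recTime <- rep(Inf, n)           # scheduled recovery of infected
  infected <- which(traits$role == "seeder")
  susceptible <- which(traits$role == "contact")
  tInf[infected] <- 0
  recTime[infected] <- rgamma(length(infected), shape = params@k,
                              rate = params@k * rateRec[infected])
  Fsum <- sum(wI[infected])
  t <- 0
  while (length(infected)) {
    totRate <- betaG * Fsum * sum(wS[susceptible])
    dtInf <- if (totRate > 0) rexp(1, totRate) else Inf
    iNext <- infected[which.min(recTime[infected])]
    if (t + dtInf < recTime[iNext] && length(susceptible)) {
      t <- t + dtInf
      j <- if (length(susceptible) == 1L) susceptible
           else susceptible[sample.int(length(susceptible), 1L,
                                       prob = wS[susceptible])]
      tInf[j] <- t
      dur <- rgamma(1, shape = params@k, rate = params@k * rateRec[j])
      recTime[j] <- t + dur
      susceptible <- susceptible[susceptible != j]
      infected <- c(infected, j)
      Fsum <- Fsum + wI[j]
    } else {
      t <- recTime[iNext]
      tRec[iNext] <- t
      infected <- infected[infected != iNext]
      Fsum <- Fsum - wI[iNext]
      if (length(infected)) Fsum <- sum(wI[infected]) # refresh rounding
    }
  }
  cbind(traits, t_inf = tInf, t_rec = tRec)
}

#' Simulate a full transmission experiment
#'
#' Expands the design into individuals ([assignGenotypes()]), draws traits
#' and one group effect per contact group, and simulates every group with
#' [simulateGroup()]. The same seed reproduces the event table exactly.
#'
#' @param design an [ExperimentDesign-class]
#' @param params an [EpidemicParams-class]
#' @param seed integer RNG seed (NULL leaves the RNG state alone)
#' @return event table data.frame with columns id, group, replicate, role,
#'   genotype, t_inf, t_rec, G_z (t_inf is 0 for seeders and NA for
#'   never-infected contacts)
#' @examples
#' d <- canonicalDesign("pure", gSize = 30)
#' ev <- simulateExperiment(d, epidemicParams(beta = 0.2, k = 3), seed = 1)
#' head(ev)
#' @export
simulateExperiment <- function(design, params, seed = NULL) {
  stopifnot(is(design, "ExperimentDesign"), is(params, "EpidemicParams"))
  if (!is.null(seed)) set.seed(seed)
  ind <- assignGenotypes(design = design)
  out <- lapply(split(ind, list(ind$replicate, ind$group)), function(gi) {
    traits <- drawTraits(params, gi$genotype)
    traits$role <- gi$role
    gz <- if (params@sigmaG > 0) rnorm(1, 0, params@sigmaG) else 0
    sim <- simulateGroup(traits, params, groupEffect = gz)
    data.frame(group = gi$group[1], replicate = gi$replicate[1],
               role = gi$role, genotype = gi$genotype,
               t_inf = sim$t_inf, t_rec = sim$t_rec, G_z = gz)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$replicate, out$group), ]
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Deterministic final-size fraction of infected contacts
#'
#' Solves the SIR final-size fixed point
#' \eqn{\phi = 1 - \exp(-R_0 (h_0 + (1 - h_0)\phi))}, where h0 is the
#' initial seeder fraction of the group, by damped fixed-point iteration
#' (tolerance 1e-10) with a bisection fallback. R0 follows the convention
#' R0 = beta * G_size / gamma at baseline traits.
#'
#' @param r0 basic reproduction number (>= 0)
#' @param h0 initial seeder fraction of the group, in (0, 1)
#' @return phi, the expected fraction of contacts ultimately infected
#' @examples
#' finalSizePhi(2, h0 = 1e-9)  # ~0.7968
#' @export
finalSizePhi <- function(r0, h0) {
  stopifnot(r0 >= 0, h0 > 0, h0 < 1)
  if (r0 == 0) return(0)
  step <- function(phi) 1 - exp(-r0 * (h0 + (1 - h0) * phi))
  phi <- 1
  for (i in 1:10000) {
    phiNew <- 0.5 * phi + 0.5 * step(phi)
    if (abs(phiNew - phi) < 1e-12) return(phiNew)
    phi <- phiNew
  }
  uniroot(function(x) x - step(x), c(1e-12, 1), tol = 1e-12)$root
}

#' Probability that the epidemic goes extinct before taking off
#'
#' Branching mode returns the branching-process approximation
#' \eqn{\min(1, (1/R_0)^{N_{seed}})}; Monte-Carlo mode simulates groups at
#' baseline traits and reports the fraction of runs that infect less than
#' `threshold` of the contacts.
#'
#' @param r0 basic reproduction number (> 0)
#' @param nSeed number of seeders
#' @param mode "branching" or "monte_carlo"
#' @param gSize group size for Monte-Carlo runs
#' @param nRuns number of Monte-Carlo runs
#' @param threshold infected-contact fraction below which a run counts as
#'   extinct
#' @param k,gamma recovery distribution for Monte-Carlo runs
#' @param seed RNG seed for Monte-Carlo runs
#' @return extinction probability in [0, 1]
#' @export
extinctionProbability <- function(r0, nSeed, mode = c("branching",
                                                      "monte_carlo"),
                                  gSize = 200, nRuns = 2000, threshold = 0.1,
                                  k = 1, gamma = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(r0 > 0, nSeed >= 1)
  if (mode == "branching") return(min(1, (1 / r0)^nSeed))
  if (!is.null(seed)) set.seed(seed)
  params <- epidemicParams(beta = betaFromR0(r0, gSize, gamma),
                           gamma = gamma, k = k)
  nCont <- gSize - nSeed
  traits <- data.frame(genotype = "AA", g = 0, f = 0, r = 0,
                       role = rep(c("seeder", "contact"), c(nSeed, nCont)))
  extinct <- vapply(seq_len(nRuns), function(i) {
    sim <- simulateGroup(traits, params)
    sum(!is.na(sim$t_inf[sim$role == "contact"])) < threshold * nCont
  }, TRUE)
  mean(extinct)
}

#' Read or write an event table
#'
#' Event tables are stored as CSV with columns id, group, replicate, role,
#' genotype, t_inf, t_rec, G_z (empty fields for never-infected contacts).
#' `writeEvents` also writes a JSON sidecar (`<path>.meta.json`) recording
#' the seed and any parameters supplied.
#'
#' @param events event table data.frame
#' @param path CSV file path
#' @param params optional [EpidemicParams-class] recorded in the sidecar
#' @param seed optional seed recorded in the sidecar
#' @return `readEvents` returns the event table data.frame
#' @export
writeEvents <- function(events, path, params = NULL, seed = NULL) {
  write.csv(events, path, row.names = FALSE, na = "")
  meta <- list(schema_version = "1.0", seed = seed)
  if (!is.null(params))
    meta$params <- list(beta = params@beta, gamma = params@gamma,
                        k = params@k, aG = params@aG, aF = params@aF,
                        aR = params@aR, deltaG = params@deltaG,
                        deltaF = params@deltaF, deltaR = params@deltaR,
                        sigmaG = params@sigmaG)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "replicate", "role", "genotype", "t_inf", "t_rec")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ev
}
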