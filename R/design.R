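#' Construct a genotype count vector
#'
#' @param AA,AB,BB non-negative counts of each genotype
#' @return named numeric vector c(AA=, AB=, BB=)
#' @export
genotypeCounts <- function(AA = 0, AB = 0, BB = 0) {
  x <- c(AA = as.numeric(AA), AB = as.numeric(AB), BB = as.numeric(BB))
  chk <- checkGenotypeCounts(x)
  if (!isTRUE(chk)) stop(chk, call. = FALSE)
  x
}

asGenotypeCounts <- function(x, what = "genotype counts") {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) && length(x) == 3L) names(x) <- GENOTYPES
  x <- x[GENOTYPES]
  names(x) <- GENOTYPES
  x[is.na(x)] <- 0
  chk <- checkGenotypeCounts(x, what)
  if (!isTRUE(chk)) stop(chk, call. = FALSE)
  x
}

#' Construct a contact-group design
#'
#' @param seeders,contacts genotype counts (named AA/AB/BB vectors, or plain
#'   length-3 vectors in AA, AB, BB order)
#' @return a [GroupDesign-class] object
#' @examples
#' groupDesign(seeders = c(AA = 0, AB = 0, BB = 15),
#'             contacts = c(AA = 77, AB = 0, BB = 8))
#' @export
groupDesign <- function(seeders, contacts = c(AA = 0, AB = 0, BB = 0)) {
  new("GroupDesign",
      seeders = asGenotypeCounts(seeders, "seeders"),
      contacts = asGenotypeCounts(contacts, "contacts"))
}

#' Construct an experiment design
#'
#' @param groups a list of [GroupDesign-class] objects (a single GroupDesign
#'   is promoted to a one-group list)
#' @param replicates how many times the block of groups is replicated
#' @return an [ExperimentDesign-class] object
#' @export
experimentDesign <- function(groups, replicates = 1) {
  if (is(groups, "GroupDesign")) groups <- list(groups)
  new("ExperimentDesign", groups = groups, replicates = as.numeric(replicates))
}

#' Total number of individuals in a design
#' @param x an ExperimentDesign or DesignSummary
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' Total number of contact groups (including replication)
#' @param x an ExperimentDesign or DesignSummary
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' Seeder fraction of the final infected population
#' @param x a DesignSummary
#' @export
setGeneric("seederFraction", function(x) standardGeneric("seederFraction"))

#' Per-group composition table
#' @param x an ExperimentDesign or DesignSummary
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' Across-group averages and variances
#' @param x a DesignSummary
#' @export
setGeneric("designAverages", function(x) standardGeneric("designAverages"))

#' @rdname nTotal
setMethod("nTotal", "ExperimentDesign", function(x)
  sum(vapply(x@groups, function(g) sum(g@seeders) + sum(g@contacts), 0)) *
    x@replicates)

#' @rdname nGroups
setMethod("nGroups", "ExperimentDesign", function(x)
  length(x@groups) * x@replicates)

#' @rdname groupTable
setMethod("groupTable", "ExperimentDesign", function(x) {
  do.call(rbind, lapply(seq_along(x@groups), function(i) {
    g <- x@groups[[i]]
    data.frame(group = i,
               seedAA = g@seeders["AA"], seedAB = g@seeders["AB"],
               seedBB = g@seeders["BB"],
               contAA = g@contacts["AA"], contAB = g@contacts["AB"],
               contBB = g@contacts["BB"], row.names = NULL)
  }))
})

#' @rdname nTotal
setMethod("nTotal", "DesignSummary", function(x) x@nTotal)
#' @rdname nGroups
setMethod("nGroups", "DesignSummary", function(x) x@nGroup)
#' @rdname seederFraction
setMethod("seederFraction", "DesignSummary", function(x) x@h)
#' @rdname groupTable
setMethod("groupTable", "DesignSummary", function(x) x@perGroup)
#' @rdname designAverages
setMethod("designAverages", "DesignSummary", function(x) x@averages)

setMethod("show", "GroupDesign", function(object) {
  cat("GroupDesign: seeders", paste(object@seeders, collapse = "/"),
      "(AA/AB/BB), contacts", paste(object@contacts, collapse = "/"), "\n")
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign with %d group(s) x %d replicate(s), N_total = %g\n",
              length(object@groups), as.integer(object@replicates),
              nTotal(object)))
  print(groupTable(object))
})

setMethod("show", "DesignSummary", function(object) {
  cat(sprintf("DesignSummary: %g group(s), N_seed = %g, N_cont = %g, phi = %g, h = %.4g\n",
              object@nGroup, object@nSeed, object@nCont, object@phi, object@h))
  av <- object@averages
  cat(sprintf("  <H_cont> = %.4g  <chi_cont> = %.4g  Var(chi_cont) = %.4g\n",
              av["HCont"], av["chiCont"], av["varChiCont"]))
  cat(sprintf("  Hbar = %.4g  chibar = %.4g\n", av["HBar"], av["chiBar"]))
})

## weighted mean / population variance across the distinct groups of one block
wmean <- function(x, w) {
  if (sum(w) <= 0) return(0)
  sum(x * w) / sum(w)
}
wvarPop <- function(x, w) wmean((x - wmean(x, w))^2, w)

roleHchi <- function(counts, dominantAllele = "none") {
  n <- sum(counts)
  if (n <= 0) return(c(H = 0, chi = 0, n = 0))
  switch(dominantAllele,
    none = c(H = unname((counts["AA"] + counts["BB"]) / n),
             chi = unname((counts["AA"] - counts["BB"]) / n), n = n),
    A = c(H = 1,
          chi = unname((counts["AA"] + counts["AB"] - counts["BB"]) / n),
          n = n),
    B = c(H = 1,
          chi = unname((counts["AA"] - counts["AB"] - counts["BB"]) / n),
          n = n))
}

#' Summarise the genotype composition of a design
#'
#' Computes the per-group homozygosity H and homozygote balance chi for
#' seeders and contacts, their across-group averages and population variances,
#' the seeder fraction \eqn{h = N_{seed}/(N_{seed} + \phi N_{cont})} and the
#' infected-population averages \eqn{\bar H} and \eqn{\bar\chi} (seeder/contact
#' mixtures weighted by phi). These are the ingredients of every analytic
#' precision expression.
#'
#' Averaging across groups is unweighted when all groups have equal
#' contact/seeder counts and count-weighted otherwise. Variances use the
#' population (divide-by-N-groups) convention over the distinct groups of one
#' block; replication changes neither averages nor variances.
#'
#' Under complete dominance of one allele the heterozygote is phenotypically
#' indistinguishable from that homozygote; setting `dominantAllele` redefines
#' chi to count the dominant phenotype class against the recessive one and
#' fixes H at 1, after which the no-dominance formulas apply unchanged.
#'
#' @param design an [ExperimentDesign-class] (or single [GroupDesign-class])
#' @param phi assumed fraction of contacts that ultimately become infected,
#'   in [0, 1] (use [finalSizePhi()] to derive it from R0)
#' @param dominantAllele "none" (default), "A" or "B": complete-dominance
#'   recoding of the genotype classes
#' @param allowEmptyContacts permit groups with zero contacts (degenerate
#'   summaries for seeder-only groups)
#' @return a [DesignSummary-class] object
#' @examples
#' d <- canonicalDesign("pure", gSize = 100)
#' summarizeDesign(d, phi = 1)
#' @export
summarizeDesign <- function(design, phi = 1,
                            dominantAllele = c("none", "A", "B"),
                            allowEmptyContacts = FALSE) {
  dominantAllele <- match.arg(dominantAllele)
  if (is(design, "GroupDesign")) design <- experimentDesign(design)
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  if (length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1)
    stop("phi must be a single value in [0, 1]", call. = FALSE)

  pg <- do.call(rbind, lapply(design@groups, function(g) {
    s <- roleHchi(g@seeders, dominantAllele)
    co <- roleHchi(g@contacts, dominantAllele)
    data.frame(nSeed = s["n"], nCont = co["n"],
               HSeed = s["H"], chiSeed = s["chi"],
               HCont = co["H"], chiCont = co["chi"], row.names = NULL)
  }))
  if (any(pg$nSeed + pg$nCont <= 0))
    stop("invalid design: a group has total size 0", call. = FALSE)
  if (!allowEmptyContacts && any(pg$nCont <= 0))
    stop("invalid design: a group has no contacts ",
         "(set allowEmptyContacts = TRUE for a degenerate summary)",
         call. = FALSE)

  wc <- if (length(unique(pg$nCont)) == 1L) rep(1, nrow(pg)) else pg$nCont
  ws <- if (length(unique(pg$nSeed)) == 1L) rep(1, nrow(pg)) else pg$nSeed
  nSeed <- mean(pg$nSeed)
  nCont <- mean(pg$nCont)
  h <- nSeed / (nSeed + phi * nCont)
  HContM <- wmean(pg$HCont, wc); chiContM <- wmean(pg$chiCont, wc)
  HSeedM <- wmean(pg$HSeed, ws); chiSeedM <- wmean(pg$chiSeed, ws)
  denom <- nSeed + phi * nCont
  av <- c(HCont = HContM, chiCont = chiContM,
          HSeed = HSeedM, chiSeed = chiSeedM,
          varChiCont = wvarPop(pg$chiCont, wc),
          varHCont = wvarPop(pg$HCont, wc),
          HBar = (nSeed * HSeedM + phi * nCont * HContM) / denom,
          chiBar = (nSeed * chiSeedM + phi * nCont * chiContM) / denom)
  new("DesignSummary", perGroup = pg, phi = phi, h = h,
      nGroup = nrow(pg) * design@replicates,
      nSeed = nSeed, nCont = nCont, nTotal = nTotal(design), averages = av)
}

## largest-remainder apportionment of `total` units to target proportions
largestRemainder <- function(props, total) {
  stopifnot(abs(sum(props) - 1) < 1e-8, total >= 0)
  raw <- props * total
  out <- floor(raw)
  left <- round(total - sum(out))
  if (left > 0) {
    ord <- order(raw - out, decreasing = TRUE) # stable: ties to earlier class
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  out
}

#' Blueprint designs optimised for SNP-effect precision
#'
#' Returns the integer realisation, at a given group size, of one of the five
#' reference designs:
#' \describe{
#'   \item{single}{one group; ~15\% seeders, all BB; contacts 90\% AA / 10\%
#'     BB (homozygote balance targeted at 0.8).}
#'   \item{pure}{four groups with ~47\% seeders; seeder/contact genotype
#'     combinations (AA,AA), (AA,BB), (BB,AA), (BB,BB).}
#'   \item{pure_dominance}{nine groups with ~47\% seeders; all 3x3
#'     seeder/contact combinations of AA, AB, BB.}
#'   \item{mixed}{two groups with 3 seeders (all AA); contacts split so the
#'     homozygote balance is as close as possible to +1/sqrt(2) in group 1 and
#'     -1/sqrt(2) in group 2 (~85\%/15\% AA/BB and vice versa).}
#'   \item{mixed_dominance}{three groups with 3 seeders (all AA); contacts
#'     80\%/10\%/10\% AA/AB/BB with the proportions permuted cyclically.}
#' }
#' Target proportions are apportioned to integers by largest-remainder
#' rounding within each role; the realised (not target) composition is what
#' [summarizeDesign()] reports.
#'
#' @param name one of "single", "pure", "pure_dominance", "mixed",
#'   "mixed_dominance"
#' @param gSize individuals per group (>= 20 recommended so that the target
#'   proportions are realisable)
#' @param replicates number of replicates of the block
#' @return an [ExperimentDesign-class]
#' @examples
#' canonicalDesign("pure", gSize = 100)
#' @export
canonicalDesign <- function(name = c("single", "pure", "pure_dominance",
                                     "mixed", "mixed_dominance"),
                            gSize = 100, replicates = 1) {
  name <- match.arg(name)
  if (gSize < 7) stop("gSize too small to realise the design", call. = FALSE)
  pureSeed <- round(0.47 * gSize)
  gcount <- function(v) setNames(as.numeric(v), GENOTYPES)
  groups <- switch(name,
    single = {
      ns <- round(0.15 * gSize)
      if (ns < 1) stop("gSize too small: no seeders", call. = FALSE)
      nc <- gSize - ns
      cont <- largestRemainder(c(0.9, 0, 0.1), nc)
      list(groupDesign(gcount(c(0, 0, ns)), gcount(cont)))
    },
    pure = {
      nc <- gSize - pureSeed
      combos <- list(c("AA", "AA"), c("AA", "BB"), c("BB", "AA"), c("BB", "BB"))
      lapply(combos, function(cm) {
        s <- gcount(c(0, 0, 0)); s[cm[1]] <- pureSeed
        co <- gcount(c(0, 0, 0)); co[cm[2]] <- nc
        groupDesign(s, co)
      })
    },
    pure_dominance = {
      nc <- gSize - pureSeed
      combos <- expand.grid(seed = GENOTYPES, cont = GENOTYPES,
                            stringsAsFactors = FALSE)
      lapply(seq_len(nrow(combos)), function(i) {
        s <- gcount(c(0, 0, 0)); s[combos$seed[i]] <- pureSeed
        co <- gcount(c(0, 0, 0)); co[combos$cont[i]] <- nc
        groupDesign(s, co)
      })
    },
    mixed = {
      ns <- 3
      nc <- gSize - ns
      pAA <- (1 + 1 / sqrt(2)) / 2
      c1 <- largestRemainder(c(pAA, 0, 1 - pAA), nc)
      lapply(list(c1, rev(c1)), function(co)
        groupDesign(gcount(c(ns, 0, 0)), gcount(co)))
    },
    mixed_dominance = {
      ns <- 3
      nc <- gSize - ns
      base <- largestRemainder(c(0.8, 0.1, 0.1), nc)
      perms <- list(base, base[c(3, 1, 2)], base[c(2, 3, 1)])
      lapply(perms, function(co)
        groupDesign(gcount(c(ns, 0, 0)), gcount(co)))
    })
  experimentDesign(groups, replicates)
}

#' SNP contribution to a log-scale trait
#'
#' Maps a genotype to its contribution to the fractional (log-scale) trait
#' deviation: AA gives +a, BB gives -a, and the heterozygote AB gives
#' a * delta, where delta in [-1, 1] is the scaled dominance factor (+1/-1 =
#' complete dominance of A/B, 0 = purely additive).
#'
#' @param genotype character vector of "AA", "AB", "BB"
#' @param a additive SNP effect (half the AA - BB trait difference)
#' @param delta scaled dominance factor in [-1, 1]
#' @return numeric vector of trait contributions
#' @examples
#' genotypeEffect(c("AA", "AB", "BB"), a = 0.4, delta = -1)
#' @export
genotypeEffect <- function(genotype, a, delta = 0) {
  if (!all(genotype %in% GENOTYPES))
    stop("unknown genotype label: ",
         paste(setdiff(genotype, GENOTYPES), collapse = ", "), call. = FALSE)
  if (abs(delta) > 1) stop("delta must lie in [-1, 1]", call. = FALSE)
  unname(c(AA = a, AB = a * delta, BB = -a)[genotype])
}

#' Read or write a design configuration file
#'
#' Designs are stored as JSON (canonical) or YAML with the structure
#' `groups: [{seeders: {AA,AB,BB}, contacts: {AA,AB,BB}}, ...],
#' replicates: n`. The epidemic parameters (phi or R0, k) are supplied
#' separately, not in the design file.
#'
#' @param path file path; format chosen by extension (.json, .yml/.yaml)
#' @param design an [ExperimentDesign-class] (for writing)
#' @return `readDesign` returns an [ExperimentDesign-class]
#' @export
readDesign <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  designFromList(cfg)
}

designFromList <- function(cfg) {
  if (is.null(cfg$groups)) stop("design config: missing key 'groups'",
                                call. = FALSE)
  grps <- cfg$groups
  if (is.data.frame(grps)) grps <- split(grps, seq_len(nrow(grps)))
  groups <- lapply(grps, function(g) {
    s <- g$seeders; co <- g$contacts
    if (is.data.frame(s)) s <- as.list(s)
    if (is.data.frame(co)) co <- as.list(co)
    groupDesign(asGenotypeCounts(s, "groups[].seeders"),
                asGenotypeCounts(co, "groups[].contacts"))
  })
  experimentDesign(unname(groups),
                   replicates = if (is.null(cfg$replicates)) 1
                                else cfg$replicates)
}

designToList <- function(design) {
  list(groups = lapply(design@groups, function(g)
         list(seeders = as.list(g@seeders), contacts = as.list(g@contacts))),
       replicates = design@replicates)
}

#' @rdname readDesign
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "ExperimentDesign"))
  lst <- designToList(design)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
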