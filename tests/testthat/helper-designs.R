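# shared fixture builders (everything is generated in code)

gc3 <- function(AA = 0, AB = 0, BB = 0) c(AA = AA, AB = AB, BB = BB)

# single group with given contact counts and all-BB seeders
oneGroupDesign <- function(contAA, contAB, contBB, nSeed = 10) {
  experimentDesign(groupDesign(gc3(BB = nSeed),
                               gc3(contAA, contAB, contBB)))
}

# proportion-space two-group mixed design in the negligible-seeder limit
mixedLimitDesign <- function(chi = 1 / sqrt(2), seedEps = 1e-8) {
  role <- function(tot, x) gc3((1 + x) / 2 * tot, 0, (1 - x) / 2 * tot)
  experimentDesign(list(
    groupDesign(gc3(AA = seedEps), role(1 - seedEps, chi)),
    groupDesign(gc3(AA = seedEps), role(1 - seedEps, -chi))))
}

# proportion-space four-group pure design with seeder fraction s
pureFracDesign <- function(s) {
  experimentDesign(lapply(list(c("AA", "AA"), c("AA", "BB"),
                               c("BB", "AA"), c("BB", "BB")), function(cm) {
    sd <- co <- gc3()
    sd[cm[1]] <- s; co[cm[2]] <- 1 - s
    groupDesign(sd, co)
  }))
}

baselineTraits <- function(nSeed, nCont) {
  data.frame(genotype = "AA", g = 0, f = 0, r = 0,
             role = rep(c("seeder", "contact"), c(nSeed, nCont)))
}

smallEffectParams <- function(r0, gSize, a = 0.2, k = 1)
  epidemicParams(beta = betaFromR0(r0, gSize), gamma = 1, k = k,
                 aG = a, aF = a, aR = a)
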