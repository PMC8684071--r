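test_that("simulation is deterministic under a fixed seed", {
    cfg <- SimulationConfig(nSnps = 300L, seed = 99L)
    a <- simulateFamily(cfg)
    b <- simulateFamily(cfg)
    expect_identical(S4Vectors::mcols(a$truth@sites),
                     S4Vectors::mcols(b$truth@sites))
    expect_identical(S4Vectors::mcols(a$trio), S4Vectors::mcols(b$trio))
    expect_identical(S4Vectors::mcols(a$plasma),
                     S4Vectors::mcols(b$plasma))
})

test_that("informative-site count matches the analytic expectation", {
    n <- 1200L
    truth <- simulateHaplotypes(SimulationConfig(nSnps = n, seed = 17L))
    mc <- S4Vectors::mcols(truth@sites)
    lab <- classifyGenotypes(mc$fatherHapP + mc$fatherHapW,
                             mc$motherHapP + mc$motherHapW, mc$probandGT)
    got <- sum(lab %in% paste0("S", 1:8))
    # closed form: P(informative | q) = 2 h (1 - h), h = 2 q (1 - q);
    # every one-parent-het / other-hom site is informative because both
    # proband outcomes appear among the eight patterns
    lo <- 0.1; hi <- 0.9
    pInf <- integrate(function(q) {
        h <- 2 * q * (1 - q)
        2 * h * (1 - h) / (hi - lo)
    }, lo, hi)$value
    expect_lt(abs(got - n * pInf), 3 * sqrt(n * pInf * (1 - pInf)))
})

test_that("an affected fetus duplicates the proband at every site", {
    truth <- simulateHaplotypes(SimulationConfig(
        nSnps = 400L, maternalInheritance = "PATHOGENIC",
        paternalInheritance = "PATHOGENIC", seed = 23L))
    mc <- S4Vectors::mcols(truth@sites)
    expect_identical(mc$fetusGT, mc$probandGT)
    # proband is always the two pathogenic haplotypes
    expect_identical(mc$probandGT,
                     as.integer(mc$fatherHapP + mc$motherHapP))
})

test_that("exact informative-locus truncation works", {
    truth <- simulateHaplotypes(SimulationConfig(
        nSnps = 900L, nInformative = 270L, seed = 7L))
    mc <- S4Vectors::mcols(truth@sites)
    lab <- classifyGenotypes(mc$fatherHapP + mc$fatherHapW,
                             mc$motherHapP + mc$motherHapW, mc$probandGT)
    expect_identical(sum(lab %in% paste0("S", 1:8)), 270L)
    expect_error(simulateHaplotypes(SimulationConfig(
        nSnps = 50L, nInformative = 200L, seed = 7L)), "nSnps too small")
})

test_that("genomic counts respect genotypes, error rate and depth model", {
    cfg <- SimulationConfig(nSnps = 1200L, genomicDepthMean = 1889,
                            seqErrorRate = 0, seed = 11L)
    fam <- simulateFamily(cfg)
    mc <- S4Vectors::mcols(fam$trio)
    # error 0: hom-ref mothers have zero alt reads, hom-alt all alt
    expect_true(all(mc$motherADalt[mc$motherGT == 0L] == 0L))
    expect_true(all((mc$motherADalt == mc$motherDP)[mc$motherGT == 2L]))
    # het mother ratios concentrate near 0.5 (binomial at ~1900x)
    het <- mc$motherGT == 1L
    r <- mc$motherADalt[het] / mc$motherDP[het]
    expect_gt(mean(abs(r - 0.5) <= 0.04), 0.99 - 3 * sqrt(0.01 / sum(het)))
    # Poisson depth mean within 2%
    expect_lt(abs(mean(mc$motherDP) - 1889) / 1889, 0.02)
})

test_that("plasma counts follow the maternal-fetal binomial mixture", {
    e <- 0.1
    cfg <- SimulationConfig(nSnps = 3000L, fetalFraction = e,
                            plasmaDepthMean = 3000, seqErrorRate = 0,
                            seed = 13L)
    fam <- simulateFamily(cfg)
    tmc <- S4Vectors::mcols(fam$truth@sites)
    pmc <- S4Vectors::mcols(fam$plasma)
    ratio <- pmc$adAlt / pmc$dp
    mix <- (1 - e) * (tmc$motherHapP + tmc$motherHapW) / 2 +
        e * tmc$fetusGT / 2
    # per-group empirical means match the analytic mixture within 3 SE
    lab <- classifyGenotypes(tmc$fatherHapP + tmc$fatherHapW,
                             tmc$motherHapP + tmc$motherHapW, tmc$probandGT)
    for (g in paste0("S", 1:8)) {
        sel <- lab == g
        n <- sum(sel)
        se <- sqrt(mean(mix[sel] * (1 - mix[sel]) / pmc$dp[sel]) / n)
        expect_lt(abs(mean(ratio[sel]) - mean(mix[sel])),
                  3 * se + 1e-12)
    }
})

test_that("zero fetal fraction leaves plasma maternal", {
    # e in (0,1) is enforced; approximate the limit with a tiny e
    cfg <- SimulationConfig(nSnps = 2000L, fetalFraction = 1e-9,
                            plasmaDepthMean = 3000, seqErrorRate = 0,
                            seed = 29L)
    fam <- simulateFamily(cfg)
    tmc <- S4Vectors::mcols(fam$truth@sites)
    pmc <- S4Vectors::mcols(fam$plasma)
    motherFrac <- (tmc$motherHapP + tmc$motherHapW) / 2
    expect_true(all(pmc$adAlt[motherFrac == 0] == 0L))
    expect_true(all((pmc$adAlt == pmc$dp)[motherFrac == 1]))
    het <- motherFrac == 0.5
    expect_lt(abs(mean(pmc$adAlt[het] / pmc$dp[het]) - 0.5), 0.003)
})

test_that("the scenario bank mirrors the 21-family cohort", {
    bank <- scenarioBank()
    expect_identical(nrow(bank), 21L)
    expect_equal(round(mean(bank$fetalFraction) * 100, 1), 6.4)
    expect_equal(round(sd(bank$fetalFraction) * 100, 2), 1.68)
    expect_identical(as.integer(table(bank$truthClass)[
        c("Affected", "Paternal mutation carriers",
          "Maternal mutation carriers", "N")]), c(6L, 6L, 5L, 4L))
    expect_true(all(bank$fetalFraction >= 0.036 &
                    bank$fetalFraction <= 0.097))
})

test_that("recombination injection corrupts a transmitted haplotype block", {
    base <- simulateHaplotypes(SimulationConfig(
        nSnps = 500L, recombinationRate = 0, seed = 77L))
    rec <- simulateHaplotypes(SimulationConfig(
        nSnps = 500L, recombinationRate = 1, seed = 77L))
    mcB <- S4Vectors::mcols(base@sites)
    mcR <- S4Vectors::mcols(rec@sites)
    # with certain recombination, the transmitted allele switches source
    # haplotype after a breakpoint for each parent
    expect_false(identical(mcR$fetusPatAllele, mcB$fetusPatAllele) &&
                 identical(mcR$fetusMatAllele, mcB$fetusMatAllele))
})
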