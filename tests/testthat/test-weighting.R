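test_that("mutation ratio is AD/DP with zero-depth rejected", {
    expect_equal(siteMutationRatio(0, 3000), 0)
    expect_equal(siteMutationRatio(1500, 3000), 0.5)
    expect_equal(siteMutationRatio(3000, 3000), 1)
    expect_error(siteMutationRatio(0, 0), "zero-depth")
})

test_that("group means use observed ME for S1-S4 and fixed dosage for S5-S8", {
    obs <- groupObserved("S2", c(0.48, 0.52), c(0.49, 0.51))
    expect_equal(unname(obs), c(0.50, 0.50))
    # maternal homozygous groups pin ME regardless of observed ratios
    expect_equal(groupObserved("S5", c(0.03), c(0.02))[["ME"]], 0)
    expect_equal(groupObserved("S6", c(0.03), c(0.02))[["ME"]], 0)
    expect_equal(groupObserved("S7", c(0.97), c(0.98))[["ME"]], 1)
    expect_equal(groupObserved("S8", c(0.97), c(0.98))[["ME"]], 1)
})

test_that("expected ratios reproduce all eight symbolic table rows", {
    e <- 0.08; ME <- 0.5
    rows <- list(S1 = c(ME - e/2, ME), S2 = c(ME, ME - e/2),
                 S3 = c(ME, ME + e/2), S4 = c(ME + e/2, ME),
                 S5 = c(0, e/2),       S6 = c(e/2, 0),
                 S7 = c(1 - e/2, 1),   S8 = c(1, 1 - e/2))
    for (lab in names(rows))
        expect_equal(unname(expectedRatios(lab, ME = ME, e = e)),
                     rows[[lab]], info = lab)
    expect_equal(unname(expectedRatios("S5", e = 0.10)), c(0, 0.05))
    expect_equal(unname(expectedRatios("S3", ME = 0.5, e = 0.08)),
                 c(0.50, 0.54))
})

test_that("expected ratios equal the brute-force mixture model", {
    tab <- groupTable()
    for (e in c(0.01, 0.036, 0.064, 0.097, 0.2)) {
        for (i in seq_len(nrow(tab))) {
            oracle <- mixtureOracle(tab$father[i], tab$mother[i],
                                    tab$proband[i], e)
            got <- expectedRatios(tab$label[i], ME = tab$mother[i] / 2,
                                  e = e)
            expect_equal(unname(got), unname(oracle),
                         tolerance = 1e-12,
                         info = paste(tab$label[i], "e =", e))
            # PE and BE always differ by exactly e/2
            expect_equal(abs(oracle[["PE"]] - oracle[["BE"]]), e / 2)
        }
    }
})

test_that("PE converges to BE as the fetal signal vanishes", {
    for (lab in paste0("S", 1:8)) {
        r <- expectedRatios(lab, ME = 0.5, e = 1e-9)
        expect_equal(r[["PE"]], r[["BE"]], tolerance = 1e-8)
    }
})

test_that("group factor follows |FE-BE|/|FE-PE| with floor and cap", {
    ctl <- haplodoseControl()
    # printed-arithmetic case: S6 at e = 0.036
    expect_equal(groupFactor(0.02, PE = 0.018, BE = 0, ctl), 10)
    # FE = PE (pathogenic-consistent limit): epsilon-guarded denominator
    expect_equal(groupFactor(0.5, PE = 0.5, BE = 0.52, ctl),
                 0.02 / ctl$factorEps)
    # with a tighter guard the cap binds
    expect_equal(groupFactor(0.5, PE = 0.5, BE = 0.52,
                             haplodoseControl(factorEps = 1e-6)),
                 ctl$factorCap)
    expect_equal(groupFactor(0.52, PE = 0.5, BE = 0.52, ctl),
                 ctl$factorFloor)    # FE = BE: wild-type-consistent limit
    expect_error(groupFactor(0.5, PE = 0.3, BE = 0.3, ctl), "PE equals BE")
})

test_that("group factor is monotone as FE moves from PE toward BE", {
    ctl <- haplodoseControl()
    PE <- 0.532; BE <- 0.5
    fe <- seq(PE, BE, length.out = 40)
    f <- vapply(fe, groupFactor, numeric(1), PE = PE, BE = BE,
                control = ctl)
    expect_true(all(diff(f) <= 1e-12))
})

test_that("S-values are per-parent products over surviving groups", {
    # build sites with known per-group plasma and maternal ratios
    e <- 0.08
    tab <- groupTable()
    nPer <- 6L
    mkSites <- function(labels) {
        rows <- tab[tab$label %in% labels, ]
        idx <- rep(seq_len(nrow(rows)), each = nPer)
        n <- length(idx)
        ts <- TrioSites("chr12", seq_len(n) * 10,
                        ref = rep("A", n), alt = rep("G", n),
                        fatherGT = rows$father[idx],
                        motherGT = rows$mother[idx],
                        probandGT = rows$proband[idx],
                        fatherDP = rep(2000L, n), motherDP = rep(2000L, n),
                        probandDP = rep(2000L, n),
                        motherADalt = rep(1000L, n) * (rows$mother[idx] / 2) * 2)
        ts <- classifyTrioSites(ts)
        # plasma exactly at PE for every site: every factor hits the cap
        peFrac <- vapply(seq_len(n), function(k) {
            me <- rows$mother[idx[k]] / 2
            expectedRatios(rows$label[idx[k]], ME = me, e = e)[["PE"]]
        }, numeric(1))
        S4Vectors::mcols(ts)$plasmaADalt <- as.integer(round(3000 * peFrac))
        S4Vectors::mcols(ts)$plasmaADref <-
            3000L - S4Vectors::mcols(ts)$plasmaADalt
        S4Vectors::mcols(ts)$plasmaDP <- 3000L
        ts
    }
    ctl <- haplodoseControl()
    sv <- computeSValues(mkSites(paste0("S", 1:8)), e = e, ctl)
    # FE sits exactly on PE, so every factor is (e/2) / factorEps
    perGroup <- (e / 2) / ctl$factorEps
    expect_equal(sMother(sv), perGroup^4)
    expect_equal(sFather(sv), perGroup^4)
    g <- as.data.frame(groupSummaries(sv))
    expect_identical(g$nLoci, rep(nPer, 8))
    expect_true(all(g$included))

    # a side with no surviving group is NA -> inconclusive downstream
    svM <- computeSValues(mkSites(paste0("S", 1:4)), e = e, ctl)
    expect_true(is.na(sFather(svM)))
    expect_identical(callFetus(svM)@paternal, "INCONCLUSIVE")
    expect_identical(overallCall(callFetus(svM)), "Inconclusive")

    # groups below the locus floor are skipped
    svFloor <- computeSValues(mkSites(paste0("S", 1:8)), e = e,
                              haplodoseControl(minGroupLoci = 10))
    expect_true(is.na(sMother(svFloor)) && is.na(sFather(svFloor)))
})

test_that("fetal calls follow the 10 / 0.1 thresholds and gray zone", {
    mkReport <- function(sm, sf)
        new("SValueReport",
            groups = S4Vectors::DataFrame(
                label = "S1", parent = "mother", nLoci = 10L, FE = 0.5,
                ME = 0.5, PE = 0.48, BE = 0.5, factor = 1, included = TRUE),
            sMother = sm, sFather = sf, e = 0.05,
            thresholds = c(upper = 10, lower = 0.1))
    # the published example values
    expect_identical(overallCall(callFetus(mkReport(447, 3280))),
                     "Affected")
    expect_identical(overallCall(callFetus(mkReport(0.02, 647))),
                     "Paternal mutation carriers")
    expect_identical(overallCall(callFetus(mkReport(5, 0.01))),
                     "Inconclusive")
    expect_identical(overallCall(callFetus(mkReport(0.05, 0.1))), "N")
    expect_identical(overallCall(callFetus(mkReport(10, 0.05))),
                     "Maternal mutation carriers")
    # boundary values are calls, not gray zone
    cl <- callFetus(mkReport(10, 0.1))
    expect_identical(cl@maternal, "PATHOGENIC")
    expect_identical(cl@paternal, "WILD_TYPE")
})

test_that("relabelling ref/alt leaves both S-values unchanged", {
    fam <- simulateFamily(SimulationConfig(nSnps = 800L, seed = 31L))
    ctl <- haplodoseControl()
    run <- function(trio, plasma) {
        sites <- quiet(qcTrioSites(trio))
        e <- fetalFraction(estimateFetalFraction(
            quiet(selectFFSites(sites, plasma)), ctl))
        sv <- computeSValues(quiet(joinPlasma(sites, plasma)), e, ctl)
        c(sv@sMother, sv@sFather, e)
    }
    a <- run(fam$trio, fam$plasma)
    b <- run(flipTrio(fam$trio), flipPlasma(fam$plasma))
    expect_equal(a, b, tolerance = 1e-9)
})
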