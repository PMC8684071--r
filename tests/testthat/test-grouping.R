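test_that("Mendelian consistency matches brute-force allele enumeration", {
    g <- trioGrid()
    expected <- mapply(mendelBruteForce, g$father, g$mother, g$proband)
    got <- isMendelianConsistent(g$father, g$mother, g$proband)
    expect_identical(got, unname(expected))
    # spot checks
    expect_false(isMendelianConsistent(0L, 0L, 2L))
    expect_true(isMendelianConsistent(1L, 1L, 0L))
    expect_true(isMendelianConsistent(0L, 1L, 1L))
    expect_error(isMendelianConsistent(NA_integer_, 0L, 0L), "missing")
})

test_that("exactly 8 of the 27 trio combinations are group-informative", {
    g <- trioGrid()
    lab <- classifyGenotypes(g$father, g$mother, g$proband)
    expect_identical(sort(lab[grepl("^S", lab)]), paste0("S", 1:8))
    # each labelled combination matches its table row exactly
    tab <- groupTable()
    for (i in which(grepl("^S", lab))) {
        row <- tab[tab$label == lab[i], ]
        expect_identical(c(row$father, row$mother, row$proband),
                         c(g$father[i], g$mother[i], g$proband[i]))
    }
    # S1-S4 mother het / father hom; S5-S8 father het / mother hom
    m14 <- g[lab %in% paste0("S", 1:4), ]
    expect_true(all(m14$mother == 1L & m14$father != 1L))
    m58 <- g[lab %in% paste0("S", 5:8), ]
    expect_true(all(m58$father == 1L & m58$mother != 1L))
})

test_that("classification handles the edge patterns", {
    expect_identical(classifyGenotypes(0L, 1L, 0L), "S1")
    expect_identical(classifyGenotypes(1L, 2L, 2L), "S8")
    expect_identical(classifyGenotypes(1L, 1L, 1L), "NotInformative")
    expect_identical(classifyGenotypes(0L, 0L, 1L), "MendelianError")
})

test_that("allele relabelling maps S1<->S4, S2<->S3, S5<->S8, S6<->S7", {
    g <- trioGrid()
    lab <- classifyGenotypes(g$father, g$mother, g$proband)
    flipped <- classifyGenotypes(2L - g$father, 2L - g$mother,
                                 2L - g$proband)
    map <- c(S1 = "S4", S2 = "S3", S3 = "S2", S4 = "S1",
             S5 = "S8", S6 = "S7", S7 = "S6", S8 = "S5")
    expectFlip <- ifelse(lab %in% names(map), map[lab], lab)
    expect_identical(flipped, unname(expectFlip))
})

test_that("QC enforces the genomic depth floor and drops Mendelian errors", {
    ts <- TrioSites("chr12", c(10, 20, 30, 40),
                    ref = rep("A", 4), alt = rep("G", 4),
                    fatherGT = c(0L, 0L, 0L, 1L),
                    motherGT = c(1L, 1L, 0L, 0L),
                    probandGT = c(0L, 0L, 1L, 1L),
                    fatherDP = c(19L, 20L, 2000L, 2000L),
                    motherDP = rep(2000L, 4), probandDP = rep(2000L, 4),
                    motherADalt = c(1000L, 1000L, 0L, 0L))
    out <- qcTrioSites(ts, minGenomicDepth = 20L)
    # site 1 fails the 20x floor, site 3 is a Mendelian error
    expect_identical(GenomicRanges::start(out), c(20L, 40L))
    expect_identical(groupLabels(out), c("S1", "S6"))
    log <- S4Vectors::metadata(out)$qcLog
    expect_identical(log$sitesIn[log$stage == "low_depth"], 4L)
    expect_identical(log$sitesOut[log$stage == "low_depth"], 3L)
    expect_identical(log$sitesIn[log$stage == "mendelian_error"] -
                     log$sitesOut[log$stage == "mendelian_error"], 1L)
})

test_that("QC keeps opposite-homozygote fetal-fraction sites by default", {
    ts <- TrioSites("chr12", c(10, 20),
                    ref = c("A", "A"), alt = c("G", "G"),
                    fatherGT = c(2L, 0L), motherGT = c(0L, 0L),
                    probandGT = c(1L, 0L),
                    fatherDP = rep(100L, 2), motherDP = rep(100L, 2),
                    probandDP = rep(100L, 2), motherADalt = c(0L, 0L))
    expect_length(qcTrioSites(ts), 1L)             # opposite hom retained
    expect_length(qcTrioSites(ts, keep = "grouping"), 0L)
    expect_length(qcTrioSites(ts, keep = "all"), 2L)
})

test_that("injected Mendelian errors are exactly the QC exclusions", {
    truth <- simulateHaplotypes(SimulationConfig(
        nSnps = 1000L, mendelianErrorRate = 0.02, seed = 42L))
    mc <- S4Vectors::mcols(truth@sites)
    lab <- classifyGenotypes(mc$fatherHapP + mc$fatherHapW,
                             mc$motherHapP + mc$motherHapW, mc$probandGT)
    nErr <- sum(lab == "MendelianError")
    expect_identical(nErr, sum(mc$mendelianErrorInjected))
    # ~20 expected from a 2% rate (some injections have no inconsistent
    # genotype available, e.g. both parents heterozygous)
    expect_gt(nErr, 5L)
    expect_lt(nErr, 40L)
})

test_that("classification is a pure function of the three genotypes", {
    g <- trioGrid()
    a <- classifyGenotypes(g$father, g$mother, g$proband)
    b <- classifyGenotypes(g$father, g$mother, g$proband)
    expect_identical(a, b)
    # per-element agrees with vectorised call
    one <- vapply(seq_len(nrow(g)), function(i)
        classifyGenotypes(g$father[i], g$mother[i], g$proband[i]),
        character(1))
    expect_identical(one, a)
})
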