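## Synthetic-family generator. Emulates the targeted-capture design the
## caller assumes: a 2-Mb window of biallelic SNPs around an
## autosomal-recessive disease locus, phased parental haplotypes with one
## pathogenic-flagged haplotype per parent, an affected proband carrying
## both pathogenic haplotypes, a fetus with configurable inheritance, and
## consensus read counts drawn as Poisson depth x binomial allele draws,
## with plasma a maternal+fetal binomial mixture at the true fetal
## fraction.

.SIM_CHROM <- "chr12"
.SIM_REGION_START <- 102e6   # 2-Mb window, 1 Mb flanking each side of the locus
.SIM_REGION_WIDTH <- 2e6

#' Build a simulation configuration
#'
#' @param nSnps SNPs drawn in the 2-Mb region (default 1200, the scale of
#'   a targeted SNP panel).
#' @param nInformative optional: truncate the region so that exactly this
#'   many haplotype-informative (S1-S8) sites remain.
#' @param altFreqRange uniform range of population alt-allele frequencies
#'   (default 0.1-0.9, the panel's design range).
#' @param fetalFraction true fetal fraction in (0, 1) (default 0.064, the
#'   cohort mean).
#' @param plasmaDepthMean,genomicDepthMean Poisson means of consensus
#'   depth (defaults 3000 and 2000).
#' @param seqErrorRate symmetric per-read miscall rate (default 0.001).
#' @param maternalInheritance,paternalInheritance `"PATHOGENIC"` or
#'   `"WILD_TYPE"`: which haplotype of each parent the fetus inherits
#'   (default both pathogenic, i.e. an affected fetus).
#' @param mendelianErrorRate fraction of sites whose proband genotype is
#'   corrupted to a Mendelian-inconsistent value (default 0).
#' @param recombinationRate per-meiosis probability of one crossover in
#'   each fetal transmission (default 0; the caller assumes none).
#' @param seed RNG seed (NA = leave the RNG alone).
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(nSnps = 1200L, nInformative = NA_integer_,
                             altFreqRange = c(0.1, 0.9),
                             fetalFraction = 0.064,
                             plasmaDepthMean = 3000, genomicDepthMean = 2000,
                             seqErrorRate = 0.001,
                             maternalInheritance = "PATHOGENIC",
                             paternalInheritance = "PATHOGENIC",
                             mendelianErrorRate = 0,
                             recombinationRate = 0,
                             seed = NA_integer_) {
    new("SimulationConfig", nSnps = as.integer(nSnps),
        nInformative = as.integer(nInformative),
        altFreqRange = as.numeric(altFreqRange),
        fetalFraction = fetalFraction,
        plasmaDepthMean = plasmaDepthMean,
        genomicDepthMean = genomicDepthMean,
        seqErrorRate = seqErrorRate,
        maternalInheritance = maternalInheritance,
        paternalInheritance = paternalInheritance,
        mendelianErrorRate = mendelianErrorRate,
        recombinationRate = recombinationRate,
        seed = as.integer(seed))
}

## genotypes Mendelian-inconsistent with a given parental pair
.inconsistentGenotypes <- function(f, m) {
    setdiff(0:2, unique(c(outer(
        if (f == 1L) 0:1 else as.integer(f == 2L),
        if (m == 1L) 0:1 else as.integer(m == 2L), `+`))))
}

.simHaplotypes <- function(config) {
    drawBatch <- function(n) {
        af <- runif(n, config@altFreqRange[1], config@altFreqRange[2])
        h <- function() rbinom(n, 1L, af)
        list(af = af, fP = h(), fW = h(), mP = h(), mW = h())
    }
    n <- config@nSnps
    b <- drawBatch(n)
    proband <- b$fP + b$mP

    ## inject Mendelian-inconsistent proband genotypes
    mendInjected <- rep(FALSE, n)
    if (config@mendelianErrorRate > 0) {
        hit <- which(runif(n) < config@mendelianErrorRate)
        for (i in hit) {
            bad <- .inconsistentGenotypes(b$fP[i] + b$fW[i], b$mP[i] + b$mW[i])
            if (length(bad)) {
                proband[i] <- if (length(bad) == 1L) bad else sample(bad, 1L)
                mendInjected[i] <- TRUE
            }
        }
    }

    ## fetal transmissions, optionally with one crossover per meiosis
    transmit <- function(hapP, hapW, inheritance) {
        fromP <- rep(inheritance == "PATHOGENIC", n)
        if (config@recombinationRate > 0 &&
            runif(1) < config@recombinationRate) {
            bp <- sample.int(n, 1L)
            fromP[seq_len(n) > bp] <- !fromP[seq_len(n) > bp]
        }
        ifelse(fromP, hapP, hapW)
    }
    fetPat <- transmit(b$fP, b$fW, config@paternalInheritance)
    fetMat <- transmit(b$mP, b$mW, config@maternalInheritance)

    ## truncate to an exact number of haplotype-informative sites
    if (!is.na(config@nInformative)) {
        grp <- classifyGenotypes(b$fP + b$fW, b$mP + b$mW, proband)
        inf <- cumsum(grp %in% .S_GROUPS)
        if (max(inf) < config@nInformative)
            stop("nSnps too small for the requested nInformative (",
                 max(inf), " informative of ", n, " sites); raise nSnps")
        keep <- seq_len(match(config@nInformative, inf))
        b <- lapply(b, `[`, keep)
        proband <- proband[keep]; mendInjected <- mendInjected[keep]
        fetPat <- fetPat[keep]; fetMat <- fetMat[keep]
        n <- length(keep)
    }

    pos <- .SIM_REGION_START + sort(sample.int(.SIM_REGION_WIDTH, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

    sites <- GRanges(.SIM_CHROM, IRanges(pos, width = 1L))
    mcols(sites) <- DataFrame(
        ref = ref, alt = unname(alt), altFreq = b$af,
        fatherHapP = b$fP, fatherHapW = b$fW,
        motherHapP = b$mP, motherHapW = b$mW,
        probandGT = as.integer(proband),
        fetusPatAllele = as.integer(fetPat),
        fetusMatAllele = as.integer(fetMat),
        fetusGT = as.integer(fetPat + fetMat),
        mendelianErrorInjected = mendInjected)
    new("FamilyTruth", config = config, sites = sites)
}

## symmetric per-read error: observed alt prob from a true alt fraction
.errAdjust <- function(frac, err) frac * (1 - err) + (1 - frac) * err

.simGenomic <- function(truth) {
    cfg <- truth@config
    mc <- mcols(truth@sites)
    n <- length(truth@sites)
    dp <- function() pmax(rpois(n, cfg@genomicDepthMean), 1L)
    fatherDP <- dp(); motherDP <- dp(); probandDP <- dp()
    motherGT <- mc$motherHapP + mc$motherHapW
    motherADalt <- rbinom(n, motherDP,
                          .errAdjust(motherGT / 2, cfg@seqErrorRate))
    TrioSites(as.character(seqnames(truth@sites)), start(truth@sites),
              ref = mc$ref, alt = mc$alt,
              fatherGT = mc$fatherHapP + mc$fatherHapW,
              motherGT = motherGT, probandGT = mc$probandGT,
              fatherDP = fatherDP, motherDP = motherDP,
              probandDP = probandDP, motherADalt = motherADalt)
}

.simPlasma <- function(truth) {
    cfg <- truth@config
    mc <- mcols(truth@sites)
    n <- length(truth@sites)
    e <- cfg@fetalFraction
    motherFrac <- (mc$motherHapP + mc$motherHapW) / 2
    fetusFrac <- mc$fetusGT / 2
    mix <- (1 - e) * motherFrac + e * fetusFrac
    dp <- pmax(rpois(n, cfg@plasmaDepthMean), 1L)
    adAlt <- rbinom(n, dp, .errAdjust(mix, cfg@seqErrorRate))
    PlasmaSites(as.character(seqnames(truth@sites)), start(truth@sites),
                ref = mc$ref, alt = mc$alt,
                adRef = dp - adAlt, adAlt = adAlt, dp = dp)
}

#' Simulate the phased truth of one family
#'
#' Draws per-site population alt frequencies uniform on the configured
#' range, four parental haplotype alleles per site (haplotype 1 of each
#' parent flagged pathogenic), an affected proband inheriting both
#' pathogenic haplotypes, and fetal transmissions per the configured
#' inheritance. Deterministic under `config@seed`.
#'
#' @param config a [SimulationConfig()].
#' @return A [FamilyTruth-class].
#' @export
simulateHaplotypes <- function(config = SimulationConfig()) {
    if (!is.na(config@seed)) set.seed(config@seed)
    .simHaplotypes(config)
}

#' Simulate trio genomic allele depths for a family truth
#'
#' Per sample and site: depth ~ Poisson(`genomicDepthMean`); maternal alt
#' reads ~ Binomial(depth, dosage adjusted by the symmetric error rate).
#' Genotypes are the truth genotypes (consensus-level variant calling is
#' assumed resolved upstream).
#'
#' @param truth a [FamilyTruth-class].
#' @return A [TrioSites-class].
#' @export
simulateGenomicCounts <- function(truth) .simGenomic(truth)

#' Simulate maternal plasma cfDNA counts for a family truth
#'
#' Per site the expected alt fraction is the maternal-fetal mixture
#' `(1-e) * motherDosage + e * fetusDosage` (dosages in \{0, 1/2, 1\}),
#' adjusted by the symmetric error rate; depth ~
#' Poisson(`plasmaDepthMean`), alt reads binomial.
#'
#' @param truth a [FamilyTruth-class].
#' @return A [PlasmaSites-class].
#' @export
simulatePlasmaCounts <- function(truth) .simPlasma(truth)

#' Simulate a complete family
#'
#' Seeds the RNG once from `config@seed`, then draws haplotypes, trio
#' genomic counts and plasma counts; two runs with the same config are
#' identical.
#'
#' @param config a [SimulationConfig()].
#' @return list with elements `truth` ([FamilyTruth-class]), `trio`
#'   ([TrioSites-class]) and `plasma` ([PlasmaSites-class]).
#' @examples
#' fam <- simulateFamily(SimulationConfig(nSnps = 200, seed = 1))
#' fam$truth
#' @export
simulateFamily <- function(config = SimulationConfig()) {
    if (!is.na(config@seed)) set.seed(config@seed)
    truth <- .simHaplotypes(config)
    trio <- .simGenomic(truth)
    plasma <- .simPlasma(truth)
    list(truth = truth, trio = trio, plasma = plasma)
}

#' The 21-family benchmark scenario bank
#'
#' Default in-silico cohort mirroring the clinical validation set: 21
#' families with fetal fractions between 3.6% and 9.7% (mean 6.4%) and
#' truth classes 6 affected, 6 paternal carriers, 5 maternal carriers and
#' 4 normal.
#'
#' @return data.frame with columns family, fetalFraction (fraction),
#'   truthClass, maternalInheritance, paternalInheritance.
#' @export
scenarioBank <- function() {
    ffPct <- c(3.8, 8.1, 5.0, 7.7, 9.7, 8.7, 5.8, 5.8, 5.6, 6.8, 6.7,
               4.7, 5.4, 5.1, 6.3, 7.9, 9.0, 5.1, 6.3, 3.6, 7.6)
    cls <- c("Affected", "Affected", "Paternal mutation carriers", "N",
             "Paternal mutation carriers", "Paternal mutation carriers",
             "Affected", "Affected", "Paternal mutation carriers", "N",
             "Paternal mutation carriers", "Maternal mutation carriers",
             "Paternal mutation carriers", "Maternal mutation carriers",
             "Affected", "N", "Maternal mutation carriers",
             "Maternal mutation carriers", "N", "Affected",
             "Maternal mutation carriers")
    mat <- ifelse(cls %in% c("Affected", "Maternal mutation carriers"),
                  "PATHOGENIC", "WILD_TYPE")
    pat <- ifelse(cls %in% c("Affected", "Paternal mutation carriers"),
                  "PATHOGENIC", "WILD_TYPE")
    data.frame(family = sprintf("F%02d", seq_along(ffPct)),
               fetalFraction = ffPct / 100, truthClass = cls,
               maternalInheritance = mat, paternalInheritance = pat,
               stringsAsFactors = FALSE)
}

#' Write a simulated family as pipeline input files
#'
#' Emits `trio.vcf` (GT/AD/DP for father, mother, proband), `plasma.vcf`
#' (AD/DP for the single plasma sample) and `truth.json` (config and
#' per-site truth) into a directory. The files round-trip losslessly
#' through [readTrioVcf()] / [readPlasmaVcf()].
#'
#' @param fam list from [simulateFamily()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeFixture <- function(fam, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    trioPath <- file.path(dir, "trio.vcf")
    plasmaPath <- file.path(dir, "plasma.vcf")
    truthPath <- file.path(dir, "truth.json")
    .writeTrioVcf(fam$trio, trioPath)
    .writePlasmaVcf(fam$plasma, plasmaPath)

    cfg <- fam$truth@config
    mc <- mcols(fam$truth@sites)
    truthList <- list(
        config = list(
            nSnps = cfg@nSnps, nInformative = cfg@nInformative,
            altFreqRange = cfg@altFreqRange,
            fetalFraction = cfg@fetalFraction,
            plasmaDepthMean = cfg@plasmaDepthMean,
            genomicDepthMean = cfg@genomicDepthMean,
            seqErrorRate = cfg@seqErrorRate,
            maternalInheritance = cfg@maternalInheritance,
            paternalInheritance = cfg@paternalInheritance,
            mendelianErrorRate = cfg@mendelianErrorRate,
            recombinationRate = cfg@recombinationRate,
            seed = cfg@seed),
        sites = c(list(chrom = as.character(seqnames(fam$truth@sites)),
                       pos = start(fam$truth@sites)),
                  as.list(as.data.frame(mc))))
    jsonlite::write_json(truthList, truthPath, auto_unbox = TRUE,
                         digits = NA)
    invisible(c(trio = trioPath, plasma = plasmaPath, truth = truthPath))
}
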