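#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata metadata<- isSingleNumber isSingleString
#' @importFrom IRanges IRanges CharacterList DataFrameList
#' @importFrom GenomicRanges GRanges seqnames start granges
#' @importFrom stats rbinom rpois runif setNames sd qbinom
#' @importFrom utils write.table read.table head
NULL

.GT_LEVELS <- c(0L, 1L, 2L)

.S_GROUPS <- paste0("S", 1:8)

## The eight informative trio-genotype patterns. Genotypes are alt-allele
## counts (0 = hom ref, 1 = het, 2 = hom alt). Within each row the proband's
## genotype pins down which allele of the heterozygous parent travels with the
## pathogenic variant, because the proband is affected and therefore carries
## the pathogenic haplotype of both parents. Expected plasma alt-ratios if the
## fetus inherited the pathogenic (PE) or wild-type (BE) haplotype of the
## heterozygous parent are linear in the maternal ratio ME and the fetal
## fraction e: value = ME + peK * e/2 (with ME fixed at 0 or 1 for the
## paternal groups S5-S8, where the mother is homozygous).
.GROUP_TABLE <- data.frame(
    label    = .S_GROUPS,
    father   = c(0L, 0L, 2L, 2L, 1L, 1L, 1L, 1L),
    mother   = c(1L, 1L, 1L, 1L, 0L, 0L, 2L, 2L),
    proband  = c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L),
    parent   = rep(c("mother", "father"), each = 4L),
    # PE = meBase + peK*e/2 ; BE = meBase + beK*e/2 ; meBase "ME" means the
    # observed maternal ratio (S1-S4), otherwise the fixed homozygous dosage.
    meFixed  = c(NA, NA, NA, NA, 0, 0, 1, 1),
    peK      = c(-1L, 0L, 0L, 1L, 0L, 1L, -1L, 0L),
    beK      = c(0L, -1L, 1L, 0L, 1L, 0L, 0L, -1L),
    stringsAsFactors = FALSE
)

#' Trio SNP sites
#'
#' A [GenomicRanges::GRanges] subclass holding one biallelic SNP per range,
#' with the genomic genotypes and sequencing depths of a father / mother /
#' affected-proband trio as metadata columns, plus the maternal alt-supporting
#' read count used for the maternal allele ratio. Positions are 1-based.
#'
#' Required metadata columns: `ref`, `alt` (single bases), `fatherGT`,
#' `motherGT`, `probandGT` (integer alt-allele counts 0/1/2, `NA` = missing),
#' `fatherDP`, `motherDP`, `probandDP` (non-negative depths), `motherADalt`
#' (maternal alt reads, `<= motherDP`). After classification a `group` column
#' (one of S1-S8, `NotInformative`, `MendelianError`) is present, and after
#' joining plasma counts `plasmaADref`, `plasmaADalt`, `plasmaDP`.
#'
#' @seealso [TrioSites()], [classifyTrioSites()], [qcTrioSites()]
#' @export
setClass("TrioSites", contains = "GRanges")

.TRIO_MCOLS <- c("ref", "alt", "fatherGT", "motherGT", "probandGT",
                 "fatherDP", "motherDP", "probandDP", "motherADalt")

setValidity("TrioSites", function(object) {
    mc <- mcols(object)
    missing <- setdiff(.TRIO_MCOLS, colnames(mc))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    for (col in c("fatherGT", "motherGT", "probandGT")) {
        v <- mc[[col]]
        if (!all(v %in% .GT_LEVELS | is.na(v)))
            return(paste0(col, " must be 0, 1, 2 or NA"))
    }
    if (any(mc$ref == mc$alt))
        return("ref and alt allele identical at some site")
    bad <- !is.na(mc$motherADalt) & !is.na(mc$motherDP) &
        mc$motherADalt > mc$motherDP
    if (any(bad))
        return("motherADalt exceeds motherDP at some site")
    dp <- c(mc$fatherDP, mc$motherDP, mc$probandDP)
    if (any(dp < 0, na.rm = TRUE))
        return("negative depth")
    TRUE
})

#' Plasma cfDNA allele counts
#'
#' A [GenomicRanges::GRanges] subclass with one biallelic SNP per range and
#' consensus-level plasma read counts as metadata columns: `ref`, `alt`,
#' `adRef`, `adAlt` (reads supporting each allele) and `dp` (total depth;
#' `adRef + adAlt <= dp`, reads of other alleles may occupy the gap).
#'
#' @seealso [PlasmaSites()], [readPlasmaVcf()], [joinPlasma()]
#' @export
setClass("PlasmaSites", contains = "GRanges")

.PLASMA_MCOLS <- c("ref", "alt", "adRef", "adAlt", "dp")

setValidity("PlasmaSites", function(object) {
    mc <- mcols(object)
    missing <- setdiff(.PLASMA_MCOLS, colnames(mc))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (any(mc$dp < 0, na.rm = TRUE))
        return("negative depth")
    bad <- mc$adRef + mc$adAlt > mc$dp
    if (any(bad, na.rm = TRUE))
        return("adRef + adAlt exceeds dp at some site")
    TRUE
})

#' Fetal-fraction estimate
#'
#' Result of [estimateFetalFraction()]: the mean `e` of the per-site
#' fractions `f = 2p/(p+q)` over informative sites, their standard
#' deviation, the number of sites used, and the per-site values with the
#' site kind (`OPPOSITE_HOMOZYGOTES` or `FATHER_HET_MOTHER_HOM`).
#'
#' @slot e numeric(1), fetal fraction in [0, 1].
#' @slot sd numeric(1), standard deviation of the per-site fractions.
#' @slot nSites integer(1), sites used.
#' @slot perSiteF numeric, per-site fractions.
#' @slot kind character, site kind per used site.
#' @export
setClass("FetalFraction",
    representation(e = "numeric", sd = "numeric", nSites = "integer",
                   perSiteF = "numeric", kind = "character"))

setValidity("FetalFraction", function(object) {
    if (length(object@e) != 1L || is.na(object@e) ||
        object@e < 0 || object@e > 1)
        return("e must be a single value in [0, 1]")
    if (object@nSites != length(object@perSiteF))
        return("nSites must equal length(perSiteF)")
    if (object@nSites < 1L)
        return("at least one informative site required")
    TRUE
})

#' Per-parent S-value report
#'
#' Result of [computeSValues()]: one row per genotype group (S1-S8) with its
#' locus count, observed mean plasma ratio FE, maternal ratio ME, expected
#' ratios PE (pathogenic) and BE (benign/wild-type), and the group's factor
#' `|FE-BE| / |FE-PE|`; plus the per-parent products `sMother` (over S1-S4)
#' and `sFather` (over S5-S8). A side with no group passing the locus floor
#' has an `NA` product and is reported Inconclusive downstream.
#'
#' @slot groups DataFrame with columns label, parent, nLoci, FE, ME, PE, BE,
#'   factor, included.
#' @slot sMother,sFather numeric(1), weighting products (NA when no group
#'   survives on that side).
#' @slot e numeric(1), the fetal fraction used.
#' @slot thresholds numeric(2), upper/lower call bounds (default 10 and 0.1).
#' @export
setClass("SValueReport",
    representation(groups = "DataFrame", sMother = "numeric",
                   sFather = "numeric", e = "numeric",
                   thresholds = "numeric"))

setValidity("SValueReport", function(object) {
    need <- c("label", "parent", "nLoci", "FE", "ME", "PE", "BE",
              "factor", "included")
    missing <- setdiff(need, colnames(object@groups))
    if (length(missing))
        return(paste("groups lacks column(s):",
                     paste(missing, collapse = ", ")))
    if (length(object@thresholds) != 2L ||
        object@thresholds[1] <= 1 || object@thresholds[2] >= 1)
        return("thresholds must be c(upper > 1, lower < 1)")
    TRUE
})

#' Fetal haplotype call
#'
#' Per-parent inheritance (`PATHOGENIC`, `WILD_TYPE` or `INCONCLUSIVE`) and
#' the overall clinical call, using the reporting vocabulary `Affected`,
#' `Maternal mutation carriers`, `Paternal mutation carriers`, `N`
#' (normal) and `Inconclusive`.
#'
#' @slot maternal,paternal character(1) inheritance of each parental
#'   haplotype.
#' @slot overall character(1) overall call.
#' @export
setClass("FetalCall",
    representation(maternal = "character", paternal = "character",
                   overall = "character"))

.INHERITANCE <- c("PATHOGENIC", "WILD_TYPE", "INCONCLUSIVE")
.CALLS <- c("Affected", "Maternal mutation carriers",
            "Paternal mutation carriers", "N", "Inconclusive")

setValidity("FetalCall", function(object) {
    if (!object@maternal %in% .INHERITANCE ||
        !object@paternal %in% .INHERITANCE)
        return("per-parent inheritance must be PATHOGENIC, WILD_TYPE or INCONCLUSIVE")
    if (!object@overall %in% .CALLS)
        return(paste("overall must be one of:", paste(.CALLS, collapse = ", ")))
    TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic-family generator. Defaults emulate the
#' targeted-capture design the caller assumes: a 2-Mb region of biallelic
#' SNPs with population alt-allele frequencies uniform on 10-90%, about
#' 1,200 SNPs per family, plasma consensus depth 3,000x, genomic depth
#' 2,000x, and a symmetric per-read error rate of 0.001.
#'
#' @slot nSnps integer(1), SNPs drawn in the region.
#' @slot nInformative integer(1) or NA; when set, sites are truncated so
#'   that exactly this many S1-S8 (haplotype-informative) sites remain.
#' @slot altFreqRange numeric(2), uniform range of population alt-allele
#'   frequencies.
#' @slot fetalFraction numeric(1), true fetal fraction e in (0, 1).
#' @slot plasmaDepthMean,genomicDepthMean numeric(1), Poisson depth means.
#' @slot seqErrorRate numeric(1), symmetric per-read miscall probability.
#' @slot maternalInheritance,paternalInheritance character(1),
#'   `"PATHOGENIC"` or `"WILD_TYPE"`: which haplotype of each parent the
#'   fetus inherits.
#' @slot mendelianErrorRate numeric(1), fraction of sites whose proband
#'   genotype is corrupted to a Mendelian-inconsistent state.
#' @slot recombinationRate numeric(1), per-meiosis probability of a single
#'   crossover in the fetal transmission of each parent.
#' @slot seed integer(1) RNG seed (NA = do not seed).
#' @export
setClass("SimulationConfig",
    representation(nSnps = "integer", nInformative = "integer",
                   altFreqRange = "numeric", fetalFraction = "numeric",
                   plasmaDepthMean = "numeric", genomicDepthMean = "numeric",
                   seqErrorRate = "numeric",
                   maternalInheritance = "character",
                   paternalInheritance = "character",
                   mendelianErrorRate = "numeric",
                   recombinationRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@fetalFraction <= 0 || object@fetalFraction >= 1)
        return("fetalFraction must be in (0, 1)")
    if (object@plasmaDepthMean <= 0 || object@genomicDepthMean <= 0)
        return("depth means must be positive")
    r <- object@altFreqRange
    if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
        return("altFreqRange must be an ordered interval inside (0, 1)")
    inh <- c(object@maternalInheritance, object@paternalInheritance)
    if (!all(inh %in% c("PATHOGENIC", "WILD_TYPE")))
        return("inheritance must be PATHOGENIC or WILD_TYPE")
    if (object@nSnps < 1L)
        return("nSnps must be positive")
    TRUE
})

#' Simulated family ground truth
#'
#' Full phased truth of a synthetic family: per-site population alt-allele
#' frequency and the four parental haplotype alleles (haplotype 1 of each
#' parent is flagged pathogenic, i.e. in linkage with the disease variant),
#' the proband (who inherits both pathogenic haplotypes), and the fetal
#' transmitted alleles under the configured inheritance.
#'
#' @slot config the [SimulationConfig-class] used.
#' @slot sites GRanges with per-site truth columns (`ref`, `alt`, `altFreq`,
#'   `fatherHapP`, `fatherHapW`, `motherHapP`, `motherHapW`, `probandGT`,
#'   `fetusPatAllele`, `fetusMatAllele`, `fetusGT`,
#'   `mendelianErrorInjected`).
#' @export
setClass("FamilyTruth",
    representation(config = "SimulationConfig", sites = "GRanges"))

#' Full pipeline result
#'
#' Bundle returned by [runCall()]: the fetal-fraction estimate (or NULL if
#' not estimable), the S-value report (or NULL), the fetal call, and a QC
#' log with the site counts at each filtering stage.
#'
#' @slot ff [FetalFraction-class] or NULL.
#' @slot sValues [SValueReport-class] or NULL.
#' @slot call [FetalCall-class].
#' @slot qcLog data.frame with columns stage, sitesIn, sitesOut, reason.
#' @slot reason character(1), why the call is Inconclusive ("" otherwise).
#' @export
setClass("NIPDResult",
    representation(ff = "ANY", sValues = "ANY", call = "FetalCall",
                   qcLog = "data.frame", reason = "character"))
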