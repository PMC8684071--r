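## Trio grouping: select informative, Mendelian-consistent SNPs and assign
## each to one of the eight genotype groups that anchor the pathogenic and
## wild-type parental haplotypes through the affected proband.

#' Mendelian consistency of a trio genotype combination
#'
#' A proband genotype is consistent when it can be formed from one paternal
#' and one maternal allele. Vectorised over sites.
#'
#' @param fatherGT,motherGT,probandGT integer alt-allele counts (0, 1, 2).
#' @return logical vector.
#' @examples
#' isMendelianConsistent(0L, 0L, 2L)  # FALSE: no alt allele in parents
#' isMendelianConsistent(1L, 1L, 0L)  # TRUE
#' @export
isMendelianConsistent <- function(fatherGT, motherGT, probandGT) {
    n <- max(length(fatherGT), length(motherGT), length(probandGT))
    f <- rep_len(as.integer(fatherGT), n)
    m <- rep_len(as.integer(motherGT), n)
    p <- rep_len(as.integer(probandGT), n)
    if (anyNA(f) || anyNA(m) || anyNA(p))
        stop("missing genotype: site unusable for Mendelian check")
    ## transmissible alleles: gt 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    fMin <- as.integer(f == 2L); fMax <- as.integer(f >= 1L)
    mMin <- as.integer(m == 2L); mMax <- as.integer(m >= 1L)
    p >= fMin + mMin & p <= fMax + mMax
}

#' The eight-group genotype table
#'
#' One row per informative trio pattern: the parental and proband genotypes,
#' which parent's haplotype the group informs on, and the symbolic expected
#' plasma alt-ratios. `PE = ME + peK * e/2` is the expectation if the fetus
#' inherited the pathogenic haplotype of the heterozygous parent and
#' `BE = ME + beK * e/2` if it inherited the wild-type haplotype, where `ME`
#' is the maternal allele ratio (observed for the maternal groups S1-S4;
#' fixed at the homozygous dosage `meFixed` of 0 or 1 for the paternal
#' groups S5-S8) and `e` the fetal fraction.
#'
#' @return data.frame with columns label, father, mother, proband, parent,
#'   meFixed, peK, beK.
#' @export
groupTable <- function() .GROUP_TABLE

#' Classify trio genotype combinations into haplotype groups
#'
#' @param fatherGT,motherGT,probandGT integer alt-allele counts.
#' @return character vector: `"S1"`-`"S8"`, `"NotInformative"` (consistent
#'   but not one of the eight patterns, e.g. both parents heterozygous or
#'   both homozygous) or `"MendelianError"`.
#' @examples
#' classifyGenotypes(0L, 1L, 0L)  # "S1"
#' classifyGenotypes(1L, 1L, 1L)  # "NotInformative"
#' @export
classifyGenotypes <- function(fatherGT, motherGT, probandGT) {
    n <- max(length(fatherGT), length(motherGT), length(probandGT))
    f <- rep_len(as.integer(fatherGT), n)
    m <- rep_len(as.integer(motherGT), n)
    p <- rep_len(as.integer(probandGT), n)
    out <- rep("NotInformative", n)
    out[!isMendelianConsistent(f, m, p)] <- "MendelianError"
    key <- paste(f, m, p)
    tabKey <- paste(.GROUP_TABLE$father, .GROUP_TABLE$mother,
                    .GROUP_TABLE$proband)
    hit <- match(key, tabKey)
    ok <- !is.na(hit) & out == "NotInformative"
    out[ok] <- .GROUP_TABLE$label[hit[ok]]
    out
}

#' @describeIn classifyGenotypes classify a [TrioSites-class] object,
#'   adding/overwriting its `group` metadata column.
#' @param sites a `TrioSites` object with non-missing genotypes.
#' @export
classifyTrioSites <- function(sites) {
    stopifnot(is(sites, "TrioSites"))
    gm <- genotypeMatrix(sites)
    grp <- rep(NA_character_, length(sites))
    ok <- !is.na(gm[, 1]) & !is.na(gm[, 2]) & !is.na(gm[, 3])
    grp[ok] <- classifyGenotypes(gm[ok, 1], gm[ok, 2], gm[ok, 3])
    mcols(sites)$group <- grp
    sites
}

#' Quality-control filter for trio sites
#'
#' Drops sites with a missing genotype, a genomic depth below the floor in
#' any trio sample, or a Mendelian-inconsistent genotype combination;
#' classifies the survivors. By default sites that are informative neither
#' for haplotype grouping (S1-S8) nor for fetal-fraction estimation
#' (opposite parental homozygotes) are also dropped, so the output feeds
#' both downstream stages; set `keep = "grouping"` to retain S1-S8 only.
#'
#' @param sites a [TrioSites-class] object.
#' @param minGenomicDepth depth floor applied to all three samples
#'   (default 20).
#' @param keep `"informative"` (default: S1-S8 plus opposite-homozygote
#'   fetal-fraction sites), `"grouping"` (S1-S8 only) or `"all"` (only
#'   depth/missing/Mendelian filters).
#' @return The filtered, classified `TrioSites`, sorted by position, with
#'   a `qcLog` data.frame (stage, sitesIn, sitesOut, reason) in
#'   `metadata()`.
#' @export
qcTrioSites <- function(sites, minGenomicDepth = 20L,
                        keep = c("informative", "grouping", "all")) {
    stopifnot(is(sites, "TrioSites"))
    keep <- match.arg(keep)
    log <- data.frame(stage = character(), sitesIn = integer(),
                      sitesOut = integer(), reason = character())
    note <- function(stage, nin, nout, reason)
        rbind(log, data.frame(stage = stage, sitesIn = nin, sitesOut = nout,
                              reason = reason))

    gm <- genotypeMatrix(sites)
    ok <- !is.na(gm[, 1]) & !is.na(gm[, 2]) & !is.na(gm[, 3])
    log <- note("missing_genotype", length(sites), sum(ok),
                "genotype missing in a trio sample")
    sites <- sites[ok]

    mc <- mcols(sites)
    ok <- mc$fatherDP >= minGenomicDepth & mc$motherDP >= minGenomicDepth &
        mc$probandDP >= minGenomicDepth
    ok[is.na(ok)] <- FALSE
    log <- note("low_depth", length(sites), sum(ok),
                sprintf("genomic depth < %d in a trio sample",
                        as.integer(minGenomicDepth)))
    sites <- sites[ok]

    sites <- classifyTrioSites(sites)
    grp <- groupLabels(sites)
    ok <- grp != "MendelianError"
    log <- note("mendelian_error", length(sites), sum(ok),
                "proband genotype inconsistent with parents")
    sites <- sites[ok]
    grp <- grp[ok]

    if (keep != "all") {
        keepMask <- grp %in% .S_GROUPS
        if (keep == "informative") {
            mc <- mcols(sites)
            oppHom <- (mc$fatherGT == 0L & mc$motherGT == 2L) |
                (mc$fatherGT == 2L & mc$motherGT == 0L)
            keepMask <- keepMask | oppHom
        }
        log <- note("not_informative", length(sites), sum(keepMask),
                    "site informs neither haplotype grouping nor fetal fraction")
        sites <- sites[keepMask]
    }

    sites <- sites[order(as.factor(seqnames(sites)), start(sites))]
    metadata(sites)$qcLog <- log
    sites
}
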