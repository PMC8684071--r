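#' Construct trio SNP sites
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions.
#' @param ref,alt single-base reference and alternate alleles.
#' @param fatherGT,motherGT,probandGT integer alt-allele counts (0, 1, 2;
#'   `NA` for missing).
#' @param fatherDP,motherDP,probandDP per-sample sequencing depths.
#' @param motherADalt maternal alt-supporting read count (used for the
#'   maternal allele ratio MR = AD/DP).
#'
#' @return A [TrioSites-class] object sorted by position.
#' @examples
#' ts <- TrioSites("chr12", c(100, 200), ref = c("A", "C"),
#'                 alt = c("G", "T"),
#'                 fatherGT = c(0L, 1L), motherGT = c(1L, 0L),
#'                 probandGT = c(0L, 0L),
#'                 fatherDP = c(2000L, 2000L), motherDP = c(2000L, 2000L),
#'                 probandDP = c(2000L, 2000L), motherADalt = c(990L, 0L))
#' classifyTrioSites(ts)
#' @export
TrioSites <- function(chrom, pos, ref, alt, fatherGT, motherGT, probandGT,
                      fatherDP, motherDP, probandDP, motherADalt) {
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        fatherGT = as.integer(fatherGT), motherGT = as.integer(motherGT),
        probandGT = as.integer(probandGT),
        fatherDP = as.integer(fatherDP), motherDP = as.integer(motherDP),
        probandDP = as.integer(probandDP),
        motherADalt = as.integer(motherADalt))
    new("TrioSites", GenomicRanges::sort(gr))
}

#' Construct plasma cfDNA allele counts
#'
#' @param chrom,pos,ref,alt site coordinates and alleles (1-based).
#' @param adRef,adAlt reads supporting the reference / alternate allele.
#' @param dp total depth; defaults to `adRef + adAlt`.
#' @return A [PlasmaSites-class] object sorted by position.
#' @export
PlasmaSites <- function(chrom, pos, ref, alt, adRef, adAlt,
                        dp = adRef + adAlt) {
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        adRef = as.integer(adRef), adAlt = as.integer(adAlt),
        dp = as.integer(dp))
    new("PlasmaSites", GenomicRanges::sort(gr))
}

#' @describeIn TrioSites-class trio genotypes as an integer matrix with
#'   columns father, mother, proband.
#' @param x a `TrioSites` object.
#' @export
genotypeMatrix <- function(x) {
    stopifnot(is(x, "TrioSites"))
    cbind(father = mcols(x)$fatherGT, mother = mcols(x)$motherGT,
          proband = mcols(x)$probandGT)
}

#' @describeIn TrioSites-class group labels (`NA` before classification).
#' @export
groupLabels <- function(x) {
    stopifnot(is(x, "TrioSites"))
    if ("group" %in% colnames(mcols(x))) mcols(x)$group
    else rep(NA_character_, length(x))
}

setMethod("show", "TrioSites", function(object) {
    grp <- groupLabels(object)
    cat(class(object), "with", length(object), "site(s)")
    if (!all(is.na(grp))) {
        n <- sum(grp %in% .S_GROUPS)
        cat(";", n, "haplotype-informative (S1-S8)")
    }
    cat("\n")
    if (length(object)) methods::callNextMethod()
})

setMethod("show", "FetalFraction", function(object) {
    cat("FetalFraction: e =", format(object@e, digits = 4),
        "(sd", format(object@sd, digits = 3), "over",
        object@nSites, "sites)\n")
    tab <- table(object@kind)
    cat("  site kinds:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "SValueReport", function(object) {
    cat("SValueReport (e =", format(object@e, digits = 4), ")\n")
    cat("  S_mother =", format(object@sMother, digits = 4),
        " S_father =", format(object@sFather, digits = 4), "\n")
    g <- as.data.frame(object@groups)
    num <- vapply(g, is.numeric, logical(1))
    g[num] <- lapply(g[num], signif, digits = 4)
    print(g, row.names = FALSE)
})

setMethod("show", "FetalCall", function(object) {
    cat("FetalCall:", object@overall, "\n")
    cat("  maternal haplotype:", object@maternal,
        "| paternal haplotype:", object@paternal, "\n")
})

setMethod("show", "NIPDResult", function(object) {
    show(object@call)
    if (!is.null(object@ff)) show(object@ff)
    if (nzchar(object@reason)) cat("  reason:", object@reason, "\n")
})

setMethod("show", "FamilyTruth", function(object) {
    cfg <- object@config
    cat("FamilyTruth:", length(object@sites), "sites; true e =",
        cfg@fetalFraction, "\n")
    cat("  fetal inheritance: maternal", cfg@maternalInheritance,
        "/ paternal", cfg@paternalInheritance, "\n")
})

#' @describeIn FetalFraction-class the estimated fetal fraction.
#' @param object a `FetalFraction`.
#' @export
fetalFraction <- function(object) {
    stopifnot(is(object, "FetalFraction"))
    object@e
}

#' @describeIn SValueReport-class maternal-side weighting product.
#' @param object a `SValueReport`.
#' @export
sMother <- function(object) {
    stopifnot(is(object, "SValueReport"))
    object@sMother
}

#' @describeIn SValueReport-class paternal-side weighting product.
#' @export
sFather <- function(object) {
    stopifnot(is(object, "SValueReport"))
    object@sFather
}

#' @describeIn SValueReport-class per-group summary table.
#' @export
groupSummaries <- function(object) {
    stopifnot(is(object, "SValueReport"))
    object@groups
}

#' @describeIn FetalCall-class the overall clinical call string.
#' @param object a `FetalCall`.
#' @export
overallCall <- function(object) {
    stopifnot(is(object, "FetalCall"))
    object@overall
}
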