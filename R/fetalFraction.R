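## Fetal-fraction estimation from paternal-specific alleles in plasma.
##
## Two site kinds carry a paternal-specific allele: opposite parental
## homozygotes (the fetus is an obligate heterozygote, so the paternal
## allele is always present at mixture fraction e/2) and father-het /
## mother-hom sites (the paternal-specific allele is present only when the
## father transmitted it, which happens for half the sites). Per site,
## f = 2p/(p+q) estimates e, where p counts plasma reads of the
## paternal-specific allele and q reads of the shared maternal allele.

#' Per-site fetal fraction
#'
#' `f = 2p / (p + q)`, clamped to [0, 1]; `p` is the paternal-specific
#' allele read count, `q` the shared maternal allele read count.
#'
#' @param p,q non-negative read counts; vectorised.
#' @return numeric fractions.
#' @examples
#' siteFetalFraction(96, 2904)  # 0.064
#' @export
siteFetalFraction <- function(p, q) {
    if (any(p + q <= 0))
        stop("uninformative site: zero reads at both alleles")
    pmin(2 * p / (p + q), 1)
}

#' Select fetal-fraction informative sites and attach plasma counts
#'
#' @param sites QC-passed [TrioSites-class] (genotypes non-missing,
#'   Mendelian-consistent).
#' @param plasma [PlasmaSites-class] counts for the maternal plasma sample.
#' @param kinds which informative kinds to use (see
#'   [haplodoseControl()]'s `ffSiteKinds`).
#' @return data.frame with columns chrom, pos, kind, paternalAllele
#'   (`"ref"`/`"alt"`), p, q, dp.
#' @export
selectFFSites <- function(sites, plasma,
                          kinds = c("both", "opposite_hom", "father_het")) {
    stopifnot(is(sites, "TrioSites"))
    kinds <- match.arg(kinds)
    joined <- joinPlasma(sites, plasma)
    mc <- mcols(joined)

    oppHom <- (mc$fatherGT == 0L & mc$motherGT == 2L) |
        (mc$fatherGT == 2L & mc$motherGT == 0L)
    fatherHet <- mc$fatherGT == 1L & mc$motherGT %in% c(0L, 2L)
    use <- switch(kinds,
        both = oppHom | fatherHet,
        opposite_hom = oppHom,
        father_het = fatherHet)
    use[is.na(use)] <- FALSE
    joined <- joined[use]
    mc <- mcols(joined)
    oppHom <- oppHom[use]

    ## paternal-specific allele = the paternal allele absent from the mother
    patIsAlt <- mc$motherGT == 0L
    p <- ifelse(patIsAlt, mc$plasmaADalt, mc$plasmaADref)
    q <- ifelse(patIsAlt, mc$plasmaADref, mc$plasmaADalt)
    data.frame(
        chrom = as.character(seqnames(joined)), pos = start(joined),
        kind = ifelse(oppHom, "OPPOSITE_HOMOZYGOTES", "FATHER_HET_MOTHER_HOM"),
        paternalAllele = ifelse(patIsAlt, "alt", "ref"),
        p = as.integer(p), q = as.integer(q), dp = mc$plasmaDP)
}

#' Estimate the fetal fraction of cell-free DNA
#'
#' Averages the per-site fractions `f = 2p/(p+q)` over informative sites:
#' `e = sum(f_i) / n`. Sites below the plasma depth floor are excluded.
#' Father-het / mother-hom sites enter only when the paternal-specific
#' allele is actually detected (fraction above `ffDetectionFloor` and at
#' least `ffMinPaternalReads` reads), since at half of those sites the
#' fetus did not inherit it and the site carries no signal.
#'
#' @param ffSites data.frame from [selectFFSites()].
#' @param control a [haplodoseControl()] list.
#' @return A [FetalFraction-class] object.
#' @examples
#' ff <- data.frame(kind = "OPPOSITE_HOMOZYGOTES",
#'                  p = c(90, 100, 110), q = rep(2900, 3),
#'                  dp = rep(3000, 3))
#' estimateFetalFraction(ff, haplodoseControl(minFFSites = 1))
#' @export
estimateFetalFraction <- function(ffSites, control = haplodoseControl()) {
    stopifnot(is.data.frame(ffSites),
              all(c("kind", "p", "q", "dp") %in% names(ffSites)))
    keep <- ffSites$dp >= control$plasmaDepthFloor & ffSites$p + ffSites$q > 0
    ffSites <- ffSites[keep, , drop = FALSE]

    het <- ffSites$kind == "FATHER_HET_MOTHER_HOM"
    fRaw <- siteFetalFraction(ffSites$p, ffSites$q)
    detected <- fRaw >= control$ffDetectionFloor &
        ffSites$p >= control$ffMinPaternalReads
    ffSites <- ffSites[!het | detected, , drop = FALSE]
    f <- fRaw[!het | detected]

    if (nrow(ffSites) < control$minFFSites)
        stop("fetal fraction not estimable: ", nrow(ffSites),
             " usable sites (minimum ", control$minFFSites, ")")

    e <- if (control$ffRobust) stats::median(f) else mean(f)
    new("FetalFraction", e = e,
        sd = if (length(f) > 1) sd(f) else 0,
        nSites = length(f), perSiteF = as.numeric(f),
        kind = as.character(ffSites$kind))
}
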