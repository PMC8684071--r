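#' Pipeline tuning parameters
#'
#' Collects every threshold the caller uses, with the published operating
#' values as defaults. All depths are consensus read counts; ratios are
#' fractions in [0, 1].
#'
#' @param sUpper,sLower S-value call bounds: a parental S-value `>= sUpper`
#'   calls the pathogenic haplotype, `<= sLower` the wild-type haplotype,
#'   and the open interval between them is the inconclusive gray zone.
#'   Defaults 10 and 0.1.
#' @param minGroupLoci minimum loci for a genotype group to enter the
#'   weighting product (default 5); sparser groups are skipped and logged.
#' @param minFFSites minimum informative sites for the fetal fraction to be
#'   estimable (default 20).
#' @param genomicDepthFloor minimum genomic depth in all three trio samples
#'   for a site to pass QC (default 20).
#' @param plasmaDepthFloor minimum plasma depth for a site to contribute to
#'   either the fetal fraction or a group mean (default 100).
#' @param factorEps denominator guard in the group factor
#'   `|FE-BE| / max(|FE-PE|, factorEps)` (default 1e-4).
#' @param factorFloor,factorCap clamp range for a single group's factor
#'   (defaults 1e-4 and 1e4), bounding any one group's influence on the
#'   product.
#' @param ffSiteKinds which informative-site kinds feed the fetal-fraction
#'   estimate: `"both"` (default), `"opposite_hom"` or `"father_het"`.
#' @param ffDetectionFloor for father-het / mother-hom sites only: minimum
#'   plasma fraction of the paternal-specific allele for the site to count
#'   as carrying it (default 0.01). At such sites the fetus inherits the
#'   paternal-specific allele only half the time; sites where it is absent
#'   carry no fetal-fraction signal and would bias the mean toward zero.
#' @param ffMinPaternalReads companion absolute floor on the
#'   paternal-specific read count (default 3).
#' @param ffRobust use the median instead of the mean of per-site fractions
#'   (default FALSE; the plain mean is the published estimator).
#'
#' @return A named list of class `haplodoseControl`.
#' @export
haplodoseControl <- function(sUpper = 10, sLower = 0.1,
                             minGroupLoci = 5L, minFFSites = 20L,
                             genomicDepthFloor = 20L, plasmaDepthFloor = 100L,
                             factorEps = 1e-4, factorFloor = 1e-4,
                             factorCap = 1e4,
                             ffSiteKinds = c("both", "opposite_hom",
                                             "father_het"),
                             ffDetectionFloor = 0.01,
                             ffMinPaternalReads = 3L,
                             ffRobust = FALSE) {
    ffSiteKinds <- match.arg(ffSiteKinds)
    stopifnot(sUpper > 1, sLower < 1, sLower > 0,
              minGroupLoci >= 1, minFFSites >= 1,
              genomicDepthFloor >= 0, plasmaDepthFloor >= 0,
              factorEps > 0, factorFloor > 0, factorCap > factorFloor)
    structure(list(sUpper = sUpper, sLower = sLower,
                   minGroupLoci = as.integer(minGroupLoci),
                   minFFSites = as.integer(minFFSites),
                   genomicDepthFloor = as.integer(genomicDepthFloor),
                   plasmaDepthFloor = as.integer(plasmaDepthFloor),
                   factorEps = factorEps, factorFloor = factorFloor,
                   factorCap = factorCap, ffSiteKinds = ffSiteKinds,
                   ffDetectionFloor = ffDetectionFloor,
                   ffMinPaternalReads = as.integer(ffMinPaternalReads),
                   ffRobust = isTRUE(ffRobust)),
              class = "haplodoseControl")
}
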