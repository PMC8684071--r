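## The weighting-product caller. For each genotype group the observed mean
## plasma alt-ratio FE is compared with the two model expectations: PE if
## the fetus inherited the pathogenic haplotype of the group's heterozygous
## parent, BE if it inherited the wild-type haplotype. Each group
## contributes the factor |FE-BE| / |FE-PE| and the per-parent product of
## factors (S_mother over S1-S4, S_father over S5-S8) is compared with the
## call bounds.

#' Per-site mutation ratio
#'
#' `R = AD / DP`: alt-supporting reads over total depth.
#'
#' @param adAlt,dp non-negative integers; vectorised. `dp` must be > 0.
#' @return numeric fractions in [0, 1].
#' @export
siteMutationRatio <- function(adAlt, dp) {
    if (any(dp <= 0))
        stop("zero-depth site: exclude before computing ratios")
    adAlt / dp
}

#' Observed group means FE and ME
#'
#' `FE` is the mean plasma mutation ratio over the group's loci. `ME` is
#' the mean maternal genomic mutation ratio for the maternal groups S1-S4;
#' for the paternal groups S5-S8 the mother is homozygous and `ME` is fixed
#' at her dosage (0 for 0/0 in S5-S6, 1 for 1/1 in S7-S8) regardless of the
#' observed maternal ratios.
#'
#' @param label group label, `"S1"`-`"S8"`.
#' @param plasmaRatios per-locus plasma alt ratios for the group.
#' @param maternalRatios per-locus maternal genomic alt ratios.
#' @return named numeric: `FE`, `ME`.
#' @export
groupObserved <- function(label, plasmaRatios, maternalRatios) {
    stopifnot(label %in% .S_GROUPS, length(plasmaRatios) >= 1,
              length(plasmaRatios) == length(maternalRatios))
    row <- .GROUP_TABLE[.GROUP_TABLE$label == label, ]
    me <- if (is.na(row$meFixed)) mean(maternalRatios) else row$meFixed
    c(FE = mean(plasmaRatios), ME = me)
}

#' Expected plasma ratios PE and BE for a group
#'
#' Evaluates the symbolic group table: S1 `(ME-e/2, ME)`, S2 `(ME, ME-e/2)`,
#' S3 `(ME, ME+e/2)`, S4 `(ME+e/2, ME)`, S5 `(0, e/2)`, S6 `(e/2, 0)`,
#' S7 `(1-e/2, 1)`, S8 `(1, 1-e/2)`; results clamped to [0, 1]. These are
#' exactly the plasma alt-fraction expectations of the maternal-fetal
#' mixture `(1-e) * maternalDosage + e * fetalDosage` for the two possible
#' fetal inheritances.
#'
#' @param label group label, `"S1"`-`"S8"`.
#' @param ME maternal ratio in [0, 1] (ignored for S5-S8, where the fixed
#'   homozygous dosage is used).
#' @param e fetal fraction in (0, 1).
#' @return named numeric: `PE`, `BE`.
#' @examples
#' expectedRatios("S5", e = 0.10)            # PE 0.00, BE 0.05
#' expectedRatios("S3", ME = 0.5, e = 0.08)  # PE 0.50, BE 0.54
#' @export
expectedRatios <- function(label, ME = NA_real_, e) {
    stopifnot(label %in% .S_GROUPS, e > 0, e < 1)
    row <- .GROUP_TABLE[.GROUP_TABLE$label == label, ]
    base <- if (is.na(row$meFixed)) ME else row$meFixed
    if (is.na(base) || base < 0 || base > 1)
        stop("ME must be supplied in [0, 1] for maternal groups S1-S4")
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    c(PE = clamp01(base + row$peK * e / 2),
      BE = clamp01(base + row$beK * e / 2))
}

#' A group's contribution to the weighting product
#'
#' `|FE - BE| / max(|FE - PE|, factorEps)`, clamped to
#' `[factorFloor, factorCap]`. Values above 1 favour pathogenic
#' inheritance (FE closer to PE), values below 1 wild-type.
#'
#' @param FE,PE,BE fractions in [0, 1]; `PE` must differ from `BE`.
#' @param control a [haplodoseControl()] list supplying `factorEps`,
#'   `factorFloor`, `factorCap`.
#' @return positive numeric.
#' @export
groupFactor <- function(FE, PE, BE, control = haplodoseControl()) {
    if (isTRUE(all.equal(PE, BE, tolerance = 1e-12)))
        stop("PE equals BE: fetal fraction too small to separate hypotheses")
    raw <- abs(FE - BE) / pmax(abs(FE - PE), control$factorEps)
    pmin(pmax(raw, control$factorFloor), control$factorCap)
}

#' Compute the per-parent S-values
#'
#' Groups classified sites (S1-S8), computes FE/ME/PE/BE per group, and
#' multiplies the factors of the groups passing the locus floor into
#' `S_mother` (maternal groups S1-S4) and `S_father` (paternal groups
#' S5-S8). Each group is treated as an independent event with equal
#' weight. Sites below the plasma depth floor are dropped from group
#' means; groups with fewer than `minGroupLoci` loci are skipped (marked
#' not included). A side where no group survives has an `NA` product.
#'
#' @param sites classified [TrioSites-class] with joined plasma counts
#'   (columns `group`, `plasmaADalt`, `plasmaDP`; see [joinPlasma()]).
#' @param e fetal fraction in (0, 1).
#' @param control a [haplodoseControl()] list.
#' @return A [SValueReport-class] object.
#' @export
computeSValues <- function(sites, e, control = haplodoseControl()) {
    stopifnot(is(sites, "TrioSites"), e > 0, e < 1)
    mc <- mcols(sites)
    if (!all(c("group", "plasmaADalt", "plasmaDP") %in% colnames(mc)))
        stop("sites must be classified and joined with plasma counts")

    use <- mc$group %in% .S_GROUPS & !is.na(mc$plasmaDP) &
        mc$plasmaDP >= control$plasmaDepthFloor
    mc <- mc[use, , drop = FALSE]

    rows <- lapply(.S_GROUPS, function(lab) {
        sel <- mc$group == lab
        n <- sum(sel)
        parent <- .GROUP_TABLE$parent[.GROUP_TABLE$label == lab]
        if (n == 0L)
            return(DataFrame(label = lab, parent = parent, nLoci = 0L,
                             FE = NA_real_, ME = NA_real_, PE = NA_real_,
                             BE = NA_real_, factor = NA_real_,
                             included = FALSE))
        plasmaR <- siteMutationRatio(mc$plasmaADalt[sel], mc$plasmaDP[sel])
        motherR <- siteMutationRatio(mc$motherADalt[sel], mc$motherDP[sel])
        obs <- groupObserved(lab, plasmaR, motherR)
        exp <- expectedRatios(lab, ME = obs[["ME"]], e = e)
        fac <- groupFactor(obs[["FE"]], exp[["PE"]], exp[["BE"]], control)
        DataFrame(label = lab, parent = parent, nLoci = n,
                  FE = obs[["FE"]], ME = obs[["ME"]], PE = exp[["PE"]],
                  BE = exp[["BE"]], factor = fac,
                  included = n >= control$minGroupLoci)
    })
    groups <- do.call(rbind, rows)

    prodSide <- function(parent) {
        g <- groups[groups$parent == parent & groups$included, , drop = FALSE]
        if (nrow(g) == 0L) NA_real_ else prod(g$factor)
    }
    new("SValueReport", groups = groups,
        sMother = prodSide("mother"), sFather = prodSide("father"),
        e = e, thresholds = c(upper = control$sUpper,
                              lower = control$sLower))
}

#' Call the fetal genotype from the S-values
#'
#' Per parental side: `S >= upper` (default 10) calls the pathogenic
#' haplotype, `S <= lower` (default 0.1) the wild-type haplotype, the gray
#' zone in between (or an `NA` product) is inconclusive. The overall call
#' is `Affected` when both sides are pathogenic, `N` (normal) when both
#' are wild-type, a carrier call when exactly one side is pathogenic and
#' the other wild-type, and `Inconclusive` whenever either side is.
#'
#' @param report a [SValueReport-class].
#' @return A [FetalCall-class].
#' @examples
#' \dontrun{callFetus(report)}
#' @export
callFetus <- function(report) {
    stopifnot(is(report, "SValueReport"))
    upper <- report@thresholds[[1]]; lower <- report@thresholds[[2]]
    side <- function(s) {
        if (is.na(s)) "INCONCLUSIVE"
        else if (s >= upper) "PATHOGENIC"
        else if (s <= lower) "WILD_TYPE"
        else "INCONCLUSIVE"
    }
    mat <- side(report@sMother); pat <- side(report@sFather)
    overall <-
        if (mat == "INCONCLUSIVE" || pat == "INCONCLUSIVE") "Inconclusive"
        else if (mat == "PATHOGENIC" && pat == "PATHOGENIC") "Affected"
        else if (mat == "PATHOGENIC") "Maternal mutation carriers"
        else if (pat == "PATHOGENIC") "Paternal mutation carriers"
        else "N"
    new("FetalCall", maternal = mat, paternal = pat, overall = overall)
}
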