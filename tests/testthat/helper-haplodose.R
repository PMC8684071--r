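quiet <- function(expr) suppressMessages(expr)

## Brute-force mixture oracle for the expected plasma alt-ratios of a
## genotype group, derived from first principles and independent of
## expectedRatios(): the plasma alt fraction is (1-e) * maternalDosage +
## e * fetalDosage, where the fetal genotype is the homozygous parent's
## transmitted allele plus either the pathogenic or the wild-type allele
## of the heterozygous parent. The pathogenic allele of the heterozygous
## parent is the one it transmitted to the affected proband.
mixtureOracle <- function(father, mother, proband, e) {
    hetIsMother <- mother == 1L
    homGT <- if (hetIsMother) father else mother
    homTransmit <- homGT / 2                     # 0 or 1
    pathAllele <- proband - homTransmit          # allele proband got from het parent
    stopifnot(pathAllele %in% c(0, 1))
    fetalPath <- homTransmit + pathAllele
    fetalWild <- homTransmit + (1 - pathAllele)
    c(PE = (1 - e) * mother / 2 + e * fetalPath / 2,
      BE = (1 - e) * mother / 2 + e * fetalWild / 2)
}

## Exhaustive trio-genotype enumeration oracle for Mendelian consistency
mendelBruteForce <- function(f, m, p) {
    fAlleles <- if (f == 1L) 0:1 else rep(f / 2, 2)
    mAlleles <- if (m == 1L) 0:1 else rep(m / 2, 2)
    any(outer(fAlleles, mAlleles, `+`) == p)
}

## Swap ref/alt labels at every site of a simulated family
flipTrio <- function(trio) {
    mc <- S4Vectors::mcols(trio)
    TrioSites(as.character(GenomicRanges::seqnames(trio)),
              GenomicRanges::start(trio),
              ref = mc$alt, alt = mc$ref,
              fatherGT = 2L - mc$fatherGT, motherGT = 2L - mc$motherGT,
              probandGT = 2L - mc$probandGT,
              fatherDP = mc$fatherDP, motherDP = mc$motherDP,
              probandDP = mc$probandDP,
              motherADalt = mc$motherDP - mc$motherADalt)
}

flipPlasma <- function(plasma) {
    mc <- S4Vectors::mcols(plasma)
    PlasmaSites(as.character(GenomicRanges::seqnames(plasma)),
                GenomicRanges::start(plasma),
                ref = mc$alt, alt = mc$ref,
                adRef = mc$adAlt, adAlt = mc$adRef, dp = mc$dp)
}

## all 27 trio genotype combinations
trioGrid <- function() expand.grid(father = 0:2, mother = 0:2,
                                   proband = 0:2)
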