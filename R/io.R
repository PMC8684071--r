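## Readers and writers for the formats the pipeline touches: VCF v4.2 with
## per-sample GT/AD/DP (via VariantAnnotation), simple TSV dialects, and
## the JSON/TSV result report.

.gtToInt <- function(gt) {
    gt <- sub("\\|", "/", gt)
    out <- rep(NA_integer_, length(gt))
    out[gt %in% c("0/0")] <- 0L
    out[gt %in% c("0/1", "1/0")] <- 1L
    out[gt %in% c("1/1")] <- 2L
    out
}

## AD comes back as an n x samples x 2 array for uniform biallelic records,
## or as a matrix of integer vectors; normalise to list-of-pairs access
.adSlice <- function(ad, sampleIdx, alleleIdx) {
    if (is.array(ad) && length(dim(ad)) == 3L)
        return(as.integer(ad[, sampleIdx, alleleIdx]))
    vapply(ad[, sampleIdx], function(v)
        if (length(v) >= alleleIdx) as.integer(v[alleleIdx]) else NA_integer_,
        integer(1))
}

.readBiallelicSnvVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    refA <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altL)
    altA <- rep(NA_character_, length(vcf))
    altA[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    snv <- nAlt == 1L & nchar(refA) == 1L & !is.na(altA) &
        nchar(altA) == 1L & refA %in% c("A", "C", "G", "T") &
        altA %in% c("A", "C", "G", "T")
    nDropped <- sum(!snv)
    if (nDropped)
        message(nDropped, " record(s) dropped: multi-allelic or not a SNV")
    list(vcf = vcf[snv], rr = rr[snv], ref = refA[snv], alt = altA[snv])
}

#' Read a trio VCF
#'
#' Reads GT, AD and DP for the three named samples; keeps biallelic SNVs
#' only; drops records with a missing genotype in any sample (logged). DP
#' is reconstructed as the sum of AD when absent. AD is taken in VCF
#' order (ref, alt); coordinates are 1-based.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples named character vector with elements `father`, `mother`,
#'   `proband` giving the VCF sample names.
#' @return A [TrioSites-class].
#' @export
readTrioVcf <- function(path, samples = c(father = "FATHER",
                                          mother = "MOTHER",
                                          proband = "PROBAND")) {
    stopifnot(all(c("father", "mother", "proband") %in% names(samples)))
    x <- .readBiallelicSnvVcf(path)
    have <- colnames(x$vcf)
    missing <- setdiff(unname(samples[c("father", "mother", "proband")]),
                       have)
    if (length(missing))
        stop("sample(s) not found in VCF: ", paste(missing, collapse = ", "))
    g <- VariantAnnotation::geno(x$vcf)
    idx <- match(samples[c("father", "mother", "proband")], have)
    gts <- lapply(idx, function(i) .gtToInt(g$GT[, i]))
    ok <- !is.na(gts[[1]]) & !is.na(gts[[2]]) & !is.na(gts[[3]])
    if (any(!ok))
        message(sum(!ok), " record(s) dropped: missing genotype")
    dpOf <- function(i) {
        if ("DP" %in% names(g) && !all(is.na(g$DP[, i])))
            as.integer(g$DP[, i])
        else .adSlice(g$AD, i, 1L) + .adSlice(g$AD, i, 2L)
    }
    ts <- TrioSites(
        chrom = as.character(seqnames(x$rr)), pos = start(x$rr),
        ref = x$ref, alt = x$alt,
        fatherGT = gts[[1]], motherGT = gts[[2]], probandGT = gts[[3]],
        fatherDP = dpOf(idx[1]), motherDP = dpOf(idx[2]),
        probandDP = dpOf(idx[3]),
        motherADalt = .adSlice(g$AD, idx[2], 2L))
    ts[!is.na(mcols(ts)$fatherGT) & !is.na(mcols(ts)$motherGT) &
       !is.na(mcols(ts)$probandGT)]
}

#' Read plasma cfDNA allele counts from a VCF
#'
#' Expects AD (ref, alt order) and optionally DP for a single plasma
#' sample; biallelic SNVs only.
#'
#' @param path VCF file.
#' @param sample sample name or index (default 1, the only sample).
#' @return A [PlasmaSites-class].
#' @export
readPlasmaVcf <- function(path, sample = 1L) {
    x <- .readBiallelicSnvVcf(path)
    g <- VariantAnnotation::geno(x$vcf)
    i <- if (is.character(sample)) match(sample, colnames(x$vcf))
         else as.integer(sample)
    if (is.na(i)) stop("plasma sample not found in VCF: ", sample)
    adRef <- .adSlice(g$AD, i, 1L)
    adAlt <- .adSlice(g$AD, i, 2L)
    dp <- if ("DP" %in% names(g) && !all(is.na(g$DP[, i])))
        as.integer(g$DP[, i]) else adRef + adAlt
    PlasmaSites(as.character(seqnames(x$rr)), start(x$rr),
                ref = x$ref, alt = x$alt,
                adRef = adRef, adAlt = adAlt, dp = dp)
}

#' Read a trio site table (TSV)
#'
#' Tab-separated alternative to VCF input, with header columns `chrom`,
#' `pos`, `ref`, `alt`, `father_gt`, `mother_gt`, `proband_gt` (written
#' `0/0`, `0/1`, `1/1`), `father_dp`, `mother_dp`, `proband_dp`,
#' `mother_ad_alt`.
#'
#' @param path TSV file.
#' @return A [TrioSites-class].
#' @export
readTrioTable <- function(path) {
    d <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "father_gt", "mother_gt",
              "proband_gt", "father_dp", "mother_dp", "proband_dp",
              "mother_ad_alt")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop("trio table lacks column(s): ", paste(missing, collapse = ", "))
    asGT <- function(v) if (is.character(v)) .gtToInt(v) else as.integer(v)
    TrioSites(d$chrom, d$pos, d$ref, d$alt,
              fatherGT = asGT(d$father_gt), motherGT = asGT(d$mother_gt),
              probandGT = asGT(d$proband_gt),
              fatherDP = d$father_dp, motherDP = d$mother_dp,
              probandDP = d$proband_dp, motherADalt = d$mother_ad_alt)
}

#' Read plasma counts from a TSV
#'
#' Header columns `chrom`, `pos`, `ref`, `alt`, `ad_ref`, `ad_alt` and
#' optionally `dp` (default `ad_ref + ad_alt`). Zero-depth records are
#' retained (they are excluded by depth floors downstream).
#'
#' @param path TSV file.
#' @return A [PlasmaSites-class].
#' @export
readPlasmaTable <- function(path) {
    d <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    if (nrow(d) == 0L) {
        warning("empty plasma table: ", path)
        return(PlasmaSites(character(), integer(), character(), character(),
                           integer(), integer(), integer()))
    }
    need <- c("chrom", "pos", "ref", "alt", "ad_ref", "ad_alt")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop("plasma table lacks column(s): ",
             paste(missing, collapse = ", "))
    dp <- if ("dp" %in% names(d)) d$dp else d$ad_ref + d$ad_alt
    PlasmaSites(d$chrom, d$pos, d$ref, d$alt,
                adRef = d$ad_ref, adAlt = d$ad_alt, dp = dp)
}

#' Join plasma counts onto trio sites
#'
#' Exact join on (chrom, pos, ref, alt). Trio sites without a plasma match
#' get `NA` plasma columns; unmatched plasma records are dropped; both are
#' logged.
#'
#' @param sites a [TrioSites-class].
#' @param plasma a [PlasmaSites-class].
#' @return `sites` with metadata columns `plasmaADref`, `plasmaADalt`,
#'   `plasmaDP` added.
#' @export
joinPlasma <- function(sites, plasma) {
    stopifnot(is(sites, "TrioSites"), is(plasma, "PlasmaSites"))
    mcS <- mcols(sites); mcP <- mcols(plasma)
    keyS <- paste(as.character(seqnames(sites)), start(sites),
                  mcS$ref, mcS$alt)
    keyP <- paste(as.character(seqnames(plasma)), start(plasma),
                  mcP$ref, mcP$alt)
    if (anyDuplicated(keyP))
        stop("duplicate (chrom, pos, ref, alt) keys in plasma counts")
    hit <- match(keyS, keyP)
    nUnmatchedPlasma <- sum(!keyP %in% keyS)
    if (nUnmatchedPlasma)
        message(nUnmatchedPlasma,
                " plasma record(s) without a trio site: dropped")
    if (any(is.na(hit)))
        message(sum(is.na(hit)), " trio site(s) without plasma coverage")
    mcols(sites)$plasmaADref <- mcP$adRef[hit]
    mcols(sites)$plasmaADalt <- mcP$adAlt[hit]
    mcols(sites)$plasmaDP <- mcP$dp[hit]
    sites
}

## ---- VCF writing -----------------------------------------------------

.vcfHeader <- function(samples, withGT = TRUE) {
    hdr <- VariantAnnotation::VCFHeader(samples = samples)
    VariantAnnotation::meta(hdr) <- DataFrameList(
        META = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    fmt <- DataFrame(
        Number = c("1", "R", "1"), Type = c("String", "Integer", "Integer"),
        Description = c("Genotype", "Allelic depths (ref,alt)",
                        "Total read depth"),
        row.names = c("GT", "AD", "DP"))
    VariantAnnotation::geno(hdr) <- fmt
    hdr
}

## htslib insists on ##fileformat being the first header line; writeVcf
## emits ##fileDate first, so reorder after writing
.fixVcfHeader <- function(path) {
    x <- readLines(path)
    ff <- grep("^##fileformat", x)
    if (length(ff) && ff[1] != 1L) {
        x <- c(x[ff[1]], x[-ff])
        writeLines(x, path)
    }
    invisible(path)
}

.writeVcfCore <- function(path, chrom, pos, ref, alt, samples, gtMat,
                          adArr, dpMat) {
    n <- length(pos)
    rr <- GRanges(chrom, IRanges(pos, width = 1L))
    names(rr) <- paste0("site", seq_len(n))
    dimnames(gtMat) <- list(names(rr), samples)
    dimnames(dpMat) <- list(names(rr), samples)
    dimnames(adArr) <- list(names(rr), samples, NULL)
    vcf <- VariantAnnotation::VCF(
        rowRanges = rr,
        colData = DataFrame(Samples = seq_along(samples),
                            row.names = samples),
        exptData = list(header = .vcfHeader(samples)),
        fixed = DataFrame(REF = Biostrings::DNAStringSet(ref),
                          ALT = CharacterList(as.list(alt)),
                          QUAL = rep(NA_real_, n),
                          FILTER = rep("PASS", n)),
        geno = SimpleList(GT = gtMat, AD = adArr, DP = dpMat))
    VariantAnnotation::writeVcf(vcf, path)
    .fixVcfHeader(path)
}

.gtString <- function(gt) c("0/0", "0/1", "1/1")[gt + 1L]

.writeTrioVcf <- function(trio, path) {
    mc <- mcols(trio)
    n <- length(trio)
    samples <- c("FATHER", "MOTHER", "PROBAND")
    gtMat <- cbind(.gtString(mc$fatherGT), .gtString(mc$motherGT),
                   .gtString(mc$probandGT))
    dpMat <- cbind(mc$fatherDP, mc$motherDP, mc$probandDP)
    ## only the maternal AD split is tracked; emit missing AD (".") for
    ## father and proband by using NA, which writeVcf serialises as "."
    adArr <- array(NA_integer_, dim = c(n, 3, 2))
    adArr[, 2, 1] <- mc$motherDP - mc$motherADalt
    adArr[, 2, 2] <- mc$motherADalt
    .writeVcfCore(path, as.character(seqnames(trio)), start(trio),
                  mc$ref, mc$alt, samples, gtMat, adArr, dpMat)
}

.writePlasmaVcf <- function(plasma, path) {
    mc <- mcols(plasma)
    n <- length(plasma)
    gtMat <- matrix("./.", n, 1)
    adArr <- array(NA_integer_, dim = c(n, 1, 2))
    adArr[, 1, 1] <- mc$adRef
    adArr[, 1, 2] <- mc$adAlt
    dpMat <- matrix(as.integer(mc$dp), n, 1)
    .writeVcfCore(path, as.character(seqnames(plasma)), start(plasma),
                  mc$ref, mc$alt, "PLASMA", gtMat, adArr, dpMat)
}

## ---- result report ---------------------------------------------------

.reportList <- function(result) {
    sig <- function(x) if (is.null(x) || is.na(x)) NULL else signif(x, 6)
    ff <- result@ff
    sv <- result@sValues
    out <- list(
        fetalFraction = if (is.null(ff)) NULL else list(
            e = sig(ff@e), sd = sig(ff@sd), nSites = ff@nSites,
            perKind = as.list(table(ff@kind))),
        sValues = if (is.null(sv)) NULL else list(
            sMother = sig(sv@sMother), sFather = sig(sv@sFather),
            thresholds = list(upper = sv@thresholds[[1]],
                              lower = sv@thresholds[[2]]),
            groups = lapply(seq_len(nrow(sv@groups)), function(i) {
                g <- sv@groups[i, ]
                list(label = g$label, parent = g$parent, nLoci = g$nLoci,
                     FE = sig(g$FE), ME = sig(g$ME), PE = sig(g$PE),
                     BE = sig(g$BE), factor = sig(g$factor),
                     included = g$included)
            })),
        call = list(maternalInheritance = result@call@maternal,
                    paternalInheritance = result@call@paternal,
                    overall = result@call@overall),
        reason = result@reason,
        qc = result@qcLog)
    out[!vapply(out, is.null, logical(1))]
}

#' Write a pipeline result report
#'
#' JSON (schema shipped at
#' `system.file("schema", "report-schema.json", package = "haplodose")`)
#' or a flat TSV in long `section / key / value` form. Numbers carry 6
#' significant digits; re-running on the same inputs gives a
#' byte-identical file.
#'
#' @param result a [NIPDResult-class] from [runCall()].
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
writeReport <- function(result, path, format = c("json", "tsv")) {
    stopifnot(is(result, "NIPDResult"))
    format <- match.arg(format)
    rep <- .reportList(result)
    if (format == "json") {
        jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
    } else {
        flat <- .flattenReport(rep)
        write.table(flat, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

.flattenReport <- function(x, prefix = character()) {
    rows <- list()
    add <- function(key, value)
        rows[[length(rows) + 1L]] <<- data.frame(
            key = key, value = as.character(value))
    walk <- function(x, pre) {
        if (is.data.frame(x)) {
            for (i in seq_len(nrow(x)))
                for (j in names(x))
                    add(paste(c(pre, i, j), collapse = "."), x[i, j])
        } else if (is.list(x)) {
            nm <- names(x)
            for (i in seq_along(x)) {
                lab <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
                walk(x[[i]], c(pre, lab))
            }
        } else if (length(x)) {
            add(paste(pre, collapse = "."), paste(x, collapse = ","))
        }
    }
    walk(x, prefix)
    do.call(rbind, rows)
}
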