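## Orchestration: QC -> grouping -> fetal fraction -> S-values -> call.

.inconclusiveResult <- function(reason, qcLog, ff = NULL, sv = NULL) {
    new("NIPDResult", ff = ff, sValues = sv,
        call = new("FetalCall", maternal = "INCONCLUSIVE",
                   paternal = "INCONCLUSIVE", overall = "Inconclusive"),
        qcLog = qcLog, reason = reason)
}

#' Run the full haplotype-dosage calling pipeline
#'
#' QC-filters the trio sites, joins plasma counts, estimates the fetal
#' fraction from paternal-specific alleles, computes the per-parent
#' S-values over the eight genotype groups, and calls the fetal
#' inheritance. A clinically inconclusive result is a result, not an
#' error: failure to estimate the fetal fraction or an empty group side
#' yields an `Inconclusive` call with a reason.
#'
#' @param trio a [TrioSites-class], or a path to a trio VCF (read with
#'   [readTrioVcf()]) or TSV (extension `.tsv`/`.txt`, read with
#'   [readTrioTable()]).
#' @param plasma a [PlasmaSites-class], or a path to a plasma VCF or TSV.
#' @param control a [haplodoseControl()] list.
#' @param samples trio VCF sample names, passed to [readTrioVcf()].
#' @param reportPath optional path to write the report to.
#' @param reportFormat `"json"` or `"tsv"`.
#' @return A [NIPDResult-class].
#' @examples
#' fam <- simulateFamily(SimulationConfig(seed = 7))
#' res <- runCall(fam$trio, fam$plasma)
#' overallCall(res@call)
#' @export
runCall <- function(trio, plasma, control = haplodoseControl(),
                    samples = c(father = "FATHER", mother = "MOTHER",
                                proband = "PROBAND"),
                    reportPath = NULL, reportFormat = c("json", "tsv")) {
    reportFormat <- match.arg(reportFormat)
    isTab <- function(p) grepl("\\.(tsv|txt)$", p, ignore.case = TRUE)
    if (is.character(trio))
        trio <- if (isTab(trio)) readTrioTable(trio)
                else readTrioVcf(trio, samples)
    if (is.character(plasma))
        plasma <- if (isTab(plasma)) readPlasmaTable(plasma)
                  else readPlasmaVcf(plasma)

    sites <- qcTrioSites(trio, control$genomicDepthFloor,
                         keep = "informative")
    qcLog <- metadata(sites)$qcLog
    logStage <- function(stage, nin, nout, reason)
        rbind(qcLog, data.frame(stage = stage, sitesIn = nin,
                                sitesOut = nout, reason = reason))

    joined <- joinPlasma(sites, plasma)
    mc <- mcols(joined)
    covered <- !is.na(mc$plasmaDP)
    qcLog <- logStage("plasma_join", length(joined), sum(covered),
                      "no plasma coverage at site")

    result <- tryCatch({
        ffSites <- selectFFSites(sites, plasma, kinds = control$ffSiteKinds)
        ff <- estimateFetalFraction(ffSites, control)

        nInformative <- sum(groupLabels(joined) %in% .S_GROUPS & covered)
        if (nInformative == 0L)
            stop("no informative loci")
        sv <- computeSValues(joined, fetalFraction(ff), control)
        call <- callFetus(sv)
        reason <- if (call@overall == "Inconclusive") {
            sides <- c(mother = sv@sMother, father = sv@sFather)
            if (anyNA(sides))
                paste0("no surviving group on the ",
                       paste(names(sides)[is.na(sides)], collapse = " and "),
                       " side")
            else "S-value in the gray zone"
        } else ""
        new("NIPDResult", ff = ff, sValues = sv, call = call,
            qcLog = qcLog, reason = reason)
    }, error = function(err)
        .inconclusiveResult(conditionMessage(err), qcLog))

    if (!is.null(reportPath))
        writeReport(result, reportPath, reportFormat)
    result
}

#' Estimate the fetal fraction from input files or objects
#'
#' Convenience wrapper: QC-filters the trio sites, selects informative
#' sites and runs [estimateFetalFraction()].
#'
#' @inheritParams runCall
#' @return A [FetalFraction-class].
#' @export
runEstimateFF <- function(trio, plasma, control = haplodoseControl(),
                          samples = c(father = "FATHER", mother = "MOTHER",
                                      proband = "PROBAND")) {
    isTab <- function(p) grepl("\\.(tsv|txt)$", p, ignore.case = TRUE)
    if (is.character(trio))
        trio <- if (isTab(trio)) readTrioTable(trio)
                else readTrioVcf(trio, samples)
    if (is.character(plasma))
        plasma <- if (isTab(plasma)) readPlasmaTable(plasma)
                  else readPlasmaVcf(plasma)
    sites <- qcTrioSites(trio, control$genomicDepthFloor,
                         keep = "informative")
    estimateFetalFraction(
        selectFFSites(sites, plasma, kinds = control$ffSiteKinds), control)
}

#' Benchmark the caller on simulated scenarios
#'
#' Simulates each scenario `replicates` times, runs the full pipeline and
#' tabulates calls against the simulated truth. Deterministic for a given
#' seed.
#'
#' @param scenarios data.frame as from [scenarioBank()]: columns `family`,
#'   `fetalFraction`, `truthClass`, `maternalInheritance`,
#'   `paternalInheritance`.
#' @param replicates simulations per scenario.
#' @param seed base RNG seed; each simulation uses a distinct derived
#'   seed.
#' @param nSnps,plasmaDepthMean,genomicDepthMean,seqErrorRate simulation
#'   parameters shared by all scenarios.
#' @param control a [haplodoseControl()] list.
#' @return list with `calls` (one row per simulation: family, replicate,
#'   truthClass, call, correct, wrongSide, sMother, sFather, eTrue, eHat)
#'   and `summary` (accuracy, wrong-side rate, inconclusive rate).
#' @export
runBenchmark <- function(scenarios = scenarioBank(), replicates = 1L,
                         seed = 1L, nSnps = 1200L, plasmaDepthMean = 3000,
                         genomicDepthMean = 2000, seqErrorRate = 0.001,
                         control = haplodoseControl()) {
    rows <- list()
    if (replicates >= 1L && nrow(scenarios) >= 1L) {
        grid <- expand.grid(s = seq_len(nrow(scenarios)),
                            r = seq_len(replicates))
        for (k in seq_len(nrow(grid))) {
            i <- grid$s[k]; r <- grid$r[k]
            cfg <- SimulationConfig(
                nSnps = nSnps, fetalFraction = scenarios$fetalFraction[i],
                plasmaDepthMean = plasmaDepthMean,
                genomicDepthMean = genomicDepthMean,
                seqErrorRate = seqErrorRate,
                maternalInheritance = scenarios$maternalInheritance[i],
                paternalInheritance = scenarios$paternalInheritance[i],
                seed = (seed + 7919L * (k - 1L)) %% .Machine$integer.max)
            fam <- simulateFamily(cfg)
            res <- runCall(fam$trio, fam$plasma, control)
            call <- res@call@overall
            truth <- scenarios$truthClass[i]
            rows[[k]] <- data.frame(
                family = scenarios$family[i], replicate = r,
                truthClass = truth, call = call,
                correct = call == truth,
                wrongSide = call != truth & call != "Inconclusive",
                sMother = if (is.null(res@sValues)) NA_real_
                          else res@sValues@sMother,
                sFather = if (is.null(res@sValues)) NA_real_
                          else res@sValues@sFather,
                eTrue = scenarios$fetalFraction[i],
                eHat = if (is.null(res@ff)) NA_real_ else res@ff@e)
        }
    }
    calls <- if (length(rows)) do.call(rbind, rows)
        else data.frame(family = character(), replicate = integer(),
                        truthClass = character(), call = character(),
                        correct = logical(), wrongSide = logical(),
                        sMother = numeric(), sFather = numeric(),
                        eTrue = numeric(), eHat = numeric())
    summary <- data.frame(
        n = nrow(calls),
        accuracy = if (nrow(calls)) mean(calls$correct) else NA_real_,
        wrongSideRate = if (nrow(calls)) mean(calls$wrongSide) else NA_real_,
        inconclusiveRate = if (nrow(calls))
            mean(calls$call == "Inconclusive") else NA_real_)
    list(calls = calls, summary = summary)
}
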