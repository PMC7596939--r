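#' Default run configuration
#'
#' All tunable thresholds of the workflow with their default values:
#' interactome gates (`alpha` 0.05, `bottom_frac` 0.10, `min_reads` 12,
#' `null_rate` `"independence"`), TF scoring window (`window` 1e5 bp),
#' differential-expression gates (`fc` 2, `de_p` 0.05), regression
#' settings (`q` 0.05, `max_exhaustive` 15, `inference` `"full"`,
#' `pseudocount` 0), consensus settings (`n_splits` 20, `consistency`
#' 0.7, `strategy` `"auto"`, `subsample_frac` 0.8, `oversample_target`
#' NULL = auto, `noise_low` 0.95, `noise_high` 1.05), and the master
#' `seed` from which all stage seeds derive.
#'
#' @param ... named overrides of the defaults.
#' @return a validated config list of class `"RunConfig"`.
#' @seealso [validateConfig()]
#' @export
metaRegulonConfig <- function(...) {
    validateConfig(list(...))
}

runConfigDefaults <- function() {
    list(alpha = 0.05, bottom_frac = 0.10, min_reads = 12L,
         null_rate = "independence",
         window = 1e5,
         fc = 2, de_p = 0.05,
         q = 0.05, max_exhaustive = 15L, inference = "full",
         pseudocount = 0,
         n_splits = 20L, consistency = 0.7, strategy = "auto",
         subsample_frac = 0.8, oversample_target = NULL,
         noise_low = 0.95, noise_high = 1.05,
         seed = 1L)
}

#' Validate and complete a run configuration
#'
#' Fills unset keys with the defaults of [metaRegulonConfig()], rejects
#' unknown keys, and reports *all* constraint violations at once.
#' `consistency = 1` is legal and corresponds to requiring detection in
#' every split.
#'
#' @param config named list of overrides (possibly empty).
#' @return the completed config list, classed `"RunConfig"`.
#' @export
validateConfig <- function(config = list()) {
    defaults <- runConfigDefaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)
    problems <- character()
    chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
    inUnit <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
    chk(inUnit(cfg$alpha) && cfg$alpha > 0, "alpha must be in (0, 1]")
    chk(inUnit(cfg$bottom_frac), "bottom_frac must be in [0, 1]")
    chk(cfg$min_reads >= 0, "min_reads must be non-negative")
    chk(identical(cfg$null_rate, "independence") ||
        identical(cfg$null_rate, "observed") ||
        (is.numeric(cfg$null_rate) && inUnit(cfg$null_rate)),
        "null_rate must be 'independence', 'observed', or a rate in [0, 1]")
    chk(cfg$window > 0, "window must be positive")
    chk(cfg$fc >= 1, "fc must be >= 1")
    chk(inUnit(cfg$de_p) && cfg$de_p > 0, "de_p must be in (0, 1]")
    chk(inUnit(cfg$q) && cfg$q > 0, "q must be in (0, 1]")
    chk(cfg$max_exhaustive >= 1, "max_exhaustive must be >= 1")
    chk(cfg$inference %in% c("full", "selected"),
        "inference must be 'full' or 'selected'")
    chk(cfg$pseudocount >= 0, "pseudocount must be non-negative")
    chk(cfg$n_splits >= 2, "n_splits must be >= 2")
    chk(inUnit(cfg$consistency), "consistency must be in [0, 1]")
    chk(cfg$strategy %in% c("auto", "subsample", "oversample"),
        "strategy must be auto/subsample/oversample")
    chk(inUnit(cfg$subsample_frac) && cfg$subsample_frac > 0,
        "subsample_frac must be in (0, 1]")
    chk(cfg$noise_low <= cfg$noise_high, "noise_low must be <= noise_high")
    chk(cfg$noise_low > 0, "noise_low must be positive")
    chk(length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
        "seed must be a single integer")
    if (length(problems))
        stop("invalid configuration:\n  - ",
             paste(problems, collapse = "\n  - "))
    structure(cfg, class = c("RunConfig", "list"))
}

#' Run the full workflow for one condition
#'
#' Orchestrates the end-to-end analysis on in-memory inputs:
#' interactome filtering and miRNA scoring (when `sites`/`singles` are
#' given), TF scoring from peaks/TSS (when given), competitive score
#' normalization, differential-expression detection, the per-gene
#' meta-regression, and consensus calling over randomized splits. A
#' precomputed `rsTable` bypasses the scoring stages. Every random stage
#' derives its seed from `config$seed` by stage-name hashing, so a rerun
#' with identical inputs is byte-identical.
#'
#' @param dataset a [ConditionDataset-class].
#' @param sites,singles interactome tables (see [readBindingSites()]),
#'   or `NULL`.
#' @param peaks,tss TF peak / TSS tables (see [readTfPeaks()]), or
#'   `NULL`.
#' @param rsTable optional precomputed [RegulatoryScoreTable-class].
#' @param config a config from [metaRegulonConfig()].
#' @param outDir optional directory; when set, writes
#'   `interactions.tsv` (retained consensus pairs), `consensus.tsv`
#'   (full consensus table), `fits.tsv` (original-dataset calls),
#'   `de_genes.tsv`, `de_mirnas.tsv`, `scores.tsv` and `manifest.txt`,
#'   all deterministically formatted.
#' @return list with elements `rsTable`, `deGenes`, `deMirnas`, `fits`,
#'   `consensus`, `interactions` (an [interactionSet()] of retained
#'   pairs) and `manifest`.
#' @export
runCondition <- function(dataset, sites = NULL, singles = NULL,
                         peaks = NULL, tss = NULL, rsTable = NULL,
                         config = metaRegulonConfig(), outDir = NULL) {
    config <- validateConfig(unclass(config))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed for condition '",
                 conditionId(dataset), "': ", conditionMessage(e),
                 call. = FALSE))
    }
    if (is.null(rsTable)) {
        raw <- list()
        if (!is.null(sites)) {
            filt <- stage("interactome", scoreInteractome(
                sites, singles, alpha = config$alpha,
                bottomFrac = config$bottom_frac,
                minReads = config$min_reads,
                nullRate = if (identical(config$null_rate, "observed")) NULL
                           else config$null_rate))
            raw$mirna <- stage("mirna_scores",
                               mirnaScores(filt$sites, filt$abundance))
        }
        if (!is.null(peaks))
            raw$tf <- stage("tf_scores",
                            peaksToTfScores(peaks, tss,
                                            window = config$window))
        if (!length(raw))
            stop("stage 'scores' failed: no interactome, peaks or rsTable given")
        rsTable <- stage("normalize",
                         normalizeRS(do.call(rbind,
                                             unname(lapply(raw, `[`,
                                                    c("regulator_id",
                                                      "regulator_kind",
                                                      "gene_id", "rs_raw"))))))
    }
    deGenes <- stage("de_genes",
                     differentialEntities(dataset, "gene",
                                          fcThreshold = config$fc,
                                          pThreshold = config$de_p))
    deMirnas <- stage("de_mirnas",
                      differentialEntities(dataset, "mirna",
                                           fcThreshold = config$fc,
                                           pThreshold = config$de_p))
    consensus <- stage("consensus", consensusCondition(
        dataset, rsTable,
        nSplits = config$n_splits, strategy = config$strategy,
        threshold = config$consistency, frac = config$subsample_frac,
        targetN = config$oversample_target,
        low = config$noise_low, high = config$noise_high,
        seed = childSeed(config$seed, "consensus"),
        qThreshold = config$q, maxExhaustive = config$max_exhaustive,
        inference = config$inference, pseudocount = config$pseudocount))
    fits <- attr(consensus, "wOrg")
    retained <- consensus[consensus$retained, , drop = FALSE]
    interactions <- interactionSet(retained, conditionId(dataset))
    manifest <- list(
        package = as.character(utils::packageVersion("metaRegulon")),
        condition = conditionId(dataset),
        config = unclass(config),
        n_samples = length(sampleLabels(dataset)),
        n_disease = length(diseaseSamples(dataset)),
        n_genes = nrow(exprMatrix(dataset, "gene")),
        n_scored_pairs = nrow(scores(rsTable)),
        n_calls_original = nrow(fits),
        n_retained = nrow(retained))
    out <- list(rsTable = rsTable, deGenes = deGenes, deMirnas = deMirnas,
                fits = fits, consensus = consensus,
                interactions = interactions, manifest = manifest)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeRegulatoryScores(rsTable, file.path(outDir, "scores.tsv"))
        writeTsv(deGenes, file.path(outDir, "de_genes.tsv"))
        writeTsv(deMirnas, file.path(outDir, "de_mirnas.tsv"))
        writeTsv(fits, file.path(outDir, "fits.tsv"))
        writeTsv(consensus, file.path(outDir, "consensus.tsv"))
        writeTsv(as.data.frame(interactions),
                 file.path(outDir, "interactions.tsv"))
        files <- list.files(outDir, pattern = "\\.tsv$", full.names = TRUE)
        manifest$md5 <- tools::md5sum(sort(files))
        writeLines(c(
            paste0("metaRegulon ", manifest$package),
            paste0("condition: ", manifest$condition),
            paste0("seed: ", config$seed),
            vapply(names(manifest$md5), function(f)
                paste0("md5 ", basename(f), ": ", manifest$md5[[f]]),
                character(1))),
            file.path(outDir, "manifest.txt"))
        out$manifest <- manifest
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
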