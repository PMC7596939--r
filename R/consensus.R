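#' Generate randomized datasets for consensus calling
#'
#' Produces `nSplits` perturbed copies of a condition dataset. Strategy
#' `"subsample"` keeps a without-replacement fraction `frac` of the
#' disease samples (all controls retained); `"oversample"` augments the
#' disease group to `targetN` samples with [oversampleDataset()] under a
#' distinct child seed per split. `"auto"` picks `"oversample"` for
#' cohorts with fewer than 30 disease samples (the small-cohort regime)
#' and `"subsample"` otherwise. The whole family is a deterministic
#' function of the master seed.
#'
#' @param dataset a [ConditionDataset-class].
#' @param nSplits number of randomized datasets (>= 2).
#' @param strategy `"auto"`, `"subsample"` or `"oversample"`.
#' @param frac subsample fraction of disease samples.
#' @param targetN oversample target disease count; default doubles the
#'   cohort (at least 30).
#' @param low,high oversampling noise bounds.
#' @param seed master seed.
#' @return list of [ConditionDataset-class] objects.
#' @export
generateSplits <- function(dataset, nSplits = 20L,
                           strategy = c("auto", "subsample", "oversample"),
                           frac = 0.8, targetN = NULL,
                           low = 0.95, high = 1.05, seed = 1L) {
    strategy <- match.arg(strategy)
    if (nSplits < 2L) stop("nSplits must be >= 2")
    dis <- diseaseSamples(dataset)
    if (strategy == "auto")
        strategy <- if (length(dis) < 30L) "oversample" else "subsample"
    if (strategy == "subsample") {
        nKeep <- floor(frac * length(dis))
        if (nKeep < 4L)
            stop("subsampling would leave fewer than 4 disease samples")
        lapply(seq_len(nSplits), function(i) {
            keep <- withSeed(childSeed(seed, paste0("subsample", i)),
                             sort(sample(dis, nKeep)))
            subsetSamples(dataset, c(controlSamples(dataset), keep))
        })
    } else {
        if (is.null(targetN)) targetN <- max(30L, 2L * length(dis))
        lapply(seq_len(nSplits), function(i) {
            oversampleDataset(dataset, targetN, low = low, high = high,
                              seed = childSeed(seed, paste0("oversample", i)))
        })
    }
}

# Restrict a dataset to a sample subset (keeping matrix column order).
subsetSamples <- function(dataset, samples) {
    keep <- colnames(dataset@geneExpr) %in% samples
    samp <- colnames(dataset@geneExpr)[keep]
    labels <- dataset@labels[samp]
    dis <- samp[labels == "disease"]
    cut <- function(m) if (is.null(m)) NULL else m[, colnames(m) %in% dis, drop = FALSE]
    new("ConditionDataset",
        conditionId = dataset@conditionId,
        geneExpr = dataset@geneExpr[, samp, drop = FALSE],
        mirnaExpr = dataset@mirnaExpr[, samp, drop = FALSE],
        tfExpr = dataset@tfExpr[, samp, drop = FALSE],
        labels = labels,
        cnvChange = cut(dataset@cnvChange),
        methChange = cut(dataset@methChange))
}

#' Consensus regulator calls across randomized splits
#'
#' For every (gene, regulator) pair seen in the original fit or any
#' split, the consistency is the proportion of splits in which the
#' pair's regression coefficient is nonzero (i.e. the regulator was in
#' the split's selected model). A pair is retained when it is present in
#' the original-fit call set `wOrg` *and* its consistency reaches
#' `threshold` (inclusive; `threshold = 1` recovers the strict
#' detected-in-all-splits reading). `beta_summary` is the median of the
#' pair's nonzero split coefficients.
#'
#' @param wOrg original-dataset calls: data.frame with `gene_id`,
#'   `regulator_id`, `regulator_kind`, `beta` (e.g. from
#'   [fitCondition()]).
#' @param splitResults list of per-split call data.frames with `gene_id`,
#'   `regulator_id`, `beta` (the split's nonzero coefficients).
#' @param threshold consistency threshold in \[0, 1\].
#' @return data.frame `gene_id`, `regulator_id`, `regulator_kind`,
#'   `beta_original`, `beta_summary`, `consistency`, `in_original`,
#'   `retained`, ordered by (gene_id, regulator_id).
#' @export
consensusRegulators <- function(wOrg, splitResults, threshold = 0.7) {
    if (!length(splitResults)) stop("splitResults must be non-empty")
    nSplits <- length(splitResults)
    keyOf <- function(df) paste(df$gene_id, df$regulator_id, sep = "\r")
    orgKey <- keyOf(wOrg)
    splitKeys <- lapply(splitResults, keyOf)
    allKeys <- unique(c(orgKey, unlist(splitKeys)))
    if (!length(allKeys))
        return(data.frame(gene_id = character(), regulator_id = character(),
                          regulator_kind = character(),
                          beta_original = numeric(), beta_summary = numeric(),
                          consistency = numeric(), in_original = logical(),
                          retained = logical()))
    hits <- matrix(FALSE, length(allKeys), nSplits)
    betas <- matrix(NA_real_, length(allKeys), nSplits)
    for (i in seq_len(nSplits)) {
        m <- match(allKeys, splitKeys[[i]])
        hits[, i] <- !is.na(m)
        betas[, i] <- splitResults[[i]]$beta[m]
    }
    consistency <- rowMeans(hits)
    betaSummary <- apply(betas, 1L, function(b) {
        b <- b[!is.na(b) & b != 0]
        if (length(b)) stats::median(b) else NA_real_
    })
    parts <- strsplit(allKeys, "\r", fixed = TRUE)
    inOrg <- allKeys %in% orgKey
    mo <- match(allKeys, orgKey)
    kinds <- wOrg$regulator_kind[mo]
    if (is.null(kinds)) kinds <- rep(NA_character_, length(allKeys))
    out <- data.frame(
        gene_id = vapply(parts, `[`, character(1), 1L),
        regulator_id = vapply(parts, `[`, character(1), 2L),
        regulator_kind = kinds,
        beta_original = wOrg$beta[mo],
        beta_summary = betaSummary,
        consistency = consistency,
        in_original = inOrg,
        retained = inOrg & consistency >= threshold,
        stringsAsFactors = FALSE)
    out <- out[order(out$gene_id, out$regulator_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Run the consensus procedure for one condition
#'
#' Fits the meta-regression on the original dataset, generates the
#' randomized splits, refits on each, and summarizes with
#' [consensusRegulators()]. Per-split detection uses the model's nonzero
#' coefficients (the Cp selection); the original-dataset call set
#' additionally applies the q-value gate, matching the roles of the two
#' in consensus calling.
#'
#' @inheritParams generateSplits
#' @inheritParams fitCondition
#' @param threshold consistency threshold.
#' @return the [consensusRegulators()] data.frame; the original fit is
#'   attached as attribute `wOrg`.
#' @export
consensusCondition <- function(dataset, rsTable, nSplits = 20L,
                               strategy = c("auto", "subsample", "oversample"),
                               threshold = 0.7, frac = 0.8, targetN = NULL,
                               low = 0.95, high = 1.05, seed = 1L,
                               qThreshold = 0.05, maxExhaustive = 15L,
                               inference = c("full", "selected"),
                               pseudocount = 0) {
    strategy <- match.arg(strategy)
    inference <- match.arg(inference)
    wOrg <- fitCondition(dataset, rsTable, qThreshold = qThreshold,
                         maxExhaustive = maxExhaustive,
                         inference = inference, pseudocount = pseudocount)
    splits <- generateSplits(dataset, nSplits = nSplits, strategy = strategy,
                             frac = frac, targetN = targetN,
                             low = low, high = high, seed = seed)
    splitCalls <- lapply(splits, function(d) {
        fit <- fitCondition(d, rsTable, qThreshold = qThreshold,
                            maxExhaustive = maxExhaustive,
                            inference = inference, pseudocount = pseudocount)
        # nonzero coefficients of the split model = Cp-selected pairs
        attr(fit, "cpSelected")
    })
    out <- consensusRegulators(wOrg, splitCalls, threshold = threshold)
    attr(out, "wOrg") <- wOrg
    out
}
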