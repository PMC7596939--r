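#' Per-sample log2 expression change versus the control mean
#'
#' For every entity j and disease sample s,
#' \deqn{\Delta_{js} = \log_2\frac{x_{js} + \epsilon}{\bar{x}_{j,ctrl} + \epsilon}}
#' where the denominator is the mean over control samples. With the
#' default pseudocount 0 (appropriate for microarray-scale values),
#' entities whose control mean is zero cannot be ratioed and are dropped;
#' their ids are recorded in the `"excluded"` attribute. For count-scale
#' data set `pseudocount = 1`.
#'
#' @param dataset a [ConditionDataset-class].
#' @param kind which entity matrix to transform: `"gene"`, `"mirna"`, `"tf"`.
#' @param pseudocount value added to numerator and denominator.
#' @return entities x disease-samples matrix of finite log2 changes, with
#'   attribute `excluded` naming entities removed by the zero-control rule.
#' @export
deltaExpression <- function(dataset, kind = c("gene", "mirna", "tf"),
                            pseudocount = 0) {
    kind <- match.arg(kind)
    m <- exprMatrix(dataset, kind)
    ctrl <- controlSamples(dataset)
    dis <- diseaseSamples(dataset)
    if (length(ctrl) == 0L) stop("no control samples in dataset")
    ctrlMean <- rowMeans(m[, ctrl, drop = FALSE])
    denom <- ctrlMean + pseudocount
    bad <- denom <= 0
    delta <- log2(sweep(m[!bad, dis, drop = FALSE] + pseudocount,
                        1L, denom[!bad], `/`))
    if (any(!is.finite(delta)))
        stop("non-finite log2 changes; consider a positive pseudocount")
    structure(delta, excluded = rownames(m)[bad])
}

#' Differentially expressed entities between disease and control
#'
#' Fold change is the ratio of group means (disease over control); an
#' entity is differentially expressed when `max(FC, 1/FC) >= fcThreshold`
#' and the two-sample t-test p-value is below `pThreshold`. The fold
#' change gate is hard: a tiny p-value cannot rescue FC below threshold.
#'
#' @param dataset a [ConditionDataset-class] with at least two samples
#'   per group.
#' @param kind entity matrix to test.
#' @param fcThreshold fold-change gate (applied to whichever of FC, 1/FC
#'   exceeds 1).
#' @param pThreshold t-test p-value gate.
#' @param var.equal `FALSE` (default) for Welch's t-test, `TRUE` for the
#'   pooled-variance Student's t-test.
#' @return data.frame `entity_id`, `fc`, `pvalue`, `direction`
#'   (`up`/`down`), `de` (logical). Entities with zero variance in both
#'   groups have no defined p-value and are excluded with a warning.
#' @export
differentialEntities <- function(dataset, kind = c("gene", "mirna", "tf"),
                                 fcThreshold = 2, pThreshold = 0.05,
                                 var.equal = FALSE) {
    kind <- match.arg(kind)
    m <- exprMatrix(dataset, kind)
    dis <- m[, diseaseSamples(dataset), drop = FALSE]
    ctl <- m[, controlSamples(dataset), drop = FALSE]
    if (ncol(dis) < 2L || ncol(ctl) < 2L)
        stop("need at least two samples per group for the t-test")
    degenerate <- apply(dis, 1L, stats::var) == 0 &
                  apply(ctl, 1L, stats::var) == 0
    if (any(degenerate))
        warning(sum(degenerate),
                " entit(ies) with zero variance in both groups excluded")
    keep <- which(!degenerate)
    fc <- rowMeans(dis[keep, , drop = FALSE]) /
          rowMeans(ctl[keep, , drop = FALSE])
    pv <- vapply(keep, function(i) {
        stats::t.test(dis[i, ], ctl[i, ], var.equal = var.equal)$p.value
    }, numeric(1))
    out <- data.frame(
        entity_id = rownames(m)[keep],
        fc = as.numeric(fc),
        pvalue = pv,
        direction = ifelse(fc >= 1, "up", "down"),
        stringsAsFactors = FALSE)
    out$de <- pmax(out$fc, 1 / out$fc) >= fcThreshold & out$pvalue < pThreshold
    rownames(out) <- NULL
    out
}

#' Augment a small cohort by multiplicative over-sampling
#'
#' Generates synthetic disease samples until the disease group reaches
#' `targetN`: each new sample is an existing disease sample (chosen
#' uniformly with replacement) multiplied elementwise by a fresh variation
#' vector with i.i.d. Uniform(`low`, `high`) entries spanning the whole
#' profile (genes, miRNAs and TFs). The originals are retained, so sample
#' ranks within each copy are preserved up to the noise band and
#' non-negative inputs stay non-negative. CNV/methylation columns of a
#' synthetic sample are copied from its source sample.
#'
#' The default band (0.95, 1.05) is the symmetric small-variation reading;
#' set `high = 1` for the one-sided Uniform(0.95, 1) alternative.
#'
#' @param dataset a [ConditionDataset-class].
#' @param targetN desired number of disease samples (>= current count).
#' @param low,high bounds of the multiplicative noise, `low <= high`.
#' @param seed integer seed; the augmentation is a pure function of
#'   (dataset, targetN, low, high, seed).
#' @return an augmented [ConditionDataset-class]; synthetic samples are
#'   named `<source>_os<i>`.
#' @export
oversampleDataset <- function(dataset, targetN, low = 0.95, high = 1.05,
                              seed = 1L) {
    if (low > high) stop("'low' must be <= 'high'")
    dis <- diseaseSamples(dataset)
    nNew <- targetN - length(dis)
    if (nNew < 0L) stop("targetN must be >= current disease sample count")
    if (nNew == 0L) return(dataset)
    nG <- nrow(dataset@geneExpr); nM <- nrow(dataset@mirnaExpr)
    nT <- nrow(dataset@tfExpr)
    withSeed(seed, {
        src <- sample(dis, nNew, replace = TRUE)
        V <- matrix(stats::runif(nNew * (nG + nM + nT), low, high),
                    ncol = nNew)
    })
    newNames <- paste0(src, "_os", seq_len(nNew))
    grow <- function(m, rows) {
        add <- m[, src, drop = FALSE] * V[rows, , drop = FALSE]
        colnames(add) <- newNames
        cbind(m, add)
    }
    geneExpr <- grow(dataset@geneExpr, seq_len(nG))
    mirnaExpr <- grow(dataset@mirnaExpr, nG + seq_len(nM))
    tfExpr <- grow(dataset@tfExpr, nG + nM + seq_len(nT))
    labels <- factor(c(as.character(dataset@labels),
                       rep("disease", nNew)),
                     levels = levels(dataset@labels))
    names(labels) <- colnames(geneExpr)
    copyBg <- function(m) {
        if (is.null(m)) return(NULL)
        add <- m[, src, drop = FALSE]
        colnames(add) <- newNames
        cbind(m, add)
    }
    new("ConditionDataset",
        conditionId = dataset@conditionId,
        geneExpr = geneExpr, mirnaExpr = mirnaExpr, tfExpr = tfExpr,
        labels = labels,
        cnvChange = copyBg(dataset@cnvChange),
        methChange = copyBg(dataset@methChange))
}

#' Read / write a ConditionDataset from TSV files
#'
#' Expression matrices are headered TSVs whose first column is
#' `entity_id` and remaining columns are sample ids; the label file maps
#' `sample_id` to `group` (`disease`/`control`). CNV and methylation
#' tables use the same layout restricted to the disease samples.
#'
#' @param dir directory holding `genes.tsv`, `mirnas.tsv`, `tfs.tsv`,
#'   `labels.tsv`, and optionally `cnv.tsv` and `meth.tsv`.
#' @param conditionId condition identifier for the object.
#' @export
readConditionDataset <- function(dir, conditionId = basename(dir)) {
    readMat <- function(f) {
        df <- readTsv(file.path(dir, f))
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        m
    }
    lab <- readTsv(file.path(dir, "labels.tsv"))
    geneExpr <- readMat("genes.tsv")
    labels <- factor(lab$group[match(colnames(geneExpr), lab$sample_id)],
                     levels = c("control", "disease"))
    names(labels) <- colnames(geneExpr)
    cnv <- if (file.exists(file.path(dir, "cnv.tsv"))) readMat("cnv.tsv")
    meth <- if (file.exists(file.path(dir, "meth.tsv"))) readMat("meth.tsv")
    new("ConditionDataset", conditionId = conditionId,
        geneExpr = geneExpr, mirnaExpr = readMat("mirnas.tsv"),
        tfExpr = readMat("tfs.tsv"), labels = labels,
        cnvChange = cnv, methChange = meth)
}

#' @rdname readConditionDataset
#' @param dataset a [ConditionDataset-class] to write.
#' @export
writeConditionDataset <- function(dataset, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeMat <- function(m, f) {
        df <- data.frame(entity_id = rownames(m), m, check.names = FALSE)
        writeTsv(df, file.path(dir, f))
    }
    writeMat(dataset@geneExpr, "genes.tsv")
    writeMat(dataset@mirnaExpr, "mirnas.tsv")
    writeMat(dataset@tfExpr, "tfs.tsv")
    writeTsv(data.frame(sample_id = names(dataset@labels),
                        group = as.character(dataset@labels)),
             file.path(dir, "labels.tsv"))
    if (!is.null(dataset@cnvChange)) writeMat(dataset@cnvChange, "cnv.tsv")
    if (!is.null(dataset@methChange)) writeMat(dataset@methChange, "meth.tsv")
    invisible(dir)
}
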