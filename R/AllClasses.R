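#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Chimeric/single read abundance bookkeeping for a CLASH interactome
#'
#' Holds the read totals that parameterize the binding-probability model:
#' the grand total of chimeric reads over all interactions, and per-entity
#' chimeric and single-read totals for every miRNA and mRNA.
#'
#' @slot cAll total chimeric reads over all binding sites.
#' @slot cMirna,mMirna named numeric vectors: chimeric and single-read totals
#'   per miRNA.
#' @slot cMrna,mMrna named numeric vectors: chimeric and single-read totals
#'   per mRNA.
#'
#' @details Validity enforces non-negative integer counts and the
#'   bookkeeping identities \eqn{\sum_i C_i = C_{all}} and
#'   \eqn{\sum_j C_j = C_{all}}.
#'
#' @seealso [abundanceTable()] which constructs one from a binding-site
#'   table and single-read counts.
#' @export
setClass("AbundanceTable",
    representation(
        cAll   = "numeric",
        cMirna = "numeric",
        mMirna = "numeric",
        cMrna  = "numeric",
        mMrna  = "numeric"
    )
)

setValidity("AbundanceTable", function(object) {
    msg <- character()
    all_counts <- c(object@cAll, object@cMirna, object@mMirna,
                    object@cMrna, object@mMrna)
    if (any(all_counts < 0) || any(all_counts != round(all_counts)))
        msg <- c(msg, "all counts must be non-negative integers")
    if (length(object@cAll) != 1L)
        msg <- c(msg, "cAll must be a single number")
    if (is.null(names(object@cMirna)) || is.null(names(object@cMrna)))
        msg <- c(msg, "per-entity counts must be named")
    if (!isTRUE(all.equal(sum(object@cMirna), object@cAll)))
        msg <- c(msg, "sum of per-miRNA chimeric counts must equal cAll")
    if (!isTRUE(all.equal(sum(object@cMrna), object@cAll)))
        msg <- c(msg, "sum of per-mRNA chimeric counts must equal cAll")
    if (!identical(sort(names(object@cMirna)), sort(names(object@mMirna))))
        msg <- c(msg, "cMirna and mMirna must cover the same miRNAs")
    if (!identical(sort(names(object@cMrna)), sort(names(object@mMrna))))
        msg <- c(msg, "cMrna and mMrna must cover the same mRNAs")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AbundanceTable", function(object) {
    cat("AbundanceTable:", object@cAll, "chimeric reads,",
        length(object@cMirna), "miRNAs,", length(object@cMrna), "mRNAs\n")
})

#' Competition-normalized regulatory scores
#'
#' A table of regulatory scores per (regulator, gene) pair. The raw score
#' RS quantifies regulatory potential (binding probability weighted by
#' duplex stability for miRNAs; noisy-OR of exponential TSS-distance decays
#' for TFs); the normalized score RS' divides each regulator's raw scores
#' by their sum over all of that regulator's targets, so a regulator's
#' total influence is partitioned competitively across its targets.
#'
#' @slot scores data.frame with columns `regulator_id`, `regulator_kind`
#'   (`"mirna"` or `"tf"`), `gene_id`, `rs_raw`, `rs_norm`.
#'
#' @details Validity enforces non-negative `rs_norm`, raw TF scores in
#'   \[0, 1), and per-regulator `rs_norm` sums of 1 (tolerance 1e-9).
#' @export
setClass("RegulatoryScoreTable",
    representation(scores = "data.frame")
)

setValidity("RegulatoryScoreTable", function(object) {
    sc <- object@scores
    need <- c("regulator_id", "regulator_kind", "gene_id", "rs_raw", "rs_norm")
    if (!all(need %in% names(sc)))
        return(paste("scores must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (!all(sc$regulator_kind %in% c("mirna", "tf")))
        msg <- c(msg, "regulator_kind must be 'mirna' or 'tf'")
    if (any(sc$rs_norm < 0))
        msg <- c(msg, "rs_norm must be non-negative")
    if (any(sc$rs_raw < 0))
        msg <- c(msg, "rs_raw must be non-negative")
    tf <- sc$regulator_kind == "tf"
    if (any(sc$rs_raw[tf] >= 1))
        msg <- c(msg, "TF rs_raw must lie in [0, 1)")
    if (anyDuplicated(paste(sc$regulator_id, sc$gene_id)))
        msg <- c(msg, "duplicate (regulator_id, gene_id) entries")
    if (nrow(sc)) {
        sums <- tapply(sc$rs_norm, sc$regulator_id, sum)
        if (any(abs(sums - 1) > 1e-9))
            msg <- c(msg, "per-regulator rs_norm must sum to 1 (tol 1e-9)")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "RegulatoryScoreTable", function(object) {
    sc <- object@scores
    cat("RegulatoryScoreTable:", nrow(sc), "pairs (",
        sum(sc$regulator_kind == "tf"), "TF,",
        sum(sc$regulator_kind == "mirna"), "miRNA ),",
        length(unique(sc$regulator_id)), "regulators,",
        length(unique(sc$gene_id)), "genes\n")
})

#' Multi-omics expression dataset for one disease condition
#'
#' Bundles the entities-by-samples expression matrices for genes, miRNAs
#' and TFs together with disease/control sample labels and, optionally,
#' per-gene copy-number and DNA-methylation change matrices over the
#' disease samples.
#'
#' @slot conditionId single condition identifier.
#' @slot geneExpr,mirnaExpr,tfExpr numeric matrices (entities x samples)
#'   sharing identical sample columns; non-negative expression values.
#' @slot labels factor with levels `control`, `disease`, named by sample
#'   in the matrices' column order.
#' @slot cnvChange,methChange genes x disease-samples matrices of change
#'   values versus normal, or `NULL` when unavailable (e.g. the obesity
#'   cohorts).
#' @export
setClass("ConditionDataset",
    representation(
        conditionId = "character",
        geneExpr    = "matrix",
        mirnaExpr   = "matrix",
        tfExpr      = "matrix",
        labels      = "factor",
        cnvChange   = "matrixOrNULL",
        methChange  = "matrixOrNULL"
    ),
    prototype(cnvChange = NULL, methChange = NULL)
)

setValidity("ConditionDataset", function(object) {
    msg <- character()
    samples <- colnames(object@geneExpr)
    if (is.null(samples))
        return("geneExpr must have sample column names")
    for (nm in c("mirnaExpr", "tfExpr")) {
        m <- slot(object, nm)
        if (!identical(colnames(m), samples))
            msg <- c(msg, sprintf("%s columns must match geneExpr columns", nm))
    }
    if (!identical(names(object@labels), samples))
        msg <- c(msg, "labels must be named by sample, in column order")
    if (!all(levels(object@labels) %in% c("control", "disease")))
        msg <- c(msg, "label levels must be 'control'/'disease'")
    if (sum(object@labels == "control") < 1L ||
        sum(object@labels == "disease") < 1L)
        msg <- c(msg, "need at least one control and one disease sample")
    dis <- samples[object@labels == "disease"]
    for (nm in c("cnvChange", "methChange")) {
        m <- slot(object, nm)
        if (!is.null(m) && !identical(colnames(m), dis))
            msg <- c(msg, sprintf("%s columns must be exactly the disease samples", nm))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ConditionDataset", function(object) {
    cat("ConditionDataset '", object@conditionId, "': ",
        nrow(object@geneExpr), " genes, ",
        nrow(object@mirnaExpr), " miRNAs, ",
        nrow(object@tfExpr), " TFs; ",
        sum(object@labels == "disease"), " disease / ",
        sum(object@labels == "control"), " control samples",
        if (!is.null(object@cnvChange)) "; CNV+methylation background" else "",
        "\n", sep = "")
})

#' Per-gene meta-regression problem
#'
#' The assembled design for one target gene: response `Y` of per-sample
#' log2 expression changes, background block `X1` (CNV and methylation
#' change; zero columns when unavailable), regulator-change matrix `P`,
#' the gene's regulatory-score vector `rsVec` (RS'), and the score-weighted
#' design `X2` with `X2[s, r] = P[s, r] * rsVec[r]`.
#'
#' @slot geneId target gene id.
#' @slot Y numeric response vector (length S).
#' @slot X1 S x k background matrix (k = 2 or 0).
#' @slot P S x R regulator expression-change matrix, columns ordered TFs
#'   first then miRNAs.
#' @slot rsVec length-R positive RS' weights, matching `P` columns.
#' @slot regulatorIds,regulatorKinds length-R ids and kinds of the columns.
#' @slot X2 the row-wise product of `P` and `rsVec`.
#' @export
setClass("GeneRegressionProblem",
    representation(
        geneId         = "character",
        Y              = "numeric",
        X1             = "matrix",
        P              = "matrix",
        rsVec          = "numeric",
        regulatorIds   = "character",
        regulatorKinds = "character",
        X2             = "matrix"
    )
)

setValidity("GeneRegressionProblem", function(object) {
    msg <- character()
    S <- length(object@Y)
    R <- length(object@rsVec)
    if (nrow(object@P) != S || nrow(object@X2) != S)
        msg <- c(msg, "P and X2 must have one row per sample")
    if (ncol(object@X1) > 0L && nrow(object@X1) != S)
        msg <- c(msg, "X1 rows must match Y length")
    if (ncol(object@P) != R || ncol(object@X2) != R ||
        length(object@regulatorIds) != R || length(object@regulatorKinds) != R)
        msg <- c(msg, "regulator dimensions disagree")
    if (any(object@rsVec <= 0))
        msg <- c(msg, "rsVec entries must be positive")
    if (R > 0L && S > 0L) {
        expect <- sweep(object@P, 2L, object@rsVec, `*`)
        if (max(abs(expect - object@X2)) > 1e-12 * max(1, max(abs(expect))))
            msg <- c(msg, "X2 must equal P scaled column-wise by rsVec")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneRegressionProblem", function(object) {
    cat("GeneRegressionProblem for '", object@geneId, "': S=",
        length(object@Y), ", R=", length(object@rsVec),
        " (", sum(object@regulatorKinds == "tf"), " TF, ",
        sum(object@regulatorKinds == "mirna"), " miRNA), background cols=",
        ncol(object@X1), "\n", sep = "")
})

#' Ground-truth regulatory network for simulation
#'
#' The generative model behind [simulateCondition()]: a normalized
#' regulatory-score table, sparse true regulator coefficients beta2 per
#' (regulator, gene), per-gene background coefficients beta1 for CNV and
#' methylation effects, and the Gaussian noise standard deviation sigma.
#'
#' @slot rsTable a [RegulatoryScoreTable-class] of candidate regulators
#'   per gene.
#' @slot beta2 data.frame `regulator_id`, `gene_id`, `beta` listing the
#'   nonzero true coefficients.
#' @slot beta1 genes x 2 matrix of background coefficients (CNV,
#'   methylation), all zero when no background is simulated.
#' @slot sigma Gaussian noise sd on the gene log2-change scale.
#' @slot genes,tfs,mirnas entity id vectors.
#' @export
setClass("GroundTruthNetwork",
    representation(
        rsTable = "RegulatoryScoreTable",
        beta2   = "data.frame",
        beta1   = "matrix",
        sigma   = "numeric",
        genes   = "character",
        tfs     = "character",
        mirnas  = "character"
    )
)

setValidity("GroundTruthNetwork", function(object) {
    msg <- character()
    if (!all(c("regulator_id", "gene_id", "beta") %in% names(object@beta2)))
        msg <- c(msg, "beta2 needs columns regulator_id, gene_id, beta")
    if (!all(object@beta2$gene_id %in% object@genes))
        msg <- c(msg, "beta2 gene ids outside gene universe")
    sc <- object@rsTable@scores
    key_truth <- paste(object@beta2$regulator_id, object@beta2$gene_id)
    key_rs <- paste(sc$regulator_id, sc$gene_id)
    if (!all(key_truth %in% key_rs))
        msg <- c(msg, "every true pair must be a scored candidate pair")
    if (object@sigma < 0)
        msg <- c(msg, "sigma must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthNetwork", function(object) {
    cat("GroundTruthNetwork:", length(object@genes), "genes,",
        length(object@tfs), "TFs,", length(object@mirnas), "miRNAs;",
        nrow(object@beta2), "true regulator-gene effects; sigma =",
        object@sigma, "\n")
})

#' @describeIn RegulatoryScoreTable-class extract the score data.frame.
#' @param x,object a `RegulatoryScoreTable`.
#' @export
scores <- function(x) {
    stopifnot(is(x, "RegulatoryScoreTable"))
    x@scores
}

#' Accessors for ConditionDataset
#'
#' @param x a [ConditionDataset-class].
#' @param kind one of `"gene"`, `"mirna"`, `"tf"`.
#' @return `exprMatrix` returns the requested entities-by-samples matrix;
#'   `sampleLabels` the named label factor; `diseaseSamples` /
#'   `controlSamples` the sample id vectors; `conditionId` the id string.
#' @export
exprMatrix <- function(x, kind = c("gene", "mirna", "tf")) {
    stopifnot(is(x, "ConditionDataset"))
    kind <- match.arg(kind)
    switch(kind, gene = x@geneExpr, mirna = x@mirnaExpr, tf = x@tfExpr)
}

#' @rdname exprMatrix
#' @export
sampleLabels <- function(x) {
    stopifnot(is(x, "ConditionDataset"))
    x@labels
}

#' @rdname exprMatrix
#' @export
diseaseSamples <- function(x) names(sampleLabels(x))[sampleLabels(x) == "disease"]

#' @rdname exprMatrix
#' @export
controlSamples <- function(x) names(sampleLabels(x))[sampleLabels(x) == "control"]

#' @rdname exprMatrix
#' @export
conditionId <- function(x) {
    stopifnot(is(x, "ConditionDataset"))
    x@conditionId
}
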