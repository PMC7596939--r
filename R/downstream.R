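#' Construct an interaction set
#'
#' A per-condition set of (regulator, gene) interactions. Interaction
#' identity is the id pair alone; coefficients and binding sites play no
#' role in set comparisons.
#'
#' @param pairs data.frame with columns `regulator_id`, `gene_id`.
#' @param conditionId condition label.
#' @param associationGroup optional condition metadata (`"SAG"`, `"WAG"`
#'   or `"none"`), carried along for reporting only.
#' @return data.frame of the unique pairs with attributes `conditionId`
#'   and `associationGroup`.
#' @export
interactionSet <- function(pairs, conditionId = "condition",
                           associationGroup = "none") {
    stopifnot(all(c("regulator_id", "gene_id") %in% names(pairs)))
    out <- unique(pairs[, c("regulator_id", "gene_id"), drop = FALSE])
    out <- out[order(out$regulator_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "conditionId") <- conditionId
    attr(out, "associationGroup") <- match.arg(associationGroup,
                                               c("none", "SAG", "WAG"))
    out
}

pairKeys <- function(set) paste(set$regulator_id, set$gene_id, sep = "\r")

#' Overlap statistics between two interaction sets
#'
#' Reports, for interactions, regulated genes and active regulators, the
#' intersection count with `other` and the percentage of the *reference*
#' set covered (to one decimal). An empty reference yields `NA`
#' percentages, not zero.
#'
#' @param reference,other interaction sets from [interactionSet()].
#' @return data.frame `level` (`interactions`/`genes`/`regulators`),
#'   `n_reference`, `n_overlap`, `pct_of_reference`.
#' @export
overlapStats <- function(reference, other) {
    one <- function(refIds, otherIds) {
        n <- length(refIds)
        k <- length(intersect(refIds, otherIds))
        c(n, k, if (n == 0L) NA_real_ else round(100 * k / n, 1))
    }
    rows <- rbind(
        interactions = one(pairKeys(reference), pairKeys(other)),
        genes = one(unique(reference$gene_id), unique(other$gene_id)),
        regulators = one(unique(reference$regulator_id),
                         unique(other$regulator_id)))
    data.frame(level = rownames(rows),
               n_reference = rows[, 1], n_overlap = rows[, 2],
               pct_of_reference = rows[, 3], row.names = NULL)
}

#' Fraction of reference interactions found in at least one other set
#'
#' @param reference an interaction set.
#' @param others non-empty list of interaction sets.
#' @return list: `fraction` of reference pairs present in the union of
#'   `others`, and `pairs`, the surviving reference rows.
#' @export
detectedInAny <- function(reference, others) {
    if (!length(others)) stop("'others' must be non-empty")
    refKeys <- pairKeys(reference)
    pool <- unique(unlist(lapply(others, pairKeys)))
    hit <- refKeys %in% pool
    list(fraction = if (length(refKeys)) mean(hit) else NA_real_,
         pairs = reference[hit, , drop = FALSE])
}

#' Read a GMT pathway database
#'
#' Standard GMT: one pathway per line, tab-separated
#' `pathway_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        stats::setNames(list(unique(f[-(1:2)])), f[1])
    })
    do.call(c, out)
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, tests whether the query gene set overlaps it more
#' than expected for a random draw of the same size from the universe:
#' upper-tail hypergeometric p-value, BH-adjusted across pathways.
#' Pathways with no overlap are reported with p = 1, not dropped.
#'
#' @param genes query gene set (must be a subset of `universe`).
#' @param db named list of pathway gene sets (see [readGmt()]); pathway
#'   genes outside the universe are ignored.
#' @param universe background gene universe.
#' @return data.frame `pathway_id`, `n_pathway`, `n_overlap`, `pvalue`,
#'   `qvalue`, sorted by `qvalue` then `pvalue`.
#' @export
enrichmentOra <- function(genes, db, universe) {
    genes <- unique(genes)
    universe <- unique(universe)
    if (!all(genes %in% universe))
        stop("query genes must be a subset of the universe")
    N <- length(universe)
    n <- length(genes)
    rows <- lapply(names(db), function(pw) {
        pwGenes <- intersect(db[[pw]], universe)
        K <- length(pwGenes)
        k <- length(intersect(genes, pwGenes))
        p <- if (k == 0L) 1
             else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(pathway_id = pw, n_pathway = K, n_overlap = k,
                   pvalue = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
    out <- out[order(out$qvalue, out$pvalue, out$pathway_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Expression-correlation validation of called interactions
#'
#' For each (regulator, gene) pair, the Pearson correlation of their
#' expression across the shared samples; pairs with PCC at or below
#' `-cutoff` are flagged as showing the strong negative co-expression
#' expected of repressive miRNA regulation. Constant vectors leave the
#' PCC undefined; such pairs are reported unflagged with a reason.
#'
#' @param pairs data.frame `regulator_id`, `gene_id`.
#' @param exprRegulators,exprGenes entities x samples expression
#'   matrices; columns are matched by sample name.
#' @param cutoff absolute-PCC threshold.
#' @return data.frame `regulator_id`, `gene_id`, `pcc`,
#'   `strong_negative`, `note`; attribute `n_flagged` gives the flagged
#'   count.
#' @export
correlationCheck <- function(pairs, exprRegulators, exprGenes, cutoff = 0.7) {
    shared <- intersect(colnames(exprRegulators), colnames(exprGenes))
    if (length(shared) < 3L)
        stop("need at least 3 shared samples for correlation")
    res <- lapply(seq_len(nrow(pairs)), function(i) {
        r <- pairs$regulator_id[i]; g <- pairs$gene_id[i]
        if (!r %in% rownames(exprRegulators) || !g %in% rownames(exprGenes))
            return(data.frame(regulator_id = r, gene_id = g,
                              pcc = NA_real_, strong_negative = FALSE,
                              note = "missing expression"))
        x <- exprRegulators[r, shared]; y <- exprGenes[g, shared]
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(data.frame(regulator_id = r, gene_id = g,
                              pcc = NA_real_, strong_negative = FALSE,
                              note = "constant expression"))
        pcc <- stats::cor(x, y)
        data.frame(regulator_id = r, gene_id = g, pcc = pcc,
                   strong_negative = pcc <= -cutoff, note = "")
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "n_flagged") <- sum(out$strong_negative)
    out
}
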