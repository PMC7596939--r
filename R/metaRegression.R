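#' Assemble the per-gene regression problem
#'
#' Builds the design for one target gene: response `Y` (the gene's log2
#' changes across disease samples), background block `X1` (CNV and
#' methylation change rows for the gene; included only when *both* are
#' provided, as for cancer cohorts), regulator-change matrix `P`
#' (columns: the gene's scored TFs first, then miRNAs), the RS' weight
#' vector, and the weighted design `X2 = P * diag(RS')`.
#'
#' Regulators qualify when they have `rs_norm > 0` for this gene in
#' `rsTable` and a corresponding row in `deltaTf`/`deltaMirna`.
#'
#' @param geneId target gene id (must be a row of `deltaGene`).
#' @param deltaGene,deltaTf,deltaMirna entities x disease-samples log2
#'   change matrices from [deltaExpression()].
#' @param rsTable a [RegulatoryScoreTable-class].
#' @param cnv,meth optional genes x disease-samples change matrices; both
#'   must be present (with a row for the gene) for `X1` to be built.
#' @return a [GeneRegressionProblem-class], or `NULL` (with a message)
#'   when the gene has no scored regulator with expression data.
#' @export
buildProblem <- function(geneId, deltaGene, deltaTf, deltaMirna, rsTable,
                         cnv = NULL, meth = NULL) {
    stopifnot(geneId %in% rownames(deltaGene))
    sc <- scores(rsTable)
    sc <- sc[sc$gene_id == geneId & sc$rs_norm > 0, , drop = FALSE]
    # TFs first, then miRNAs; stable id order within kind
    sc <- sc[order(match(sc$regulator_kind, c("tf", "mirna")),
                   sc$regulator_id), , drop = FALSE]
    hasDelta <- ifelse(sc$regulator_kind == "tf",
                       sc$regulator_id %in% rownames(deltaTf),
                       sc$regulator_id %in% rownames(deltaMirna))
    sc <- sc[hasDelta, , drop = FALSE]
    if (nrow(sc) == 0L) {
        message("gene ", geneId, " skipped: no scored regulator with expression data")
        return(NULL)
    }
    samples <- colnames(deltaGene)
    P <- t(vapply(seq_len(nrow(sc)), function(r) {
        m <- if (sc$regulator_kind[r] == "tf") deltaTf else deltaMirna
        m[sc$regulator_id[r], samples]
    }, numeric(length(samples))))
    P <- t(P)   # samples x regulators
    colnames(P) <- sc$regulator_id
    rsVec <- sc$rs_norm
    X1 <- if (!is.null(cnv) && !is.null(meth) &&
              geneId %in% rownames(cnv) && geneId %in% rownames(meth)) {
        cbind(cnv_change = cnv[geneId, samples],
              meth_change = meth[geneId, samples])
    } else {
        matrix(numeric(0), nrow = length(samples), ncol = 0L)
    }
    new("GeneRegressionProblem",
        geneId = geneId,
        Y = as.numeric(deltaGene[geneId, samples]),
        X1 = X1, P = P, rsVec = rsVec,
        regulatorIds = sc$regulator_id,
        regulatorKinds = sc$regulator_kind,
        X2 = sweep(P, 2L, rsVec, `*`))
}

#' Frisch-Waugh-Lovell residualization
#'
#' Projects the background block out of the response and the regulator
#' design with the annihilator \eqn{M = I - B (B'B)^{-1} B'}, returning
#' \eqn{(M Y, M X_2)}. Because every fitted model here carries an
#' intercept, the intercept belongs to the background block: B is
#' `[1, X1]`. Regressing the residualized response on the residualized
#' regulators (plus intercept, whose coefficient is then zero) yields
#' exactly the X2-block coefficients of the joint regression on
#' `[1 X1 X2]`. When `X1` has no columns the inputs are returned
#' unchanged. A rank-deficient `X1` is projected onto the column space
#' it actually spans (with a warning).
#'
#' @param Y numeric response vector.
#' @param X1 background matrix (may have zero columns).
#' @param X2 regulator design matrix.
#' @return list with elements `Y`, `X2` (residualized), and `df1`, the
#'   degrees of freedom consumed by the projection beyond the intercept
#'   (the rank contribution of `X1`).
#' @export
fwlResidualize <- function(Y, X1, X2) {
    if (is.null(X1) || ncol(X1) == 0L)
        return(list(Y = Y, X2 = X2, df1 = 0L))
    B <- cbind(1, X1)
    qx <- qr(B)
    if (qx$rank < ncol(B))
        warning("X1 is rank deficient; projecting onto its actual column space")
    # M v = v - Q Q' v over the rank-revealing Q
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    resid <- function(v) v - Q %*% crossprod(Q, v)
    list(Y = as.numeric(resid(Y)),
         X2 = apply(X2, 2L, function(col) as.numeric(resid(col))),
         df1 = qx$rank - 1L)
}

# Mallows's Cp for given subset SSE and size (p counts the intercept).
mallowsCp <- function(sse, p, sigma2, n) sse / sigma2 - n + 2 * p

#' Subset selection by Mallows's Cp
#'
#' Scores every candidate subset with
#' \deqn{C_p = SSE_p / \hat\sigma^2 - S + 2p}
#' where \eqn{\hat\sigma^2 = SSE_{full} / (S - p_{full})} comes from the
#' full candidate model and p counts the always-included intercept. The
#' minimizing subset is found exhaustively when the number of candidates
#' is at most `maxExhaustive`, and by forward stepwise search (tracking
#' the best Cp along the greedy path) above that.
#'
#' @param Y numeric response (typically FWL-residualized).
#' @param X2 S x R candidate design (typically FWL-residualized).
#' @param maxExhaustive exhaustive-search cutoff on R.
#' @param df1 residual degrees of freedom consumed upstream (FWL), used
#'   in \eqn{\hat\sigma^2}.
#' @return list: `selected` (integer column indices, possibly empty),
#'   `cp` (Cp of the selection), `cpFull` (Cp of the full model, equal to
#'   \eqn{p_{full}} by construction), `sigma2`, `method`
#'   (`"exhaustive"`/`"forward"`/`"degenerate"`).
#' @export
mallowsCpSelect <- function(Y, X2, maxExhaustive = 15L, df1 = 0L) {
    n <- length(Y)
    R <- ncol(X2)
    full <- olsFit(X2, Y, dfAdjust = df1)
    pFull <- full$rank
    dfFull <- n - pFull - df1
    if (dfFull <= 0)
        stop("too few samples for the full candidate model")
    sigma2 <- full$sse / dfFull
    if (sigma2 <= .Machine$double.eps * max(1, sum(Y^2))) {
        warning("perfect full-model fit; Cp selection degenerates to the full model")
        return(list(selected = seq_len(R), cp = NA_real_, cpFull = NA_real_,
                    sigma2 = sigma2, method = "degenerate"))
    }
    if (R <= maxExhaustive) {
        sse <- allSubsetSSE(X2, Y)
        sizes <- vapply(0:(2^R - 1), function(b) sum(bitwAnd(b, 2^(0:(R - 1))) > 0),
                        numeric(1))
        cp <- mallowsCp(sse, sizes + 1, sigma2, n)
        best <- which.min(cp)   # NA subsets never win which.min
        mask <- best - 1L
        selected <- which(bitwAnd(mask, 2^(0:(R - 1))) > 0)
        return(list(selected = selected, cp = cp[best],
                    cpFull = mallowsCp(full$sse, pFull, sigma2, n),
                    sigma2 = sigma2, method = "exhaustive"))
    }
    # forward stepwise: greedily add the column that lowers Cp most,
    # remember the best model visited
    inset <- integer(0)
    bestSet <- integer(0)
    f0 <- olsFit(X2[, inset, drop = FALSE], Y, dfAdjust = df1)
    bestCp <- curCp <- mallowsCp(f0$sse, 1, sigma2, n)
    repeat {
        cand <- setdiff(seq_len(R), inset)
        if (!length(cand)) break
        cps <- vapply(cand, function(j) {
            f <- olsFit(X2[, c(inset, j), drop = FALSE], Y, dfAdjust = df1)
            mallowsCp(f$sse, length(inset) + 2, sigma2, n)
        }, numeric(1))
        j <- cand[which.min(cps)]
        if (min(cps) >= curCp) break
        inset <- c(inset, j)
        curCp <- min(cps)
        if (curCp < bestCp) { bestCp <- curCp; bestSet <- inset }
    }
    list(selected = sort(bestSet), cp = bestCp,
         cpFull = mallowsCp(full$sse, pFull, sigma2, n),
         sigma2 = sigma2, method = "forward")
}

#' Coefficient significance with Benjamini-Hochberg pruning
#'
#' Computes two-sided t-test p-values for the non-intercept coefficients
#' of an OLS fit (as returned by the internal fitting path), adjusts them
#' by the BH step-up procedure across those coefficients, and flags those
#' with q-value below `alphaQ`.
#'
#' @param fit a fit list with elements `coef`, `p` (intercept first) and
#'   `df`, e.g. the `fit` element returned by [fitGene()] internals.
#' @param regulatorIds ids of the non-intercept columns, in order.
#' @param alphaQ FDR gate.
#' @return data.frame `regulator_id`, `beta`, `pvalue`, `qvalue`,
#'   `selected`. With zero residual degrees of freedom all q-values are 1
#'   (warning).
#' @export
regulatorSignificance <- function(fit, regulatorIds, alphaQ = 0.05) {
    p <- fit$p[-1]
    beta <- fit$coef[-1]
    if (is.na(fit$df) || fit$df < 1) {
        warning("zero residual degrees of freedom; all q-values set to 1")
        p <- rep(NA_real_, length(beta))
        q <- rep(1, length(beta))
    } else {
        q <- stats::p.adjust(p, method = "BH")
    }
    data.frame(regulator_id = regulatorIds,
               beta = as.numeric(beta),
               pvalue = as.numeric(p),
               qvalue = as.numeric(q),
               selected = !is.na(q) & q < alphaQ,
               stringsAsFactors = FALSE)
}

# Drop exact duplicate columns (keep first occurrence); returns kept indices.
dedupColumns <- function(X) {
    if (ncol(X) < 2L) return(seq_len(ncol(X)))
    keep <- !duplicated(lapply(seq_len(ncol(X)), function(j) X[, j]))
    which(keep)
}

#' Fit the meta-regression for one gene
#'
#' The full per-gene inference path: exact-duplicate regulator columns
#' are dropped (first kept); the background block is projected out by
#' [fwlResidualize()]; when the number of candidates R reaches S - 3 an
#' identifiability guard prescreens to the `floor(S/3)` candidates most
#' correlated with the residualized response; [mallowsCpSelect()] picks
#' the subset; and regulators are pruned at `qThreshold` by BH-adjusted
#' coefficient t-tests.
#'
#' Two inference modes control where the p-values come from.
#' `"full"` (default) tests each candidate in the full pre-selection
#' model and BH-adjusts across all of the gene's candidates, so under a
#' global null the chance of any call is held at the nominal FDR level;
#' the reported set is the intersection of the Cp selection with the
#' q-gate. `"selected"` tests coefficients inside the Cp-selected model
#' and BH-adjusts across the selected set only; being conditioned on
#' selection, this mode is anti-conservative under the null.
#'
#' @param problem a [GeneRegressionProblem-class].
#' @param qThreshold FDR gate on regulator q-values.
#' @param maxExhaustive exhaustive Cp cutoff (see [mallowsCpSelect()]).
#' @param inference `"full"` or `"selected"` (see Details).
#' @return data.frame `gene_id`, `regulator_id`, `regulator_kind`,
#'   `beta`, `pvalue`, `qvalue` for the regulators passing both gates;
#'   attribute `cpSelected` carries a data.frame (`regulator_id`, `beta`)
#'   of the Cp-selected model before the q-gate (the model's nonzero
#'   coefficients).
#' @export
fitGene <- function(problem, qThreshold = 0.05, maxExhaustive = 15L,
                    inference = c("full", "selected")) {
    inference <- match.arg(inference)
    empty <- data.frame(gene_id = character(), regulator_id = character(),
                        regulator_kind = character(), beta = numeric(),
                        pvalue = numeric(), qvalue = numeric(),
                        stringsAsFactors = FALSE)
    noSel <- data.frame(regulator_id = character(), beta = numeric(),
                        stringsAsFactors = FALSE)
    attr(empty, "cpSelected") <- noSel
    S <- length(problem@Y)
    if (all(problem@Y == 0) || stats::var(problem@Y) == 0)
        return(empty)
    keep <- dedupColumns(problem@X2)
    ids <- problem@regulatorIds[keep]
    kinds <- problem@regulatorKinds[keep]
    X2 <- problem@X2[, keep, drop = FALSE]
    rs <- fwlResidualize(problem@Y, problem@X1, X2)
    # identifiability guard: too many candidates for a stable full model
    if (length(ids) >= S - 3) {
        nKeep <- max(1L, floor(S / 3))
        sc <- abs(apply(rs$X2, 2L, function(col) {
            if (stats::sd(col) == 0) return(0)
            stats::cor(col, rs$Y)
        }))
        ord <- order(-sc)[seq_len(min(nKeep, length(ids)))]
        ord <- sort(ord)
        ids <- ids[ord]; kinds <- kinds[ord]
        rs$X2 <- rs$X2[, ord, drop = FALSE]
    }
    sel <- mallowsCpSelect(rs$Y, rs$X2, maxExhaustive = maxExhaustive,
                           df1 = rs$df1)
    cpIds <- ids[sel$selected]
    if (!length(sel$selected))
        return(empty)
    finalFit <- olsFit(rs$X2[, sel$selected, drop = FALSE], rs$Y,
                       dfAdjust = rs$df1)
    cpSelected <- data.frame(regulator_id = cpIds,
                             beta = as.numeric(finalFit$coef[-1]),
                             stringsAsFactors = FALSE)
    if (inference == "full") {
        fullFit <- olsFit(rs$X2, rs$Y, dfAdjust = rs$df1)
        sig <- regulatorSignificance(fullFit, ids, alphaQ = qThreshold)
        sig <- sig[match(cpIds, sig$regulator_id), , drop = FALSE]
        sig$beta <- finalFit$coef[-1]   # report betas from the selected model
    } else {
        sig <- regulatorSignificance(finalFit, cpIds, alphaQ = qThreshold)
    }
    out <- data.frame(gene_id = problem@geneId,
                      regulator_id = sig$regulator_id,
                      regulator_kind = kinds[match(sig$regulator_id, ids)],
                      beta = sig$beta,
                      pvalue = sig$pvalue,
                      qvalue = sig$qvalue,
                      stringsAsFactors = FALSE)
    out <- out[sig$selected, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "cpSelected") <- cpSelected
    out
}

#' Fit the meta-regression across all genes of a condition
#'
#' Builds and fits one [GeneRegressionProblem-class] per gene of the
#' dataset that has scored regulators, returning the concatenated
#' regulator calls. Skipped genes (no scored regulator with expression
#' data) are summarized in the `skipped` attribute.
#'
#' @param dataset a [ConditionDataset-class].
#' @param rsTable a [RegulatoryScoreTable-class].
#' @param qThreshold,maxExhaustive,inference passed to [fitGene()].
#' @param pseudocount passed to [deltaExpression()].
#' @return data.frame of calls as in [fitGene()], plus attributes
#'   `cpSelected` (data.frame `gene_id`, `regulator_id`, `beta` of all
#'   Cp-selected, pre-q-gate pairs with their selected-model
#'   coefficients) and `skipped`.
#' @export
fitCondition <- function(dataset, rsTable, qThreshold = 0.05,
                         maxExhaustive = 15L,
                         inference = c("full", "selected"),
                         pseudocount = 0) {
    inference <- match.arg(inference)
    dG <- deltaExpression(dataset, "gene", pseudocount)
    dT <- deltaExpression(dataset, "tf", pseudocount)
    dM <- deltaExpression(dataset, "mirna", pseudocount)
    calls <- list(); cpSel <- list(); skipped <- character(0)
    for (g in rownames(dG)) {
        prob <- suppressMessages(
            buildProblem(g, dG, dT, dM, rsTable,
                         cnv = dataset@cnvChange, meth = dataset@methChange))
        if (is.null(prob)) { skipped <- c(skipped, g); next }
        fit <- fitGene(prob, qThreshold = qThreshold,
                       maxExhaustive = maxExhaustive, inference = inference)
        calls[[g]] <- fit
        sel <- attr(fit, "cpSelected")
        if (nrow(sel))
            cpSel[[g]] <- data.frame(gene_id = g, sel,
                                     stringsAsFactors = FALSE)
    }
    out <- if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
           else data.frame(gene_id = character(), regulator_id = character(),
                           regulator_kind = character(), beta = numeric(),
                           pvalue = numeric(), qvalue = numeric())
    attr(out, "cpSelected") <- if (length(cpSel))
        do.call(rbind, c(cpSel, make.row.names = FALSE))
    else data.frame(gene_id = character(), regulator_id = character(),
                    beta = numeric())
    attr(out, "skipped") <- skipped
    out
}
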