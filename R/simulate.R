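#' Simulate a CLASH-style interactome with known true pairs
#'
#' Generates binding-site and single-read tables that mimic a chimeric
#' read assay. Each miRNA is given `targetsPerMirna` true target genes;
#' true sites draw overdispersed chimeric counts whose floor scales with
#' `depth` (count = ceiling(depth/2) + NegBin(mu = depth/2)), so at
#' sufficient depth every true site clears a read-support filter. Decoy
#' pairs receive low Poisson counts. MFE values are uniform in
#' \[-25, -5\] kcal/mol. Single-read totals are drawn per entity so the
#' abundance bookkeeping identities hold by construction.
#'
#' @param nMirna,nGene numbers of miRNAs and genes.
#' @param targetsPerMirna true target genes per miRNA.
#' @param decoysPerMirna low-count decoy pairs per miRNA.
#' @param meanSitesPerPair mean binding sites per true pair (>= 1).
#' @param depth sequencing-depth scale for true-site chimeric counts.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return list: `sites` (binding-site data.frame), `singles`
#'   (single-read data.frame), `abundance` (an [AbundanceTable-class]),
#'   `truth` (data.frame `mirna_id`, `gene_id`, `is_true`).
#' @export
simulateInteractome <- function(nMirna, nGene, targetsPerMirna = 3L,
                                decoysPerMirna = 2L, meanSitesPerPair = 1.5,
                                depth = 50, seed = 1L) {
    stopifnot(nMirna > 0, nGene > 0, depth > 0,
              targetsPerMirna + decoysPerMirna <= nGene)
    mirnas <- sprintf("miR-%03d", seq_len(nMirna))
    genes <- sprintf("G%04d", seq_len(nGene))
    withSeed(seed, {
        rows <- list()
        truth <- list()
        for (i in seq_along(mirnas)) {
            picks <- sample(genes, targetsPerMirna + decoysPerMirna)
            trueG <- picks[seq_len(targetsPerMirna)]
            decoyG <- picks[-seq_len(targetsPerMirna)]
            for (g in trueG) {
                nSites <- 1L + stats::rpois(1, max(0, meanSitesPerPair - 1))
                starts <- sort(sample.int(3000L, nSites)) - 1L
                counts <- ceiling(depth / 2) +
                          stats::rnbinom(nSites, mu = depth / 2, size = 8)
                rows[[length(rows) + 1L]] <- data.frame(
                    mirna_id = mirnas[i], gene_id = g,
                    site_start = starts, site_end = starts + 22L,
                    chimeric_count = counts,
                    mfe = stats::runif(nSites, -25, -5))
            }
            for (g in decoyG) {
                start <- sample.int(3000L, 1) - 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    mirna_id = mirnas[i], gene_id = g,
                    site_start = start, site_end = start + 22L,
                    chimeric_count = 1L + stats::rpois(1, 2),
                    mfe = stats::runif(1, -25, -5))
            }
            truth[[i]] <- data.frame(mirna_id = mirnas[i],
                                     gene_id = picks,
                                     is_true = picks %in% trueG)
        }
        sites <- do.call(rbind, rows)
        sites$site_id <- paste(sites$mirna_id, sites$gene_id,
                               sites$site_start, sep = ":")
        usedM <- unique(sites$mirna_id); usedG <- unique(sites$gene_id)
        singles <- rbind(
            data.frame(entity_id = usedM, entity_kind = "mirna",
                       single_reads = stats::rnbinom(length(usedM),
                                                     mu = depth, size = 5)),
            data.frame(entity_id = usedG, entity_kind = "mrna",
                       single_reads = stats::rnbinom(length(usedG),
                                                     mu = depth, size = 5)))
    })
    sites <- sites[order(sites$gene_id, sites$mirna_id, sites$site_start), ]
    rownames(sites) <- NULL
    list(sites = sites, singles = singles,
         abundance = abundanceTable(sites, singles),
         truth = do.call(rbind, truth))
}

#' Simulate TF ChIP peaks and gene TSS coordinates
#'
#' Genes are laid out along one synthetic chromosome with well-separated
#' TSSs; each (TF, gene) regulatory pair receives 1-3 peaks whose
#' midpoints fall within `window` bp of the TSS.
#'
#' @param nTf,nGene numbers of TFs and genes.
#' @param genesPerTf target genes per TF.
#' @param window maximum midpoint-to-TSS distance of generated peaks.
#' @param seed integer seed.
#' @return list: `peaks` (data.frame `tf_id`, `chrom`, `start`, `end`),
#'   `tss` (data.frame `gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulateTfPeaks <- function(nTf, nGene, genesPerTf = 3L, window = 1e5,
                            seed = 1L) {
    stopifnot(genesPerTf <= nGene)
    tfs <- sprintf("TF%02d", seq_len(nTf))
    genes <- sprintf("G%04d", seq_len(nGene))
    tss <- data.frame(gene_id = genes, chrom = "chrS",
                      tss = 5e5 + (seq_len(nGene) - 1L) * 2.5e5,
                      strand = "+")
    withSeed(seed, {
        peaks <- list()
        for (t in tfs) {
            for (g in sample(genes, genesPerTf)) {
                nPk <- sample(1:3, 1)
                mid <- tss$tss[tss$gene_id == g] +
                       round(stats::runif(nPk, -window, window))
                halfw <- sample(100:300, nPk, replace = TRUE)
                peaks[[length(peaks) + 1L]] <- data.frame(
                    tf_id = t, chrom = "chrS",
                    start = pmax(0, mid - halfw), end = mid + halfw)
            }
        }
    })
    list(peaks = do.call(rbind, peaks), tss = tss)
}

#' Simulate a ground-truth regulatory network
#'
#' Builds the generative model behind [simulateCondition()]: a pool of
#' TF and miRNA regulators, `regulatorsPerGene` scored candidates per
#' gene (raw scores uniform in \[0.3, 0.9\], competitively normalized per
#' regulator), of which `nTruePerGene` carry nonzero effects with
#' magnitudes uniform in `betaRange` and random sign. The pool size is
#' set so each regulator targets about `targetsPerRegulator` genes,
#' which controls how concentrated the normalized scores are.
#'
#' @param nGenes number of target genes.
#' @param regulatorsPerGene scored candidate regulators per gene.
#' @param nTruePerGene true (nonzero-effect) regulators per gene.
#' @param targetsPerRegulator average targets per regulator.
#' @param tfFraction fraction of the regulator pool that are TFs.
#' @param betaRange magnitude range of true effects.
#' @param beta1 length-2 background coefficients (CNV, methylation)
#'   applied to every gene when a background is simulated.
#' @param sigma Gaussian noise sd on the gene log2-change scale.
#' @param seed integer seed.
#' @return a [GroundTruthNetwork-class].
#' @export
simulateGroundTruth <- function(nGenes = 10L, regulatorsPerGene = 10L,
                                nTruePerGene = 3L, targetsPerRegulator = 3L,
                                tfFraction = 0.4, betaRange = c(0.5, 1.5),
                                beta1 = c(0.5, -0.5), sigma = 0.2,
                                seed = 1L) {
    stopifnot(nTruePerGene <= regulatorsPerGene)
    poolSize <- max(regulatorsPerGene + 1L,
                    ceiling(nGenes * regulatorsPerGene / targetsPerRegulator))
    nTf <- round(tfFraction * poolSize)
    pool <- c(sprintf("TF%03d", seq_len(nTf)),
              sprintf("miR-%03d", seq_len(poolSize - nTf)))
    kinds <- c(rep("tf", nTf), rep("mirna", poolSize - nTf))
    genes <- sprintf("G%04d", seq_len(nGenes))
    withSeed(seed, {
        rs <- list(); b2 <- list()
        for (g in genes) {
            idx <- sample.int(poolSize, regulatorsPerGene)
            rs[[g]] <- data.frame(regulator_id = pool[idx],
                                  regulator_kind = kinds[idx],
                                  gene_id = g,
                                  rs_raw = stats::runif(regulatorsPerGene,
                                                        0.3, 0.9))
            if (nTruePerGene > 0L) {
                tru <- sample(idx, nTruePerGene)
                b2[[g]] <- data.frame(
                    regulator_id = pool[tru], gene_id = g,
                    beta = sample(c(-1, 1), nTruePerGene, replace = TRUE) *
                           stats::runif(nTruePerGene, betaRange[1],
                                        betaRange[2]))
            }
        }
    })
    raw <- do.call(rbind, rs)
    b1 <- matrix(rep(beta1, each = nGenes), nrow = nGenes,
                 dimnames = list(genes, c("cnv", "meth")))
    beta2 <- if (length(b2)) do.call(rbind, c(b2, make.row.names = FALSE))
             else data.frame(regulator_id = character(),
                             gene_id = character(), beta = numeric())
    new("GroundTruthNetwork",
        rsTable = normalizeRS(raw),
        beta2 = beta2,
        beta1 = b1, sigma = sigma, genes = genes,
        tfs = pool[kinds == "tf"], mirnas = pool[kinds == "mirna"])
}

#' Simulate a multi-omics condition dataset from a ground truth
#'
#' Draws regulator log2 changes i.i.d. standard normal per disease
#' sample, optional CNV/methylation backgrounds (standard normal), and
#' gene log2 changes from the linear generative model
#' \deqn{\Delta g_{js} = X_1 \beta_1^* + \sum_r RS'_{rj}\,
#' \Delta reg_{rs}\, \beta_{2,rj}^* + N(0, \sigma).}
#' Changes are exponentiated back to expression scale around a constant
#' control baseline, so [deltaExpression()] recovers them exactly (with
#' pseudocount 0).
#'
#' @param truth a [GroundTruthNetwork-class].
#' @param nDisease,nControl sample counts (`nDisease >= 4`,
#'   `nControl >= 2`).
#' @param withBackground simulate CNV/methylation matrices and their
#'   effects on gene expression.
#' @param baseline control-level expression for every entity.
#' @param seed integer seed.
#' @return a [ConditionDataset-class] named `synthetic`.
#' @export
simulateCondition <- function(truth, nDisease = 60L, nControl = 20L,
                              withBackground = FALSE, baseline = 100,
                              seed = 1L) {
    stopifnot(nDisease >= 4L, nControl >= 2L)
    regs <- c(truth@tfs, truth@mirnas)
    genes <- truth@genes
    sc <- scores(truth@rsTable)
    disNames <- sprintf("d%03d", seq_len(nDisease))
    ctlNames <- sprintf("c%03d", seq_len(nControl))
    withSeed(seed, {
        dReg <- matrix(stats::rnorm(length(regs) * nDisease),
                       nrow = length(regs),
                       dimnames = list(regs, disNames))
        cnv <- meth <- NULL
        if (withBackground) {
            cnv <- matrix(stats::rnorm(length(genes) * nDisease),
                          nrow = length(genes),
                          dimnames = list(genes, disNames))
            meth <- matrix(stats::rnorm(length(genes) * nDisease),
                           nrow = length(genes),
                           dimnames = list(genes, disNames))
        }
        dGene <- matrix(0, length(genes), nDisease,
                        dimnames = list(genes, disNames))
        for (g in genes) {
            gs <- sc[sc$gene_id == g, , drop = FALSE]
            bt <- truth@beta2[truth@beta2$gene_id == g, , drop = FALSE]
            beta <- stats::setNames(rep(0, nrow(gs)), gs$regulator_id)
            beta[bt$regulator_id] <- bt$beta
            w <- gs$rs_norm * beta          # per-regulator effective weight
            sig <- as.numeric(crossprod(dReg[gs$regulator_id, , drop = FALSE], w))
            if (withBackground)
                sig <- sig + truth@beta1[g, 1] * cnv[g, ] +
                             truth@beta1[g, 2] * meth[g, ]
            dGene[g, ] <- sig + stats::rnorm(nDisease, sd = truth@sigma)
        }
    })
    toExpr <- function(delta, ids) {
        dis <- baseline * 2^delta
        ctl <- matrix(baseline, length(ids), nControl,
                      dimnames = list(ids, ctlNames))
        cbind(ctl, dis)
    }
    labels <- factor(c(rep("control", nControl), rep("disease", nDisease)),
                     levels = c("control", "disease"))
    names(labels) <- c(ctlNames, disNames)
    new("ConditionDataset",
        conditionId = "synthetic",
        geneExpr = toExpr(dGene, genes),
        mirnaExpr = toExpr(dReg[truth@mirnas, , drop = FALSE], truth@mirnas),
        tfExpr = toExpr(dReg[truth@tfs, , drop = FALSE], truth@tfs),
        labels = labels,
        cnvChange = cnv, methChange = meth)
}

#' Recovery metrics of calls against the ground truth
#'
#' @param truth a [GroundTruthNetwork-class].
#' @param calls a call table: either a [fitGene()]/[fitCondition()]
#'   result (`gene_id`, `regulator_id`, `beta`) or a
#'   [consensusRegulators()] result (rows with `retained == TRUE` are
#'   used, betas from `beta_original`).
#' @return list: `sensitivity` (fraction of true pairs called), `fdr`
#'   (fraction of calls that are not true; `NA` when nothing is called),
#'   `rmse` (coefficient root-mean-square error over true positives),
#'   `n_called`, `n_true`.
#' @export
recoveryReport <- function(truth, calls) {
    if ("retained" %in% names(calls)) {
        calls <- calls[calls$retained, , drop = FALSE]
        calls$beta <- calls$beta_original
    }
    trueKey <- paste(truth@beta2$regulator_id, truth@beta2$gene_id)
    callKey <- paste(calls$regulator_id, calls$gene_id)
    tp <- intersect(callKey, trueKey)
    sens <- if (length(trueKey)) length(tp) / length(trueKey) else NA_real_
    fdr <- if (length(callKey)) 1 - length(tp) / length(callKey) else NA_real_
    rmse <- if (length(tp)) {
        est <- calls$beta[match(tp, callKey)]
        tru <- truth@beta2$beta[match(tp, trueKey)]
        sqrt(mean((est - tru)^2))
    } else NA_real_
    list(sensitivity = sens, fdr = fdr, rmse = rmse,
         n_called = length(callKey), n_true = length(trueKey))
}
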