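#' Binding probability of a miRNA-gene site from read abundances
#'
#' The probability that a chimeric read reflects a genuine binding event
#' between miRNA i and gene j at site k, from the conditional-probability
#' construction \deqn{P_{ijk} = \frac{C_{ijk}^2}{(C_i + M_i)(C_j + M_j)}}
#' where C are chimeric and M single-read totals.
#'
#' @param cijk site chimeric read count(s).
#' @param ci,mi chimeric and single-read totals of the miRNA.
#' @param cj,mj chimeric and single-read totals of the mRNA.
#' @return non-negative binding probability(ies).
#' @examples
#' mirnaBindingProbability(4, ci = 6, mi = 2, cj = 4, mj = 0)  # 16/32 = 0.5
#' @export
mirnaBindingProbability <- function(cijk, ci, mi, cj, mj) {
    di <- ci + mi
    dj <- cj + mj
    if (any(di <= 0))
        stop("miRNA with no reads (chimeric + single = 0)")
    if (any(dj <= 0))
        stop("mRNA with no reads (chimeric + single = 0)")
    if (any(cijk > pmin(ci, cj)))
        stop("site chimeric count exceeds an entity total")
    cijk^2 / (di * dj)
}

#' Raw regulatory score of one miRNA-gene pair
#'
#' Aggregates binding probability and binding affinity over the pair's K
#' sites: \deqn{RS_{ij} = \frac{1}{K} \sum_k |MFE_k| \, P_{ijk}} with MFE
#' the minimum free energy of the duplex at site k (kcal/mol).
#'
#' @param sites data.frame of binding sites for a single (miRNA, gene)
#'   pair, with columns `mirna_id`, `gene_id`, `chimeric_count`, `mfe`.
#' @param abundance an [AbundanceTable-class].
#' @return the raw RS value (non-negative scalar).
#' @export
mirnaGeneRS <- function(sites, abundance) {
    if (nrow(sites) == 0L)
        stop("mirnaGeneRS needs at least one binding site")
    i <- unique(sites$mirna_id)
    j <- unique(sites$gene_id)
    if (length(i) != 1L || length(j) != 1L)
        stop("all sites must belong to one (miRNA, gene) pair")
    p <- mirnaBindingProbability(sites$chimeric_count,
                                 abundance@cMirna[[i]], abundance@mMirna[[i]],
                                 abundance@cMrna[[j]], abundance@mMrna[[j]])
    mean(abs(sites$mfe) * p)
}

#' Raw miRNA regulatory scores for a whole site table
#'
#' @param sites filtered binding-site data.frame (any number of pairs).
#' @param abundance an [AbundanceTable-class].
#' @return data.frame `regulator_id`, `regulator_kind` (= "mirna"),
#'   `gene_id`, `rs_raw`, one row per pair.
#' @export
mirnaScores <- function(sites, abundance) {
    if (nrow(sites) == 0L)
        return(data.frame(regulator_id = character(), regulator_kind = character(),
                          gene_id = character(), rs_raw = numeric()))
    key <- paste(sites$mirna_id, sites$gene_id, sep = "\r")
    raw <- vapply(split(sites, key), mirnaGeneRS, numeric(1),
                  abundance = abundance)
    parts <- strsplit(names(raw), "\r", fixed = TRUE)
    out <- data.frame(
        regulator_id = vapply(parts, `[`, character(1), 1L),
        regulator_kind = "mirna",
        gene_id = vapply(parts, `[`, character(1), 2L),
        rs_raw = as.numeric(raw))
    out[order(out$regulator_id, out$gene_id), , drop = FALSE]
}

#' Competitive normalization of raw regulatory scores
#'
#' Divides each regulator's raw scores by their sum over all of its
#' targets (\eqn{RS'_{ij} = RS_{ij}/RS_i}), so each regulator's normalized
#' scores sum to 1. Regulators whose raw scores are all zero cannot be
#' normalized and are dropped with a warning.
#'
#' @param raw data.frame with columns `regulator_id`, `regulator_kind`,
#'   `gene_id`, `rs_raw`.
#' @return a [RegulatoryScoreTable-class].
#' @export
normalizeRS <- function(raw) {
    stopifnot(all(c("regulator_id", "regulator_kind", "gene_id", "rs_raw")
                  %in% names(raw)))
    if (nrow(raw)) {
        tot <- tapply(raw$rs_raw, raw$regulator_id, sum)
        dead <- names(tot)[tot <= 0]
        if (length(dead)) {
            warning("dropping regulator(s) with all-zero raw scores: ",
                    paste(dead, collapse = ", "))
            raw <- raw[!raw$regulator_id %in% dead, , drop = FALSE]
            tot <- tot[!names(tot) %in% dead]
        }
        raw$rs_norm <- raw$rs_raw / as.numeric(tot[raw$regulator_id])
    } else {
        raw$rs_norm <- numeric(0)
    }
    raw <- raw[order(raw$regulator_id, raw$gene_id), , drop = FALSE]
    rownames(raw) <- NULL
    new("RegulatoryScoreTable", scores = raw)
}

#' Distance-decay score of one TF binding site
#'
#' Regulatory potential of a TF peak as a function of its distance d (bp)
#' to the gene's transcription start site:
#' \deqn{RS_{tjk} = e^{-(0.5 + 4 d / 10^5)}.}
#' The score is \eqn{e^{-0.5} \approx 0.607} at the TSS and decays
#' exponentially with a 25-kb e-folding scale.
#'
#' @param d non-negative distance(s) in bp.
#' @return score(s) in (0, exp(-0.5)].
#' @export
tfSiteRS <- function(d) {
    if (any(d < 0)) stop("distance must be non-negative")
    exp(-(0.5 + 4 * (d / 1e5)))
}

#' Noisy-OR aggregation of TF site scores into a pair score
#'
#' \deqn{RS_{tj} = 1 - \prod_k (1 - RS_{tjk})}: the probability that at
#' least one site is regulatory, treating sites independently.
#'
#' @param siteScores numeric vector of per-site scores, each in \[0, 1).
#' @return the aggregated score in \[0, 1); at least the maximum input.
#' @export
tfGeneRS <- function(siteScores) {
    if (length(siteScores) == 0L)
        stop("tfGeneRS needs at least one site score")
    if (any(siteScores < 0 | siteScores >= 1))
        stop("site scores must lie in [0, 1)")
    1 - prod(1 - siteScores)
}

#' Raw TF regulatory scores from ChIP peaks and TSS coordinates
#'
#' For each (TF, gene) pair with at least one peak whose midpoint lies
#' within `window` bp of the gene's TSS on the same chromosome, computes
#' the unstranded midpoint-to-TSS distances, scores them with
#' [tfSiteRS()], and aggregates with [tfGeneRS()].
#'
#' @param peaks data.frame with columns `tf_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param tss data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @param window candidate window half-width in bp around the TSS.
#' @return data.frame `regulator_id`, `regulator_kind` (= "tf"),
#'   `gene_id`, `rs_raw`. Genes with no peak in the window are absent.
#' @export
peaksToTfScores <- function(peaks, tss, window = 1e5) {
    stopifnot(all(c("tf_id", "chrom", "start", "end") %in% names(peaks)),
              all(c("gene_id", "chrom", "tss") %in% names(tss)))
    if (any(peaks$start >= peaks$end))
        stop("peak start must be < end")
    out <- list()
    mid <- (peaks$start + peaks$end) / 2
    for (g in seq_len(nrow(tss))) {
        onChr <- peaks$chrom == tss$chrom[g]
        d <- abs(mid[onChr] - tss$tss[g])
        inWin <- d <= window
        if (!any(inWin)) next
        sc <- tfSiteRS(d[inWin])
        tfid <- peaks$tf_id[onChr][inWin]
        agg <- vapply(split(sc, tfid), tfGeneRS, numeric(1))
        out[[g]] <- data.frame(regulator_id = names(agg),
                               regulator_kind = "tf",
                               gene_id = tss$gene_id[g],
                               rs_raw = as.numeric(agg))
    }
    if (!length(out))
        return(data.frame(regulator_id = character(),
                          regulator_kind = character(),
                          gene_id = character(), rs_raw = numeric()))
    res <- do.call(rbind, out)
    res <- res[order(res$regulator_id, res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Read / write regulatory-score tables
#'
#' TSV with columns `regulator_id`, `regulator_kind`, `gene_id`,
#' `rs_raw`, `rs_norm`. Numeric columns are written with 17 significant
#' digits so a write/read round trip reproduces every double bit-exactly.
#'
#' @param x a [RegulatoryScoreTable-class].
#' @param path file path.
#' @export
writeRegulatoryScores <- function(x, path) {
    stopifnot(is(x, "RegulatoryScoreTable"))
    writeTsv(x@scores, path)
}

#' @rdname writeRegulatoryScores
#' @export
readRegulatoryScores <- function(path) {
    new("RegulatoryScoreTable", scores = readTsv(path))
}

#' Read BED3+1 TF peaks and TSS tables
#'
#' Peaks: four tab-separated columns `chrom`, `start`, `end`, `tf_id`
#' (BED3+1, no header). TSS: headered TSV `gene_id`, `chrom`, `tss`,
#' `strand`.
#'
#' @param path file path.
#' @export
readTfPeaks <- function(path) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("expected BED3+1: chrom, start, end, tf_id")
    names(df)[1:4] <- c("chrom", "start", "end", "tf_id")
    df[, c("tf_id", "chrom", "start", "end")]
}

#' @rdname readTfPeaks
#' @export
readTss <- function(path) {
    df <- readTsv(path)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(df)))
        stop("TSS table must have columns: ", paste(need, collapse = ", "))
    df
}
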