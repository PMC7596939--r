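#' Binomial confidence p-value for a CLASH binding site
#'
#' Assesses how surprising the chimeric-read support of a binding site is
#' relative to a random draw from the whole interactome: the upper-tail
#' binomial sum \deqn{p = \sum_{c = C_{ijk}}^{C_{all}} \binom{C_{all}}{c}
#' \pi^c (1-\pi)^{C_{all}-c}.}
#'
#' By default the success probability is the observed proportion
#' \eqn{\pi = C_{ijk}/C_{all}}. Because that null is centred on the
#' observation itself, the tail probability hovers near 0.5 for any
#' moderately supported site; `nullRate` lets the caller supply an
#' expectation-based rate instead (for example the product of the marginal
#' read fractions of the miRNA and the mRNA).
#'
#' @param cijk chimeric read count(s) of the site, `0 <= cijk <= call`.
#' @param call total chimeric reads over all interactions; must be > 0.
#' @param nullRate optional success probability in \[0, 1\] replacing the
#'   observed proportion; recycled against `cijk`.
#' @return p-value(s) in \[0, 1\].
#' @examples
#' bindingSitePValue(15, 20)
#' bindingSitePValue(15, 20, nullRate = 0.25)
#' @export
bindingSitePValue <- function(cijk, call, nullRate = NULL) {
    if (length(call) != 1L || call <= 0)
        stop("'call' must be a single positive total; the interactome is empty otherwise")
    if (any(cijk < 0) || any(cijk > call))
        stop("'cijk' must lie in [0, call]")
    pi <- if (is.null(nullRate)) cijk / call else rep_len(nullRate, length(cijk))
    if (any(pi < 0 | pi > 1)) stop("'nullRate' must lie in [0, 1]")
    # upper tail including cijk itself
    stats::pbinom(cijk - 1, size = call, prob = pi, lower.tail = FALSE)
}

#' Bonferroni adjustment over a set of tested binding sites
#'
#' Sets `adj_pvalue = min(1, pvalue * N)` with N the number of tested
#' sites in the table.
#'
#' @param sites data.frame of binding sites with a `pvalue` column.
#' @return the same data.frame with an `adj_pvalue` column set.
#' @export
adjustBonferroni <- function(sites) {
    if (nrow(sites) == 0L) {
        sites$adj_pvalue <- numeric(0)
        return(sites)
    }
    if (is.null(sites$pvalue) || anyNA(sites$pvalue))
        stop("every site must have a pvalue before adjustment")
    sites$adj_pvalue <- pmin(1, sites$pvalue * nrow(sites))
    sites
}

#' Three-stage quality filter for binding sites
#'
#' Applies, in order: (1) the significance gate `adj_pvalue < alpha`;
#' (2) removal of the bottom `bottomFrac` fraction of low-confidence
#' survivors, where confidence ranks by `adj_pvalue` (descending = worst),
#' ties broken by ascending `chimeric_count` then lexicographic `site_id`,
#' and the number dropped is `floor(bottomFrac * n)`; (3) removal of sites
#' with `chimeric_count < minReads`.
#'
#' @param sites data.frame of binding sites with columns `mirna_id`,
#'   `gene_id`, `site_id`, `site_start`, `site_end`, `chimeric_count`,
#'   `mfe`, `pvalue`, `adj_pvalue`.
#' @param alpha significance level on the Bonferroni-adjusted p-value.
#' @param bottomFrac fraction of low-confidence survivors to drop.
#' @param minReads minimum chimeric read support (sites with fewer reads
#'   are discarded; the boundary is exclusive, 12 means "< 12 dropped").
#' @return the surviving sites, ordered by (`gene_id`, `mirna_id`,
#'   `site_start`).
#' @export
filterBindingSites <- function(sites, alpha = 0.05, bottomFrac = 0.10,
                               minReads = 12L) {
    if (is.null(sites$adj_pvalue) || anyNA(sites$adj_pvalue))
        stop("adj_pvalue must be set on all sites; run adjustBonferroni() first")
    keep <- sites[sites$adj_pvalue < alpha, , drop = FALSE]
    nDrop <- floor(bottomFrac * nrow(keep))
    if (nDrop > 0L) {
        # worst first: largest adj p, then fewest reads, then site id
        worst <- order(-keep$adj_pvalue, keep$chimeric_count, keep$site_id)
        keep <- keep[-worst[seq_len(nDrop)], , drop = FALSE]
    }
    keep <- keep[keep$chimeric_count >= minReads, , drop = FALSE]
    keep <- keep[order(keep$gene_id, keep$mirna_id, keep$site_start), ,
                 drop = FALSE]
    rownames(keep) <- NULL
    keep
}

#' Build an AbundanceTable from binding sites and single-read counts
#'
#' Per-entity chimeric totals are the sums of site chimeric counts over
#' that entity's sites; single-read totals come from the companion table.
#' Entities appearing in the sites but absent from `singles` get zero
#' single reads.
#'
#' @param sites binding-site data.frame (see [filterBindingSites()]).
#' @param singles data.frame with columns `entity_id`, `entity_kind`
#'   (`"mirna"` or `"mrna"`), `single_reads`.
#' @return an [AbundanceTable-class].
#' @export
abundanceTable <- function(sites, singles) {
    cM <- tapply(sites$chimeric_count, sites$mirna_id, sum)
    cG <- tapply(sites$chimeric_count, sites$gene_id, sum)
    cM <- stats::setNames(as.numeric(cM), names(cM))
    cG <- stats::setNames(as.numeric(cG), names(cG))
    lookup <- function(ids, kind) {
        sub <- singles[singles$entity_kind == kind, , drop = FALSE]
        out <- stats::setNames(rep(0, length(ids)), ids)
        hit <- intersect(ids, sub$entity_id)
        out[hit] <- sub$single_reads[match(hit, sub$entity_id)]
        out
    }
    new("AbundanceTable",
        cAll = sum(sites$chimeric_count),
        cMirna = cM, mMirna = lookup(names(cM), "mirna"),
        cMrna = cG, mMrna = lookup(names(cG), "mrna"))
}

#' Read / write binding-site tables
#'
#' TSV dialect: header columns `mirna_id`, `gene_id`, `site_start`,
#' `site_end`, `chimeric_count`, `mfe` (plus `site_id`, `pvalue`,
#' `adj_pvalue` when present). Coordinates are 0-based half-open on the
#' transcript. `readSingleReads` reads the companion `entity_id`,
#' `entity_kind`, `single_reads` table.
#'
#' @param path file path.
#' @param sites binding-site data.frame to write.
#' @return `readBindingSites` returns a data.frame with a `site_id`
#'   column synthesized as `mirna:gene:start` when absent.
#' @export
readBindingSites <- function(path) {
    df <- readTsv(path)
    need <- c("mirna_id", "gene_id", "site_start", "site_end",
              "chimeric_count", "mfe")
    if (!all(need %in% names(df)))
        stop("binding-site table must have columns: ",
             paste(need, collapse = ", "))
    if (any(df$site_start >= df$site_end))
        stop("site_start must be < site_end (0-based half-open)")
    if (any(df$chimeric_count < 0))
        stop("chimeric_count must be non-negative")
    if (is.null(df$site_id))
        df$site_id <- paste(df$mirna_id, df$gene_id, df$site_start, sep = ":")
    df
}

#' @rdname readBindingSites
#' @export
readSingleReads <- function(path) {
    df <- readTsv(path)
    need <- c("entity_id", "entity_kind", "single_reads")
    if (!all(need %in% names(df)))
        stop("single-read table must have columns: ",
             paste(need, collapse = ", "))
    df
}

#' @rdname readBindingSites
#' @export
writeBindingSites <- function(sites, path) {
    writeTsv(sites, path)
}

#' Score and filter a CLASH interactome in one step
#'
#' Convenience composition: compute per-site binomial p-values, apply the
#' Bonferroni adjustment, and run the three-stage filter.
#'
#' @inheritParams filterBindingSites
#' @inheritParams bindingSitePValue
#' @param nullRate `NULL` for the observed-proportion null, a numeric rate,
#'   or `"independence"` to use the product of marginal read fractions
#'   \eqn{(C_i/C_{all}) (C_j/C_{all})} per site (requires `singles` to
#'   build the abundance table; marginals use chimeric totals).
#' @param singles single-read table, only needed for bookkeeping of the
#'   returned abundance table.
#' @return list with elements `sites` (filtered, with p-value columns) and
#'   `abundance` (an [AbundanceTable-class] built from the *unfiltered*
#'   sites, since single reads and totals describe the assay, not the
#'   filtered subset).
#' @export
scoreInteractome <- function(sites, singles, alpha = 0.05, bottomFrac = 0.10,
                             minReads = 12L, nullRate = NULL) {
    ab <- abundanceTable(sites, singles)
    if (identical(nullRate, "independence")) {
        rate <- (ab@cMirna[sites$mirna_id] / ab@cAll) *
                (ab@cMrna[sites$gene_id] / ab@cAll)
        sites$pvalue <- bindingSitePValue(sites$chimeric_count, ab@cAll,
                                          nullRate = as.numeric(rate))
    } else {
        sites$pvalue <- bindingSitePValue(sites$chimeric_count, ab@cAll,
                                          nullRate = nullRate)
    }
    sites <- adjustBonferroni(sites)
    list(sites = filterBindingSites(sites, alpha, bottomFrac, minReads),
         abundance = ab)
}
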