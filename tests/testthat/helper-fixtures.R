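# Shared fixtures and independent oracles, built in code.

# Binding-site table with controllable counts and adjusted p-values.
makeSites <- function(n = 10, counts = rep(20L, n), adjP = rep(0.001, n),
                      mirna = sprintf("miR-%02d", seq_len(n)),
                      gene = sprintf("G%02d", seq_len(n))) {
    data.frame(mirna_id = mirna, gene_id = gene,
               site_id = sprintf("s%02d", seq_len(n)),
               site_start = seq_len(n) * 10L,
               site_end = seq_len(n) * 10L + 22L,
               chimeric_count = counts,
               mfe = rep(-10, n), pvalue = adjP / max(n, 1),
               adj_pvalue = adjP, stringsAsFactors = FALSE)
}

# Independent upper-tail binomial oracle: direct log-space summation with
# lchoose, no pbinom.
binomTailOracle <- function(c, n, pi) {
    if (c <= 0) return(1)
    if (pi == 0) return(0)
    if (pi == 1) return(1)
    ks <- c:n
    sum(exp(lchoose(n, ks) + ks * log(pi) + (n - ks) * log1p(-pi)))
}

# Brute-force best-subset Cp oracle using naive per-subset lm.fit.
cpBruteForce <- function(X, y) {
    n <- length(y)
    R <- ncol(X)
    sseOf <- function(cols) {
        Xa <- cbind(1, X[, cols, drop = FALSE])
        sum(stats::lm.fit(Xa, y)$residuals^2)
    }
    sigma2 <- sseOf(seq_len(R)) / (n - R - 1)
    best <- NULL; bestCp <- Inf
    for (b in 0:(2^R - 1)) {
        cols <- which(bitwAnd(b, 2^(0:(R - 1))) > 0)
        cp <- sseOf(cols) / sigma2 - n + 2 * (length(cols) + 1)
        if (cp < bestCp) { bestCp <- cp; best <- cols }
    }
    list(selected = best, cp = bestCp)
}

# A tiny one-regulator/one-gene ground truth with configurable effect.
tinyTruth <- function(beta = 1, sigma = 0) {
    rs <- new("RegulatoryScoreTable",
              scores = data.frame(regulator_id = "miR-001",
                                  regulator_kind = "mirna",
                                  gene_id = "G0001",
                                  rs_raw = 5, rs_norm = 1))
    new("GroundTruthNetwork", rsTable = rs,
        beta2 = data.frame(regulator_id = "miR-001", gene_id = "G0001",
                           beta = beta),
        beta1 = matrix(0, 1, 2, dimnames = list("G0001", c("cnv", "meth"))),
        sigma = sigma, genes = "G0001", tfs = character(0),
        mirnas = "miR-001")
}
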