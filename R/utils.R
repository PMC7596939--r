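# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a stage label.
# Polynomial string hash folded into [0, 2^31 - 2]; avoids collisions between
# stages without an external digest dependency.
childSeed <- function(seed, stage) {
    h <- 0
    for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
    as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# Evaluate expr under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Ordinary least squares with intercept on columns `X` (may be 0-col),
# returning coefficients, standard errors and two-sided t-test p-values.
# `dfAdjust` subtracts extra residual degrees of freedom consumed upstream
# (e.g. background columns projected out by the FWL transform).
olsFit <- function(X, y, dfAdjust = 0L) {
    n <- length(y)
    Xa <- cbind(`(Intercept)` = rep(1, n), X)
    fit <- stats::lm.fit(Xa, y)
    p <- fit$rank
    df <- n - p - dfAdjust
    res <- fit$residuals
    sse <- sum(res^2)
    sigma2 <- if (df > 0) sse / df else NA_real_
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    XtXinv <- chol2inv(R)
    se <- rep(NA_real_, length(fit$coefficients))
    se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(XtXinv) * sigma2)
    coefs <- fit$coefficients
    tval <- coefs / se
    pval <- if (df > 0) 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
            else rep(NA_real_, length(tval))
    list(coef = coefs, se = se, t = tval, p = pval,
         sse = sse, df = df, rank = p, residuals = res)
}

# Full-precision numeric formatting so TSV round-trips are bit-exact
# (17 significant digits uniquely identify a double).
fmtNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE)
    }, character(1))
    out
}

writeTsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    out <- df
    out[num] <- lapply(df[num], fmtNum)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
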