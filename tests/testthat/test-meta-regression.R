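# Random regression instance: S samples, k background columns, R regulators.
randInstance <- function(S = 30, k = 2, R = 5, seed = 1) {
    set.seed(seed)
    list(Y = rnorm(S),
         X1 = if (k > 0) matrix(rnorm(S * k), S) else
              matrix(numeric(0), S, 0),
         X2 = matrix(rnorm(S * R), S))
}

test_that("problem assembly orders TFs before miRNAs and weights by RS'", {
    samples <- paste0("d", 1:20)
    dG <- matrix(rnorm(20), 1, dimnames = list("g1", samples))
    dT <- matrix(rnorm(40), 2, dimnames = list(c("TFb", "TFa"), samples))
    dM <- matrix(rnorm(60), 3, dimnames = list(paste0("m", 1:3), samples))
    rs <- new("RegulatoryScoreTable", scores = data.frame(
        regulator_id = c("TFa", "TFb", "m1", "m2", "m3"),
        regulator_kind = c("tf", "tf", rep("mirna", 3)),
        gene_id = "g1",
        rs_raw = c(0.2, 0.4, 1, 2, 3),
        rs_norm = c(1, 1, 1, 1, 1)))
    prob <- buildProblem("g1", dG, dT, dM, rs)
    expect_s4_class(prob, "GeneRegressionProblem")
    expect_equal(prob@regulatorIds, c("TFa", "TFb", "m1", "m2", "m3"))
    expect_equal(dim(prob@X2), c(20L, 5L))
    # rsVec of ones makes X2 = P
    expect_equal(prob@X2, prob@P)
    expect_equal(ncol(prob@X1), 0L)
    # with cnv+meth the background block appears
    cnv <- matrix(rnorm(20), 1, dimnames = list("g1", samples))
    meth <- matrix(rnorm(20), 1, dimnames = list("g1", samples))
    prob2 <- buildProblem("g1", dG, dT, dM, rs, cnv, meth)
    expect_equal(ncol(prob2@X1), 2L)
    # non-unit weights are applied column-wise (each regulator's weights
    # sum to 1 over its two targets)
    w <- c(0.5, 0.5, 0.2, 0.3, 0.5)
    sc2 <- rbind(
        transform(scores(rs), rs_norm = w),
        transform(scores(rs), gene_id = "g0", rs_norm = 1 - w))
    rs2 <- new("RegulatoryScoreTable", scores = sc2)
    prob3 <- buildProblem("g1", dG, dT, dM, rs2)
    expect_equal(unname(prob3@X2), unname(sweep(prob3@P, 2, w, `*`)))
    # a gene with no scored regulators is skipped
    rs0 <- rs; rs0@scores <- rs0@scores[0, ]
    expect_message(expect_null(buildProblem("g1", dG, dT, dM, rs0)),
                   "skipped")
})

test_that("FWL residualization reproduces the joint-OLS regulator block", {
    inst <- randInstance(seed = 5)
    beta <- c(0.8, 0, -1.2, 0, 0.5)
    y <- inst$X1 %*% c(1, -1) + inst$X2 %*% beta + rnorm(30, sd = 0.1)
    rs <- fwlResidualize(as.numeric(y), inst$X1, inst$X2)
    bF <- olsFit(rs$X2, rs$Y, dfAdjust = rs$df1)$coef[-1]
    joint <- lm.fit(cbind(1, inst$X1, inst$X2), y)$coefficients
    expect_equal(unname(bF), unname(joint[4:8]), tolerance = 1e-10)
    # empty background is the identity transform
    none <- fwlResidualize(as.numeric(y), matrix(numeric(0), 30, 0), inst$X2)
    expect_identical(none$Y, as.numeric(y))
    expect_identical(none$X2, inst$X2)
    expect_equal(none$df1, 0L)
    # rank-deficient X1: duplicated column handled via its actual span
    X1dup <- cbind(inst$X1[, 1], inst$X1[, 1])
    expect_warning(rd <- fwlResidualize(as.numeric(y), X1dup, inst$X2),
                   "rank deficient")
    expect_equal(rd$df1, 1L)
})

test_that("full-model Cp equals the parameter count", {
    for (seed in 1:5) {
        inst <- randInstance(R = 6, seed = seed)
        sel <- mallowsCpSelect(inst$Y, inst$X2)
        expect_equal(sel$cpFull, 7, tolerance = 1e-9)
    }
})

test_that("exhaustive Cp finds the brute-force optimum", {
    # planted single strong predictor among 8 columns
    set.seed(33)
    X <- matrix(rnorm(35 * 8), 35)
    y <- 2 * X[, 3] + rnorm(35, sd = 0.01)
    sel <- mallowsCpSelect(y, X)
    oracle3 <- cpBruteForce(X, y)
    expect_true(3L %in% sel$selected)
    expect_equal(sel$selected, oracle3$selected)
    expect_equal(sel$method, "exhaustive")
    # pure-noise response: whatever wins must match the oracle
    y0 <- rnorm(35)
    X5 <- X[, 1:5]
    sel0 <- mallowsCpSelect(y0, X5)
    oracle <- cpBruteForce(X5, y0)
    expect_equal(sel0$selected, oracle$selected)
    expect_equal(sel0$cp, oracle$cp, tolerance = 1e-8)
})

test_that("forward stepwise agrees with exhaustive on orthogonal designs", {
    set.seed(12)
    for (rep in 1:5) {
        Q <- qr.Q(qr(matrix(rnorm(40 * 8), 40)))   # orthonormal columns
        y <- Q %*% c(3, 0, -2, 0, 0, 1.5, 0, 0) + rnorm(40, sd = 0.3)
        ex <- mallowsCpSelect(as.numeric(y), Q, maxExhaustive = 15)
        fw <- mallowsCpSelect(as.numeric(y), Q, maxExhaustive = 2)
        expect_equal(fw$method, "forward")
        expect_equal(fw$selected, ex$selected)
    }
})

test_that("a perfect full-model fit degenerates to the full model", {
    set.seed(2)
    X <- matrix(rnorm(20 * 3), 20)
    y <- X %*% c(1, 2, 3)   # no noise
    expect_warning(sel <- mallowsCpSelect(as.numeric(y), X), "perfect")
    expect_equal(sel$selected, 1:3)
})

test_that("BH pruning follows the step-up arithmetic", {
    fit <- list(coef = c(0, 1, -2, 0.1), p = c(0.5, 0.01, 0.02, 0.9), df = 10)
    out <- regulatorSignificance(fit, c("r1", "r2", "r3"))
    expect_equal(out$qvalue, c(0.03, 0.03, 0.9))
    expect_equal(out$selected, c(TRUE, TRUE, FALSE))
    # single regulator: q equals p
    one <- regulatorSignificance(list(coef = c(0, 2), p = c(0.3, 0.04),
                                      df = 8), "r1")
    expect_equal(one$qvalue, one$pvalue)
    # all p = 1: nothing survives
    null <- regulatorSignificance(list(coef = c(0, 1, 1), p = c(1, 1, 1),
                                       df = 8), c("a", "b"))
    expect_false(any(null$selected))
    # zero residual df: everything set to q = 1 with warning
    expect_warning(z <- regulatorSignificance(
        list(coef = c(0, 1), p = c(NA, NA), df = 0), "r1"), "degrees")
    expect_equal(z$qvalue, 1)
})

test_that("fitGene recovers a strong planted regulator within 3 SE", {
    # one true regulator among five candidates with zero effect
    sc <- data.frame(
        regulator_id = c("miR-001", paste0("miR-00", 2:5)),
        regulator_kind = "mirna", gene_id = "G0001",
        rs_raw = 1, rs_norm = 1)
    rs <- new("RegulatoryScoreTable", scores = sc)
    set.seed(77)
    S <- 40
    dM <- matrix(rnorm(5 * S), 5, dimnames = list(sc$regulator_id,
                                                  paste0("d", 1:S)))
    dG <- matrix(1.2 * dM["miR-001", ] + rnorm(S, sd = 0.1), 1,
                 dimnames = list("G0001", paste0("d", 1:S)))
    dT <- matrix(numeric(0), 0, S, dimnames = list(NULL, paste0("d", 1:S)))
    prob <- buildProblem("G0001", dG, dT, dM, rs)
    fit <- fitGene(prob)
    expect_equal(fit$regulator_id, "miR-001")
    se <- 0.1 / (sd(dM["miR-001", ]) * sqrt(S))
    expect_lt(abs(fit$beta - 1.2), 3 * se)
})

test_that("identifiability guard prescreens when regulators crowd samples", {
    set.seed(55)
    S <- 6; R <- 40
    samples <- paste0("d", 1:S)
    dM <- matrix(rnorm(R * S), R, dimnames = list(sprintf("m%02d", 1:R),
                                                  samples))
    dG <- matrix(2 * dM["m01", ] , 1, dimnames = list("g1", samples))
    rs <- new("RegulatoryScoreTable", scores = data.frame(
        regulator_id = rownames(dM), regulator_kind = "mirna",
        gene_id = "g1", rs_raw = 1, rs_norm = 1))
    dT <- matrix(numeric(0), 0, S, dimnames = list(NULL, samples))
    prob <- buildProblem("g1", dG, dT, dM, rs)
    fit <- suppressWarnings(fitGene(prob))
    # floor(S/3) = 2 candidates at most can be selected
    expect_lte(nrow(attr(fit, "cpSelected")), 2L)
})

test_that("duplicate regulator columns are dropped keeping the first", {
    set.seed(66)
    S <- 30
    samples <- paste0("d", 1:S)
    base <- rnorm(S)
    dM <- rbind(mA = base, mB = base, mC = rnorm(S))
    colnames(dM) <- samples
    dG <- matrix(1.5 * base + rnorm(S, sd = 0.1), 1,
                 dimnames = list("g1", samples))
    dT <- matrix(numeric(0), 0, S, dimnames = list(NULL, samples))
    rs <- new("RegulatoryScoreTable", scores = data.frame(
        regulator_id = c("mA", "mB", "mC"), regulator_kind = "mirna",
        gene_id = "g1", rs_raw = 1, rs_norm = 1))
    prob <- buildProblem("g1", dG, dT, dM, rs)
    fit <- fitGene(prob)
    expect_true("mA" %in% fit$regulator_id)
    expect_false("mB" %in% fit$regulator_id)
})

test_that("fitGene is invariant to regulator column permutation", {
    truth <- simulateGroundTruth(nGenes = 1, regulatorsPerGene = 6,
                                 nTruePerGene = 2, seed = 10)
    ds <- simulateCondition(truth, nDisease = 40, nControl = 5, seed = 11)
    dG <- deltaExpression(ds, "gene")
    dT <- deltaExpression(ds, "tf")
    dM <- deltaExpression(ds, "mirna")
    prob <- buildProblem(truth@genes[1], dG, dT, dM, truth@rsTable)
    fit1 <- fitGene(prob)
    perm <- rev(seq_along(prob@rsVec))
    prob2 <- new("GeneRegressionProblem", geneId = prob@geneId,
                 Y = prob@Y, X1 = prob@X1,
                 P = prob@P[, perm], rsVec = prob@rsVec[perm],
                 regulatorIds = prob@regulatorIds[perm],
                 regulatorKinds = prob@regulatorKinds[perm],
                 X2 = prob@X2[, perm])
    fit2 <- fitGene(prob2)
    ord <- function(f) f[order(f$regulator_id), c("regulator_id", "beta")]
    expect_equal(ord(fit1), ord(fit2), ignore_attr = TRUE)
})

test_that("an all-zero response yields no calls", {
    S <- 20
    samples <- paste0("d", 1:S)
    dG <- matrix(0, 1, S, dimnames = list("g1", samples))
    dM <- matrix(rnorm(2 * S), 2, dimnames = list(c("m1", "m2"), samples))
    dT <- matrix(numeric(0), 0, S, dimnames = list(NULL, samples))
    rs <- new("RegulatoryScoreTable", scores = data.frame(
        regulator_id = c("m1", "m2"), regulator_kind = "mirna",
        gene_id = "g1", rs_raw = 1, rs_norm = 1))
    prob <- buildProblem("g1", dG, dT, dM, rs)
    expect_equal(nrow(fitGene(prob)), 0L)
})
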