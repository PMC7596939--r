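makeDataset <- function(gene, mirna = gene, tf = gene, labels,
                        cnv = NULL, meth = NULL) {
    lab <- factor(labels, levels = c("control", "disease"))
    names(lab) <- colnames(gene)
    new("ConditionDataset", conditionId = "test",
        geneExpr = gene, mirnaExpr = mirna, tfExpr = tf, labels = lab,
        cnvChange = cnv, methChange = meth)
}

test_that("log2 changes are taken against the control mean", {
    m <- matrix(c(2, 4, 6, 8, 4), nrow = 1,
                dimnames = list("g1", paste0("s", 1:5)))
    ds <- makeDataset(m, labels = c(rep("control", 3), "disease", "disease"))
    d <- deltaExpression(ds, "gene")
    # control mean 4; disease values 8 and 4
    expect_equal(as.numeric(d["g1", ]), c(1, 0))
    # the control-mean vector itself maps to zero
    m2 <- rbind(g1 = rep(4, 5))
    colnames(m2) <- paste0("s", 1:5)
    ds2 <- makeDataset(m2, labels = c(rep("control", 3), rep("disease", 2)))
    expect_equal(as.numeric(deltaExpression(ds2, "gene")), c(0, 0))
})

test_that("zero-control entities are excluded and recorded", {
    m <- matrix(c(0, 0, 5, 2, 2, 8), nrow = 2, byrow = TRUE,
                dimnames = list(c("dead", "ok"), paste0("s", 1:3)))
    ds <- makeDataset(m, labels = c("control", "control", "disease"))
    d <- deltaExpression(ds, "gene")
    expect_equal(rownames(d), "ok")
    expect_equal(attr(d, "excluded"), "dead")
    # a pseudocount rescues count-scale zeros
    d1 <- deltaExpression(ds, "gene", pseudocount = 1)
    expect_equal(nrow(d1), 2L)
    expect_equal(d1["dead", 1], log2(6))
})

test_that("differential calls need both the fold-change and p-value gates", {
    gene <- rbind(up = c(2, 2.1, 1.9, 8, 8.1, 7.9),
                  flat = c(5, 5.1, 4.9, 5.05, 4.95, 5),
                  hardgate = c(100, 100.2, 99.8, 199, 199.1, 198.9))
    colnames(gene) <- paste0("s", 1:6)
    ds <- makeDataset(gene, labels = rep(c("control", "disease"), each = 3))
    de <- differentialEntities(ds, "gene")
    up <- de[de$entity_id == "up", ]
    expect_true(up$de); expect_equal(up$direction, "up")
    expect_equal(up$fc, 4, tolerance = 0.05)
    expect_lt(up$pvalue, 0.05)
    expect_false(de$de[de$entity_id == "flat"])
    # FC = 1.99: tiny p-value cannot rescue it
    hg <- de[de$entity_id == "hardgate", ]
    expect_lt(hg$pvalue, 1e-6)
    expect_lt(hg$fc, 2)
    expect_false(hg$de)
})

test_that("swapping group labels inverts fold change and direction", {
    set.seed(8)
    gene <- matrix(rlnorm(40, 3, 0.4), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    lab <- rep(c("control", "disease"), each = 4)
    a <- differentialEntities(makeDataset(gene, labels = lab), "gene")
    b <- differentialEntities(makeDataset(gene, labels = rev(lab)), "gene")
    expect_equal(a$fc, 1 / b$fc, tolerance = 1e-12)
    expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
    expect_true(all(a$de == b$de))
    expect_true(all((a$direction == "up") == (b$direction == "down")))
})

test_that("zero-variance-in-both-groups entities are excluded with warning", {
    gene <- rbind(const = rep(5, 6), ok = c(1, 2, 3, 7, 8, 9))
    colnames(gene) <- paste0("s", 1:6)
    ds <- makeDataset(gene, labels = rep(c("control", "disease"), each = 3))
    expect_warning(de <- differentialEntities(ds, "gene"), "zero variance")
    expect_equal(de$entity_id, "ok")
})

test_that("over-sampling respects the noise band and is seed-deterministic", {
    set.seed(21)
    gene <- matrix(rlnorm(60, 3, 0.5), nrow = 6,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    ds <- makeDataset(gene, labels = c(rep("control", 4), rep("disease", 6)))
    aug <- oversampleDataset(ds, targetN = 15, seed = 99)
    expect_equal(length(diseaseSamples(aug)), 15L)
    expect_equal(exprMatrix(aug, "gene")[, seq_len(10)], gene)
    newCols <- setdiff(colnames(exprMatrix(aug, "gene")), colnames(gene))
    for (nc in newCols) {
        src <- sub("_os\\d+$", "", nc)
        ratio <- exprMatrix(aug, "gene")[, nc] / gene[, src]
        expect_true(all(ratio >= 0.95 - 1e-12 & ratio <= 1.05 + 1e-12))
    }
    # one-sided alternative band
    aug1 <- oversampleDataset(ds, targetN = 15, high = 1, seed = 99)
    nc1 <- setdiff(colnames(exprMatrix(aug1, "gene")), colnames(gene))
    for (nc in nc1) {
        src <- sub("_os\\d+$", "", nc)
        ratio <- exprMatrix(aug1, "gene")[, nc] / gene[, src]
        expect_true(all(ratio >= 0.95 - 1e-12 & ratio <= 1))
    }
    # determinism and identity noise
    aug2 <- oversampleDataset(ds, targetN = 15, seed = 99)
    expect_identical(exprMatrix(aug, "gene"), exprMatrix(aug2, "gene"))
    dup <- oversampleDataset(ds, targetN = 12, low = 1, high = 1, seed = 4)
    for (nc in setdiff(colnames(exprMatrix(dup, "gene")), colnames(gene))) {
        src <- sub("_os\\d+$", "", nc)
        expect_equal(exprMatrix(dup, "gene")[, nc],
                     stats::setNames(gene[, src], rownames(gene)))
    }
    expect_error(oversampleDataset(ds, 12, low = 1.1, high = 0.9), "<=")
    expect_error(oversampleDataset(ds, 2), ">=")
})

test_that("condition datasets round-trip through a TSV directory", {
    truth <- simulateGroundTruth(nGenes = 3, seed = 2)
    ds <- simulateCondition(truth, nDisease = 6, nControl = 3,
                            withBackground = TRUE, seed = 3)
    dir <- withr::local_tempdir()
    writeConditionDataset(ds, dir)
    back <- readConditionDataset(dir, conditionId(ds))
    expect_identical(exprMatrix(back, "gene"), exprMatrix(ds, "gene"))
    expect_identical(exprMatrix(back, "mirna"), exprMatrix(ds, "mirna"))
    expect_identical(back@cnvChange, ds@cnvChange)
    expect_identical(as.character(sampleLabels(back)),
                     as.character(sampleLabels(ds)))
})
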