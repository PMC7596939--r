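test_that("binding probability follows the conditional-probability form", {
    expect_equal(mirnaBindingProbability(0, 10, 5, 8, 2), 0)
    expect_equal(mirnaBindingProbability(4, 6, 2, 4, 0), 0.5)   # 16/32
    expect_equal(mirnaBindingProbability(7, 7, 0, 7, 0), 1)
    expect_error(mirnaBindingProbability(1, 0, 0, 5, 5), "miRNA with no reads")
    expect_error(mirnaBindingProbability(8, 10, 2, 7, 1), "exceeds")
})

test_that("pair RS averages |MFE| x P over the pair's sites", {
    ab <- new("AbundanceTable", cAll = 8,
              cMirna = c(`miR-a` = 8), mMirna = c(`miR-a` = 0),
              cMrna = c(Gx = 8), mMrna = c(Gx = 0))
    one <- data.frame(mirna_id = "miR-a", gene_id = "Gx",
                      chimeric_count = 4, mfe = -10)
    # P = 16/64 = 0.25 -> RS = 10 * 0.25
    expect_equal(mirnaGeneRS(one, ab), 2.5)
    # two-site average with hand-set probabilities:
    # counts (3.2.., ) chosen so P = 0.2 and 0.1 exactly under (8)(20)
    ab2 <- new("AbundanceTable", cAll = 12,
               cMirna = c(`miR-a` = 12), mMirna = c(`miR-a` = 0),
               cMrna = c(Gx = 12), mMrna = c(Gx = 8))
    two <- data.frame(mirna_id = "miR-a", gene_id = "Gx",
                      chimeric_count = c(4, 8), mfe = c(-10, -20))
    p <- c(16, 64) / (12 * 20)
    expect_equal(mirnaGeneRS(two, ab2), mean(abs(two$mfe) * p))
    # zero-count site contributes zero
    three <- rbind(two, data.frame(mirna_id = "miR-a", gene_id = "Gx",
                                   chimeric_count = 0, mfe = -25))
    expect_equal(mirnaGeneRS(three, ab2), sum(abs(two$mfe) * p) / 3)
    expect_error(mirnaGeneRS(two[0, ], ab2), "at least one")
})

test_that("competitive normalization divides by each regulator's RS total", {
    raw <- data.frame(regulator_id = c("a", "a", "b"),
                      regulator_kind = "mirna",
                      gene_id = c("g1", "g2", "g1"),
                      rs_raw = c(3, 1, 7))
    tab <- normalizeRS(raw)
    sc <- scores(tab)
    expect_equal(sc$rs_norm[sc$regulator_id == "a"], c(0.75, 0.25))
    expect_equal(sc$rs_norm[sc$regulator_id == "b"], 1)
    # all-zero regulator dropped with warning
    raw0 <- rbind(raw, data.frame(regulator_id = "z", regulator_kind = "mirna",
                                  gene_id = "g1", rs_raw = 0))
    expect_warning(tab0 <- normalizeRS(raw0), "all-zero")
    expect_false("z" %in% scores(tab0)$regulator_id)
})

test_that("per-regulator normalized scores sum to one on simulated tables", {
    sim <- simulateInteractome(nMirna = 5, nGene = 20, depth = 50, seed = 9)
    tab <- normalizeRS(mirnaScores(sim$sites, sim$abundance))
    sums <- tapply(scores(tab)$rs_norm, scores(tab)$regulator_id, sum)
    expect_true(all(abs(sums - 1) <= 1e-9))
    pk <- simulateTfPeaks(nTf = 6, nGene = 12, seed = 9)
    tfTab <- normalizeRS(peaksToTfScores(pk$peaks, pk$tss))
    sums2 <- tapply(scores(tfTab)$rs_norm, scores(tfTab)$regulator_id, sum)
    expect_true(all(abs(sums2 - 1) <= 1e-9))
})

test_that("TF site score is the exponential distance decay", {
    expect_equal(tfSiteRS(0), exp(-0.5))
    expect_equal(tfSiteRS(1e5), exp(-4.5))
    d <- seq(0, 2e5, by = 1e4)
    expect_true(all(diff(tfSiteRS(d)) < 0))
    expect_error(tfSiteRS(-1), "non-negative")
})

test_that("noisy-OR aggregation is order-invariant and monotone", {
    expect_equal(tfGeneRS(0.3), 0.3)
    expect_equal(tfGeneRS(c(0.5, 0.5)), 0.75)
    expect_equal(tfGeneRS(c(0.5, 0.5, 0)), 0.75)
    set.seed(5)
    s <- runif(6, 0, 0.6)
    expect_equal(tfGeneRS(s), tfGeneRS(rev(s)))
    expect_gte(tfGeneRS(c(s, 0.2)), tfGeneRS(s))
    expect_gte(tfGeneRS(s), max(s))
    expect_lt(tfGeneRS(s), 1)
    expect_error(tfGeneRS(c(0.5, 1)), "\\[0, 1\\)")
})

test_that("peak-to-TSS scoring uses midpoints within the window", {
    tss <- data.frame(gene_id = "G1", chrom = "chr1", tss = 1e6, strand = "+")
    peakAtTss <- data.frame(tf_id = "T1", chrom = "chr1",
                            start = 1e6 - 200, end = 1e6 + 200)
    expect_equal(peaksToTfScores(peakAtTss, tss)$rs_raw, exp(-0.5))
    far <- data.frame(tf_id = "T1", chrom = "chr1",
                      start = 1e6 + 1e5 - 100, end = 1e6 + 1e5 + 100)
    expect_equal(peaksToTfScores(far, tss)$rs_raw, exp(-4.5))
    beyond <- data.frame(tf_id = "T1", chrom = "chr1",
                         start = 1e6 + 2e5, end = 1e6 + 2e5 + 200)
    expect_equal(nrow(peaksToTfScores(beyond, tss)), 0L)
    wrongChrom <- data.frame(tf_id = "T1", chrom = "chr2",
                             start = 1e6 - 200, end = 1e6 + 200)
    expect_equal(nrow(peaksToTfScores(wrongChrom, tss)), 0L)
    # two sites aggregate by noisy-OR
    both <- rbind(peakAtTss, peakAtTss)
    expect_equal(peaksToTfScores(both, tss)$rs_raw,
                 1 - (1 - exp(-0.5))^2)
})

test_that("pair RS scales linearly under uniform MFE rescaling", {
    ab <- new("AbundanceTable", cAll = 12,
              cMirna = c(`miR-a` = 12), mMirna = c(`miR-a` = 3),
              cMrna = c(Gx = 12), mMrna = c(Gx = 5))
    sites <- data.frame(mirna_id = "miR-a", gene_id = "Gx",
                        chimeric_count = c(2, 5, 5), mfe = c(-8, -12, -20))
    scaled <- transform(sites, mfe = mfe * 3)
    expect_equal(mirnaGeneRS(scaled, ab), 3 * mirnaGeneRS(sites, ab))
})

test_that("score tables round-trip through TSV bit-exactly", {
    sim <- simulateInteractome(nMirna = 4, nGene = 12, depth = 50, seed = 13)
    tab <- normalizeRS(mirnaScores(sim$sites, sim$abundance))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeRegulatoryScores(tab, path)
    back <- readRegulatoryScores(path)
    expect_identical(scores(back)$rs_raw, scores(tab)$rs_raw)
    expect_identical(scores(back)$rs_norm, scores(tab)$rs_norm)
})
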