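# O(n^2) pair-counting AUROC with half credit for ties
aurocOracle <- function(x, inC) {
    a <- x[inC]
    b <- x[!inC]
    tot <- 0
    for (u in a) for (v in b)
        tot <- tot + (u > v) + 0.5 * (u == v)
    tot / (length(a) * length(b))
}

test_that("AUROC is exact for perfect separation and null genes", {
    m <- rbind(g1 = c(2, 3, 4, 0, 1, 1))
    labs <- rep(c("A", "B"), each = 3)
    rec <- aurocMarkers(m, labs, filter = FALSE)
    expect_equal(rec$auroc[rec$cluster == "A"], 1.0)
    expect_equal(rec$auroc[rec$cluster == "B"], 0.0)
    # identical distributions hover at 0.5 and are not retained
    set.seed(30)
    m2 <- matrix(rnorm(50 * 60), 50, 60,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
    labs2 <- rep(c("A", "B"), each = 30)
    rec2 <- aurocMarkers(m2, labs2, filter = FALSE)
    expect_lt(max(abs(rec2$auroc - 0.5)), 0.3)
    expect_equal(nrow(aurocMarkers(m2, labs2)), 0L)
})

test_that("AUROC equals the pair-counting oracle under ties", {
    set.seed(31)
    labs <- rep(c("A", "B"), each = 10)
    m <- matrix(sample(0:3, 20 * 8, replace = TRUE), 8, 20,
                dimnames = list(sprintf("g%d", 1:8), NULL))
    rec <- aurocMarkers(m, labs, filter = FALSE)
    for (g in rownames(m)) {
        expect_equal(rec$auroc[rec$gene == g & rec$cluster == "A"],
                     aurocOracle(m[g, ], labs == "A"))
        # complement symmetry within tie handling
        expect_equal(rec$auroc[rec$gene == g & rec$cluster == "A"] +
                     rec$auroc[rec$gene == g & rec$cluster == "B"], 1)
    }
})

test_that("single-cluster input is rejected", {
    m <- matrix(rnorm(10 * 5), 10, 5)
    expect_error(aurocMarkers(m, rep("A", 5)), "two clusters")
    expect_error(pairwiseTMarkers(m, rep("A", 5)), "two clusters")
})

test_that("pairwise t markers detect a planted shift", {
    set.seed(32)
    m <- matrix(rnorm(20 * 100, sd = 0.5), 20, 100,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    labs <- rep(c("A", "B"), each = 50)
    m["g01", labs == "A"] <- m["g01", labs == "A"] + 2.0
    tabs <- pairwiseTMarkers(m, labs, lfcThreshold = 0.5)
    tabA <- tabs$A
    expect_lt(tabA$fdr[tabA$gene == "g01"], 0.05)
    expect_equal(tabA$lfc_sum[tabA$gene == "g01"],
                 mean(m["g01", labs == "A"]) - mean(m["g01", labs == "B"]))
})

test_that("the type-I error of the pairwise test is controlled", {
    set.seed(33)
    m <- matrix(rnorm(100 * 90), 100, 90,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    labs <- rep(c("A", "B", "C"), each = 30)
    tabs <- pairwiseTMarkers(m, labs, lfcThreshold = 0)
    fp <- mean(tabs$A$fdr < 0.05)
    expect_lte(fp, 0.05)
})

test_that("tiny clusters and degenerate genes are handled", {
    m <- matrix(rnorm(10 * 7), 10, 7,
                dimnames = list(sprintf("g%d", 1:10), NULL))
    expect_error(pairwiseTMarkers(m, c("A", "A", rep("B", 5))),
                 "at least 3")
    m2 <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
    m2[2, 1:6] <- 7   # zero variance in cluster A
    tabs <- pairwiseTMarkers(m2, rep(c("A", "B"), each = 6))
    expect_true("g2" %in% attr(tabs, "floored_genes"))
})

test_that("the ranked list enforces the no-negative-LFC rule", {
    tabs <- list(X = data.frame(
        gene = c("up", "big"),
        `lfc.Y` = c(2, 5), `lfc.Z` = c(1, -0.1), `lfc.W` = c(1, 4),
        lfc_sum = c(4, 8.9), p_combined = c(1e-4, 1e-6),
        fdr = c(1e-3, 1e-5), check.names = FALSE))
    out <- rankedMarkerList(tabs)
    expect_identical(out$X, "up")   # "big" excluded despite larger sum
})

test_that("non-significant tables give empty marker lists", {
    tabs <- list(X = data.frame(gene = c("a", "b"),
        `lfc.Y` = c(1, 2), lfc_sum = c(1, 2),
        p_combined = c(0.4, 0.9), fdr = c(0.6, 0.9), check.names = FALSE))
    expect_length(rankedMarkerList(tabs)$X, 0)
})

test_that("ranked lists match a hand-enumerated oracle", {
    set.seed(34)
    tab <- data.frame(
        gene = sprintf("g%02d", 1:10),
        `lfc.B` = c(3, 2, -1, 4, 0.5, 2, 1, 0, 2, 2),
        `lfc.C` = c(1, 2, 2, 3, 0.5, -2, 1, 0, 2, 2),
        check.names = FALSE)
    tab$lfc_sum <- tab$`lfc.B` + tab$`lfc.C`
    tab$fdr <- c(0.01, 0.2, 0.01, 0.03, 0.04, 0.01, 0.01, 0.01, 0.02, 0.02)
    out <- rankedMarkerList(list(A = tab))$A
    # oracle: drop g03 (negative LFC), g06 (negative LFC), g02 (FDR > 0.05);
    # order the rest by decreasing lfc_sum, ties alphabetically
    keep <- tab[!(tab$gene %in% c("g02", "g03", "g06")) & tab$fdr <= 0.05, ]
    oracle <- keep$gene[order(-keep$lfc_sum, keep$gene)]
    expect_identical(out, oracle)
    # output is always a subset of the input, ordered consistently
    expect_true(all(out %in% tab$gene))
    sums <- tab$lfc_sum[match(out, tab$gene)]
    expect_true(all(diff(sums) <= 0))
})

test_that("the top-marker export pads columns to equal length", {
    rl <- list(A = c("x", "y", "z"), B = "w")
    tab <- topMarkerTable(rl, n = 3)
    expect_identical(dim(tab), c(3L, 2L))
    expect_identical(tab$B, c("w", "", ""))
})
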