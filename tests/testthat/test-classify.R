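test_that("identity scores are detection percentages over the gene list", {
    genes <- sprintf("A%02d", 1:20)
    m <- matrix(0, 25, 1, dimnames = list(c(genes, paste0("X", 1:5)), "n1"))
    m[genes[1:5], 1] <- 3                      # 5 of 20 astro genes detected
    gs <- GeneSetList(list(Astrocyte = genes))
    expect_equal(identityScores(m, gs)["n1", "Astrocyte"], 25)
    m[] <- 1
    expect_equal(unname(identityScores(m, gs)["n1", ]), 100)
})

test_that("identity scores equal brute-force intersection ratios", {
    set.seed(7)
    genes <- sprintf("G%03d", 1:50)
    m <- matrix(rbinom(50 * 100, 1, 0.3), 50, 100,
                dimnames = list(genes, sprintf("n%03d", 1:100)))
    sets <- lapply(1:6, function(i) sample(genes, sample(5:20, 1)))
    names(sets) <- paste0("S", 1:6)
    gs <- GeneSetList(sets)
    sc <- identityScores(m, gs)
    for (s in names(sets)) for (j in sample(100, 20)) {
        inUniverse <- intersect(gs@sets[[s]], genes)
        oracle <- 100 * sum(m[inUniverse, j] > 0) / length(inUniverse)
        expect_identical(sc[j, s], oracle)
    }
})

test_that("scores ignore count magnitude and grow with list hits", {
    set.seed(8)
    m <- matrix(rpois(40 * 30, 1), 40, 30,
                dimnames = list(sprintf("G%02d", 1:40), NULL))
    gs <- GeneSetList(list(A = sprintf("G%02d", 1:15)))
    expect_identical(identityScores(m, gs), identityScores(m * 17L, gs))
    # weak monotonicity when an expressed gene joins the list
    expressed <- rownames(m)[rowSums(m > 0) == ncol(m)][1]
    gs2 <- GeneSetList(list(A = c(sprintf("G%02d", 1:15), expressed)))
    expect_true(all(identityScores(m, gs2) >= 0))
    sOld <- identityScores(m, gs)[, "A"]
    sNew <- identityScores(m, gs2)[, "A"]
    # adding an always-expressed gene can only raise the detection fraction
    expect_true(all(sNew >= sOld - 1e-12))
})

test_that("an empty intersected gene set names the offending class", {
    m <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), NULL))
    gs <- GeneSetList(list(Good = c("A", "B"), Ghost = c("Z1", "Z2")))
    expect_error(identityScores(m, gs), "Ghost")
})

test_that("class assignment uses argmax with the flatness ambiguity rule", {
    sc <- rbind(n1 = c(Astrocyte = 40, Neuron = 10, Oligodendrocyte = 5,
                       OPC = 0, Microglia = 0, Endothelial = 0))
    p <- assignClasses(sc, rho = 1)
    expect_identical(assignedClass(p), "Astrocyte")
    expect_false(isAmbiguous(p))                 # 10 + 5 < 40

    sc2 <- rbind(n1 = c(A = 30, B = 20, C = 15))
    expect_true(isAmbiguous(assignClasses(sc2, rho = 1)))    # 35 > 30
    expect_false(isAmbiguous(assignClasses(sc2, rho = 2)))   # 35 < 60

    sc3 <- rbind(n1 = c(A = 0, B = 0, C = 0))
    p3 <- assignClasses(sc3)
    expect_identical(assignedClass(p3), "Unknown")
    expect_true(isAmbiguous(p3))
})

test_that("the literal rho = 2 rule can never fire on distinct scores", {
    set.seed(9)
    for (i in 1:200) {
        v <- sort(runif(6, 0, 100), decreasing = TRUE)
        while (anyDuplicated(v)) v <- sort(runif(6, 0, 100), decreasing = TRUE)
        sc <- matrix(v, 1, dimnames = list("n", paste0("C", 1:6)))
        expect_false(isAmbiguous(assignClasses(sc, rho = 2)))
        expect_identical(isAmbiguous(assignClasses(sc, rho = 1)),
                         v[2] + v[3] > v[1])
    }
})

test_that("argmax ties break by the fixed class order", {
    sc <- rbind(n1 = c(Oligodendrocyte = 50, Neuron = 50, Astrocyte = 10,
                       OPC = 0, Microglia = 0, Endothelial = 0))
    expect_identical(assignedClass(assignClasses(sc)), "Neuron")
})

test_that("the quality floor is applied to the best score", {
    sc <- rbind(n1 = c(A = 19.9, B = 5, C = 0),
                n2 = c(A = 20, B = 5, C = 0))
    p <- assignClasses(sc, identityMin = 20)
    expect_identical(unname(qualityPass(p)), c(FALSE, TRUE))
    sce <- toySCE(matrix(1, 2, 2))
    out <- filterLowQuality(sce, p)
    expect_identical(ncol(out$sce), 1L)
    expect_identical(as.character(out$log$reason), "identity")
})

test_that("mixed pre-clusters are flagged when two classes tie", {
    enr <- rbind(c1 = c(N = 0.9, A = 0.1, O = 0.0),
                 c2 = c(N = 0.85, A = 0.88, O = 0.1))
    flags <- flagMixed(enr, delta = 0.1)
    expect_identical(unname(flags), c(FALSE, TRUE))
})

test_that("mixed pre-clusters split by argmax class with provenance", {
    scores <- rbind(matrix(rep(c(80, 10), each = 6), 6, 2, byrow = FALSE),
                    matrix(rep(c(10, 80), each = 4), 4, 2, byrow = FALSE))
    colnames(scores) <- c("Astrocyte", "Neuron")
    rownames(scores) <- sprintf("n%02d", 1:10)
    prof <- assignClasses(scores)
    pre <- rep("7", 10)
    res <- resolveMixedPreclusters(pre, c(`7` = TRUE), prof)
    expect_identical(
        as.integer(table(res$resolved)[c("Astrocyte_r7", "Neuron_r7")]),
        c(6L, 4L))
    expect_true(all(res$reassigned))
    # clean clusters pass through untouched
    res2 <- resolveMixedPreclusters(pre, c(`7` = FALSE), prof)
    expect_identical(unique(res2$resolved), "7")
    expect_false(any(res2$reassigned))
})

test_that("resolving a deliberately merged pre-cluster restores purity", {
    sce <- smallCohort(seed = 31L, nPerClass = 40L, nGenes = 600L,
                       doubletRate = 0)
    truth <- simTruth(sce)
    prof <- assignClasses(identityScores(sce))
    # merge all astrocytes and neurons into one fake pre-cluster
    pre <- ifelse(truth$true_class %in% c("Astrocyte", "Neuron"),
                  "1", "2")
    res <- resolveMixedPreclusters(pre, c(`1` = TRUE, `2` = FALSE), prof)
    merged <- pre == "1"
    purity <- vapply(split(truth$true_class[merged], res$resolved[merged]),
                     function(cl) max(table(cl)) / length(cl), numeric(1))
    expect_true(all(purity >= 0.95))
})

test_that("master classes come from enrichment for clean clusters", {
    enr <- rbind(`1` = c(Neuron = 0.9, Astrocyte = -0.5),
                 `2` = c(Neuron = -0.2, Astrocyte = 0.8))
    scores <- rbind(n1 = c(Neuron = 80, Astrocyte = 10),
                    n2 = c(Neuron = 10, Astrocyte = 80),
                    n3 = c(Neuron = 10, Astrocyte = 80))
    prof <- assignClasses(scores)
    res <- resolveMixedPreclusters(c("1", "2", "2"),
                                   c(`1` = FALSE, `2` = FALSE), prof)
    expect_identical(unname(masterClasses(res, enr)),
                     c("Neuron", "Astrocyte", "Astrocyte"))
})
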