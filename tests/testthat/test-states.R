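# independent rule-table oracle: literal conjunctions of the printed rules
stateOracle <- function(s, m, g) {
    hits <- c(
        Quiescent = s >= 2 && m < 4 && g < 3,
        State1Q   = s >= 2 && m >= 4 && g < 3,
        State2R   = s < 2 && m >= 4 && g >= 3,
        State3R   = s < 2 && m < 4 && g >= 3)
    if (sum(hits) == 0) "Unknown"
    else if (sum(hits) > 1) "Ambiguous"
    else names(hits)[hits]
}

test_that("single triplets classify as the printed rules dictate", {
    rules <- defaultStateRules()
    expect_equal(as.character(classifyState(
        cbind(SLC1A2 = 3.0, MT2A = 1.0, GFAP = 0.5), rules)), "Quiescent")
    expect_equal(as.character(classifyState(
        cbind(SLC1A2 = 1.0, MT2A = 5.0, GFAP = 4.0), rules)), "State2R")
    expect_equal(as.character(classifyState(
        cbind(SLC1A2 = 3.0, MT2A = 1.0, GFAP = 5.0), rules)), "Unknown")
    expect_error(classifyState(cbind(SLC1A2 = NaN, MT2A = 1, GFAP = 1)),
                 "non-finite")
})

test_that("grid enumeration matches the oracle with no ambiguity", {
    grid <- expand.grid(SLC1A2 = 0:6, MT2A = 0:6, GFAP = 0:6)
    calls <- classifyState(as.matrix(grid))
    oracle <- mapply(stateOracle, grid$SLC1A2, grid$MT2A, grid$GFAP)
    expect_identical(as.character(calls), unname(oracle))
    expect_equal(sum(calls == "Ambiguous"), 0L)
    expect_gt(sum(calls == "Unknown"), 0L)
})

test_that("boundary conventions follow the printed inequalities", {
    # exactly at the thresholds: >= fires, < does not
    expect_equal(as.character(classifyState(
        cbind(SLC1A2 = 2, MT2A = 4, GFAP = 0))), "State1Q")
    expect_equal(as.character(classifyState(
        cbind(SLC1A2 = 0, MT2A = 4, GFAP = 3))), "State2R")
})

test_that("rule sets with overlapping patterns are rejected at load", {
    expect_error(new("StateRuleSet",
        thresholds = c(SLC1A2 = 2, MT2A = 4, GFAP = 3),
        rules = data.frame(state = c("A", "B"),
                           SLC1A2 = c("ge", "ge"), MT2A = c("lt", "lt"),
                           GFAP = c("lt", "lt"))),
        "mutually exclusive")
})

test_that("raising the GFAP threshold only demotes reactive calls", {
    set.seed(50)
    trip <- cbind(SLC1A2 = runif(500, 0, 6), MT2A = runif(500, 0, 6),
                  GFAP = runif(500, 0, 6))
    lo <- classifyState(trip, defaultStateRules(gfap = 3))
    hi <- classifyState(trip, defaultStateRules(gfap = 4))
    changed <- lo != hi
    reactive <- c("State2R", "State3R")
    expect_true(all(lo[changed] %in% c(reactive, "Unknown")))
    expect_false(any(hi[changed] %in% reactive))
})

test_that("state composition is a per-condition proportion table", {
    calls <- factor(c(rep("Quiescent", 10), rep("State1Q", 10)),
                    levels = stateLevels())
    comp <- stateComposition(calls, rep("Control", 20))
    expect_equal(comp["Control", "Quiescent"], 0.5)
    expect_equal(rowSums(comp), c(Control = 1), tolerance = 1e-9)
    expect_warning(
        comp2 <- stateComposition(calls,
                                  factor(rep("Control", 20),
                                         levels = c("Control", "HD"))),
        "no astrocytes")
    expect_identical(rownames(comp2), "Control")
})

test_that("planted state mixtures are recovered within sampling error", {
    cfg <- simConfig(nPerClass = 500L, nGenes = 600L, doubletRate = 0,
                     seed = 51L)
    sce <- simulateCohort(cfg)
    truth <- simTruth(sce)
    astro <- truth$true_class == "Astrocyte"
    comp <- stateComposition(factor(truth$true_state[astro],
                                    levels = stateLevels()),
                             truth$condition[astro])
    for (cond in rownames(cfg@stateMix)) {
        n <- sum(astro & truth$condition == cond)
        for (st in colnames(cfg@stateMix)) {
            p <- cfg@stateMix[cond, st]
            se <- sqrt(p * (1 - p) / n)
            expect_lt(abs(comp[cond, st] - p), 3 * se + 1e-9)
        }
    }
})

test_that("the cluster-by-state crosstab preserves cluster sizes", {
    calls <- factor(rep("State1Q", 15), levels = stateLevels())
    tab <- clusterStateCrosstab(calls, rep(c("c1", "c2", "c3"), each = 5))
    expect_equal(sum(tab > 0), 3L)
    expect_equal(unname(rowSums(tab)), c(5, 5, 5))
})

test_that("shuffled labels show independence, planted coupling does not", {
    set.seed(52)
    cramersV <- function(tab) {
        tab <- tab[, colSums(tab) > 0, drop = FALSE]
        chi <- suppressWarnings(chisq.test(tab)$statistic)
        sqrt(chi / (sum(tab) * (min(dim(tab)) - 1)))
    }
    # planted coupling: each cluster is dominated by one state
    states <- c("Quiescent", "State1Q", "State2R")
    cl <- rep(c("c1", "c2", "c3"), each = 60)
    coupled <- factor(ifelse(runif(180) < 0.8,
                             states[as.integer(factor(cl))],
                             sample(states, 180, TRUE)),
                      levels = stateLevels())
    expect_gte(unname(cramersV(clusterStateCrosstab(coupled, cl))), 0.5)
    # shuffled labels: chi-square p is uniform-ish, large on average
    ps <- replicate(20, {
        shuffled <- sample(coupled)
        suppressWarnings(chisq.test(
            clusterStateCrosstab(shuffled, cl)[, 1:3])$p.value)
    })
    expect_gt(mean(ps), 0.01)
})
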