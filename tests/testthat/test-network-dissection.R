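classTable <- function() {
    c(K_A = "kinase", K_B = "kinase", P_A = "phosphatase",
      P_B = "phosphatase", S = "substrate")
}

test_that("DPI removes the weakest edge of a kinase-intermediary triangle", {
    ed <- data.frame(regulator = c("K_A", "K_B", "K_A"),
                     target = c("K_B", "S", "S"),
                     mi = c(0.6, 0.5, 0.3))
    out <- dpiPrune(ed, classTable(), mode = "stdpi")
    expect_equal(nrow(out), 2)
    expect_false(any(out$regulator == "K_A" & out$target == "S"))
    expect_equal(nrow(dpiPrune(ed, classTable(), mode = "dpi")), 2)
})

test_that("stDPI assesses exactly the kinase-intermediary triangle types", {
    # all four (R1 class, R2 class) combinations with R1->T weakest
    combos <- expand.grid(r1 = c("K_A", "P_A"), r2 = c("K_B", "P_B"),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
        r1 <- combos$r1[i]; r2 <- combos$r2[i]
        ed <- data.frame(regulator = c(r1, r2, r1),
                         target = c(r2, "S", "S"),
                         mi = c(0.6, 0.5, 0.3))
        st <- dpiPrune(ed, classTable(), mode = "stdpi")
        dp <- dpiPrune(ed, classTable(), mode = "dpi")
        expect_equal(nrow(dp), 2)              # plain DPI always prunes
        if (classTable()[[r2]] == "kinase") {
            expect_equal(nrow(st), 2)          # K-K-S and P-K-S assessed
        } else {
            expect_equal(nrow(st), 3)          # K-P-S and P-P-S never pruned
        }
    }
})

test_that("DPI keeps the triangle when the cross edge is not the minimum", {
    ed <- data.frame(regulator = c("K_A", "K_B", "K_A"),
                     target = c("K_B", "S", "S"),
                     mi = c(0.3, 0.5, 0.6))
    expect_equal(nrow(dpiPrune(ed, classTable(), mode = "dpi")), 3)
})

test_that("tolerance relaxes the pruning rule", {
    ed <- data.frame(regulator = c("K_A", "K_B", "K_A"),
                     target = c("K_B", "S", "S"),
                     mi = c(0.6, 0.5, 0.45))
    expect_equal(nrow(dpiPrune(ed, classTable(), tolerance = 0.1)), 3)
    expect_equal(nrow(dpiPrune(ed, classTable(), tolerance = 0)), 2)
})

test_that("nodes without a class are rejected", {
    ed <- data.frame(regulator = "X", target = "Y", mi = 1)
    expect_error(dpiPrune(ed, classTable()), "without a class")
})

test_that("Poisson consensus keeps consistently supported edges", {
    # edge a->b in every bootstrap, a->c in one, plus background edges so the
    # Poisson rate is well defined
    m <- makeTinySet(nSites = 4, nRuns = 20, seed = 3)
    ids <- siteIds(m)
    boot <- lapply(1:50, function(b) {
        ed <- data.frame(regulator = ids[1], target = ids[2], mi = 0.5)
        if (b == 1)
            ed <- rbind(ed, data.frame(regulator = ids[1], target = ids[3],
                                       mi = 0.2))
        ed
    })
    spec <- candidateSpec(kinases = ids[1])
    net <- consensusNetwork(boot, m, spec)
    expect_equal(nrow(net), 1)
    expect_equal(net$target, ids[2])
    expect_equal(net$support, 50L)
    expect_true(net$pvalue > 0 && net$pvalue <= 1)
})

test_that("empty bootstraps yield an empty network with a warning", {
    m <- makeTinySet(nSites = 3, nRuns = 10)
    spec <- candidateSpec(kinases = siteIds(m)[1])
    expect_warning(
        net <- consensusNetwork(replicate(3, data.frame(
            regulator = character(), target = character(), mi = numeric()),
            simplify = FALSE), m, spec),
        "no edges")
    expect_equal(nrow(net), 0)
})

test_that("bootstrapNetwork validates its inputs", {
    sim <- simulatePhospho(simConfig(nKinases = 2, nPhosphatases = 1,
                                     nSubstrates = 30, targetsPerEnzyme = 10,
                                     nSamples = 40, seed = 2))
    spec <- candidateSpec(kinases = sim$truth$kinases)
    expect_error(bootstrapNetwork(sim$phospho, spec, nBoot = 1), "at least 2")
    expect_error(candidateSpec(kinases = "A", phosphatases = "A"),
                 "disjoint")
})

test_that("reference-network mode restricts the output to listed edges", {
    sim <- simulatePhospho(simConfig(nKinases = 2, nPhosphatases = 0,
                                     nSubstrates = 40, targetsPerEnzyme = 20,
                                     effectRho = 0.7, lodQuantile = 0.2,
                                     nSamples = 80, seed = 6))
    tr <- sim$truth$edges[sim$truth$edges$type == "direct", ]
    # true edges plus many decoys: the second kinase's substrates are
    # independent of the first, so decoy support stays near zero
    k1 <- sim$truth$kinases[1]; k2 <- sim$truth$kinases[2]
    ref <- rbind(
        data.frame(regulator = tr$regulator[1:15], target = tr$target[1:15],
                   prior = seq(0.3, 1, length.out = 15)),
        data.frame(regulator = k1, target = tr$target[tr$regulator == k2],
                   prior = 0.5),
        data.frame(regulator = k2, target = tr$target[tr$regulator == k1],
                   prior = 0.5))
    ref <- ref[!duplicated(paste(ref$regulator, ref$target)), ]
    spec <- candidateSpec(kinases = sim$truth$kinases,
                          mode = "reference-network", referenceEdges = ref)
    net <- dissect(sim$phospho, spec, dpi = "none", nBoot = 20, seed = 4)
    expect_gt(nrow(net), 0)
    expect_true(all(paste(net$regulator, net$target) %in%
                    paste(ref$regulator, ref$target)))
    expect_true(all(!is.na(net$prior)))
})

test_that("signed mode enforces the correlation-sign constraint", {
    sim <- simulatePhospho(simConfig(nKinases = 2, nPhosphatases = 2,
                                     nSubstrates = 80, targetsPerEnzyme = 20,
                                     effectRho = 0.7, lodQuantile = 0.2,
                                     nSamples = 100, seed = 7))
    spec <- candidateSpec(kinases = sim$truth$kinases,
                          phosphatases = sim$truth$phosphatases,
                          mode = "signed-enzyme-list")
    net <- dissect(sim$phospho, spec, dpi = "none", nBoot = 20, seed = 4)
    isKin <- net$regulator %in% sim$truth$kinases
    expect_true(all(net$rho[isKin] > 0))
    expect_true(all(net$rho[!isKin] < 0))
})

test_that("dissect is deterministic for a fixed seed", {
    sim <- simulatePhospho(simConfig(nKinases = 2, nPhosphatases = 1,
                                     nSubstrates = 30, targetsPerEnzyme = 10,
                                     nSamples = 50, seed = 9))
    spec <- candidateSpec(kinases = sim$truth$kinases,
                          phosphatases = sim$truth$phosphatases)
    n1 <- dissect(sim$phospho, spec, dpi = "stdpi", nBoot = 20, seed = 5)
    n2 <- dissect(sim$phospho, spec, dpi = "stdpi", nBoot = 20, seed = 5)
    expect_identical(n1, n2)
})

test_that("protein-level dissection aggregates regulator rows", {
    sim <- simulatePhospho(simConfig(nKinases = 2, nPhosphatases = 0,
                                     nSubstrates = 60, targetsPerEnzyme = 20,
                                     effectRho = 0.55, lodQuantile = 0.3,
                                     nSamples = 100, seed = 10))
    spec <- candidateSpec(kinases = sim$truth$kinases)
    net <- dissect(sim$phospho, spec, level = "protein", dpi = "none",
                   nBoot = 40, seed = 2)
    expect_true(all(grepl(":PA$", net$regulator)))
    expect_gt(nrow(net), 0)
})

test_that("network TSV round-trips", {
    net <- data.frame(regulator = "a", target = "b", mi = 0.5,
                      support = 10L, pvalue = 0.01, rho = 0.4,
                      prior = NA_real_)
    f <- withr::local_tempfile()
    writeNetwork(net, f)
    expect_equal(readNetwork(f)$mi, net$mi)
})
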