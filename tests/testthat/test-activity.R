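test_that("signatures impute row-min plus bounded noise and score z ranks", {
    m <- matrix(c(10, 12, NA, 11,
                  20, 20, 20, 20,
                  5, 9, 7, 8), 3, 4, byrow = TRUE,
                dimnames = list(c("A:P1:S1", "B:P2:S2", "C:P3:S3"),
                                paste0("r", 1:4)))
    imp <- imputeLowNoise(m, seed = 1)
    expect_true(imp[1, 3] >= 10 && imp[1, 3] < 12)
    sig <- makeSignature(m, test = "r4", reference = paste0("r", 1:3),
                         seed = 1)
    expect_equal(length(sigScores(sig)), 3)
    # identical test and reference values score 0 before rank mapping;
    # with every feature tied the mapped scores are all exactly 0
    mm <- matrix(15, 3, 4, dimnames = dimnames(m))
    sigFlat <- makeSignature(mm, test = "r4", reference = paste0("r", 1:3))
    expect_true(all(sigFlat@scores == 0))
})

test_that("signature null ensembles share the feature space", {
    m <- intensities(makeTinySet(nSites = 20, nRuns = 12, seed = 2))
    sig <- makeSignature(m, test = 1, reference = 2:12, nullSize = 25,
                         seed = 3)
    expect_equal(dim(sigNull(sig)), c(20L, 25L))
    expect_equal(rownames(sigNull(sig)), names(sigScores(sig)))
})

test_that("enrichment NES is large for coherent top-ranked targets", {
    sc <- structure(c(seq(3, 2, length.out = 10), rnorm(190)),
                    names = sprintf("F%03d", 1:200))
    sig <- new("Signature", scores = sc, null = matrix(numeric(), 200, 0),
               sample = "s")
    s <- Signalon("R", data.frame(target = names(sc)[1:10], weight = 1,
                                  mode = 1))
    expect_gt(enrichmentNES(sig, s), 3)
})

test_that("negating all modes exactly negates the NES", {
    sig <- makeRandomSignature(seed = 4)
    withr::with_seed(5, {
        tg <- data.frame(target = sample(names(sigScores(sig)), 20),
                         weight = runif(20, 0.2, 1),
                         mode = runif(20, -1, 1))
    })
    n1 <- enrichmentNES(sig, Signalon("R", tg))
    tg2 <- tg; tg2$mode <- -tg2$mode
    n2 <- enrichmentNES(sig, Signalon("R", tg2))
    expect_equal(n1, -n2, tolerance = 1e-12)
})

test_that("undersized signalons are rejected by enrichment", {
    sig <- makeRandomSignature(seed = 6)
    s <- Signalon("R", data.frame(target = names(sigScores(sig))[1:3],
                                  weight = 1, mode = 1))
    expect_error(enrichmentNES(sig, s), "minimum")
})

test_that("empirical null calibration has the right p-value floor", {
    nullNes <- seq(-2, 2, length.out = 1000)
    atMedian <- empiricalNullNES(0, nullNes)
    expect_gt(atMedian$pvalue, 0.95)
    beyond <- empiricalNullNES(10, nullNes)
    expect_lte(beyond$pvalue, 2 / 1001 + 1e-12)
    expect_gt(beyond$nes, 5)
})

test_that("measureActivity returns a calibrated ActivitySet", {
    sim <- simulatePhospho(simConfig(nKinases = 3, nPhosphatases = 0,
                                     nSubstrates = 60, targetsPerEnzyme = 20,
                                     effectRho = 0.7, lodQuantile = 0.2,
                                     nSamples = 40, seed = 11))
    tr <- sim$truth$edges[sim$truth$edges$type == "direct", ]
    sl <- SignalonList(lapply(sim$truth$kinases, function(k) {
        tg <- tr$target[tr$regulator == k]
        Signalon(k, data.frame(target = tg, weight = 1, mode = 1))
    }))
    am <- measureActivity(sim$phospho, sl, nullSize = 50, seed = 2)
    expect_s4_class(am, "ActivitySet")
    expect_equal(dim(nes(am)), c(3L, 40L))
    expect_true(all(activityPvalues(am) > 0 & activityPvalues(am) <= 1))
    # inferred activity tracks the truth
    rec <- recoveryReport(data.frame(regulator = character(),
                                     target = character()),
                          sim$truth, am)
    expect_gt(rec$medianActivitySpearman, 0.6)
})

test_that("activity TSV export writes NES and p-values", {
    am <- ActivitySet(matrix(c(1, -2), 2, 1,
                             dimnames = list(c("a", "b"), "s1")))
    f <- withr::local_tempfile()
    writeActivity(am, f)
    expect_true(file.exists(paste0(f, ".pvalues")))
    got <- read.delim(f)
    expect_equal(got$s1, c(1, -2))
})

test_that("crosstalk CDE and Stouffer integration match closed forms", {
    expect_equal(crosstalkCDE(1e-4, 1e-2), 2, tolerance = 1e-12)
    expect_equal(crosstalkCDE(0.05, 0.05), 0, tolerance = 1e-12)
    expect_equal(stoufferIntegrate(2, 2), 2 * sqrt(2), tolerance = 1e-12)
    expect_equal(stoufferIntegrate(2, NA), 2)
    expect_equal(stoufferIntegrate(NA, -1.5), -1.5)
})

test_that("crosstalk correction nullifies shared targets at equal p", {
    withr::with_seed(12, {
        nFeat <- 200
        feats <- sprintf("F%03d", 1:nFeat)
        m <- matrix(rnorm(nFeat * 21, 20), nFeat, 21,
                    dimnames = list(feats, c(paste0("ref", 1:20), "test")))
        shared <- feats[1:20]
        m[shared, "test"] <- m[shared, "test"] + 3
    })
    # two signalons with identical targets: p ties, CDE = 0, the weaker
    # (smaller |NES|) loses its shared contribution entirely
    sl <- SignalonList(list(
        A = Signalon("A", data.frame(target = shared, weight = 1, mode = 1)),
        B = Signalon("B", data.frame(target = c(shared[1:15], feats[101:105]),
                                     weight = 1, mode = 1))))
    amU <- measureActivity(m, sl, test = "test",
                           reference = paste0("ref", 1:20),
                           nullSize = 50, crosstalk = FALSE, seed = 3)
    amC <- measureActivity(m, sl, test = "test",
                           reference = paste0("ref", 1:20),
                           nullSize = 50, crosstalk = TRUE, seed = 3)
    expect_lt(abs(nes(amC)["B", 1]), abs(nes(amU)["B", 1]))
    expect_equal(nes(amC)["A", 1], nes(amU)["A", 1])
})

test_that("hierarchical measurement falls back to the phosphostate level", {
    sim <- simulatePhospho(simConfig(nKinases = 3, nPhosphatases = 0,
                                     nSubstrates = 60, targetsPerEnzyme = 20,
                                     effectRho = 0.7, lodQuantile = 0.2,
                                     nSamples = 40, seed = 13))
    tr <- sim$truth$edges[sim$truth$edges$type == "direct", ]
    sl <- SignalonList(lapply(sim$truth$kinases, function(k) {
        Signalon(k, data.frame(target = tr$target[tr$regulator == k],
                               weight = 1, mode = 1))
    }))
    spec <- candidateSpec(kinases = sim$truth$kinases)
    hm <- hierarchicalMeasure(sim$phospho, sl, spec, nBoot = 20, seed = 4)
    expect_s4_class(hm$integrated, "ActivitySet")
    # independent regulators: the AL pass adds nothing or is empty; either
    # way the integrated level tag reflects what was available
    expect_true(activityLevel(hm$integrated) %in%
                c("phosphostate", "integrated"))
    expect_equal(ncol(nes(hm$integrated)), 40L)
})
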