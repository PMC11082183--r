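test_that("mode of regulation separates activated and repressed targets", {
    withr::with_seed(1, {
        rhos <- c(rnorm(40, 0.6, 0.08), rnorm(40, -0.6, 0.08),
                  rnorm(20, 0, 0.05))
    })
    modes <- modeOfRegulation(rhos, seed = 2)
    expect_true(all(modes[1:40] > 0.8))
    expect_true(all(modes[41:80] < -0.8))
    expect_true(all(abs(modes[81:100]) < 0.5))
})

test_that("mode of regulation is antisymmetric under sign flips", {
    withr::with_seed(2, {
        rhos <- c(rnorm(30, 0.5, 0.1), rnorm(30, -0.4, 0.1))
    })
    m1 <- modeOfRegulation(rhos, seed = 3)
    m2 <- modeOfRegulation(-rhos, seed = 3)
    expect_equal(m1, -m2, tolerance = 0.15)
})

test_that("small target lists fall back to the linear ramp", {
    rhos <- c(0.9, -0.9, 0.2, -0.3, 0.6)
    expect_equal(modeOfRegulation(rhos),
                 sign(rhos) * pmin(1, abs(rhos) / 0.5))
    expect_equal(modeOfRegulation(rep(0.4, 20)), rep(1, 20))  # degenerate
})

test_that("signalon weights normalize by network maximum and priors", {
    expect_equal(signalonWeights(c(0.4, 0.8), networkMaxMi = 0.8), c(0.5, 1))
    # priors normalized by per-regulator maximum, then multiplied
    expect_equal(signalonWeights(c(0.8, 0.8), networkMaxMi = 0.8,
                                 priors = c(0.2, 0.4)), c(0.5, 1))
    expect_equal(signalonWeights(0.8, 0.8, priors = 0)[1], 0)
    expect_error(signalonWeights(c(0, 0), networkMaxMi = 0), "all-zero")
})

test_that("trimming accumulates squared normalized weights to the threshold", {
    tg <- data.frame(target = c("a", "b", "c"), weight = c(1, 0.5, 0.5))
    expect_equal(nrow(trimSignalon(tg, tTarget = 1.4)), 3)  # cum (1,1.25,1.5)
    expect_equal(nrow(trimSignalon(tg, tTarget = 1.2)), 2)
    expect_error(trimSignalon(tg, tTarget = 0), "positive")
    # hard cap at nMax even when the threshold is never reached
    big <- data.frame(target = sprintf("t%d", 1:600), weight = rep(1, 600))
    expect_equal(nrow(trimSignalon(big, nMax = 500L, tTarget = Inf)), 500)
    # output is a prefix of the sorted input
    out <- trimSignalon(tg, tTarget = 1.2)
    expect_equal(out$target, tg$target[seq_len(nrow(out))])
})

test_that("buildSignalons filters by minimum size and round-trips", {
    net <- data.frame(
        regulator = rep(c("K1", "K2"), c(8, 3)),
        target = sprintf("t%d", 1:11),
        mi = seq(0.8, 0.3, length.out = 11),
        support = 50L, pvalue = 0.001,
        rho = c(rep(0.5, 8), rep(-0.5, 3)), prior = NA_real_)
    sl <- buildSignalons(net, minSize = 5L, seed = 1)
    expect_equal(names(sl), "K1")                 # K2 below minimum size
    expect_equal(max(targets(sl[["K1"]])$weight), 1)
    f <- withr::local_tempfile()
    writeSignalons(sl, f)
    sl2 <- readSignalons(f)
    expect_equal(targets(sl2[["K1"]]), targets(sl[["K1"]]))
})

test_that("optimization selects the signalon with the best enrichment", {
    withr::with_seed(4, {
        nFeat <- 200
        feats <- sprintf("F%03d", 1:nFeat)
        wins <- 0L
        for (i in 1:100) {
            sc <- structure(rnorm(nFeat), names = feats)
            good <- sample(feats, 15)
            sc[good] <- sc[good] + 2
            sig <- new("Signature", scores = sc,
                       null = matrix(numeric(), nFeat, 0), sample = "s")
            correct <- Signalon("R", data.frame(target = good, weight = 1,
                                                mode = 1), source = "good")
            scrambled <- Signalon("R", data.frame(
                target = sample(setdiff(feats, good), 15), weight = 1,
                mode = 1), source = "bad")
            win <- optimizeSignalons(list(correct, scrambled), list(sig))
            if (signalonSource(win[[1]]) == "good") wins <- wins + 1L
        }
        expect_gte(wins, 90L)
    })
})

test_that("single candidates pass through optimization unchanged", {
    sig <- makeRandomSignature(seed = 5)
    s <- Signalon("R", data.frame(target = names(sigScores(sig))[1:10],
                                  weight = 1, mode = 1))
    out <- optimizeSignalons(list(s), list(sig))
    expect_equal(targets(out[[1]]), targets(s))
})

test_that("deduplication drops the hub of correlated signalon groups", {
    # activity profiles with pairwise correlations (.9, .9, .2)
    withr::with_seed(6, {
        base <- rnorm(60)
        act <- rbind(s1 = base + rnorm(60, 0, 0.1),
                     s2 = base + rnorm(60, 0, 0.1),
                     s3 = rnorm(60))
        act["s3", ] <- act["s3", ] + 0.25 * base
    })
    sl <- SignalonList(lapply(c("s1", "s2", "s3"), function(r)
        Signalon(r, data.frame(target = sprintf("t%d", 1:5), weight = 1,
                               mode = 1))))
    kept <- deduplicateSignalons(sl, act, cutoff = 0.5)
    expect_lt(length(kept), 3L)
    expect_true("s3" %in% names(kept))
    # low correlations keep everything
    withr::with_seed(7, act2 <- matrix(rnorm(120), 3,
                                       dimnames = list(c("s1", "s2", "s3"),
                                                       NULL)))
    expect_equal(length(deduplicateSignalons(sl, act2, cutoff = 0.5)), 3L)
})

test_that("deduplication follows the greedy mean-correlation contract", {
    skip_if_not_installed("caret")
    withr::with_seed(8, {
        act <- matrix(rnorm(200), 5)
        act[2, ] <- act[1, ] + rnorm(40, 0, 0.3)
        act[4, ] <- act[1, ] + rnorm(40, 0, 0.4)
        rownames(act) <- paste0("s", 1:5)
    })
    sl <- SignalonList(lapply(rownames(act), function(r)
        Signalon(r, data.frame(target = sprintf("t%d", 1:5), weight = 1,
                               mode = 1))))
    kept <- names(deduplicateSignalons(sl, act, cutoff = 0.5))
    dropRef <- caret::findCorrelation(cor(t(act)), cutoff = 0.5,
                                      exact = TRUE)
    expect_setequal(kept, setdiff(rownames(act), rownames(act)[dropRef]))
})
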