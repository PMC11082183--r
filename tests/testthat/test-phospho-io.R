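test_that("loadPvm keeps the most consistently detected precursor", {
    ps <- loadPvm(makePvmRecords())
    # pepA (4 runs) beats pepB (2 runs) despite pepB's higher intensity
    v <- intensities(ps)["EGFR:P00533:S229", ]
    expect_equal(sum(!is.na(v)), 4)
    expect_true(all(v[paste0("r", 1:4)] < 25))
})

test_that("multi-site peptides yield one identical row per site", {
    ps <- loadPvm(makePvmRecords())
    expect_equal(unname(intensities(ps)["GAB1:Q13480:S206", ]),
                 unname(intensities(ps)["GAB1:Q13480:T212", ]))
})

test_that("precursor ties break by higher median intensity", {
    rec <- makePvmRecords()
    # give pepB the same detection count as pepA but higher intensities
    extra <- rec[rec$peptide_id == "pepB", ][1:2, ]
    extra$run_id <- c("r3", "r4")
    ps <- loadPvm(rbind(rec, extra))
    expect_true(all(intensities(ps)["EGFR:P00533:S229", paste0("r", 1:4)] > 25))
})

test_that("malformed records are rejected with informative errors", {
    rec <- makePvmRecords()
    bad <- rec
    bad$phosphosite[1] <- "X99"
    bad$site_id[1] <- "EGFR:P00533:X99"
    expect_error(loadPvm(bad), "phosphosite")
    bad2 <- rec
    bad2$site_id[3] <- "WRONG:ID:S1"
    expect_error(loadPvm(bad2), "site_id")
    expect_error(loadPvm(rec[0, ]), "nonempty")
})

test_that("loadPvm is idempotent on its own output records", {
    ps <- loadPvm(makePvmRecords())
    ps2 <- loadPvm(pvmRecords(ps))
    expect_equal(intensities(ps2)[siteIds(ps), runIds(ps)[runIds(ps) %in% runIds(ps2)]],
                 intensities(ps)[, runIds(ps) %in% runIds(ps2)])
})

test_that("PVM and matrix files round-trip", {
    rec <- makePvmRecords()
    f <- withr::local_tempfile()
    writePvm(rec, f)
    expect_equal(readPvm(f)$site_id, rec$site_id)
    ps <- loadPvm(rec)
    f2 <- withr::local_tempfile()
    writePhosphoMatrix(ps, f2)
    ps2 <- readPhosphoMatrix(f2)
    expect_equal(intensities(ps2), intensities(ps))
})

test_that("quantile normalization equalizes distributions and centers rows", {
    ps <- makeTinySet(nSites = 30, nRuns = 4)
    m <- intensities(ps)
    m[1, ] <- NA                               # all-missing row
    m[2, 1:2] <- NA
    ps <- PhosphoSet(m)
    qn <- quantileNormalize(ps)
    v <- intensities(qn)
    expect_true(all(is.na(v[1, ])))            # all-missing row unchanged
    expect_equal(is.na(v), is.na(m))           # missingness preserved
    rm_ <- rowMeans(v, na.rm = TRUE)
    expect_true(all(abs(rm_[-1]) < 1e-9))      # row centering
    # two complete runs with identical rank order become identical
    m2 <- cbind(a = sort(rnorm(20)), b = sort(rnorm(20, 5)))
    rownames(m2) <- sprintf("G%d:P%d:S1", 1:20, 1:20)
    qn2 <- quantileNormalize(PhosphoSet(m2), center = FALSE)
    expect_equal(unname(intensities(qn2)[, 1]), unname(intensities(qn2)[, 2]))
})

test_that("quantile normalization preserves within-run rank order", {
    ps <- makeTinySet(nSites = 25, nRuns = 6, seed = 4)
    m <- intensities(ps)
    m[sample(length(m), 30)] <- NA
    qn <- quantileNormalize(PhosphoSet(m), center = FALSE)
    for (j in seq_len(ncol(m))) {
        ok <- !is.na(m[, j])
        expect_equal(order(intensities(qn)[ok, j]), order(m[ok, j]))
    }
})

test_that("single-run groups are skipped with a warning", {
    m <- intensities(makeTinySet(nRuns = 3))
    ps <- PhosphoSet(m, runGroups = c("a", "a", "b"))
    expect_warning(quantileNormalize(ps, byGroup = TRUE), "single run")
})

test_that("protein normalization subtracts in log2 space and passes through", {
    pm <- matrix(c(20, NA, 21, 22), 1, 4,
                 dimnames = list("EGFR:P00533:S229", paste0("r", 1:4)))
    prot <- matrix(c(18, 17, NA, 18), 1, 4,
                   dimnames = list("EGFR:P00533:PA", paste0("r", 1:4)))
    out <- proteinNormalize(PhosphoSet(pm), PhosphoSet(prot))
    v <- intensities(out)[1, ]
    expect_equal(unname(v), c(2, NA, 21, 4))   # protein-missing kept as-is
    # site with no protein row passes through with a message
    pm2 <- rbind(pm, "OTHER:Q00001:S1" = 20)
    rownames(pm2)[1] <- "EGFR:P00533:S229"
    expect_message(proteinNormalize(PhosphoSet(pm2), PhosphoSet(prot)),
                   "passed through")
    expect_error(proteinNormalize(
        PhosphoSet(pm),
        PhosphoSet(matrix(18, 1, 1, dimnames = list("EGFR:P00533:PA", "z1")))),
        "no runs")
})

test_that("protein aggregation averages observed site values", {
    m <- matrix(c(10, 12, 10, NA), 2, 2,
                dimnames = list(c("A:P1:S1", "A:P1:S2"), c("r1", "r2")))
    agg <- aggregateToProtein(PhosphoSet(m))
    expect_equal(nrow(agg), 1)
    expect_equal(unname(intensities(agg)[1, ]), c(11, 10))
    # single-site protein is the identity
    one <- aggregateToProtein(PhosphoSet(m[1, , drop = FALSE]))
    expect_equal(unname(intensities(one)[1, ]), unname(m[1, ]))
})

test_that("protein aggregation never decreases completeness", {
    sim <- simulatePhospho(simConfig(nSamples = 30, seed = 5))
    agg <- aggregateToProtein(sim$phospho)
    rd <- rowData(sim$phospho)
    key <- paste(rd$gene_id, rd$protein_id, "PA", sep = ":")
    before <- tapply(completeness(sim$phospho), key, max)
    expect_true(all(completeness(agg)[names(before)] >= before - 1e-12))
})
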