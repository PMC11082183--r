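# small in-code fixtures shared across test files

# minimal valid PVM record table
makePvmRecords <- function() {
    rec <- function(gene, prot, pep, site, run, val) {
        data.frame(gene_id = gene, protein_id = prot, peptide_id = pep,
                   site_id = paste(gene, prot, site, sep = ":"),
                   modified_peptide_sequence = paste0(pep, "(ph)"),
                   peptide_sequence = pep, phosphosite = site,
                   run_id = run, peptide_intensity = val)
    }
    rbind(
        # two precursors for the same site: pepA detected 4/5, pepB 2/5
        rec("EGFR", "P00533", "pepA", "S229", paste0("r", 1:4), 21 + 1:4 / 10),
        rec("EGFR", "P00533", "pepB", "S229", paste0("r", 1:2), 25 + 1:2 / 10),
        # a doubly phosphorylated peptide covering two sites
        rec("GAB1", "Q13480", "pepC", "S206", paste0("r", 1:5), 18 + 1:5 / 10),
        rec("GAB1", "Q13480", "pepC", "T212", paste0("r", 1:5), 18 + 1:5 / 10),
        # a single-site peptide with a gap
        rec("MK01", "P28482", "pepD", "Y187", paste0("r", c(1, 3, 5)), 19))
}

# tiny complete PhosphoSet
makeTinySet <- function(nSites = 6, nRuns = 5, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(rnorm(nSites * nRuns, 20), nSites, nRuns)
    })
    rownames(m) <- sprintf("G%d:P%05d:S%d", seq_len(nSites), seq_len(nSites),
                           seq_len(nSites))
    colnames(m) <- sprintf("r%d", seq_len(nRuns))
    PhosphoSet(m)
}

# a random signature over nFeat features
makeRandomSignature <- function(nFeat = 300, seed = 1) {
    withr::with_seed(seed, {
        sc <- structure(rnorm(nFeat), names = sprintf("F%03d", seq_len(nFeat)))
    })
    new("Signature", scores = sc,
        null = matrix(numeric(), nFeat, 0), sample = "s1")
}

# independent standard-normal pair with value-dependent (MNAR) censoring
censoredPair <- function(n = 200, lod = 0.5, rho = 0) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    x[x < quantile(x, lod)] <- NA
    y[y < quantile(y, lod)] <- NA
    list(x = x, y = y)
}

# plug-in discrete MI of a 2x2 contingency table (independent oracle for the
# forced-partition check)
pluginMI2x2 <- function(tab) {
    n <- sum(tab)
    p <- tab / n
    pr <- rowSums(p); pc <- colSums(p)
    s <- 0
    for (i in 1:2) for (j in 1:2)
        if (p[i, j] > 0)
            s <- s + unname(p[i, j] * log(p[i, j] / (pr[i] * pc[j])))
    s
}
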