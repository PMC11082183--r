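#' Quantile-normalize and row-center a PhosphoSet
#'
#' Observed values within each run group are quantile normalized against the
#' group's average empirical distribution (missingness-aware: only observed
#' values enter, tied quantiles are averaged; delegated to
#' \code{limma::normalizeQuantiles}), after which every site row is centered
#' to mean 0 over its observed entries. Missing entries stay missing. Groups
#' with a single run cannot be quantile normalized and are skipped with a
#' warning (their rows are still centered).
#'
#' @param x a [PhosphoSet-class].
#' @param byGroup if `TRUE`, normalize within each `runGroups(x)` batch.
#' @param center if `TRUE` (default), row-center over observed entries.
#' @return A normalized [PhosphoSet-class] with identical dimensions and
#'   missingness pattern.
#' @export
quantileNormalize <- function(x, byGroup = FALSE, center = TRUE) {
    stopifnot(is(x, "PhosphoSet"))
    m <- intensities(x)
    groups <- if (byGroup) {
        g <- runGroups(x)
        if (is.null(g)) stop("byGroup = TRUE but no run groups are set")
        g
    } else rep("all", ncol(m))
    out <- m
    for (g in unique(groups)) {
        j <- which(groups == g)
        if (length(j) < 2L) {
            warning("group '", g, "' has a single run; quantile ",
                    "normalization skipped for it")
            next
        }
        out[, j] <- limma::normalizeQuantiles(m[, j, drop = FALSE],
                                              ties = TRUE)
    }
    if (center) {
        rm_ <- rowMeans(out, na.rm = TRUE)
        rm_[!is.finite(rm_)] <- 0
        out <- out - rm_
    }
    ans <- x
    assay(ans, "log2i") <- out
    validObject(ans)
    ans
}

#' Normalize phosphopeptide abundance by protein abundance
#'
#' Subtracts (log2 space) the matching whole-protein abundance row
#' (`GENE:ACCESSION:PA`) from each phosphosite row, entry-wise where both are
#' observed. Where the protein value is missing the phospho value is retained
#' unnormalized, so already-sparse rows are not destroyed; sites with no
#' protein row pass through unchanged (a count is reported).
#'
#' @param phospho a [PhosphoSet-class] of phosphosite rows.
#' @param protein a [PhosphoSet-class] whose rows are keyed
#'   `GENE:ACCESSION:PA`.
#' @return A [PhosphoSet-class] like `phospho` with protein-normalized
#'   values.
#' @export
proteinNormalize <- function(phospho, protein) {
    stopifnot(is(phospho, "PhosphoSet"), is(protein, "PhosphoSet"))
    shared <- intersect(runIds(phospho), runIds(protein))
    if (!length(shared))
        stop("phospho and protein matrices share no runs")
    pm <- intensities(phospho)
    rd <- rowData(phospho)
    protKey <- paste(rd$gene_id, rd$protein_id, "PA", sep = ":")
    hit <- match(protKey, siteIds(protein))
    n_unmatched <- sum(is.na(hit))
    if (n_unmatched)
        message(n_unmatched, " site(s) had no protein abundance row and ",
                "were passed through unnormalized")
    prm <- intensities(protein)
    out <- pm
    for (i in which(!is.na(hit))) {
        pv <- prm[hit[i], match(shared, runIds(protein))]
        j <- match(shared, runIds(phospho))
        both <- !is.na(pm[i, j]) & !is.na(pv)
        out[i, j[both]] <- pm[i, j[both]] - pv[both]
    }
    ans <- phospho
    assay(ans, "log2i") <- out
    ans
}

#' Aggregate phosphosite rows to protein rows
#'
#' Combines the abundance of all phosphosites of one protein into a single
#' row (per-run mean over observed site values); an entry is missing only
#' when every site is missing in that run. Aggregated rows are keyed
#' `GENE:ACCESSION:PA`.
#'
#' @param x a [PhosphoSet-class] of site rows.
#' @return A [PhosphoSet-class] with one row per protein.
#' @export
aggregateToProtein <- function(x) {
    stopifnot(is(x, "PhosphoSet"))
    rd <- rowData(x)
    key <- paste(rd$gene_id, rd$protein_id, "PA", sep = ":")
    m <- intensities(x)
    obs <- !is.na(m)
    mz <- m
    mz[!obs] <- 0
    sums <- rowsum(mz, key)
    cnts <- rowsum(obs + 0, key)
    out <- sums / cnts
    out[cnts == 0] <- NA_real_
    keys <- rownames(out)
    first <- match(keys, key)
    rdOut <- DataFrame(gene_id = rd$gene_id[first],
                       protein_id = rd$protein_id[first],
                       phosphosite = rep("PA", length(keys)),
                       row.names = keys)
    ps <- PhosphoSet(out, rowData = rdOut, runGroups = runGroups(x))
    ps
}
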