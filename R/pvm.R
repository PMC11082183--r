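#' @name pvm-io
#' @title Long-format phosphopeptide (PVM) input and output
#' @description
#' The long-format input table ("PVM") has one row per detected peptide per
#' run with exactly nine columns: `gene_id` (UniProtKB entry name, no
#' species), `protein_id` (UniProtKB accession), `peptide_id`,
#' `site_id` (`GENE:ACCESSION:SITE`), `modified_peptide_sequence`,
#' `peptide_sequence`, `phosphosite` (`S229`-style, or `PA` for whole-protein
#' abundance rows), `run_id`, and `peptide_intensity` (log2). Identifiers are
#' case-sensitive and never remapped.
NULL

.pvm_columns <- c("gene_id", "protein_id", "peptide_id", "site_id",
                  "modified_peptide_sequence", "peptide_sequence",
                  "phosphosite", "run_id", "peptide_intensity")

.checkPvm <- function(records) {
    if (!is.data.frame(records) || nrow(records) == 0L)
        stop("PVM input must be a nonempty data.frame of records")
    missing_cols <- setdiff(.pvm_columns, names(records))
    if (length(missing_cols))
        stop("PVM is missing required columns: ",
             paste(missing_cols, collapse = ", "))
    bad_site <- !grepl("^[STY][0-9]+$", records$phosphosite) &
        records$phosphosite != "PA"
    if (any(bad_site))
        stop("invalid phosphosite identifier in record(s) ",
             paste(utils::head(which(bad_site), 5), collapse = ", "),
             " (e.g. '", records$phosphosite[which(bad_site)[1]],
             "'); expected S/T/Y + position or 'PA'")
    expect_id <- paste(records$gene_id, records$protein_id,
                       records$phosphosite, sep = ":")
    bad_id <- records$site_id != expect_id
    if (any(bad_id))
        stop("site_id does not equal gene_id:protein_id:phosphosite in ",
             "record(s) ", paste(utils::head(which(bad_id), 5), collapse = ", "),
             " (e.g. '", records$site_id[which(bad_id)[1]], "')")
    if (any(!is.finite(records$peptide_intensity) &
            !is.na(records$peptide_intensity)))
        stop("peptide_intensity must be finite where present")
    invisible(records)
}

#' Load a PVM record table into a PhosphoSet
#'
#' Pivots long-format records to one row per `site_id`. When a phosphosite is
#' represented by multiple peptide precursors, the most consistently detected
#' precursor (highest count of runs with an observed intensity) is kept, with
#' ties broken by higher median intensity. Peptides carrying multiple
#' phosphosites appear once per site, so such sites share one intensity
#' vector.
#'
#' @param records data.frame of PVM records (see [pvm-io]).
#' @param runGroups optional named vector mapping run ids to group labels.
#' @return A [PhosphoSet-class] with one row per site.
#' @examples
#' rec <- data.frame(gene_id = "EGFR", protein_id = "P00533",
#'                   peptide_id = "pep1", site_id = "EGFR:P00533:S229",
#'                   modified_peptide_sequence = "SEQ(ph)", peptide_sequence = "SEQ",
#'                   phosphosite = "S229", run_id = c("r1", "r2"),
#'                   peptide_intensity = c(21.2, 20.8))
#' loadPvm(rec)
#' @export
loadPvm <- function(records, runGroups = NULL) {
    .checkPvm(records)
    runs <- unique(records$run_id)
    # choose one precursor per site: detection count, then median intensity
    det <- records[!is.na(records$peptide_intensity), , drop = FALSE]
    key <- paste(det$site_id, det$peptide_id, sep = "\r")
    counts <- tapply(det$peptide_intensity, key, length)
    meds <- tapply(det$peptide_intensity, key, median)
    kk <- strsplit(names(counts), "\r", fixed = TRUE)
    cand <- data.frame(site_id = vapply(kk, `[`, "", 1L),
                       peptide_id = vapply(kk, `[`, "", 2L),
                       n = as.vector(counts), med = as.vector(meds))
    cand <- cand[order(cand$site_id, -cand$n, -cand$med, cand$peptide_id), ]
    best <- cand[!duplicated(cand$site_id), c("site_id", "peptide_id")]
    sel <- records[paste(records$site_id, records$peptide_id, sep = "\r") %in%
                   paste(best$site_id, best$peptide_id, sep = "\r"), ]
    sites <- sort(unique(best$site_id))
    m <- matrix(NA_real_, length(sites), length(runs),
                dimnames = list(sites, runs))
    m[cbind(match(sel$site_id, sites), match(sel$run_id, runs))] <-
        sel$peptide_intensity
    ann <- sel[!duplicated(sel$site_id),
               c("site_id", "gene_id", "protein_id", "phosphosite")]
    ann <- ann[match(sites, ann$site_id), ]
    rd <- DataFrame(gene_id = ann$gene_id, protein_id = ann$protein_id,
                    phosphosite = ann$phosphosite, row.names = sites)
    grp <- if (!is.null(runGroups)) unname(runGroups[runs]) else NULL
    PhosphoSet(m, rowData = rd, runGroups = grp)
}

#' Read / write PVM tables
#'
#' Tab-separated long format with exactly the nine PVM header names; missing
#' intensities may be encoded as empty cells or `NA`.
#'
#' @param path file path.
#' @return `readPvm()`: a data.frame of PVM records.
#' @rdname pvm-files
#' @export
readPvm <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    .checkPvm(df)
}

#' @param records PVM record data.frame.
#' @rdname pvm-files
#' @return `writePvm()`: the path, invisibly.
#' @export
writePvm <- function(records, path) {
    .checkPvm(records)
    write.table(records[.pvm_columns], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Rebuild PVM records from a PhosphoSet
#'
#' Inverse of [loadPvm()] up to precursor selection: one record per observed
#' site x run, with the site id standing in for the peptide identifiers.
#'
#' @param x a [PhosphoSet-class].
#' @return A PVM record data.frame (see [pvm-io]).
#' @export
pvmRecords <- function(x) {
    stopifnot(is(x, "PhosphoSet"))
    m <- intensities(x)
    obs <- which(!is.na(m), arr.ind = TRUE)
    rd <- rowData(x)
    i <- obs[, 1]
    data.frame(gene_id = rd$gene_id[i], protein_id = rd$protein_id[i],
               peptide_id = rownames(m)[i], site_id = rownames(m)[i],
               modified_peptide_sequence = rownames(m)[i],
               peptide_sequence = rownames(m)[i],
               phosphosite = rd$phosphosite[i],
               run_id = colnames(m)[obs[, 2]],
               peptide_intensity = m[obs],
               row.names = NULL)
}

#' Read / write wide site-by-run matrices
#'
#' Wide TSV with `site_id` as first column and run ids as remaining columns;
#' missing values are empty cells.
#'
#' @param x a [PhosphoSet-class].
#' @param path file path.
#' @rdname matrix-files
#' @return `writePhosphoMatrix()`: the path invisibly;
#'   `readPhosphoMatrix()`: a [PhosphoSet-class].
#' @export
writePhosphoMatrix <- function(x, path) {
    stopifnot(is(x, "PhosphoSet"))
    df <- data.frame(site_id = siteIds(x), intensities(x),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' @rdname matrix-files
#' @export
readPhosphoMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
    stopifnot(names(df)[1] == "site_id")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$site_id
    storage.mode(m) <- "double"
    PhosphoSet(m)
}
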