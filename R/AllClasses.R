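#' PhosphoSet: sites-by-runs log2 abundance matrix with explicit missingness
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' phosphosite (or protein) by run matrix of log2 intensities in assay
#' `"log2i"`. Missing entries (peptides not detected in a run, typically
#' censored below the limit of detection) are `NA`; the observed mask is
#' derived, not stored. Row metadata carries the site annotation
#' (`gene_id`, `protein_id`, `phosphosite`), column metadata optionally a
#' `group` label used for batch-wise normalization.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @aliases PhosphoSet
#' @exportClass PhosphoSet
setClass("PhosphoSet", contains = "SummarizedExperiment")

.validPhosphoSet <- function(object) {
    msg <- NULL
    if (!"log2i" %in% assayNames(object))
        msg <- c(msg, "assay 'log2i' is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "site ids (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "run ids (colnames) must be unique")
    v <- assay(object, "log2i")
    if (any(is.infinite(v)))
        msg <- c(msg, "observed intensities must be finite (missing = NA)")
    if (is.null(msg)) TRUE else msg
}
setValidity("PhosphoSet", .validPhosphoSet)

#' Construct a PhosphoSet
#'
#' @param values numeric matrix, sites x runs, log2 intensities, `NA` missing.
#'   Must have unique rownames (site ids) and colnames (run ids).
#' @param rowData optional data.frame/DataFrame of site annotations
#'   (`gene_id`, `protein_id`, `phosphosite`); parsed from
#'   `GENE:ACCESSION:SITE` rownames when omitted.
#' @param runGroups optional character vector of per-run group labels
#'   (batches) for group-wise normalization.
#' @return A [PhosphoSet-class] object.
#' @examples
#' m <- matrix(rnorm(12, 20), 3, 4,
#'             dimnames = list(c("A:P1:S1", "B:P2:S5", "B:P2:T9"),
#'                             paste0("run", 1:4)))
#' ps <- PhosphoSet(m)
#' completeness(ps)
#' @export
PhosphoSet <- function(values, rowData = NULL, runGroups = NULL) {
    stopifnot(is.matrix(values), !is.null(rownames(values)),
              !is.null(colnames(values)))
    if (is.null(rowData)) {
        parts <- strsplit(rownames(values), ":", fixed = TRUE)
        ok <- lengths(parts) == 3L
        rowData <- DataFrame(
            gene_id = vapply(parts, function(p) if (length(p) == 3L) p[1] else NA_character_, ""),
            protein_id = vapply(parts, function(p) if (length(p) == 3L) p[2] else NA_character_, ""),
            phosphosite = vapply(parts, function(p) if (length(p) == 3L) p[3] else NA_character_, ""),
            row.names = rownames(values))
        if (!all(ok))
            rowData$gene_id[!ok] <- rownames(values)[!ok]
    }
    cd <- DataFrame(row.names = colnames(values))
    if (!is.null(runGroups)) {
        stopifnot(length(runGroups) == ncol(values))
        cd$group <- as.character(runGroups)
    }
    new("PhosphoSet", SummarizedExperiment(
        assays = list(log2i = values), rowData = rowData, colData = cd))
}

#' Signalon: one regulator's inferred substrate set
#'
#' Targets carry a probabilistic weight in (0, 1] (mutual information
#' normalized by the network maximum, optionally multiplied by a normalized
#' reference prior) and a mode-of-regulation sign in [-1, 1] (posterior
#' activated-minus-repressed probability from a three-Gaussian mixture over
#' Spearman correlations).
#'
#' @slot regulator character, the KP-enzyme feature id.
#' @slot targets data.frame with columns `target`, `weight`, `mode`.
#' @slot level character, e.g. `"phosphostate:site"` or `"activity"`.
#' @slot source character, source dataset tag.
#' @aliases Signalon
#' @exportClass Signalon
setClass("Signalon",
         representation(regulator = "character", targets = "data.frame",
                        level = "character", source = "character"),
         prototype(level = "phosphostate:site", source = "default"))

.validSignalon <- function(object) {
    msg <- NULL
    tg <- object@targets
    need <- c("target", "weight", "mode")
    if (!all(need %in% names(tg)))
        msg <- c(msg, "targets needs columns target, weight, mode")
    else {
        if (anyDuplicated(tg$target)) msg <- c(msg, "duplicate targets")
        if (nrow(tg) && (any(tg$weight < 0) || any(tg$weight > 1)))
            msg <- c(msg, "weights must lie in [0, 1]")
        if (nrow(tg) && any(abs(tg$mode) > 1 + 1e-9))
            msg <- c(msg, "modes must lie in [-1, 1]")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("Signalon", .validSignalon)

#' Construct a Signalon
#'
#' @param regulator regulator feature id.
#' @param targets data.frame with columns `target`, `weight`, `mode`.
#' @param level level tag (`"phosphostate:site"`, `"phosphostate:protein"`,
#'   or `"activity"`).
#' @param source dataset tag.
#' @return A [Signalon-class] object.
#' @export
Signalon <- function(regulator, targets,
                     level = "phosphostate:site", source = "default") {
    new("Signalon", regulator = as.character(regulator),
        targets = as.data.frame(targets), level = level, source = source)
}

#' List of Signalon objects
#'
#' @aliases SignalonList
#' @exportClass SignalonList
setClass("SignalonList", contains = "SimpleList",
         prototype = prototype(elementType = "Signalon"))

#' Construct a SignalonList
#'
#' @param ... [Signalon-class] objects, or a single list of them.
#' @return A [SignalonList-class], named by regulator where names are absent.
#' @export
SignalonList <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "Signalon"))
        args <- args[[1]]
    if (is.null(names(args)) && length(args))
        names(args) <- vapply(args, function(s) s@regulator, "")
    new("SignalonList", SimpleList(args))
}

#' Signature: one sample's differential phosphostate (or activity) profile
#'
#' Per-feature scores on a symmetric quantile scale (z-statistic of the test
#' runs against the reference runs, rank-mapped through the normal quantile
#' function), with an optional null-signature ensemble built by resampling
#' the reference set.
#'
#' @slot scores named numeric vector of per-feature scores.
#' @slot null features x B matrix of null signatures (possibly 0 columns).
#' @slot sample sample (run) id the signature describes.
#' @aliases Signature
#' @exportClass Signature
setClass("Signature",
         representation(scores = "numeric", null = "matrix",
                        sample = "character"))

.validSignature <- function(object) {
    msg <- NULL
    if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
        msg <- c(msg, "scores must be uniquely named by feature")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (ncol(object@null) > 0 && nrow(object@null) != length(object@scores))
        msg <- c(msg, "null ensemble must share the feature space")
    if (is.null(msg)) TRUE else msg
}
setValidity("Signature", .validSignature)

#' ActivitySet: regulators-by-samples normalized enrichment scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with assays
#' `"nes"` (z-scaled normalized enrichment scores; positive = activated) and
#' `"pvalue"` (two-tailed). `metadata(x)$level` tags the inference level
#' (`"phosphostate"`, `"activity"`, or `"integrated"`).
#'
#' @aliases ActivitySet
#' @exportClass ActivitySet
setClass("ActivitySet", contains = "SummarizedExperiment")

setValidity("ActivitySet", function(object) {
    if (!all(c("nes", "pvalue") %in% assayNames(object)))
        return("assays 'nes' and 'pvalue' are required")
    TRUE
})

#' Construct an ActivitySet
#'
#' @param nes regulators x samples NES matrix.
#' @param pvalue matching two-tailed p-value matrix; derived from the normal
#'   tail of `nes` when omitted.
#' @param level inference level tag.
#' @return An [ActivitySet-class].
#' @export
ActivitySet <- function(nes, pvalue = NULL, level = "phosphostate") {
    if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(nes))
    se <- SummarizedExperiment(assays = list(nes = nes, pvalue = pvalue))
    metadata(se)$level <- level
    new("ActivitySet", se)
}
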