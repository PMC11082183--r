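#' @name accessors
#' @title Accessors for phosphonet classes
#' @param x a phosphonet object.
#' @param object a phosphonet object.
#' @description Small accessor layer: slots are never reached into directly.
NULL

#' @rdname accessors
#' @return `intensities()`: the log2 intensity matrix (`NA` = missing).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "PhosphoSet", function(x) assay(x, "log2i"))

#' @rdname accessors
#' @return `observedMask()`: logical matrix, `TRUE` where observed.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname accessors
#' @export
setMethod("observedMask", "PhosphoSet", function(x) !is.na(assay(x, "log2i")))

#' @rdname accessors
#' @return `siteIds()` / `runIds()`: row / column identifiers.
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname accessors
#' @export
setMethod("siteIds", "PhosphoSet", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("runIds", function(x) standardGeneric("runIds"))

#' @rdname accessors
#' @export
setMethod("runIds", "PhosphoSet", function(x) colnames(x))

#' @rdname accessors
#' @return `runGroups()`: per-run group labels, or `NULL`.
#' @export
setGeneric("runGroups", function(x) standardGeneric("runGroups"))

#' @rdname accessors
#' @export
setMethod("runGroups", "PhosphoSet", function(x) {
    cd <- colData(x)
    if ("group" %in% names(cd)) as.character(cd$group) else NULL
})

#' @rdname accessors
#' @return `completeness()`: per-site fraction of observed runs, in [0, 1].
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))

#' @rdname accessors
#' @export
setMethod("completeness", "PhosphoSet",
          function(x) rowMeans(observedMask(x)))

#' @rdname accessors
#' @return `regulator()`: the signalon's regulator id.
#' @export
setGeneric("regulator", function(x) standardGeneric("regulator"))

#' @rdname accessors
#' @export
setMethod("regulator", "Signalon", function(x) x@regulator)

#' @rdname accessors
#' @return `targets()`: the signalon target table
#'   (columns `target`, `weight`, `mode`).
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname accessors
#' @export
setMethod("targets", "Signalon", function(x) x@targets)

#' @rdname accessors
#' @return `signalonLevel()` / `signalonSource()`: level and dataset tags.
#' @export
setGeneric("signalonLevel", function(x) standardGeneric("signalonLevel"))

#' @rdname accessors
#' @export
setMethod("signalonLevel", "Signalon", function(x) x@level)

#' @rdname accessors
#' @export
setGeneric("signalonSource", function(x) standardGeneric("signalonSource"))

#' @rdname accessors
#' @export
setMethod("signalonSource", "Signalon", function(x) x@source)

#' @rdname accessors
#' @return `sigScores()`: named per-feature signature scores;
#'   `sigNull()`: the null-signature ensemble matrix.
#' @export
setGeneric("sigScores", function(x) standardGeneric("sigScores"))

#' @rdname accessors
#' @export
setMethod("sigScores", "Signature", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("sigNull", function(x) standardGeneric("sigNull"))

#' @rdname accessors
#' @export
setMethod("sigNull", "Signature", function(x) x@null)

#' @rdname accessors
#' @return `nes()` / `activityPvalues()`: the NES and p-value matrices;
#'   `activityLevel()`: the inference level tag.
#' @export
setGeneric("nes", function(x) standardGeneric("nes"))

#' @rdname accessors
#' @export
setMethod("nes", "ActivitySet", function(x) assay(x, "nes"))

#' @rdname accessors
#' @export
setGeneric("activityPvalues", function(x) standardGeneric("activityPvalues"))

#' @rdname accessors
#' @export
setMethod("activityPvalues", "ActivitySet", function(x) assay(x, "pvalue"))

#' @rdname accessors
#' @export
setGeneric("activityLevel", function(x) standardGeneric("activityLevel"))

#' @rdname accessors
#' @export
setMethod("activityLevel", "ActivitySet", function(x) metadata(x)$level)

#' @rdname accessors
#' @export
setMethod("show", "PhosphoSet", function(object) {
    cat(sprintf("PhosphoSet: %d sites x %d runs, %.1f%% observed\n",
                nrow(object), ncol(object),
                100 * mean(observedMask(object))))
    grp <- runGroups(object)
    if (!is.null(grp))
        cat("  run groups:", paste(unique(grp), collapse = ", "), "\n")
    callNextMethod()
})

#' @rdname accessors
#' @export
setMethod("show", "Signalon", function(object) {
    cat(sprintf("Signalon for %s [%s, %s]: %d targets\n",
                object@regulator, object@level, object@source,
                nrow(object@targets)))
    if (nrow(object@targets))
        cat(sprintf("  mode range [%.2f, %.2f], max weight %.3f\n",
                    min(object@targets$mode), max(object@targets$mode),
                    max(object@targets$weight)))
})

#' @rdname accessors
#' @export
setMethod("show", "Signature", function(object) {
    cat(sprintf("Signature for sample %s: %d features, %d null draws\n",
                object@sample, length(object@scores), ncol(object@null)))
})

#' @rdname accessors
#' @export
setMethod("show", "ActivitySet", function(object) {
    cat(sprintf("ActivitySet [%s]: %d regulators x %d samples\n",
                metadata(object)$level, nrow(object), ncol(object)))
    callNextMethod()
})
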