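#' Adaptive-partitioning mutual information on complete rank vectors
#'
#' Recursively splits the rank plane into quadrants while a chi-square
#' heterogeneity statistic over the four sub-cells exceeds `chiThreshold`
#' (7.815 = chi-square, 3 df, alpha 0.05, the ARACNe-AP convention); every
#' leaf cell then contributes `(n_c/N) * log[(n_c/N) / (w_x * w_y)]` nats,
#' where `w_x`, `w_y` are the cell's marginal rank-width fractions. The
#' result is clipped at 0.
#'
#' @param x,y complete numeric vectors of equal length >= 8 (ranked
#'   internally; ties get midranks).
#' @param chiThreshold split criterion on the 4-cell chi-square statistic.
#' @param maxDepth if > 0, forces splitting to exactly this depth with no
#'   chi-square test (a fixed final partition, useful for closed-form
#'   checks); 0 = adaptive (default).
#' @return Nonnegative mutual information in nats.
#' @examples
#' adaptivePartitionMI(1:64, 1:64)       # strong dependence
#' adaptivePartitionMI(1:64, sample(64)) # ~ 0
#' @export
adaptivePartitionMI <- function(x, y, chiThreshold = 7.814728, maxDepth = 0) {
    stopifnot(length(x) == length(y), length(x) >= 8,
              !anyNA(x), !anyNA(y))
    if (var(x) == 0 || var(y) == 0) {
        warning("constant vector: MI is 0")
        return(0)
    }
    .cpp_apmi(as.numeric(x), as.numeric(y), chiThreshold, as.integer(maxDepth))
}

#' Hybrid-partitioning mutual information for censored pairs
#'
#' Estimates mutual information between two sparse abundance vectors in which
#' missingness is informative (censoring below the limit of detection). The
#' sample plane is split into four quadrants by joint observedness; the
#' estimate is the exact chain-rule combination of (a) the plug-in MI of the
#' 2x2 observed/missing table, in which "missing" is one marginal bin per
#' axis, and (b) the adaptive-partitioning MI of the jointly observed points
#' (re-ranked among themselves), weighted by their fraction `n11/N`. Every
#' term is on the single `1/N` probability scale, so estimates are comparable
#' across pairs with different missingness. With no missing values the
#' estimate equals [adaptivePartitionMI()] exactly.
#'
#' @param x,y numeric vectors of equal length n >= 8, `NA` = missing.
#' @param chiThreshold,maxDepth passed to the quadrant-1 adaptive partition.
#' @return A list with `mi` (nats, >= 0) and `quadrant_counts`
#'   (`n11` both observed, `n00` both missing, `n01` x-missing-only,
#'   `n10` y-missing-only; they sum to n). Fewer than 4 jointly observed
#'   points set the quadrant-1 term to 0.
#' @examples
#' x <- c(1:6, NA, NA); y <- c(1, 3, 2, 4, 6, 5, NA, NA)
#' hpMI(x, y)
#' @export
hpMI <- function(x, y, chiThreshold = 7.814728, maxDepth = 0) {
    stopifnot(length(x) == length(y), length(x) >= 8)
    if (all(is.na(x)) || all(is.na(y)))
        stop("all-missing vector: hpMI is undefined")
    ox <- x[!is.na(x)]; oy <- y[!is.na(y)]
    if ((length(ox) > 1 && var(ox) == 0) || (length(oy) > 1 && var(oy) == 0))
        warning("constant observed values: quadrant-1 MI uses midranks only")
    .cpp_hpmi(as.numeric(x), as.numeric(y), chiThreshold,
              as.integer(maxDepth))
}

#' Spearman correlation over jointly observed entries
#'
#' @param x,y numeric vectors of equal length, `NA` = missing.
#' @return Spearman's rho computed on fully quantitated (jointly observed)
#'   points only, or `NA` when fewer than 3 such points exist.
#' @export
spearmanComplete <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
}

#' Impute censored values with low-intensity noise
#'
#' Row-wise minimum imputation with additive uniform noise whose range is the
#' difference between the two lowest observed values of the row (ties in the
#' imputed values are broken by the noise). Rows with fewer than two observed
#' values get range 0 with a warning.
#'
#' @param x a [PhosphoSet-class] or numeric matrix with `NA` missing.
#' @param seed integer seed for the noise draws.
#' @return Same shape as `x`, complete.
#' @export
imputeLowNoise <- function(x, seed = 1L) {
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    out <- withr::with_seed(seed, {
        warned <- FALSE
        res <- m
        for (i in seq_len(nrow(m))) {
            miss <- is.na(m[i, ])
            if (!any(miss)) next
            obs <- sort(m[i, !miss])
            if (length(obs) == 0L) next
            if (length(obs) < 2L) {
                warned <- TRUE
                rng <- 0
            } else rng <- obs[2] - obs[1]
            res[i, miss] <- obs[1] + runif(sum(miss), 0, max(rng, 0))
        }
        if (warned)
            warning("row(s) with < 2 observed values: imputation range 0, ",
                    "noise skipped")
        res
    })
    if (is(x, "PhosphoSet")) {
        ans <- x
        assay(ans, "log2i") <- out
        ans
    } else out
}

# MI for a set of candidate (regulator, target) row pairs of a value matrix.
# estimator: "hpmi" (hybrid), "dmi" (complete-case), "imi" (impute first,
# then complete adaptive partitioning). cols = column resample (bootstrap).
.miPairs <- function(m, reg, tgt, cols = seq_len(ncol(m)),
                     estimator = c("hpmi", "dmi", "imi"),
                     chiThreshold = 7.814728, seed = 1L) {
    estimator <- match.arg(estimator)
    if (estimator == "imi")
        m <- imputeLowNoise(m, seed = seed)
    est <- if (estimator == "hpmi") 0L else 1L
    .cpp_mi_pairs(m, as.integer(reg), as.integer(tgt), as.integer(cols),
                  est, chiThreshold, 0L)
}

#' Permutation-based family-wise MI significance threshold
#'
#' Generates a null by independently permuting each feature row of the value
#' matrix, including its missing values, and computing the pairwise MI of
#' candidate pairs under the chosen estimator. The family-wise error rate is
#' converted to a per-test tail level by the Sidak relation
#' `1 - (1 - fwer)^(1/n_candidates)`; the corresponding null quantile is read
#' off empirically when resolvable and otherwise extrapolated by an
#' exponential fit to the top 1 percent of the null (extreme-value tail),
#' since brute-force FWER control over ~1e5 candidates is unreachable by
#' naive permutation counts.
#'
#' @param x a [PhosphoSet-class] or numeric matrix (`NA` = missing).
#' @param regulators,targets row ids (or indices) defining the candidate
#'   pairs (all regulator x target combinations, self-pairs dropped).
#' @param fwer family-wise error rate in (0, 1]; `fwer = 1` returns the
#'   minimum of the null.
#' @param nPerm number of row-permutation rounds.
#' @param maxPairs cap on the number of candidate pairs evaluated per round
#'   (a seeded random subset is used above the cap).
#' @param estimator MI estimator, see [hpMI()].
#' @param seed integer seed.
#' @return The MI threshold (nats). Errors if the pooled null is too small to
#'   resolve the requested quantile.
#' @export
nullMIThreshold <- function(x, regulators, targets = NULL, fwer = 0.05,
                            nPerm = 10L, maxPairs = 3000L,
                            estimator = c("hpmi", "dmi", "imi"), seed = 1L) {
    estimator <- match.arg(estimator)
    stopifnot(fwer > 0, fwer <= 1)
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    idx <- .pairIndices(m, regulators, targets)
    nCand <- nrow(idx)
    withr::with_seed(seed, {
        use <- idx
        if (nCand > maxPairs)
            use <- idx[sample.int(nCand, maxPairs), , drop = FALSE]
        nullmi <- unlist(lapply(seq_len(nPerm), function(b) {
            mp <- m
            for (i in seq_len(nrow(mp)))
                mp[i, ] <- mp[i, sample.int(ncol(mp))]
            .miPairs(mp, use[, 1], use[, 2], estimator = estimator,
                     seed = seed + b)
        }), use.names = FALSE)
        nNull <- length(nullmi)
        minNull <- max(1000L, ceiling(20 / fwer))
        if (nNull < minNull)
            stop("null too small to resolve the FWER quantile: ", nNull,
                 " null MI values, need at least ", minNull,
                 "; increase nPerm")
        alpha1 <- 1 - (1 - fwer)^(1 / nCand)
        if (fwer == 1) return(min(nullmi))
        if (alpha1 >= 10 / nNull)
            return(unname(quantile(nullmi, 1 - alpha1, type = 7)))
        t0 <- unname(quantile(nullmi, 0.99, type = 7))
        excess <- nullmi[nullmi > t0] - t0
        beta <- mean(excess)
        if (!is.finite(beta) || beta <= 0) return(t0)
        t0 - beta * log(alpha1 / 0.01)
    })
}

# resolve candidate (regulator, target) row-index pairs
.pairIndices <- function(m, regulators, targets = NULL) {
    toIdx <- function(v) {
        if (is.character(v)) {
            i <- match(v, rownames(m))
            if (anyNA(i)) stop("unknown feature id(s): ",
                               paste(v[is.na(i)], collapse = ", "))
            i
        } else as.integer(v)
    }
    ri <- toIdx(regulators)
    ti <- if (is.null(targets)) seq_len(nrow(m)) else toIdx(targets)
    idx <- expand.grid(reg = ri, tgt = ti)
    idx <- idx[idx$reg != idx$tgt, , drop = FALSE]
    if (!nrow(idx)) stop("candidate specification yields zero pairs")
    as.matrix(idx)
}
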