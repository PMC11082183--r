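#' Build a per-sample differential signature
#'
#' Missing entries are first imputed as the row minimum plus uniform noise
#' with range equal to the difference between the two lowest observed values
#' of the row (ties broken by the noise, see [imputeLowNoise()]). Each
#' feature is then scored by the z-statistic of the test runs against the
#' reference runs, `z = (mean_test - mean_ref) / (sd_ref *
#' sqrt(1/n_test + 1/n_ref))`, and the z-values are rank-mapped onto a
#' symmetric quantile scale, `qnorm(rank(z) / (n + 1))`. An optional null
#' ensemble is built by resampling `n_test` reference runs (with
#' replacement) and scoring them against the reference the same way.
#'
#' @param x a [PhosphoSet-class] or numeric matrix (features x runs).
#' @param test run ids (or indices) of the test set.
#' @param reference run ids (or indices) of the reference set (nonempty).
#' @param nullSize number of null signatures to generate (0 = none).
#' @param seed integer seed for imputation noise and null resampling.
#' @return A [Signature-class].
#' @export
makeSignature <- function(x, test, reference, nullSize = 0L, seed = 1L) {
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    ti <- .colIdx(m, test)
    ri <- .colIdx(m, reference)
    if (!length(ri)) stop("reference set must be nonempty")
    mi_ <- imputeLowNoise(m, seed = seed)
    scores <- .signatureScores(mi_, ti, ri)
    nullM <- matrix(numeric(), nrow = nrow(m), ncol = 0)
    if (nullSize > 0L) {
        nullM <- withr::with_seed(seed + 7L, {
            vapply(seq_len(nullSize), function(b) {
                pseudo <- sample(ri, length(ti), replace = TRUE)
                .signatureScores(mi_, pseudo, ri)
            }, numeric(nrow(m)))
        })
        rownames(nullM) <- rownames(m)
    }
    new("Signature", scores = scores, null = nullM,
        sample = paste(colnames(m)[ti], collapse = ","))
}

.colIdx <- function(m, v) {
    if (is.character(v)) {
        i <- match(v, colnames(m))
        if (anyNA(i)) stop("unknown run id(s): ",
                           paste(v[is.na(i)], collapse = ", "))
        i
    } else as.integer(v)
}

.signatureScores <- function(m, ti, ri) {
    mt <- rowMeans(m[, ti, drop = FALSE])
    mr <- rowMeans(m[, ri, drop = FALSE])
    sr <- apply(m[, ri, drop = FALSE], 1, sd)
    sr[!is.finite(sr) | sr == 0] <- 1e-9
    z <- (mt - mr) / (sr * sqrt(1 / length(ti) + 1 / length(ri)))
    z[mt == mr] <- 0
    out <- qnorm(rank(z) / (length(z) + 1))
    names(out) <- rownames(m)
    out
}

#' Analytic rank-based enrichment score of a signalon in a signature
#'
#' The signature scores are mapped to normal quantiles twice: two-tailed
#' (`q2`, rank of the signed score) and one-tailed (`q1`, rank of the
#' absolute score). Each target contributes through its weight and mode:
#' the directional component `S1 = sum w_i * mode_i * q2_i` and the
#' magnitude component `S2 = sum w_i * (1 - |mode_i|) * q1_i`, which
#' captures non-monotonically regulated targets and is folded in with the
#' sign of `S1`: `ES = sign(S1) * (|S1| + max(S2, 0))`. The score is scaled
#' to a z-score by its exact null standard deviation under target
#' independence, `sqrt(s1^2 + (2/pi) s1 s2 + s2^2 / 2)` with
#' `s1^2 = sum (w mode)^2`, `s2^2 = sum (w (1-|mode|))^2` (the cross term
#' reflects `E|Z| E[Z^+]`). Positive NES = activated.
#'
#' @param sig a [Signature-class].
#' @param signalon a [Signalon-class].
#' @param minSize minimum number of targets present in the signature's
#'   feature space; fewer is an error (callers skip and log).
#' @return The normalized enrichment score (z-scale).
#' @export
enrichmentNES <- function(sig, signalon, minSize = 5L) {
    scores <- sigScores(sig)
    tg <- targets(signalon)
    tg <- tg[tg$target %in% names(scores), , drop = FALSE]
    if (nrow(tg) < minSize)
        stop("signalon for ", regulator(signalon), " has ", nrow(tg),
             " target(s) in the signature feature space (minimum ", minSize,
             ")")
    .nesCore(scores, tg)
}

.nesCore <- function(scores, tg) {
    n <- length(scores)
    q2 <- qnorm(rank(scores) / (n + 1))
    q1 <- qnorm(rank(abs(scores)) / (n + 1))
    i <- match(tg$target, names(scores))
    a <- tg$weight * tg$mode
    b <- tg$weight * (1 - abs(tg$mode))
    s1 <- sum(a * q2[i])
    s2 <- sum(b * q1[i])
    v1 <- sum(a^2)
    v2 <- sum(b^2)
    if (v1 == 0) {
        if (v2 == 0) return(0)
        return(s2 / sqrt(v2))
    }
    es <- sign(s1) * (abs(s1) + max(s2, 0))
    es / sqrt(v1 + (2 / pi) * sqrt(v1 * v2) + v2 / 2)
}

#' Calibrate an NES against an empirical null ensemble
#'
#' Rescales a regulator's NES by the mean and standard deviation of its NES
#' over null signatures (reference-resampled), and attaches a two-tailed
#' empirical p-value with the `2/(B+1)` floor for scores beyond all null
#' draws.
#'
#' @param nesValue observed NES.
#' @param nullNes numeric vector of the regulator's null NES values
#'   (ensemble size >= 100 recommended for p below 0.01).
#' @return List with `nes` (calibrated) and `pvalue`.
#' @export
empiricalNullNES <- function(nesValue, nullNes) {
    B <- length(nullNes)
    if (B < 2L) stop("null ensemble too small")
    s <- sd(nullNes)
    cal <- (nesValue - mean(nullNes)) / max(s, 1e-12)
    pUp <- (1 + sum(nullNes >= nesValue)) / (B + 1)
    pDn <- (1 + sum(nullNes <= nesValue)) / (B + 1)
    list(nes = cal, pvalue = min(1, 2 * min(pUp, pDn)))
}

#' Per-sample KP-enzyme activity from signalons
#'
#' For every test run, builds a differential signature against the reference
#' runs ([makeSignature()]) and scores every signalon by analytic enrichment
#' ([enrichmentNES()]). With `nullSize > 0`, a bootstrapped null model
#' (reference-resampled signatures) calibrates the NES per regulator and
#' supplies empirical p-values ([empiricalNullNES()]); otherwise p-values
#' come from the normal tail. Optional crosstalk correction
#' ([crosstalkCorrect()]) is applied last. Signalons with fewer than
#' `minSize` usable targets are skipped with a message.
#'
#' @param x a [PhosphoSet-class] or numeric matrix.
#' @param signalons a [SignalonList-class].
#' @param test test run ids (default: all runs, i.e. each sample against the
#'   cohort centroid).
#' @param reference reference run ids (default: all runs).
#' @param nullSize null-ensemble size (0 = analytic p-values).
#' @param crosstalk apply crosstalk correction.
#' @param ci,alpha crosstalk parameters, see [crosstalkCorrect()].
#' @param minSize minimum usable signalon size.
#' @param seed integer seed.
#' @return An [ActivitySet-class] (regulators x test runs).
#' @export
measureActivity <- function(x, signalons, test = NULL, reference = NULL,
                            nullSize = 0L, crosstalk = FALSE, ci = 20,
                            alpha = 0.05, minSize = 5L, seed = 1L) {
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    if (is.null(reference)) reference <- colnames(m)
    if (is.null(test)) test <- colnames(m)
    ti <- .colIdx(m, test)
    sigs <- lapply(ti, function(j)
        makeSignature(m, j, reference, nullSize = 0L, seed = seed))
    names(sigs) <- colnames(m)[ti]
    usable <- vapply(as.list(signalons), function(s)
        sum(targets(s)$target %in% rownames(m)) >= minSize, TRUE)
    if (any(!usable))
        message(sum(!usable), " signalon(s) below the minimum size were ",
                "skipped")
    sl <- as.list(signalons)[usable]
    if (!length(sl)) stop("no usable signalon")
    nesM <- vapply(sigs, function(sig)
        vapply(sl, function(s) enrichmentNES(sig, s, minSize = minSize), 0),
        numeric(length(sl)))
    nesM <- matrix(nesM, nrow = length(sl),
                   dimnames = list(names(sl), names(sigs)))
    nullStats <- NULL
    if (nullSize > 0L) {
        nullSig <- makeSignature(m, .colIdx(m, reference)[1], reference,
                                 nullSize = nullSize, seed = seed)
        nullNes <- apply(sigNull(nullSig), 2, function(sc) {
            sc <- structure(sc, names = rownames(sigNull(nullSig)))
            vapply(sl, function(s) {
                tg <- targets(s)
                tg <- tg[tg$target %in% names(sc), , drop = FALSE]
                .nesCore(sc, tg)
            }, 0)
        })
        nullNes <- matrix(nullNes, nrow = length(sl),
                          dimnames = list(names(sl), NULL))
        pM <- nesM
        for (r in rownames(nesM)) for (j in seq_len(ncol(nesM))) {
            cal <- empiricalNullNES(nesM[r, j], nullNes[r, ])
            pM[r, j] <- cal$pvalue
            nesM[r, j] <- cal$nes
        }
        nullStats <- list(mean = rowMeans(nullNes),
                          sd = apply(nullNes, 1, sd))
        am <- ActivitySet(nesM, pM, level = "phosphostate")
    } else {
        am <- ActivitySet(nesM, level = "phosphostate")
    }
    if (crosstalk)
        am <- crosstalkCorrect(am, SignalonList(sl), sigs, ci = ci,
                               alpha = alpha, minSize = minSize,
                               nullStats = nullStats)
    am
}

#' Cross-differential enrichment of a signalon pair
#'
#' `CDE = log10(pB) - log10(pA)` for a stronger regulator A (smaller p) and
#' a weaker regulator B; nonnegative by construction.
#'
#' @param pA p-value of the stronger regulator.
#' @param pB p-value of the weaker regulator (`pB >= pA`).
#' @return The cross-differential enrichment value.
#' @export
crosstalkCDE <- function(pA, pB) log10(pB) - log10(pA)

#' Stouffer integration of phosphostate- and activity-level z-scores
#'
#' `z = (zPL + zAL) / sqrt(2)`; when one level is absent (`NA`) the other
#' is returned unchanged.
#'
#' @param zPL,zAL z-scores from the two inference levels (vectorized).
#' @return Integrated z-scores.
#' @export
stoufferIntegrate <- function(zPL, zAL) {
    out <- (zPL + zAL) / sqrt(2)
    out[is.na(zAL)] <- zPL[is.na(zAL)]
    out[is.na(zPL)] <- zAL[is.na(zPL)]
    out
}

#' Crosstalk (pleiotropy) correction of an activity matrix
#'
#' Signalons of two enzymes may share substrates, so activation of one can
#' make the other appear active. For every ordered pair (A stronger = lower
#' p, B weaker) of regulators that share targets and are both significant
#' (`p < alpha`) in a sample's signature, the cross-differential enrichment
#' `CDE = log10(pB) - log10(pA) >= 0` is computed and the shared targets'
#' weights in the weaker signalon are multiplied by
#' `min(1, CDE^(CI/NT) / CDE_max)`, where `CI` is the crosstalk index, `NT`
#' the number of pairs the weaker signalon participates in, and `CDE_max`
#' the largest CDE in the sample (`CDE_max = 0` nullifies the shared
#' contribution entirely). The weaker regulator's NES is then recomputed
#' from the down-weighted signalon; samples with no interacting pair are
#' untouched.
#'
#' @param am an [ActivitySet-class].
#' @param signalons the [SignalonList-class] the activities came from.
#' @param signatures list of per-sample [Signature-class] objects aligned
#'   with `colnames(am)`.
#' @param ci crosstalk index constant.
#' @param alpha significance level gating the correction.
#' @param minSize minimum usable signalon size for recomputation.
#' @param nullStats optional list(`mean`, `sd`) of per-regulator null NES
#'   statistics used to recalibrate recomputed scores.
#' @return The corrected [ActivitySet-class].
#' @export
crosstalkCorrect <- function(am, signalons, signatures, ci = 20,
                             alpha = 0.05, minSize = 5L, nullStats = NULL) {
    nesM <- nes(am)
    pM <- activityPvalues(am)
    sl <- as.list(signalons)
    tgl <- lapply(sl, function(s) targets(s)$target)
    for (j in seq_len(ncol(nesM))) {
        sigRegs <- rownames(nesM)[pM[, j] < alpha]
        sigRegs <- intersect(sigRegs, names(sl))
        if (length(sigRegs) < 2L) next
        prs <- utils::combn(sigRegs, 2, simplify = FALSE)
        prs <- Filter(function(p)
            length(intersect(tgl[[p[1]]], tgl[[p[2]]])) > 0, prs)
        if (!length(prs)) next
        nt <- table(unlist(prs))
        cde <- vapply(prs, function(p) {
            crosstalkCDE(min(pM[p, j]), max(pM[p, j]))
        }, 0)
        cdeMax <- max(cde)
        adjusted <- list()
        for (k in seq_along(prs)) {
            p <- prs[[k]]
            # weaker = larger p; p ties (e.g. both at the empirical-null
            # floor) broken by smaller |NES|
            weakFirst <- pM[p[1], j] > pM[p[2], j] ||
                (pM[p[1], j] == pM[p[2], j] &&
                 abs(nesM[p[1], j]) <= abs(nesM[p[2], j]))
            A <- if (weakFirst) p[2] else p[1]
            B <- if (weakFirst) p[1] else p[2]
            fac <- if (cdeMax == 0) 0
                   else min(1, cde[k]^(ci / nt[[B]]) / cdeMax)
            sB <- if (!is.null(adjusted[[B]])) adjusted[[B]] else sl[[B]]
            tg <- targets(sB)
            shared <- tg$target %in% tgl[[A]]
            tg$weight[shared] <- tg$weight[shared] * fac
            adjusted[[B]] <- Signalon(B, tg, level = signalonLevel(sB),
                                      source = signalonSource(sB))
        }
        for (B in names(adjusted)) {
            tg <- targets(adjusted[[B]])
            tg <- tg[tg$target %in% names(sigScores(signatures[[j]])), ,
                     drop = FALSE]
            newNes <- .nesCore(sigScores(signatures[[j]]), tg)
            if (!is.null(nullStats))
                newNes <- (newNes - nullStats$mean[[B]]) /
                    max(nullStats$sd[[B]], 1e-12)
            nesM[B, j] <- newNes
            pM[B, j] <- 2 * pnorm(-abs(newNes))
        }
    }
    out <- ActivitySet(nesM, pM, level = activityLevel(am))
    out
}

#' Hierarchical phosphostate/activity-level inference
#'
#' The two-level pass of the method: (1) phosphostate-level (PL) activities
#' are inferred for every run from the PL signalons; (2) an activity-level
#' (AL) network is dissected from the PL activity matrix with regular DPI
#' (not the signal-transduction variant, since the second network abstracts
#' the system functionally); (3) AL activities are inferred from the AL
#' signalons on activity signatures; (4) PL and AL z-scores are integrated
#' by Stouffer's method, `z = (z_PL + z_AL) / sqrt(2)`, falling back to the
#' single available level when the other is absent. When the AL network is
#' empty the PL activities are returned with level tag `"phosphostate"`.
#'
#' @param x a [PhosphoSet-class] or matrix.
#' @param signalons PL [SignalonList-class] (from [buildSignalons()]).
#' @param spec the [candidateSpec()] carrying enzyme classes for the AL
#'   dissection.
#' @param test,reference run ids as in [measureActivity()].
#' @param nBoot,fwer,alpha AL dissection parameters.
#' @param minSize minimum signalon size at the phosphostate level.
#' @param alMinSize minimum signalon size at the activity level; defaults to
#'   `minSize`, but small simulated systems with only a handful of
#'   regulators need a lower value since an AL signalon can never exceed
#'   the regulator count.
#' @param seed integer seed.
#' @param ... further arguments passed to [measureActivity()] (both levels).
#' @return A list with `integrated`, `pl`, `al` ([ActivitySet-class] or
#'   `NULL`), and `alNetwork` (the AL interaction data.frame).
#' @export
hierarchicalMeasure <- function(x, signalons, spec, test = NULL,
                                reference = NULL, nBoot = 100L, fwer = 0.05,
                                alpha = 0.05, minSize = 5L,
                                alMinSize = minSize, seed = 1L, ...) {
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    if (is.null(reference)) reference <- colnames(m)
    if (is.null(test)) test <- colnames(m)
    # step 1: PL activities for every run (the AL substrate space)
    plAll <- measureActivity(m, signalons, test = colnames(m),
                             reference = reference, minSize = minSize,
                             seed = seed, ...)
    plM <- nes(plAll)
    pl <- ActivitySet(plM[, test, drop = FALSE],
                      activityPvalues(plAll)[, test, drop = FALSE],
                      level = "phosphostate")
    al <- NULL
    alNet <- data.frame()
    if (nrow(plM) >= 3L) {
        regClasses <- .nodeClasses(spec, rownames(plM))
        alSpec <- candidateSpec(
            kinases = rownames(plM)[regClasses == "kinase"],
            phosphatases = rownames(plM)[regClasses == "phosphatase"],
            mode = "enzyme-list")
        # an empty AL network is an expected fallback, not a user-facing
        # warning condition
        alNet <- tryCatch(
            suppressWarnings(
                dissect(PhosphoSet(plM), alSpec, level = "site", dpi = "dpi",
                        nBoot = nBoot, fwer = fwer, alpha = alpha,
                        seed = seed + 13L)),
            error = function(e) data.frame())
    }
    if (nrow(alNet)) {
        alSig <- buildSignalons(alNet, level = "activity",
                                source = "activity-level",
                                minSize = alMinSize, seed = seed)
        if (length(alSig))
            al <- tryCatch({
                a <- measureActivity(plM, alSig, test = test,
                                     reference = reference,
                                     minSize = alMinSize, seed = seed, ...)
                ActivitySet(nes(a), activityPvalues(a), level = "activity")
            }, error = function(e) NULL)
    }
    if (is.null(al)) {
        integrated <- ActivitySet(nes(pl), activityPvalues(pl),
                                  level = "phosphostate")
        return(list(integrated = integrated, pl = pl, al = NULL,
                    alNetwork = alNet))
    }
    regs <- union(rownames(nes(pl)), rownames(nes(al)))
    z <- matrix(NA_real_, length(regs), length(test),
                dimnames = list(regs, test))
    zp <- nes(pl); za <- nes(al)
    for (r in regs) {
        hasP <- r %in% rownames(zp); hasA <- r %in% rownames(za)
        z[r, ] <- stoufferIntegrate(
            if (hasP) zp[r, test] else rep(NA_real_, length(test)),
            if (hasA) za[r, test] else rep(NA_real_, length(test)))
    }
    integrated <- ActivitySet(z, level = "integrated")
    list(integrated = integrated, pl = pl, al = al, alNetwork = alNet)
}

#' Write an activity matrix (and companion p-values) as wide TSV
#'
#' @param am an [ActivitySet-class].
#' @param path NES output path; p-values go to `paste0(path, ".pvalues")`
#'   unless `pvaluePath` is given.
#' @param pvaluePath optional p-value output path.
#' @return The NES path, invisibly.
#' @export
writeActivity <- function(am, path, pvaluePath = NULL) {
    df <- data.frame(regulator = rownames(nes(am)), nes(am),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(pvaluePath)) pvaluePath <- paste0(path, ".pvalues")
    dp <- data.frame(regulator = rownames(nes(am)), activityPvalues(am),
                     check.names = FALSE)
    write.table(dp, pvaluePath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
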