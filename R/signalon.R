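#' Mode of regulation from a three-Gaussian mixture over Spearman rho
#'
#' Fits a 1-D three-component Gaussian mixture to per-target Spearman
#' correlations, the components representing repressed (rho << 0),
#' non-monotonically regulated (rho ~ 0), and activated (rho >> 0) targets.
#' Means are kept ordered (the middle component is initialized at 0) and the
#' fit uses seeded expectation-maximization with `nRestarts` restarts, ties
#' broken by best log-likelihood then lowest restart index. The mode of each
#' target is the posterior activated-minus-repressed probability,
#' `P(activated | rho) - P(repressed | rho)`, in [-1, 1].
#'
#' With fewer than 10 targets the mixture is unstable and a linear ramp
#' fallback is used: `sign(rho) * min(1, |rho| / 0.5)`. Degenerate all-equal
#' rho values yield `sign(rho)`.
#'
#' @param rhos numeric vector of Spearman correlations in [-1, 1].
#' @param nRestarts number of EM restarts.
#' @param seed integer seed for the restarts.
#' @return Numeric vector of modes, same length as `rhos`.
#' @export
modeOfRegulation <- function(rhos, nRestarts = 10L, seed = 1L) {
    stopifnot(all(abs(rhos) <= 1 + 1e-9, na.rm = TRUE))
    rhos <- pmin(1, pmax(-1, rhos))
    if (length(unique(rhos[!is.na(rhos)])) <= 1L)
        return(sign(rhos))
    if (length(rhos) < 10L)
        return(sign(rhos) * pmin(1, abs(rhos) / 0.5))
    fit <- .fitMixture3(rhos[!is.na(rhos)], nRestarts, seed)
    post <- .mixturePosterior(rhos, fit)
    out <- post[, 3] - post[, 1]
    out[is.na(rhos)] <- NA_real_
    out
}

# EM for a 3-component 1-D Gaussian mixture over Spearman rho. The middle
# (non-monotone) component mean is pinned at 0 and the outer (repressed /
# activated) means are constrained to mu1 <= 0 <= mu3, which keeps the
# components interpretable when one class of edges dominates.
.fitMixture3 <- function(x, nRestarts = 10L, seed = 1L, maxIter = 200L,
                         tol = 1e-8) {
    best <- NULL
    withr::with_seed(seed, {
        for (r in seq_len(nRestarts)) {
            mu <- if (r == 1L) c(min(-0.3, quantile(x, 0.15)), 0,
                                 max(0.3, quantile(x, 0.85)))
                  else c(runif(1, -0.9, -0.05), 0, runif(1, 0.05, 0.9))
            sig <- rep(max(sd(x) / 2, 0.05), 3)
            pi_ <- rep(1 / 3, 3)
            ll0 <- -Inf
            for (it in seq_len(maxIter)) {
                d <- vapply(1:3, function(k)
                    pi_[k] * dnorm(x, mu[k], sig[k]), numeric(length(x)))
                rowS <- pmax(rowSums(d), .Machine$double.xmin)
                ll <- sum(log(rowS))
                g <- d / rowS
                nk <- pmax(colSums(g), 1e-12)
                pi_ <- nk / length(x)
                mu <- colSums(g * x) / nk
                mu[1] <- min(mu[1], 0)
                mu[2] <- 0
                mu[3] <- max(mu[3], 0)
                sig <- sqrt(colSums(g * (outer(x, mu, "-"))^2) / nk)
                sig <- pmax(sig, 1e-3)
                if (abs(ll - ll0) < tol) break
                ll0 <- ll
            }
            if (is.null(best) || ll > best$ll + 1e-12)
                best <- list(mu = mu, sig = sig, pi = pi_, ll = ll)
        }
    })
    best
}

.mixturePosterior <- function(x, fit) {
    d <- vapply(1:3, function(k)
        fit$pi[k] * dnorm(x, fit$mu[k], fit$sig[k]), numeric(length(x)))
    d / pmax(rowSums(d), .Machine$double.xmin)
}

#' Probabilistic signalon weights
#'
#' Each interaction's weight is its MI normalized by the maximum MI across
#' the entire network; optional reference priors are first normalized by the
#' maximum prior of the same regulator and then multiplied in (a zero prior
#' drops the target).
#'
#' @param mis per-target MI values (nonnegative).
#' @param networkMaxMi maximum MI over the whole network (defaults to
#'   `max(mis)`).
#' @param priors optional per-target priors in [0, 1] for this regulator.
#' @return Per-target weights in [0, 1].
#' @export
signalonWeights <- function(mis, networkMaxMi = max(mis), priors = NULL) {
    stopifnot(all(mis >= 0))
    if (networkMaxMi <= 0) stop("all-zero MI: weights are undefined")
    w <- mis / networkMaxMi
    if (!is.null(priors)) {
        stopifnot(length(priors) == length(mis))
        mp <- max(priors, na.rm = TRUE)
        w <- if (mp > 0) w * (priors / mp) else rep(0, length(w))
    }
    w
}

#' Trim a signalon to its top-weighted substrates
#'
#' Targets (already sorted by weight, descending) are accumulated until the
#' running sum of squared normalized weights
#' `s_k = sum_{i<=k} (w_i / w_1)^2` reaches `tTarget`, subject to a hard cap
#' of `nMax` substrates; if the threshold is never reached all targets are
#' kept (up to the cap).
#'
#' @param targets data.frame with a `weight` column, sorted by weight
#'   descending.
#' @param nMax maximum number of substrates retained.
#' @param tTarget stopping threshold on the cumulative squared normalized
#'   weight (> 0).
#' @return The trimmed prefix of `targets`.
#' @export
trimSignalon <- function(targets, nMax = 500L, tTarget = 50) {
    if (tTarget <= 0) stop("tTarget must be positive")
    if (!nrow(targets)) return(targets)
    w <- targets$weight
    if (is.unsorted(-w)) stop("targets must be sorted by weight, descending")
    s <- cumsum((w / w[1])^2)
    k <- if (any(s >= tTarget)) which(s >= tTarget)[1] else nrow(targets)
    targets[seq_len(min(nMax, k)), , drop = FALSE]
}

#' Build signalons from a consensus network
#'
#' Converts an interaction table into per-regulator [Signalon-class]
#' objects: probabilistic weights ([signalonWeights()], network-wide MI
#' normalization, optional priors), mode of regulation from one
#' three-Gaussian mixture fitted to all network Spearman correlations
#' ([modeOfRegulation()]), weight-based trimming ([trimSignalon()]), and a
#' minimum-size filter (`minSize`, default 5 substrates).
#'
#' @param net interaction data.frame from [dissect()] /
#'   [consensusNetwork()].
#' @param level,source level and dataset tags stored on each signalon.
#' @param minSize minimum number of substrates for a signalon to be kept.
#' @param nMax,tTarget trimming parameters, see [trimSignalon()].
#' @param seed seed for the mixture fit.
#' @return A [SignalonList-class] keyed by regulator.
#' @export
buildSignalons <- function(net, level = "phosphostate:site",
                           source = "default", minSize = 5L, nMax = 500L,
                           tTarget = 50, seed = 1L) {
    if (!nrow(net)) return(SignalonList(list()))
    maxMi <- max(net$mi)
    if (maxMi <= 0) {
        message("all consensus edges have zero MI; no signalon built")
        return(SignalonList(list()))
    }
    rhos <- net$rho
    rhos[is.na(rhos)] <- 0
    modes <- modeOfRegulation(rhos, seed = seed)
    out <- lapply(split(seq_len(nrow(net)), net$regulator), function(i) {
        pri <- net$prior[i]
        pri <- if (all(is.na(pri))) NULL else ifelse(is.na(pri), 1, pri)
        tg <- data.frame(target = net$target[i],
                         weight = signalonWeights(net$mi[i], maxMi, pri),
                         mode = modes[i])
        tg <- tg[tg$weight > 0, , drop = FALSE]
        tg <- tg[order(-tg$weight, tg$target), , drop = FALSE]
        tg <- trimSignalon(tg, nMax = nMax, tTarget = tTarget)
        if (nrow(tg) < minSize) return(NULL)
        rownames(tg) <- NULL
        Signalon(net$regulator[i[1]], tg, level = level, source = source)
    })
    SignalonList(Filter(Negate(is.null), out))
}

#' Select the best signalon per regulator across datasets
#'
#' Given several candidate signalons for the same regulator (different
#' source datasets, sites, or priors), scores each candidate on an ensemble
#' of signatures by enrichment (|NES|) and keeps the candidate with the
#' highest median |NES|, on the assumption that an incorrect signalon can
#' only reduce the enrichment score. Candidates with fewer than `minSize`
#' targets present in the signature feature space are skipped; regulators
#' with no usable candidate are excluded with a message.
#'
#' @param candidates a [SignalonList-class] (possibly several entries per
#'   regulator) or list of SignalonLists.
#' @param signatures list of [Signature-class] objects to score on.
#' @param minSize minimum usable targets.
#' @return A [SignalonList-class] with one winner per regulator.
#' @export
optimizeSignalons <- function(candidates, signatures, minSize = 5L) {
    if (is(candidates, "SignalonList")) candidates <- as.list(candidates)
    if (length(candidates) && is(candidates[[1]], "SignalonList"))
        candidates <- unlist(lapply(candidates, as.list), recursive = FALSE)
    regs <- vapply(candidates, function(s) s@regulator, "")
    winners <- lapply(split(seq_along(candidates), regs), function(ii) {
        scores <- vapply(ii, function(i) {
            s <- candidates[[i]]
            vals <- vapply(signatures, function(sig) {
                n <- tryCatch(enrichmentNES(sig, s, minSize = minSize),
                              error = function(e) NA_real_)
                abs(n)
            }, 0)
            if (all(is.na(vals))) NA_real_ else median(vals, na.rm = TRUE)
        }, 0)
        if (all(is.na(scores))) {
            message("regulator ", candidates[[ii[1]]]@regulator,
                    ": no candidate signalon reaches the minimum size; ",
                    "excluded")
            return(NULL)
        }
        candidates[[ii[which.max(scores)]]]
    })
    SignalonList(Filter(Negate(is.null), winners))
}

#' Remove redundant, highly correlated signalons
#'
#' Site-specific signalons derived from the same phosphopeptide are often
#' near-duplicates. Given the activity matrix of the signalons, this greedy
#' filter repeatedly drops the signalon with the largest mean absolute
#' correlation to the remaining ones until no pair exceeds `cutoff`.
#'
#' @param signalons a [SignalonList-class].
#' @param activity matrix of per-signalon activity profiles (signalons x
#'   samples, rows named like `signalons`) used to measure correlation.
#' @param cutoff absolute correlation cutoff.
#' @return The reduced [SignalonList-class].
#' @export
deduplicateSignalons <- function(signalons, activity, cutoff = 0.5) {
    keep <- names(signalons)
    stopifnot(all(keep %in% rownames(activity)))
    while (length(keep) > 1L) {
        cc <- abs(cor(t(activity[keep, , drop = FALSE])))
        diag(cc) <- 0
        if (max(cc) <= cutoff) break
        meanAbs <- rowSums(cc) / (length(keep) - 1L)
        keep <- keep[-which.max(meanAbs)]
    }
    SignalonList(as.list(signalons)[keep])
}

#' Read / write signalon tables
#'
#' Round-trippable TSV with one row per target: `regulator`, `level`,
#' `source`, `target`, `weight`, `mode`.
#'
#' @param signalons a [SignalonList-class].
#' @param path file path.
#' @rdname signalon-files
#' @return `writeSignalons()`: the path invisibly; `readSignalons()`: a
#'   [SignalonList-class].
#' @export
writeSignalons <- function(signalons, path) {
    rows <- lapply(as.list(signalons), function(s) {
        data.frame(regulator = s@regulator, level = s@level,
                   source = s@source, s@targets)
    })
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname signalon-files
#' @export
readSignalons <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    out <- lapply(split(df, df$regulator), function(d) {
        Signalon(d$regulator[1],
                 data.frame(target = d$target, weight = d$weight,
                            mode = d$mode),
                 level = d$level[1], source = d$source[1])
    })
    SignalonList(out)
}
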