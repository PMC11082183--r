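#' Gold-standard edge sets for benchmarking
#'
#' @param positives,negatives data.frames with `regulator` and `target`
#'   columns (disjoint sets).
#' @param priors optional per-positive-edge prior weights.
#' @return A `GoldStandard` list.
#' @export
goldStandard <- function(positives, negatives, priors = NULL) {
    pk <- paste(positives$regulator, positives$target, sep = "\r")
    nk <- paste(negatives$regulator, negatives$target, sep = "\r")
    if (length(intersect(pk, nk)))
        stop("positive and negative gold-standard sets must be disjoint")
    structure(list(positives = positives, negatives = negatives,
                   priors = priors), class = "GoldStandard")
}

#' ROC and precision-recall curves for scored edge predictions
#'
#' Standard threshold sweep over the prediction score, trapezoidal area
#' under both curves; the AUROC is computed by the tie-aware rank
#' (Mann-Whitney) formula.
#'
#' @param scores numeric prediction scores (higher = more confident), or a
#'   data.frame with `regulator`, `target`, and a score column named by
#'   `scoreColumn`, in which case `gold` labels the edges (edges absent
#'   from the gold standard are ignored).
#' @param labels logical/0-1 vector of true labels aligned with `scores`
#'   (ignored when `gold` is given).
#' @param gold optional [goldStandard()].
#' @param scoreColumn score column name for data.frame input.
#' @return List with `roc` (fpr, tpr), `pr` (recall, precision), `auroc`,
#'   `auprc`. Errors when either class is empty.
#' @export
prRoc <- function(scores, labels = NULL, gold = NULL, scoreColumn = "mi") {
    if (is.data.frame(scores)) {
        stopifnot(!is.null(gold))
        key <- paste(scores$regulator, scores$target, sep = "\r")
        pk <- paste(gold$positives$regulator, gold$positives$target,
                    sep = "\r")
        nk <- paste(gold$negatives$regulator, gold$negatives$target,
                    sep = "\r")
        # edges never predicted still count: they get score -Inf
        s <- scores[[scoreColumn]][match(c(pk, nk), key)]
        s[is.na(s)] <- -Inf
        labels <- rep(c(TRUE, FALSE), c(length(pk), length(nk)))
        scores <- s
    }
    labels <- as.logical(labels)
    nP <- sum(labels); nN <- sum(!labels)
    if (nP == 0L || nN == 0L)
        stop("gold standard is degenerate: need >= 1 positive and >= 1 ",
             "negative")
    r <- rank(scores)
    auroc <- (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
    o <- order(scores, decreasing = TRUE)
    tp <- cumsum(labels[o]); fp <- cumsum(!labels[o])
    last <- !duplicated(scores[o][seq_along(o)], fromLast = TRUE)
    tp <- tp[last]; fp <- fp[last]
    roc <- data.frame(fpr = c(0, fp / nN), tpr = c(0, tp / nP))
    pr <- data.frame(recall = tp / nP, precision = tp / (tp + fp))
    auprc <- sum(diff(c(0, pr$recall)) * pr$precision)
    list(roc = roc, pr = pr, auroc = auroc, auprc = auprc)
}

#' Precision at a fixed recall level
#'
#' @param pr the `pr` component of [prRoc()] (or the full result).
#' @param recall target recall level in (0, 1].
#' @return Precision at the first sweep point reaching the target recall,
#'   or `NA` when the predictions never reach it.
#' @export
precisionAtRecall <- function(pr, recall = 0.25) {
    if (is.list(pr) && !is.data.frame(pr)) pr <- pr$pr
    i <- which(pr$recall >= recall)
    if (!length(i)) return(NA_real_)
    pr$precision[i[1]]
}

#' Integrated drug-sensitivity benchmark score
#'
#' Partial sum of per-protein differential-activity scores weighted by drug
#' sensitivity: `S(n) = sum_{i=1..n} w_i * DP_i` over the top `n` proteins
#' (ranked most to least significant).
#'
#' @param dp differential activity scores, ranked most to least
#'   significant.
#' @param w aligned per-protein sensitivity weights.
#' @param n number of top proteins integrated (truncated with a warning
#'   when larger than the list).
#' @return The score.
#' @export
weightedSensitivityScore <- function(dp, w, n) {
    stopifnot(length(dp) == length(w), n >= 0)
    if (n > length(dp)) {
        warning("n exceeds the ranked list length; truncated to ",
                length(dp))
        n <- length(dp)
    }
    if (n == 0L) return(0)
    sum(w[seq_len(n)] * dp[seq_len(n)])
}

#' Score an inferred network and activities against simulation ground truth
#'
#' @param net predicted interaction data.frame (`regulator`, `target`).
#' @param truth the `truth` component of [simulatePhospho()].
#' @param activity optional [ActivitySet-class] of inferred activities.
#' @return List with `precision` (NA when nothing was predicted), `recall`,
#'   `indirectFalseInclusion` (fraction of true indirect pairs present in
#'   the prediction), and, when `activity` is given, `activitySpearman`
#'   (per-regulator correlation of inferred NES with true activity) and its
#'   `medianActivitySpearman`.
#' @export
recoveryReport <- function(net, truth, activity = NULL) {
    direct <- truth$edges[truth$edges$type == "direct", ]
    indirect <- truth$edges[truth$edges$type == "indirect", ]
    dk <- paste(direct$regulator, direct$target, sep = "\r")
    ik <- paste(indirect$regulator, indirect$target, sep = "\r")
    pk <- if (nrow(net)) paste(net$regulator, net$target, sep = "\r")
          else character()
    out <- list(
        precision = if (length(pk)) mean(pk %in% dk) else NA_real_,
        recall = if (length(dk)) mean(dk %in% pk) else NA_real_,
        indirectFalseInclusion = if (length(ik)) mean(ik %in% pk)
                                 else NA_real_)
    if (!is.null(activity)) {
        nesM <- nes(activity)
        shared <- intersect(rownames(nesM), rownames(truth$activities))
        rho <- vapply(shared, function(r)
            suppressWarnings(cor(nesM[r, colnames(truth$activities)],
                                 truth$activities[r, ],
                                 method = "spearman")), 0)
        out$activitySpearman <- rho
        out$medianActivitySpearman <- median(rho, na.rm = TRUE)
    }
    out
}
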