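#' Candidate interaction specification
#'
#' Restricts which regulator-target pairs the network dissection considers.
#' Three modes: `"enzyme-list"` (all enzyme x substrate combinations),
#' `"signed-enzyme-list"` (additionally requires positive Spearman
#' correlation for kinase edges and negative for phosphatase edges before an
#' edge can enter the consensus), and `"reference-network"` (candidates are
#' restricted to a supplied edge list with optional priors in [0, 1]).
#'
#' @param kinases,phosphatases character vectors of enzyme feature ids
#'   (disjoint).
#' @param mode candidate-restriction mode.
#' @param substrates optional whitelist of substrate feature ids; by default
#'   every feature (including other enzymes) is a candidate target.
#' @param referenceEdges optional data.frame `regulator`, `target`,
#'   `prior` (in [0, 1]) for `"reference-network"` mode.
#' @return A `CandidateSpec` list used by [bootstrapNetwork()] / [dissect()].
#' @export
candidateSpec <- function(kinases, phosphatases = character(),
                          mode = c("enzyme-list", "signed-enzyme-list",
                                   "reference-network"),
                          substrates = NULL, referenceEdges = NULL) {
    mode <- match.arg(mode)
    if (length(intersect(kinases, phosphatases)))
        stop("kinases and phosphatases must be disjoint")
    if (mode == "reference-network") {
        if (is.null(referenceEdges))
            stop("reference-network mode needs referenceEdges")
        if (is.null(referenceEdges$prior))
            referenceEdges$prior <- 1
        if (any(referenceEdges$prior < 0 | referenceEdges$prior > 1))
            stop("priors must lie in [0, 1]")
    }
    structure(list(mode = mode, kinases = unique(kinases),
                   phosphatases = unique(phosphatases),
                   substrates = substrates,
                   referenceEdges = referenceEdges),
              class = "CandidateSpec")
}

# node class lookup: kinase / phosphatase / substrate
.nodeClasses <- function(spec, ids) {
    cls <- rep("substrate", length(ids))
    cls[ids %in% spec$kinases] <- "kinase"
    cls[ids %in% spec$phosphatases] <- "phosphatase"
    names(cls) <- ids
    cls
}

# candidate (regulator, target) id pairs for a matrix + spec
.candidatePairs <- function(m, spec) {
    ids <- rownames(m)
    regs <- intersect(c(spec$kinases, spec$phosphatases), ids)
    if (!length(regs)) stop("no regulator features present in the matrix")
    if (spec$mode == "reference-network") {
        re <- spec$referenceEdges
        keep <- re$regulator %in% ids & re$target %in% ids &
            re$regulator %in% regs
        re <- re[keep & re$regulator != re$target, , drop = FALSE]
        if (!nrow(re)) stop("candidate specification yields zero pairs")
        return(data.frame(regulator = re$regulator, target = re$target,
                          prior = re$prior))
    }
    tg <- if (is.null(spec$substrates)) ids
          else intersect(union(spec$substrates, regs), ids)
    pairs <- expand.grid(regulator = regs, target = tg,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
    if (!nrow(pairs)) stop("candidate specification yields zero pairs")
    pairs$prior <- NA_real_
    pairs
}

#' Prune indirect edges by the (signal-transduction) data processing
#' inequality
#'
#' For every information triangle `R1 -> R2`, `R2 -> T`, `R1 -> T`, the edge
#' `R1 -> T` is removed when its MI is the strict minimum of the three
#' (within `tolerance`). Under `"stdpi"` a triangle is only assessed when the
#' intermediary `R2` is a kinase: kinase-kinase-substrate and
#' phosphatase-kinase-substrate triangles are tested, while
#' kinase-phosphatase-substrate and phosphatase-phosphatase-substrate
#' triangles are never pruned, because an indirect path through a phosphatase
#' would invert the effect on the substrate. Under `"dpi"` all triangles are
#' assessed.
#'
#' @param edges data.frame with columns `regulator`, `target`, `mi`.
#' @param classes named character vector mapping every node id to
#'   `"kinase"`, `"phosphatase"`, or `"substrate"`.
#' @param mode `"dpi"` or `"stdpi"`.
#' @param tolerance nonnegative slack: `R1 -> T` is pruned when
#'   `mi(R1,T) < min(mi(R1,R2), mi(R2,T)) - tolerance`.
#' @return The pruned edge data.frame.
#' @export
dpiPrune <- function(edges, classes, mode = c("stdpi", "dpi"),
                     tolerance = 0) {
    mode <- match.arg(mode)
    if (!nrow(edges)) return(edges)
    nodes <- unique(c(edges$regulator, edges$target))
    if (!all(nodes %in% names(classes)))
        stop("node(s) without a class: ",
             paste(utils::head(setdiff(nodes, names(classes)), 5),
                   collapse = ", "))
    key <- paste(edges$regulator, edges$target, sep = "\r")
    mi <- structure(edges$mi, names = key)
    drop <- logical(nrow(edges))
    byReg <- split(seq_len(nrow(edges)), edges$regulator)
    for (r1 in names(byReg)) {
        e1 <- byReg[[r1]]
        tg1 <- edges$target[e1]
        # intermediaries: targets of r1 that are regulators themselves
        mids <- intersect(tg1, names(byReg))
        for (r2 in mids) {
            if (mode == "stdpi" && classes[[r2]] != "kinase") next
            mi12 <- mi[[paste(r1, r2, sep = "\r")]]
            e2 <- byReg[[r2]]
            shared <- intersect(tg1, edges$target[e2])
            shared <- setdiff(shared, c(r1, r2))
            for (tt in shared) {
                mi1t <- mi[[paste(r1, tt, sep = "\r")]]
                mi2t <- mi[[paste(r2, tt, sep = "\r")]]
                if (mi1t < min(mi12, mi2t) - tolerance)
                    drop[e1[match(tt, tg1)]] <- TRUE
            }
        }
    }
    edges[!drop, , drop = FALSE]
}

#' Bootstrapped network reconstruction
#'
#' For each bootstrap round, runs (columns) are resampled with replacement,
#' MI is recomputed for every candidate pair, edges below the full-data
#' significance threshold are dropped, and the selected DPI variant prunes
#' indirect edges. Per-bootstrap seeds are derived deterministically from the
#' master seed and the bootstrap index, so results are reproducible and
#' independent of execution order.
#'
#' @param x a [PhosphoSet-class] or numeric matrix.
#' @param spec a [candidateSpec()].
#' @param nBoot number of bootstrap rounds (>= 2).
#' @param dpi `"stdpi"`, `"dpi"`, or `"none"`.
#' @param fwer family-wise error rate for the MI threshold (ignored when
#'   `threshold` is given).
#' @param threshold precomputed MI threshold; computed from the full matrix
#'   by [nullMIThreshold()] when `NULL`.
#' @param tolerance DPI tolerance, see [dpiPrune()].
#' @param seed master integer seed.
#' @param nPerm permutation rounds for the threshold when computed here.
#' @return A list with `edgeSets` (one data.frame `regulator`, `target`,
#'   `mi` per bootstrap), `threshold`, and `pairs` (the candidate pairs).
#' @export
bootstrapNetwork <- function(x, spec, nBoot = 200L,
                             dpi = c("stdpi", "dpi", "none"), fwer = 0.05,
                             threshold = NULL, tolerance = 0, seed = 1L,
                             nPerm = 10L) {
    dpi <- match.arg(dpi)
    if (nBoot < 2L) stop("nBoot must be at least 2")
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    pairs <- .candidatePairs(m, spec)
    ri <- match(pairs$regulator, rownames(m))
    ti <- match(pairs$target, rownames(m))
    if (is.null(threshold)) {
        # enough permutation rounds to resolve the null for small networks
        nPermUse <- max(nPerm, ceiling(max(1000, 20 / fwer) /
                                       min(nrow(pairs), 3000L)) + 1L)
        threshold <- nullMIThreshold(m, unique(pairs$regulator),
                                     unique(pairs$target), fwer = fwer,
                                     nPerm = nPermUse, seed = seed)
    }
    classes <- .nodeClasses(spec, rownames(m))
    edgeSets <- lapply(seq_len(nBoot), function(b) {
        bseed <- (seed * 1009L + b) %% .Machine$integer.max
        cols <- withr::with_seed(bseed,
                                 sample.int(ncol(m), ncol(m), replace = TRUE))
        mis <- .miPairs(m, ri, ti, cols = cols, seed = bseed)
        keep <- mis >= threshold
        ed <- data.frame(regulator = pairs$regulator[keep],
                         target = pairs$target[keep], mi = mis[keep])
        if (dpi != "none" && nrow(ed))
            ed <- dpiPrune(ed, classes, mode = dpi, tolerance = tolerance)
        ed
    })
    list(edgeSets = edgeSets, threshold = threshold, pairs = pairs)
}

#' Poisson consensus over bootstrap networks
#'
#' Each candidate edge's bootstrap support `k` is scored by the upper-tail
#' Poisson probability `P(X >= k)` with rate `lambda` equal to the mean
#' support over all edges ever detected (total edge occurrences divided by
#' the number of distinct detected edges); p-values are Benjamini-Hochberg
#' adjusted and edges with adjusted p below `alpha` are retained. Full-data
#' MI, Spearman rho on jointly observed points, and any reference prior are
#' attached. In `"signed-enzyme-list"` mode, kinase edges additionally
#' require `rho > 0` and phosphatase edges `rho < 0`.
#'
#' @param boot result of [bootstrapNetwork()], or a bare list of per-bootstrap
#'   edge data.frames.
#' @param x the [PhosphoSet-class] or matrix the bootstraps were drawn from.
#' @param spec the [candidateSpec()].
#' @param alpha significance level on BH-adjusted Poisson p-values.
#' @return An interaction data.frame with columns `regulator`, `target`,
#'   `mi`, `support`, `pvalue`, `rho`, `prior`; empty (with a warning) when
#'   no bootstrap detected any edge.
#' @export
consensusNetwork <- function(boot, x, spec, alpha = 0.05) {
    edgeSets <- if (is.list(boot) && !is.null(boot$edgeSets)) boot$edgeSets
                else boot
    if (length(edgeSets) < 2L) stop("need at least 2 bootstraps")
    m <- if (is(x, "PhosphoSet")) intensities(x) else x
    allEdges <- do.call(rbind, edgeSets)
    emptyNet <- data.frame(regulator = character(), target = character(),
                           mi = numeric(), support = integer(),
                           pvalue = numeric(), rho = numeric(),
                           prior = numeric())
    if (is.null(allEdges) || !nrow(allEdges)) {
        warning("no edges detected in any bootstrap; empty network")
        return(emptyNet)
    }
    key <- paste(allEdges$regulator, allEdges$target, sep = "\r")
    support <- table(key)
    lambda <- length(key) / length(support)
    kk <- strsplit(names(support), "\r", fixed = TRUE)
    net <- data.frame(regulator = vapply(kk, `[`, "", 1L),
                      target = vapply(kk, `[`, "", 2L),
                      support = as.integer(support))
    net$pvalue <- ppois(net$support - 1L, lambda, lower.tail = FALSE)
    net$pvalue <- pmin(pmax(net$pvalue, .Machine$double.xmin), 1)
    padj <- p.adjust(net$pvalue, method = "BH")
    net <- net[padj < alpha, , drop = FALSE]
    if (!nrow(net)) {
        warning("no edge reached consensus significance; empty network")
        return(emptyNet)
    }
    ri <- match(net$regulator, rownames(m))
    ti <- match(net$target, rownames(m))
    net$mi <- .miPairs(m, ri, ti)
    net$rho <- vapply(seq_len(nrow(net)), function(i)
        spearmanComplete(m[ri[i], ], m[ti[i], ]), 0)
    if (!is.null(boot$pairs)) {
        pk <- paste(boot$pairs$regulator, boot$pairs$target, sep = "\r")
        net$prior <- boot$pairs$prior[match(paste(net$regulator, net$target,
                                                  sep = "\r"), pk)]
    } else net$prior <- NA_real_
    if (spec$mode == "signed-enzyme-list") {
        sgn <- ifelse(net$regulator %in% spec$kinases, 1, -1)
        net <- net[!is.na(net$rho) & sign(net$rho) == sgn, , drop = FALSE]
    }
    rownames(net) <- NULL
    net[order(net$regulator, net$target),
        c("regulator", "target", "mi", "support", "pvalue", "rho", "prior")]
}

#' Full network dissection pipeline
#'
#' Threshold selection, bootstrapped MI network reconstruction, DPI pruning,
#' and Poisson consensus in one call. `level = "protein"` first combines the
#' regulator phosphosite rows into whole-protein abundance rows
#' ([aggregateToProtein()]) so the network associates protein-level enzyme
#' abundance with substrate sites. Deterministic for a fixed seed.
#'
#' @inheritParams bootstrapNetwork
#' @param level `"site"` (phosphosite-phosphosite) or `"protein"`.
#' @param threshold optional precomputed MI threshold (skips the
#'   permutation null).
#' @param alpha consensus significance level.
#' @return An interaction data.frame, see [consensusNetwork()].
#' @export
dissect <- function(x, spec, level = c("site", "protein"),
                    dpi = c("stdpi", "dpi", "none"), nBoot = 200L,
                    fwer = 0.05, alpha = 0.05, tolerance = 0, seed = 1L,
                    nPerm = 10L, threshold = NULL) {
    level <- match.arg(level)
    dpi <- match.arg(dpi)
    ps <- if (is(x, "PhosphoSet")) x else PhosphoSet(x)
    if (level == "protein") {
        regIds <- intersect(c(spec$kinases, spec$phosphatases), siteIds(ps))
        regSet <- aggregateToProtein(ps[regIds, ])
        rest <- ps[setdiff(siteIds(ps), regIds), ]
        m <- rbind(intensities(regSet), intensities(rest))
        ps <- PhosphoSet(m, rowData = rbind(rowData(regSet), rowData(rest)))
        spec <- candidateSpec(
            kinases = .proteinKey(regIds, spec$kinases),
            phosphatases = .proteinKey(regIds, spec$phosphatases),
            mode = spec$mode, substrates = spec$substrates,
            referenceEdges = spec$referenceEdges)
    }
    boot <- bootstrapNetwork(ps, spec, nBoot = nBoot, dpi = dpi, fwer = fwer,
                             threshold = threshold, tolerance = tolerance,
                             seed = seed, nPerm = nPerm)
    consensusNetwork(boot, ps, spec, alpha = alpha)
}

# map site ids to their protein (PA) keys, restricted to a subset
.proteinKey <- function(regIds, subset) {
    ids <- intersect(regIds, subset)
    unique(vapply(strsplit(ids, ":", fixed = TRUE), function(p)
        paste(p[1], p[2], "PA", sep = ":"), ""))
}

#' Read / write interaction networks
#'
#' Tab-separated edge lists (`regulator`, `target`, `mi`, `support`,
#' `pvalue`, `rho`, `prior`) in the de-facto ARACNe interchange layout.
#'
#' @param net interaction data.frame.
#' @param path file path.
#' @rdname network-files
#' @return `writeNetwork()`: the path invisibly; `readNetwork()`: the edge
#'   data.frame.
#' @export
writeNetwork <- function(net, path) {
    write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname network-files
#' @export
readNetwork <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
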