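#' Configuration for the synthetic phosphoproteomic generator
#'
#' The generator emulates the statistical structure the network-dissection
#' and activity-inference steps assume: a known bipartite (and optionally
#' hierarchical) enzyme-substrate network with signed monotone effects,
#' log2-intensity observations with additive Gaussian noise, value-dependent
#' censoring below a per-feature limit of detection (MNAR missingness), and
#' optional batch mean-shifts.
#'
#' Latent enzyme activities are standard normal around a basal level of 1;
#' substrate log-intensities are signed, scaled sums of their parent
#' activities plus noise, with the scale chosen so the expected Spearman
#' correlation of a planted edge is `effectRho` (via the normal-score
#' relation `r_pearson = 2 sin(pi rho / 6)`). Kinase edges are signed `+`,
#' phosphatase edges `-`; a phosphatase parent in a regulatory chain
#' deactivates its child enzyme. Chains of `chainDepth` enzymes (interleaved
#' kinases and phosphatases) create known indirect regulator-substrate
#' pairs; for kinase-parent/phosphatase-child links a fraction `chainCoreg`
#' of the child's substrates is also directly co-regulated by the parent
#' (both loadings at `coregWeight` times the edge scale), producing the
#' incoherent triangles that distinguish the plain and signal-transduction
#' DPI variants.
#'
#' @param nKinases,nPhosphatases,nSubstrates network size.
#' @param targetsPerEnzyme substrates per enzyme (blocks of the substrate
#'   list; remaining substrates are independent noise).
#' @param effectRho expected Spearman correlation of a planted edge,
#'   in (0, 1).
#' @param effectRhoSpread half-width of a uniform per-substrate spread
#'   around `effectRho` (0 = all edges equally strong); real networks show
#'   a continuum of effect sizes.
#' @param chainRho expected Spearman correlation of an enzyme-enzyme chain
#'   link (enzyme cascades are typically tighter than enzyme-substrate
#'   edges); defaults to `effectRho`.
#' @param kpLinkRho chain-link strength used specifically for
#'   kinase-parent/phosphatase-child links (the incoherent-triangle motif
#'   is only feasible when this stays moderate); defaults to `chainRho`.
#' @param chainDepth number of hierarchy levels in the enzyme chain
#'   (1 = none).
#' @param chainChildren number of child enzymes per hierarchy level (each
#'   linked round-robin to a parent of the previous level); 1 gives a plain
#'   chain, larger values a tree.
#' @param chainCoreg fraction of a chain child's substrates co-regulated
#'   directly by the parent.
#' @param coregWeight parent loading (relative to the standard edge scale)
#'   on co-regulated substrates; with a kinase parent and phosphatase child
#'   large values approach the correlation-feasibility limit of the
#'   incoherent triangle (all three pairwise correlations near 0.5).
#' @param coregChildWeight child loading on co-regulated substrates
#'   (defaults to `coregWeight`); a slightly larger child loading makes the
#'   parent edge the weakest of the triangle.
#' @param nSamples number of runs.
#' @param noiseSd substrate noise standard deviation (> 0).
#' @param proxyNoiseSd noise on the enzyme phosphopeptide proxy rows.
#' @param lodQuantile per-feature censoring level in [0, 1): values below
#'   this quantile of the feature's marginal are set missing.
#' @param enzymeLodQuantile censoring level for the enzyme proxy peptide
#'   rows (defaults to `lodQuantile`); enzyme phosphopeptides usable as
#'   network proxies are typically well-detected, so lower values are
#'   realistic.
#' @param batchShiftSd standard deviation of optional per-feature batch
#'   mean-shifts (two batches; 0 = none).
#' @param censorRegulators enzyme indices (1-based over kinases then
#'   phosphatases) whose phosphopeptide rows are removed entirely; a
#'   whole-protein abundance (`PA`) row with weaker activity correlation
#'   `paProxyRho` is emitted instead (the protein-abundance proxy mode for
#'   enzymes without measured phosphopeptides).
#' @param paProxyRho Spearman correlation of a `PA` proxy row with the
#'   enzyme's activity.
#' @param seed integer seed; fixed seed implies identical output.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(nKinases = 5L, nPhosphatases = 3L, nSubstrates = 320L,
                      targetsPerEnzyme = 40L, effectRho = 0.5,
                      effectRhoSpread = 0, chainRho = effectRho,
                      kpLinkRho = chainRho,
                      chainDepth = 1L, chainChildren = 1L,
                      chainCoreg = 0.25, coregWeight = 1,
                      coregChildWeight = coregWeight,
                      nSamples = 150L,
                      noiseSd = 1, proxyNoiseSd = 0.2, lodQuantile = 0.4,
                      enzymeLodQuantile = lodQuantile,
                      batchShiftSd = 0, censorRegulators = integer(),
                      paProxyRho = 0.4, seed = 1L) {
    stopifnot(nKinases >= 1, nSubstrates >= 1, targetsPerEnzyme >= 1,
              nSamples >= 1, effectRho > 0, effectRho < 1,
              lodQuantile >= 0, lodQuantile < 1, chainCoreg >= 0,
              chainCoreg <= 1)
    if (noiseSd <= 0)
        stop("noiseSd must be > 0: with zero noise the attainable edge ",
             "correlation is exactly 1, not effectRho")
    E <- nKinases + nPhosphatases
    if (nSubstrates < E * targetsPerEnzyme)
        stop("nSubstrates must be at least (nKinases + nPhosphatases) * ",
             "targetsPerEnzyme = ", E * targetsPerEnzyme)
    structure(list(nKinases = as.integer(nKinases),
                   nPhosphatases = as.integer(nPhosphatases),
                   nSubstrates = as.integer(nSubstrates),
                   targetsPerEnzyme = as.integer(targetsPerEnzyme),
                   effectRho = effectRho, effectRhoSpread = effectRhoSpread,
                   chainRho = chainRho, kpLinkRho = kpLinkRho,
                   chainDepth = as.integer(chainDepth),
                   chainChildren = as.integer(chainChildren),
                   chainCoreg = chainCoreg, coregWeight = coregWeight,
                   coregChildWeight = coregChildWeight,
                   nSamples = as.integer(nSamples),
                   noiseSd = noiseSd, proxyNoiseSd = proxyNoiseSd,
                   lodQuantile = lodQuantile,
                   enzymeLodQuantile = enzymeLodQuantile,
                   batchShiftSd = batchShiftSd,
                   censorRegulators = as.integer(censorRegulators),
                   paProxyRho = paProxyRho, seed = as.integer(seed)),
              class = "SimConfig")
}

# Spearman -> Pearson for bivariate normal scores
.rhoPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)

# enzyme bookkeeping shared by the generators
.enzymeLayout <- function(cfg) {
    E <- cfg$nKinases + cfg$nPhosphatases
    isKin <- c(rep(TRUE, cfg$nKinases), rep(FALSE, cfg$nPhosphatases))
    gene <- ifelse(isKin, sprintf("KIN%d", seq_len(E)),
                   sprintf("PHO%d", seq_len(E)))
    prot <- sprintf("P%05d", seq_len(E))
    censored <- seq_len(E) %in% cfg$censorRegulators
    site <- ifelse(censored, "PA", "S100")
    featureId <- paste(gene, prot, site, sep = ":")
    # interleave kinases and phosphatases for the chain ordering
    kIdx <- which(isKin); pIdx <- which(!isKin)
    ord <- integer(0)
    for (i in seq_len(max(length(kIdx), length(pIdx)))) {
        if (i <= length(kIdx)) ord <- c(ord, kIdx[i])
        if (i <= length(pIdx)) ord <- c(ord, pIdx[i])
    }
    links <- NULL
    if (cfg$chainDepth >= 2L) {
        nc <- if (is.null(cfg$chainChildren)) 1L
              else max(1L, cfg$chainChildren)
        pos <- 1L
        level <- ord[1L]
        for (d in seq_len(cfg$chainDepth - 1L)) {
            lo <- pos + 1L
            hi <- min(pos + nc, E)
            if (lo > hi) break
            children <- ord[lo:hi]
            parent <- rep_len(level, length(children))
            links <- rbind(links, cbind(parent = unname(parent),
                                        child = unname(children)))
            level <- children
            pos <- hi
        }
    }
    list(E = E, isKin = isKin, gene = gene, prot = prot,
         censored = censored, featureId = featureId, ord = ord,
         links = links)
}

# latent activities (E x n) given innovations (E x n); chains resolved in
# link order, phosphatase parents deactivate their children
.latentActivities <- function(cfg, lay, innov) {
    act <- innov
    rpChain <- .rhoPearson(if (is.null(cfg$chainRho)) cfg$effectRho
                           else cfg$chainRho)
    rpKP <- .rhoPearson(if (is.null(cfg$kpLinkRho)) cfg$chainRho
                        else cfg$kpLinkRho)
    if (!is.null(lay$links)) {
        for (k in seq_len(nrow(lay$links))) {
            p <- lay$links[k, "parent"]; ch <- lay$links[k, "child"]
            rp <- if (lay$isKin[p] && !lay$isKin[ch]) rpKP else rpChain
            s <- if (lay$isKin[p]) 1 else -1
            act[ch, ] <- s * rp * act[p, ] + sqrt(1 - rp^2) * innov[ch, ]
        }
    }
    act + 1  # basal activity level
}

# substrate parent map: list per substrate of (enzyme, weightFactor)
.substrateParents <- function(cfg, lay) {
    parents <- vector("list", cfg$nSubstrates)
    tpe <- cfg$targetsPerEnzyme
    for (e in seq_len(lay$E)) {
        block <- ((e - 1L) * tpe + 1L):(e * tpe)
        for (s in block) parents[[s]] <- list(c(enzyme = e, w = 1))
    }
    if (!is.null(lay$links)) {
        for (k in seq_len(nrow(lay$links))) {
            p <- lay$links[k, "parent"]; ch <- lay$links[k, "child"]
            nCo <- round(cfg$chainCoreg * tpe)
            wCo <- if (is.null(cfg$coregWeight)) 1 else cfg$coregWeight
            wCh <- if (is.null(cfg$coregChildWeight)) wCo
                   else cfg$coregChildWeight
            # opposing co-regulation arises only for a kinase parent with a
            # phosphatase child (e.g. a kinase inducing its own negative
            # regulator); other sign combinations act in concert and are
            # left to the child alone
            if (!(lay$isKin[p] && !lay$isKin[ch])) nCo <- 0L
            if (nCo > 0) {
                block <- ((ch - 1L) * tpe + 1L):((ch - 1L) * tpe + nCo)
                for (s in block)
                    parents[[s]] <- list(c(enzyme = unname(ch), w = wCh),
                                         c(enzyme = unname(p), w = wCo))
            }
        }
    }
    parents
}

# per-substrate edge scale: b_s achieves the substrate's planted Spearman
.edgeScales <- function(cfg, rhoS) {
    rp <- .rhoPearson(pmin(0.95, pmax(0.05, rhoS)))
    cfg$noiseSd * rp / sqrt(1 - rp^2)
}

# assemble the value matrix from activities + fixed noise draws
.assembleValues <- function(cfg, lay, act, eps, proxyEps, baseline, rhoS) {
    n <- ncol(act)
    bS <- .edgeScales(cfg, rhoS)
    bRef <- .edgeScales(cfg, cfg$effectRho)
    parents <- .substrateParents(cfg, lay)
    nFeat <- lay$E + cfg$nSubstrates
    m <- matrix(0, nFeat, n)
    rpa <- .rhoPearson(cfg$paProxyRho)
    for (e in seq_len(lay$E)) {
        m[e, ] <- if (lay$censored[e])
            rpa * (act[e, ] - 1) + sqrt(1 - rpa^2) * proxyEps[e, ] + 1
        else act[e, ] + cfg$proxyNoiseSd * proxyEps[e, ]
    }
    for (s in seq_len(cfg$nSubstrates)) {
        v <- cfg$noiseSd * eps[s, ]
        for (pa in parents[[s]]) {
            e <- pa[["enzyme"]]
            sgn <- if (lay$isKin[e]) 1 else -1
            # co-regulated substrates use the reference scale so the
            # incoherent-triangle calibration is independent of the spread
            b <- if (length(parents[[s]]) > 1L) bRef else bS[s]
            v <- v + sgn * pa[["w"]] * b * act[e, ]
        }
        m[lay$E + s, ] <- v
    }
    m + baseline
}

.censorMatrix <- function(cfg, lay, m) {
    lod <- rep(-Inf, nrow(m))
    eLod <- if (is.null(cfg$enzymeLodQuantile)) cfg$lodQuantile
            else cfg$enzymeLodQuantile
    for (i in seq_len(nrow(m))) {
        if (i <= lay$E && lay$censored[i]) next  # PA rows stay complete
        q <- if (i <= lay$E) eLod else cfg$lodQuantile
        if (q <= 0) next
        lod[i] <- quantile(m[i, ], q, type = 7)
        m[i, m[i, ] < lod[i]] <- NA_real_
    }
    list(values = m, lod = lod)
}

#' Simulate a censored phosphoproteomic cohort with known ground truth
#'
#' @param cfg a [simConfig()].
#' @return A list with `phospho` (a [PhosphoSet-class]), and `truth`: a list
#'   of `edges` (data.frame `regulator`, `target`, `sign`, `type` =
#'   direct/indirect, `via` path witness for indirect edges), `activities`
#'   (enzymes x samples latent activity matrix, rows named by the enzymes'
#'   proxy feature ids), `lod` (per-feature censoring threshold),
#'   `kinases` / `phosphatases` (proxy feature ids by class), and
#'   `substrates` (substrate feature ids).
#' @examples
#' sim <- simulatePhospho(simConfig(nSamples = 40, nSubstrates = 320,
#'                                  seed = 7))
#' sim$phospho
#' head(sim$truth$edges)
#' @export
simulatePhospho <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    lay <- .enzymeLayout(cfg)
    n <- cfg$nSamples
    withr::with_seed(cfg$seed, {
        innov <- matrix(rnorm(lay$E * n), lay$E, n)
        proxyEps <- matrix(rnorm(lay$E * n), lay$E, n)
        eps <- matrix(rnorm(cfg$nSubstrates * n), cfg$nSubstrates, n)
        baseline <- rnorm(lay$E + cfg$nSubstrates, 20, 1.5)
        spread <- if (is.null(cfg$effectRhoSpread)) 0 else cfg$effectRhoSpread
        rhoS <- cfg$effectRho + runif(cfg$nSubstrates, -spread, spread)
        batch <- NULL
        if (cfg$batchShiftSd > 0)
            batch <- matrix(rnorm((lay$E + cfg$nSubstrates) * 2, 0,
                                  cfg$batchShiftSd),
                            ncol = 2)
    })
    act <- .latentActivities(cfg, lay, innov)
    m <- .assembleValues(cfg, lay, act, eps, proxyEps, baseline, rhoS)
    runGroups <- NULL
    if (!is.null(batch)) {
        half <- ceiling(n / 2)
        runGroups <- rep(c("batch1", "batch2"), c(half, n - half))
        m <- m + batch[, ifelse(runGroups == "batch1", 1, 2)]
    }
    subIds <- sprintf("SUB%03d:Q%05d:S10", seq_len(cfg$nSubstrates),
                      seq_len(cfg$nSubstrates))
    rownames(m) <- c(lay$featureId, subIds)
    colnames(m) <- sprintf("run%03d", seq_len(n))
    cen <- .censorMatrix(cfg, lay, m)
    ps <- PhosphoSet(cen$values, runGroups = runGroups)
    edges <- .truthEdges(cfg, lay, subIds)
    rownames(act) <- lay$featureId
    colnames(act) <- colnames(m)
    list(phospho = ps,
         truth = list(edges = edges, activities = act, lod = cen$lod,
                      kinases = lay$featureId[lay$isKin],
                      phosphatases = lay$featureId[!lay$isKin],
                      substrates = subIds))
}

.truthEdges <- function(cfg, lay, subIds) {
    parents <- .substrateParents(cfg, lay)
    rows <- list()
    for (s in seq_len(cfg$nSubstrates)) {
        for (pa in parents[[s]]) {
            e <- pa[["enzyme"]]
            rows[[length(rows) + 1L]] <- data.frame(
                regulator = lay$featureId[e], target = subIds[s],
                sign = if (lay$isKin[e]) 1 else -1, type = "direct",
                via = NA_character_)
        }
    }
    if (!is.null(lay$links)) {
        for (k in seq_len(nrow(lay$links))) {
            p <- lay$links[k, "parent"]; ch <- lay$links[k, "child"]
            rows[[length(rows) + 1L]] <- data.frame(
                regulator = lay$featureId[p],
                target = lay$featureId[ch],
                sign = if (lay$isKin[p]) 1 else -1, type = "direct",
                via = NA_character_)
            # parent -> child's exclusively-owned substrates are indirect
            tpe <- cfg$targetsPerEnzyme
            nCo <- round(cfg$chainCoreg * tpe)
            if (!(lay$isKin[p] && !lay$isKin[ch])) nCo <- 0L
            block <- ((ch - 1L) * tpe + nCo + 1L):(ch * tpe)
            # sign through the path: link sign times child's edge sign
            linkSign <- if (lay$isKin[p]) 1 else -1
            childSign <- if (lay$isKin[ch]) 1 else -1
            for (s in block) {
                rows[[length(rows) + 1L]] <- data.frame(
                    regulator = lay$featureId[p], target = subIds[s],
                    sign = linkSign * childSign, type = "indirect",
                    via = lay$featureId[ch])
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Simulate a drug-perturbation time series with matched vehicle control
#'
#' Generates `timepoints` blocks of `nReps` runs from the same latent model
#' and noise draws as the control series; in the perturbed series the target
#' enzyme's activity is multiplied by `(1 - inhibition)` from the first
#' timepoint on. An optional adaptive rebound linearly restores the activity
#' from `reboundStart` to full recovery at the last timepoint (an
#' adaptive-resistance surrogate). With `inhibition = 0` the perturbed
#' series equals the control series exactly.
#'
#' @param cfg a [simConfig()] (`nSamples` is ignored;
#'   `timepoints * nReps` runs are generated).
#' @param target enzyme index (1-based, kinases then phosphatases) or proxy
#'   feature id.
#' @param inhibition fraction of activity removed, in [0, 1].
#' @param timepoints number of timepoints.
#' @param nReps replicate runs per timepoint.
#' @param reboundStart optional timepoint at which adaptive recovery begins
#'   (`NULL` = no rebound).
#' @return List with `perturbed` and `control` ([PhosphoSet-class], run ids
#'   `t<k>_r<j>`), `factors` (per-timepoint activity multiplier of the
#'   target), and `truth` as in [simulatePhospho()] (activities are the
#'   perturbed ones).
#' @export
simulatePerturbation <- function(cfg, target, inhibition, timepoints = 7L,
                                 nReps = 3L, reboundStart = NULL) {
    stopifnot(inherits(cfg, "SimConfig"), inhibition >= 0, inhibition <= 1)
    lay <- .enzymeLayout(cfg)
    tIdx <- if (is.character(target)) match(target, lay$featureId)
            else as.integer(target)
    if (is.na(tIdx) || tIdx < 1L || tIdx > lay$E)
        stop("unknown target regulator: ", target)
    n <- timepoints * nReps
    withr::with_seed(cfg$seed, {
        innov <- matrix(rnorm(lay$E * n), lay$E, n)
        proxyEps <- matrix(rnorm(lay$E * n), lay$E, n)
        eps <- matrix(rnorm(cfg$nSubstrates * n), cfg$nSubstrates, n)
        baseline <- rnorm(lay$E + cfg$nSubstrates, 20, 1.5)
        spread <- if (is.null(cfg$effectRhoSpread)) 0 else cfg$effectRhoSpread
        rhoS <- cfg$effectRho + runif(cfg$nSubstrates, -spread, spread)
    })
    tp <- rep(seq_len(timepoints), each = nReps)
    recovery <- rep(0, timepoints)
    if (!is.null(reboundStart) && reboundStart <= timepoints) {
        span <- max(timepoints - reboundStart, 1L)
        recovery[reboundStart:timepoints] <-
            pmin(1, (seq(reboundStart, timepoints) - reboundStart) / span)
    }
    factors <- 1 - inhibition * (1 - recovery)
    build <- function(fac) {
        act <- .latentActivities(cfg, lay, innov)
        act[tIdx, ] <- act[tIdx, ] * fac[tp]
        m <- .assembleValues(cfg, lay, act, eps, proxyEps, baseline, rhoS)
        rownames(m) <- c(lay$featureId,
                         sprintf("SUB%03d:Q%05d:S10",
                                 seq_len(cfg$nSubstrates),
                                 seq_len(cfg$nSubstrates)))
        colnames(m) <- sprintf("t%d_r%d", tp, rep(seq_len(nReps), timepoints))
        cen <- .censorMatrix(cfg, lay, m)
        list(ps = PhosphoSet(cen$values), act = act)
    }
    pert <- build(factors)
    ctrl <- build(rep(1, timepoints))
    subIds <- sprintf("SUB%03d:Q%05d:S10", seq_len(cfg$nSubstrates),
                      seq_len(cfg$nSubstrates))
    rownames(pert$act) <- lay$featureId
    list(perturbed = pert$ps, control = ctrl$ps, factors = factors,
         timepoint = tp,
         truth = list(edges = .truthEdges(cfg, lay, subIds),
                      activities = pert$act,
                      kinases = lay$featureId[lay$isKin],
                      phosphatases = lay$featureId[!lay$isKin],
                      substrates = subIds,
                      target = lay$featureId[tIdx]))
}
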