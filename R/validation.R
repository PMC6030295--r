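#' @include passage.R
NULL

#' Log-likelihood-ratio goodness-of-fit test (G-test)
#'
#' \deqn{G = 2 \sum_i O_i \ln(O_i/E_i)} with expected counts
#' \eqn{E_i = p_i \sum_i O_i}. Cells with `O = 0` contribute nothing;
#' a cell with `E = 0` but `O > 0` makes `G` infinite (flagged). The
#' degrees of freedom are the number of cells with positive expectation
#' minus one, and the p-value comes from the upper \eqn{\chi^2} tail.
#'
#' @param observed numeric vector of non-negative counts (need not be
#'   integer).
#' @param expected numeric vector of expected proportions (normalised
#'   internally to sum to one).
#' @return list with `G`, `df`, `p`, `impossible` (`TRUE` when some
#'   observed count had zero expectation).
#' @examples
#' gTest(c(10, 0), c(0.5, 0.5))  # G = 20 * log(2) = 13.86
#' @export
gTest <- function(observed, expected) {
    stopifnot(length(observed) == length(expected),
              all(observed >= 0), all(expected >= 0))
    tot <- sum(observed)
    if (tot <= 0) stop("total observed count must be positive")
    p <- expected / sum(expected)
    E <- p * tot
    impossible <- any(observed > 0 & E == 0)
    pos <- observed > 0 & E > 0
    G <- if (impossible) Inf else 2 * sum(observed[pos] * log(observed[pos] / E[pos]))
    df <- sum(E > 0) - 1L
    pval <- if (is.infinite(G)) 0 else stats::pchisq(G, df, lower.tail = FALSE)
    list(G = G, df = df, p = pval, impossible = impossible)
}

#' Compare empirical and fitted transition rates
#'
#' Pairs every (link, interval) with a non-zero empirical rate with the
#' fitted network's von Mises rate at the same interval midpoint and
#' runs a paired two-sided Wilcoxon signed-rank test, alongside the
#' mean and standard deviation of the relative deviations
#' \eqn{|\tilde r - r|/\tilde r}. The exact signed-rank distribution is
#' used for 25 or fewer pairs, the continuity-corrected normal
#' approximation otherwise.
#'
#' @param rates empirical rate table from [empiricalRates()].
#' @param net the fitted [MigrationNetwork-class].
#' @return list with `statistic`, `p`, `n`, `meanRelDev`,
#'   `medianRelDev`, `sdRelDev` and the paired table `pairs`.
#' @export
compareRates <- function(rates, net) {
    mids <- seasonMidpoints(net)
    lk <- links(net)
    sel <- rates[rates$rate > 0, ]
    key <- paste(sel$from, sel$to)
    lkey <- paste(lk$from, lk$to)
    idx <- match(key, lkey)
    sel <- sel[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
    if (!nrow(sel)) stop("no non-zero empirical rates on fitted links")
    fitted <- vonMisesRate(mids[sel$season], lk$phase[idx],
                           lk$width[idx], lk$amplitude[idx])
    reldev <- abs(sel$rate - fitted) / sel$rate
    n <- nrow(sel)
    if (all(sel$rate == fitted)) {
        ## identical series: no evidence of any difference
        wt <- list(statistic = NA_real_, p.value = 1)
    } else {
        wt <- stats::wilcox.test(sel$rate, fitted, paired = TRUE,
                                 exact = n <= 25, correct = TRUE)
    }
    pairs <- data.frame(from = sel$from, to = sel$to,
                        season = sel$season, empirical = sel$rate,
                        fitted = fitted, relDev = reldev)
    list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
         meanRelDev = mean(reldev), medianRelDev = stats::median(reldev),
         sdRelDev = stats::sd(reldev), pairs = pairs)
}

#' Compare counted occupancies with model densities
#'
#' For every seasonal interval, runs a G-test of the observed per-node
#' counts against the model's stationary densities as expected
#' proportions, and summarises by the mean G over testable seasons and
#' the fraction of seasons with p above `pClose`.
#'
#' @param counts `m x n` matrix of observed per-node counts by season
#'   (e.g. `N` from [countOccupancyAndFlows()], or pseudo-counts).
#' @param field [DensityField-class] of model densities (same node
#'   order).
#' @param pClose p-value level defining a "close" season (default 0.1).
#' @return list with `perSeason` (data.frame `season`, `G`, `df`, `p`),
#'   `meanG`, `fracClose` and `nTested` (seasons with positive total
#'   count).
#' @export
compareDensities <- function(counts, field, pClose = 0.1) {
    v <- densityValues(field)
    stopifnot(nrow(counts) == nrow(v), ncol(counts) == ncol(v))
    rows <- lapply(seq_len(nrow(v)), function(k) {
        if (sum(counts[k, ]) <= 0)
            return(data.frame(season = k, G = NA_real_,
                              df = NA_integer_, p = NA_real_))
        gt <- gTest(counts[k, ], v[k, ])
        data.frame(season = k, G = gt$G, df = gt$df, p = gt$p)
    })
    per <- do.call(rbind, rows)
    tested <- !is.na(per$p)
    list(perSeason = per,
         meanG = mean(per$G[tested & is.finite(per$G)]),
         fracClose = if (any(tested)) mean(per$p[tested] > pClose) else NA_real_,
         nTested = sum(tested))
}

#' Default perturbation grids for the sensitivity scan
#'
#' Amplitudes are perturbed multiplicatively by factors log-spaced from
#' 0.01 to 100; phases are shifted additively and widths
#' increased/decreased by values in \eqn{[-1.58, 1.58]} (about plus or
#' minus three months), 13 points per sweep.
#'
#' @param points number of grid points per parameter sweep.
#' @return named list with components `amplitude`, `phase`, `width`.
#' @export
sensitivityGrids <- function(points = 13L) {
    list(amplitude = 10^seq(-2, 2, length.out = points),
         phase = seq(-1.58, 1.58, length.out = points),
         width = seq(-1.58, 1.58, length.out = points))
}

#' Parameter-perturbation sensitivity scan
#'
#' For each link and each von Mises parameter in turn, sweeps the
#' perturbation grid, recomputes the stationary seasonal densities and
#' compares them with the unperturbed baseline by seasonal G-tests
#' (baseline densities scaled to expected counts by a pseudo-population
#' size). A perturbation is "close" when more than `fracClose` of the
#' seasonal G-tests have p > `pClose`, else "altered". Widths are
#' truncated below at the one-day minimum 0.017; a perturbation that
#' drives a link's amplitude to zero is treated as link removal and
#' flagged.
#'
#' @param net a [MigrationNetwork-class].
#' @param grids perturbation grids as from [sensitivityGrids()].
#' @param pseudoPopulation population size used to convert baseline
#'   densities into counts for the G-tests (default 32 tracked
#'   individuals).
#' @param pClose,fracClose the closeness rule (defaults 0.1 and 0.67).
#' @return a [SensitivityReport-class].
#' @export
sensitivityScan <- function(net, grids = sensitivityGrids(),
                            pseudoPopulation = 32,
                            pClose = 0.1, fracClose = 0.67) {
    baseline <- stationaryDensities(net)
    obs <- densityValues(baseline) * pseudoPopulation
    lk <- links(net)
    rows <- list()
    for (li in seq_len(nrow(lk))) {
        for (param in c("phase", "width", "amplitude")) {
            for (val in grids[[param]]) {
                lk2 <- lk
                removed <- FALSE
                if (param == "amplitude") {
                    lk2$amplitude[li] <- lk2$amplitude[li] * val
                    removed <- lk2$amplitude[li] == 0
                } else if (param == "phase") {
                    lk2$phase[li] <- wrapAngle(lk2$phase[li] + val)
                } else {
                    lk2$width[li] <- max(lk2$width[li] + val, MIN_WIDTH)
                }
                pert <- MigrationNetwork(nodes(net), lk2, m = net@m)
                fld <- stationaryDensities(pert)
                cmp <- compareDensities(obs, fld, pClose = pClose)
                rows[[length(rows) + 1L]] <- data.frame(
                    from = lk$from[li], to = lk$to[li], parameter = param,
                    perturbation = val, meanG = cmp$meanG,
                    fracClose = cmp$fracClose,
                    verdict = if (cmp$fracClose > fracClose) "close" else "altered",
                    removedLink = removed)
            }
        }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    new("SensitivityReport", results = res, baseline = baseline,
        pseudoPopulation = pseudoPopulation,
        pClose = pClose, fracClose = fracClose)
}

#' Write a sensitivity report as CSV
#'
#' @param report a [SensitivityReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSensitivityReport <- function(report, path) {
    utils::write.csv(report@results, path, row.names = FALSE)
    invisible(path)
}
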