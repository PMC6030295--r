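#' @include tracks.R
NULL

#' Count seasonal node occupancy and transition flows
#'
#' From the occupancy and event tables of a clustered track set (see
#' [extractLinks()]) or of a simulated agent population (see
#' [simulateAgents()]), counts for every seasonal interval the number
#' of individuals present in each node (`N`; an individual occupying a
#' node on at least one day of the interval counts once) and the number
#' of observed transition events along each directed link (`J`).
#'
#' @param occupancy data.frame with columns `id`, `season`, `node`.
#' @param events data.frame with columns `from`, `to`, `season`.
#' @param nodeIds integer vector of node ids defining the column order
#'   of `N` (defaults to the sorted ids seen in `occupancy`).
#' @param m number of seasonal intervals.
#' @return list with `N` (`m x n` matrix of occupancy counts, columns
#'   named by node id) and `flows` (data.frame `from`, `to`, `season`,
#'   `count`, complete over the `m` seasons for every observed link).
#' @export
countOccupancyAndFlows <- function(occupancy, events, nodeIds = NULL,
                                   m = 48L) {
    if (is.null(nodeIds))
        nodeIds <- sort(unique(c(occupancy$node, events$from, events$to)))
    occ <- unique(occupancy[c("id", "season", "node")])
    N <- matrix(0L, m, length(nodeIds),
                dimnames = list(NULL, as.character(nodeIds)))
    if (nrow(occ)) {
        tb <- table(factor(occ$season, levels = seq_len(m)),
                    factor(occ$node, levels = nodeIds))
        N[] <- as.integer(tb)
    }
    if (nrow(events)) {
        key <- paste(events$from, events$to, sep = "->")
        linkkeys <- sort(unique(key))
        tb <- table(factor(key, levels = linkkeys),
                    factor(events$season, levels = seq_len(m)))
        parts <- do.call(rbind, strsplit(linkkeys, "->", fixed = TRUE))
        flows <- data.frame(
            from = rep(as.integer(parts[, 1]), each = m),
            to = rep(as.integer(parts[, 2]), each = m),
            season = rep(seq_len(m), times = length(linkkeys)),
            count = as.integer(t(tb)))
    } else {
        flows <- data.frame(from = integer(), to = integer(),
                            season = integer(), count = integer())
    }
    list(N = N, flows = flows)
}

#' Empirical seasonal transition rates
#'
#' Converts counted flows and occupancies into empirical per-interval
#' transition rates
#' \deqn{\tilde r_{ij}(\tau) = \frac{J_{ij}(\tau,\tau+\Delta\tau)}{N_j(\tau)\,\Delta\tau}.}
#' Intervals with no animals at risk (`N = 0`) carry no information and
#' get rate 0 with `noInfo = TRUE` rather than `NaN`.
#'
#' With `correct = "exit"` the raw ratio — which estimates the
#' transition *probability* per unit time and therefore saturates when
#' total exit rates are large relative to \eqn{1/\Delta\tau} — is
#' replaced by the discrete-observation maximum-likelihood rate for
#' competing exponential risks: the total exit rate of the source node
#' is \eqn{\hat\rho_j = -\ln(1 - \sum_i J_{ij}/N_j)/\Delta\tau},
#' apportioned over the outgoing links by their flow shares. The two
#' estimators agree when \eqn{\rho_j\Delta\tau \ll 1}.
#'
#' Intervals with fewer than `minAtRisk` animals at risk are treated
#' the same way as `N = 0` (rate 0, flagged): a single departure among
#' two or three stragglers produces rate spikes whose variance exceeds
#' any signal, and they would otherwise dominate the circular moments
#' of the fit. The default `minAtRisk = 1` keeps the plain estimator;
#' the fitting pipelines use 5.
#'
#' @param counts list as returned by [countOccupancyAndFlows()].
#' @param dt seasonal interval width in radians.
#' @param correct `"none"` for the raw ratio (default), `"exit"` for
#'   the exit-rate corrected estimator.
#' @param minAtRisk minimum occupancy count for an interval to be
#'   considered informative.
#' @return data.frame with columns `from`, `to`, `season`, `flow`,
#'   `atRisk`, `rate`, `noInfo`; attribute `"dt"` carries `dt`.
#' @export
empiricalRates <- function(counts, dt, correct = c("none", "exit"),
                           minAtRisk = 1L) {
    correct <- match.arg(correct)
    fl <- counts$flows
    N <- counts$N
    atRisk <- N[cbind(fl$season, match(as.character(fl$from), colnames(N)))]
    out <- data.frame(from = fl$from, to = fl$to, season = fl$season,
                      flow = fl$count, atRisk = as.integer(atRisk))
    out$noInfo <- out$atRisk < minAtRisk
    if (correct == "none") {
        out$rate <- ifelse(out$atRisk == 0L, 0,
                           out$flow / (out$atRisk * dt))
    } else {
        key <- paste(out$from, out$season)
        exitFlow <- stats::ave(out$flow, key, FUN = sum)
        q <- ifelse(out$atRisk == 0L, 0, exitFlow / out$atRisk)
        ## guard against q >= 1 (every animal at risk seen to leave)
        q <- pmin(q, ifelse(out$atRisk > 0, 1 - 1 / (2 * out$atRisk), 0))
        rho <- ifelse(q > 0, -log(1 - q) / dt, 0)
        out$rate <- ifelse(exitFlow > 0, rho * out$flow / exitFlow, 0)
    }
    out$rate[out$noInfo] <- 0
    attr(out, "dt") <- dt
    out[order(out$from, out$to, out$season), ]
}

#' Fit von Mises parameters to an empirical rate series
#'
#' Characterises one link's empirical seasonal rate series by the three
#' von Mises parameters: the phase \eqn{\varphi} is the weighted
#' circular mean of the interval midpoints with weights
#' \eqn{\tilde r(\tau_k)}; the width \eqn{\sigma} is the weighted
#' circular standard deviation \eqn{\sqrt{-2\ln\bar R}}, truncated below
#' at the one-day minimum 0.017; and the amplitude \eqn{\omega} is
#' chosen so that the fitted curve's total yearly mass
#' \eqn{\sum_k r(\tau_k)\Delta\tau} matches the empirical mass
#' (`omega = "mass"`, the default, which preserves the total yearly
#' flow driving the dynamics) or so that its maximum over the interval
#' midpoints matches the empirical maximum (`omega = "peak"`).
#'
#' @param rate numeric vector of length `m`: the empirical rate in each
#'   seasonal interval.
#' @param dt seasonal interval width in radians.
#' @param omega amplitude matching criterion, `"mass"` or `"peak"`.
#' @return named numeric vector `c(phase, width, amplitude)`.
#' @examples
#' m <- 48; dt <- 2 * pi / m
#' r <- vonMisesRate((seq_len(m) - 0.5) * dt, 1.7, 0.26, 5)
#' round(fitVonMises(r, dt), 3)
#' @export
fitVonMises <- function(rate, dt, omega = c("mass", "peak")) {
    omega <- match.arg(omega)
    stopifnot(all(rate >= 0))
    if (all(rate == 0))
        stop("all-zero rate series: no transitions to fit")
    m <- length(rate)
    theta <- (seq_len(m) - 0.5) * dt
    w <- rate / sum(rate)
    C <- sum(w * cos(theta))
    S <- sum(w * sin(theta))
    phase <- wrapAngle(atan2(S, C))
    Rbar <- sqrt(C^2 + S^2)
    width <- if (Rbar >= 1) MIN_WIDTH else sqrt(-2 * log(Rbar))
    width <- max(width, MIN_WIDTH)
    shape <- exp((cos(theta - phase) - 1) / width^2)
    amplitude <- if (omega == "mass") {
        sum(rate * dt) / sum(shape * dt)
    } else {
        max(rate) / max(shape)
    }
    c(phase = phase, width = width, amplitude = amplitude)
}

#' Fit a whole migration network from empirical rates
#'
#' Runs [fitVonMises()] on every directed link of an empirical rate
#' table and assembles the result into a [MigrationNetwork-class] ready
#' for the periodic Markov machinery. Links whose series are all zero
#' are dropped with a warning.
#'
#' @param rates data.frame from [empiricalRates()].
#' @param nodes node table (`id`, and optionally `label`, `lon`, `lat`),
#'   e.g. cluster centroids from [clusterRestingPositions()] with the
#'   cluster number as `id`.
#' @param m number of seasonal intervals.
#' @param omega passed to [fitVonMises()].
#' @return list with `network` (the fitted [MigrationNetwork-class])
#'   and `fits` (data.frame `from`, `to`, `phase`, `phase_week`,
#'   `width`, `width_days`, `amplitude`, `n_events`).
#' @export
fitMigrationNetwork <- function(rates, nodes, m = 48L,
                                omega = c("mass", "peak")) {
    omega <- match.arg(omega)
    dt <- attr(rates, "dt")
    if (is.null(dt)) dt <- 2 * pi / m
    if (!nrow(rates)) stop("empty rate table: no links to fit")
    grp <- split(rates, paste(rates$from, rates$to, sep = "->"))
    fits <- do.call(rbind, lapply(grp, function(g) {
        g <- g[order(g$season), ]
        if (all(g$rate == 0)) return(NULL)
        f <- fitVonMises(g$rate, dt, omega = omega)
        data.frame(from = g$from[1], to = g$to[1],
                   phase = unname(f["phase"]),
                   width = unname(f["width"]),
                   amplitude = unname(f["amplitude"]),
                   n_events = sum(g$flow))
    }))
    if (is.null(fits)) stop("no link with non-zero empirical rates")
    dropped <- length(grp) - nrow(fits)
    if (dropped > 0)
        warning(dropped, " link(s) with all-zero rate series dropped")
    fits <- fits[order(fits$from, fits$to), ]
    rownames(fits) <- NULL
    fits$phase_week <- phaseToWeek(fits$phase, m)
    fits$width_days <- radiansToDays(fits$width)
    fits <- fits[c("from", "to", "phase", "phase_week", "width",
                   "width_days", "amplitude", "n_events")]
    net <- MigrationNetwork(
        nodes = nodes,
        links = fits[c("from", "to", "phase", "width", "amplitude")],
        m = m)
    list(network = net, fits = fits)
}

#' Full track-to-model pipeline
#'
#' Convenience wrapper running the whole estimation chain: best daily
#' positions, velocities, resting classification, node clustering, link
#' extraction, occupancy/flow counting, empirical rates and von Mises
#' fitting.
#'
#' @param fixes fix table from [readTracks()].
#' @param threshold resting-velocity threshold in km/day.
#' @param m number of seasonal intervals.
#' @param cutKm,minMembers,linkage passed to
#'   [clusterRestingPositions()].
#' @param correct rate estimator passed to [empiricalRates()]
#'   (`"exit"` by default: the corrected estimator remains consistent
#'   when seasonal exit rates are large).
#' @param minAtRisk passed to [empiricalRates()] (default 5).
#' @param omega passed to [fitVonMises()].
#' @param maxGapDays passed to [dailyVelocities()].
#' @return list with `network`, `fits`, `clusters`, `links`, `events`,
#'   `rates`, `counts`, `daily`.
#' @export
fitFromTracks <- function(fixes, threshold, m = 48L, cutKm = 750,
                          minMembers = 4L, linkage = "complete",
                          correct = "exit", minAtRisk = 5L,
                          omega = "mass", maxGapDays = 3) {
    daily <- classifyResting(dailyVelocities(bestDailyPositions(fixes),
                                             maxGapDays = maxGapDays),
                             threshold)
    clustering <- clusterRestingPositions(daily[daily$resting, ],
                                          cutKm = cutKm,
                                          minMembers = minMembers,
                                          linkage = linkage)
    ext <- extractLinks(daily, clustering, m = m)
    counts <- countOccupancyAndFlows(ext$occupancy, ext$events,
                                     nodeIds = clustering$clusters$cluster,
                                     m = m)
    rates <- empiricalRates(counts, dt = 2 * pi / m, correct = correct,
                            minAtRisk = minAtRisk)
    nodetab <- data.frame(id = clustering$clusters$cluster,
                          label = paste0("node", clustering$clusters$cluster),
                          lon = clustering$clusters$lon,
                          lat = clustering$clusters$lat)
    fit <- fitMigrationNetwork(rates, nodetab, m = m, omega = omega)
    c(fit, list(clusters = clustering$clusters, links = ext$links,
                events = ext$events, occupancy = ext$occupancy,
                rates = rates, counts = counts, daily = daily))
}


#' Fit a migration network from simulated agent histories
#'
#' Convenience wrapper for the node-level estimation chain on the
#' output of [simulateAgents()]: occupancy/flow counting, empirical
#' rate estimation and von Mises fitting, bypassing the GPS-emission
#' and clustering stages.
#'
#' @param sim result of [simulateAgents()].
#' @param correct,minAtRisk passed to [empiricalRates()].
#' @param omega passed to [fitVonMises()].
#' @return list with `network`, `fits`, `rates`, `counts`.
#' @export
fitFromAgents <- function(sim, correct = "exit", minAtRisk = 5L,
                          omega = "mass") {
    net <- sim$net
    counts <- countOccupancyAndFlows(sim$occupancy, sim$events,
                                     nodeIds = nodes(net)$id, m = net@m)
    rates <- empiricalRates(counts, dt = seasonWidth(net),
                            correct = correct, minAtRisk = minAtRisk)
    fit <- fitMigrationNetwork(rates, nodes(net), m = net@m, omega = omega)
    c(fit, list(rates = rates, counts = counts))
}
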