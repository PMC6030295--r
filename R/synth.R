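#' @include validation.R
NULL

#' Four-node example migration network
#'
#' A small worked example: one breeding node (1), one stopover node (2)
#' and two wintering nodes (3, 4) joined by seven directed links with
#' common amplitude 5 and width 0.26, and phases placing spring arrivals
#' around weeks 10-13 and autumn departures around weeks 35-40
#' (m = 48 weekly intervals). Its stationary seasonal cycle
#' concentrates the whole population in node 1 in summer, routes autumn
#' migration through node 2, splits winter between nodes 3 and 4 (with
#' node 3 holding more because the transition towards it starts
#' earlier) and empties node 3 earlier than node 4 in spring. Node
#' coordinates are fixed but arbitrary, laid out along a plausible
#' European-African flyway.
#'
#' @return a [MigrationNetwork-class] with 4 nodes and 7 links.
#' @examples
#' net <- exampleNetwork()
#' stationaryDensities(net)
#' @export
exampleNetwork <- function() {
    nodes <- data.frame(
        id = 1:4,
        label = c("breeding", "stopover", "winterA", "winterB"),
        lon = c(9, 32, 33, 36),
        lat = c(52, 31, 14, -1))
    links <- data.frame(
        from = c(3, 3, 4, 2, 1, 2, 2),
        to   = c(1, 2, 2, 1, 2, 3, 4),
        phase = c(1.31, 1.31, 1.31, 1.70, 4.58, 5.11, 5.24),
        width = 0.26,
        amplitude = 5)
    MigrationNetwork(nodes, links, m = 48L)
}

#' Random valid migration network
#'
#' Generates a random network for property-style testing: a directed
#' ring through all nodes (guaranteeing irreducibility) plus extra
#' random links, with phases uniform on the year, widths in
#' `[0.15, 0.8]` and amplitudes in `[0.5, 8]`.
#'
#' @param n number of nodes.
#' @param seed integer seed.
#' @param m number of seasonal intervals.
#' @param extraLinks number of extra random directed links beyond the
#'   ring (default `n`).
#' @return a [MigrationNetwork-class].
#' @export
randomMigrationNetwork <- function(n, seed, m = 48L, extraLinks = n) {
    stopifnot(n >= 2)
    set.seed(seed)
    from <- seq_len(n)
    to <- c(seq_len(n)[-1], 1L)
    pool <- expand.grid(from = seq_len(n), to = seq_len(n))
    pool <- pool[pool$from != pool$to, ]
    pool$key <- paste(pool$from, pool$to)
    have <- paste(from, to)
    pool <- pool[!pool$key %in% have, ]
    if (extraLinks > 0 && nrow(pool)) {
        pick <- pool[sample.int(nrow(pool), min(extraLinks, nrow(pool))), ]
        from <- c(from, pick$from)
        to <- c(to, pick$to)
    }
    links <- data.frame(
        from = from, to = to,
        phase = stats::runif(length(from), 0, 2 * pi),
        width = stats::runif(length(from), 0.15, 0.8),
        amplitude = stats::runif(length(from), 0.5, 8))
    nodes <- data.frame(id = seq_len(n),
                        label = paste0("node", seq_len(n)),
                        lon = stats::runif(n, -10, 40),
                        lat = stats::runif(n, -10, 60))
    MigrationNetwork(nodes, links, m = m)
}

#' Simulate individual agents on a migration network
#'
#' Each agent is an independent realisation of the time-discrete
#' periodic Markov chain: its state in the next interval is drawn from
#' the relevant column of the exact per-interval transition matrix, so
#' the synthetic population is distributed exactly per the model the
#' estimators target. Initial states are drawn from the stationary
#' density at the starting season (or placed in a fixed node).
#'
#' @param net a [MigrationNetwork-class].
#' @param nAgents number of agents.
#' @param years number of simulated years; each agent-year is treated
#'   as one yearly track (individual ids carry the year).
#' @param seed integer seed (mandatory, all randomness flows from it).
#' @param startSeason 1-based starting interval.
#' @param initNode optional node id to start every agent in (default:
#'   draw from the stationary density at `startSeason`).
#' @return list with `states` (integer matrix, agents by
#'   `years * m + 1` interval states, entries are node ids), `events`
#'   (data.frame `id`, `season`, `from`, `to`), `occupancy`
#'   (data.frame `id`, `season`, `node`, one row per agent-year and
#'   interval) and `net`.
#' @export
simulateAgents <- function(net, nAgents, years = 1L, seed,
                           startSeason = 1L, initNode = NULL) {
    stopifnot(nAgents >= 1, !missing(seed))
    set.seed(seed)
    P <- transitionMatrices(net)
    m <- net@m
    ids <- nodes(net)$id
    n <- length(ids)
    steps <- years * m
    states <- matrix(0L, nAgents, steps + 1L)
    if (is.null(initNode)) {
        p0 <- densityValues(stationaryDensities(net))[startSeason, ]
        states[, 1] <- sample.int(n, nAgents, replace = TRUE, prob = p0)
    } else {
        states[, 1] <- nodeIndex(net, initNode)
    }
    k <- startSeason
    for (s in seq_len(steps)) {
        cur <- states[, s]
        nxt <- integer(nAgents)
        for (j in unique(cur)) {
            sel <- cur == j
            nxt[sel] <- sample.int(n, sum(sel), replace = TRUE,
                                   prob = P[[k]][, j])
        }
        states[, s + 1] <- nxt
        k <- (k %% m) + 1
    }
    season <- (((startSeason - 1 + seq_len(steps + 1) - 1) %% m) + 1)
    year <- ((seq_len(steps + 1) - 1) %/% m) + 1
    year[steps + 1] <- years            # closing state belongs to the last year
    agentYearId <- function(a, y) sprintf("a%03d_y%d", a, y)
    moved <- states[, -1, drop = FALSE] != states[, -(steps + 1), drop = FALSE]
    mi <- which(moved, arr.ind = TRUE)
    events <- data.frame(
        id = agentYearId(mi[, 1], year[mi[, 2]]),
        season = season[mi[, 2]],
        from = ids[states[cbind(mi[, 1], mi[, 2])]],
        to = ids[states[cbind(mi[, 1], mi[, 2] + 1L)]])
    events <- events[order(events$id, events$season), ]
    rownames(events) <- NULL
    occ <- data.frame(
        id = agentYearId(rep(seq_len(nAgents), steps),
                         rep(year[seq_len(steps)], each = nAgents)),
        season = rep(season[seq_len(steps)], each = nAgents),
        node = ids[as.vector(states[, seq_len(steps), drop = FALSE])])
    states[] <- ids[states]
    list(states = states, events = events, occupancy = occ, net = net)
}

#' Emit GPS-like daily fixes from simulated agents
#'
#' Turns the interval-level node occupancy of [simulateAgents()] into a
#' Movebank-style daily fix table: every simulated day the agent emits
#' one or more positions jittered around its node's centre with
#' Gaussian noise (km, converted to degrees at the node's latitude);
#' on days where the node changes, intermediate days are interpolated
#' along the great circle at the configured flight speed so that
#' migration days exceed any realistic resting-velocity threshold.
#' Days go missing independently with probability `missingProb`;
#' per-fix horizontal accuracies are drawn log-normally.
#'
#' @param sim result of [simulateAgents()].
#' @param noiseKm standard deviation of the positional jitter around
#'   node centres, km.
#' @param flightSpeedKmd migratory flight speed, km/day.
#' @param missingProb probability that a day has no fix at all.
#' @param meanFixesPerDay mean number of fixes per day (at least one is
#'   emitted on non-missing days).
#' @param accuracyMeanLog,accuracySdLog log-normal parameters of the
#'   horizontal accuracy in metres.
#' @param seed integer seed.
#' @param startDate calendar date of day 1 of year 1.
#' @return data.frame of fixes with Movebank-style columns (see
#'   [movebankColumns()]).
#' @export
emitTracks <- function(sim, noiseKm = 10, flightSpeedKmd = 600,
                       missingProb = 0.05, meanFixesPerDay = 2,
                       accuracyMeanLog = log(15), accuracySdLog = 0.5,
                       seed, startDate = as.Date("2020-01-01")) {
    stopifnot(!missing(seed))
    set.seed(seed)
    net <- sim$net
    m <- net@m
    nd <- nodes(net)
    nAgents <- nrow(sim$states)
    years <- (ncol(sim$states) - 1L) %/% m
    dayInterval <- floor((seq_len(DAYS_PER_YEAR) - 1) / DAYS_PER_YEAR * m) + 1L
    out <- vector("list", nAgents)
    for (a in seq_len(nAgents)) {
        rows <- vector("list", years)
        for (y in seq_len(years)) {
            stateIdx <- (y - 1L) * m + dayInterval
            node <- sim$states[a, stateIdx]
            ni <- match(node, nd$id)
            lon <- nd$lon[ni]; lat <- nd$lat[ni]
            ## interpolate travel days at the flight speed across changes
            chg <- which(diff(ni) != 0) + 1L
            for (d in chg) {
                p1 <- c(nd$lon[ni[d - 1]], nd$lat[ni[d - 1]])
                p2 <- c(nd$lon[ni[d]], nd$lat[ni[d]])
                D <- haversineKm(p1[1], p1[2], p2[1], p2[2])
                tdays <- max(1L, ceiling(D / flightSpeedKmd))
                pts <- geosphere::gcIntermediate(p1, p2,
                    n = max(tdays - 1L, 0L), addStartEnd = TRUE)
                for (t in seq_len(min(tdays, DAYS_PER_YEAR - d + 1L)) - 1L) {
                    lon[d + t] <- pts[t + 2L, 1]
                    lat[d + t] <- pts[t + 2L, 2]
                }
            }
            keep <- stats::runif(DAYS_PER_YEAR) >= missingProb
            days <- which(keep)
            if (!length(days)) next
            nf <- 1L + stats::rpois(length(days), max(meanFixesPerDay - 1, 0))
            di <- rep(days, nf)
            jit <- noiseKm * matrix(stats::rnorm(2 * length(di)), ncol = 2)
            kmPerDegLat <- pi * EARTH_RADIUS_KM / 180
            lonF <- lon[di] + jit[, 1] / (kmPerDegLat * cos(lat[di] * pi / 180))
            latF <- lat[di] + jit[, 2] / kmPerDegLat
            secs <- stats::runif(length(di), 0, 86399)
            ts <- as.POSIXct(startDate, tz = "UTC") +
                ((y - 1) * DAYS_PER_YEAR + di - 1) * 86400 + secs
            rows[[y]] <- data.frame(
                id = sprintf("a%03d_y%d", a, y),
                timestamp = ts, lon = lonF, lat = latF,
                accuracy = stats::rlnorm(length(di), accuracyMeanLog,
                                         accuracySdLog))
        }
        out[[a]] <- do.call(rbind, rows)
    }
    fx <- do.call(rbind, out)
    fx <- fx[order(fx$id, fx$timestamp), ]
    rownames(fx) <- NULL
    fx
}

#' Write fixes as a Movebank-style CSV
#'
#' @param fixes fix table from [emitTracks()] (internal column names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(fixes, path) {
    cols <- movebankColumns()
    df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
        a = fixes$id,
        b = format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        c = fixes$lon, d = fixes$lat, e = fixes$accuracy)
    names(df) <- unname(cols[c("id", "timestamp", "lon", "lat", "accuracy")])
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
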