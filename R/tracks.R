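#' @include io.R
NULL

EARTH_RADIUS_KM <- 6371

## Great-circle distance in km between (lon, lat) points (vectorised).
haversineKm <- function(lon1, lat1, lon2, lat2) {
    geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                             r = EARTH_RADIUS_KM)
}

#' Species presets for the resting-velocity threshold
#'
#' Daily positions are classified as resting when both the approaching
#' and the departing velocity fall below a species-specific threshold:
#' 50 km/day for white storks and 20 km/day for white-fronted geese.
#'
#' @param species `"stork"` or `"goose"`.
#' @return threshold in km/day.
#' @export
velocityThreshold <- function(species = c("stork", "goose")) {
    c(stork = 50, goose = 20)[[match.arg(species)]]
}

#' Select one best daily position per individual and day
#'
#' For each individual and each calendar day with at least one fix,
#' keeps a single position: the fix with the best (smallest) accuracy
#' value, ties broken by the latest timestamp of the day (the position
#' at the end of the day). Days without fixes are simply absent. Fixes
#' with missing accuracy rank after any fix with known accuracy.
#'
#' @param fixes data.frame as returned by [readTracks()] (`id`,
#'   `timestamp`, `lon`, `lat`, `accuracy`).
#' @return data.frame with columns `id`, `date` (Date), `lon`, `lat`,
#'   `accuracy`, one row per individual-day.
#' @export
bestDailyPositions <- function(fixes) {
    if (!nrow(fixes)) {
        warning("no fixes supplied")
        return(data.frame(id = character(), date = as.Date(character()),
                          lon = numeric(), lat = numeric(),
                          accuracy = numeric()))
    }
    fx <- fixes
    fx$date <- as.Date(fx$timestamp, tz = "UTC")
    acc <- fx$accuracy
    acc[is.na(acc)] <- Inf
    ## order so the preferred fix comes first within each id-date group:
    ## best accuracy, then latest timestamp
    o <- order(fx$id, fx$date, acc, -as.numeric(fx$timestamp))
    fx <- fx[o, ]
    keep <- !duplicated(fx[c("id", "date")])
    out <- fx[keep, c("id", "date", "lon", "lat", "accuracy")]
    out <- out[order(out$id, out$date), ]
    rownames(out) <- NULL
    out
}

#' Approach and departure velocities of daily positions
#'
#' For each daily position, computes the velocity towards the previous
#' day's position (`v_in`) and towards the next day's position
#' (`v_out`) as great-circle distance divided by the gap in days.
#' Velocities across gaps longer than `maxGapDays` are set to missing
#' (a long gap at face value would average a fast flight into an
#' apparent slow crawl); the first day of a track has no `v_in`, the
#' last no `v_out`.
#'
#' @param daily data.frame from [bestDailyPositions()].
#' @param maxGapDays maximum day gap over which a velocity is still
#'   computed (default 3).
#' @return `daily` with numeric columns `v_in` and `v_out` (km/day)
#'   appended.
#' @export
dailyVelocities <- function(daily, maxGapDays = 3) {
    daily <- daily[order(daily$id, daily$date), ]
    rownames(daily) <- NULL
    n <- nrow(daily)
    v_in <- rep(NA_real_, n)
    if (n >= 2) {
        prev <- seq_len(n - 1)
        cur <- prev + 1
        same <- daily$id[cur] == daily$id[prev]
        gap <- as.numeric(daily$date[cur] - daily$date[prev])
        d <- haversineKm(daily$lon[prev], daily$lat[prev],
                         daily$lon[cur], daily$lat[cur])
        ok <- same & gap >= 1 & gap <= maxGapDays
        v_in[cur][ok] <- (d / gap)[ok]
    }
    daily$v_in <- v_in
    daily$v_out <- c(v_in[-1], NA_real_)
    ## v_out of the last row of each individual must be missing
    lastrow <- c(daily$id[-n] != daily$id[-1], TRUE)
    daily$v_out[lastrow] <- NA_real_
    daily
}

#' Classify daily positions as resting or migrating
#'
#' A position is resting when every available velocity among
#' `v_in`/`v_out` is strictly below the threshold; track endpoints are
#' judged on their single available side. Positions with neither
#' velocity available are not classified as resting.
#'
#' @param daily data.frame from [dailyVelocities()].
#' @param threshold velocity threshold in km/day (see
#'   [velocityThreshold()] for the species presets).
#' @return `daily` with a logical `resting` column appended.
#' @export
classifyResting <- function(daily, threshold) {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    vin_ok <- is.na(daily$v_in) | daily$v_in < threshold
    vout_ok <- is.na(daily$v_out) | daily$v_out < threshold
    any_v <- !(is.na(daily$v_in) & is.na(daily$v_out))
    daily$resting <- vin_ok & vout_ok & any_v
    daily
}

#' Cluster resting positions into network nodes
#'
#' Agglomeratively clusters resting positions on great-circle distances
#' and cuts the tree at `cutKm` (complete linkage by default, so the
#' cut bounds cluster diameter). Clusters with fewer than `minMembers`
#' resting positions are discarded as outliers; survivors are numbered
#' 1, 2, ... by decreasing member count and their centroids are the
#' circular-safe coordinate means of their members.
#'
#' @param resting data.frame of resting positions (rows of the output
#'   of [classifyResting()] with `resting == TRUE`).
#' @param cutKm tree cut distance in km (default 750, a typical spacing
#'   of migratory stopover sites).
#' @param minMembers minimum cluster size retained (default 4, i.e.
#'   more than three resting positions).
#' @param linkage hierarchical linkage criterion (`"complete"`,
#'   `"single"` or `"average"`).
#' @return list with `clusters` (data.frame `cluster`, `lon`, `lat`,
#'   `members`) and `assignment` (integer vector along `resting`;
#'   `NA` for positions in discarded clusters).
#' @export
clusterRestingPositions <- function(resting, cutKm = 750, minMembers = 4L,
                                    linkage = c("complete", "single",
                                                "average")) {
    linkage <- match.arg(linkage)
    if (!nrow(resting)) stop("no resting positions to cluster")
    n <- nrow(resting)
    if (n == 1L) {
        raw <- 1L
    } else {
        ## haversine scales linearly with the sphere radius: rescale the
        ## default-radius metres to km on the R = 6371 km sphere
        d <- geosphere::distm(cbind(resting$lon, resting$lat),
                              fun = geosphere::distHaversine) *
            (EARTH_RADIUS_KM / 6378137)
        hc <- stats::hclust(stats::as.dist(d), method = linkage)
        raw <- stats::cutree(hc, h = cutKm)
    }
    sizes <- table(raw)
    keep <- names(sizes)[sizes >= minMembers]
    if (!length(keep))
        stop("all clusters fall below the minimum size of ", minMembers,
             " resting positions; no network nodes can be formed")
    ## renumber by descending member count (ties: first appearance)
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    newid <- stats::setNames(seq_along(keep), keep)
    assignment <- unname(newid[as.character(raw)])
    centroids <- do.call(rbind, lapply(seq_along(keep), function(ci) {
        sel <- which(assignment == ci)
        lon <- circularMeanDegrees(resting$lon[sel])
        data.frame(cluster = ci, lon = lon,
                   lat = mean(resting$lat[sel]),
                   members = length(sel))
    }))
    list(clusters = centroids, assignment = assignment)
}

## Circular mean of longitudes in degrees (safe across the date line).
circularMeanDegrees <- function(deg) {
    a <- deg * pi / 180
    atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
}

#' Extract directed links and transition events from clustered tracks
#'
#' For each individual, consecutive resting positions assigned to
#' different clusters create (or support) a directed link between the
#' two nodes. Each transition event records the season of the movement,
#' taken at the midpoint between the last day in the source node and
#' the first day in the target node. Resting positions in discarded
#' clusters are dropped before the sequence is formed.
#'
#' @param daily data.frame from [classifyResting()].
#' @param clustering result of [clusterRestingPositions()] on the
#'   resting subset of `daily` (same row order).
#' @param m number of seasonal intervals for event attribution.
#' @return list with `links` (data.frame `from`, `to`, `nEvents`),
#'   `events` (data.frame `id`, `from`, `to`, `date`, `season`) and
#'   `occupancy` (data.frame `id`, `date`, `season`, `node` for every
#'   retained resting day).
#' @export
extractLinks <- function(daily, clustering, m = 48L) {
    resting <- daily[daily$resting, ]
    stopifnot(nrow(resting) == length(clustering$assignment))
    resting$node <- clustering$assignment
    resting <- resting[!is.na(resting$node), ]
    if (!nrow(resting)) stop("no resting positions in retained clusters")
    resting <- resting[order(resting$id, resting$date), ]
    resting$season <- dateSeason(resting$date, m)
    occupancy <- resting[c("id", "date", "season", "node")]
    rownames(occupancy) <- NULL

    ev <- lapply(split(resting, resting$id), function(tr) {
        if (nrow(tr) < 2) return(NULL)
        i <- which(tr$node[-1] != tr$node[-nrow(tr)])
        if (!length(i)) return(NULL)
        middate <- tr$date[i] + as.numeric(tr$date[i + 1] - tr$date[i]) / 2
        data.frame(id = tr$id[i], from = tr$node[i], to = tr$node[i + 1],
                   date = as.Date(middate),
                   season = dateSeason(middate, m))
    })
    events <- do.call(rbind, ev)
    if (is.null(events))
        events <- data.frame(id = character(), from = integer(),
                             to = integer(), date = as.Date(character()),
                             season = integer())
    events <- events[order(events$from, events$to, events$id, events$date), ]
    rownames(events) <- NULL
    if (nrow(events)) {
        linkdf <- stats::aggregate(list(nEvents = rep(1L, nrow(events))),
                                   events[c("from", "to")], sum)
        linkdf <- linkdf[order(linkdf$from, linkdf$to), ]
        rownames(linkdf) <- NULL
    } else {
        linkdf <- data.frame(from = integer(), to = integer(),
                             nEvents = integer())
    }
    noRest <- setdiff(unique(daily$id), unique(resting$id))
    if (length(noRest))
        warning("individual(s) without retained resting positions: ",
                paste(noRest, collapse = ", "))
    list(links = linkdf, events = events, occupancy = occupancy)
}

## Seasonal interval (1..m) of a calendar date within its year
## (365-day convention; Dec 31 of leap years folds into interval m).
dateSeason <- function(date, m = 48L) {
    doy <- as.POSIXlt(date)$yday  # 0-based day of year
    k <- floor(doy / DAYS_PER_YEAR * m) + 1L
    pmin(as.integer(k), as.integer(m))
}
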