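#' @include netmeasures.R
NULL

## Peak-density season of a node (1-based interval index).
peakSeason <- function(field, nodeIdx) {
    which.max(densityValues(field)[, nodeIdx])
}

#' Expected first passage time between nodes
#'
#' Expected time for a single walker, started in `from` at the season
#' of that node's highest stationary density, to first reach `to` on
#' the time-inhomogeneous periodic chain. Computed by making the target
#' absorbing and propagating the walker's occupation distribution
#' interval by interval; the horizon is capped (default 200 years) and
#' any unabsorbed residual mass is reported (its contribution is
#' counted at the cap, so the value is a lower bound when `residual`
#' is non-negligible).
#'
#' @param net a [MigrationNetwork-class].
#' @param from,to node ids (distinct).
#' @param startSeason optional 1-based starting interval; default is
#'   the source's peak-density season.
#' @param horizonYears horizon cap in years.
#' @param field optional precomputed [stationaryDensities()] result.
#' @param P optional precomputed transition-matrix list.
#' @return list with `time` (radians), `days`, `residual` and
#'   `startSeason`.
#' @export
firstPassageTime <- function(net, from, to, startSeason = NULL,
                             horizonYears = 200L, field = NULL, P = NULL) {
    stopifnot(from != to)
    i <- nodeIndex(net, from); j <- nodeIndex(net, to)
    stopifnot(!is.na(i), !is.na(j))
    if (is.null(P)) P <- transitionMatrices(net)
    if (is.null(startSeason)) {
        if (is.null(field)) field <- stationaryDensities(net)
        startSeason <- peakSeason(field, i)
    }
    dt <- seasonWidth(net)
    v <- numeric(nNodes(net)); v[i] <- 1
    expT <- 0; absorbed <- 0
    k <- startSeason
    for (s in seq_len(horizonYears * net@m)) {
        v <- as.vector(P[[k]] %*% v)
        hit <- v[j]
        expT <- expT + s * dt * hit
        absorbed <- absorbed + hit
        v[j] <- 0
        k <- (k %% net@m) + 1
        if (sum(v) < 1e-12) break
    }
    residual <- 1 - absorbed
    expT <- expT + residual * horizonYears * net@m * dt
    list(time = expT, days = radiansToDays(expT),
         residual = residual, startSeason = startSeason)
}

#' Expected return time to a node
#'
#' Expected time for a walker started in `node` at its peak-density
#' season to first return there after at least one departure. Mass that
#' leaves and comes back within a single interval (a multi-hop round
#' trip inside one \eqn{\Delta\tau}) counts as having stayed.
#'
#' @inheritParams firstPassageTime
#' @param node node id.
#' @return list with `time` (radians), `days`, `residual` and
#'   `startSeason`.
#' @export
returnTime <- function(net, node, startSeason = NULL,
                       horizonYears = 200L, field = NULL, P = NULL) {
    i <- nodeIndex(net, node)
    stopifnot(!is.na(i))
    if (is.null(P)) P <- transitionMatrices(net)
    if (is.null(startSeason)) {
        if (is.null(field)) field <- stationaryDensities(net)
        startSeason <- peakSeason(field, i)
    }
    dt <- seasonWidth(net)
    n <- nNodes(net)
    u <- 1                      # mass that has never departed (sits in i)
    w <- numeric(n)             # departed, not yet returned
    expT <- 0; absorbed <- 0
    k <- startSeason
    for (s in seq_len(horizonYears * net@m)) {
        col_i <- unname(P[[k]][, i])
        w2 <- as.vector(P[[k]] %*% w) + u * col_i
        w2[i] <- w2[i] - u * col_i[i]        # staying mass is not a departure
        u <- u * col_i[i]
        hit <- w2[i]
        expT <- expT + s * dt * hit
        absorbed <- absorbed + hit
        w2[i] <- 0
        w <- w2
        k <- (k %% net@m) + 1
        if (u + sum(w) < 1e-12) break
    }
    residual <- 1 - absorbed
    expT <- expT + residual * horizonYears * net@m * dt
    list(time = expT, days = radiansToDays(expT),
         residual = residual, startSeason = startSeason)
}

#' First-passage / return time matrix
#'
#' Matrix of expected first passage times between all ordered node
#' pairs, each started at the source node's peak-density season, with
#' expected return times on the diagonal.
#'
#' @inheritParams firstPassageTime
#' @return numeric `n x n` matrix (entry `[j, i]`: from node `j` to
#'   node `i`, in radians), with attribute `"days"` holding the same
#'   matrix in days.
#' @export
firstPassageMatrix <- function(net, horizonYears = 200L) {
    P <- transitionMatrices(net)
    field <- stationaryDensities(net)
    ids <- nodes(net)$id
    n <- length(ids)
    M <- matrix(NA_real_, n, n,
                dimnames = list(nodes(net)$label, nodes(net)$label))
    for (a in seq_len(n)) for (b in seq_len(n)) {
        M[a, b] <- if (a == b)
            returnTime(net, ids[a], horizonYears = horizonYears,
                       field = field, P = P)$time
        else
            firstPassageTime(net, ids[a], ids[b],
                             horizonYears = horizonYears,
                             field = field, P = P)$time
    }
    attr(M, "days") <- radiansToDays(M)
    M
}
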