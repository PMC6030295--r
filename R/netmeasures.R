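#' @include rates.R
NULL

#' Season-specific network topologies
#'
#' Derives, for each seasonal interval, the directed edge set obtained
#' by thresholding the transition probabilities: node `j` is connected
#' to node `i` at season `k` whenever \eqn{p_{ij}(\tau_k;\Delta\tau)}
#' exceeds `threshold` (default 0.05). The seasonal edge sets are also
#' merged by overlap into a cumulative topology.
#'
#' @param net a [MigrationNetwork-class].
#' @param threshold transition-probability threshold.
#' @return list with `seasonal` (length-`m` list of igraph digraphs on
#'   the network's node ids) and `cumulative` (their union).
#' @export
seasonalTopologies <- function(net, threshold = 0.05) {
    P <- transitionMatrices(net)
    ids <- as.character(nodes(net)$id)
    seasonal <- lapply(P, function(p) {
        idx <- which(p > threshold & row(p) != col(p), arr.ind = TRUE)
        edges <- data.frame(from = ids[idx[, 2]], to = ids[idx[, 1]])
        igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = ids)
    })
    alledges <- unique(do.call(rbind, lapply(seasonal, function(g)
        igraph::as_data_frame(g, what = "edges"))))
    cumulative <- igraph::graph_from_data_frame(alledges, directed = TRUE,
                                                vertices = ids)
    list(seasonal = seasonal, cumulative = cumulative)
}

#' Per-season degree and giant component size
#'
#' Mean node degree (in-degree plus out-degree) and the size of the
#' giant component of each season-specific network. The giant component
#' is measured in the weak (undirected) sense by default because the
#' seasonal sub-networks are nearly unidirectional flow snapshots; an
#' isolated node counts as a component of size 1.
#'
#' @param topo result of [seasonalTopologies()].
#' @param mode `"weak"` or `"strong"` connectivity.
#' @return data.frame with columns `season`, `meanDegree`,
#'   `giantComponent`.
#' @export
topologyMeasures <- function(topo, mode = c("weak", "strong")) {
    mode <- match.arg(mode)
    rows <- lapply(seq_along(topo$seasonal), function(k) {
        g <- topo$seasonal[[k]]
        data.frame(season = k,
                   meanDegree = mean(igraph::degree(g, mode = "all")),
                   giantComponent = max(igraph::components(g, mode = mode)$csize))
    })
    do.call(rbind, rows)
}

#' Directed shortest path lengths
#'
#' All-pairs directed shortest topological path lengths (minimum number
#' of links to traverse) of a cumulative topology, and their mean over
#' all reachable ordered pairs of distinct nodes.
#'
#' @param g an igraph digraph (e.g. `$cumulative` from
#'   [seasonalTopologies()]).
#' @return list with `lengths` (numeric matrix, `Inf` where
#'   unreachable) and `mean` (mean over reachable ordered pairs).
#' @export
shortestPathLengths <- function(g) {
    d <- igraph::distances(g, mode = "out")
    off <- d[row(d) != col(d)]
    list(lengths = d, mean = mean(off[is.finite(off)]))
}

#' Betweenness centrality
#'
#' Directed betweenness centrality of every node: the number of
#' shortest paths between other node pairs that pass through the node
#' (fractionally counted when several shortest paths exist).
#'
#' @param g an igraph digraph.
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(g) {
    igraph::betweenness(g, directed = TRUE, normalized = FALSE)
}

## The 13 connected directed-triad classes in standard (MAN) order:
## positions 4..16 of igraph's 16-class triad census.
TRIAD13 <- c("021D", "021U", "021C", "111D", "111U", "030T", "030C",
             "201", "120D", "120U", "120C", "210", "300")

#' Triad (motif) census of the 13 connected classes
#'
#' @param g an igraph digraph with at least 3 nodes.
#' @return named integer vector of counts of the 13 connected
#'   directed-triad classes.
#' @export
triadCensus13 <- function(g) {
    stopifnot(igraph::vcount(g) >= 3)
    full <- igraph::triad_census(g)
    stats::setNames(as.integer(full[4:16]), TRIAD13)
}

#' Triad significance profile
#'
#' Compares the connected-triad census of a digraph against a
#' degree-sequence-preserving null model (double-edge swaps; `10 * l`
#' attempted swaps per sample). Classes are scored by
#' \eqn{z = (obs - mean_{null})/sd_{null}} (z set to 0 and flagged when
#' the null standard deviation vanishes) and the profile is the z-score
#' vector normalised to unit Euclidean length.
#'
#' @param g an igraph digraph.
#' @param nRandom number of null-model samples (default 1000).
#' @param seed integer seed for the null-model randomisation.
#' @return list with `census`, `nullMean`, `nullSd`, `z`, `profile`
#'   (unit-norm), and `degenerate` (logical: classes with zero null
#'   variance).
#' @export
triadProfile <- function(g, nRandom = 1000L, seed = 1L) {
    obs <- triadCensus13(g)
    nswap <- 10L * igraph::ecount(g)
    null <- matrix(0L, nRandom, length(obs))
    set.seed(seed)
    for (b in seq_len(nRandom)) {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = nswap))
        null[b, ] <- triadCensus13(gr)
    }
    mu <- colMeans(null)
    sdv <- apply(null, 2, stats::sd)
    z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
    degenerate <- sdv == 0
    nrm <- sqrt(sum(z^2))
    profile <- if (nrm > 0) z / nrm else z
    list(census = obs, nullMean = stats::setNames(mu, TRIAD13),
         nullSd = stats::setNames(sdv, TRIAD13),
         z = stats::setNames(z, TRIAD13),
         profile = stats::setNames(profile, TRIAD13),
         degenerate = stats::setNames(degenerate, TRIAD13))
}

#' Cumulative density and post-peak staying time per node
#'
#' The cumulative density of a node is its stationary density summed
#' over the `m` seasonal intervals (units: density times intervals,
#' range `[0, m]`; `m` means the whole population sits in that node all
#' year). The staying time is the length of the contiguous run of
#' intervals, starting at the node's peak-density interval, during
#' which its density stays above half the peak (reported in intervals
#' and in days under the 365-day year); a node never occupied has
#' staying time 0.
#'
#' @param field a [DensityField-class].
#' @return data.frame with columns `node`, `cumulativeDensity`,
#'   `peakSeason`, `stayingIntervals`, `stayingDays`.
#' @export
cumulativeDensityAndStaying <- function(field) {
    v <- densityValues(field)
    m <- nrow(v)
    rows <- lapply(seq_len(ncol(v)), function(i) {
        x <- v[, i]
        cum <- sum(x)
        if (max(x) <= 0)
            return(data.frame(node = colnames(v)[i], cumulativeDensity = 0,
                              peakSeason = NA_integer_,
                              stayingIntervals = 0, stayingDays = 0))
        pk <- which.max(x)
        half <- x[pk] / 2
        run <- 0L
        for (s in seq_len(m)) {             # wrap around the year
            k <- ((pk - 1 + s - 1) %% m) + 1
            if (x[k] > half) run <- run + 1L else break
        }
        data.frame(node = colnames(v)[i], cumulativeDensity = cum,
                   peakSeason = pk, stayingIntervals = run,
                   stayingDays = run * DAYS_PER_YEAR / m)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
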