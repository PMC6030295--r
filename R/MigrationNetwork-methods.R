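#' @include AllClasses.R
NULL

#' Construct a seasonal migration network
#'
#' Builds a validated [MigrationNetwork-class] from a node table and a
#' link table. Nodes are geographic regions (breeding, stopover,
#' wintering); each directed link `from -> to` carries a von Mises
#' seasonal transition-rate profile \eqn{r(\tau) = \omega\,
#' \exp[(\cos(\tau-\varphi)-1)/\sigma^2]}.
#'
#' @param nodes data.frame with columns `id`, and optionally `label`,
#'   `lon`, `lat` (labels default to `"node<id>"`, coordinates to `NA`
#'   replaced by 0).
#' @param links data.frame with columns `from`, `to`, `phase`, `width`,
#'   `amplitude`. Phases are wrapped into `[0, 2*pi)`.
#' @param m number of seasonal intervals the year is split into
#'   (default 48, about one week each).
#' @param allowNarrow logical; permit widths below the one-day
#'   truncation 0.017 (only sensible for studying the \eqn{\delta}-limit).
#' @return a [MigrationNetwork-class] object.
#' @examples
#' net <- MigrationNetwork(
#'   nodes = data.frame(id = 1:2, label = c("north", "south"),
#'                      lon = c(10, 15), lat = c(55, 35)),
#'   links = data.frame(from = c(1, 2), to = c(2, 1),
#'                      phase = c(4.6, 1.6), width = 0.3, amplitude = 4))
#' net
#' @export
MigrationNetwork <- function(nodes, links, m = 48L, allowNarrow = FALSE) {
    nodes <- as.data.frame(nodes)
    if (is.null(nodes$label)) nodes$label <- paste0("node", nodes$id)
    if (is.null(nodes$lon)) nodes$lon <- 0
    if (is.null(nodes$lat)) nodes$lat <- 0
    nodes$id <- as.integer(nodes$id)
    nodes <- nodes[order(nodes$id), c("id", "label", "lon", "lat")]
    rownames(nodes) <- NULL
    if (is.null(links) || !nrow(as.data.frame(links))) {
        links <- data.frame(from = integer(), to = integer(),
                            phase = numeric(), width = numeric(),
                            amplitude = numeric())
    } else {
        links <- as.data.frame(links)
        links$from <- as.integer(links$from)
        links$to <- as.integer(links$to)
        links$phase <- wrapAngle(as.numeric(links$phase))
        links$width <- as.numeric(links$width)
        links$amplitude <- as.numeric(links$amplitude)
        links <- links[c("from", "to", "phase", "width", "amplitude")]
        rownames(links) <- NULL
    }
    if (allowNarrow) attr(links, "allowNarrow") <- TRUE
    new("MigrationNetwork", nodes = nodes, links = links,
        m = as.integer(m), period = 2 * pi)
}

#' @rdname network-accessors
#' @export
setMethod("nodes", "MigrationNetwork", function(x) x@nodes)

#' @rdname network-accessors
#' @export
setMethod("links", "MigrationNetwork", function(x) x@links)

#' @rdname network-accessors
#' @export
setMethod("nNodes", "MigrationNetwork", function(x) nrow(x@nodes))

#' @rdname network-accessors
#' @export
setMethod("nLinks", "MigrationNetwork", function(x) nrow(x@links))

#' @rdname network-accessors
#' @export
setMethod("nSeasons", "MigrationNetwork", function(x) x@m)

#' @rdname network-accessors
#' @export
setMethod("seasonWidth", "MigrationNetwork",
          function(x) x@period / x@m)

setMethod("show", "MigrationNetwork", function(object) {
    cat(sprintf("MigrationNetwork: %d nodes, %d directed links, m = %d (dt = %.4f rad ~ %.1f days)\n",
                nNodes(object), nLinks(object), nSeasons(object),
                seasonWidth(object), radiansToDays(seasonWidth(object))))
    if (nLinks(object)) {
        lk <- links(object)
        cat(sprintf("  phases span weeks %d-%d; amplitude range [%.3g, %.3g]\n",
                    min(phaseToWeek(lk$phase, object@m)),
                    max(phaseToWeek(lk$phase, object@m)),
                    min(lk$amplitude), max(lk$amplitude)))
    }
    invisible(object)
})

## Season midpoints tau_k = (k - 1/2) * dt, k = 1..m (1-based seasons).
seasonMidpoints <- function(net) {
    (seq_len(net@m) - 0.5) * seasonWidth(net)
}

## Map node ids to matrix indices 1..n.
nodeIndex <- function(net, ids) {
    match(ids, net@nodes$id)
}

#' @rdname densityValues
#' @export
setMethod("densityValues", "DensityField", function(x) {
    v <- x@values
    v[v < 0] <- 0
    v
})

#' @describeIn densityValues matrix coercion.
#' @param ... unused.
#' @export
setMethod("as.matrix", "DensityField", function(x, ...) densityValues(x))

setMethod("show", "DensityField", function(object) {
    v <- densityValues(object)
    cat(sprintf("DensityField: %d seasons x %d nodes\n", nrow(v), ncol(v)))
    peak <- apply(v, 2, max)
    cat("  peak density per node:",
        paste(sprintf("%s=%.3f", colnames(v), peak), collapse = ", "), "\n")
    invisible(object)
})

setMethod("show", "SensitivityReport", function(object) {
    r <- object@results
    cat(sprintf("SensitivityReport: %d perturbations on %d links (rule: >%.0f%% of seasonal G-tests with p > %.2g)\n",
                nrow(r), length(unique(paste(r$from, r$to))),
                100 * object@fracClose, object@pClose))
    cat(sprintf("  verdicts: %d close, %d altered\n",
                sum(r$verdict == "close"), sum(r$verdict == "altered")))
    invisible(object)
})
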