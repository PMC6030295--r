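#' @include core-model.R
NULL

#' Read and write migration-network model files
#'
#' Networks are serialised as JSON (or YAML, if the file extension is
#' `.yml`/`.yaml` and the yaml package is available) with fields
#' `nodes: [{id, label, lon, lat}]`,
#' `links: [{from, to, phase, width, amplitude}]` and `m`. The format
#' round-trips: `readMigrationNetwork(writeMigrationNetwork(net, f))`
#' reconstructs an identical network.
#'
#' @param path file path.
#' @param net a [MigrationNetwork-class].
#' @return `readMigrationNetwork` returns a [MigrationNetwork-class];
#'   `writeMigrationNetwork` returns `path` invisibly.
#' @export
readMigrationNetwork <- function(path) {
    if (grepl("[.]ya?ml$", path, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("reading YAML network files requires the yaml package")
        x <- yaml::read_yaml(path)
        nodes <- do.call(rbind, lapply(x$nodes, as.data.frame))
        links <- if (length(x$links))
            do.call(rbind, lapply(x$links, as.data.frame)) else NULL
    } else {
        x <- jsonlite::fromJSON(path)
        nodes <- as.data.frame(x$nodes)
        links <- if (length(x$links)) as.data.frame(x$links) else NULL
    }
    MigrationNetwork(nodes = nodes, links = links,
                     m = if (is.null(x$m)) 48L else as.integer(x$m))
}

#' @rdname readMigrationNetwork
#' @export
writeMigrationNetwork <- function(net, path) {
    stopifnot(is(net, "MigrationNetwork"))
    obj <- list(nodes = nodes(net), links = links(net), m = net@m)
    if (grepl("[.]ya?ml$", path, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("writing YAML network files requires the yaml package")
        obj$nodes <- lapply(seq_len(nrow(obj$nodes)),
                            function(i) as.list(obj$nodes[i, ]))
        obj$links <- lapply(seq_len(nrow(obj$links)),
                            function(i) as.list(obj$links[i, ]))
        yaml::write_yaml(obj, path)
    } else {
        jsonlite::write_json(obj, path, dataframe = "rows",
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(path)
}

#' Write a density field as CSV
#'
#' @param field a [DensityField-class].
#' @param path output file.
#' @param long if `TRUE`, write long format (`season`, `node`,
#'   `density`); otherwise one row per seasonal interval and one column
#'   per node (plus a `season` column).
#' @return `path`, invisibly.
#' @export
writeDensityField <- function(field, path, long = FALSE) {
    v <- densityValues(field)
    if (long) {
        df <- data.frame(
            season = rep(seq_len(nrow(v)), times = ncol(v)),
            node = rep(colnames(v), each = nrow(v)),
            density = as.vector(v))
    } else {
        df <- data.frame(season = seq_len(nrow(v)), v, check.names = FALSE)
    }
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Default Movebank-style column mapping for track files
#'
#' @return named character vector mapping internal field names
#'   (`id`, `timestamp`, `lon`, `lat`, `accuracy`) to CSV column names.
#' @export
movebankColumns <- function() {
    c(id = "individual-local-identifier",
      timestamp = "timestamp",
      lon = "location-long",
      lat = "location-lat",
      accuracy = "gps:horizontal-accuracy")
}

#' Read a multi-individual track table
#'
#' Reads a CSV of GPS/satellite-telemetry fixes into the internal fix
#' table used by the track-processing pipeline. Columns are located via
#' a configurable mapping (Movebank names by default). Accuracy may be a
#' numeric horizontal error in metres or an ordinal location class
#' (e.g. Argos classes, ranked via `classRanking`, best first).
#' Within each individual, fixes are de-duplicated on timestamp and
#' sorted in time; latitudes are validated and longitudes wrapped into
#' `(-180, 180]`.
#'
#' @param path CSV file with a header row.
#' @param columns named character vector as in [movebankColumns()].
#' @param classRanking character vector of location classes ordered best
#'   to worst, used when the accuracy column is non-numeric.
#' @return data.frame with columns `id`, `timestamp` (POSIXct, UTC),
#'   `lon`, `lat`, `accuracy` (numeric; ordinal classes mapped to their
#'   rank, lower = better).
#' @export
readTracks <- function(path, columns = movebankColumns(),
                       classRanking = c("3", "2", "1", "0", "A", "B")) {
    raw <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    missing <- setdiff(unname(columns[c("id", "timestamp", "lon", "lat")]),
                       names(raw))
    if (length(missing))
        stop("track file ", path, " is missing required column(s): ",
             paste(missing, collapse = ", "))
    fx <- data.frame(
        id = as.character(raw[[columns[["id"]]]]),
        timestamp = as.POSIXct(raw[[columns[["timestamp"]]]], tz = "UTC"),
        lon = as.numeric(raw[[columns[["lon"]]]]),
        lat = as.numeric(raw[[columns[["lat"]]]]),
        stringsAsFactors = FALSE)
    acc_col <- columns[["accuracy"]]
    if (!is.na(acc_col) && acc_col %in% names(raw)) {
        acc <- raw[[acc_col]]
        num <- suppressWarnings(as.numeric(acc))
        if (all(is.na(num) == is.na(acc))) {
            fx$accuracy <- num
        } else {
            fx$accuracy <- as.numeric(match(as.character(acc), classRanking))
        }
    } else {
        fx$accuracy <- NA_real_
    }
    if (any(is.na(fx$timestamp))) stop("unparseable timestamps in ", path)
    if (any(abs(fx$lat) > 90, na.rm = TRUE)) stop("latitudes outside [-90, 90]")
    fx$lon <- ((fx$lon + 180) %% 360) - 180
    fx$lon[fx$lon == -180] <- 180
    fx <- fx[order(fx$id, fx$timestamp), ]
    dup <- duplicated(fx[c("id", "timestamp")])
    fx <- fx[!dup, ]
    rownames(fx) <- NULL
    fx
}

#' Export a directed topology as GraphML
#'
#' @param g an igraph graph, a [MigrationNetwork-class] (its cumulative
#'   link structure), or an edge data.frame with `from`/`to` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(g, path) {
    if (is(g, "MigrationNetwork")) {
        gr <- igraph::graph_from_data_frame(
            links(g)[c("from", "to", "phase", "width", "amplitude")],
            directed = TRUE,
            vertices = nodes(g)[c("id", "label", "lon", "lat")])
    } else if (igraph::is_igraph(g)) {
        gr <- g
    } else {
        gr <- igraph::graph_from_data_frame(as.data.frame(g), directed = TRUE)
    }
    igraph::write_graph(gr, path, format = "graphml")
    invisible(path)
}
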