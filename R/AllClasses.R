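#' @include AllGenerics.R
NULL

## Central numerical tolerances (one place, used throughout).
TOL <- list(
    colsum_zero   = 1e-12,  # rate-matrix columns sum to zero
    stochastic    = 1e-9,   # transition-matrix columns sum to one
    perron        = 1e-8,   # |dominant eigenvalue - 1| of a year map
    fixed_point   = 1e-8,   # ||S N* - N*||_inf
    conservation  = 1e-9,   # per-step total-density drift
    density_neg   = 1e-9    # tolerated numerical negativity before clipping
)

## Minimum admissible seasonal width: one day on the annual circle.
MIN_WIDTH <- 0.017

#' Seasonal migration network
#'
#' An S4 container for a spatial migration network: a set of geographic
#' nodes (breeding, stopover and wintering regions) joined by directed
#' links, each link carrying a von Mises seasonal transition-rate profile
#' with parameters phase \eqn{\varphi} (peak timing, radians), width
#' \eqn{\sigma} (length of the transition period, radians) and amplitude
#' \eqn{\omega} (maximum transition intensity, per unit time). The year is
#' the circle of circumference `period` (fixed at \eqn{2\pi}) split into
#' `m` equal seasonal intervals.
#'
#' @slot nodes data.frame with columns `id` (integer), `label`
#'   (character), `lon`, `lat` (WGS84 degrees).
#' @slot links data.frame with columns `from`, `to` (node ids),
#'   `phase`, `width`, `amplitude` (von Mises parameters).
#' @slot m integer, number of seasonal intervals (default 48).
#' @slot period numeric, length of the year in radians (always
#'   \eqn{2\pi}).
#'
#' @seealso [MigrationNetwork()] for construction, [rateMatrix()],
#'   [poincareMap()], [stationaryDensities()].
#' @name MigrationNetwork-class
#' @exportClass MigrationNetwork
setClass("MigrationNetwork",
    representation(
        nodes  = "data.frame",
        links  = "data.frame",
        m      = "integer",
        period = "numeric"
    )
)

setValidity("MigrationNetwork", function(object) {
    msg <- character()
    nd <- object@nodes
    lk <- object@links
    need_n <- c("id", "label", "lon", "lat")
    need_l <- c("from", "to", "phase", "width", "amplitude")
    if (!all(need_n %in% names(nd)))
        msg <- c(msg, paste("nodes must have columns",
                            paste(need_n, collapse = ", ")))
    if (!all(need_l %in% names(lk)))
        msg <- c(msg, paste("links must have columns",
                            paste(need_l, collapse = ", ")))
    if (length(msg)) return(msg)
    if (anyDuplicated(nd$id))
        msg <- c(msg, "duplicated node ids")
    if (nrow(lk)) {
        if (!all(lk$from %in% nd$id) || !all(lk$to %in% nd$id))
            msg <- c(msg, "every link endpoint must be a declared node")
        if (any(lk$from == lk$to))
            msg <- c(msg, "self-links are not allowed")
        if (anyDuplicated(lk[c("from", "to")]))
            msg <- c(msg, "duplicated links")
        if (any(!is.finite(lk$phase)))
            msg <- c(msg, "non-finite phase")
        if (any(lk$phase < 0 | lk$phase >= 2 * pi))
            msg <- c(msg, "phases must be wrapped into [0, 2*pi)")
        if (any(lk$width < MIN_WIDTH & is.finite(lk$width)) &&
            !isTRUE(attr(object@links, "allowNarrow")))
            msg <- c(msg, sprintf("widths below the one-day truncation %.3f", MIN_WIDTH))
        if (any(lk$width <= 0))
            msg <- c(msg, "widths must be positive")
        if (any(lk$amplitude < 0))
            msg <- c(msg, "amplitudes must be non-negative")
    }
    if (length(object@m) != 1L || object@m < 1L)
        msg <- c(msg, "m must be a single positive integer")
    if (length(object@period) != 1L ||
        abs(object@period - 2 * pi) > 1e-12)
        msg <- c(msg, "period must be 2*pi")
    if (length(msg)) msg else TRUE
})

#' Seasonal density field
#'
#' An `m x n` matrix of population densities: entry `[k, i]` is the
#' fraction of the population in node `i` during seasonal interval `k`.
#' Every row sums to one (the population is conserved); values are
#' non-negative up to numerical noise and clipped at zero on output.
#'
#' @slot values numeric matrix (`m` seasons by `n` nodes, columns named
#'   by node label).
#' @name DensityField-class
#' @exportClass DensityField
setClass("DensityField", representation(values = "matrix"))

setValidity("DensityField", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (any(!is.finite(v))) return("non-finite densities")
    if (any(v < -TOL$density_neg)) return("negative densities")
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-6))
        return("each seasonal row must sum to 1")
    TRUE
})

#' Parameter-perturbation sensitivity report
#'
#' Result container for [sensitivityScan()]: one row per (link,
#' parameter, perturbation value) with the fraction of seasonal G-tests
#' whose p-value exceeded the closeness level, and the resulting verdict
#' (`"close"` if the fraction exceeds the closeness fraction, else
#' `"altered"`).
#'
#' @slot results data.frame with columns `from`, `to`, `parameter`,
#'   `perturbation`, `meanG`, `fracClose`, `verdict`, `removedLink`.
#' @slot baseline the unperturbed [DensityField-class].
#' @slot pseudoPopulation population size used to convert baseline
#'   densities into expected counts for the G-tests.
#' @slot pClose,fracClose the closeness rule: verdict is `"close"` when
#'   more than `fracClose` of seasonal G-tests have p > `pClose`.
#' @name SensitivityReport-class
#' @exportClass SensitivityReport
setClass("SensitivityReport",
    representation(
        results          = "data.frame",
        baseline         = "DensityField",
        pseudoPopulation = "numeric",
        pClose           = "numeric",
        fracClose        = "numeric"
    )
)

setValidity("SensitivityReport", function(object) {
    r <- object@results
    need <- c("from", "to", "parameter", "perturbation",
              "meanG", "fracClose", "verdict")
    if (!all(need %in% names(r)))
        return(paste("results must have columns", paste(need, collapse = ", ")))
    if (nrow(r) && any(r$fracClose < 0 | r$fracClose > 1))
        return("fracClose must lie in [0, 1]")
    TRUE
})
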