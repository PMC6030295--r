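#' @include MigrationNetwork-methods.R
NULL

#' von Mises seasonal transition rate
#'
#' Evaluates the seasonal transition-rate profile
#' \deqn{r(\tau) = \omega \exp\!\left(\frac{\cos(\tau-\varphi)-1}{\sigma^2}\right),}
#' the von Mises-shaped rate used on every network link. The rate peaks
#' at value `amplitude` when `tau == phase`; `width` controls how long
#' the transition period lasts. The limits are the uniform rate
#' (`width = Inf`, constant `amplitude`) and a delta-like spike
#' (`width -> 0`, admitted only with `allowNarrow = TRUE`).
#'
#' @param tau season angle(s) in radians (wrapped mod \eqn{2\pi}).
#' @param phase peak season \eqn{\varphi} in radians.
#' @param width seasonal width \eqn{\sigma} in radians; must be at least
#'   the one-day truncation 0.017 unless `allowNarrow = TRUE`.
#' @param amplitude maximum intensity \eqn{\omega \ge 0} per unit time.
#' @param allowNarrow logical, permit `width < 0.017` for studying the
#'   delta limit.
#' @return numeric vector of rates in `[0, amplitude]`.
#' @examples
#' vonMisesRate(1.31, phase = 1.31, width = 0.26, amplitude = 5)  # = 5
#' vonMisesRate(0.7, phase = 0, width = Inf, amplitude = 2)       # = 2
#' @export
vonMisesRate <- function(tau, phase, width, amplitude, allowNarrow = FALSE) {
    stopifnot(is.finite(tau), amplitude >= 0, width > 0)
    if (any(width < MIN_WIDTH) && !allowNarrow)
        stop("width below the one-day truncation ", MIN_WIDTH,
             "; use allowNarrow = TRUE for the delta limit")
    arg <- (cos(tau - phase) - 1) / width^2
    arg[!is.finite(width) | width == Inf] <- 0
    amplitude * exp(arg)
}

#' Seasonal rate matrix
#'
#' Builds the `n x n` instantaneous rate matrix \eqn{R(\tau_k)} of the
#' continuous process for seasonal interval `season`: entry `[i, j]` is
#' the von Mises rate from node `j` to node `i` evaluated at the
#' interval midpoint \eqn{\tau_k = (k - 1/2)\,\Delta\tau}, and each
#' diagonal entry is minus the total outflow of its column so that
#' columns sum to zero and total density is conserved.
#'
#' @param net a [MigrationNetwork-class].
#' @param season 1-based seasonal interval index in `1..m`.
#' @return numeric `n x n` matrix with zero column sums; row/column
#'   names are node labels.
#' @export
rateMatrix <- function(net, season) {
    stopifnot(is(net, "MigrationNetwork"),
              season >= 1, season <= net@m)
    n <- nNodes(net)
    tau <- seasonMidpoints(net)[season]
    R <- matrix(0, n, n, dimnames = list(net@nodes$label, net@nodes$label))
    lk <- links(net)
    if (nrow(lk)) {
        i <- nodeIndex(net, lk$to)
        j <- nodeIndex(net, lk$from)
        allowNarrow <- isTRUE(attr(net@links, "allowNarrow"))
        R[cbind(i, j)] <- vonMisesRate(tau, lk$phase, lk$width,
                                       lk$amplitude,
                                       allowNarrow = allowNarrow)
    }
    diag(R) <- diag(R) - colSums(R)
    R
}

#' Transition-probability matrix for one seasonal interval
#'
#' Maps an instantaneous rate matrix to the column-stochastic matrix of
#' transition probabilities over a time step `dt` by the matrix
#' exponential \eqn{P = e^{R\,\Delta\tau}}. Entry `[i, j]` is the
#' probability that an animal in node `j` is in node `i` after `dt`.
#'
#' @param R numeric square rate matrix with non-negative off-diagonals
#'   and zero column sums.
#' @param dt time-step length in radians.
#' @return column-stochastic matrix of the same dimension.
#' @export
transitionMatrix <- function(R, dt) {
    R <- as.matrix(R)
    if (any(!is.finite(R))) stop("non-finite entries in rate matrix")
    stopifnot(nrow(R) == ncol(R), is.finite(dt), dt > 0)
    P <- .expmDense(R * dt)
    ## clip exponentially small negative noise
    P[P < 0 & P > -1e-12] <- 0
    dimnames(P) <- dimnames(R)
    P
}

## All m per-interval transition matrices of a network.
transitionMatrices <- function(net) {
    dt <- seasonWidth(net)
    lapply(seq_len(net@m), function(k) transitionMatrix(rateMatrix(net, k), dt))
}

#' One-year Poincare map
#'
#' Composes the `m` per-interval transition matrices chronologically
#' into the year map
#' \eqn{S(\tau) = P(\tau+(m-1)\Delta\tau)\cdots P(\tau+\Delta\tau)\,P(\tau)},
#' which advances a density at season `start` by exactly one year. Every
#' year map is column-stochastic and, by Perron-Frobenius, has dominant
#' eigenvalue 1; its eigenvector is the stationary seasonal density at
#' `start`.
#'
#' @param net a [MigrationNetwork-class].
#' @param start 1-based seasonal interval at which the year starts.
#' @param P optional precomputed list of the `m` transition matrices
#'   (from the internal per-interval builder) to avoid recomputation.
#' @return column-stochastic `n x n` matrix.
#' @export
poincareMap <- function(net, start = 1L, P = NULL) {
    stopifnot(start >= 1, start <= net@m)
    if (is.null(P)) P <- transitionMatrices(net)
    m <- net@m
    ord <- ((start - 1 + seq_len(m) - 1) %% m) + 1  # chronological k, k+1, ...
    S <- diag(nNodes(net))
    for (k in ord) S <- P[[k]] %*% S
    dimnames(S) <- dimnames(P[[1]])
    S
}

## Eigenvector of S for the eigenvalue closest to 1 (real part, clipped,
## normalised). Falls back to power iteration for defective cases.
stationaryVector <- function(S) {
    ev <- eigen(S)
    i <- which.min(Mod(ev$values - 1))
    if (Mod(ev$values[i] - 1) > 1e-6) {
        warning("year map has no eigenvalue near 1 (reducible or degenerate network); ",
                "falling back to power iteration from the uniform density")
        v <- rep(1 / nrow(S), nrow(S))
        for (it in 1:5000) v <- as.vector(S %*% v)
    } else {
        v <- Re(ev$vectors[, i])
        if (sum(v) < 0) v <- -v
    }
    v[v < 0 & v > -TOL$density_neg] <- 0
    if (any(v < 0)) {
        ## mixed-sign eigenvector: not the Perron vector, refine by power iteration
        v <- abs(v)
        for (it in 1:2000) v <- as.vector(S %*% v)
    }
    v / sum(v)
}

#' Stationary seasonal densities
#'
#' Solves the periodic fixed-point problem
#' \eqn{N^*(\tau) = S(\tau)\,N^*(\tau)}: for each seasonal interval the
#' stationary density is the eigenvalue-1 eigenvector of the year map
#' starting there. The solution is computed once at season 1 and
#' propagated forward through the per-interval transition matrices,
#' which yields exactly the eigenvectors of every `S(k)` while keeping
#' the `m` seasonal solutions one coherent orbit
#' (`P(k) N*(k) = N*(k+1)`).
#'
#' @param net a [MigrationNetwork-class].
#' @param method `"eigen"` (default) for the eigen-solution, `"power"`
#'   for 50-year power iteration from the uniform density (used as an
#'   independent cross-check).
#' @param years number of years to iterate when `method = "power"`.
#' @return a [DensityField-class] (`m` seasons by `n` nodes).
#' @examples
#' nst <- stationaryDensities(exampleNetwork())
#' nst
#' @export
stationaryDensities <- function(net, method = c("eigen", "power"),
                                years = 50L) {
    method <- match.arg(method)
    P <- transitionMatrices(net)
    n <- nNodes(net)
    if (method == "eigen") {
        S1 <- poincareMap(net, 1L, P = P)
        v <- stationaryVector(S1)
    } else {
        v <- rep(1 / n, n)
        for (y in seq_len(years)) for (k in seq_len(net@m))
            v <- as.vector(P[[k]] %*% v)
    }
    vals <- matrix(0, net@m, n,
                   dimnames = list(NULL, net@nodes$label))
    vals[1, ] <- v
    for (k in seq_len(net@m - 1))
        vals[k + 1, ] <- as.vector(P[[k]] %*% vals[k, ])
    vals[vals < 0 & vals > -TOL$density_neg] <- 0
    vals <- vals / rowSums(vals)
    new("DensityField", values = vals)
}

#' Forward simulation of the density dynamics
#'
#' Iterates the time-discrete Markov chain
#' \eqn{N(t+\Delta\tau) = P(\tau;\Delta\tau)\,N(t)} step by step from an
#' initial density. Total density is conserved at every step; on a
#' well-mixed (regular) network the trajectory converges to the
#' stationary seasonal cycle.
#'
#' @param net a [MigrationNetwork-class].
#' @param initial numeric density vector of length `n`, non-negative,
#'   summing to 1 (default: all mass in the first node).
#' @param years number of years to simulate.
#' @param startSeason 1-based seasonal interval of the initial density.
#' @return numeric matrix with `years * m + 1` rows (the initial state
#'   and one row per step) and `n` node columns; attribute `"season"`
#'   holds each row's 1-based seasonal interval.
#' @export
simulateDensities <- function(net, initial = NULL, years = 10L,
                              startSeason = 1L) {
    n <- nNodes(net)
    if (is.null(initial)) initial <- c(1, rep(0, n - 1))
    stopifnot(length(initial) == n, all(initial >= 0),
              abs(sum(initial) - 1) < 1e-9)
    P <- transitionMatrices(net)
    steps <- years * net@m
    out <- matrix(0, steps + 1, n,
                  dimnames = list(NULL, net@nodes$label))
    out[1, ] <- initial
    season <- integer(steps + 1)
    season[1] <- startSeason
    k <- startSeason
    for (s in seq_len(steps)) {
        out[s + 1, ] <- as.vector(P[[k]] %*% out[s, ])
        k <- (k %% net@m) + 1
        season[s + 1] <- k
    }
    attr(out, "season") <- season
    out
}
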