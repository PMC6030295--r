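net4 <- exampleNetwork()

test_that("von Mises rate peaks at the phase and handles the limits", {
    expect_equal(vonMisesRate(1.31, 1.31, 0.26, 5), 5)
    expect_equal(vonMisesRate(c(0, 1, 4), 0, Inf, 2), rep(2, 3))
    ## independent scalar evaluation of the formula at one point
    expect_equal(vonMisesRate(1.31, 1.70, 0.26, 5), 1.64645614704,
                 tolerance = 1e-10)
    tau <- seq(0, 2 * pi, length.out = 200)
    r <- vonMisesRate(tau, 2.5, 0.4, 3)
    expect_true(all(r >= 0 & r <= 3))
    expect_equal(tau[which.max(r)], 2.5, tolerance = 0.02)
    expect_error(vonMisesRate(1, 0, 0.001, 1), "truncation")
    expect_silent(vonMisesRate(1, 0, 0.001, 1, allowNarrow = TRUE))
})

test_that("network validity rejects malformed inputs", {
    nd <- data.frame(id = 1:2, label = c("a", "b"), lon = 0:1, lat = 0:1)
    expect_error(MigrationNetwork(nd, data.frame(
        from = 1, to = 1, phase = 1, width = 0.3, amplitude = 1)),
        "self-link")
    expect_error(MigrationNetwork(nd, data.frame(
        from = 1, to = 3, phase = 1, width = 0.3, amplitude = 1)),
        "declared node")
    expect_error(MigrationNetwork(nd, data.frame(
        from = 1, to = 2, phase = 1, width = 0.001, amplitude = 1)),
        "truncation")
    expect_error(MigrationNetwork(nd, data.frame(
        from = 1, to = 2, phase = 1, width = 0.3, amplitude = -1)),
        "non-negative")
    ## phases are wrapped on construction
    net <- MigrationNetwork(nd, data.frame(
        from = 1, to = 2, phase = -0.5, width = 0.3, amplitude = 1))
    expect_equal(links(net)$phase, 2 * pi - 0.5)
})

test_that("rate matrices have von Mises off-diagonals and zero column sums", {
    for (k in c(1, 11, 25, 48)) {
        R <- rateMatrix(net4, k)
        expect_true(all(R[row(R) != col(R)] >= 0))
        expect_lt(max(abs(colSums(R))), 1e-12)
    }
    ## at the interval containing tau = 1.31 the spring links are near peak
    k10 <- ceiling(1.31 / seasonWidth(net4))
    R <- rateMatrix(net4, k10)
    expect_gt(R[1, 3], 4.7)   # 3 -> 1
    expect_gt(R[2, 3], 4.7)   # 3 -> 2
    expect_gt(R[2, 4], 4.7)   # 4 -> 2
    ## zero-amplitude network gives the zero matrix
    z <- MigrationNetwork(nodes(net4),
                          transform(links(net4), amplitude = 0), m = 48L)
    expect_equal(rateMatrix(z, 5), matrix(0, 4, 4), ignore_attr = TRUE)
})

test_that("transition matrices are column-stochastic and match the series oracle", {
    dt <- seasonWidth(net4)
    expect_equal(transitionMatrix(matrix(0, 3, 3), dt), diag(3),
                 ignore_attr = TRUE)
    ## 2-node closed form: p = 1 - exp(-r dt)
    r <- 2.4
    R2 <- matrix(c(-r, r, 0, 0), 2, 2)
    P2 <- transitionMatrix(R2, dt)
    expect_equal(P2[2, 1], 1 - exp(-r * dt), tolerance = 1e-12)
    ## random valid rate matrices vs Taylor-series summation
    set.seed(7)
    for (rep in 1:5) {
        A <- matrix(runif(16, 0, 4), 4, 4)
        diag(A) <- 0
        diag(A) <- -colSums(A)
        P <- transitionMatrix(A, dt)
        expect_equal(P, expmTaylor(A * dt), tolerance = 1e-8,
                     ignore_attr = TRUE)
        expect_lt(max(abs(colSums(P) - 1)), 1e-9)
        expect_true(all(P >= 0 & P <= 1 + 1e-12))
    }
    expect_error(transitionMatrix(matrix(c(NA, 1, 1, NA), 2, 2), dt),
                 "non-finite")
})

test_that("the year map is stochastic with dominant eigenvalue 1 and matches stepwise composition", {
    P <- migflow:::transitionMatrices(net4)
    for (k in c(1, 17, 48)) {
        S <- poincareMap(net4, k, P = P)
        expect_lt(max(abs(colSums(S) - 1)), 1e-9)
        expect_lt(abs(max(Mod(eigen(S)$values)) - 1), 1e-8)
        ## forward-simulation oracle: apply the m matrices to each basis vector
        for (b in 1:4) {
            v <- numeric(4); v[b] <- 1
            kk <- k
            for (s in 1:48) {
                v <- as.vector(P[[kk]] %*% v)
                kk <- (kk %% 48) + 1
            }
            expect_equal(as.vector(S[, b]), v, tolerance = 1e-12)
        }
    }
})

test_that("stationary densities solve the periodic fixed point coherently", {
    fld <- stationaryDensities(net4)
    v <- densityValues(fld)
    expect_equal(rowSums(v), rep(1, 48))
    expect_true(all(v >= 0))
    P <- migflow:::transitionMatrices(net4)
    ## fixed point of every year map, and one coherent orbit
    for (k in c(1, 10, 30)) {
        S <- poincareMap(net4, k, P = P)
        expect_lt(max(abs(S %*% v[k, ] - v[k, ])), 1e-8)
    }
    for (k in 1:47)
        expect_equal(as.vector(P[[k]] %*% v[k, ]), unname(v[k + 1, ]),
                     tolerance = 1e-8)
    ## power-iteration oracle
    pw <- densityValues(stationaryDensities(net4, method = "power"))
    expect_lt(max(abs(v - pw)), 1e-7)
})

test_that("stationary densities show the seasonal pattern of the worked example", {
    v <- densityValues(stationaryDensities(net4))
    expect_gt(v[25, 1], 0.95)              # mid-summer: everyone breeding
    expect_gt(max(v[, 2]), 0.5)            # autumn passage through stopover
    expect_equal(which.max(v[, 2]), 36, tolerance = 1)
    expect_gt(v[1, 3], v[1, 4])            # winter split favours node 3
    ## node 3 empties earlier in spring than node 4
    springEmpty <- function(i) which(v[1:24, i] < 0.5 * v[1, i])[1]
    expect_lt(springEmpty(3), springEmpty(4))
})

test_that("single-node and disconnected networks degrade gracefully", {
    solo <- MigrationNetwork(data.frame(id = 1), NULL, m = 48L)
    v <- densityValues(stationaryDensities(solo))
    expect_equal(as.vector(v), rep(1, 48))
    ## two disconnected pairs: fixed point exists but is not unique;
    ## the solver still returns a valid density field
    dis <- MigrationNetwork(
        data.frame(id = 1:4),
        data.frame(from = c(1, 2), to = c(2, 1),
                   phase = c(4.58, 1.57), width = 0.3, amplitude = 4),
        m = 48L)
    vd <- densityValues(stationaryDensities(dis))
    expect_equal(rowSums(vd), rep(1, 48))
})

test_that("forward simulation conserves total density and converges to stationarity", {
    traj <- simulateDensities(net4, years = 10)
    expect_equal(nrow(traj), 481)
    expect_lt(max(abs(rowSums(traj) - 1)), 1e-9)
    ## identity dynamics: zero-amplitude network keeps the initial state
    z <- MigrationNetwork(nodes(net4),
                          transform(links(net4), amplitude = 0), m = 48L)
    tz <- simulateDensities(z, initial = c(0.4, 0.3, 0.2, 0.1), years = 2)
    expect_equal(tz[nrow(tz), ], c(0.4, 0.3, 0.2, 0.1),
                 ignore_attr = TRUE)
    ## long-run convergence to the eigen solution
    long <- simulateDensities(net4, years = 50)
    v <- densityValues(stationaryDensities(net4))
    lastCycle <- long[(50 - 1) * 48 + 1 + (1:48) - 1, ]
    expect_lt(max(abs(lastCycle - v)), 1e-6)
})

test_that("the delta and uniform limits behave as the theory says", {
    ## sigma -> 0: all transitions collapse onto the interval containing
    ## the phase (put the spike on an interval midpoint so the piecewise-
    ## constant discretisation samples it); the moved mass approaches
    ## 1 - exp(-omega dt), monotone in omega
    dt <- 2 * pi / 48
    kPhase <- 8L
    spike <- (kPhase - 0.5) * dt
    mass <- vapply(c(1, 3, 9), function(om) {
        net <- MigrationNetwork(
            data.frame(id = 1:2),
            data.frame(from = 1, to = 2, phase = spike, width = 0.02,
                       amplitude = om),
            m = 48L, allowNarrow = TRUE)
        poincareMap(net, 1)[2, 1]
    }, numeric(1))
    expect_true(all(diff(mass) > 0))
    expect_equal(mass, 1 - exp(-c(1, 3, 9) * dt), tolerance = 0.02)
    net <- MigrationNetwork(
        data.frame(id = 1:2),
        data.frame(from = 1, to = 2, phase = spike, width = 0.02,
                   amplitude = 5),
        m = 48L, allowNarrow = TRUE)
    P <- migflow:::transitionMatrices(net)
    move <- vapply(P, function(p) p[2, 1], numeric(1))
    expect_gt(move[kPhase], 0.45)
    expect_lt(max(move[-kPhase]), 1e-6)
    ## sigma -> Inf: time-homogeneous chain, season-independent density
    uni <- MigrationNetwork(
        data.frame(id = 1:2),
        data.frame(from = c(1, 2), to = c(2, 1), phase = c(1, 4),
                   width = Inf, amplitude = c(2, 3)),
        m = 48L)
    vu <- densityValues(stationaryDensities(uni))
    expect_lt(max(abs(sweep(vu, 2, vu[1, ]))), 1e-10)
    expect_equal(vu[1, ], c(3, 2) / 5, tolerance = 1e-9,
                 ignore_attr = TRUE)
})
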