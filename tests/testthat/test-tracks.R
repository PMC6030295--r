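test_that("best daily positions pick best accuracy, latest-time tie-break", {
    fx <- rbind(
        makeFixes("b1", "2020-05-01", 10.0, 50.0, accuracy = 12, hour = 8),
        makeFixes("b1", "2020-05-01", 10.1, 50.1, accuracy = 5, hour = 10),
        makeFixes("b1", "2020-05-02", 10.2, 50.2, accuracy = 7, hour = 9),
        makeFixes("b1", "2020-05-02", 10.3, 50.3, accuracy = 7, hour = 18),
        makeFixes("b2", "2020-05-01", 20.0, 40.0, accuracy = 3, hour = 7))
    bd <- bestDailyPositions(fx)
    expect_equal(nrow(bd), 3)
    expect_equal(bd$lon[bd$id == "b1" & bd$date == as.Date("2020-05-01")], 10.1)
    ## equal accuracy: the fix at the end of the day wins
    expect_equal(bd$lon[bd$id == "b1" & bd$date == as.Date("2020-05-02")], 10.3)
    ## one fix per day passes through unchanged
    one <- makeFixes("s", as.Date("2020-01-01") + 0:9, 1:10, rep(45, 10))
    expect_equal(bestDailyPositions(one)$lon, 1:10)
    expect_warning(bestDailyPositions(one[0, ]), "no fixes")
})

test_that("daily velocities use great-circle distance over day gaps", {
    d <- makeFixes("b", c("2020-01-01", "2020-01-02"), c(20, 20), c(10, 11))
    bd <- dailyVelocities(bestDailyPositions(d))
    ## 1 degree along a meridian on the 6371 km sphere
    expect_equal(bd$v_out[1], 111.195, tolerance = 1e-4)
    expect_equal(bd$v_in[2], bd$v_out[1])
    expect_true(is.na(bd$v_in[1]) && is.na(bd$v_out[2]))
    ## stationary bird: all zero
    st <- dailyVelocities(bestDailyPositions(
        makeFixes("b", as.Date("2020-01-01") + 0:5, rep(3, 6), rep(47, 6))))
    expect_equal(st$v_in[-1], rep(0, 5))
    ## gaps above 3 days give missing velocities
    gap <- dailyVelocities(bestDailyPositions(makeFixes(
        "b", as.Date("2020-01-01") + c(0, 2, 7), c(0, 1, 2), c(50, 50, 50))))
    expect_equal(gap$v_out[1], haversineOracle(0, 50, 1, 50) / 2,
                 tolerance = 1e-6)
    expect_true(is.na(gap$v_in[3]))
    ## randomised tracks match an independent haversine implementation
    set.seed(11)
    rnd <- makeFixes("r", as.Date("2020-06-01") + 0:30,
                     runif(31, -10, 30), runif(31, 0, 60))
    rv <- dailyVelocities(bestDailyPositions(rnd))
    expected <- haversineOracle(rnd$lon[-31], rnd$lat[-31],
                                rnd$lon[-1], rnd$lat[-1])
    expect_equal(rv$v_in[-1], expected, tolerance = 1e-3)
})

test_that("resting classification is strict and endpoint-aware", {
    d <- data.frame(id = "b", date = as.Date("2020-01-01") + 0:4,
                    lon = 0, lat = 0,
                    v_in = c(NA, 10, 10, 400, 50),
                    v_out = c(10, 10, 400, 50, NA))
    r <- classifyResting(d, threshold = 50)
    expect_equal(r$resting, c(TRUE, TRUE, FALSE, FALSE, FALSE))
    ## boundary: v == threshold is not resting (strict <)
    expect_false(classifyResting(
        data.frame(v_in = 50, v_out = 10), 50)$resting)
    ## no velocity at all: not classifiable as resting
    expect_false(classifyResting(
        data.frame(v_in = NA_real_, v_out = NA_real_), 50)$resting)
    ## monotonicity: a higher threshold never loses resting positions
    set.seed(3)
    dd <- data.frame(v_in = runif(200, 0, 100), v_out = runif(200, 0, 100))
    lo <- classifyResting(dd, 20)$resting
    hi <- classifyResting(dd, 50)$resting
    expect_true(all(hi[lo]))
    expect_equal(velocityThreshold("stork"), 50)
    expect_equal(velocityThreshold("goose"), 20)
})

test_that("clustering partitions resting positions and filters small clusters", {
    ## two tight clumps 2000 km apart
    set.seed(5)
    clump <- function(lon, lat, n)
        data.frame(lon = lon + rnorm(n, sd = 0.3),
                   lat = lat + rnorm(n, sd = 0.3))
    two <- rbind(clump(10, 50, 5), clump(10, 32, 5))
    cl <- clusterRestingPositions(two)
    expect_equal(nrow(cl$clusters), 2)
    expect_equal(sort(table(cl$assignment)), sort(c(5, 5)),
                 ignore_attr = TRUE)
    ## a clump of 3 points is filtered out entirely
    expect_error(clusterRestingPositions(clump(5, 45, 3)),
                 "minimum size")
    ## planted clusters: 6 centres, 20 points each, sd ~ 100 km
    centres <- data.frame(lon = c(0, 10, 20, 30, 15, 5),
                          lat = c(55, 40, 25, 10, 60, 20))
    pts <- do.call(rbind, lapply(seq_len(6), function(i)
        data.frame(lon = centres$lon[i] + rnorm(20, sd = 0.9),
                   lat = centres$lat[i] + rnorm(20, sd = 0.9),
                   truth = i)))
    cp <- clusterRestingPositions(pts)
    expect_equal(nrow(cp$clusters), 6)
    expect_equal(cp$clusters$members, rep(20L, 6))
    ## memberships agree with the generator (up to label permutation)
    expect_equal(length(unique(paste(pts$truth, cp$assignment))), 6)
    ## every retained position belongs to exactly one cluster
    expect_true(all(!is.na(cp$assignment)))
    ## centroids sit near the planted centres
    ord <- vapply(seq_len(6), function(i)
        cp$assignment[pts$truth == i][1], integer(1))
    expect_lt(max(haversineOracle(centres$lon, centres$lat,
                                  cp$clusters$lon[ord],
                                  cp$clusters$lat[ord])), 60)
})

test_that("link extraction yields directed links with midpoint seasons", {
    mkday <- function(id, dates, node) {
        data.frame(id = id, date = as.Date(dates), lon = 0, lat = 0,
                   v_in = 0, v_out = 0, resting = TRUE,
                   node = node)
    }
    daily <- rbind(
        mkday("b1", as.Date("2020-03-01") + 0:5, c(1, 1, 2, 2, 3, 3)),
        mkday("b2", as.Date("2020-03-01") + 0:3, c(2, 2, 1, 1)))
    clustering <- list(assignment = daily$node)
    ex <- extractLinks(daily, clustering, m = 48L)
    expect_equal(ex$links[c("from", "to")],
                 data.frame(from = c(1, 2, 2), to = c(2, 1, 3)),
                 ignore_attr = TRUE)
    ## both directions of 1-2 exist as distinct links
    expect_true(all(c("1->2", "2->1") %in%
                    paste0(ex$links$from, "->", ex$links$to)))
    ## event season: midpoint of the day before/after the move
    expect_equal(ex$events$date[1], as.Date("2020-03-02") + 0.5,
                 tolerance = 1)
    ## invariant to individual ordering
    daily2 <- daily[rev(seq_len(nrow(daily))), ]
    ex2 <- extractLinks(daily2, list(assignment = daily2$node), m = 48L)
    expect_equal(ex$links, ex2$links)
    expect_equal(ex$events, ex2$events)
})

test_that("date-to-season mapping covers the year consistently", {
    d <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
    s <- migflow:::dateSeason(d, 48L)
    expect_equal(range(s), c(1L, 48L))
    expect_true(all(diff(s) %in% c(0L, 1L)))
    expect_equal(as.vector(table(s) >= 7), rep(TRUE, 48))
})
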