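## Independent brute-force oracles used to cross-check the implementation.

## Matrix exponential by direct Taylor-series summation.
expmTaylor <- function(A, terms = 80L) {
    S <- diag(nrow(A))
    term <- diag(nrow(A))
    for (k in seq_len(terms)) {
        term <- term %*% A / k
        S <- S + term
    }
    S
}

## Haversine great-circle distance, written out from the formula.
haversineOracle <- function(lon1, lat1, lon2, lat2, R = 6371) {
    toRad <- pi / 180
    dlat <- (lat2 - lat1) * toRad
    dlon <- (lon2 - lon1) * toRad
    a <- sin(dlat / 2)^2 +
        cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
    2 * R * asin(pmin(1, sqrt(a)))
}

## Adjacency matrix of an igraph digraph in a fixed vertex order.
adjacencyOf <- function(g) {
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

## All-pairs shortest directed path lengths by breadth-first search.
bfsDistancesOracle <- function(adj) {
    n <- nrow(adj)
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        D[s, s] <- 0
        frontier <- s
        d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- integer()
            for (v in frontier) {
                for (w in which(adj[v, ] > 0)) {
                    if (!is.finite(D[s, w])) {
                        D[s, w] <- d
                        nxt <- c(nxt, w)
                    }
                }
            }
            frontier <- unique(nxt)
        }
    }
    D
}

## Shortest-path counts from every source along the BFS DAG.
pathCountsOracle <- function(adj, D) {
    n <- nrow(adj)
    sig <- matrix(0, n, n)
    for (s in seq_len(n)) {
        sig[s, s] <- 1
        for (d in seq_len(n)) {
            for (v in which(D[s, ] == d)) {
                preds <- which(adj[, v] > 0 & D[s, ] == d - 1)
                sig[s, v] <- sum(sig[s, preds])
            }
        }
    }
    sig
}

## Directed betweenness by explicit shortest-path enumeration.
betweennessOracle <- function(g) {
    adj <- adjacencyOf(g)
    n <- nrow(adj)
    D <- bfsDistancesOracle(adj)
    sig <- pathCountsOracle(adj, D)
    b <- numeric(n)
    for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (!is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
            b[v] <- b[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
    stats::setNames(b, igraph::V(g)$name)
}

## Triad census over the 13 connected classes by exhaustive triple
## classification via dyad types (mutual/asymmetric/null) plus the
## orientation rules of the standard MAN taxonomy.
triadCensusOracle <- function(g) {
    adj <- adjacencyOf(g)
    n <- nrow(adj)
    classes <- c("021D", "021U", "021C", "111D", "111U", "030T", "030C",
                 "201", "120D", "120U", "120C", "210", "300")
    counts <- stats::setNames(integer(13), classes)
    if (n < 3) return(counts)
    classifyTriple <- function(v) {
        a <- adj[v, v]
        pairs <- list(c(1, 2), c(1, 3), c(2, 3))
        typ <- vapply(pairs, function(p) {
            e1 <- a[p[1], p[2]] > 0; e2 <- a[p[2], p[1]] > 0
            if (e1 && e2) "M" else if (e1 || e2) "A" else "N"
        }, character(1))
        M <- sum(typ == "M"); A <- sum(typ == "A"); N <- sum(typ == "N")
        if (M == 3) return("300")
        if (M == 2 && A == 1) return("210")
        if (M == 2 && N == 1) return("201")
        if (M == 0 && A == 3) {
            outdeg <- rowSums(a)
            return(if (all(outdeg == 1)) "030C" else "030T")
        }
        if (M == 1 && A == 2) {
            mp <- pairs[[which(typ == "M")]]
            third <- setdiff(1:3, mp)
            into <- sum(a[third, mp])   # arcs third -> dyad
            outof <- sum(a[mp, third])  # arcs dyad -> third
            if (into == 2) return("120D")
            if (outof == 2) return("120U")
            return("120C")
        }
        if (M == 1 && A == 1) {
            mp <- pairs[[which(typ == "M")]]
            ap <- pairs[[which(typ == "A")]]
            third <- setdiff(1:3, mp)
            other <- setdiff(ap, third)
            return(if (a[third, other] > 0) "111D" else "111U")
        }
        if (M == 0 && A == 2) {
            aps <- pairs[typ == "A"]
            arcs <- lapply(aps, function(p) {
                if (a[p[1], p[2]] > 0) c(p[1], p[2]) else c(p[2], p[1])
            })
            if (arcs[[1]][1] == arcs[[2]][1]) return("021D")
            if (arcs[[1]][2] == arcs[[2]][2]) return("021U")
            return("021C")
        }
        NA_character_  # disconnected triple (003, 012, 102)
    }
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        cl <- classifyTriple(c(i, j, k))
        if (!is.na(cl)) counts[cl] <- counts[cl] + 1L
    }
    counts
}

## Monte-Carlo first-passage / return time estimate on the periodic
## chain; returns mean, standard error and the fraction not absorbed.
mcPassageOracle <- function(net, from, to, nWalkers, seed,
                            startSeason, maxYears = 60) {
    set.seed(seed)
    P <- migflow:::transitionMatrices(net)
    m <- nSeasons(net)
    dt <- seasonWidth(net)
    ids <- nodes(net)$id
    iFrom <- match(from, ids); iTo <- match(to, ids)
    state <- rep(iFrom, nWalkers)
    departed <- rep(from != to, nWalkers)  # passage: any arrival counts
    if (from == to) departed <- rep(FALSE, nWalkers)
    hitStep <- rep(NA_integer_, nWalkers)
    k <- startSeason
    for (s in seq_len(maxYears * m)) {
        alive <- which(is.na(hitStep))
        if (!length(alive)) break
        for (j in unique(state[alive])) {
            sel <- alive[state[alive] == j]
            state[sel] <- sample.int(length(ids), length(sel),
                                     replace = TRUE, prob = P[[k]][, j])
        }
        departed[alive[state[alive] != iFrom]] <- TRUE
        hit <- alive[state[alive] == iTo & departed[alive]]
        hitStep[hit] <- s
        k <- (k %% m) + 1
    }
    t <- hitStep[!is.na(hitStep)] * dt
    list(mean = mean(t), se = stats::sd(t) / sqrt(length(t)),
         lost = mean(is.na(hitStep)))
}

## Random digraph fixture on n nodes (igraph, named vertices).
randomDigraph <- function(n, p, seed) {
    set.seed(seed)
    adj <- matrix(stats::runif(n * n) < p, n, n)
    diag(adj) <- FALSE
    igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}
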