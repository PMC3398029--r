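#' Pairwise discordance cost matrix
#'
#' For each pair of markers, the number of hybrids with both calls
#' determined and discordant (one retained, one absent). This is the
#' decomposable ordering cost: on complete data the obligate-break count of
#' an order equals the sum of adjacent-pair discordances.
#'
#' @param panel an [RHPanel-class].
#' @param markers marker ids to include (default all).
#' @return symmetric integer matrix with dimnames = markers.
#' @export
discordanceMatrix <- function(panel, markers = markerNames(panel)) {
    stopifnot(is(panel, "RHPanel"))
    m <- calls(panel)[markers, , drop = FALSE]
    n <- length(markers)
    C <- matrix(0L, n, n, dimnames = list(markers, markers))
    for (i in seq_len(max(n - 1L, 0L)))
        for (j in seq.int(i + 1L, n)) {
            d <- sum(m[i, ] != m[j, ], na.rm = TRUE)
            C[i, j] <- C[j, i] <- d
        }
    C
}

#' Obligate chromosome breaks of an order
#'
#' Per hybrid, take its calls in map order, drop missing calls, and count
#' adjacent retained/absent transitions in the remaining subsequence: the
#' minimum number of breaks the data force under that order. The total over
#' hybrids scores the order (fewer is better) and, summed on the accepted
#' map, measures panel resolution.
#'
#' @param panel an [RHPanel-class].
#' @param order character vector of marker ids (subset of the panel).
#' @return integer, total obligate breaks; 0 for an empty order.
#' @examples
#' p <- RHPanel(matrix(c(1, 0, 1), ncol = 1,
#'              dimnames = list(c("a", "b", "c"), "h1")))
#' countObligateBreaks(p, c("a", "b", "c"))  # 2
#' @export
countObligateBreaks <- function(panel, order) {
    stopifnot(is(panel, "RHPanel"))
    if (length(order) == 0L)
        return(0L)
    if (!all(order %in% markerNames(panel)))
        stop("order contains markers not in the panel")
    m <- calls(panel)[order, , drop = FALSE]
    total <- 0L
    for (h in seq_len(ncol(m))) {
        v <- m[, h]
        v <- v[!is.na(v)]
        if (length(v) > 1L)
            total <- total + sum(abs(diff(v)))
    }
    as.integer(total)
}

.pathCost <- function(C, idx) {
    if (length(idx) < 2L) return(0)
    sum(C[cbind(idx[-length(idx)], idx[-1])])
}

# of an order and its reversal, return the one starting at the
# lexicographically smaller marker id (deterministic orientation)
.orientOrder <- function(ord) {
    if (length(ord) > 1L && ord[length(ord)] < ord[1L]) rev(ord) else ord
}

#' Exact marker ordering by pairwise-discordance minimization
#'
#' Finds the open marker path minimizing the sum of adjacent pairwise
#' discordance costs by Held-Karp subset dynamic programming. Limited to 12
#' markers (the state space doubles per marker); larger sets should use
#' [orderHeuristic()]. Of the optimal order and its reversal, the one whose
#' first marker id sorts lexicographically smaller is returned.
#'
#' @param panel an [RHPanel-class].
#' @param markers marker ids to order (2..12; default all).
#' @return list: `order` (character), `criterion` (minimal total adjacent
#'   discordance), `obligate_breaks` (exact OCB of the returned order).
#' @export
orderExact <- function(panel, markers = markerNames(panel)) {
    stopifnot(is(panel, "RHPanel"))
    n <- length(markers)
    if (n < 2L)
        stop("need >= 2 markers")
    if (n > 12L)
        stop("orderExact is limited to 12 markers; use orderHeuristic()")
    C <- discordanceMatrix(panel, markers)
    full <- bitwShiftL(1L, n) - 1L
    dp <- matrix(Inf, nrow = full, ncol = n)
    par <- matrix(NA_integer_, nrow = full, ncol = n)
    bits <- bitwShiftL(1L, seq_len(n) - 1L)
    for (j in seq_len(n)) dp[bits[j], j] <- 0
    for (S in seq_len(full)) {
        inS <- bitwAnd(S, bits) != 0L
        js <- which(inS)
        if (length(js) == n) next
        ks <- which(!inS)
        for (j in js) {
            d <- dp[S, j]
            if (!is.finite(d)) next
            for (k in ks) {
                S2 <- bitwOr(S, bits[k])
                nd <- d + C[j, k]
                if (nd < dp[S2, k]) {
                    dp[S2, k] <- nd
                    par[S2, k] <- j
                }
            }
        }
    }
    end <- which.min(dp[full, ])
    crit <- dp[full, end]
    idx <- integer(n)
    S <- full
    j <- end
    for (pos in n:1) {
        idx[pos] <- j
        pj <- par[S, j]
        S <- bitwAnd(S, bitwNot(bits[j]))
        j <- pj
    }
    ord <- .orientOrder(markers[idx])
    list(order = ord, criterion = crit,
         obligate_breaks = countObligateBreaks(panel, ord))
}

# 2-opt on an open path: reverse [i, j] while any reversal lowers the cost
.twoOpt <- function(C, idx) {
    n <- length(idx)
    repeat {
        improved <- FALSE
        for (i in seq_len(n - 1L)) {
            for (j in seq.int(i + 1L, n)) {
                if (i == 1L && j == n) next
                delta <- 0
                if (i > 1L)
                    delta <- delta + C[idx[i - 1L], idx[j]] - C[idx[i - 1L], idx[i]]
                if (j < n)
                    delta <- delta + C[idx[i], idx[j + 1L]] - C[idx[j], idx[j + 1L]]
                if (delta < -1e-9) {
                    idx[i:j] <- idx[j:i]
                    improved <- TRUE
                }
            }
        }
        if (!improved) break
    }
    idx
}

#' Heuristic marker ordering (nearest neighbour + 2-opt)
#'
#' Builds a greedy nearest-neighbour path from every start marker, keeps the
#' cheapest (ties broken by a seed-shuffled start sequence, so the result is
#' deterministic given the seed), then improves it by 2-opt segment reversal
#' to a local optimum. The criterion is never worse than the greedy start.
#'
#' @param panel an [RHPanel-class].
#' @param markers marker ids to order (>= 2; default all).
#' @param seed integer tie-break seed.
#' @return list: `order`, `criterion`, `obligate_breaks` as in [orderExact()].
#' @export
orderHeuristic <- function(panel, markers = markerNames(panel), seed = 1L) {
    stopifnot(is(panel, "RHPanel"))
    n <- length(markers)
    if (n < 2L)
        stop("need >= 2 markers")
    C <- discordanceMatrix(panel, markers)
    set.seed(seed)
    starts <- sample.int(n)
    best <- NULL
    best_cost <- Inf
    for (s in starts) {
        idx <- s
        left <- setdiff(seq_len(n), s)
        while (length(left)) {
            cur <- idx[length(idx)]
            nxt <- left[which.min(C[cur, left])]
            idx <- c(idx, nxt)
            left <- setdiff(left, nxt)
        }
        cost <- .pathCost(C, idx)
        if (cost < best_cost) {
            best <- idx
            best_cost <- cost
        }
    }
    idx <- .twoOpt(C, best)
    ord <- .orientOrder(markers[idx])
    list(order = ord, criterion = .pathCost(C, match(ord, markers)),
         obligate_breaks = countObligateBreaks(panel, ord))
}
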