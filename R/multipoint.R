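#' Multipoint log-likelihood of an ordered panel
#'
#' Likelihood of the observed call sequences under a two-state Markov chain
#' along the marker order: the hidden state is whether the hybrid retains the
#' fragment carrying each marker. Initial probability of retention is `r`;
#' across interval \eqn{i} with breakage fraction \eqn{\theta_i} the
#' transitions are \eqn{P(1\to1) = (1-\theta_i) + \theta_i r},
#' \eqn{P(1\to0) = \theta_i(1-r)}, \eqn{P(0\to1) = \theta_i r},
#' \eqn{P(0\to0) = (1-\theta_i) + \theta_i(1-r)}: with no break the state is
#' copied, with a break the new fragment is retained afresh with probability
#' `r`. Determined calls observe the state exactly; missing calls are
#' marginalized by a forward recursion over the hidden states. Returns the
#' sum of per-hybrid log-likelihoods.
#'
#' @param panel an [RHPanel-class].
#' @param order marker ids, length k >= 1.
#' @param theta numeric vector of per-interval breakage fractions in
#'   \eqn{[0,1]}, length k - 1.
#' @param r retention probability in (0, 1).
#' @return total log-likelihood (may be `-Inf` if some hybrid's calls have
#'   probability zero, e.g. a forced transition across a `theta = 0`
#'   interval).
#' @export
multipointLogLik <- function(panel, order, theta, r) {
    stopifnot(is(panel, "RHPanel"))
    k <- length(order)
    if (k < 1L) stop("empty order")
    if (length(theta) != k - 1L)
        stop("theta must have length(order) - 1 entries")
    if (any(theta < 0 | theta > 1))
        stop("theta must lie in [0, 1]")
    if (r <= 0 || r >= 1)
        stop("r must lie in (0, 1)")
    m <- calls(panel)[order, , drop = FALSE]
    nh <- ncol(m)
    # forward recursion, vectorized over hybrids, with per-step scaling
    f1 <- rep(r, nh)
    f0 <- rep(1 - r, nh)
    obs <- m[1L, ]
    f1[!is.na(obs) & obs == 0L] <- 0
    f0[!is.na(obs) & obs == 1L] <- 0
    ll <- rep(0, nh)
    s <- f0 + f1
    dead <- s == 0
    ll[dead] <- -Inf
    s[dead] <- 1
    f0 <- f0 / s; f1 <- f1 / s
    ll <- ll + ifelse(is.infinite(ll), 0, log(s))
    if (k > 1L) for (i in seq_len(k - 1L)) {
        th <- theta[i]
        t11 <- (1 - th) + th * r
        t10 <- th * (1 - r)
        t01 <- th * r
        t00 <- (1 - th) + th * (1 - r)
        g1 <- f1 * t11 + f0 * t01
        g0 <- f1 * t10 + f0 * t00
        obs <- m[i + 1L, ]
        g1[!is.na(obs) & obs == 0L] <- 0
        g0[!is.na(obs) & obs == 1L] <- 0
        s <- g0 + g1
        newdead <- s == 0 & !dead
        ll[newdead] <- -Inf
        dead <- dead | newdead
        s[s == 0] <- 1
        f0 <- g0 / s; f1 <- g1 / s
        ll <- ll + ifelse(dead, 0, log(s))
    }
    ll[dead] <- -Inf
    sum(ll)
}

# theta initial values from two-point estimates of adjacent pairs;
# non-informative pairs fall back to 0.5
.initTheta <- function(panel, order) {
    k <- length(order)
    if (k < 2L) return(numeric(0))
    vapply(seq_len(k - 1L), function(i) {
        est <- estimateTwoPoint(pairCounts(panel, order[i], order[i + 1L]))
        if (!est$informative || is.na(est$theta_hat)) 0.5 else est$theta_hat
    }, 0)
}

.panelRetention <- function(panel) {
    m <- calls(panel)
    r <- sum(m == 1L, na.rm = TRUE) / sum(!is.na(m))
    min(max(r, 1e-4), 1 - 1e-4)
}

#' Fit a centiRay map on a fixed marker order
#'
#' Initializes per-interval breakage fractions from two-point estimates of
#' adjacent pairs (0.5 where a pair is non-informative), then refines
#' \eqn{(\theta_1..\theta_{k-1}, r)} by coordinate-wise 1-D maximization of
#' [multipointLogLik()] until the log-likelihood improves by less than a
#' relative tolerance of 1e-6 (at most 200 sweeps). Positions are cumulative
#' \eqn{-100\ln(1-\theta_i)}; the obligate-break count of the order is
#' recorded alongside.
#'
#' @param panel an [RHPanel-class].
#' @param order marker ids (k >= 2), e.g. from [orderHeuristic()].
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum coordinate sweeps.
#' @return an [RHMap-class].
#' @export
fitMap <- function(panel, order, tol = 1e-6, max_sweeps = 200L) {
    stopifnot(is(panel, "RHPanel"))
    if (is.list(order) && !is.null(order$order))
        order <- order$order
    k <- length(order)
    if (k < 2L) stop("need >= 2 markers")
    theta <- pmin(pmax(.initTheta(panel, order), 0), 1 - 1e-9)
    r <- .panelRetention(panel)
    ll <- multipointLogLik(panel, order, theta, r)
    for (sweep in seq_len(max_sweeps)) {
        for (i in seq_len(k - 1L)) {
            opt <- optimize(function(t) {
                theta[i] <- t
                multipointLogLik(panel, order, theta, r)
            }, c(0, 1 - 1e-9), maximum = TRUE, tol = 1e-8)
            theta[i] <- opt$maximum
        }
        opt <- optimize(function(rr)
            multipointLogLik(panel, order, theta, rr),
            c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
        r <- opt$maximum
        ll_new <- opt$objective
        if (is.finite(ll) && abs(ll_new - ll) <= tol * (abs(ll) + 1)) {
            ll <- ll_new
            break
        }
        ll <- ll_new
    }
    # near-zero interval estimates are genuinely zero-length
    theta[theta < 1e-7] <- 0
    pos <- cumsum(c(0, -100 * log(1 - theta)))
    new("RHMap", markerOrder = as.character(order), theta = theta, r = r,
        positionsCR = pos, logLik = ll,
        obligateBreaks = countObligateBreaks(panel, order),
        unplaced = character(0))
}

#' Build a comprehensive map by marker insertion
#'
#' Extends a fitted framework map with the remaining markers: each is taken
#' in decreasing order of its best two-point LOD to any framework marker and
#' inserted at the position (including both ends) maximizing the multipoint
#' log-likelihood with interval fractions re-initialized from adjacent
#' two-point estimates. Markers whose best LOD falls below `lod_insert` are
#' left on the unplaced list (the relaxed-confidence step used when all
#' markers are known to come from one chromosome). The final order is refit
#' with [fitMap()].
#'
#' @param panel an [RHPanel-class].
#' @param framework an [RHMap-class] (fitted framework).
#' @param remaining marker ids to insert; defaults to all panel markers not
#'   in the framework.
#' @param lod_insert minimum best two-point LOD for placement (default 2).
#' @return an [RHMap-class] with `unplacedMarkers()` filled in.
#' @export
buildComprehensiveMap <- function(panel, framework,
                                  remaining = setdiff(markerNames(panel),
                                                      markerOrder(framework)),
                                  lod_insert = 2) {
    stopifnot(is(panel, "RHPanel"), is(framework, "RHMap"))
    ord <- markerOrder(framework)
    if (!length(remaining)) return(framework)
    best_lod <- vapply(remaining, function(id) {
        max(vapply(ord, function(f) {
            est <- estimateTwoPoint(pairCounts(panel, id, f))
            if (est$informative) est$lod else 0
        }, 0))
    }, 0)
    remaining <- remaining[order(-best_lod)]
    best_lod <- sort(best_lod, decreasing = TRUE)
    unplaced <- character(0)
    r <- framework@r
    for (j in seq_along(remaining)) {
        id <- remaining[j]
        if (best_lod[j] < lod_insert) {
            unplaced <- c(unplaced, id)
            next
        }
        cand_ll <- vapply(0:length(ord), function(pos) {
            cand <- append(ord, id, after = pos)
            multipointLogLik(panel, cand, .initTheta(panel, cand), r)
        }, 0)
        ord <- append(ord, id, after = which.max(cand_ll) - 1L)
    }
    fitted <- fitMap(panel, ord)
    fitted@unplaced <- unplaced
    fitted
}
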