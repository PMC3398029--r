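#' Pairwise retention counts for two markers
#'
#' Tallies, over hybrids where both markers have determined calls
#' (pairwise-complete), the 2x2 retention table: `n11` both retained, `n10`
#' first only, `n01` second only, `n00` neither.
#'
#' @param panel an [RHPanel-class].
#' @param marker_a,marker_b marker ids.
#' @return named integer vector `c(n11, n10, n01, n00)`.
#' @export
pairCounts <- function(panel, marker_a, marker_b) {
    stopifnot(is(panel, "RHPanel"))
    m <- calls(panel)
    for (id in c(marker_a, marker_b))
        if (!id %in% rownames(m))
            stop("unknown marker id: ", id)
    a <- m[marker_a, ]
    b <- m[marker_b, ]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    c(n11 = sum(a == 1L & b == 1L),
      n10 = sum(a == 1L & b == 0L),
      n01 = sum(a == 0L & b == 1L),
      n00 = sum(a == 0L & b == 0L))
}

# log-likelihood of a pair table under the equal-retention breakage model:
# P11 = r(1 - theta(1 - r)), P10 = P01 = r theta (1 - r), P00 = (1 - r)(1 - theta r)
.twoPointLogLik <- function(counts, theta, r) {
    p <- c(r * (1 - theta * (1 - r)),
           r * theta * (1 - r),
           r * theta * (1 - r),
           (1 - r) * (1 - theta * r))
    n <- counts[c("n11", "n10", "n01", "n00")]
    sum(ifelse(n > 0, n * log(p), 0))
}

#' Two-point breakage/retention estimate
#'
#' Maximum-likelihood estimation under the haploid equal-retention RH model:
#' with breakage fraction \eqn{\theta} (probability of at least one break
#' between the markers) and retention probability \eqn{r} shared by the pair,
#' cell probabilities are \eqn{P_{11} = r(1-\theta(1-r))},
#' \eqn{P_{10} = P_{01} = r\theta(1-r)}, \eqn{P_{00} = (1-r)(1-\theta r)}.
#' The closed-form MLEs are \eqn{\hat r = (2n_{11}+n_{10}+n_{01})/(2n)} and
#' \eqn{\hat\theta = (n_{10}+n_{01})/(2n\hat r(1-\hat r))}, clipped to
#' \eqn{[0,1]}. The LOD score is the base-10 log-likelihood ratio against
#' independence (\eqn{\theta = 1}) at the same \eqn{\hat r}, and the
#' centiRay distance is \eqn{-100\ln(1-\hat\theta)} (`Inf` at
#' \eqn{\hat\theta = 1}).
#'
#' A monomorphic pair (\eqn{\hat r} 0 or 1) is flagged non-informative:
#' `theta_hat`/`d_cR` are `NA` and `lod` is 0.
#'
#' @param counts named vector/list with `n11`, `n10`, `n01`, `n00`
#'   (as from [pairCounts()]); total must be >= 1.
#' @return list: `n`, `r_hat`, `theta_hat`, `lod`, `d_cR`, `informative`.
#' @examples
#' estimateTwoPoint(c(n11 = 10, n10 = 2, n01 = 1, n00 = 17))
#' @export
estimateTwoPoint <- function(counts) {
    counts <- unlist(counts)[c("n11", "n10", "n01", "n00")]
    if (any(is.na(counts)) || any(counts < 0))
        stop("counts must be non-negative n11, n10, n01, n00")
    n <- sum(counts)
    if (n < 1)
        stop("no informative hybrids (n = 0)")
    r <- (2 * counts["n11"] + counts["n10"] + counts["n01"]) / (2 * n)
    if (r <= 0 || r >= 1)
        return(list(n = n, r_hat = unname(r), theta_hat = NA_real_,
                    lod = 0, d_cR = NA_real_, informative = FALSE))
    theta <- (counts["n10"] + counts["n01"]) / (2 * n * r * (1 - r))
    theta <- min(max(theta, 0), 1)
    lod <- (.twoPointLogLik(counts, theta, r) -
            .twoPointLogLik(counts, 1, r)) / log(10)
    lod <- max(lod, 0)
    list(n = unname(n), r_hat = unname(r), theta_hat = unname(theta),
         lod = unname(lod),
         d_cR = unname(-100 * log(1 - theta)), informative = TRUE)
}

#' All pairwise two-point estimates of a panel
#'
#' @param panel an [RHPanel-class] with >= 2 markers.
#' @return long-format data.frame over unordered marker pairs (each pair once;
#'   the estimate is symmetric in the two markers) with columns `marker_a`,
#'   `marker_b`, `n`, `n11`, `n10`, `n01`, `n00`, `r_hat`, `theta_hat`,
#'   `lod`, `d_cR`, `informative`. The full marker set is attached as
#'   `attr(, "markers")` for [buildLinkageGroups()].
#' @export
allPairs <- function(panel) {
    stopifnot(is(panel, "RHPanel"))
    ids <- markerNames(panel)
    if (length(ids) < 2L)
        stop("need >= 2 markers")
    pairs <- utils::combn(length(ids), 2L)
    m <- calls(panel)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        a <- m[i1, ]; b <- m[i2, ]
        ok <- !is.na(a) & !is.na(b)
        a <- a[ok]; b <- b[ok]
        cnt <- c(n11 = sum(a == 1L & b == 1L), n10 = sum(a == 1L & b == 0L),
                 n01 = sum(a == 0L & b == 1L), n00 = sum(a == 0L & b == 0L))
        est <- estimateTwoPoint(cnt)
        data.frame(marker_a = ids[i1], marker_b = ids[i2], n = est$n,
                   n11 = cnt[["n11"]], n10 = cnt[["n10"]],
                   n01 = cnt[["n01"]], n00 = cnt[["n00"]],
                   r_hat = est$r_hat, theta_hat = est$theta_hat,
                   lod = est$lod, d_cR = est$d_cR,
                   informative = est$informative,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "markers") <- ids
    out
}

#' Linkage groups from two-point estimates
#'
#' Markers are vertices; an edge joins a pair whose estimate is informative
#' with `lod >= lod_min` and `d_cR <= d_max_cR` (both inclusive). Groups are
#' the connected components (single linkage); singleton components are
#' reported as unlinked.
#'
#' @param estimates data.frame from [allPairs()] (columns `marker_a`,
#'   `marker_b`, `lod`, `d_cR`, `informative`).
#' @param markers full marker set; defaults to `attr(estimates, "markers")`.
#' @param lod_min minimum LOD for linkage (default 4).
#' @param d_max_cR maximum centiRay distance for linkage (default 100).
#' @return list: `groups` (list of character vectors, largest first),
#'   `unlinked` (character), `lod_min`, `d_max_cR`.
#' @export
buildLinkageGroups <- function(estimates, markers = attr(estimates, "markers"),
                               lod_min = 4, d_max_cR = 100) {
    if (is.null(markers))
        markers <- unique(c(estimates$marker_a, estimates$marker_b))
    keep <- estimates$informative &
        !is.na(estimates$lod) & estimates$lod >= lod_min &
        !is.na(estimates$d_cR) & estimates$d_cR <= d_max_cR
    g <- igraph::graph_from_data_frame(
        estimates[keep, c("marker_a", "marker_b"), drop = FALSE],
        directed = FALSE, vertices = data.frame(name = markers))
    comp <- igraph::components(g)
    grp <- split(markers, comp$membership)
    sizes <- lengths(grp)
    groups <- grp[sizes > 1L]
    groups <- groups[order(-lengths(groups))]
    names(groups) <- NULL
    list(groups = lapply(groups, unname),
         unlinked = sort(unlist(grp[sizes == 1L], use.names = FALSE)),
         lod_min = lod_min, d_max_cR = d_max_cR)
}
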