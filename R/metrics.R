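# truncate (not round) to `digits` decimal places, the printing convention
# used for kb/break and kb/cR resolution figures
.truncDecimal <- function(x, digits = 1L) {
    s <- 10^digits
    floor(x * s + 1e-9) / s
}

#' Retention report of an RH panel
#'
#' Per-marker retention frequencies (as a percentage of determined calls,
#' and separately of all calls), per-hybrid donor retention frequency (DF:
#' the number, and percentage, of markers retained in that hybrid), overall
#' averages, and optional aggregates over a marker partition (subgenome,
#' chromosome group, ...). The panel-wide average marker retention frequency
#' is retained calls / total assayed calls x 100.
#'
#' @param panel an [RHPanel-class].
#' @param partition optional marker grouping: either a vector/factor of
#'   length `nMarkers(panel)` or the name of a `markerInfo()` column (e.g.
#'   `"chromosome"`).
#' @return list with
#'   `per_marker` (data.frame: marker, retained, absent, missing,
#'   pct_nonmissing, pct_all — `pct_nonmissing` is `NaN` for a marker whose
#'   calls are all missing),
#'   `per_hybrid` (data.frame: hybrid, df_count, df_pct),
#'   `average_pct_all`, `average_pct_nonmissing`, and `by_partition`
#'   (data.frame or NULL).
#' @examples
#' p <- simulatePanel(simConfig(n_hybrids = 30, markers_per_chromosome = 12))
#' retentionReport(p)$average_pct_all
#' @export
retentionReport <- function(panel, partition = NULL) {
    stopifnot(is(panel, "RHPanel"))
    m <- calls(panel)
    ret <- rowSums(m == 1L, na.rm = TRUE)
    abs_ <- rowSums(m == 0L, na.rm = TRUE)
    mis <- rowSums(is.na(m))
    per_marker <- data.frame(
        marker = rownames(m),
        retained = ret, absent = abs_, missing = mis,
        pct_nonmissing = 100 * ret / (ret + abs_),
        pct_all = 100 * ret / ncol(m),
        row.names = NULL, stringsAsFactors = FALSE)
    dfc <- colSums(m == 1L, na.rm = TRUE)
    per_hybrid <- data.frame(
        hybrid = colnames(m),
        df_count = dfc,
        df_pct = 100 * dfc / nrow(m),
        row.names = NULL, stringsAsFactors = FALSE)
    by_part <- NULL
    if (!is.null(partition)) {
        if (is.character(partition) && length(partition) == 1L)
            partition <- markerInfo(panel)[[partition]]
        if (length(partition) != nrow(m))
            stop("partition must have one entry per marker")
        grp <- factor(partition)
        by_part <- data.frame(
            group = levels(grp),
            n_markers = as.integer(table(grp)),
            retained = as.numeric(tapply(ret, grp, sum)),
            assayed = as.integer(table(grp)) * ncol(m),
            row.names = NULL, stringsAsFactors = FALSE)
        by_part$pct_all <- 100 * by_part$retained / by_part$assayed
        by_part$pct_nonmissing <-
            100 * as.numeric(tapply(ret, grp, sum)) /
            as.numeric(tapply(ret + abs_, grp, sum))
    }
    list(per_marker = per_marker,
         per_hybrid = per_hybrid,
         average_pct_all = 100 * sum(ret) / length(m),
         average_pct_nonmissing = 100 * sum(ret) / sum(ret + abs_),
         by_partition = by_part)
}

#' Friedman two-way homogeneity test
#'
#' Rank-based test that treatment distributions are homogeneous across
#' blocks (here typically: donor retention across subgenomes or chromosome
#' groups, blocked by hybridization combination). Values are mid-ranked
#' within each block and the statistic is
#' \deqn{\chi^2 = \frac{12}{bk(k+1)} \sum_j R_j^2 - 3b(k+1)}
#' with \eqn{b} blocks, \eqn{k} treatments and \eqn{R_j} the rank sum of
#' treatment \eqn{j}; the p-value comes from \eqn{\chi^2_{k-1}}. No tie
#' correction is applied.
#'
#' @param values numeric matrix, blocks x treatments (complete design).
#' @return list: `statistic`, `df`, `p_value`, `rank_sums`.
#' @examples
#' friedmanHomogeneity(matrix(c(1, 2, 3, 2, 4, 6, 3, 6, 9), 3))
#' @export
friedmanHomogeneity <- function(values) {
    values <- as.matrix(values)
    b <- nrow(values)
    k <- ncol(values)
    if (k < 2L || b < 2L)
        stop("need >= 2 treatments and >= 2 blocks")
    if (anyNA(values))
        stop("complete block design required (no NA)")
    R <- colSums(t(apply(values, 1L, rank)))
    stat <- 12 / (b * k * (k + 1)) * sum(R^2) - 3 * b * (k + 1)
    stat <- max(stat, 0)
    list(statistic = stat, df = k - 1L,
         p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
         rank_sums = R)
}

#' Panel resolution arithmetic
#'
#' Average physical distance per detected break and per centiRay:
#' `kb_per_break = size_kb / obligate_breaks` (reported with one-decimal
#' truncation) and `kb_per_cR = size_kb / total_cR` (reported with integer
#' truncation, each matching the conventional printed precision). The exact
#' quotients are returned alongside.
#'
#' @param size_bp chromosome (or region) size in bp.
#' @param breaks obligate break count (> 0), or NULL.
#' @param total_cR total map length in centiRay (> 0), or NULL.
#' @return list: `chromosome_size_bp`, and for each provided denominator
#'   `obligate_breaks`, `kb_per_break`, `kb_per_break_exact`, `total_cR`,
#'   `kb_per_cR`, `kb_per_cR_exact`.
#' @examples
#' resolutionReport(781e6, breaks = 1557)$kb_per_break  # 501.6
#' @export
resolutionReport <- function(size_bp, breaks = NULL, total_cR = NULL) {
    if (size_bp <= 0)
        stop("size_bp must be > 0")
    if (is.null(breaks) && is.null(total_cR))
        stop("give breaks and/or total_cR")
    kb <- size_bp / 1000
    out <- list(chromosome_size_bp = size_bp)
    if (!is.null(breaks)) {
        if (breaks <= 0) stop("breaks must be > 0")
        out$obligate_breaks <- breaks
        out$kb_per_break_exact <- kb / breaks
        out$kb_per_break <- .truncDecimal(kb / breaks, 1L)
    }
    if (!is.null(total_cR)) {
        if (total_cR <= 0) stop("total_cR must be > 0")
        out$total_cR <- total_cR
        out$kb_per_cR_exact <- kb / total_cR
        out$kb_per_cR <- .truncDecimal(kb / total_cR, 0L)
    }
    out
}

#' Hybrid frequency and differentiation table
#'
#' Per-combination percentages from regeneration counts: hybrid frequency =
#' hybrid clones / regenerated clones x 100, and, for any additional count
#' columns (differentiation classes), class percentage = class count /
#' hybrid clones x 100; all rounded to one decimal.
#'
#' @param counts data.frame with columns `combination`, `clones`, `hybrids`
#'   plus optional numeric class-count columns.
#' @return the input with appended `hybrid_pct` and one `<class>_pct` column
#'   per class (NA when a combination has no hybrids).
#' @examples
#' frequencyTable(data.frame(combination = "WB5K", clones = 58, hybrids = 24))
#' @export
frequencyTable <- function(counts) {
    need <- c("combination", "clones", "hybrids")
    if (!all(need %in% names(counts)))
        stop("counts needs columns: ", paste(need, collapse = ", "))
    num <- counts[setdiff(names(counts), "combination")]
    if (any(unlist(num) < 0, na.rm = TRUE))
        stop("counts must be >= 0")
    if (any(counts$hybrids > counts$clones))
        stop("hybrids cannot exceed clones")
    out <- counts
    out$hybrid_pct <- round(100 * counts$hybrids / counts$clones, 1L)
    classes <- setdiff(names(counts)[vapply(counts, is.numeric, TRUE)],
                       c("clones", "hybrids"))
    for (cl in classes)
        out[[paste0(cl, "_pct")]] <-
            ifelse(counts$hybrids > 0,
                   round(100 * counts[[cl]] / counts$hybrids, 1L), NA_real_)
    out
}

.lcsLength <- function(a, b) {
    n <- length(a); m <- length(b)
    if (n == 0L || m == 0L) return(0L)
    prev <- integer(m + 1L)
    for (i in seq_len(n)) {
        cur <- integer(m + 1L)
        for (j in seq_len(m)) {
            cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                           else max(cur[j], prev[j + 1L])
        }
        prev <- cur
    }
    prev[m + 1L]
}

#' Order concordance against a reference order
#'
#' Restricts both orders to their shared markers and measures agreement as
#' the longest common subsequence (LCS), taking the better of the reference
#' as given and reversed (map orientation is arbitrary). The consistent
#' fraction is LCS / number of shared markers; it is invariant to markers
#' absent from either order and to reversing either order.
#'
#' @param test marker order to evaluate (character vector, or a list with an
#'   `order` element, or an [RHMap-class]).
#' @param reference reference marker order (character vector, e.g. a
#'   deletion-bin or genome-zipper order from [readReferenceOrder()]).
#' @return list: `shared` (character, in test order), `n_shared`, `lcs`,
#'   `consistent_fraction`, `orientation` (`"as-is"` or `"reversed"`),
#'   `comparable` (FALSE, with NA fraction, when < 2 shared markers).
#' @examples
#' orderConcordance(c("A", "C", "B", "D"), c("A", "B", "C", "D"))
#' @export
orderConcordance <- function(test, reference) {
    if (is(test, "RHMap")) test <- markerOrder(test)
    if (is.list(test) && !is.null(test$order)) test <- test$order
    test <- as.character(test)
    reference <- as.character(reference)
    shared_t <- test[test %in% reference]
    shared_r <- reference[reference %in% test]
    if (length(shared_t) < 2L)
        return(list(shared = shared_t, n_shared = length(shared_t),
                    lcs = NA_integer_, consistent_fraction = NA_real_,
                    orientation = NA_character_, comparable = FALSE))
    fwd <- .lcsLength(shared_t, shared_r)
    bwd <- .lcsLength(shared_t, rev(shared_r))
    lcs <- max(fwd, bwd)
    list(shared = shared_t, n_shared = length(shared_t), lcs = lcs,
         consistent_fraction = lcs / length(shared_t),
         orientation = if (fwd >= bwd) "as-is" else "reversed",
         comparable = TRUE)
}
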