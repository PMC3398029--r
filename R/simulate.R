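#' Simulate one radiation hybrid
#'
#' Draws a single hybrid under the fragmentation-retention model of a
#' [SimConfig-class]: per chromosome, break positions form a Poisson process
#' with rate `break_rate` per Mb on `[0, length)`; the resulting fragments are
#' retained independently with probability `retention_prob`; a marker is
#' retained iff its fragment is, so markers sharing a fragment are perfectly
#' correlated. With `break_rate = 0` the whole chromosome is one fragment.
#'
#' Uses the current RNG stream; [simulatePanel()] seeds it from the config.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `retained` (logical per marker, in config marker order)
#'   and `fragments` (data.frame: chromosome, start_bp, end_bp, retained).
#' @export
simulateHybrid <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    ret <- logical(0)
    frags <- list()
    for (i in seq_len(nrow(cfg@chromosomes))) {
        lab <- cfg@chromosomes$label[i]
        L <- cfg@chromosomes$length_bp[i]
        nb <- rpois(1L, cfg@break_rate * L / 1e6)
        cuts <- sort(runif(nb, 0, L))
        bounds <- c(0, cuts, L)
        nf <- length(bounds) - 1L
        keep <- runif(nf) < cfg@retention_prob
        pos <- cfg@positions[[lab]]
        frag_of <- findInterval(pos, bounds, rightmost.closed = TRUE)
        ret <- c(ret, keep[frag_of])
        frags[[lab]] <- data.frame(chromosome = lab,
                                   start_bp = bounds[-length(bounds)],
                                   end_bp = bounds[-1],
                                   retained = keep)
    }
    list(retained = ret, fragments = do.call(rbind, c(frags, make.row.names = FALSE)))
}

.markerIds <- function(cfg) {
    unlist(lapply(cfg@chromosomes$label, function(lab)
        sprintf("%s_M%02d", lab, seq_along(cfg@positions[[lab]]))),
        use.names = FALSE)
}

#' Simulate a radiation hybrid panel
#'
#' Draws `n_hybrids` independent hybrids with [simulateHybrid()], then flips
#' each true call to missing independently with probability `missing_rate`.
#' All randomness flows from `cfg@seed` through one RNG stream (hybrids in
#' order, then the missing mask), so the same config yields the same panel
#' call-for-call.
#'
#' @param cfg a [SimConfig-class].
#' @param keep_truth logical; store per-hybrid fragment intervals and the
#'   pre-missing truth matrix in `metadata(panel)$truth`.
#' @return an [RHPanel-class]; `metadata` carries the config and, optionally,
#'   the simulation truth.
#' @examples
#' p <- simulatePanel(simConfig(n_hybrids = 20, markers_per_chromosome = 10))
#' callCounts(p)
#' @export
simulatePanel <- function(cfg, keep_truth = FALSE) {
    stopifnot(is(cfg, "SimConfig"))
    if (cfg@n_hybrids <= 0L)
        stop("n_hybrids must be > 0")
    set.seed(cfg@seed)
    .simulatePanelNoSeed(cfg, keep_truth)
}

# panel draw using the current RNG state (shared by dose series)
.simulatePanelNoSeed <- function(cfg, keep_truth = FALSE) {
    n <- cfg@n_hybrids
    ids <- .markerIds(cfg)
    truth <- vector("list", n)
    M <- matrix(NA_integer_, nrow = length(ids), ncol = n)
    for (h in seq_len(n)) {
        hy <- simulateHybrid(cfg)
        M[, h] <- as.integer(hy$retained)
        if (keep_truth) truth[[h]] <- hy$fragments
    }
    true_calls <- M
    if (cfg@missing_rate > 0) {
        miss <- matrix(runif(length(M)) < cfg@missing_rate, nrow = nrow(M))
        M[miss] <- NA_integer_
    }
    dimnames(M) <- list(ids, sprintf("RH%03d", seq_len(n)))
    chrom <- rep(cfg@chromosomes$label, lengths(cfg@positions[cfg@chromosomes$label]))
    pos <- unlist(cfg@positions[cfg@chromosomes$label], use.names = FALSE)
    meta <- list(config = cfg)
    if (keep_truth)
        meta$truth <- list(fragments = truth,
                           calls = `dimnames<-`(true_calls, dimnames(M)))
    RHPanel(M, chromosome = chrom, position_bp = pos, meta = meta)
}

#' Simulate a dose series of RH panels
#'
#' One panel per dose, with `(break_rate, retention_prob)` taken from the
#' config's `dose_model`. Because retention is non-increasing in dose, the
#' mean per-hybrid donor retention frequency (DF) is non-increasing in dose
#' in expectation, mirroring the dose-dependent decline of donor retention.
#'
#' @param cfg a [SimConfig-class] with a non-empty `dose_model`.
#' @param doses character vector of dose labels to simulate, in order; all
#'   must exist in `cfg@dose_model`. Empty input gives an empty list.
#' @param keep_truth passed to [simulatePanel()].
#' @return named list of [RHPanel-class], one per dose.
#' @export
simulateDoseSeries <- function(cfg, doses = names(cfg@dose_model),
                               keep_truth = FALSE) {
    stopifnot(is(cfg, "SimConfig"))
    if (!length(cfg@dose_model))
        stop("cfg has no dose_model")
    if (!length(doses))
        return(setNames(list(), character(0)))
    if (!all(doses %in% names(cfg@dose_model)))
        stop("unknown dose label(s): ",
             paste(setdiff(doses, names(cfg@dose_model)), collapse = ", "))
    set.seed(cfg@seed)
    out <- vector("list", length(doses))
    for (i in seq_along(doses)) {
        d <- cfg@dose_model[[doses[i]]]
        cfg_d <- cfg
        cfg_d@break_rate <- as.numeric(d$break_rate)
        cfg_d@retention_prob <- as.numeric(d$retention_prob)
        out[[i]] <- .simulatePanelNoSeed(cfg_d, keep_truth)
    }
    setNames(out, doses)
}
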