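#' SimConfig: generative parameters for a simulated RH panel
#'
#' Describes the generative model of an in vitro radiation hybrid panel:
#' donor chromosomes are fragmented by a homogeneous Poisson process
#' (`break_rate` expected breaks per Mb, a dose surrogate), each fragment is
#' rescued into the recipient background independently with probability
#' `retention_prob`, a marker is retained iff its fragment is, and each call
#' is independently turned into a missing (undetermined) score with
#' probability `missing_rate`.
#'
#' @slot chromosomes data.frame with columns `label`, `length_bp`.
#' @slot positions named list (one entry per chromosome label) of sorted
#'   marker positions in bp, each within `[0, length_bp)`.
#' @slot break_rate expected breaks per Mb (lambda >= 0).
#' @slot retention_prob per-fragment retention probability in \[0, 1\].
#' @slot missing_rate per-call missing probability in \[0, 1).
#' @slot n_hybrids panel size (> 0).
#' @slot dose_model list mapping dose label to `list(break_rate, retention_prob)`,
#'   with retention_prob non-increasing in dose order; may be empty.
#' @slot seed integer seed; all draws flow from one stream so panels are
#'   reproducible call-for-call.
#'
#' @seealso [simConfig()], [simulatePanel()]
#' @export
setClass("SimConfig", representation(
    chromosomes = "data.frame",
    positions = "list",
    break_rate = "numeric",
    retention_prob = "numeric",
    missing_rate = "numeric",
    n_hybrids = "integer",
    dose_model = "list",
    seed = "integer"))

.validSimConfig <- function(object) {
    msg <- NULL
    ch <- object@chromosomes
    if (!all(c("label", "length_bp") %in% names(ch)))
        msg <- c(msg, "chromosomes needs columns label, length_bp")
    else {
        if (any(ch$length_bp <= 0))
            msg <- c(msg, "chromosome lengths must be > 0")
        if (anyDuplicated(ch$label))
            msg <- c(msg, "chromosome labels must be unique")
        if (!setequal(names(object@positions), ch$label))
            msg <- c(msg, "positions must name every chromosome")
        else for (lab in ch$label) {
            p <- object@positions[[lab]]
            L <- ch$length_bp[ch$label == lab]
            if (any(p < 0 | p >= L))
                msg <- c(msg, sprintf("marker positions on %s outside [0, length)", lab))
        }
    }
    if (object@break_rate < 0) msg <- c(msg, "break_rate must be >= 0")
    if (object@retention_prob < 0 || object@retention_prob > 1)
        msg <- c(msg, "retention_prob must be in [0, 1]")
    if (object@missing_rate < 0 || object@missing_rate >= 1)
        msg <- c(msg, "missing_rate must be in [0, 1)")
    if (object@n_hybrids <= 0L)
        msg <- c(msg, "n_hybrids must be > 0")
    if (length(object@dose_model)) {
        rho <- vapply(object@dose_model, function(d) d$retention_prob, 0)
        if (is.unsorted(rev(rho)))
            msg <- c(msg, "dose_model retention_prob must be non-increasing in dose")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("SimConfig", .validSimConfig)

#' Build a simulation configuration
#'
#' Defaults emulate a published-scale in vitro wheat RH panel: one 781 Mb
#' chromosome ("5A") carrying 68 uniformly spaced markers, 184 hybrids,
#' per-fragment retention 0.34, 1\% undetermined calls, and a break rate of
#' 0.027 breaks/Mb (about 0.3 expected breaks per ~11.5 Mb marker interval,
#' i.e. roughly 30 cR per interval).
#'
#' @param chromosome_lengths named numeric vector of chromosome lengths (bp).
#' @param markers_per_chromosome integer count(s) for uniform marker
#'   placement (markers at `(i - 0.5) / n * length`), recycled across
#'   chromosomes; ignored when `marker_positions` is given.
#' @param marker_positions optional named list of explicit positions (bp).
#' @param break_rate expected breaks per Mb.
#' @param retention_prob per-fragment retention probability.
#' @param missing_rate per-call missing probability.
#' @param n_hybrids number of hybrids to simulate.
#' @param dose_model optional named list: dose label ->
#'   `list(break_rate =, retention_prob =)`, retention non-increasing in dose.
#' @param seed integer seed.
#'
#' @return a [SimConfig-class].
#' @examples
#' cfg <- simConfig(n_hybrids = 92, retention_prob = 0.15, seed = 7)
#' panel <- simulatePanel(cfg)
#' panel
#' @export
simConfig <- function(chromosome_lengths = c(`5A` = 781e6),
                      markers_per_chromosome = 68L,
                      marker_positions = NULL,
                      break_rate = 0.027,
                      retention_prob = 0.34,
                      missing_rate = 0.01,
                      n_hybrids = 184L,
                      dose_model = NULL,
                      seed = 1L) {
    labs <- names(chromosome_lengths)
    if (is.null(labs))
        labs <- paste0("chr", seq_along(chromosome_lengths))
    ch <- data.frame(label = labs, length_bp = as.numeric(chromosome_lengths),
                     stringsAsFactors = FALSE)
    if (is.null(marker_positions)) {
        nper <- rep_len(as.integer(markers_per_chromosome), nrow(ch))
        marker_positions <- lapply(seq_len(nrow(ch)), function(i)
            (seq_len(nper[i]) - 0.5) / nper[i] * ch$length_bp[i])
        names(marker_positions) <- ch$label
    } else {
        marker_positions <- lapply(marker_positions, function(p) sort(as.numeric(p)))
    }
    new("SimConfig",
        chromosomes = ch,
        positions = marker_positions,
        break_rate = as.numeric(break_rate),
        retention_prob = as.numeric(retention_prob),
        missing_rate = as.numeric(missing_rate),
        n_hybrids = as.integer(n_hybrids),
        dose_model = if (is.null(dose_model)) list() else dose_model,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    nm <- sum(lengths(object@positions))
    cat(sprintf(paste0("SimConfig: %d chromosome(s), %d markers, %d hybrids\n",
                       "  break_rate %.4g /Mb, retention %.3g, missing %.3g, seed %d\n"),
                nrow(object@chromosomes), nm, object@n_hybrids,
                object@break_rate, object@retention_prob,
                object@missing_rate, object@seed))
})
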