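# build an RHPanel straight from a call matrix (rows = markers)
makePanel <- function(calls, ...) {
    RHPanel(calls, ...)
}

# random panel with iid calls; p = P(retained), pmiss = P(missing)
randomPanel <- function(n_markers, n_hybrids, p = 0.3, pmiss = 0.1) {
    m <- matrix(rbinom(n_markers * n_hybrids, 1L, p), n_markers, n_hybrids)
    if (pmiss > 0)
        m[matrix(runif(length(m)) < pmiss, n_markers, n_hybrids)] <- NA_integer_
    dimnames(m) <- list(sprintf("m%02d", seq_len(n_markers)),
                        sprintf("h%02d", seq_len(n_hybrids)))
    RHPanel(m)
}

# fraction of true adjacent marker pairs present (either orientation) in ord
adjacencyRecovery <- function(truth, ord) {
    stopifnot(setequal(truth, ord))
    key <- function(v) paste(pmin(v[-length(v)], v[-1]),
                             pmax(v[-length(v)], v[-1]))
    mean(key(truth) %in% key(ord))
}
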