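# Independent oracles used to validate the closed-form / DP implementations.
# These deliberately use brute force (grids, exhaustive enumeration) and never
# call the code paths they check.

# joint grid maximization of the two-point likelihood over (theta, r)
oracleGridTwoPoint <- function(counts, step = 1e-3) {
    counts <- unlist(counts)[c("n11", "n10", "n01", "n00")]
    th <- seq(0, 1, by = step)
    r <- seq(step, 1 - step, by = step)
    TH <- matrix(th, nrow = length(th), ncol = length(r))
    R <- matrix(r, nrow = length(th), ncol = length(r), byrow = TRUE)
    term <- function(n, p) if (n > 0) n * log(p) else 0
    ll <- term(counts[["n11"]], R * (1 - TH * (1 - R))) +
        term(counts[["n10"]], R * TH * (1 - R)) +
        term(counts[["n01"]], R * TH * (1 - R)) +
        term(counts[["n00"]], (1 - R) * (1 - TH * R))
    best <- arrayInd(which.max(ll), dim(ll))
    list(theta = th[best[1]], r = r[best[2]], loglik = max(ll))
}

# per-hybrid minimal break count by enumerating all completions of the
# missing calls and counting transitions, summed over hybrids
oracleObligateBreaks <- function(panel, ord) {
    m <- calls(panel)[ord, , drop = FALSE]
    total <- 0L
    for (h in seq_len(ncol(m))) {
        v <- m[, h]
        nas <- which(is.na(v))
        if (length(nas) == 0L) {
            total <- total + sum(abs(diff(v)))
            next
        }
        best <- Inf
        for (mask in 0:(2^length(nas) - 1L)) {
            w <- v
            w[nas] <- as.integer(bitwAnd(bitwShiftR(mask, seq_along(nas) - 1L), 1L))
            best <- min(best, sum(abs(diff(w))))
        }
        total <- total + best
    }
    as.integer(total)
}

# multipoint likelihood by exhaustive summation over all 2^k hidden
# retention vectors
oracleMultipointLogLik <- function(panel, ord, theta, r) {
    m <- calls(panel)[ord, , drop = FALSE]
    k <- nrow(m)
    states <- as.matrix(expand.grid(rep(list(0:1), k)))
    trans <- function(a, b, th) {
        if (a == 1 && b == 1) (1 - th) + th * r
        else if (a == 1 && b == 0) th * (1 - r)
        else if (a == 0 && b == 1) th * r
        else (1 - th) + th * (1 - r)
    }
    total <- 0
    for (h in seq_len(ncol(m))) {
        obs <- m[, h]
        ph <- 0
        for (s in seq_len(nrow(states))) {
            z <- states[s, ]
            if (any(!is.na(obs) & obs != z)) next
            p <- if (z[1] == 1) r else 1 - r
            if (k > 1) for (i in seq_len(k - 1L))
                p <- p * trans(z[i], z[i + 1L], theta[i])
            ph <- ph + p
        }
        total <- total + log(ph)
    }
    total
}

# all permutations of v (n! vectors; keep n small)
allPermutations <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in allPermutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

# minimal adjacent-discordance criterion over every marker order
oracleBestOrderCost <- function(panel, markers) {
    C <- discordanceMatrix(panel, markers)
    best <- Inf
    for (perm in allPermutations(markers)) {
        idx <- match(perm, markers)
        cost <- sum(C[cbind(idx[-length(idx)], idx[-1])])
        best <- min(best, cost)
    }
    best
}

# independent re-parser of the CarthaGene radiated-hybrid dialect
parseCarthagene <- function(path) {
    lines <- readLines(path)
    stopifnot(lines[1] == "data type radiated hybrid")
    dims <- as.integer(strsplit(lines[2], " ")[[1]][1:2])
    rows <- strsplit(sub("^\\*", "", lines[-(1:2)]), " ")
    ids <- vapply(rows, `[`, "", 1L)
    geno <- vapply(rows, `[`, "", 2L)
    m <- t(vapply(strsplit(geno, ""), function(s) {
        v <- rep(NA_integer_, length(s))
        v[s != "-"] <- as.integer(s[s != "-"])
        v
    }, integer(dims[1])))
    rownames(m) <- ids
    stopifnot(nrow(m) == dims[2])
    m
}
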