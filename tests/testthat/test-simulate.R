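test_that("degenerate break rates give whole-chromosome fragments", {
    cfg1 <- simConfig(chromosome_lengths = c(c1 = 50e6),
                      markers_per_chromosome = 8, break_rate = 0,
                      retention_prob = 1, missing_rate = 0, n_hybrids = 5)
    expect_true(all(calls(simulatePanel(cfg1)) == 1L))
    cfg0 <- simConfig(chromosome_lengths = c(c1 = 50e6),
                      markers_per_chromosome = 8, break_rate = 0,
                      retention_prob = 0, missing_rate = 0, n_hybrids = 5)
    expect_true(all(calls(simulatePanel(cfg0)) == 0L))
})

test_that("the same seed reproduces a panel call-for-call", {
    cfg <- simConfig(n_hybrids = 25, markers_per_chromosome = 15, seed = 99)
    expect_identical(calls(simulatePanel(cfg)), calls(simulatePanel(cfg)))
    cfg2 <- cfg
    cfg2@seed <- 100L
    expect_false(identical(calls(simulatePanel(cfg)), calls(simulatePanel(cfg2))))
})

test_that("simConfig validates its generative parameters", {
    expect_error(simConfig(break_rate = -1), "break_rate")
    expect_error(simConfig(retention_prob = 1.2), "retention_prob")
    expect_error(simConfig(missing_rate = 1), "missing_rate")
    expect_error(simConfig(n_hybrids = 0), "n_hybrids")
    expect_error(simConfig(marker_positions = list(`5A` = c(-5, 10))),
                 "outside")
    expect_error(
        simConfig(dose_model = list(
            low = list(break_rate = 0.01, retention_prob = 0.2),
            high = list(break_rate = 0.05, retention_prob = 0.4))),
        "non-increasing")
})

test_that("markers on one fragment are perfectly correlated within a hybrid", {
    # break_rate 0: every marker shares the chromosome fragment
    cfg <- simConfig(chromosome_lengths = c(c1 = 100e6),
                     markers_per_chromosome = 10, break_rate = 0,
                     retention_prob = 0.5, missing_rate = 0,
                     n_hybrids = 60, seed = 5)
    m <- calls(simulatePanel(cfg))
    expect_true(all(apply(m, 2, function(v) length(unique(v)) == 1L)))
})

test_that("dense breakage decorrelates markers: discordance -> 2*rho*(1-rho)", {
    rho <- 0.3
    cfg <- simConfig(chromosome_lengths = c(c1 = 10e6),
                     markers_per_chromosome = 2, break_rate = 20,
                     retention_prob = rho, missing_rate = 0,
                     n_hybrids = 3000, seed = 11)
    m <- calls(simulatePanel(cfg))
    disc <- mean(m[1, ] != m[2, ])
    expected <- 2 * rho * (1 - rho)
    se <- sqrt(expected * (1 - expected) / 3000)
    expect_lt(abs(disc - expected), 4 * se)
})

test_that("adjacent-marker discordance matches 2*rho*(1-rho)*(1-exp(-lambda*d))", {
    rho <- 0.34
    lam <- 0.027
    cfg <- simConfig(chromosome_lengths = c(c1 = 115e6),
                     markers_per_chromosome = 10, break_rate = lam,
                     retention_prob = rho, missing_rate = 0,
                     n_hybrids = 2000, seed = 21)
    p <- simulatePanel(cfg)
    m <- calls(p)
    d <- diff(markerInfo(p)$position_bp)[1] / 1e6
    expected <- 2 * rho * (1 - rho) * (1 - exp(-lam * d))
    disc <- vapply(seq_len(9), function(i) mean(m[i, ] != m[i + 1, ]), 0)
    se <- sqrt(expected * (1 - expected) / (2000 * 9))
    expect_lt(abs(mean(disc) - expected), 4 * se)
})

test_that("marginal retention equals rho regardless of break rate", {
    rho <- 0.34
    for (lam in c(0.002, 0.2)) {
        cfg <- simConfig(chromosome_lengths = c(c1 = 200e6),
                         markers_per_chromosome = 20, break_rate = lam,
                         retention_prob = rho, missing_rate = 0,
                         n_hybrids = 400, seed = round(1000 * lam))
        m <- calls(simulatePanel(cfg))
        # calls within a hybrid are correlated through shared fragments,
        # so use the empirical SE of per-hybrid retention means
        per_hyb <- colMeans(m)
        se <- sd(per_hyb) / sqrt(ncol(m))
        expect_lt(abs(mean(per_hyb) - rho), 4 * se)
    }
})

test_that("missing calls appear at the configured per-call rate", {
    cfg <- simConfig(n_hybrids = 200, markers_per_chromosome = 40,
                     missing_rate = 0.05, seed = 31)
    m <- calls(simulatePanel(cfg))
    frac <- mean(is.na(m))
    se <- sqrt(0.05 * 0.95 / length(m))
    expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("low retention produces hybrids that lost every marker", {
    # expected fragments per hybrid ~ 1 + lambda*L/1e6; with small rho the
    # all-absent probability is appreciable, mirroring empty hybrids
    cfg <- simConfig(chromosome_lengths = c(c1 = 100e6),
                     markers_per_chromosome = 20, break_rate = 0.02,
                     retention_prob = 0.1, missing_rate = 0,
                     n_hybrids = 200, seed = 41)
    m <- calls(simulatePanel(cfg))
    n_empty <- sum(colSums(m) == 0L)
    # rough lower bound: P(all fragments lost) >= (1-rho)^(1+E[breaks]) ~ 0.73
    expect_gt(n_empty, 0.5 * 0.73 * 200)
})

test_that("truth metadata matches emitted calls before the missing mask", {
    cfg <- simConfig(n_hybrids = 12, markers_per_chromosome = 10,
                     missing_rate = 0.2, seed = 55)
    p <- simulatePanel(cfg, keep_truth = TRUE)
    truth <- S4Vectors::metadata(p)$truth$calls
    obs <- calls(p)
    ok <- !is.na(obs)
    expect_identical(obs[ok], truth[ok])
    frg <- S4Vectors::metadata(p)$truth$fragments
    expect_length(frg, 12L)
    expect_true(all(vapply(frg, function(f) all(f$end_bp > f$start_bp), TRUE)))
})

test_that("dose series: retention declines with dose; edge cases behave", {
    dm <- list(low = list(break_rate = 0.01, retention_prob = 0.4),
               high = list(break_rate = 0.05, retention_prob = 0.15))
    cfg <- simConfig(chromosome_lengths = c(c1 = 300e6),
                     markers_per_chromosome = 25, missing_rate = 0,
                     n_hybrids = 150, dose_model = dm, seed = 61)
    panels <- simulateDoseSeries(cfg)
    expect_named(panels, c("low", "high"))
    df <- vapply(panels, function(p) mean(colMeans(calls(p))), 0)
    expect_gt(df[["low"]], df[["high"]])
    expect_length(simulateDoseSeries(cfg, doses = character(0)), 0L)
    single <- simulateDoseSeries(cfg, doses = "low")[[1]]
    expect_s4_class(single, "RHPanel")
    cfg_nodm <- simConfig()
    expect_error(simulateDoseSeries(cfg_nodm), "dose_model")
})
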