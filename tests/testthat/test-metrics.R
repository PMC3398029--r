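test_that("panel-wide average retention reproduces the count arithmetic", {
    # 68 x 184 panel with 4252 retained, 8144 absent, 116 missing calls
    n_ret <- 4252L; n_abs <- 8144L; n_mis <- 116L
    v <- rep(c(1L, 0L, NA_integer_), c(n_ret, n_abs, n_mis))
    m <- matrix(v, nrow = 68, ncol = 184)
    rep_ <- retentionReport(makePanel(m))
    expect_equal(round(rep_$average_pct_all, 2), 33.98)
    expect_equal(rep_$average_pct_all, 100 * 4252 / 12512)
    # the non-missing denominator variant is computed alongside
    expect_equal(rep_$average_pct_nonmissing, 100 * 4252 / 12396)
    # conservation: per-marker tallies sum to the panel totals
    pm <- rep_$per_marker
    expect_equal(sum(pm$retained), n_ret)
    expect_equal(sum(pm$absent), n_abs)
    expect_equal(sum(pm$missing), n_mis)
})

test_that("retention report handles degenerate and simulated panels", {
    p0 <- makePanel(matrix(0L, 3, 4))
    r0 <- retentionReport(p0)
    expect_true(all(r0$per_marker$pct_all == 0))
    expect_equal(r0$average_pct_all, 0)
    # all-missing marker flagged undefined (NaN) in the non-missing variant
    m <- rbind(a = c(NA_integer_, NA_integer_), b = c(1L, 0L))
    rm_ <- retentionReport(makePanel(m))
    expect_true(is.nan(rm_$per_marker$pct_nonmissing[1]))
    expect_equal(rm_$per_marker$pct_all[1], 0)
    # simulated panel at rho = 0.2 recovers its retention
    cfg <- simConfig(chromosome_lengths = c(c1 = 300e6),
                     markers_per_chromosome = 30, break_rate = 0.03,
                     retention_prob = 0.2, missing_rate = 0,
                     n_hybrids = 250, seed = 19)
    p <- simulatePanel(cfg)
    rr <- retentionReport(p)
    se <- sd(rr$per_hybrid$df_pct / 100) / sqrt(250)
    expect_lt(abs(mean(rr$per_hybrid$df_pct) / 100 - 0.2), 4 * se)
})

test_that("partition aggregates conserve the panel totals", {
    cfg <- simConfig(chromosome_lengths = c(A = 50e6, B = 50e6, D = 50e6),
                     markers_per_chromosome = 6, break_rate = 0.05,
                     retention_prob = 0.3, missing_rate = 0.05,
                     n_hybrids = 40, seed = 23)
    p <- simulatePanel(cfg)
    rr <- retentionReport(p, partition = "chromosome")
    bp <- rr$by_partition
    expect_setequal(bp$group, c("A", "B", "D"))
    expect_equal(sum(bp$retained), sum(rr$per_marker$retained))
    expect_equal(sum(bp$assayed), nMarkers(p) * nHybrids(p))
    # the all-calls average is a weighted mean of the partition averages
    expect_equal(sum(bp$pct_all * bp$assayed) / sum(bp$assayed),
                 rr$average_pct_all)
})

test_that("Friedman statistic matches the rank formula and edge cases", {
    # identical treatments: statistic 0, p 1
    same <- matrix(5, nrow = 4, ncol = 3)
    f0 <- friedmanHomogeneity(same)
    expect_equal(f0$statistic, 0)
    expect_equal(f0$p_value, 1)
    # fully concordant ranks across 3 blocks: R = (3, 6, 9) gives 6
    x <- matrix(c(1, 2, 3, 2, 4, 6, 3, 6, 9), nrow = 3, byrow = TRUE)
    f <- friedmanHomogeneity(x)
    expect_equal(unname(f$rank_sums), c(3, 6, 9))
    expect_equal(f$statistic, 6)
    expect_equal(f$df, 2)
    # permuting treatment labels permutes rank sums, statistic unchanged
    fp <- friedmanHomogeneity(x[, c(3, 1, 2)])
    expect_equal(fp$statistic, f$statistic)
    expect_setequal(unname(fp$rank_sums), unname(f$rank_sums))
    expect_error(friedmanHomogeneity(x[, 1, drop = FALSE]), ">= 2")
    expect_error(friedmanHomogeneity(x[1, , drop = FALSE]), ">= 2")
})

test_that("Friedman agrees with stats::friedman.test on tie-free data", {
    set.seed(29)
    for (i in 1:5) {
        x <- matrix(sample(100, 24), nrow = 6)  # distinct values: no ties
        ours <- friedmanHomogeneity(x)
        ref <- stats::friedman.test(x)
        expect_equal(ours$statistic, unname(ref$statistic))
        expect_equal(ours$p_value, unname(ref$p.value))
    }
})

test_that("resolution arithmetic reproduces the printed conventions", {
    r1 <- resolutionReport(781e6, breaks = 1557)
    expect_equal(r1$kb_per_break, 501.6)
    r2 <- resolutionReport(781e6, breaks = 2034)
    expect_equal(r2$kb_per_break, 383.9)  # truncation, not rounding (383.97)
    r3 <- resolutionReport(781e6, total_cR = 2103)
    expect_equal(r3$kb_per_cR, 371)
    expect_equal(resolutionReport(1e6, breaks = 1)$kb_per_break, 1000.0)
    expect_error(resolutionReport(781e6, breaks = 0), "> 0")
    expect_error(resolutionReport(781e6), "breaks and/or")
    expect_error(resolutionReport(0, breaks = 10), "size_bp")
})

test_that("frequency table computes hybrid and differentiation percentages", {
    tab <- read.delim(system.file("extdata", "hybrid_combinations.tsv",
                                  package = "rhmap"))
    ft <- frequencyTable(tab)
    expect_equal(ft$hybrid_pct[ft$combination == "WB5K"], 41.4)
    expect_equal(ft$hybrid_pct[ft$combination == "WB"], 14.0)
    expect_equal(ft$shoots_pct[ft$combination == "WB"], 25.0)
    asym <- ft$hybrid_pct[ft$combination != "WB"]
    expect_equal(range(asym), c(13.7, 41.4))
    # degenerate and invalid inputs
    z <- frequencyTable(data.frame(combination = "X", clones = 10, hybrids = 0))
    expect_equal(z$hybrid_pct, 0)
    expect_error(frequencyTable(data.frame(combination = "X", clones = 5,
                                           hybrids = 6)), "exceed")
})

test_that("order concordance uses orientation-maximized LCS", {
    expect_equal(orderConcordance(LETTERS[1:10], LETTERS[1:10])$consistent_fraction, 1)
    res <- orderConcordance(c("A", "C", "B", "D"), c("A", "B", "C", "D"))
    expect_equal(res$lcs, 3L)
    expect_equal(res$consistent_fraction, 0.75)
    # reversing either order changes nothing
    res_rt <- orderConcordance(rev(c("A", "C", "B", "D")), c("A", "B", "C", "D"))
    res_rr <- orderConcordance(c("A", "C", "B", "D"), rev(c("A", "B", "C", "D")))
    expect_equal(res_rt$consistent_fraction, 0.75)
    expect_equal(res_rr$consistent_fraction, 0.75)
    # a fully reversed order is fully consistent
    expect_equal(orderConcordance(rev(LETTERS[1:8]),
                                  LETTERS[1:8])$consistent_fraction, 1)
})

test_that("concordance ignores unshared markers and flags tiny overlaps", {
    res <- orderConcordance(c("X", "A", "C", "Y", "B", "D"),
                            c("A", "B", "Q", "C", "D", "Z"))
    base <- orderConcordance(c("A", "C", "B", "D"), c("A", "B", "C", "D"))
    expect_equal(res$consistent_fraction, base$consistent_fraction)
    tiny <- orderConcordance(c("A", "X"), c("A", "B"))
    expect_false(tiny$comparable)
    expect_true(is.na(tiny$consistent_fraction))
})
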