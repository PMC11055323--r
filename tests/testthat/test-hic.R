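test_that("contact map generator output is symmetric and deterministic", {
  cfg <- sim_hic_config(n_bins = 120, depth = 2e5, seed = 5)
  g1 <- gen_contact_maps(cfg)
  g2 <- gen_contact_maps(cfg)
  expect_identical(g1$case$counts, g2$case$counts)
  expect_identical(g1$marked, g2$marked)
  expect_identical(g1$control$counts, t(g1$control$counts))
  expect_identical(g1$case$counts, t(g1$case$counts))
  expect_true(all(diag(g1$case$counts) == 0))
  # totals scale with depth
  expect_equal(g1$control$total, 2e5, tolerance = 0.02)
  expect_error(sim_hic_config(n_bins = 40, bin_size = 20000, min_dist = 1e6),
               "long-range")
})

test_that("null generator (factor 1) shows no enhancement", {
  g <- gen_contact_maps(sim_hic_config(n_bins = 150, enhancement_factor = 1,
                                       depth = 5e5, seed = 8))
  r <- enhancement_ratio(
    longrange_profile(total_count_normalize(g$case)),
    longrange_profile(total_count_normalize(g$control)))
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("total-count normalization scales, is idempotent, and errors on zero", {
  toy <- contact_matrix(matrix(c(0, 10, 10, 0), 2), bin_size = 1e6)
  nm <- total_count_normalize(toy, target_total = 100)
  expect_equal(nm$counts, matrix(c(0, 50, 50, 0), 2))
  expect_true(nm$normalized)
  expect_equal(total_count_normalize(nm, 100)$counts, nm$counts)
  expect_error(total_count_normalize(
    contact_matrix(matrix(0, 2, 2), bin_size = 1e6)), "all-zero")
})

test_that("long-range profile equals the brute-force double loop", {
  # 4-bin toy at 1 Mb bins, hand-checkable
  cnt <- matrix(c(0, 5, 7, 2,
                  5, 0, 1, 3,
                  7, 1, 0, 4,
                  2, 3, 4, 0), 4, byrow = TRUE)
  m <- contact_matrix(cnt, bin_size = 1e6)
  L <- longrange_profile(m, min_dist = 1e6)
  # strictly > 1 Mb between midpoints: adjacent bins (exactly 1 Mb) excluded
  expect_equal(L, c(7 + 2, 3, 7, 2 + 3))
  expect_equal(L, brute_longrange(m, 1e6))

  # random matrices up to 200 bins, exact agreement
  set.seed(3)
  for (n in c(37, 120, 200)) {
    cnt <- matrix(rpois(n * n, 3), n)
    cnt <- cnt + t(cnt); diag(cnt) <- 0
    m <- contact_matrix(cnt, bin_size = 20000)
    expect_identical(longrange_profile(m, 1e6), brute_longrange(m, 1e6))
  }

  # linearity and the all-zero limit
  expect_equal(longrange_profile(contact_matrix(2 * cnt, bin_size = 20000)),
               2 * longrange_profile(contact_matrix(cnt, bin_size = 20000)))
  expect_equal(longrange_profile(m, min_dist = 200 * 20000), rep(0, 200))
})

test_that("enhancement ratio arithmetic and pseudocount behaviour", {
  expect_equal(enhancement_ratio(c(1, 5), c(1, 5)), c(0, 0))
  expect_equal(enhancement_ratio(31, 15, pseudocount = 1), 1)
  expect_error(enhancement_ratio(1:3, 1:4), "mismatch")
  # pseudocount bounds ratios at empty bins
  for (eps in c(0.1, 1, 5))
    expect_true(is.finite(enhancement_ratio(0, 0, pseudocount = eps)))
})

test_that("bin marking uses a strict threshold and recovers ground truth", {
  tk <- bin_track(data.frame(chrom = "chrS", start = 0:2 * 100,
                             end = 1:3 * 100, bin_id = 0:2),
                  signal = c(41, 40, 0))
  mk <- mark_modified_bins(tk)
  expect_identical(mk$marked, c(TRUE, FALSE, FALSE))

  g <- gen_contact_maps(sim_hic_config(n_bins = 100, depth = 1e5, seed = 12))
  expect_identical(mark_modified_bins(g$track)$marked, g$marked)
})

test_that("correlation of enhancement with signal behaves", {
  tk <- bin_track(data.frame(chrom = "chrS", start = 0:19 * 100,
                             end = 1:20 * 100, bin_id = 0:19),
                  signal = 1:20)
  expect_error(correlate_enhancement(rep(1, 20), tk), "zero variance")
  perfect <- correlate_enhancement(as.numeric(1:20), tk)
  expect_equal(perfect$estimate, 1)

  g <- gen_contact_maps(sim_hic_config(seed = 2))
  r <- enhancement_ratio(
    longrange_profile(total_count_normalize(g$case)),
    longrange_profile(total_count_normalize(g$control)))
  ct <- correlate_enhancement(r, g$track)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # quantile-group aggregation keeps the association
  ct5 <- correlate_enhancement(r, g$track, n_groups = 5)
  expect_gt(ct5$estimate, 0)
})

test_that("stratified enhancement detects the planted boost", {
  g <- gen_contact_maps(sim_hic_config(seed = 1))
  r <- enhancement_ratio(
    longrange_profile(total_count_normalize(g$case)),
    longrange_profile(total_count_normalize(g$control)))
  st <- stratified_enhancement(r, g$marked)
  expect_gt(st$median_marked, st$median_unmarked)
  expect_lt(st$p.value, 0.01)
  # complement swap flips the sign of the difference
  sw <- stratified_enhancement(r, !g$marked)
  expect_equal(sw$delta_median, -st$delta_median)
  expect_error(stratified_enhancement(r, rep(TRUE, length(r))), "non-empty")
})

test_that("per-bin marked mean matches its analytic expectation", {
  # enhancement on marked-marked pairs dilutes per-bin to
  # log2(1 + marked_fraction * (factor - 1))
  vals <- vapply(1:5, function(s) {
    g <- gen_contact_maps(sim_hic_config(seed = 700 + s))
    r <- enhancement_ratio(
      longrange_profile(total_count_normalize(g$case)),
      longrange_profile(total_count_normalize(g$control)))
    mean(r[g$marked])
  }, numeric(1))
  expect_equal(mean(vals), log2(1 + 0.2 * (2 - 1)), tolerance = 0.05)
})

test_that("pair-class analysis recovers the planted factor", {
  # 3-bin toy against brute-force enumeration
  cnt_c <- matrix(c(0, 2, 8,
                    2, 0, 4,
                    8, 4, 0), 3, byrow = TRUE)
  cnt_s <- matrix(c(0, 6, 16,
                    6, 0, 4,
                    16, 4, 0), 3, byrow = TRUE)
  mc <- contact_matrix(cnt_c, bin_size = 1e6)
  ms <- contact_matrix(cnt_s, bin_size = 1e6)
  marked <- c(TRUE, FALSE, TRUE)
  pc <- pair_enhancement(ms, mc, marked, min_dist = 1e6, pseudocount = 1)
  # eligible pairs (> 1 Mb): (1,3) MM
  expect_equal(unname(pc$mean_log2["marked_marked"]), log2(17 / 9))
  expect_true(is.na(pc$mean_log2["unmarked_unmarked"]))
  expect_identical(pc$n_pairs, c(1L, 0L, 0L))

  # case == control -> all class means 0
  g <- gen_contact_maps(sim_hic_config(n_bins = 150, depth = 2e5, seed = 4))
  same <- pair_enhancement(total_count_normalize(g$control),
                           total_count_normalize(g$control), g$marked)
  expect_equal(unname(same$aggregate_log2), rep(0, 3))

  # planted factor 2 -> MM aggregate ~ 1, other classes ~ 0
  gg <- gen_contact_maps(sim_hic_config(seed = 6))
  pc2 <- pair_enhancement(total_count_normalize(gg$case),
                          total_count_normalize(gg$control), gg$marked)
  expect_equal(unname(pc2$aggregate_log2["marked_marked"]), 1,
               tolerance = 0.15)
  expect_lt(abs(pc2$aggregate_log2["marked_unmarked"]), 0.15)
  expect_lt(abs(pc2$aggregate_log2["unmarked_unmarked"]), 0.15)
})

test_that("the report is invariant to rescaling raw counts", {
  g <- gen_contact_maps(sim_hic_config(n_bins = 150, depth = 3e5, seed = 9))
  rep1 <- hic_enhancement_report(g$case, g$control, g$track)
  scaled <- contact_matrix(g$case$counts * 7.5, bins = g$case$bins,
                           bin_size = g$case$bin_size)
  rep2 <- hic_enhancement_report(scaled, g$control, g$track)
  expect_equal(rep1$per_bin$log2_ratio, rep2$per_bin$log2_ratio)
  expect_equal(rep1$stratified$p.value, rep2$stratified$p.value)
  expect_equal(rep1$pair_classes$aggregate_log2,
               rep2$pair_classes$aggregate_log2)
})
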