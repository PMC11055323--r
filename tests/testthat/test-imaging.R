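test_that("connected-component labeling uses 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # touch only diagonally
  lab <- condq:::label_components(m)
  expect_identical(max(lab), 1L)
  m[5, 5] <- TRUE                            # isolated pixel
  expect_identical(max(condq:::label_components(m)), 2L)
  expect_identical(max(condq:::label_components(matrix(FALSE, 3, 3))), 0L)
})

test_that("detection finds planted foci and rejects flat images", {
  g <- gen_nucleus_images(small_image_config(n_nuclei = 1, noise_sd = 2,
                                             seed = 301))
  img <- g$images[[1]]
  labs <- detect_condensates(img)
  planted <- g$truth[g$truth$nucleus == 1, ]
  expect_identical(labs$count, nrow(planted))
  # each centroid within 1 px of some planted center
  for (i in seq_len(labs$count)) {
    d <- sqrt((planted$x - labs$per_condensate$centroid_x[i])^2 +
              (planted$y - labs$per_condensate$centroid_y[i])^2)
    expect_lt(min(d), 1)
  }

  flat <- nucleus_image(matrix(5, 20, 20), matrix(5, 20, 20),
                        matrix(TRUE, 20, 20))
  expect_error(detect_condensates(flat), "flat image")

  # uniform nucleoplasm with noise only: no components of area >= 4
  g0 <- gen_nucleus_images(small_image_config(
    n_nuclei = 1, condensates_per_nucleus = 0, noise_sd = 5, seed = 17))
  expect_identical(detect_condensates(g0$images[[1]])$count, 0L)
})

test_that("detection recall and precision reach 0.95 at high contrast", {
  tp <- fp <- fn <- 0
  for (s in 1:10) {
    g <- gen_nucleus_images(small_image_config(n_nuclei = 2, noise_sd = 10,
                                               seed = 400 + s))
    for (k in 1:2) {
      labs <- detect_condensates(g$images[[k]])
      planted <- g$truth[g$truth$nucleus == k, ]
      used <- rep(FALSE, nrow(planted))
      for (i in seq_len(labs$count)) {
        d <- sqrt((planted$x - labs$per_condensate$centroid_x[i])^2 +
                  (planted$y - labs$per_condensate$centroid_y[i])^2)
        j <- which(d < 3 & !used)[1]
        if (!is.na(j)) { used[j] <- TRUE; tp <- tp + 1 } else fp <- fp + 1
      }
      fn <- fn + sum(!used)
    }
  }
  expect_gte(tp / (tp + fn), 0.95)   # recall
  expect_gte(tp / (tp + fp), 0.95)   # precision
})

test_that("a 4x nucleation-rate contrast yields >= 3x the mean count", {
  count_mean <- function(rate, seed) {
    g <- gen_nucleus_images(sim_image_config(
      image_size = 140, nucleus_radius = 58, condensates_per_nucleus = rate,
      condensate_radius_mean = 1.6, condensate_radius_sd = 0.1,
      min_separation = 6.5, n_nuclei = 8, noise_sd = 10, seed = seed))
    mean(vapply(g$images, function(im) detect_condensates(im)$count,
                numeric(1)))
  }
  expect_gte(count_mean(40, 21) / count_mean(10, 22), 3)
})

test_that("pixel sampling is seeded, exhaustive, and stratified", {
  g <- gen_nucleus_images(small_image_config(n_nuclei = 1, seed = 33))
  img <- g$images[[1]]
  labs <- detect_condensates(img)
  s1 <- sample_pixels(img, labs, 10, seed = 4)
  s2 <- sample_pixels(img, labs, 10, seed = 4)
  expect_identical(s1, s2)
  expect_error(sample_pixels(img, labs, 1e6, seed = 1), "inside")

  # toy: exactly 4 labeled pixels -> the inside sample is those intensities
  toy <- nucleus_image(matrix(rnorm(100), 10, 10),
                       matrix(seq_len(100), 10, 10), matrix(TRUE, 10, 10))
  lab <- matrix(0L, 10, 10); lab[2:3, 2:3] <- 1L
  labs4 <- structure(list(label_raster = lab,
                          per_condensate = data.frame(label = 1L),
                          count = 1L), class = "condensate_labels")
  s <- sample_pixels(toy, labs4, 4, seed = 99)
  expect_setequal(s$inside, toy$query_channel[lab == 1L])
})

test_that("Z-scoring is an affine normalization", {
  expect_equal(zscore_pixels(100, 100, 10), 0)
  expect_equal(zscore_pixels(120, 100, 10), 2)
  expect_error(zscore_pixels(1, 0, 0), "ref_sd")
  x <- rnorm(500, 50, 4)
  z <- zscore_pixels(x, mean(x), sd(x))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("exclusion test matches exact enumeration and handles ties", {
  same <- exclusion_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$p_raw, 1)
  expect_equal(same$delta_median, 0)
  expect_identical(same$verdict, "neutral")

  sep <- exclusion_test(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(sep$p_raw, 2 / 252)           # exact rank-sum enumeration
  expect_identical(sep$verdict, "excluded")

  tied <- exclusion_test(rep(2, 6), rep(2, 6))
  expect_equal(tied$p_raw, 1)
  expect_identical(tied$verdict, "neutral")

  # permutation of sample order never changes the report
  set.seed(1)
  a <- rnorm(12); b <- rnorm(12, 1)
  r1 <- exclusion_test(a, b)
  r2 <- exclusion_test(sample(a), sample(b))
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(r1$delta_median, r2$delta_median)
})

test_that("Holm adjustment is monotone and matches the hand-derived values", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(rep(1, 4)), rep(1, 4))
  # step-down: sorted {0.01,0.03,0.04} x {3,2,1} with running max
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), method = "BH"),
               p.adjust(c(0.01, 0.04, 0.03), "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("adjusted verdicts follow the adjusted p-values", {
  reps <- list(exclusion_test(c(1, 2, 3, 4, 5) / 10, c(6, 7, 8, 9, 10)),
               exclusion_test(c(1, 3, 2, 5, 4), c(1.1, 3.1, 2.1, 5.1, 4.1)))
  adj <- adjust_reports(reps)
  expect_true(all(vapply(adj, function(r) r$p_adj >= r$p_raw, logical(1))))
  expect_identical(adj[[2]]$verdict, "neutral")
})

test_that("delta_median is monotone in the partition coefficient", {
  pcs <- c(0.25, 0.5, 1, 2, 4)
  mean_delta <- vapply(seq_along(pcs), function(i) {
    deltas <- vapply(1:15, function(s) {
      g <- gen_nucleus_images(small_image_config(
        n_nuclei = 5, partition_coefficient = pcs[i], noise_sd = 20,
        seed = 5000 + 100 * i + s))
      exclusion_analysis(g$images, seed = s)$delta_median
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  expect_identical(order(mean_delta), seq_along(pcs))
})
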