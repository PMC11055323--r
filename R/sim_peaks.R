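#' Generate paired peak sets with a controlled shared fraction
#'
#' Builds two peak sets on a simulated chromosome such that exactly
#' `round(shared_fraction * min(n_a, n_b))` intervals are identical between
#' the sets and every other interval is disjoint from all others (>= 1 bp
#' gaps). Both sets come back sorted and non-overlapping.
#'
#' @param n_a,n_b interval counts of the two sets.
#' @param shared_fraction fraction in `[0, 1]` of `min(n_a, n_b)` shared.
#' @param genome_size chromosome length in bp.
#' @param interval_len interval length in bp.
#' @param seed integer seed.
#' @return list with `A`, `B` ([peak_set()]), and `shared_truth` (count).
#' @export
gen_peak_sets <- function(n_a, n_b, shared_fraction, genome_size = 1e6,
                          interval_len = 500, seed = 1) {
  check_number(n_a, "n_a", lower = 0)
  check_number(n_b, "n_b", lower = 0)
  check_number(shared_fraction, "shared_fraction", lower = 0, upper = 1)
  n_shared <- round(shared_fraction * min(n_a, n_b))
  n_total <- n_a + n_b - n_shared
  free <- genome_size - n_total * interval_len - (n_total - 1)
  if (n_total > 0 && free < 0)
    stopf("infeasible packing: %d disjoint intervals of %d bp do not fit in %g bp",
          n_total, interval_len, genome_size)
  with_seed(seed, {
    offs <- if (n_total > 0) sort(sample.int(free + 1, n_total, replace = TRUE)) - 1
            else integer(0)
    starts <- (seq_len(n_total) - 1) * (interval_len + 1) + offs
    roles <- sample(rep(c("shared", "a", "b"),
                        c(n_shared, n_a - n_shared, n_b - n_shared)))
    a_idx <- which(roles %in% c("shared", "a"))
    b_idx <- which(roles %in% c("shared", "b"))
    mk <- function(idx, prefix)
      peak_set(data.frame(chrom = "chrS", start = starts[idx],
                          end = starts[idx] + interval_len,
                          name = sprintf("%s_%03d", prefix, seq_along(idx))))
    list(A = mk(a_idx, "peakA"), B = mk(b_idx, "peakB"),
         shared_truth = n_shared)
  })
}
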