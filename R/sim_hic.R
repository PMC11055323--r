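#' Configuration for synthetic paired Hi-C contact maps
#'
#' Emulates a control and a case ("SS") contact matrix for one simulated
#' chromosome at fixed bin width: expected contacts decay with genomic
#' distance as a power law, and in the case matrix the contacts between
#' pairs of "marked" bins (high-signal bins of the companion track) at
#' distances above `min_dist` are multiplied by `enhancement_factor` before
#' Poisson sampling.
#'
#' @param n_bins bins per simulated chromosome.
#' @param bin_size bin width in bp (default 20000).
#' @param decay_exponent power-law exponent of the distance decay.
#' @param marked_fraction fraction of bins given high track signal (0-1,
#'   exclusive).
#' @param enhancement_factor multiplicative boost on marked-marked
#'   long-range pairs in the case matrix (>= 1).
#' @param min_dist distance threshold in bp (default 1e6; strict `>`).
#' @param depth expected total contact count per condition.
#' @param track_high,track_low track signal at marked / unmarked bins; the
#'   defaults straddle the marking threshold of 40 so thresholding recovers
#'   the ground truth.
#' @param track_jitter_sd optional Gaussian jitter s.d. on the track.
#' @param seed integer seed.
#' @return a `sim_hic_config` list.
#' @export
sim_hic_config <- function(n_bins = 300, bin_size = 20000,
                           decay_exponent = 1, marked_fraction = 0.2,
                           enhancement_factor = 2, min_dist = 1e6,
                           depth = 2e6, track_high = 60, track_low = 10,
                           track_jitter_sd = 0, seed = 1) {
  check_number(n_bins, "n_bins", lower = 2)
  check_number(bin_size, "bin_size", lower = 1)
  check_number(decay_exponent, "decay_exponent", lower = 0)
  check_number(marked_fraction, "marked_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (marked_fraction >= 1) stopf("marked_fraction must be < 1")
  check_number(enhancement_factor, "enhancement_factor", lower = 1)
  check_number(min_dist, "min_dist", lower = 0)
  check_number(depth, "depth", lower = 1)
  if (!(track_high > 40 && track_low <= 40))
    stopf("track_high must be > 40 >= track_low so thresholding recovers truth")
  if (n_bins * bin_size <= min_dist)
    stopf("no long-range pairs possible: n_bins*bin_size (%g) <= min_dist (%g)",
          n_bins * bin_size, min_dist)
  structure(list(n_bins = as.integer(n_bins), bin_size = bin_size,
                 decay_exponent = decay_exponent,
                 marked_fraction = marked_fraction,
                 enhancement_factor = enhancement_factor,
                 min_dist = min_dist, depth = depth,
                 track_high = track_high, track_low = track_low,
                 track_jitter_sd = track_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_hic_config")
}

#' Generate paired contact maps with a planted long-range enhancement
#'
#' Builds the power-law expectation matrix, scales it so the control's
#' expected total equals `depth`, applies the enhancement to marked-marked
#' pairs beyond `min_dist` in the case matrix, and draws symmetric Poisson
#' counts (upper triangle sampled, mirrored; diagonal zero). The companion
#' track is `track_high` at marked bins and `track_low` elsewhere, plus
#' optional jitter.
#'
#' @param cfg a [sim_hic_config()].
#' @return list with `control` and `case` ([contact_matrix()]), `track`
#'   ([bin_track()]), `marked` (logical ground truth), and `config`.
#' @export
gen_contact_maps <- function(cfg) {
  stopifnot(inherits(cfg, "sim_hic_config"))
  n <- cfg$n_bins
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- ifelse(D == 0, 0, D^(-cfg$decay_exponent))
  E <- E * (cfg$depth / sum(E))

  with_seed(cfg$seed, {
    marked <- rep(FALSE, n)
    marked[sample.int(n, round(cfg$marked_fraction * n))] <- TRUE
    boost <- outer(marked, marked, "&") & (D * cfg$bin_size > cfg$min_dist)
    E_case <- E
    E_case[boost] <- E_case[boost] * cfg$enhancement_factor

    sample_sym <- function(EM) {
      up <- upper.tri(EM)
      cnt <- matrix(0, n, n)
      cnt[up] <- rpois(sum(up), EM[up])
      cnt + t(cnt)
    }
    ctrl <- sample_sym(E)
    case <- sample_sym(E_case)

    sig <- ifelse(marked, cfg$track_high, cfg$track_low)
    if (cfg$track_jitter_sd > 0)
      sig <- pmax(0, sig + rnorm(n, 0, cfg$track_jitter_sd))

    bins <- data.frame(chrom = "chrS",
                       start = (seq_len(n) - 1) * cfg$bin_size,
                       end = seq_len(n) * cfg$bin_size,
                       bin_id = seq_len(n) - 1L)
    list(control = contact_matrix(ctrl, bins = bins, bin_size = cfg$bin_size),
         case = contact_matrix(case, bins = bins, bin_size = cfg$bin_size),
         track = bin_track(bins, sig),
         marked = marked,
         config = cfg)
  })
}
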