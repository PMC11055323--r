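#' Configuration for synthetic half-FRAP traces
#'
#' @param k_int internal half-to-half mixing rate (1/s, >= 0).
#' @param k_ext exchange rate with the external pool (1/s, >= 0); `k_int`
#'   and `k_ext` cannot both be zero.
#' @param times sampling grid in seconds, strictly increasing with
#'   `times[1] = 0` (the bleach instant).
#' @param noise_sd additive Gaussian noise s.d. per sample on the normalized
#'   intensity scale.
#' @param n_traces number of replicate traces.
#' @param seed integer seed.
#' @return a `sim_frap_config` list.
#' @export
sim_frap_config <- function(k_int = 1, k_ext = 1,
                            times = seq(0, 20, by = 0.1),
                            noise_sd = 0.02, n_traces = 5, seed = 1) {
  check_number(k_int, "k_int", lower = 0)
  check_number(k_ext, "k_ext", lower = 0)
  if (k_int == 0 && k_ext == 0) stopf("k_int and k_ext cannot both be zero")
  if (length(times) < 2 || any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  if (times[1] != 0) stopf("times[1] must be 0 (the bleach instant)")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_traces, "n_traces", lower = 1)
  structure(list(k_int = k_int, k_ext = k_ext, times = times,
                 noise_sd = noise_sd, n_traces = as.integer(n_traces),
                 seed = as.integer(seed)),
            class = "sim_frap_config")
}

#' Generate synthetic half-FRAP traces with known ground truth
#'
#' Draws `n_traces` normalized-scale traces from the two-compartment
#' exchange model ([frap_theory()]) with independent additive Gaussian noise
#' per sample, and attaches the true dip depth from the closed form.
#' Deterministic given the config (including seed).
#'
#' @param cfg a [sim_frap_config()].
#' @return list with `traces` (list of [frap_trace()]), `true_dip`,
#'   `true_k_int`, `true_k_ext`, and `config`.
#' @export
gen_frap_traces <- function(cfg) {
  stopifnot(inherits(cfg, "sim_frap_config"))
  th <- frap_theory(cfg$times, cfg$k_int, cfg$k_ext)
  traces <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_traces), function(i) {
      nb <- rnorm(length(cfg$times), 0, cfg$noise_sd)
      nu <- rnorm(length(cfg$times), 0, cfg$noise_sd)
      frap_trace(cfg$times, th$bleached + nb, th$unbleached + nu,
                 trace_id = sprintf("trace_%03d", i), normalized = TRUE)
    })
  })
  list(traces = traces,
       true_dip = dip_depth_closed_form(cfg$k_int, cfg$k_ext),
       true_k_int = cfg$k_int, true_k_ext = cfg$k_ext,
       config = cfg)
}
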