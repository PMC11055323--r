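# shared fixtures built in code

# small, fast image config for pipeline tests
small_image_config <- function(...) {
  args <- list(image_size = 72, nucleus_radius = 28,
               condensates_per_nucleus = 4,
               condensate_radius_mean = 2.2, condensate_radius_sd = 0.15)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_image_config, args)
}

# numerical ODE oracle for the two-compartment half-FRAP model,
# independent of the closed form used by the implementation
ode_frap <- function(k_int, k_ext, times) {
  sol <- deSolve::ode(
    y = c(b = 0, u = 1),
    times = times,
    func = function(t, y, p) {
      list(c(p["ki"] * (y["u"] - y["b"]) + p["ke"] * (1 - y["b"]),
             p["ki"] * (y["b"] - y["u"]) + p["ke"] * (1 - y["u"])))
    },
    parms = c(ki = k_int, ke = k_ext),
    method = "lsoda", rtol = 1e-10, atol = 1e-12)
  as.data.frame(sol)
}

# dip depth from the ODE oracle: fine grid around the analytic dip window
# plus parabolic refinement through the three points around the minimum
ode_dip_depth <- function(k_int, k_ext, t_max = NULL) {
  if (k_ext == 0) return(0.5)
  if (k_int == 0) return(0)
  B <- 2 * k_int + k_ext
  t_star <- log(B / k_ext) / (B - k_ext)
  if (is.null(t_max)) t_max <- 4 * t_star
  tt <- seq(0, t_max, length.out = 4001)
  u <- ode_frap(k_int, k_ext, tt)$u
  i <- which.min(u)
  if (i > 1 && i < length(u)) {
    y1 <- u[i - 1]; y2 <- u[i]; y3 <- u[i + 1]
    denom <- y1 - 2 * y2 + y3
    umin <- if (denom > 0) y2 - (y1 - y3)^2 / (8 * denom) else y2
  } else umin <- u[i]
  1 - umin
}

# per-base brute-force overlap oracle for interval operations
brute_overlap_hits <- function(A, B, min_overlap_bp = 1) {
  vapply(seq_len(nrow(A)), function(i) {
    bs <- B[B$chrom == A$chrom[i], , drop = FALSE]
    if (!nrow(bs)) return(FALSE)
    any(pmin(bs$end, A$end[i]) - pmax(bs$start, A$start[i]) >= min_overlap_bp)
  }, logical(1))
}

# brute-force O(n^2) long-range profile oracle
brute_longrange <- function(m, min_dist = 1e6) {
  n <- nrow(m$counts)
  mid <- (m$bins$start + m$bins$end) / 2
  L <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(mid[i] - mid[j]) > min_dist) L[i] <- L[i] + m$counts[i, j]
  L
}
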