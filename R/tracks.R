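# Genomic interval operations: Venn partition, colocalization, profiles.

#' Ordered genomic interval set (BED semantics)
#'
#' 0-based half-open intervals, sorted by (chrom, start); overlapping
#' intervals within the set are merged at construction (touching intervals
#' stay separate).
#'
#' @param df data frame with `chrom`, `start`, `end` and optionally `name`.
#' @return an object of class `peak_set` (a sorted data frame).
#' @export
peak_set <- function(df) {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stopf("peak_set needs chrom, start, end columns")
  if (any(df$start >= df$end)) stopf("intervals must satisfy start < end")
  if (is.null(df$name)) df$name <- sprintf("peak_%04d", seq_len(nrow(df)))
  df <- df[order(df$chrom, df$start), c("chrom", "start", "end", "name")]
  rownames(df) <- NULL
  # merge strictly overlapping intervals within the set
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1) {
      keep_end <- d$end[1]; first <- 1L; rows <- list()
      for (i in 2:nrow(d)) {
        if (d$start[i] < keep_end) {          # overlap -> extend
          keep_end <- max(keep_end, d$end[i])
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start = d$start[first], end = keep_end,
            name = d$name[first])
          first <- i; keep_end <- d$end[i]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = d$start[first], end = keep_end,
        name = d$name[first])
      d <- do.call(rbind, rows)
    }
    out[[ch]] <- d
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... and %d more\n", nrow(x) - 6))
  invisible(x)
}

# per-chromosome sweep: for each query interval, the maximum single-interval
# overlap (bp) with the subject set; both sides sorted and non-overlapping
max_overlap_sweep <- function(q_start, q_end, s_start, s_end) {
  res <- numeric(length(q_start))
  j <- 1L
  for (i in seq_along(q_start)) {
    while (j <= length(s_start) && s_end[j] <= q_start[i]) j <- j + 1L
    k <- j
    best <- 0
    while (k <= length(s_start) && s_start[k] < q_end[i]) {
      best <- max(best, min(q_end[i], s_end[k]) - max(q_start[i], s_start[k]))
      k <- k + 1L
    }
    res[i] <- best
  }
  res
}

# bp of best single-interval overlap for each interval of A against B
overlap_bp <- function(A, B) {
  res <- numeric(nrow(A))
  for (ch in unique(A$chrom)) {
    ai <- which(A$chrom == ch)
    bi <- which(B$chrom == ch)
    if (!length(bi)) next
    res[ai] <- max_overlap_sweep(A$start[ai], A$end[ai],
                                 B$start[bi], B$end[bi])
  }
  res
}

#' Venn partition of two peak sets
#'
#' Sweep-line intersection: an interval counts as shared when it overlaps at
#' least `min_overlap_bp` with some interval of the other set. Counts are
#' interval counts from each side (A's shared count and B's shared count can
#' differ when one interval of A spans several of B); the Venn partition
#' `(a_only, shared, b_only)` uses the A-side shared count.
#'
#' @param A,B [peak_set()] objects.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return list with `a_only`, `shared`, `b_only`, `shared_b` (B-side
#'   count), and interval subsets `a_only_peaks`, `shared_peaks` (from A),
#'   `b_only_peaks`.
#' @export
intersect_peaks <- function(A, B, min_overlap_bp = 1) {
  stopifnot(inherits(A, "peak_set"), inherits(B, "peak_set"))
  check_number(min_overlap_bp, "min_overlap_bp", lower = 1)
  a_hit <- overlap_bp(A, B) >= min_overlap_bp
  b_hit <- overlap_bp(B, A) >= min_overlap_bp
  list(a_only = sum(!a_hit), shared = sum(a_hit), b_only = sum(!b_hit),
       shared_b = sum(b_hit),
       a_only_peaks = A[!a_hit, , drop = FALSE],
       shared_peaks = A[a_hit, , drop = FALSE],
       b_only_peaks = B[!b_hit, , drop = FALSE])
}

#' Fraction of sites overlapping a reference set
#'
#' @param sites non-empty [peak_set()].
#' @param reference [peak_set()].
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return fraction in `[0, 1]` of `sites` intervals overlapping `reference`.
#' @export
colocalization_fraction <- function(sites, reference, min_overlap_bp = 1) {
  stopifnot(inherits(sites, "peak_set"), inherits(reference, "peak_set"))
  if (nrow(sites) == 0) stopf("empty sites set")
  mean(overlap_bp(sites, reference) >= min_overlap_bp)
}

#' Aggregate track signal around site midpoints
#'
#' For each site, the window `[mid - window_bp/2, mid + window_bp/2)` is
#' split into `n_bins` equal bins and each bin takes the mean track signal
#' over its bases (bases without track coverage count as 0, the bedGraph
#' gap convention). Rows follow the site order (chrom, start); column means
#' give the aggregate profile.
#'
#' @param sites a [peak_set()].
#' @param track data frame with `chrom`, `start`, `end`, `value`
#'   (bedGraph semantics; see [read_bedgraph()]).
#' @param window_bp window width in bp, divisible by `n_bins`.
#' @param n_bins number of profile bins.
#' @param chrom_sizes optional named vector of chromosome lengths; windows
#'   extending past `[0, size)` are clipped and flagged.
#' @return a `signal_profile`: `matrix` (sites x bins), `column_means`,
#'   `clipped` (logical per site).
#' @export
aggregate_signal <- function(sites, track, window_bp = 4000, n_bins = 100,
                             chrom_sizes = NULL) {
  stopifnot(inherits(sites, "peak_set"))
  if (window_bp %% n_bins != 0)
    stopf("window_bp (%g) must be divisible by n_bins (%d)", window_bp, n_bins)
  bw <- window_bp / n_bins
  M <- matrix(0, nrow(sites), n_bins)
  clipped <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    mid <- floor((sites$start[i] + sites$end[i]) / 2)
    w0 <- mid - window_bp / 2
    lim <- c(0, if (!is.null(chrom_sizes)) chrom_sizes[[sites$chrom[i]]] else Inf)
    if (w0 < lim[1] || w0 + window_bp > lim[2]) clipped[i] <- TRUE
    tr <- track[track$chrom == sites$chrom[i] &
                track$end > w0 & track$start < w0 + window_bp, , drop = FALSE]
    for (b in seq_len(n_bins)) {
      b0 <- w0 + (b - 1) * bw
      b1 <- b0 + bw
      v0 <- max(b0, lim[1]); v1 <- min(b1, lim[2])
      if (v1 <= v0 || !nrow(tr)) next
      ov <- pmin(tr$end, v1) - pmax(tr$start, v0)
      keep <- ov > 0
      # mean over the bin's valid bases; uncovered bases contribute 0
      M[i, b] <- sum(tr$value[keep] * ov[keep]) / (v1 - v0)
    }
  }
  structure(list(matrix = M, column_means = colMeans(M), clipped = clipped,
                 window_bp = window_bp, n_bins = n_bins),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf("signal_profile: %d sites x %d bins (%g bp window)%s\n",
              nrow(x$matrix), x$n_bins, x$window_bp,
              if (any(x$clipped)) sprintf(", %d clipped", sum(x$clipped)) else ""))
  invisible(x)
}

#' @export
plot.signal_profile <- function(x, ...) {
  pos <- (seq_len(x$n_bins) - 0.5) * (x$window_bp / x$n_bins) - x$window_bp / 2
  graphics::plot(pos, x$column_means, type = "l",
                 xlab = "distance from site midpoint (bp)",
                 ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
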