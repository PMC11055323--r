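#' Configuration for synthetic nucleus images
#'
#' Describes two-channel fluorescence images of single nuclei: a condensate
#' marker channel with bright Gaussian foci over a nucleoplasm baseline, and
#' a query-protein channel whose intensity inside condensate footprints is
#' the baseline scaled by a partition coefficient (< 1 = excluded,
#' > 1 = enriched, 1 = neutral).
#'
#' Condensates are isotropic 2D Gaussians truncated at 3 sigma; the
#' ground-truth footprint is the disk of radius 2 sigma. The nucleus mask is
#' a filled circle and pixels outside it are zero.
#'
#' @param image_size pixels per side.
#' @param n_nuclei number of nuclei (one image per nucleus).
#' @param nucleus_radius nucleus radius in pixels.
#' @param condensates_per_nucleus expected condensate count (Poisson mean).
#' @param condensate_radius_mean,condensate_radius_sd Gaussian sigma of a
#'   condensate, drawn per condensate (pixels).
#' @param condensate_amplitude marker-channel peak height as a fold over the
#'   nucleoplasm baseline.
#' @param partition_coefficient query-channel inside/outside intensity ratio
#'   (> 0).
#' @param noise_sd additive Gaussian noise s.d. (intensity units).
#' @param baseline nucleoplasm intensity of both channels (intensity units).
#' @param min_separation minimum center-to-center distance between planted
#'   condensates (pixels); default 4x the mean radius keeps foci resolvable.
#' @param pixel_size microns per pixel (metadata only).
#' @param seed integer seed.
#' @return a `sim_image_config` list.
#' @export
sim_image_config <- function(image_size = 96, n_nuclei = 8,
                             nucleus_radius = 36,
                             condensates_per_nucleus = 5,
                             condensate_radius_mean = 2.5,
                             condensate_radius_sd = 0.25,
                             condensate_amplitude = 5,
                             partition_coefficient = 1,
                             noise_sd = 15,
                             baseline = 100,
                             min_separation = 4 * condensate_radius_mean,
                             pixel_size = 0.1,
                             seed = 1) {
  check_number(image_size, "image_size", lower = 8)
  check_number(n_nuclei, "n_nuclei", lower = 1)
  check_number(nucleus_radius, "nucleus_radius", lower = 2)
  check_number(condensates_per_nucleus, "condensates_per_nucleus", lower = 0)
  check_number(condensate_radius_mean, "condensate_radius_mean", lower = 0,
               strict_lower = TRUE)
  check_number(condensate_radius_sd, "condensate_radius_sd", lower = 0)
  check_number(condensate_amplitude, "condensate_amplitude", lower = 0)
  check_number(partition_coefficient, "partition_coefficient", lower = 0,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  if (condensate_radius_mean >= nucleus_radius)
    stopf("condensate_radius_mean must be smaller than nucleus_radius")
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 condensates_per_nucleus = condensates_per_nucleus,
                 condensate_radius_mean = condensate_radius_mean,
                 condensate_radius_sd = condensate_radius_sd,
                 condensate_amplitude = condensate_amplitude,
                 partition_coefficient = partition_coefficient,
                 noise_sd = noise_sd, baseline = baseline,
                 min_separation = min_separation,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "sim_image_config")
}

#' Two-channel nucleus image container
#'
#' @param marker_channel,query_channel numeric matrices of identical shape.
#' @param nucleus_mask logical matrix, same shape, with at least one `TRUE`.
#' @param pixel_size microns per pixel.
#' @param nucleus_id identifier.
#' @return an object of class `nucleus_image`.
#' @export
nucleus_image <- function(marker_channel, query_channel, nucleus_mask,
                          pixel_size = 0.1, nucleus_id = "nucleus") {
  if (!identical(dim(marker_channel), dim(query_channel)) ||
      !identical(dim(marker_channel), dim(nucleus_mask)))
    stopf("channel and mask shapes must be identical")
  if (!any(nucleus_mask)) stopf("nucleus_mask must be non-empty")
  structure(list(marker_channel = marker_channel,
                 query_channel = query_channel,
                 nucleus_mask = nucleus_mask,
                 pixel_size = pixel_size,
                 nucleus_id = as.character(nucleus_id)),
            class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  d <- dim(x$marker_channel)
  cat(sprintf("nucleus_image '%s': %dx%d px, %d in-mask px, %.3g um/px\n",
              x$nucleus_id, d[1], d[2], sum(x$nucleus_mask), x$pixel_size))
  invisible(x)
}

# place n centers in a disk of radius rmax around (cx, cy), pairwise
# separated by >= sep; sequential rejection sampling can jam on tight but
# feasible layouts, so restart from scratch before declaring overcrowding
place_centers <- function(n, cx, cy, rmax, sep,
                          max_attempts = 400L * max(n, 1L),
                          max_restarts = 25L) {
  for (restart in seq_len(max_restarts)) {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- rmax * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      x <- cx + r * cos(th); y <- cy + r * sin(th)
      if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= sep^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) == n) return(cbind(x = xs, y = ys))
  }
  stopf("overcrowded: cannot place %d condensates with separation %.1f px",
        n, sep)
}

#' Generate synthetic nucleus images with ground truth
#'
#' For each nucleus, draws a Poisson number of condensates, places them in
#' the nucleus with a minimum separation, and renders marker and query
#' channels plus additive Gaussian noise. Ground truth records every planted
#' condensate (center, sigma, footprint radius). Deterministic given the
#' config.
#'
#' @param cfg a [sim_image_config()].
#' @return list with `images` (list of [nucleus_image()]), `truth` (data
#'   frame: nucleus, x, y, sigma, footprint_radius), and `config`.
#' @export
gen_nucleus_images <- function(cfg) {
  stopifnot(inherits(cfg, "sim_image_config"))
  n <- cfg$image_size
  cx <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), each = n), n, n)   # column index (x)
  yg <- matrix(rep(seq_len(n), times = n), n, n)  # row index (y)
  mask <- (xg - cx)^2 + (yg - cx)^2 <= cfg$nucleus_radius^2

  # feasibility: total footprint area must fit in the nucleus
  exp_area <- cfg$condensates_per_nucleus * pi * (2 * cfg$condensate_radius_mean)^2
  if (exp_area > 0.7 * pi * cfg$nucleus_radius^2)
    stopf("overcrowded: expected condensate area exceeds the nucleus")

  with_seed(cfg$seed, {
    images <- vector("list", cfg$n_nuclei)
    truth <- list()
    for (k in seq_len(cfg$n_nuclei)) {
      nc <- rpois(1, cfg$condensates_per_nucleus)
      sig <- pmax(0.5, rnorm(nc, cfg$condensate_radius_mean,
                             cfg$condensate_radius_sd))
      rmax <- max(1, cfg$nucleus_radius - 3 * max(sig, 0.5) - 1)
      cen <- if (nc > 0)
        place_centers(nc, cx, cx, rmax, cfg$min_separation)
      else cbind(x = numeric(0), y = numeric(0))

      marker <- matrix(cfg$baseline, n, n)
      query <- matrix(cfg$baseline, n, n)
      for (j in seq_len(nc)) {
        d2 <- (xg - cen[j, "x"])^2 + (yg - cen[j, "y"])^2
        g <- exp(-d2 / (2 * sig[j]^2))
        g[d2 > (3 * sig[j])^2] <- 0           # truncate at 3 sigma
        marker <- marker + cfg$condensate_amplitude * cfg$baseline * g
        foot <- d2 <= (2 * sig[j])^2          # footprint disk, radius 2 sigma
        query[foot] <- cfg$baseline * cfg$partition_coefficient
      }
      marker <- marker + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
      query <- query + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
      marker[!mask] <- 0
      query[!mask] <- 0

      images[[k]] <- nucleus_image(marker, query, mask,
                                   pixel_size = cfg$pixel_size,
                                   nucleus_id = sprintf("nucleus_%03d", k))
      if (nc > 0)
        truth[[length(truth) + 1L]] <-
          data.frame(nucleus = k, x = cen[, "x"], y = cen[, "y"],
                     sigma = sig, footprint_radius = 2 * sig)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(nucleus = integer(0), x = numeric(0),
                             y = numeric(0), sigma = numeric(0),
                             footprint_radius = numeric(0))
    list(images = images, truth = truth, config = cfg)
  })
}

# ground-truth footprint mask for one nucleus (disk of radius 2 sigma)
truth_footprint_mask <- function(img, truth, nucleus) {
  n <- nrow(img$marker_channel)
  xg <- matrix(rep(seq_len(n), each = n), n, n)
  yg <- matrix(rep(seq_len(n), times = n), n, n)
  m <- matrix(FALSE, n, n)
  tr <- truth[truth$nucleus == nucleus, , drop = FALSE]
  for (j in seq_len(nrow(tr)))
    m <- m | ((xg - tr$x[j])^2 + (yg - tr$y[j])^2 <= tr$footprint_radius[j]^2)
  m & img$nucleus_mask
}
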