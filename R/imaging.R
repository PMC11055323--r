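# Condensate detection and the inside-vs-outside pixel Z-score statistic.

# label connected components of a logical matrix (8-connectivity) by
# iterative flood fill; returns an integer matrix, 0 = background
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      nb_r <- r + off_r
      nb_c <- cc + off_c
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nq <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nq <- nq[mask[nq] & lab[nq] == 0L]
      if (length(nq)) {
        lab[nq] <- cur
        stack <- c(stack, nq)
      }
    }
  }
  lab
}

#' Detect condensates in the marker channel
#'
#' A pixel is foreground when its marker intensity exceeds
#' `mean + k_sigma * sd` of the in-mask marker pixels; 8-connected
#' components with at least `min_area` pixels become condensates.
#'
#' @param img a [nucleus_image()].
#' @param min_area minimum component area in pixels (default 4).
#' @param k_sigma threshold stringency in s.d. units (default 2.5).
#' @return an object of class `condensate_labels`: `label_raster` (integer
#'   matrix, 0 = background, labels 1..count), `per_condensate` (data frame:
#'   label, area, centroid_x, centroid_y, mean_marker), `count`.
#' @export
detect_condensates <- function(img, min_area = 4L, k_sigma = 2.5) {
  stopifnot(inherits(img, "nucleus_image"))
  vals <- img$marker_channel[img$nucleus_mask]
  mu <- mean(vals); s <- sd(vals)
  if (!is.finite(s) || s == 0) stopf("flat image: zero in-mask marker variance")
  fg <- img$nucleus_mask & img$marker_channel > mu + k_sigma * s
  lab0 <- label_components(fg)
  if (max(lab0) > 0) {
    areas <- tabulate(lab0[lab0 > 0L], nbins = max(lab0))
    keep <- which(areas >= min_area)
  } else keep <- integer(0)

  lab <- matrix(0L, nrow(lab0), ncol(lab0))
  per <- data.frame(label = integer(0), area = integer(0),
                    centroid_x = numeric(0), centroid_y = numeric(0),
                    mean_marker = numeric(0))
  nr <- nrow(lab0)
  for (i in seq_along(keep)) {
    px <- which(lab0 == keep[i])
    lab[px] <- i
    rr <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    per <- rbind(per, data.frame(
      label = i, area = length(px),
      centroid_x = mean(cc), centroid_y = mean(rr),
      mean_marker = mean(img$marker_channel[px])))
  }
  structure(list(label_raster = lab, per_condensate = per,
                 count = length(keep)),
            class = "condensate_labels")
}

#' @export
print.condensate_labels <- function(x, ...) {
  cat(sprintf("condensate_labels: %d condensate(s), %d labeled px\n",
              x$count, sum(x$label_raster > 0)))
  invisible(x)
}

# in-mask pixels farther than `margin` from every condensate pixel
outside_pool_mask <- function(img, labels, margin) {
  cond <- labels$label_raster > 0L
  if (!any(cond)) return(img$nucleus_mask)
  nr <- nrow(cond); nc <- ncol(cond)
  dil <- cond
  m <- ceiling(margin)
  if (m >= 1) {
    px <- which(cond)
    rr <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    for (dr in -m:m) for (dc in -m:m) {
      if (dr * dr + dc * dc > margin^2) next
      r2 <- rr + dr; c2 <- cc + dc
      ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
      dil[(c2[ok] - 1L) * nr + r2[ok]] <- TRUE
    }
  }
  img$nucleus_mask & !dil
}

#' Sample query-channel pixels inside and outside condensates
#'
#' Draws `n_pixels` query-channel intensities uniformly without replacement
#' from condensate-labeled pixels ("inside") and from in-mask pixels farther
#' than `margin` pixels from any condensate pixel ("outside"). The margin
#' avoids partial-volume pixels at condensate edges.
#'
#' @param img a [nucleus_image()].
#' @param labels a `condensate_labels` (from [detect_condensates()] or built
#'   from a ground-truth mask).
#' @param n_pixels pixels per stratum.
#' @param margin exclusion margin around condensates, pixels (default 2).
#' @param seed integer seed for reproducible sampling.
#' @return list with numeric vectors `inside` and `outside`.
#' @export
sample_pixels <- function(img, labels, n_pixels, margin = 2, seed = 1) {
  stopifnot(inherits(img, "nucleus_image"))
  inside_px <- which(labels$label_raster > 0L)
  outside_px <- which(outside_pool_mask(img, labels, margin))
  if (length(inside_px) < n_pixels)
    stopf("insufficient pixels in stratum 'inside': %d available, %d requested",
          length(inside_px), n_pixels)
  if (length(outside_px) < n_pixels)
    stopf("insufficient pixels in stratum 'outside': %d available, %d requested",
          length(outside_px), n_pixels)
  with_seed(seed, {
    ii <- sample(inside_px, n_pixels)
    oo <- sample(outside_px, n_pixels)
    list(inside = img$query_channel[ii], outside = img$query_channel[oo])
  })
}

#' Z-score pixel intensities against a reference population
#'
#' `z = (x - ref_mean) / ref_sd`. The reference is the full in-mask
#' query-channel pixel population of the nucleus (see
#' [nucleus_reference()]), which puts inside and outside samples on one
#' comparable scale per nucleus.
#'
#' @param x numeric intensities.
#' @param ref_mean,ref_sd reference mean and s.d. (`ref_sd > 0`).
#' @return numeric Z-scores.
#' @export
zscore_pixels <- function(x, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) stopf("ref_sd must be > 0")
  (x - ref_mean) / ref_sd
}

#' Per-nucleus Z-score reference statistics
#'
#' Mean and s.d. of all in-mask query-channel pixels of one nucleus.
#'
#' @param img a [nucleus_image()].
#' @return list with `mean` and `sd`.
#' @export
nucleus_reference <- function(img) {
  v <- img$query_channel[img$nucleus_mask]
  list(mean = mean(v), sd = sd(v))
}

#' Inside-vs-outside exclusion test
#'
#' Two-sided Wilcoxon rank-sum test on inside vs outside pixel Z-scores
#' (exact for small untied samples, normal approximation with continuity
#' correction and midranks otherwise). The sign of
#' `median(inside) - median(outside)` gives the direction: negative means
#' the query protein is excluded from condensates.
#'
#' @param inside_z,outside_z numeric Z-score samples (length >= 5 each).
#' @param alpha significance level (default 0.05).
#' @return an `exclusion_report`: `inside_z`, `outside_z`, `n_pixels`,
#'   `delta_median`, `p_raw`, `p_adj` (`NA` until adjusted across a batch
#'   with [adjust_reports()]), `verdict` in
#'   `{"enriched", "excluded", "neutral"}`, `alpha`.
#' @export
exclusion_test <- function(inside_z, outside_z, alpha = 0.05) {
  if (length(inside_z) < 5 || length(outside_z) < 5)
    stopf("each sample must have length >= 5")
  if (length(inside_z) != length(outside_z))
    stopf("inside and outside samples must have equal length")
  all_tied <- length(unique(c(inside_z, outside_z))) == 1L
  p <- if (all_tied) 1 else
    suppressWarnings(wilcox.test(inside_z, outside_z)$p.value)
  dm <- median(inside_z) - median(outside_z)
  rep <- structure(list(inside_z = inside_z, outside_z = outside_z,
                        n_pixels = length(inside_z),
                        delta_median = dm, p_raw = p, p_adj = NA_real_,
                        verdict = NA_character_, alpha = alpha),
                   class = "exclusion_report")
  rep$verdict <- exclusion_verdict(p, dm, alpha)
  rep
}

exclusion_verdict <- function(p, delta_median, alpha) {
  if (!is.finite(p) || p >= alpha || delta_median == 0) "neutral"
  else if (delta_median < 0) "excluded"
  else "enriched"
}

#' @export
print.exclusion_report <- function(x, ...) {
  star <- if (!is.finite(x$p_raw)) "" else if (x$p_raw < 1e-4) " ****"
          else if (x$p_raw < 0.05) " *" else " ns"
  cat(sprintf("exclusion_report: n = %d px/group, delta_median = %.3f\n",
              x$n_pixels, x$delta_median))
  cat(sprintf("  Wilcoxon p = %.3g%s%s -> verdict: %s\n", x$p_raw, star,
              if (is.na(x$p_adj)) "" else sprintf(" (adj %.3g)", x$p_adj),
              x$verdict))
  invisible(x)
}

#' Multiplicity adjustment
#'
#' Adjusts p-values across comparisons: Holm step-down by default,
#' Benjamini-Hochberg selectable. Adjusted values are monotone and never
#' below the raw p.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"holm"` (default) or `"BH"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) stopf("p-values must be in [0, 1]")
  p.adjust(p, method = method)
}

#' Adjust a batch of exclusion reports for multiple comparisons
#'
#' Sets `p_adj` across the reports and recomputes each verdict from the
#' adjusted p-value.
#'
#' @param reports list of `exclusion_report` objects.
#' @param method passed to [adjust_pvalues()].
#' @return the list with `p_adj` and `verdict` updated.
#' @export
adjust_reports <- function(reports, method = c("holm", "BH")) {
  padj <- adjust_pvalues(vapply(reports, function(r) r$p_raw, numeric(1)),
                         method)
  for (i in seq_along(reports)) {
    reports[[i]]$p_adj <- padj[i]
    reports[[i]]$verdict <- exclusion_verdict(padj[i],
                                              reports[[i]]$delta_median,
                                              reports[[i]]$alpha)
  }
  reports
}

# build condensate_labels directly from a logical ground-truth mask
labels_from_mask <- function(mask) {
  lab <- label_components(mask)
  structure(list(label_raster = lab,
                 per_condensate = data.frame(label = seq_len(max(lab))),
                 count = max(lab)),
            class = "condensate_labels")
}

#' Pooled multi-nucleus exclusion analysis
#'
#' The full imaging statistic: for each nucleus, detect condensates (or use
#' ground-truth footprints), draw `n_pixels / n_nuclei` query-channel pixels
#' per stratum, Z-score them against that nucleus's full in-mask pixel
#' population, pool across nuclei, and run the Wilcoxon exclusion test.
#' Defaults mirror a 30-pixel draw across 3 nuclei.
#'
#' @param images list of [nucleus_image()]; the first `n_nuclei` images that
#'   contain at least one condensate are used (imaging experiments select
#'   nuclei that carry condensates), so supplying a few spare images guards
#'   against condensate-free nuclei.
#' @param n_pixels total pixels per stratum across nuclei (default 30).
#' @param n_nuclei nuclei to pool over (default 3).
#' @param truth_masks optional list of logical matrices; when supplied,
#'   condensate footprints are taken from these instead of detection.
#' @param margin,min_area,k_sigma,alpha see [sample_pixels()] and
#'   [detect_condensates()].
#' @param seed integer seed.
#' @return an `exclusion_report` (pooled).
#' @export
exclusion_analysis <- function(images, n_pixels = 30, n_nuclei = 3,
                               truth_masks = NULL, margin = 2,
                               min_area = 4L, k_sigma = 2.5,
                               alpha = 0.05, seed = 1) {
  if (length(images) < n_nuclei)
    stopf("need at least %d images, got %d", n_nuclei, length(images))
  per <- ceiling(n_pixels / n_nuclei)
  inside <- outside <- numeric(0)
  used <- 0L
  for (k in seq_along(images)) {
    if (used >= n_nuclei) break
    img <- images[[k]]
    labs <- if (is.null(truth_masks)) detect_condensates(img, min_area, k_sigma)
            else labels_from_mask(truth_masks[[k]])
    if (labs$count == 0) next              # condensate-free nucleus: skip
    sm <- sample_pixels(img, labs, per, margin = margin,
                        seed = derive_seed(seed, k))
    ref <- nucleus_reference(img)
    inside <- c(inside, zscore_pixels(sm$inside, ref$mean, ref$sd))
    outside <- c(outside, zscore_pixels(sm$outside, ref$mean, ref$sd))
    used <- used + 1L
  }
  if (used < n_nuclei)
    stopf("no condensates found in enough nuclei: %d of %d usable",
          used, n_nuclei)
  inside <- inside[seq_len(n_pixels)]
  outside <- outside[seq_len(n_pixels)]
  exclusion_test(inside, outside, alpha = alpha)
}
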