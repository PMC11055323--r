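# Readers and writers for the package's on-disk interchange formats:
# multi-page TIFF + JSON sidecar for images, CSV for FRAP traces, COO TSV +
# bins table for contact matrices, BED/bedGraph (via rtracklayer) for
# intervals and tracks.

#' Write / read a synthetic image set
#'
#' Each nucleus becomes one channel-major multi-page TIFF (pages: marker,
#' query, mask) plus a shared JSON sidecar holding the ground truth, the
#' per-channel intensity ranges used for TIFF scaling, and the pixel size.
#'
#' @param imgset result of [gen_nucleus_images()], or for the reader the
#'   directory written earlier.
#' @param dir output directory (created if needed).
#' @return `write_image_set()`: the directory, invisibly.
#' @export
write_image_set <- function(imgset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ranges <- list()
  for (img in imgset$images) {
    rng <- range(c(img$marker_channel, img$query_channel))
    if (diff(rng) == 0) rng <- rng + c(0, 1)
    sc <- function(x) (x - rng[1]) / (rng[2] - rng[1])
    pages <- list(sc(img$marker_channel), sc(img$query_channel),
                  matrix(as.numeric(img$nucleus_mask), nrow(img$nucleus_mask)))
    tiff::writeTIFF(pages, file.path(dir, paste0(img$nucleus_id, ".tiff")),
                    bits.per.sample = 16L)
    ranges[[img$nucleus_id]] <- rng
  }
  sidecar <- list(pixel_size = imgset$images[[1]]$pixel_size,
                  ranges = ranges,
                  truth = imgset$truth)
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_image_set
#' @return `read_image_set()`: list with `images` and `truth`.
#' @export
read_image_set <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.tiff$", full.names = TRUE))
  images <- lapply(files, function(f) {
    id <- sub("\\.tiff$", "", basename(f))
    pages <- tiff::readTIFF(f, all = TRUE)
    rng <- unlist(sidecar$ranges[[id]])
    un <- function(x) x * (rng[2] - rng[1]) + rng[1]
    nucleus_image(un(pages[[1]]), un(pages[[2]]), pages[[3]] > 0.5,
                  pixel_size = sidecar$pixel_size, nucleus_id = id)
  })
  truth <- as.data.frame(sidecar$truth)
  list(images = images, truth = truth)
}

#' Write / read FRAP traces as CSV
#'
#' Long format with columns `time`, `bleached`, `unbleached`, `trace_id`.
#'
#' @param traces list of [frap_trace()] objects.
#' @param file CSV path.
#' @param normalized whether the stored traces are on the normalized scale.
#' @return `read_frap_traces()`: list of `frap_trace` objects.
#' @export
write_frap_traces <- function(traces, file) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df[, c("time", "bleached", "unbleached", "trace_id")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_frap_traces
#' @export
read_frap_traces <- function(file, normalized = TRUE) {
  df <- utils::read.csv(file)
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time), ]
    frap_trace(d$time, d$bleached, d$unbleached, trace_id = d$trace_id[1],
               normalized = normalized)
  })
}

#' Write / read a contact matrix as COO triplets plus a bins table
#'
#' The COO TSV has columns `bin_i`, `bin_j`, `count` (0-based bin ids,
#' upper triangle including the diagonal); the bins table is BED-like:
#' `chrom`, `start`, `end`, `bin_id` (0-based half-open).
#'
#' @param m a [contact_matrix()].
#' @param coo_file,bins_file TSV paths.
#' @return `read_contact_matrix()`: a `contact_matrix`.
#' @export
write_contact_matrix <- function(m, coo_file, bins_file) {
  stopifnot(inherits(m, "contact_matrix"))
  up <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  coo <- data.frame(bin_i = m$bins$bin_id[up[, 1]],
                    bin_j = m$bins$bin_id[up[, 2]],
                    count = m$counts[up])
  utils::write.table(coo, coo_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(m$bins, bins_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(coo_file)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(coo_file, bins_file) {
  coo <- utils::read.table(coo_file, header = TRUE, sep = "\t")
  bins <- utils::read.table(bins_file, header = TRUE, sep = "\t")
  n <- nrow(bins)
  id2row <- match(c(coo$bin_i, coo$bin_j), bins$bin_id)
  if (anyNA(id2row)) stopf("COO bin ids missing from the bins table")
  cnt <- matrix(0, n, n)
  ii <- id2row[seq_len(nrow(coo))]
  jj <- id2row[nrow(coo) + seq_len(nrow(coo))]
  cnt[cbind(ii, jj)] <- coo$count
  cnt[cbind(jj, ii)] <- coo$count
  contact_matrix(cnt, bins = bins,
                 bin_size = bins$end[1] - bins$start[1])
}

#' Read a dense contact matrix from TSV
#'
#' A square whitespace-separated numeric table, no header.
#'
#' @param file TSV path.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix_dense <- function(file, bin_size = 20000, chrom = "chrS") {
  cnt <- as.matrix(utils::read.table(file, header = FALSE))
  dimnames(cnt) <- NULL
  contact_matrix(cnt, bin_size = bin_size, chrom = chrom)
}

#' BED and bedGraph IO
#'
#' Thin wrappers over rtracklayer import/export, converting between the
#' package's plain data-frame representations (0-based half-open) and GRanges.
#'
#' @param x a [peak_set()] (`write_bed`) or a track data frame with `chrom`,
#'   `start`, `end`, `value` (`write_bedgraph`).
#' @param file path.
#' @return readers return a `peak_set` / track data frame.
#' @export
write_bed <- function(x, file) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1, x$end),
                               name = x$name)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_bed
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  peak_set(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr),
                      name = if (!is.null(gr$name)) gr$name else
                        sprintf("peak_%04d", seq_along(gr))))
}

#' @rdname write_bed
#' @export
write_bedgraph <- function(x, file) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1, x$end),
                               score = x$value)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_bed
#' @export
read_bedgraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Bin a bedGraph track onto a matrix's bin grid
#'
#' Each bin takes the mean track signal over its bases; bases without
#' coverage count as 0 (the bedGraph gap convention).
#'
#' @param track track data frame (`chrom`, `start`, `end`, `value`).
#' @param bins bins table of a [contact_matrix()].
#' @return a [bin_track()].
#' @export
bin_bedgraph <- function(track, bins) {
  sig <- numeric(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    tr <- track[track$chrom == bins$chrom[i] &
                track$end > bins$start[i] & track$start < bins$end[i], ,
                drop = FALSE]
    if (!nrow(tr)) next
    ov <- pmin(tr$end, bins$end[i]) - pmax(tr$start, bins$start[i])
    sig[i] <- sum(tr$value * ov) / (bins$end[i] - bins$start[i])
  }
  bin_track(bins, sig)
}
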