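# Colocalization of myelin (MBP) and axon (NF200) immunofluorescence:
# maximum projection, thresholding, and the two reported metrics --
# the NF200 pixel fraction (axonal density, percent of image area) and the
# MBP/NF200 overlap ratio (myelination normalised against axonal density,
# which makes the ratio insensitive to MBP signal outside the axon mask).

#' Maximum-intensity projection of an image stack
#'
#' @param stack Numeric array `planes x rows x cols`, or a single matrix
#'   (returned unchanged).
#' @return Matrix of per-pixel maxima across planes.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (length(dim(stack)) != 3) stop2("stack must be planes x rows x cols")
  Reduce(pmax, lapply(seq_len(dim(stack)[1]), function(p) stack[p, , ]))
}

#' Threshold an intensity image into a binary mask
#'
#' @param plane Numeric matrix of intensities.
#' @param method `"otsu"` (Otsu's threshold on a 256-level histogram, via
#'   EBImage) or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"`; pixels strictly
#'   above it are foreground.
#' @return Logical matrix with attributes `method` and `threshold` recording
#'   what was applied.
#' @export
make_mask <- function(plane, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(plane)
    if (diff(rng) == 0)
      stop2("constant image: Otsu threshold undefined; use method='fixed'")
    scaled <- (plane - rng[1]) / diff(rng)
    t01 <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
    threshold <- t01 * diff(rng) + rng[1]
  } else {
    if (is.null(threshold)) stop2("method='fixed' requires a threshold")
  }
  mask <- plane > threshold
  attr(mask, "method") <- method
  attr(mask, "threshold") <- threshold
  mask
}

#' Colocalization metrics from two binary masks
#'
#' `nf200_pixel_fraction` is the percentage of image area covered by the
#' NF200 (axon) mask; `mbp_nf200_ratio` is the overlap |MBP and NF200| /
#' |NF200|, i.e. myelination normalised against axonal density. An optional
#' dilation of the MBP mask (square structuring element) can absorb small
#' chromatic offsets; the default is none.
#'
#' @param nf200_mask,mbp_mask Logical matrices of equal dimensions.
#' @param dilation_radius Integer pixel radius for dilating the MBP mask
#'   before overlap (default 0).
#' @return One-row data frame with `nf200_pixel_fraction` (percent),
#'   `mbp_nf200_ratio` (0-1, `NA` with a warning if the NF200 mask is empty),
#'   `n_nf200_px` and `n_overlap_px`.
#' @export
coloc_metrics <- function(nf200_mask, mbp_mask, dilation_radius = 0L) {
  if (!identical(dim(nf200_mask), dim(mbp_mask)))
    stop2("masks must have identical dimensions")
  if (dilation_radius > 0) {
    kern <- matrix(1, 2 * dilation_radius + 1, 2 * dilation_radius + 1)
    mbp_mask <- EBImage::dilate(mbp_mask * 1, kern) > 0
  }
  n_nf <- sum(nf200_mask)
  n_ov <- sum(nf200_mask & mbp_mask)
  ratio <- if (n_nf == 0) {
    warning("empty NF200 mask: MBP/NF200 ratio undefined", call. = FALSE)
    NA_real_
  } else n_ov / n_nf
  data.frame(nf200_pixel_fraction = 100 * n_nf / length(nf200_mask),
             mbp_nf200_ratio = ratio,
             n_nf200_px = n_nf, n_overlap_px = n_ov)
}

#' Analyse one NF200/MBP stack pair
#'
#' Maximum-projects both channels, thresholds each, and computes the
#' colocalization metrics. Threshold method and values are recorded in the
#' output for provenance.
#'
#' @param nf200,mbp Numeric stacks (`planes x rows x cols`) or matrices.
#' @param method,threshold Passed to [make_mask()] (per channel).
#' @param dilation_radius Passed to [coloc_metrics()].
#' @return One-row data frame with metrics plus `threshold_method`,
#'   `nf200_threshold`, `mbp_threshold`.
#' @export
analyze_coloc_pair <- function(nf200, mbp, method = "otsu", threshold = NULL,
                               dilation_radius = 0L) {
  mn <- make_mask(max_project(nf200), method, threshold)
  mm <- make_mask(max_project(mbp), method, threshold)
  out <- coloc_metrics(mn, mm, dilation_radius)
  out$threshold_method <- attr(mn, "method")
  out$nf200_threshold <- attr(mn, "threshold")
  out$mbp_threshold <- attr(mm, "threshold")
  out
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into a
#' `planes x rows x cols` array of raw intensities.
#'
#' @param path TIFF file path.
#' @param scale Multiplier applied to the values returned by the TIFF reader
#'   (which maps integer data to 0-1); default 65535 restores 16-bit counts.
#' @return Numeric array `planes x rows x cols`.
#' @export
read_channel_stack <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (p in seq_along(pages)) arr[p, , ] <- pages[[p]] * scale
  arr
}

#' Write a stack as a multi-page 16-bit TIFF
#'
#' @param stack Numeric array `planes x rows x cols`; values are scaled by
#'   `1/scale` and clipped to 0-1 before writing.
#' @param path Output path.
#' @param scale Intensity corresponding to full scale (default 65535).
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path, scale = 65535) {
  pages <- lapply(seq_len(dim(stack)[1]), function(p)
    pmin(pmax(stack[p, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Analyse a directory of NF200/MBP TIFF pairs
#'
#' Pairs files by shared basename: `<name><nf_suffix>.tif` with
#' `<name><mbp_suffix>.tif`.
#'
#' @param dir Directory of TIFF files.
#' @param nf_suffix,mbp_suffix Channel filename suffixes (before the
#'   extension).
#' @param ... Passed to [analyze_coloc_pair()].
#' @return Data frame, one row per image pair, with an `image` column.
#' @export
analyze_coloc_dir <- function(dir, nf_suffix = "_nf200", mbp_suffix = "_mbp",
                              ...) {
  nf_files <- sort(list.files(dir, pattern = paste0(nf_suffix,
                                                    "\\.tiff?$"),
                              full.names = TRUE, ignore.case = TRUE))
  if (length(nf_files) == 0) stop2("no '*", nf_suffix, ".tif' files in ", dir)
  rows <- lapply(nf_files, function(nf) {
    base <- sub(paste0(nf_suffix, "\\.tiff?$"), "", basename(nf),
                ignore.case = TRUE)
    mbp <- list.files(dir, pattern = paste0("^", base, mbp_suffix,
                                            "\\.tiff?$"),
                      full.names = TRUE, ignore.case = TRUE)
    if (length(mbp) != 1)
      stop2("no unique MBP partner for ", basename(nf))
    out <- analyze_coloc_pair(read_channel_stack(nf),
                              read_channel_stack(mbp), ...)
    out$image <- base
    out
  })
  res <- do.call(rbind, rows)
  res[, c("image", setdiff(names(res), "image"))]
}
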