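# Synthetic two-channel fiber/myelin image stacks with known pixel-level
# ground truth, emulating NF200 (axon) / MBP (myelin) immunofluorescence:
# roughly tract-aligned fibers of a few pixels width distributed across
# focal planes, with MBP signal drawn over a configured fraction of each
# fiber's length (contiguous internode-like runs), plus Gaussian noise.

#' Image generator parameters
#'
#' @param n_fibers Number of fibers.
#' @param width_px Fiber width, pixels.
#' @param coverage Fraction of each fiber's length covered by MBP signal
#'   (0-1).
#' @param noise_sd Gaussian noise standard deviation (intensity counts).
#' @param background,signal Mean background and signal intensities.
#' @param nrow,ncol Image size, pixels.
#' @param n_planes Number of focal planes in each stack.
#' @param pixel_size Micrometres per pixel (metadata only).
#' @param max_slope Maximum fiber slope (rows per column).
#' @return An object of class `image_params`.
#' @export
image_params <- function(n_fibers = 9, width_px = 3, coverage = 0.4,
                         noise_sd = 4, background = 10, signal = 200,
                         nrow = 128, ncol = 128, n_planes = 3,
                         pixel_size = 0.25, max_slope = 0.1) {
  stopifnot(coverage >= 0, coverage <= 1, n_fibers >= 1, width_px >= 1,
            noise_sd >= 0, signal > background, n_planes >= 1)
  structure(as.list(environment()), class = "image_params")
}

#' Generate one synthetic NF200/MBP stack pair with ground truth
#'
#' @param params An [image_params()] object.
#' @param seed Integer seed.
#' @return List with `nf200` and `mbp` (numeric `planes x rows x cols`
#'   arrays), and `truth`: logical ground-truth masks `nf_mask` and
#'   `mbp_mask`, the exact `true_ratio` |MBP and NF200|/|NF200|, the true
#'   `nf_fraction` (percent), and the configured `coverage`.
#' @export
generate_coloc_image <- function(params = image_params(), seed = NULL) {
  stopifnot(inherits(params, "image_params"))
  P <- params
  with_seed(seed, {
    nf_mask <- matrix(FALSE, P$nrow, P$ncol)
    mbp_mask <- matrix(FALSE, P$nrow, P$ncol)
    nf <- array(stats::rnorm(P$n_planes * P$nrow * P$ncol,
                             P$background, P$noise_sd),
                dim = c(P$n_planes, P$nrow, P$ncol))
    mbp <- array(stats::rnorm(P$n_planes * P$nrow * P$ncol,
                              P$background, P$noise_sd),
                 dim = c(P$n_planes, P$nrow, P$ncol))
    half <- (P$width_px - 1) / 2
    for (f in seq_len(P$n_fibers)) {
      r0 <- stats::runif(1, 1 + half, P$nrow - half)
      slope <- stats::runif(1, -P$max_slope, P$max_slope)
      plane <- sample.int(P$n_planes, 1)
      # contiguous MBP run along the fiber
      k <- round(P$coverage * P$ncol)
      run_start <- if (k < P$ncol) sample.int(P$ncol - k + 1L, 1) else 1L
      covered_cols <- if (k > 0) seq(run_start, run_start + k - 1L) else integer(0)
      for (col in seq_len(P$ncol)) {
        rc <- r0 + slope * (col - P$ncol / 2)
        rows <- round(rc - half):round(rc + half)
        rows <- rows[rows >= 1 & rows <= P$nrow]
        nf_mask[rows, col] <- TRUE
        nf[plane, rows, col] <- P$signal + stats::rnorm(length(rows), 0,
                                                        P$noise_sd)
        if (col %in% covered_cols) {
          mbp_mask[rows, col] <- TRUE
          mbp[plane, rows, col] <- P$signal + stats::rnorm(length(rows), 0,
                                                           P$noise_sd)
        }
      }
    }
    nf <- pmax(nf, 0)
    mbp <- pmax(mbp, 0)
    truth <- list(
      nf_mask = nf_mask, mbp_mask = mbp_mask,
      true_ratio = sum(mbp_mask & nf_mask) / sum(nf_mask),
      nf_fraction = 100 * sum(nf_mask) / length(nf_mask),
      coverage = P$coverage
    )
    list(nf200 = nf, mbp = mbp, truth = truth, params = P)
  })
}

#' Write a synthetic image pair as TIFF files with a truth sidecar
#'
#' Writes `<basename>_nf200.tif`, `<basename>_mbp.tif` (multi-page 16-bit)
#' and `<basename>_truth.json`.
#'
#' @param img Result of [generate_coloc_image()].
#' @param dir Output directory.
#' @param basename File basename.
#' @return Files written, invisibly.
#' @export
write_coloc_pair <- function(img, dir, basename = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(nf200 = file.path(dir, paste0(basename, "_nf200.tif")),
             mbp = file.path(dir, paste0(basename, "_mbp.tif")),
             truth = file.path(dir, paste0(basename, "_truth.json")))
  write_channel_stack(img$nf200, files["nf200"])
  write_channel_stack(img$mbp, files["mbp"])
  jsonlite::write_json(
    list(true_ratio = img$truth$true_ratio,
         nf_fraction = img$truth$nf_fraction,
         coverage = img$truth$coverage),
    files["truth"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
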