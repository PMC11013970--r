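#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in dB. Identical frames (MSE = 0) return
#' `Inf`. For synthetic data pass the known ground-truth range; for real
#' data without ground truth any PSNR is only as meaningful as its
#' reference.
#'
#' @param reference,test numeric arrays of identical shape.
#' @param data_range positive scalar; defaults to the range of the
#'   reference.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = NULL) {
  if (!identical(dim(reference), dim(test)) ||
      length(reference) != length(test))
    stop("shape mismatch between reference and test")
  if (is.null(data_range)) data_range <- diff(range(reference))
  if (data_range <= 0) stop("`data_range` must be positive")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# Normalized 2-D Gaussian kernel.
gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 'valid'-mode 2-D convolution (kernel fully inside the image), via FFT.
conv2_valid <- function(img, kern) {
  di <- dim(img); dk <- dim(kern)
  if (any(dk > di)) stop("kernel larger than image")
  pd <- di + dk - 1L
  a <- matrix(0, pd[1], pd[2]); a[seq_len(di[1]), seq_len(di[2])] <- img
  b <- matrix(0, pd[1], pd[2]); b[seq_len(dk[1]), seq_len(dk[2])] <- kern
  full <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) /
    prod(pd)
  full[dk[1]:di[1], dk[2]:di[2], drop = FALSE]
}

#' Mean squared error and structural similarity
#'
#' MSE is the plain pixel mean of squared differences. SSIM follows the
#' standard formulation: local means, variances and covariance under a
#' Gaussian window (sigma 1.5, 11 x 11), stabilizers `C1 = (K1 d)^2`,
#' `C2 = (K2 d)^2` with `K1 = 0.01`, `K2 = 0.03` and `d` the data range of
#' the reference; the score is the mean of the local SSIM map over all
#' fully-covered (valid) windows. SSIM is symmetric in its arguments and
#' lies in [-1, 1].
#'
#' @param reference,test numeric matrices (single frames) of equal shape.
#' @param data_range positive scalar; defaults to the reference range.
#' @param window_size,sigma Gaussian window parameters.
#' @param K1,K2 stabilizing constants.
#' @return list with `mse`, `ssim`, and the constants used.
#' @export
mse_ssim <- function(reference, test, data_range = NULL,
                     window_size = 11L, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03) {
  reference <- as.matrix(reference); test <- as.matrix(test)
  if (!identical(dim(reference), dim(test)))
    stop("shape mismatch between reference and test")
  if (is.null(data_range)) data_range <- diff(range(reference))
  if (data_range <= 0) data_range <- max(abs(reference), 1e-12)
  mse <- mean((reference - test)^2)
  w <- gaussian_kernel(window_size, sigma)
  mu1 <- conv2_valid(reference, w)
  mu2 <- conv2_valid(test, w)
  s11 <- conv2_valid(reference^2, w) - mu1^2
  s22 <- conv2_valid(test^2, w) - mu2^2
  s12 <- conv2_valid(reference * test, w) - mu1 * mu2
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  list(mse = mse, ssim = mean(map),
       constants = list(window_size = window_size, sigma = sigma,
                        K1 = K1, K2 = K2, data_range = data_range))
}

#' Integrated intensity profile
#'
#' Per-frame sum of intensities along the stack axis — the standard 1-D
#' summary for judging whether a reconstruction assigns structure to the
#' right frames (mode mixing shows up immediately here).
#'
#' @param stack an [image_stack].
#' @return numeric vector of length `m`.
#' @export
integrated_intensity <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$data, 3, sum)
}

#' Singular-value spectrum of a stack
#'
#' Full singular spectrum of the snapshot matrix, plus the index at which
#' the spectrum flattens into the noise plateau: the first position where
#' the ratio of consecutive values exceeds `1 - epsilon`.
#'
#' @param stack an [image_stack] with at least 2 frames.
#' @param epsilon plateau-detection tolerance.
#' @return list with `values` (descending) and `plateau_index`
#'   (`NA` if the spectrum never flattens).
#' @export
singular_spectrum <- function(stack, epsilon = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_frames(stack) < 2L) stop("need at least 2 frames")
  d <- svd(to_snapshot_matrix(stack)$matrix, nu = 0, nv = 0)$d
  ratio <- d[-1] / d[-length(d)]
  idx <- which(ratio > 1 - epsilon)
  list(values = d,
       plateau_index = if (length(idx)) idx[1] else NA_integer_)
}

#' Numerical rank of a single frame
#'
#' Count of singular values above `tolerance * largest`. Default tolerance
#' is the usual numerical-rank convention `max(dim) * eps`; the result is
#' tolerance-dependent, so the tolerance is configurable.
#'
#' @param frame numeric matrix.
#' @param tolerance relative threshold.
#' @return integer rank (0 for an all-zero frame).
#' @export
frame_rank <- function(frame, tolerance = NULL) {
  frame <- as.matrix(frame)
  d <- svd(frame, nu = 0, nv = 0)$d
  if (d[1] == 0) return(0L)
  if (is.null(tolerance)) tolerance <- max(dim(frame)) * .Machine$double.eps
  sum(d > tolerance * d[1])
}

#' Frame-wise quality report between two stacks
#'
#' PSNR, MSE and SSIM per frame of `test` against `reference`, with the
#' integrated-intensity profiles of both, the singular spectrum of the
#' reference, and the SSIM constants used.
#'
#' @param reference,test [image_stack]s of identical shape.
#' @param data_range scalar used for PSNR and SSIM; defaults to the range
#'   of the reference stack.
#' @return A `quality_report`: list with data.frame `per_frame` and the
#'   profiles.
#' @export
quality_report <- function(reference, test, data_range = NULL) {
  stopifnot(inherits(reference, "image_stack"), inherits(test, "image_stack"))
  if (!identical(dim(reference$data), dim(test$data)))
    stop("shape mismatch between reference and test stacks")
  if (is.null(data_range)) data_range <- diff(range(reference$data))
  m <- n_frames(reference)
  per <- do.call(rbind, lapply(seq_len(m), function(k) {
    ref <- reference$data[, , k]; te <- test$data[, , k]
    ms <- mse_ssim(ref, te, data_range = data_range)
    data.frame(frame = k, coordinate = frame_coords(reference, k),
               psnr = psnr(ref, te, data_range), mse = ms$mse,
               ssim = ms$ssim)
  }))
  structure(list(per_frame = per,
                 intensity_reference = integrated_intensity(reference),
                 intensity_test = integrated_intensity(test),
                 spectrum = if (m >= 2) singular_spectrum(reference)$values
                            else NULL,
                 data_range = data_range),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d frames\n", nrow(x$per_frame)))
  cat(sprintf("  PSNR [%.2f, %.2f] dB, SSIM [%.4f, %.4f], mean MSE %.4g\n",
              min(x$per_frame$psnr), max(x$per_frame$psnr),
              min(x$per_frame$ssim), max(x$per_frame$ssim),
              mean(x$per_frame$mse)))
  invisible(x)
}
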