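#' Reconstruct frames at integer indices
#'
#' Evaluates the discrete DMD expansion
#' `x_k = Re( sum_j phi_j lambda_j^(k-1) b_j )` at the requested frame
#' indices. The real part is taken for the output stack; the largest
#' discarded imaginary magnitude is attached as attribute
#' `imag_residual` (for a model of real data fitted with conjugate-closed
#' spectra it is at numerical-noise level).
#'
#' @param model a `dmd_model` from [fit_dmd()] or [fit_hodmd()].
#' @param frame_indices integer frame indices (>= 1); defaults to all
#'   frames the model was fitted on.
#' @return An [image_stack] of the reconstructed frames.
#' @export
reconstruct <- function(model, frame_indices = seq_len(model$n_frames)) {
  stopifnot(inherits(model, "dmd_model"))
  if (any(frame_indices < 1)) stop("frame indices must be >= 1")
  lam <- model$eigenvalues
  wb <- model$amplitudes
  cols <- vapply(frame_indices,
                 function(k) drop(model$modes %*% (wb * lambda_power(lam, k - 1))),
                 complex(nrow(model$modes)))
  cols <- matrix(cols, nrow = nrow(model$modes))
  out <- from_snapshot_matrix(Re(cols), model$frame_shape, model$axis_kind,
                              model$step,
                              model$origin + (frame_indices[1] - 1) * model$step)
  attr(out, "imag_residual") <- max(abs(Im(cols)))
  out
}

#' Predict frames at arbitrary (fractional) stack coordinates
#'
#' Evaluates the continuous form `x(c) = Re( sum_j phi_j e^{omega_j (c -
#' origin)} b_j )` at coordinates along the stack axis, enabling axial
#' up-sampling: interpolation of frames that were never acquired. At
#' coordinates of integer frames this agrees with [reconstruct()] to
#' round-off. Positions outside the acquired range are refused unless
#' `allow_extrapolation = TRUE` — the linearized dynamics are not trusted
#' outside the data window. Modes with `lambda = 0` have no continuous
#' representation and are skipped with a diagnostic message.
#'
#' @param model a `dmd_model`.
#' @param positions coordinates (same units as `model$step`).
#' @param allow_extrapolation permit positions outside
#'   `[origin, origin + (m-1) step]`.
#' @return An [image_stack] of predicted frames (step set to the median
#'   position spacing, or the model step for a single position).
#' @export
predict_frames <- function(model, positions, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "dmd_model"))
  lo <- model$origin
  hi <- model$origin + (model$n_frames - 1) * model$step
  eps <- 1e-9 * model$step
  if (!allow_extrapolation &&
      (any(positions < lo - eps) || any(positions > hi + eps)))
    stop("positions outside the acquired range [", lo, ", ", hi,
         "]; pass allow_extrapolation = TRUE to force")
  zero <- attr(model$omegas, "zero_modes")
  keep <- !zero
  if (any(zero))
    message(sum(zero), " mode(s) with lambda = 0 skipped in continuous ",
            "evaluation")
  om <- model$omegas[keep]
  wb <- model$amplitudes[keep]
  Phi <- model$modes[, keep, drop = FALSE]
  cols <- vapply(positions,
                 function(p) drop(Phi %*% (wb * exp(om * (p - lo)))),
                 complex(nrow(Phi)))
  cols <- matrix(cols, nrow = nrow(Phi))
  stp <- if (length(positions) > 1) stats::median(diff(positions))
         else model$step
  out <- from_snapshot_matrix(Re(cols), model$frame_shape, model$axis_kind,
                              max(stp, .Machine$double.eps), positions[1])
  attr(out, "imag_residual") <- max(abs(Im(cols)))
  out
}

#' Down-sample a stack by a keep stride
#'
#' Keeps frames `1, 1+s, 1+2s, ...` (so a 40-frame stack at stride 3 keeps
#' 14 frames) and records which original indices were kept and which must
#' be predicted. The kept stack's step is `s` times the original, so
#' coordinates of the removed frames are fractional multiples of the new
#' step — exactly what [predict_frames()] consumes.
#'
#' @param stack an [image_stack].
#' @param stride integer keep stride, >= 2.
#' @return list with `stack` (the down-sampled [image_stack]) and `plan`
#'   (an `interpolation_plan`: `keep_stride`, `kept_indices`,
#'   `predicted_indices`, `original_coords`).
#' @export
downsample <- function(stack, stride) {
  stopifnot(inherits(stack, "image_stack"))
  stride <- as.integer(stride)
  if (stride < 2L) stop("`stride` must be >= 2")
  m <- n_frames(stack)
  kept <- seq(1L, m, by = stride)
  predicted <- setdiff(seq_len(m), kept)
  ds <- image_stack(stack$data[, , kept, drop = FALSE], stack$axis_kind,
                    stack$step * stride, stack$origin)
  plan <- structure(
    list(keep_stride = stride, kept_indices = kept,
         predicted_indices = predicted,
         original_coords = frame_coords(stack)),
    class = "interpolation_plan")
  list(stack = ds, plan = plan)
}

#' Pixel-wise linear interpolation between bracketing frames
#'
#' The baseline against which DMD frame prediction is judged. At existing
#' frame coordinates the frame is returned unchanged; in between, each
#' pixel is linearly interpolated between the two bracketing frames.
#'
#' @param stack an [image_stack].
#' @param positions coordinates within the stack's range.
#' @return An [image_stack] of interpolated frames.
#' @export
linear_interpolate <- function(stack, positions) {
  stopifnot(inherits(stack, "image_stack"))
  co <- frame_coords(stack)
  eps <- 1e-9 * stack$step
  if (any(positions < co[1] - eps) || any(positions > co[length(co)] + eps))
    stop("positions outside the stack coordinate range")
  d <- dim(stack$data)
  out <- array(0, c(d[1], d[2], length(positions)))
  for (i in seq_along(positions)) {
    f <- (positions[i] - stack$origin) / stack$step + 1
    k0 <- max(1L, min(d[3] - 1L, floor(f)))
    w <- f - k0
    if (d[3] == 1L) { out[, , i] <- stack$data[, , 1]; next }
    out[, , i] <- (1 - w) * stack$data[, , k0] + w * stack$data[, , k0 + 1L]
  }
  stp <- if (length(positions) > 1) stats::median(diff(positions))
         else stack$step
  image_stack(out, stack$axis_kind, max(stp, .Machine$double.eps),
              positions[1])
}

#' Per-frame quality of interpolated frames
#'
#' For every predicted frame of an interpolation plan, computes MSE and
#' SSIM of the DMD prediction and of the linear baseline against the
#' reference stack, plus integrated-intensity profiles. Note that because
#' DMD denoises, it can score a *higher* MSE than linear interpolation on
#' noisy references while being visually cleaner; SSIM is less sensitive
#' to that.
#'
#' @param truth reference [image_stack] (all original frames).
#' @param plan an `interpolation_plan` from [downsample()].
#' @param dmd_result [image_stack] of DMD-predicted frames at all original
#'   positions, or only at `plan$predicted_indices` (in that order).
#' @param linear_result same, for the linear baseline.
#' @return data.frame with columns `frame_index`, `coordinate`, `method`,
#'   `mse`, `ssim`, `integrated_intensity`.
#' @export
evaluate_interpolation <- function(truth, plan, dmd_result, linear_result) {
  stopifnot(inherits(truth, "image_stack"),
            inherits(plan, "interpolation_plan"))
  pick <- function(res) {
    if (n_frames(res) == n_frames(truth))
      res$data[, , plan$predicted_indices, drop = FALSE]
    else if (n_frames(res) == length(plan$predicted_indices))
      res$data
    else stop("result stack has neither all frames nor exactly the ",
              "predicted frames")
  }
  dmd <- pick(dmd_result); lin <- pick(linear_result)
  if (!identical(dim(dmd)[1:2], dim(truth$data)[1:2]))
    stop("frame shape mismatch between truth and results")
  dr <- diff(range(truth$data))
  rows <- lapply(seq_along(plan$predicted_indices), function(i) {
    k <- plan$predicted_indices[i]
    ref <- truth$data[, , k]
    do.call(rbind, lapply(list(dmd = dmd[, , i], lin = lin[, , i]),
      function(fr) {
        ms <- mse_ssim(ref, fr, data_range = dr)
        data.frame(frame_index = k, coordinate = plan$original_coords[k],
                   mse = ms$mse, ssim = ms$ssim,
                   integrated_intensity = sum(fr))
      }))
  })
  out <- do.call(rbind, rows)
  out$method <- rep(c("dmd", "linear"), length(plan$predicted_indices))
  rownames(out) <- NULL
  out[, c("frame_index", "coordinate", "method", "mse", "ssim",
          "integrated_intensity")]
}
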