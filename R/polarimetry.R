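#' Classify dynamic modes as oscillatory, decaying or constant
#'
#' An eigenvalue is oscillatory when its relative imaginary part exceeds
#' `imag_tol` (a complex-conjugate pair counts as two modes). Among the
#' real-classified eigenvalues, those with `|lambda| < 1 - unit_tol` are
#' decaying (photobleaching-type), those with `||lambda| - 1| <= unit_tol`
#' are constant (static background). Growing real modes
#' (`|lambda| > 1 + unit_tol`) fall in none of the three bins, so the
#' counts sum to at most the model rank.
#'
#' The defaults separate Poisson-noise jitter from genuine orientation
#' oscillation at the photon budgets the synthetic generator emulates.
#'
#' @param model a `dmd_model`.
#' @param imag_tol relative imaginary-part threshold.
#' @param unit_tol tolerance around the unit circle.
#' @return list with `n_oscillatory`, `n_decaying`, `n_constant`.
#' @export
classify_modes <- function(model, imag_tol = 1e-3, unit_tol = 1e-3) {
  lam <- if (inherits(model, "dmd_model")) model$eigenvalues
         else as.complex(model)
  mod <- Mod(lam)
  osc <- abs(Im(lam)) / pmax(mod, .Machine$double.xmin) > imag_tol
  real_part <- !osc
  decaying <- real_part & mod < 1 - unit_tol
  constant <- real_part & abs(mod - 1) <= unit_tol
  list(n_oscillatory = sum(osc), n_decaying = sum(decaying),
       n_constant = sum(constant))
}

# Indices of strict local maxima of a circular profile (wrap-around).
circular_peaks <- function(profile) {
  n <- length(profile)
  if (n < 3L) return(integer(0))
  prev <- profile[c(n, seq_len(n - 1L))]
  nxt <- profile[c(seq_len(n)[-1], 1L)]
  which(profile > prev & profile > nxt)
}

#' Analyze a two-photon polarimetry angle sweep
#'
#' Fits a (Ho)DMD model to an angle-indexed stack, reconstructs it,
#' computes the integrated-intensity profile versus polarization angle,
#' finds the intensity peaks of the reconstructed (denoised) profile, and
#' classifies the modes. The peaks of the angle profile locate the
#' predominant probe orientation (a cos 2-theta response gives two peaks
#' 180 degrees apart); real eigenvalues slightly below unity quantify
#' photobleaching over the sweep, which a plain Fourier decomposition
#' cannot absorb.
#'
#' @param stack an [image_stack] with `axis_kind = "angle"`, at least 4
#'   equally spaced angles, step in degrees.
#' @param d delay for [fit_hodmd()]; `d = 1` uses plain [fit_dmd()].
#'   Six shifts is a good default for angle sweeps; very large delays
#'   (e.g. 20) fit noise and trigger the overfitting warning.
#' @param policy a [rank_policy()].
#' @param imag_tol,unit_tol passed to [classify_modes()].
#' @return A `polarimetry_report`: peak angles (degrees in [0, 360)),
#'   mode counts, decaying real eigenvalue moduli
#'   (`bleaching_eigenvalues`), angle profiles (raw and reconstructed) and
#'   the fitted model.
#' @export
analyze_polarimetry <- function(stack, d = 6L,
                                policy = rank_policy("hard_threshold"),
                                imag_tol = 1e-3, unit_tol = 1e-3) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axis_kind != "angle")
    stop("polarimetry analysis requires an angle-axis stack")
  if (n_frames(stack) < 4L) stop("need at least 4 angles")
  model <- if (d == 1L) fit_dmd(stack, policy)
           else fit_hodmd(stack, d, policy)
  recon <- reconstruct(model)
  prof_raw <- integrated_intensity(stack)
  prof_rec <- integrated_intensity(recon)
  angles <- frame_coords(stack) %% 360
  flat <- diff(range(prof_rec)) <=
    1e-6 * max(abs(prof_rec), .Machine$double.eps)
  peaks <- if (flat) integer(0) else circular_peaks(prof_rec)
  cls <- classify_modes(model, imag_tol, unit_tol)
  lam <- model$eigenvalues
  mod <- Mod(lam)
  real_dec <- abs(Im(lam)) / pmax(mod, .Machine$double.xmin) <= imag_tol &
    mod < 1 - unit_tol & mod > 0
  structure(
    list(peak_angles = sort(angles[peaks]),
         n_oscillatory = cls$n_oscillatory,
         n_decaying = cls$n_decaying, n_constant = cls$n_constant,
         bleaching_eigenvalues = sort(mod[real_dec], decreasing = TRUE),
         flat_profile = flat, angles = angles,
         profile_raw = prof_raw, profile_reconstructed = prof_rec,
         model = model),
    class = "polarimetry_report")
}

#' @export
print.polarimetry_report <- function(x, ...) {
  cat("<polarimetry_report>\n")
  cat(sprintf("  peaks at: %s deg\n",
              if (length(x$peak_angles)) paste(round(x$peak_angles, 1),
                                               collapse = ", ")
              else if (x$flat_profile) "none (flat profile)" else "none"))
  cat(sprintf("  modes: %d oscillatory, %d decaying, %d constant\n",
              x$n_oscillatory, x$n_decaying, x$n_constant))
  if (length(x$bleaching_eigenvalues))
    cat(sprintf("  bleaching eigenvalue(s): %s\n",
                paste(round(x$bleaching_eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' Compare mean-subtracted DMD with the discrete Fourier transform
#'
#' Subtracting the temporal mean of every pixel removes the non-oscillatory
#' content, and DMD of the centred data becomes the temporal DFT: all
#' eigenvalues move onto the unit circle at roots of unity
#' `exp(2 pi i q / m)`. This routine mean-subtracts, fits DMD at the
#' numerical rank of the centred matrix, and tabulates each eigenvalue
#' angle against the nearest DFT bin. A constant stack is entirely removed
#' by centring; that case is reported as an empty table with
#' `note = "no signal after mean subtraction"`.
#'
#' @param stack an [image_stack] with at least 3 frames.
#' @return data.frame with `re_lambda`, `im_lambda`, `modulus`, `angle`,
#'   `nearest_dft_angle`, `mismatch`; attributes `max_mismatch`,
#'   `max_modulus_deviation`, and `note`.
#' @export
dft_compare <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  m <- n_frames(stack)
  if (m < 3L) stop("need at least 3 frames")
  snap <- to_snapshot_matrix(stack)
  Xc <- snap$matrix - rowMeans(snap$matrix)
  empty <- data.frame(re_lambda = numeric(0), im_lambda = numeric(0),
                      modulus = numeric(0), angle = numeric(0),
                      nearest_dft_angle = numeric(0), mismatch = numeric(0))
  X1 <- Xc[, -m, drop = FALSE]
  sv <- svd(X1, nu = 0, nv = 0)
  tol <- max(dim(X1)) * .Machine$double.eps * sv$d[1]
  rr <- sum(sv$d > max(tol, 0))
  if (sv$d[1] == 0 || rr == 0) {
    attr(empty, "note") <- "no signal after mean subtraction"
    attr(empty, "max_mismatch") <- NA_real_
    attr(empty, "max_modulus_deviation") <- NA_real_
    return(empty)
  }
  centred <- image_stack(array(Xc, dim(stack$data)), stack$axis_kind,
                         stack$step, stack$origin)
  model <- fit_dmd(centred, rank_policy("fixed", fixed_rank = rr))
  lam <- model$eigenvalues
  ang <- Arg(lam) %% (2 * pi)
  bins <- 2 * pi * (0:(m - 1)) / m
  near <- vapply(ang, function(a) {
    dd <- abs(a - bins)
    bins[which.min(pmin(dd, 2 * pi - dd))]
  }, numeric(1))
  mism <- pmin(abs(ang - near), 2 * pi - abs(ang - near))
  out <- data.frame(re_lambda = Re(lam), im_lambda = Im(lam),
                    modulus = Mod(lam), angle = ang,
                    nearest_dft_angle = near, mismatch = mism)
  attr(out, "max_mismatch") <- max(mism)
  attr(out, "max_modulus_deviation") <- max(abs(Mod(lam) - 1))
  attr(out, "note") <- ""
  out
}

#' Export a polarimetry report as CSV
#'
#' Writes `<prefix>_profile.csv` (angle, raw and reconstructed integrated
#' intensity) and `<prefix>_eigenvalues.csv` (classified eigenvalues).
#'
#' @param report a `polarimetry_report`.
#' @param prefix output path prefix.
#' @return profile CSV path, invisibly.
#' @export
export_polarimetry <- function(report, prefix) {
  stopifnot(inherits(report, "polarimetry_report"))
  prof <- data.frame(angle = report$angles,
                     raw_intensity = report$profile_raw,
                     reconstructed_intensity = report$profile_reconstructed)
  path <- paste0(prefix, "_profile.csv")
  utils::write.csv(prof, path, row.names = FALSE)
  export_model(report$model, prefix)
  invisible(path)
}
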