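#' Rank-truncation policies
#'
#' How many singular values / DMD modes to retain. Three policies:
#' \describe{
#'   \item{`hard_threshold`}{optimal singular-value hard threshold for the
#'     matrix aspect ratio, with the noise level estimated from the median
#'     singular value. This is the automatic choice that separates signal
#'     modes from the noise plateau of a shot-noise-limited stack.}
#'   \item{`fixed`}{retain `min(fixed_rank, available)` components.}
#'   \item{`energy`}{smallest rank whose cumulative squared singular values
#'     reach `energy_fraction` of the total.}
#' }
#' At least one component is always kept.
#'
#' @param mode policy name.
#' @param fixed_rank integer, for `mode = "fixed"`.
#' @param energy_fraction scalar in (0, 1], for `mode = "energy"`.
#' @return A `rank_policy` object.
#' @export
rank_policy <- function(mode = c("hard_threshold", "fixed", "energy"),
                        fixed_rank = NULL, energy_fraction = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_rank) || fixed_rank < 1)
      stop("fixed policy requires a positive `fixed_rank`")
    fixed_rank <- as.integer(fixed_rank)
  } else if (!is.null(fixed_rank))
    stop("`fixed_rank` only applies to mode = \"fixed\"")
  if (mode == "energy") {
    if (is.null(energy_fraction) || energy_fraction <= 0 ||
        energy_fraction > 1)
      stop("energy policy requires `energy_fraction` in (0, 1]")
  } else if (!is.null(energy_fraction))
    stop("`energy_fraction` only applies to mode = \"energy\"")
  structure(list(mode = mode, fixed_rank = fixed_rank,
                 energy_fraction = energy_fraction),
            class = "rank_policy")
}

# Median of the Marchenko-Pastur distribution with aspect ratio beta in
# (0, 1]: root of the CDF at 1/2, by numerical integration of the density
# on [(1-sqrt(beta))^2, (1+sqrt(beta))^2].
marchenko_pastur_median <- function(beta) {
  lo <- (1 - sqrt(beta))^2
  hi <- (1 + sqrt(beta))^2
  dens <- function(x) suppressWarnings(
    sqrt(pmax((hi - x) * (x - lo), 0)) / (2 * pi * beta * x))
  cdf <- function(x) stats::integrate(dens, lo, x, rel.tol = 1e-10)$value
  stats::uniroot(function(x) cdf(x) - 0.5, c(lo + 1e-12, hi - 1e-12),
                 tol = 1e-10)$root
}

# Optimal hard-threshold coefficient for unknown noise, applied to the
# median singular value: omega(beta) = lambda_star(beta) / sqrt(mu_beta).
# Exact coefficient, not the tabulated approximation.
hard_threshold_coef <- function(beta) {
  stopifnot(beta > 0, beta <= 1)
  lambda_star <- sqrt(2 * (beta + 1) +
                        8 * beta / (beta + 1 + sqrt(beta^2 + 14 * beta + 1)))
  lambda_star / sqrt(marchenko_pastur_median(beta))
}

# Number of components to retain for a singular-value spectrum `d` of a
# matrix with dimensions `dims`, under a rank policy. Always >= 1, and
# never beyond the numerical rank (singular values at round-off level
# cannot be inverted meaningfully).
select_rank <- function(d, dims, policy) {
  stopifnot(inherits(policy, "rank_policy"))
  if (d[1] <= 0) stop("no signal: all singular values are zero")
  num_rank <- sum(d > max(dims) * .Machine$double.eps * d[1])
  r <- switch(policy$mode,
    fixed = min(policy$fixed_rank, length(d)),
    energy = {
      frac <- cumsum(d^2) / sum(d^2)
      which(frac >= policy$energy_fraction - 1e-12)[1]
    },
    hard_threshold = {
      if (min(dims) < 2L)
        stop("hard_threshold requires at least 2 rows and 2 columns")
      beta <- min(dims) / max(dims)
      tau <- hard_threshold_coef(beta) * stats::median(d)
      sum(d > tau)
    })
  max(1L, min(as.integer(r), num_rank))
}

#' Truncated singular value decomposition of a snapshot matrix
#'
#' SVD of `X1` with rank selection by a [rank_policy()]. The returned
#' factors are truncated to the retained rank; the full spectrum is kept
#' for diagnostics (noise-plateau inspection).
#'
#' @param X1 numeric matrix (pixels x snapshots).
#' @param policy a [rank_policy()].
#' @return list with `u` (n x r), `d` (r singular values, descending),
#'   `v` ((m-1) x r), `rank`, `full_spectrum`.
#' @export
truncated_svd <- function(X1, policy = rank_policy("hard_threshold")) {
  X1 <- as.matrix(X1)
  if (ncol(X1) < 1L) stop("X1 must have at least one column")
  sv <- svd(X1)
  r <- select_rank(sv$d, dim(X1), policy)
  structure(list(u = sv$u[, seq_len(r), drop = FALSE],
                 d = sv$d[seq_len(r)],
                 v = sv$v[, seq_len(r), drop = FALSE],
                 rank = r, full_spectrum = sv$d),
            class = "svd_factors")
}

#' Reduced one-step operator
#'
#' Projection of the (never explicitly formed) full propagator `A` onto the
#' leading left singular vectors: `Atilde = U' X2 V' S'^-1`, an `r x r`
#' matrix similar to the restriction of `A` to the retained subspace.
#'
#' @param svd an `svd_factors` object from [truncated_svd()].
#' @param X2 the forward-shifted snapshot matrix.
#' @return list with the `r x r` matrix `Atilde`.
#' @export
reduced_operator <- function(svd, X2) {
  stopifnot(inherits(svd, "svd_factors"))
  r <- svd$rank
  if (any(svd$d <= max(dim(X2)) * .Machine$double.eps * svd$d[1]))
    stop("zero singular value within retained rank: cannot invert Sigma'")
  vs <- svd$v %*% diag(1 / svd$d, nrow = r)
  structure(list(Atilde = crossprod(svd$u, X2 %*% vs)),
            class = "reduced_operator")
}

#' Eigendecomposition and exact DMD modes
#'
#' Eigenvalues of the reduced operator and the corresponding exact DMD
#' modes `Phi = X2 V S^-1 W` (with `W` the reduced eigenvectors),
#' normalized to unit Euclidean norm. Exact modes are used rather than the
#' projected form `U W`: they are better behaved when the model is later
#' evaluated outside the span of `X1`.
#'
#' @param op a `reduced_operator`.
#' @param svd the `svd_factors` the operator was built from.
#' @param X2 the forward-shifted snapshot matrix.
#' @return list with complex `eigenvalues` (length r) and complex `modes`
#'   (n x r, unit columns).
#' @export
eigendecompose <- function(op, svd, X2) {
  stopifnot(inherits(op, "reduced_operator"), inherits(svd, "svd_factors"))
  e <- tryCatch(eigen(op$Atilde),
                error = function(err)
                  stop("eigendecomposition of reduced operator failed: ",
                       conditionMessage(err)))
  lam <- as.complex(e$values)
  W <- e$vectors
  if (!is.complex(W)) W <- W + 0i
  vs <- svd$v %*% diag(1 / svd$d, nrow = svd$rank)
  modes <- (X2 %*% vs) %*% W
  nrm <- sqrt(colSums(Mod(modes)^2))
  nrm[nrm == 0] <- 1
  modes <- sweep(modes, 2, nrm, "/")
  list(eigenvalues = lam, modes = modes)
}

# Minimum-norm least-squares solve via (complex) SVD pseudoinverse.
pinv_solve <- function(A, y, tol = NULL) {
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!any(keep)) return(rep(0 + 0i, ncol(A)))
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  list(x = v %*% ((Conj(t(u)) %*% y) / sv$d[keep]),
       deficient = sum(keep) < min(dim(A)))
}

# lambda^p with the 0^0 = 1 convention and 0^p = 0 for p > 0 (the complex
# power of exactly-zero eigenvalues is otherwise NaN).
lambda_power <- function(lambda, p) {
  out <- lambda^p
  z <- lambda == 0
  if (any(z)) out[z] <- ifelse(p == 0, 1 + 0i, 0 + 0i)
  out
}

# r x m Vandermonde matrix W[j, k] = lambda_j^(k-1).
vandermonde <- function(lambda, m) {
  vapply(seq_len(m), function(k) lambda_power(lambda, k - 1),
         complex(length(lambda)))
}

#' Mode amplitudes
#'
#' Scalar weights `b_j` that scale each unit-norm mode to the data.
#' `first_frame` fits the first snapshot only (`Phi b = x_1`);
#' `all_frames` (the default, the amplitude-optimal or "optimal DMD" fit)
#' minimizes the residual over every snapshot,
#' `sum_k || Phi diag(lambda^(k-1)) b - x_k ||^2`, which is markedly more
#' noise-robust. Rank-deficient mode matrices fall back to the
#' minimum-norm solution with a warning.
#'
#' @param modes complex n x r mode matrix.
#' @param eigenvalues complex eigenvalues, length r.
#' @param snap `snapshot_matrix` (or bare matrix) of the data being fitted.
#' @param method `"all_frames"` or `"first_frame"`.
#' @return complex amplitude vector, length r.
#' @export
compute_amplitudes <- function(modes, eigenvalues, snap,
                               method = c("all_frames", "first_frame")) {
  method <- match.arg(method)
  X <- if (inherits(snap, "snapshot_matrix")) snap$matrix else as.matrix(snap)
  if (method == "first_frame") {
    sol <- pinv_solve(modes, X[, 1])
    if (sol$deficient)
      warning("rank-deficient mode matrix: minimum-norm amplitudes")
    return(drop(sol$x))
  }
  m <- ncol(X)
  W <- matrix(vandermonde(eigenvalues, m), nrow = length(eigenvalues))
  PhiH <- Conj(t(modes))
  G <- (PhiH %*% modes) * (Conj(W) %*% t(W))
  rhs <- rowSums(Conj(W) * (PhiH %*% X))
  b <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(b)) {
    warning("rank-deficient mode matrix: minimum-norm amplitudes")
    b <- pinv_solve(G, rhs)$x
  }
  drop(b)
}

#' Continuous-frequency eigenvalues
#'
#' Rescales the discrete eigenvalues to continuous growth rates and
#' angular frequencies, `omega = log(lambda) / step`, using the principal
#' branch of the complex logarithm. `Re(omega)` is the decay (or growth)
#' rate per coordinate unit, `Im(omega)` the oscillation frequency.
#' Eigenvalues at exactly zero have no finite logarithm; they are returned
#' as `NA` and flagged, and are skipped in continuous-coordinate
#' evaluation. Frequencies near the Nyquist limit (`arg lambda` near
#' +/- pi) are inherently sign-ambiguous; they are reported on the
#' principal branch, not unwrapped.
#'
#' @param eigenvalues complex discrete eigenvalues.
#' @param step frame spacing (must be > 0).
#' @return complex vector of the same length (NA where `lambda == 0`),
#'   with attribute `zero_modes` marking the flagged entries.
#' @export
continuous_eigenvalues <- function(eigenvalues, step) {
  if (step <= 0) stop("`step` must be positive")
  z <- eigenvalues == 0
  om <- log(as.complex(eigenvalues)) / step
  om[z] <- NA_complex_
  attr(om, "zero_modes") <- z
  om
}

# Deterministic mode ordering: descending energy proxy |b| |lambda|^((m-1)/2),
# ties by descending |lambda| then ascending arg(lambda).
mode_order <- function(eigenvalues, amplitudes, m) {
  energy <- Mod(amplitudes) * Mod(eigenvalues)^((m - 1) / 2)
  order(-energy, -Mod(eigenvalues), Arg(eigenvalues))
}

new_dmd_model <- function(modes, eigenvalues, amplitudes, snap, delay,
                          rank1 = NULL, spectrum = NULL) {
  m <- ncol(snap$matrix)
  ord <- mode_order(eigenvalues, amplitudes, m)
  modes <- modes[, ord, drop = FALSE]
  eigenvalues <- eigenvalues[ord]
  amplitudes <- amplitudes[ord]
  structure(
    list(modes = modes, eigenvalues = eigenvalues,
         omegas = continuous_eigenvalues(eigenvalues, snap$step),
         amplitudes = amplitudes, rank = length(eigenvalues),
         rank1 = rank1, delay = delay, step = snap$step,
         origin = snap$origin, frame_shape = snap$frame_shape,
         axis_kind = snap$axis_kind, n_frames = m, spectrum = spectrum),
    class = "dmd_model")
}

#' @export
print.dmd_model <- function(x, ...) {
  cat(sprintf("<dmd_model> rank %d, delay %d, %d frames along %s axis\n",
              x$rank, x$delay, x$n_frames, x$axis_kind))
  n_osc <- sum(abs(Im(x$eigenvalues)) / pmax(Mod(x$eigenvalues), 1e-300)
               > 1e-3)
  cat(sprintf("  |lambda| in [%.4g, %.4g], %d oscillatory eigenvalue(s)\n",
              min(Mod(x$eigenvalues)), max(Mod(x$eigenvalues)), n_osc))
  invisible(x)
}

#' Fit a dynamic mode decomposition
#'
#' End-to-end exact DMD of an image stack: reshape to the snapshot matrix,
#' form the shifted pair, truncated SVD of `X1` under the rank policy,
#' reduced operator, eigendecomposition, amplitudes, continuous
#' eigenvalues. Modes are ordered deterministically by decreasing energy.
#'
#' @param stack an [image_stack] with at least two frames.
#' @param policy a [rank_policy()]; the default automatic hard threshold
#'   separates signal modes from the shot-noise plateau.
#' @param amplitude_method see [compute_amplitudes()].
#' @return A `dmd_model` with fields `modes` (complex n x r), `eigenvalues`
#'   (discrete, lambda), `omegas` (continuous), `amplitudes`, `rank`,
#'   `delay` (1 for plain DMD), the axis metadata, and the full singular
#'   spectrum.
#' @export
fit_dmd <- function(stack, policy = rank_policy("hard_threshold"),
                    amplitude_method = c("all_frames", "first_frame")) {
  stopifnot(inherits(stack, "image_stack"))
  amplitude_method <- match.arg(amplitude_method)
  if (n_frames(stack) < 2L) stop("at least two snapshots required")
  snap <- to_snapshot_matrix(stack)
  sh <- shift_matrices(snap)
  sv <- truncated_svd(sh$X1, policy)
  op <- reduced_operator(sv, sh$X2)
  ed <- eigendecompose(op, sv, sh$X2)
  b <- compute_amplitudes(ed$modes, ed$eigenvalues, snap, amplitude_method)
  new_dmd_model(ed$modes, ed$eigenvalues, b, snap, delay = 1L,
                spectrum = sv$full_spectrum)
}

#' Export a fitted model as CSV tables and mode TIFFs
#'
#' Writes `<prefix>_eigenvalues.csv` with one row per mode (Re/Im of
#' lambda and omega, |b|, delay, ranks) and, optionally, per-mode TIFF
#' stacks of the real and imaginary parts of the spatial modes.
#'
#' @param model a `dmd_model`.
#' @param prefix output path prefix.
#' @param modes_tiff also write `<prefix>_modes_re.tif` / `_modes_im.tif`.
#' @return The eigenvalue CSV path, invisibly.
#' @export
export_model <- function(model, prefix, modes_tiff = FALSE) {
  stopifnot(inherits(model, "dmd_model"))
  tab <- data.frame(
    mode = seq_len(model$rank),
    re_lambda = Re(model$eigenvalues), im_lambda = Im(model$eigenvalues),
    re_omega = Re(model$omegas), im_omega = Im(model$omegas),
    abs_amplitude = Mod(model$amplitudes),
    delay = model$delay,
    rank = model$rank,
    rank_first_stage = if (is.null(model$rank1)) NA_integer_ else model$rank1)
  path <- paste0(prefix, "_eigenvalues.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  if (modes_tiff) {
    re <- from_snapshot_matrix(Re(model$modes), model$frame_shape,
                               model$axis_kind, model$step, model$origin)
    im <- from_snapshot_matrix(Im(model$modes), model$frame_shape,
                               model$axis_kind, model$step, model$origin)
    write_stack(re, paste0(prefix, "_modes_re.tif"))
    write_stack(im, paste0(prefix, "_modes_im.tif"))
  }
  invisible(path)
}
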