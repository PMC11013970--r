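test_that("rank policies select the documented ranks", {
  # forced-by-construction spectra
  X <- cbind(c(10, 0, 0, 0), c(0, 8, 0, 0), c(1e-14, 0, 0, 0))
  sv <- truncated_svd(X, rank_policy("fixed", fixed_rank = 2))
  expect_equal(sv$rank, 2L)
  expect_equal(sv$d, c(10, 8))
  # rank-1 outer product under the hard threshold
  op <- outer(1:20, seq(0.5, 2, length.out = 10))
  expect_equal(truncated_svd(op, rank_policy("hard_threshold"))$rank, 1L)
  # energy policy
  d3 <- diag(c(3, 2, 1)) # energies 9, 4, 1 -> cumulative 9/14, 13/14, 1
  expect_equal(truncated_svd(d3, rank_policy("energy",
                                             energy_fraction = 0.9))$rank, 2L)
  expect_equal(truncated_svd(d3, rank_policy("energy",
                                             energy_fraction = 0.95))$rank, 3L)
  expect_error(truncated_svd(matrix(0, 4, 4), rank_policy("fixed",
                                                          fixed_rank = 1)),
               "no signal")
  expect_error(rank_policy("fixed"), "fixed_rank")
  expect_error(rank_policy("energy", energy_fraction = 1.5), "energy")
})

test_that("optimal hard threshold matches its independent evaluation", {
  # coefficient values frozen from an independent quadrature (scipy)
  expect_equal(hard_threshold_coef(0.2), 1.7650464327, tolerance = 1e-8)
  expect_equal(hard_threshold_coef(0.5), 2.1711853485, tolerance = 1e-8)
  expect_equal(hard_threshold_coef(1.0), 2.8583624241, tolerance = 1e-8)

  # 200 x 40 rank-3 signal + iid noise: retains exactly the 3 signal values,
  # and agrees with direct evaluation of the threshold on the spectrum
  set.seed(42)
  A <- matrix(rnorm(200 * 3), 200, 3) %*% diag(c(50, 30, 20)) %*%
    matrix(rnorm(3 * 40), 3, 40) / sqrt(40)
  Y <- A + matrix(rnorm(200 * 40), 200, 40)
  sv <- truncated_svd(Y, rank_policy("hard_threshold"))
  spec <- svd(Y, nu = 0, nv = 0)$d
  tau <- 1.7650464327 * median(spec)  # beta = 40/200 = 0.2
  expect_equal(sv$rank, sum(spec > tau))
  expect_equal(sv$rank, 3L)
})

test_that("svd factors are orthonormal with descending spectrum", {
  set.seed(7)
  Y <- matrix(rnorm(60 * 12), 60, 12)
  sv <- truncated_svd(Y, rank_policy("fixed", fixed_rank = 5))
  expect_lt(max(abs(crossprod(sv$u) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(sv$v) - diag(5))), 1e-10)
  expect_true(all(diff(sv$full_spectrum) <= 0))
})

test_that("reduced operator reproduces known linear dynamics", {
  set.seed(11)
  # X2 = c X1  =>  Atilde = c I
  X1 <- matrix(rnorm(30 * 4), 30, 4)
  sv <- truncated_svd(X1, rank_policy("fixed", fixed_rank = 4))
  op <- reduced_operator(sv, 1.7 * X1)
  expect_equal(op$Atilde, 1.7 * diag(4), tolerance = 1e-10)

  # scalar decaying series: 1x1 Atilde = ratio
  x <- 5 * 0.9^(0:9)
  X <- matrix(x, 1, 10)
  svs <- truncated_svd(X[, 1:9, drop = FALSE],
                       rank_policy("fixed", fixed_rank = 1))
  ops <- reduced_operator(svs, X[, 2:10, drop = FALSE])
  expect_equal(drop(ops$Atilde), 0.9, tolerance = 1e-12)

  # consistent system x_{k+1} = M x_k: eigenvalues recovered exactly
  M <- matrix(c(0.9, 0.2, 0, 0.1, 0.7, 0.3, 0, -0.2, 0.5), 3, 3)
  x0 <- c(1, 2, 3)
  X <- matrix(0, 3, 12); X[, 1] <- x0
  for (k in 2:12) X[, k] <- M %*% X[, k - 1]
  sv3 <- truncated_svd(X[, 1:11], rank_policy("fixed", fixed_rank = 3))
  op3 <- reduced_operator(sv3, X[, 2:12])
  expect_equal(sort(Mod(eigen(op3$Atilde)$values)),
               sort(Mod(eigen(M)$values)), tolerance = 1e-8)

  bad <- list(u = diag(3), d = c(1, 1e-20, 1e-30), v = diag(3), rank = 3L,
              full_spectrum = c(1, 1e-20, 1e-30))
  class(bad) <- "svd_factors"
  expect_error(reduced_operator(bad, diag(3)), "cannot invert")
})

test_that("eigendecomposition recovers closed-form spectra and modes", {
  # rotation operator -> e^{+-i alpha}
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  X1 <- matrix(0, 2, 20); X1[, 1] <- c(1, 0)
  for (k in 2:20) X1[, k] <- R %*% X1[, k - 1]
  sv <- truncated_svd(X1[, 1:19], rank_policy("fixed", fixed_rank = 2))
  op <- reduced_operator(sv, X1[, 2:20])
  ed <- eigendecompose(op, sv, X1[, 2:20])
  expect_equal(sort(Arg(ed$eigenvalues)), c(-a, a), tolerance = 1e-10)
  expect_equal(Mod(ed$eigenvalues), c(1, 1), tolerance = 1e-10)
  expect_equal(colSums(Mod(ed$modes)^2), c(1, 1), tolerance = 1e-10)

  # two known spatial patterns with known decay factors
  st <- modal_stack(c(0.95, 0.80), c(3, 2), m = 15, seed = 5)
  mod <- fit_dmd(st, rank_policy("fixed", fixed_rank = 2))
  expect_equal(sort(Re(mod$eigenvalues)), c(0.80, 0.95), tolerance = 1e-8)
  expect_lt(max(abs(Im(mod$eigenvalues))), 1e-10)
})

test_that("amplitudes identify generative weights and beat first-frame fits", {
  # single mode, unit-norm pattern, coefficient 3
  v <- rep(1 / 8, 64); v <- v / sqrt(sum(v^2))
  X <- sapply(1:10, function(k) 3 * v * 0.9^(k - 1))
  st <- image_stack(array(X, c(8, 8, 10)), "time", 1)
  mod <- fit_dmd(st, rank_policy("fixed", fixed_rank = 1))
  # amplitude is defined up to the mode's phase; compare |b| and the product
  expect_equal(Mod(mod$amplitudes), 3, tolerance = 1e-8)

  # noiseless two-mode data: both amplitude methods agree
  st2 <- modal_stack(c(0.95, 0.7), c(2, 5), m = 12, seed = 6)
  snap <- to_snapshot_matrix(st2)
  m_all <- fit_dmd(st2, rank_policy("fixed", fixed_rank = 2), "all_frames")
  m_first <- fit_dmd(st2, rank_policy("fixed", fixed_rank = 2), "first_frame")
  expect_equal(m_all$amplitudes, m_first$amplitudes, tolerance = 1e-8)

  # with noise, the all-frames fit has no larger residual (oracle: direct
  # residual computation for both fits)
  set.seed(13)
  noisy <- st2
  noisy$data <- noisy$data + array(rnorm(length(noisy$data), sd = 0.1),
                                   dim(noisy$data))
  resid <- function(model) {
    rec <- reconstruct(model)
    sqrt(sum((rec$data - noisy$data)^2))
  }
  p2 <- rank_policy("fixed", fixed_rank = 2)
  expect_lte(resid(fit_dmd(noisy, p2, "all_frames")),
             resid(fit_dmd(noisy, p2, "first_frame")) + 1e-12)
})

test_that("continuous eigenvalues use the principal log over the step", {
  om <- continuous_eigenvalues(c(1 + 0i, exp(-0.1), 1i), step = 1)
  expect_equal(om[1], 0 + 0i)
  expect_equal(om[2], -0.1 + 0i, tolerance = 1e-12)
  expect_equal(om[3], complex(real = 0, imaginary = pi / 2))
  expect_equal(continuous_eigenvalues(1 + 0i, 0.5), 0 + 0i,
               ignore_attr = TRUE)
  z <- continuous_eigenvalues(c(0.5 + 0i, 0 + 0i), 1)
  expect_true(is.na(z[2]))
  expect_identical(attr(z, "zero_modes"), c(FALSE, TRUE))
  expect_error(continuous_eigenvalues(1 + 0i, 0), "positive")
})

test_that("eigenvalue recovery holds across generated systems", {
  # property: distinct mu_j, independent v_j, m >= r+1 -> recovery to 1e-6
  set.seed(99)
  for (trial in 1:8) {
    r <- sample(2:4, 1)
    mu <- sort(runif(r, 0.4, 1.05))
    while (any(diff(mu) < 0.05)) mu <- sort(runif(r, 0.4, 1.05))
    st <- modal_stack(mu, runif(r, 1, 3), m = 2 * r + 6, seed = trial + 100)
    mod <- fit_dmd(st, rank_policy("fixed", fixed_rank = r))
    expect_equal(sort(Re(mod$eigenvalues)), mu, tolerance = 1e-6)
    expect_lt(max(abs(Im(mod$eigenvalues))), 1e-6)
  }
})

test_that("spectra of real data are closed under conjugation", {
  set.seed(21)
  for (trial in 1:5) {
    st <- image_stack(array(runif(64 * 12), c(8, 8, 12)), "time", 1)
    mod <- fit_dmd(st, rank_policy("fixed", fixed_rank = 8))
    lam <- mod$eigenvalues
    unpaired <- vapply(lam, function(l)
      min(Mod(Conj(l) - lam)), numeric(1))
    expect_lt(max(unpaired), 1e-8)
  }
})

test_that("model ordering and export are deterministic", {
  st <- modal_stack(c(0.9, 0.6), c(1, 10), m = 12, seed = 3)
  mod <- fit_dmd(st, rank_policy("fixed", fixed_rank = 2))
  en <- Mod(mod$amplitudes) * Mod(mod$eigenvalues)^((mod$n_frames - 1) / 2)
  expect_true(all(diff(en) <= 1e-12))
  pre <- withr::local_tempfile()
  path <- export_model(mod, pre, modes_tiff = TRUE)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 2L)
  expect_true(file.exists(paste0(pre, "_modes_re.tif")))
  re_modes <- read_stack(paste0(pre, "_modes_re.tif"), "time", 1)
  expect_equal(dim(re_modes$data)[3], 2L)
})

test_that("fit_dmd rejects degenerate input and projection is idempotent", {
  expect_error(fit_dmd(image_stack(matrix(1, 2, 2), "time", 1)),
               "two snapshots")
  st <- modal_stack(c(0.97, 0.85), c(4, 1), m = 14, seed = 8)
  mod <- fit_dmd(st, rank_policy("fixed", fixed_rank = 2))
  rec1 <- reconstruct(mod)
  mod2 <- fit_dmd(rec1, rank_policy("fixed", fixed_rank = 2))
  rec2 <- reconstruct(mod2)
  expect_lt(max_rel_err(rec2$data, rec1$data), 1e-8)
})
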