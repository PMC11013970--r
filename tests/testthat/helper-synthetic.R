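# Shared fixtures, all generated in code.

# Stack whose snapshot matrix is exactly sum_j c_j v_j mu_j^(k-1).
modal_stack <- function(mu, coef, m, frame_shape = c(8, 8), seed = 1,
                        axis = "time", step = 1) {
  set.seed(seed)
  n <- prod(frame_shape)
  V <- matrix(runif(n * length(mu)), n)
  X <- sapply(seq_len(m), function(k)
    Re(V %*% (coef * mu^(k - 1))))
  image_stack(array(X, c(frame_shape, m)), axis, step)
}

# Independent SSIM oracle: naive per-window evaluation of the formula.
ssim_naive <- function(a, b, data_range, size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in seq_len(nrow(a) - size + 1))
    for (j in seq_len(ncol(a) - size + 1)) {
      p <- a[i:(i + size - 1), j:(j + size - 1)]
      q <- b[i:(i + size - 1), j:(j + size - 1)]
      m1 <- sum(w * p); m2 <- sum(w * q)
      s1 <- sum(w * p^2) - m1^2; s2 <- sum(w * q^2) - m2^2
      s12 <- sum(w * p * q) - m1 * m2
      vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * s12 + C2)) /
                  ((m1^2 + m2^2 + C1) * (s1 + s2 + C2)))
    }
  mean(vals)
}

max_rel_err <- function(got, want) {
  max(abs(got - want)) / max(abs(want))
}
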