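# Internal numeric helpers shared across modules.

# Separable Gaussian blur of a matrix with symmetric (edge-reflecting)
# boundary handling. sigma may be length 1 (isotropic) or 2 (row, col);
# a zero sigma skips smoothing along that axis.
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x))
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  x <- blur_along(x, sigma[1L])          # down columns (row direction)
  t(blur_along(t(x), sigma[2L]))         # along rows
}

blur_along <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x)
  xp <- x[reflect_index(seq_len(n + 2L * rad) - rad, n), , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) {
    out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Symmetric reflection of out-of-range indices into 1..n (edge repeated).
reflect_index <- function(i, n) {
  i <- abs(i - 1L)               # 0-based, reflect below
  p <- 2L * n - 2L
  if (n == 1L) return(rep(1L, length(i)))
  i <- i %% (p + 2L)
  i <- ifelse(i > n - 1L, p + 1L - i, i)
  i + 1L
}

# Local box mean and population SD over a w x w window (w odd) with
# symmetric padding. Returns list(mean =, sd =) of matrices like x.
box_stats <- function(x, w) {
  stopifnot(is.matrix(x), w >= 1L, w %% 2L == 1L)
  if (w == 1L) {
    return(list(mean = x, sd = matrix(0, nrow(x), ncol(x))))
  }
  rad <- (w - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  ri <- reflect_index(seq_len(n + 2L * rad) - rad, n)
  ci <- reflect_index(seq_len(m + 2L * rad) - rad, m)
  xp <- x[ri, ci, drop = FALSE]
  s1 <- box_sum(xp, w)
  s2 <- box_sum(xp * xp, w)
  mu <- s1 / (w * w)
  v <- s2 / (w * w) - mu * mu
  v[v < 1e-10] <- 0   # cancellation noise on locally constant input
  list(mean = mu, sd = sqrt(v))
}

# Sliding w x w window sums of a padded matrix via 2-D cumulative sums;
# output drops the padding border.
box_sum <- function(xp, w) {
  cs <- apply(apply(xp, 2L, cumsum), 1L, cumsum)   # transposed cumsum matrix
  cs <- t(cs)
  n <- nrow(xp) - w + 1L
  m <- ncol(xp) - w + 1L
  z <- rbind(0, cbind(0, cs))
  z[w + seq_len(n), w + seq_len(m)] -
    z[w + seq_len(n), seq_len(m)] -
    z[seq_len(n), w + seq_len(m)] +
    z[seq_len(n), seq_len(m)]
}

# Parameter validation helper: stop with a classed error.
fq_stop <- function(msg, class) {
  stop(structure(class = c(class, "fibroquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    fq_stop("`seed` must be a single integer", "fq_parameter_error")
  }
  as.integer(seed)
}
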