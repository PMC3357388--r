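# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: direct formulas and brute-force searches, never the
# code path under test.

# Brute-force cosinor: two-stage grid over (A, phi), mesor profiled out in
# closed form at each grid point (the exact minimum over m for fixed A,
# phi). Final resolution 0.001 in amplitude, 0.01 h in phase.
grid_cosinor_oracle <- function(times, y, T = 24) {
  ybar <- mean(y)
  rss_at <- function(A_grid, phi) {
    cph <- cos(2 * pi * (times - phi) / T)
    cc <- cph - mean(cph)
    yy <- y - ybar
    sum(yy^2) - 2 * A_grid * sum(yy * cc) + A_grid^2 * sum(cc^2)
  }
  search <- function(A_grid, phi_grid) {
    best <- list(rss = Inf)
    for (phi in phi_grid) {
      r <- rss_at(A_grid, phi)
      i <- which.min(r)
      if (r[i] < best$rss) best <- list(A = A_grid[i], phi = phi, rss = r[i])
    }
    best
  }
  A_max <- max(diff(range(y)), 0.1)
  coarse <- search(seq(0, A_max, by = 0.01), seq(0, T, by = 0.1))
  fine <- search(seq(max(0, coarse$A - 0.02), coarse$A + 0.02, by = 0.001),
                 seq(coarse$phi - 0.2, coarse$phi + 0.2, by = 0.01))
  fine$phi <- fine$phi %% T
  fine
}

# Welch two-sample t-test from first principles
welch_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- sum((x1 - mean(x1))^2) / (n1 - 1)
  v2 <- sum((x2 - mean(x2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x2) - mean(x1)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(lfc = mean(x2) - mean(x1), t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

# Balanced two-way ANOVA sums of squares from cell/marginal means
anova_ss_oracle <- function(profile) {
  A <- factor(profile$condition); B <- factor(profile$zt); y <- profile$value
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  cell <- tapply(y, list(A, B), mean)
  r <- length(y) / (nlevels(A) * nlevels(B))
  ss_A <- nlevels(B) * r * sum((mA - grand)^2)
  ss_B <- nlevels(A) * r * sum((mB - grand)^2)
  ss_int <- r * sum((sweep(sweep(cell, 1, mA), 2, mB) + grand)^2)
  ss_res <- sum((y - cell[cbind(A, B)])^2)
  list(condition = ss_A, time = ss_B, interaction = ss_int,
       residual = ss_res, total = sum((y - grand)^2))
}

# Hypergeometric upper tail by explicit enumeration of binomial coefficients
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Mean resultant vector through complex arithmetic
circular_oracle <- function(hours, T = 24) {
  z <- sum(exp(2i * pi * hours / T)) / length(hours)
  list(R = Mod(z), mean_dir = (Arg(z) * T / (2 * pi)) %% T)
}
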