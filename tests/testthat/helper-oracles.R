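# Independent numerical oracles, kept free of the package's own code paths.

# Student-t upper-tail quantile by numerical integration of the hand-coded
# density (no qt/pt): find x with integral_x^Inf f(t) dt = p.
oracle_t_upper_quantile <- function(p, df) {
  dens <- function(t) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  tail_prob <- function(x) {
    0.5 - stats::integrate(dens, 0, x, rel.tol = 1e-12, abs.tol = 1e-14,
                           subdivisions = 400L)$value
  }
  upper <- 2
  while (tail_prob(upper) > p) upper <- upper * 2
  stats::uniroot(function(x) tail_prob(x) - p,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

# Textbook balanced two-way decomposition: sums of squared deviations of
# marginal/cell means, accumulated per observation.
oracle_balanced_ss <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  grand <- mean(y)
  ma <- tapply(y, A, mean); mb <- tapply(y, B, mean)
  mab <- tapply(y, paste(A, B, sep = "\r"), mean)
  cell <- mab[paste(A, B, sep = "\r")]
  list(
    ss_a = sum((ma[A] - grand)^2),
    ss_b = sum((mb[B] - grand)^2),
    ss_ab = sum((cell - ma[A] - mb[B] + grand)^2),
    ss_e = sum((y - cell)^2)
  )
}
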