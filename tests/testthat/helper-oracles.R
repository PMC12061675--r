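# Independent numeric oracles used across the suite. These deliberately
# avoid the package's closed forms: derivatives come from Richardson-
# extrapolated finite differences of the plain curve formula, extrema from
# optimize()/uniroot() on those differences, integrals from independent
# quadrature, and ranks/bins/tails from brute-force implementations.

richards_raw <- function(x, a, b, c, d) a * (1 + b * exp(-c * x))^(-1 / d)

# Richardson-extrapolated first derivative of the raw formula
oracle_d1 <- function(x, a, b, c, d, h) {
  (8 * (richards_raw(x + h, a, b, c, d) -
          richards_raw(x - h, a, b, c, d)) -
     (richards_raw(x + 2 * h, a, b, c, d) -
        richards_raw(x - 2 * h, a, b, c, d))) / (12 * h)
}

# double-Richardson third derivative of the raw formula
oracle_d3 <- function(x, a, b, c, d, h) {
  g <- function(hh) {
    (-richards_raw(x - 2 * hh, a, b, c, d) +
       2 * richards_raw(x - hh, a, b, c, d) -
       2 * richards_raw(x + hh, a, b, c, d) +
       richards_raw(x + 2 * hh, a, b, c, d)) / (2 * hh^3)
  }
  g1 <- (4 * g(h / 2) - g(h)) / 3
  g2 <- (4 * g(h / 4) - g(h / 2)) / 3
  (16 * g2 - g1) / 15
}

# numeric growth characteristics: dense-bracket extrema of the finite-
# difference derivatives, no closed forms involved
oracle_characteristics <- function(a, b, c, d, span_guess = NULL) {
  # coarse grid to bracket the derivative maximum
  grid <- seq(-5 / c, log(b * 1e6) / c, length.out = 2000)
  vals <- oracle_d1(grid, a, b, c, d, h = 1e-3 / c)
  x0 <- grid[which.max(vals)]
  w <- diff(range(grid)) / 100
  opt <- optimize(oracle_d1, c(x0 - w, x0 + w), a = a, b = b, c = c,
                  d = d, h = 0.005 * w, maximum = TRUE, tol = 1e-11)
  span <- span_guess %||% (4 * w)
  s <- uniroot(oracle_d3, c(opt$maximum - 3 * span, opt$maximum),
               a = a, b = b, c = c, d = d, h = 0.05 * span, tol = 1e-13)
  e <- uniroot(oracle_d3, c(opt$maximum, opt$maximum + 3 * span),
               a = a, b = b, c = c, d = d, h = 0.05 * span, tol = 1e-13)
  list(day_max_gr = opt$maximum, max_gr = opt$objective,
       start_logg = s$root, end_logg = e$root,
       duration = e$root - s$root)
}

rel_err <- function(est, ref) abs(est - ref) / pmax(abs(ref), 1)

# random valid parameter sets representing plausible growth curves
random_params <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    a = runif(n, 50, 500),
    c = runif(n, 0.02, 0.3),
    d = exp(runif(n, log(0.2), log(5))),
    x_star = runif(n, 60, 250),
    b = d * exp(c * x_star)
  )
}

# balanced two-way method-of-moments variance components from expected
# mean squares (genotype x block, one observation per cell)
mom_variance_components <- function(data) {
  y <- data$value
  g <- factor(data$genotype)
  b <- factor(data$block)
  G <- nlevels(g); B <- nlevels(b)
  stopifnot(length(y) == G * B)
  mu <- mean(y)
  gm <- tapply(y, g, mean)
  bm <- tapply(y, b, mean)
  ss_g <- B * sum((gm - mu)^2)
  ss_b <- G * sum((bm - mu)^2)
  ss_t <- sum((y - mu)^2)
  ss_e <- ss_t - ss_g - ss_b
  ms_g <- ss_g / (G - 1)
  ms_b <- ss_b / (B - 1)
  ms_e <- ss_e / ((G - 1) * (B - 1))
  list(v_g = max(0, (ms_g - ms_e) / B),
       v_block = max(0, (ms_b - ms_e) / G),
       v_e = ms_e)
}

# from-scratch Pearson r and two-sided p (sum formulas + t distribution)
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}
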