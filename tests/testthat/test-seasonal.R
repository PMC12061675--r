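test_that("duration bins honour the minimum count and alignment", {
  # 9 identical durations: below threshold, nothing retained
  d9 <- tibble::tibble(duration = rep(45, 9))
  b9 <- bin_by_duration(d9)
  expect_equal(nrow(b9), 0)
  expect_false(any(attr(b9, "bins")$retained))
  # 10 plants exactly at threshold: one [40, 50) bin
  d10 <- tibble::tibble(duration = rep(45, 10))
  b10 <- bin_by_duration(d10)
  expect_equal(nrow(b10), 10)
  expect_equal(unique(b10$bin_lo), 40)
  expect_equal(unique(b10$bin_hi), 50)
})

test_that("bin membership equals the floor-division oracle", {
  set.seed(500)
  d <- tibble::tibble(plant = 1:500, duration = rnorm(500, 75, 20))
  b <- bin_by_duration(d, bin_width = 10, min_count = 10)
  oracle_lo <- floor(d$duration / 10) * 10
  keep <- oracle_lo %in% names(which(table(oracle_lo) >= 10))
  expect_setequal(b$plant, d$plant[keep])
  expect_equal(b$bin_lo, oracle_lo[match(b$plant, d$plant)])
  # partition: retained + discarded account for everyone, no overlaps
  census <- attr(b, "bins")
  expect_equal(sum(census$n), 500)
  expect_equal(anyDuplicated(b$plant), 0)
})

test_that("within-bin correlations flag exact and degenerate cases", {
  d <- tibble::tibble(
    duration = rep(45, 24),
    start_logg = rep(c(110, 120, 130, 140), 6)
  )
  d$dw <- -2 * d$start_logg + 400
  b <- bin_by_duration(d)
  res <- within_bin_correlation(b)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_true(res$significant)

  d$start_logg <- 120
  res2 <- within_bin_correlation(bin_by_duration(d))
  expect_true(is.na(res2$r))
  expect_equal(res2$reason, "zero_variance")
})

test_that("planted within-bin correlation is recovered with its sign", {
  cfg <- sim_config(
    n_genotypes = 600, n_blocks = 1, seed = 77,
    planted_dw_cor = list(r = -0.5, duration_range = c(40, 110),
                          x_trait = "start_logg")
  )
  sim <- simulate_trial(cfg)
  tr <- dplyr::left_join(sim$truth,
                         dplyr::select(sim$harvest, "plant_id", "dw"),
                         by = "plant_id")
  res <- within_bin_correlation(bin_by_duration(tr))
  in_range <- res$bin_lo >= 40 & res$bin_hi <= 110 & !is.na(res$r)
  expect_gt(sum(in_range), 2)
  expect_true(all(res$r[in_range] < 0))
  expect_gt(mean(res$significant[in_range]), 0.7)
  # Fisher-z sampling bounds around the planted -0.5
  z <- atanh(res$r[in_range])
  bound <- atanh(0.5) + 4 / sqrt(res$n[in_range] - 3)
  expect_true(all(abs(z) < bound))
})

test_that("binning controls the rate-duration confound", {
  # when the rate depends only on duration, within-bin correlation with
  # the phase start is centred on zero
  set.seed(303)
  d <- tibble::tibble(duration = runif(2000, 40, 120),
                      start_logg = rnorm(2000, 143, 15))
  d$max_gr <- 150 / d$duration + rnorm(2000, 0, 0.1)
  res <- within_bin_correlation(bin_by_duration(d), x_trait = "start_logg",
                                y_trait = "max_gr")
  expect_lt(abs(mean(res$r, na.rm = TRUE)), 0.1)
  # about alpha of the null bins reject (loose binomial bound)
  expect_lt(mean(res$significant, na.rm = TRUE), 0.3)
})

test_that("composite traits: hand examples and tie handling", {
  d <- tibble::tibble(max_gr = c(2, 1), duration = c(50, 100))
  cp <- composite_traits(d)
  expect_equal(cp$ratio_maxgr_duration, c(0.04, 0.01))
  expect_equal(cp$rank_sum_maxgr_duration, c(3, 3))

  same <- tibble::tibble(max_gr = rep(2, 5), duration = rep(60, 5))
  cps <- composite_traits(same)
  expect_equal(unique(cps$rank_sum_maxgr_duration), 6) # 2 * mean rank 3

  set.seed(10)
  r50 <- tibble::tibble(max_gr = rnorm(50, 2), duration = rnorm(50, 75))
  cpr <- composite_traits(r50)
  oracle <- function(v) { # sort-based average ranks
    o <- order(v)
    rk <- numeric(length(v)); rk[o] <- seq_along(v)
    ave(rk, v, FUN = mean)
  }
  expect_equal(cpr$rank_sum_maxgr_duration,
               oracle(r50$max_gr) + oracle(r50$duration))

  bad <- tibble::tibble(max_gr = c(2, 3), duration = c(50, -1))
  expect_warning(cpb <- composite_traits(bad), "non-positive")
  expect_equal(nrow(cpb), 1)
})

test_that("extremes table equals brute-force enumeration on a toy trial", {
  # 40 plants, two species of 20; the top-2 max_gr both in species A
  d <- tibble::tibble(
    species_group = rep(c("A", "B"), each = 20),
    max_gr = c(seq(2, 3.9, by = 0.1), seq(1, 2.9, by = 0.1))
  )
  ex <- extremes_table(d, "max_gr")
  hi <- ex[ex$tail == "high", ]
  expect_equal(hi$percent[hi$species_group == "A"], 10)
  expect_equal(hi$percent[hi$species_group == "B"], 0)
  # conservation: counts per tail sum to k = round(0.05 * 40) = 2
  expect_equal(sum(hi$n_in_tail), 2)
  lo <- ex[ex$tail == "low", ]
  expect_equal(sum(lo$n_in_tail), 2)
  expect_equal(lo$percent[lo$species_group == "B"], 10)

  # full brute force on a random toy population
  set.seed(6)
  d2 <- tibble::tibble(
    species_group = sample(c("A", "B", "C"), 60, replace = TRUE),
    trait = rnorm(60)
  )
  ex2 <- extremes_table(d2, "trait")
  k <- round(0.05 * 60)
  top <- d2$species_group[order(-d2$trait)][1:k]
  for (s in unique(d2$species_group)) {
    got <- ex2$percent[ex2$species_group == s & ex2$tail == "high"]
    expect_equal(got, 100 * sum(top == s) / sum(d2$species_group == s))
  }
})

test_that("single-species populations put the whole tail in that species", {
  d <- tibble::tibble(species_group = "only", trait = rnorm(50))
  ex <- extremes_table(d, "trait")
  k <- floor(0.05 * 50 + 0.5) # half-up tail size: 3 of 50
  expect_equal(unique(ex$percent), 100 * k / 50)
})

test_that("a planted species shift dominates the matching tail", {
  set.seed(41)
  d <- tibble::tibble(
    species_group = rep(c("shifted", "s2", "s3"), each = 60),
    max_gr = c(rnorm(60, 4), rnorm(60, 2), rnorm(60, 2))
  )
  ex <- extremes_table(d, "max_gr")
  hi <- ex[ex$tail == "high", ]
  expect_equal(hi$species_group[which.max(hi$percent)], "shifted")
})

test_that("extreme fractions outside (0, 0.5) are rejected", {
  d <- tibble::tibble(species_group = "s", trait = rnorm(30))
  expect_error(extremes_table(d, "trait", fraction = 0),
               class = "stemseason_domain_error")
  expect_error(extremes_table(d, "trait", fraction = 0.6),
               class = "stemseason_domain_error")
})

test_that("geographic regression: exact, null and planted cases", {
  set.seed(71)
  d <- tibble::tibble(lat = runif(60, 25, 45), lon = runif(60, 100, 140),
                      alt_m = runif(60, 0, 1500))
  d$day_at_15cm <- 2 * d$lat
  res <- geographic_regression(d)
  lat_row <- res[res$predictor == "lat", ]
  expect_equal(lat_row$slope, 2, tolerance = 1e-10)
  expect_equal(lat_row$adj_r2, 1, tolerance = 1e-10)
  expect_equal(attr(res, "selected"), "lat")

  d$day_at_15cm <- rnorm(60, 120, 5)
  res_null <- geographic_regression(d)
  if (min(res_null$p, na.rm = TRUE) >= 0.05) {
    expect_equal(attr(res_null, "selected"), "none")
    expect_false(any(res_null$selected))
  }

  set.seed(72)
  d2 <- tibble::tibble(lat = runif(200, 25, 45),
                       lon = runif(200, 100, 140),
                       alt_m = runif(200, 0, 1500))
  d2$day_at_15cm <- 110 + 1.2 * (d2$lat - 30) + rnorm(200, 0, 3)
  res2 <- geographic_regression(d2)
  expect_equal(res2$slope[res2$predictor == "lat"], 1.2, tolerance = 0.2)
  expect_equal(attr(res2, "selected"), "lat")
  # closed-form OLS oracle on the same design
  beta <- cov(d2$lat, d2$day_at_15cm) / var(d2$lat)
  expect_equal(res2$slope[res2$predictor == "lat"], beta,
               tolerance = 1e-10)
})

test_that("constant predictors are non-estimable", {
  d <- tibble::tibble(lat = 30, lon = runif(20, 100, 140), alt_m = 200,
                      day_at_15cm = rnorm(20, 120))
  res <- geographic_regression(d, include_lat_alt2 = FALSE)
  expect_true(is.na(res$p[res$predictor == "lat"]))
  expect_true(is.na(res$p[res$predictor == "alt"]))
})
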