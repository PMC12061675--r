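test_that("dry weight and moisture content follow the subsample", {
  hw <- estimate_dry_weight(1000, 200, 100)
  expect_equal(hw$mc, 0.5)
  expect_equal(hw$dw, 500)
  # bone-dry subsample
  hw2 <- estimate_dry_weight(800, 150, 150)
  expect_equal(hw2$mc, 0)
  expect_equal(hw2$dw, 800)
  # frozen hand calculation
  hw3 <- estimate_dry_weight(2500, 198.4, 87.3)
  expect_equal(hw3$mc, 0.5599798387096774, tolerance = 1e-12)
  expect_equal(hw3$dw, 1100.0504032258065, tolerance = 1e-10)
})

test_that("inconsistent harvest measurements are rejected", {
  expect_error(estimate_dry_weight(1000, 100, 150),
               class = "stemseason_measurement_error")
  expect_error(estimate_dry_weight(1000, 0, 0),
               class = "stemseason_domain_error")
})

test_that("variance components hit the noiseless limits", {
  # pure genotype signal: v_e ~ 0, h2 ~ 1
  g <- rnorm(40, 0, 2)
  d <- tidyr::expand_grid(genotype = sprintf("g%02d", 1:40), block = 1:3)
  d$value <- 10 + g[as.integer(factor(d$genotype))]
  vc <- estimate_variance_components(d, "value")
  expect_lt(vc$v_e, 1e-8)
  expect_equal(broad_sense_heritability(vc$v_g, vc$v_e), 1,
               tolerance = 1e-6)
  # no genotype signal: v_g ~ 0
  set.seed(8)
  d$value <- 10 + rnorm(nrow(d))
  vc0 <- estimate_variance_components(d, "value")
  expect_lt(vc0$v_g / (vc0$v_g + vc0$v_e), 0.15)
})

test_that("REML matches the balanced method-of-moments decomposition", {
  d <- simulate_trait_table(n_genotypes = 200, n_blocks = 3, v_g = 1,
                            v_block = 0.25, v_e = 1, seed = 31)
  vc <- estimate_variance_components(d, "value")
  mom <- mom_variance_components(d)
  expect_equal(vc$v_g, mom$v_g, tolerance = 1e-4)
  expect_equal(vc$v_block, mom$v_block, tolerance = 1e-3)
  expect_equal(vc$v_e, mom$v_e, tolerance = 1e-4)
  # estimates are in the right neighbourhood of truth
  expect_lt(abs(vc$v_g - 1) / 1, 0.15)
  expect_lt(abs(vc$v_e - 1) / 1, 0.15)
})

test_that("heritability formula and invariances", {
  expect_equal(broad_sense_heritability(2, 2), 0.5)
  expect_equal(broad_sense_heritability(1, 0), 1)
  expect_equal(broad_sense_heritability(1, 3), 0.25)
  expect_error(broad_sense_heritability(0, 0),
               class = "stemseason_domain_error")
  expect_error(broad_sense_heritability(-1, 2),
               class = "stemseason_domain_error")
  # affine rescaling of the trait leaves H^2 unchanged
  d <- simulate_trait_table(n_genotypes = 80, v_g = 2, v_block = 0.3,
                            v_e = 1.2, seed = 55)
  h1 <- estimate_variance_components(d, "value")
  d$scaled <- 3.7 * d$value - 12
  h2 <- estimate_variance_components(d, "scaled")
  expect_equal(broad_sense_heritability(h1$v_g, h1$v_e),
               broad_sense_heritability(h2$v_g, h2$v_e),
               tolerance = 1e-6)
})

test_that("unreplicated designs are non-estimable", {
  d <- tibble::tibble(genotype = sprintf("g%d", 1:10), block = 1,
                      value = rnorm(10))
  expect_error(estimate_variance_components(d, "value"),
               class = "stemseason_nonestimable_error")
})

test_that("correlations: exact lines, formula oracle, degenerate cells", {
  d <- tibble::tibble(x = 1:20)
  d$up <- 2 * d$x + 1
  d$down <- -d$x
  d$flat <- 5
  cm <- pearson_correlation_matrix(d, c("x", "up", "down", "flat"))
  cell <- function(i, j) {
    cm[cm$trait_i == i & cm$trait_j == j, ]
  }
  expect_equal(cell("x", "up")$r, 1, tolerance = 1e-12)
  expect_equal(cell("x", "down")$r, -1, tolerance = 1e-12)
  expect_equal(cell("x", "x")$r, 1)
  expect_equal(cell("x", "flat")$reason, "zero_variance")

  set.seed(99)
  z1 <- rnorm(50)
  d2 <- tibble::tibble(a = z1, b = 0.6 * z1 + sqrt(1 - 0.36) * rnorm(50))
  cm2 <- pearson_correlation_matrix(d2, c("a", "b"))
  o <- oracle_pearson(d2$a, d2$b)
  got <- cm2[cm2$trait_i == "a" & cm2$trait_j == "b", ]
  expect_equal(got$r, o$r, tolerance = 1e-12)
  expect_equal(got$p, o$p, tolerance = 1e-12)
  expect_equal(got$n, 50)
})

test_that("correlation matrix is positive semi-definite on complete cases", {
  sim <- simulate_trial(sim_config(n_genotypes = 40, seed = 17))
  tr <- dplyr::select(sim$truth, "max_gr", "day_max_gr", "start_logg",
                      "end_logg", "duration", "auc")
  cm <- pearson_correlation_matrix(tr, names(tr))
  wide <- matrix(NA_real_, 6, 6, dimnames = list(names(tr), names(tr)))
  for (k in seq_len(nrow(cm))) {
    wide[cm$trait_i[k], cm$trait_j[k]] <- cm$r[k]
    wide[cm$trait_j[k], cm$trait_i[k]] <- cm$r[k]
  }
  expect_gt(min(eigen(wide, symmetric = TRUE)$values), -1e-10)
})

test_that("identical group means give p ~ 1 and one shared letter", {
  d <- tibble::tibble(
    species_group = rep(c("s1", "s2", "s3"), each = 4),
    y = rep(c(5, 5, 5), each = 4) + rep(c(-1, 1), 6)
  )
  res <- species_anova_tukey(d, "y")
  expect_gt(res$anova$p_value[1], 0.99)
  expect_equal(unique(res$letters$letters), "a")
})

test_that("separated balanced groups match the one-way oracle F", {
  set.seed(123)
  d <- tibble::tibble(
    species_group = rep(c("lo", "hi"), each = 30),
    y = c(rnorm(30, 0, 1), rnorm(30, 5, 1))
  )
  res <- species_anova_tukey(d, "y")
  # hand-computed one-way ANOVA on balanced data
  gm <- tapply(d$y, d$species_group, mean)
  ssb <- 30 * sum((gm - mean(d$y))^2)
  ssw <- sum((d$y - gm[d$species_group])^2)
  f_oracle <- (ssb / 1) / (ssw / 58)
  expect_equal(res$anova$statistic[1], f_oracle, tolerance = 1e-10)
  expect_equal(sort(res$letters$letters), c("a", "b"))
})

test_that("type-III species SS equals the model-comparison definition", {
  set.seed(5)
  d <- tibble::tibble(
    species_group = rep(c("s1", "s2", "s3"), times = c(3, 5, 8)),
    y = rnorm(16, mean = rep(c(0, 1, 3), times = c(3, 5, 8)))
  )
  res <- species_anova_tukey(d, "y")
  rss_full <- sum(resid(lm(y ~ species_group, data = d))^2)
  rss_null <- sum(resid(lm(y ~ 1, data = d))^2)
  expect_equal(res$anova$sumsq[1], rss_null - rss_full,
               tolerance = 1e-10)
})

test_that("letter groups agree with an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  d <- tibble::tibble(
    species_group = rep(c("s1", "s2", "s3", "s4"),
                        times = c(12, 20, 9, 15)),
    y = rnorm(56, mean = rep(c(0, 0.4, 3, 3.2), times = c(12, 20, 9, 15)))
  )
  res <- species_anova_tukey(d, "y")
  fit <- stats::aov(y ~ species_group,
                    data = transform(d,
                                     species_group =
                                       factor(species_group)))
  ref <- multcomp::cld(
    multcomp::glht(fit, linfct = multcomp::mcp(species_group = "Tukey"))
  )$mcletters$Letters
  # same partition: groups share a letter in ours iff they do in the
  # reference (letter names may differ)
  share <- function(lab, g1, g2) {
    any(strsplit(lab[g1], "")[[1]] %in% strsplit(lab[g2], "")[[1]])
  }
  ours <- setNames(res$letters$letters, res$letters$species_group)
  for (g1 in names(ref)) {
    for (g2 in setdiff(names(ref), g1)) {
      expect_equal(share(ours, g1, g2), share(ref, g1, g2))
    }
  }
})

test_that("singleton species are dropped with a warning", {
  d <- tibble::tibble(
    species_group = c(rep("s1", 5), rep("s2", 5), "s3"),
    y = rnorm(11)
  )
  expect_warning(res <- species_anova_tukey(d, "y"), "fewer than 2")
  expect_setequal(res$letters$species_group, c("s1", "s2"))
})
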