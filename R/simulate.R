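#' Default species-group trait distributions
#'
#' Means and standard deviations of the three generator target traits
#' (maximum growth rate, its day, and the duration of the logarithmic
#' phase) for the seven species groups of a diverse *Miscanthus* trial,
#' with group weights proportional to the groups' genotype counts. A
#' small additive calibration per trait shifts all group means together
#' so that the mixture mean equals the all-plants calibration target
#' (MaxGR 2.1 cm/d, DayMaxGR 181.4, Duration 74.2 d); the between-group
#' structure is untouched.
#'
#' Each species group also carries a nominal collection-site latitude
#' around which genotype origins are drawn.
#'
#' @return A tibble with one row per species group.
#' @export
species_defaults <- function() {
  sp <- tibble::tribble(
    ~species_group, ~n_ref, ~max_gr_mean, ~max_gr_sd,
    ~day_max_gr_mean, ~day_max_gr_sd, ~duration_mean, ~duration_sd,
    ~lat_mean,
    "floridulus",        47, 1.0, 0.4, 211.1, 19.2, 96.2, 33.3, 24,
    "lutarioriparius",   79, 2.8, 0.8, 175.1, 10.6, 76.7, 11.3, 30,
    "sacchariflorus",   245, 2.5, 0.7, 174.6, 10.0, 63.8, 10.1, 40,
    "sinensis_A",       127, 1.5, 0.5, 184.6, 15.2, 87.4, 20.1, 33,
    "sinensis_B",        55, 2.3, 0.4, 180.6,  9.9, 59.3, 10.0, 36,
    "sinensis_C",       245, 1.9, 0.6, 182.0, 14.4, 78.0, 22.3, 38,
    "sinensis_D",        56, 2.0, 0.4, 184.2, 17.3, 76.8, 14.4, 36
  )
  sp$fraction <- sp$n_ref / sum(sp$n_ref)
  targets <- c(max_gr = 2.1, day_max_gr = 181.4, duration = 74.2)
  for (tr in names(targets)) {
    mcol <- paste0(tr, "_mean")
    sp[[mcol]] <- sp[[mcol]] + (targets[[tr]] -
                                  sum(sp$fraction * sp[[mcol]]))
  }
  sp
}

#' Configuration for the synthetic trial generator
#'
#' Bundles all generator settings with their defaults. The defaults
#' emulate the structure of a large perennial-grass diversity trial:
#' around 900 genotypes in 3 fully randomized blocks, species-structured
#' trait distributions, roughly fortnightly stem measurements from May to
#' late October, and 5 cm measurement noise on stem length.
#'
#' @param n_genotypes Number of genotypes (default 900).
#' @param n_blocks Number of randomized blocks (default 3).
#' @param species Species table as from [species_defaults()].
#' @param h2 Named vector of broad-sense heritabilities used to split
#'   each target trait's variance into genotype and plant-level
#'   environmental components (defaults 0.77, 0.66, 0.65 for
#'   `max_gr`, `day_max_gr`, `duration`).
#' @param block_sd_frac Block-effect SD as a fraction of each trait's SD
#'   (default 0.05; block variance is small relative to genotype and
#'   residual variance in a well-run trial).
#' @param noise_sd Measurement noise SD on stem length (cm; default 2,
#'   the precision of a tape measurement to the ligule of the youngest
#'   leaf).
#' @param stem_sample_bias Mean positive bias (cm) emulating recording
#'   the tallest of three sampled stems (default 0).
#' @param schedule Measurement days of year (default every 14 days from
#'   day 92 to 302, early April to late October, so that both early
#'   emergence and asymptotic growth are captured).
#' @param year Trial year label (default 2016).
#' @param d_sdlog SD of the log of the Richards shape parameter `d`
#'   drawn per genotype around 1 (default 0.25).
#' @param geo_lat_slope Planted within-species latitude effect on growth
#'   timing, days per degree latitude (default 0.5).
#' @param lat_sd,lon_mean,lon_sd,alt_mean,alt_sd Collection-site
#'   coordinate spreads.
#' @param dw_kappa Dry weight per unit AUC, g per cm-day (default 0.031,
#'   giving kilogram-scale plants at typical AUC).
#' @param dw_noise_sd Multiplicative dry-weight noise SD (default 0.1).
#' @param mc_range Lower bound and span of harvest moisture content
#'   (default `c(0.25, 0.4)`, i.e. MC in 0.25-0.65).
#' @param mc_noise_sd Noise SD on the moisture-content logistic score
#'   (default 0.5).
#' @param planted_dw_cor Either `NULL` (dry weight proportional to AUC)
#'   or a list `list(r, duration_range, x_trait, dw_mean, dw_sd)`
#'   planting a known within-duration-bin correlation between `x_trait`
#'   and dry weight for plants inside `duration_range` (and zero
#'   outside), used for ground-truth recovery of the binned analysis.
#' @param seed Integer seed driving all generator randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 900, n_blocks = 3,
                       species = species_defaults(),
                       h2 = c(max_gr = 0.77, day_max_gr = 0.66,
                              duration = 0.65),
                       block_sd_frac = 0.05,
                       noise_sd = 2, stem_sample_bias = 0,
                       schedule = seq(92, 302, by = 14),
                       year = 2016L,
                       d_sdlog = 0.25,
                       geo_lat_slope = 0.5, lat_sd = 3,
                       lon_mean = 120, lon_sd = 10,
                       alt_mean = 300, alt_sd = 250,
                       dw_kappa = 0.031, dw_noise_sd = 0.1,
                       mc_range = c(0.25, 0.4), mc_noise_sd = 0.5,
                       planted_dw_cor = NULL,
                       seed = 1L) {
  stopifnot(
    n_genotypes >= 1, n_blocks >= 1,
    all(c("max_gr", "day_max_gr", "duration") %in% names(h2)),
    all(h2 >= 0 & h2 <= 1),
    !is.unsorted(schedule, strictly = TRUE),
    noise_sd >= 0, d_sdlog >= 0,
    abs(sum(species$fraction) - 1) < 1e-8
  )
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Solve Richards parameters hitting target traits exactly (vectorized);
# `ok` marks solutions inside the fitter's parameter box.
solve_richards_targets <- function(max_gr, day_max_gr, duration, d) {
  disc <- sqrt((d + 3)^2 - 4)
  u_hi <- d / 2 * ((d + 3) + disc)
  r_span <- 2 * log(u_hi / d)  # log(u_hi / u_lo), since u_hi * u_lo = d^2
  c <- r_span / duration
  a <- max_gr / (c * (1 + d)^(-(d + 1) / d))
  b <- d * exp(c * day_max_gr)
  ok <- is.finite(a) & is.finite(b) & is.finite(c) &
    c > 1e-4 & c <= 1 & b > 1e-6 & b <= 1e8 & a > 0 &
    max_gr > 0.05 & duration > 5 & day_max_gr > 20
  list(a = a, b = b, c = c, d = d, ok = ok)
}

#' Generate a synthetic trial population with known ground truth
#'
#' Draws genotype trait targets from the configured species-specific
#' distributions, adds block and plant-level environmental effects to
#' realize the configured genotype/environment variance split, and solves
#' the Richards parameters per plant so that the derived growth
#' characteristics hit the targets exactly: the shape `d` is drawn per
#' genotype, the rate `c` follows from the target duration, the asymptote
#' `a` from the target maximum growth rate, and `b` from the target day
#' of maximum growth. Infeasible targets (outside the fitter's parameter
#' box) are rejection-resampled up to a cap.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` leaves the RNG state untouched (used
#'   when called from [simulate_trial()], which seeds once).
#' @return A list with `metadata` (plant_id, genotype, block,
#'   species_group, lat, lon, alt_m) and `truth` (metadata plus true
#'   Richards parameters and true growth characteristics).
#' @export
generate_population <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  sp <- config$species
  counts <- largest_remainder(sp$fraction, config$n_genotypes)
  n_g <- config$n_genotypes
  g_species <- rep(sp$species_group, counts)
  g_id <- sprintf("G%04d", seq_len(n_g))
  sp_row <- match(g_species, sp$species_group)

  h2 <- config$h2
  draw_target <- function(trait) {
    mu <- sp[[paste0(trait, "_mean")]][sp_row]
    sdv <- sp[[paste0(trait, "_sd")]][sp_row]
    mu + rnorm(n_g, 0, sqrt(h2[[trait]]) * sdv)
  }
  lat <- rnorm(n_g, sp$lat_mean[sp_row], config$lat_sd)
  lon <- rnorm(n_g, config$lon_mean, config$lon_sd)
  alt <- abs(rnorm(n_g, config$alt_mean, config$alt_sd))

  g_max_gr <- draw_target("max_gr")
  g_day <- draw_target("day_max_gr") +
    config$geo_lat_slope * (lat - sp$lat_mean[sp_row])
  g_dur <- draw_target("duration")
  g_d <- pmin(pmax(rlnorm(n_g, 0, config$d_sdlog), 0.3), 5)

  # per-block effects, shared by every plant in a block, per trait
  blocks <- seq_len(config$n_blocks)
  block_eff <- lapply(c("max_gr", "day_max_gr", "duration"), function(tr) {
    sd_pop <- sum(sp$fraction * sp[[paste0(tr, "_sd")]])
    rnorm(config$n_blocks, 0, config$block_sd_frac * sd_pop)
  })
  names(block_eff) <- c("max_gr", "day_max_gr", "duration")

  env_sd <- function(trait) {
    sdv <- sp[[paste0(trait, "_sd")]][sp_row]
    sqrt(1 - h2[[trait]]) * sdv
  }
  sd_e <- list(max_gr = env_sd("max_gr"), day_max_gr = env_sd("day_max_gr"),
               duration = env_sd("duration"))

  gi <- rep(seq_len(n_g), each = config$n_blocks)
  blk <- rep(blocks, times = n_g)
  n_p <- length(gi)
  draw_plant <- function(rows) {
    list(
      max_gr = g_max_gr[gi[rows]] + block_eff$max_gr[blk[rows]] +
        rnorm(length(rows), 0, sd_e$max_gr[gi[rows]]),
      day = g_day[gi[rows]] + block_eff$day_max_gr[blk[rows]] +
        rnorm(length(rows), 0, sd_e$day_max_gr[gi[rows]]),
      dur = g_dur[gi[rows]] + block_eff$duration[blk[rows]] +
        rnorm(length(rows), 0, sd_e$duration[gi[rows]])
    )
  }
  tgt <- draw_plant(seq_len(n_p))
  sol <- solve_richards_targets(tgt$max_gr, tgt$day, tgt$dur, g_d[gi])
  # rejection-resample plants whose targets imply parameters outside the
  # fitter's box
  for (round in 1:50) {
    bad <- which(!sol$ok)
    if (length(bad) == 0) break
    redraw <- draw_plant(bad)
    cand <- solve_richards_targets(redraw$max_gr, redraw$day, redraw$dur,
                                   g_d[gi[bad]])
    for (fld in c("max_gr", "day", "dur")) {
      tgt[[fld]][bad] <- redraw[[fld]]
    }
    for (fld in c("a", "b", "c", "d", "ok")) {
      sol[[fld]][bad] <- cand[[fld]]
    }
  }
  if (any(!sol$ok)) {
    abort(paste0("Could not find feasible Richards parameters for ",
                 sum(!sol$ok), " plant(s) after 50 resamples."),
          class = "stemseason_infeasible_target_error")
  }
  truth <- tibble::tibble(
    plant_id = paste0(g_id[gi], "_B", blk),
    genotype = g_id[gi], block = blk,
    species_group = g_species[gi],
    lat = lat[gi], lon = lon[gi], alt_m = alt[gi],
    a = sol$a, b = sol$b, c = sol$c, d = sol$d,
    max_gr = tgt$max_gr, day_max_gr = tgt$day,
    start_logg = tgt$day - tgt$dur / 2,
    end_logg = tgt$day + tgt$dur / 2,
    duration = tgt$dur
  )
  truth$year <- config$year
  truth$auc <- vapply(seq_len(nrow(truth)), function(k) {
    richards_auc(truth$a[k], truth$b[k], truth$c[k], truth$d[k])
  }, numeric(1))
  truth$day_at_15cm <- NA_real_
  reach <- truth$a > 15
  truth$day_at_15cm[reach] <- -(1 / truth$c[reach]) *
    log(expm1(truth$d[reach] * log(truth$a[reach] / 15)) / truth$b[reach])
  metadata <- dplyr::select(
    truth, "plant_id", "genotype", "block", "species_group",
    "lat", "lon", "alt_m"
  )
  list(metadata = metadata, truth = truth)
}

largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate noisy stem-elongation measurements from true curves
#'
#' Evaluates each plant's true Richards curve at the measurement schedule
#' and adds i.i.d. Gaussian noise (truncated at zero). A small positive
#' bias can emulate recording the tallest of three sampled stems.
#'
#' @param truth Truth table from [generate_population()].
#' @param config A [sim_config()].
#' @inheritParams generate_population
#' @return Long tibble with `plant_id`, `year`, `day`, `length_cm`.
#' @export
generate_measurements <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- config$schedule
  stopifnot(all(sched >= 1 & sched <= 365))
  n <- nrow(truth)
  out <- tidyr::expand_grid(
    i = seq_len(n), day = sched
  )
  out$plant_id <- truth$plant_id[out$i]
  out$year <- truth$year[out$i]
  clean <- richards_value_rows(truth, out$i, out$day)
  noise <- rnorm(nrow(out), config$stem_sample_bias, config$noise_sd)
  out$length_cm <- pmax(0, clean + noise)
  dplyr::select(out, "plant_id", "year", "day", "length_cm")
}

richards_value_rows <- function(truth, rows, x) {
  a <- truth$a[rows]; b <- truth$b[rows]
  cc <- truth$c[rows]; d <- truth$d[rows]
  a * exp(-log1p(exp(log(b) - cc * x)) / d)
}

#' Generate a temperate-season daily weather series
#'
#' Sinusoidal annual temperature course with day-to-day noise;
#' `tmax >= tmin` holds by construction.
#'
#' @param config A [sim_config()].
#' @inheritParams generate_population
#' @param t_mean_annual,t_amplitude Annual mean and seasonal amplitude of
#'   the daily mean temperature (degrees C).
#' @param diurnal_range Mean tmax - tmin (degrees C).
#' @param t_noise_sd Day-to-day noise SD (degrees C).
#' @return Tibble with `day` (1-365), `tmax_c`, `tmin_c`.
#' @export
generate_weather <- function(config, seed = NULL,
                             t_mean_annual = 9.5, t_amplitude = 5.5,
                             diurnal_range = 7, t_noise_sd = 2) {
  if (!is.null(seed)) set.seed(seed)
  day <- 1:365
  tmean <- t_mean_annual +
    t_amplitude * sin(2 * pi * (day - 105) / 365) +
    rnorm(365, 0, t_noise_sd)
  half <- pmax(0.5, diurnal_range / 2 + rnorm(365, 0, t_noise_sd / 2))
  tibble::tibble(day = day, tmax_c = tmean + half, tmin_c = tmean - half)
}

#' Generate harvest records consistent with the true growth curves
#'
#' By default dry weight is proportional to the true AUC with
#' multiplicative noise, and moisture content is a bounded logistic
#' function of the standardized end of logarithmic growth minus the
#' standardized maximum growth rate (late-growing plants carry wetter
#' biomass; fast growers drier). Subsample wet/dry weights are
#' back-computed so [estimate_dry_weight()] reproduces the planted values
#' exactly.
#'
#' When `config$planted_dw_cor` is set, dry weight is instead built to
#' have a known correlation with a chosen trait inside a duration range
#' and zero correlation outside, for ground-truth recovery of the binned
#' analysis.
#'
#' @param truth Truth table from [generate_population()].
#' @param config A [sim_config()].
#' @inheritParams generate_population
#' @return Tibble with `plant_id`, `year`, `wet_g`, `sub_wet_g`,
#'   `sub_dry_g`, plus the planted `dw` and `mc`.
#' @export
generate_harvest <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  z <- function(v) (v - mean(v)) / sd(v)
  pc <- config$planted_dw_cor
  if (is.null(pc)) {
    dw <- config$dw_kappa * truth$auc *
      pmax(0.05, 1 + rnorm(n, 0, config$dw_noise_sd))
  } else {
    r_i <- ifelse(
      truth$duration >= pc$duration_range[1] &
        truth$duration < pc$duration_range[2],
      pc$r, 0
    )
    zx <- z(truth[[pc$x_trait %||% "start_logg"]])
    dw_mean <- pc$dw_mean %||% 400
    dw_sd <- pc$dw_sd %||% 60
    dw <- dw_mean + dw_sd * (r_i * zx +
                               sqrt(1 - r_i^2) * rnorm(n))
    dw <- pmax(dw, 1)
  }
  score <- z(truth$end_logg) - z(truth$max_gr) +
    rnorm(n, 0, config$mc_noise_sd)
  mc <- config$mc_range[1] + config$mc_range[2] * plogis(score)
  sub_wet <- 200
  tibble::tibble(
    plant_id = truth$plant_id, year = truth$year,
    wet_g = dw / (1 - mc),
    sub_wet_g = sub_wet,
    sub_dry_g = sub_wet * (1 - mc),
    dw = dw, mc = mc
  )
}

#' Simulate a complete trial dataset
#'
#' Seeds the RNG once from `config$seed` and runs the four generators in
#' order, so the whole dataset is reproducible from the single seed.
#'
#' @param config A [sim_config()].
#' @return A list with `metadata`, `truth`, `measurements`, `weather`,
#'   `harvest` tibbles.
#' @examples
#' sim <- simulate_trial(sim_config(n_genotypes = 10, seed = 42))
#' names(sim)
#' @export
simulate_trial <- function(config = sim_config()) {
  set.seed(config$seed)
  pop <- generate_population(config, seed = NULL)
  measurements <- generate_measurements(pop$truth, config, seed = NULL)
  weather <- generate_weather(config, seed = NULL)
  harvest <- generate_harvest(pop$truth, config, seed = NULL)
  list(metadata = pop$metadata, truth = pop$truth,
       measurements = measurements, weather = weather, harvest = harvest)
}

#' Simulate a balanced genotype-by-block trait table
#'
#' Direct simulation of `value = mu + genotype + block + error` with
#' known variance components; the ground truth for heritability recovery.
#'
#' @param n_genotypes,n_blocks Design size (default 200 x 3).
#' @param v_g,v_block,v_e True variance components.
#' @param mu Grand mean.
#' @param seed Optional seed.
#' @return Tibble with `genotype`, `block`, `value`.
#' @export
simulate_trait_table <- function(n_genotypes = 200, n_blocks = 3,
                                 v_g = 1, v_block = 0.25, v_e = 1,
                                 mu = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- rnorm(n_genotypes, 0, sqrt(v_g))
  b <- rnorm(n_blocks, 0, sqrt(v_block))
  out <- tidyr::expand_grid(genotype = sprintf("G%04d", 1:n_genotypes),
                            block = seq_len(n_blocks))
  out$value <- mu + g[match(out$genotype,
                            sprintf("G%04d", 1:n_genotypes))] +
    b[out$block] + rnorm(nrow(out), 0, sqrt(v_e))
  out
}
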