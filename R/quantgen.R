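#' Moisture content and whole-plant dry weight from harvest records
#'
#' At harvest the whole plant is weighed fresh and a subsample (roughly
#' 200 g) is weighed fresh and again after oven-drying to constant weight.
#' The subsample's moisture content is applied to the whole-plant fresh
#' weight:
#' `mc = (sub_wet - sub_dry) / sub_wet`, `dw = plant_wet * (1 - mc)`.
#'
#' @param plant_wet Whole-plant fresh weight (g).
#' @param sub_wet,sub_dry Subsample fresh and dry weight (g); vectors are
#'   recycled to common length.
#' @return A tibble with columns `mc` (fraction in `[0, 1)`) and `dw` (g).
#' @examples
#' estimate_dry_weight(1000, 200, 100)
#' @export
estimate_dry_weight <- function(plant_wet, sub_wet, sub_dry) {
  if (any(sub_wet <= 0)) {
    abort("`sub_wet` must be positive.", class = "stemseason_domain_error")
  }
  if (any(sub_dry > sub_wet)) {
    abort("`sub_dry` exceeds `sub_wet`: inconsistent measurement.",
          class = "stemseason_measurement_error")
  }
  if (any(sub_dry <= 0)) {
    abort("`sub_dry` must be positive.", class = "stemseason_domain_error")
  }
  mc <- (sub_wet - sub_dry) / sub_wet
  tibble::tibble(mc = mc, dw = plant_wet * (1 - mc))
}

#' Variance components of a genotype-and-block random-effects model
#'
#' Fits, by REML ([lme4::lmer()]), the two-random-effect model
#' `value = mu + genotype + block + error` and returns the boundary-
#' constrained (non-negative) variance component estimates. This is the
#' standard randomized-complete-block decomposition for a clonally
#' replicated trial, in which the genotype variance is the total genetic
#' variance.
#'
#' @param data Data frame with one row per plant.
#' @param value Name (string) of the trait column.
#' @param genotype,block Names of the genotype and block columns.
#' @return A one-row tibble with `v_g`, `v_block`, `v_e`, `n_genotypes`,
#'   `n_obs`.
#' @examples
#' sim <- simulate_trait_table(n_genotypes = 50, v_g = 2, v_block = 0.3,
#'                             v_e = 1, seed = 1)
#' estimate_variance_components(sim, "value")
#' @export
estimate_variance_components <- function(data, value, genotype = "genotype",
                                         block = "block") {
  require_columns(data, c(value, genotype, block), "data")
  df <- data.frame(
    y = data[[value]],
    genotype = factor(data[[genotype]]),
    block = factor(data[[block]])
  )
  df <- df[is.finite(df$y), ]
  reps <- table(df$genotype)
  if (nlevels(df$genotype) < 2 || sum(reps >= 2) < 2) {
    abort("Need at least two genotypes with two replicates each.",
          class = "stemseason_nonestimable_error")
  }
  fit <- suppressMessages(lme4::lmer(
    y ~ 1 + (1 | genotype) + (1 | block), data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) vc$vcov[match(g, vc$grp)]
  tibble::tibble(
    v_g = max(0, get_vc("genotype")),
    v_block = max(0, get_vc("block")),
    v_e = max(0, get_vc("Residual")),
    n_genotypes = nlevels(df$genotype),
    n_obs = nrow(df)
  )
}

#' Broad-sense heritability
#'
#' `H^2 = v_g / (v_g + v_e)`: the fraction of (non-block) phenotypic
#' variance attributable to total genetic variance. The block variance is
#' deliberately excluded from the denominator.
#'
#' @param v_g,v_e Genetic and error variance components (non-negative,
#'   not both zero).
#' @return Heritability in `[0, 1]`.
#' @examples
#' broad_sense_heritability(2, 2) # 0.5
#' @export
broad_sense_heritability <- function(v_g, v_e) {
  if (any(v_g < 0) || any(v_e < 0)) {
    abort("Variance components must be non-negative.",
          class = "stemseason_domain_error")
  }
  if (any(v_g + v_e == 0)) {
    abort("H^2 is undefined when v_g and v_e are both zero.",
          class = "stemseason_domain_error")
  }
  v_g / (v_g + v_e)
}

#' Heritability of each trait in a trait table
#'
#' Runs [estimate_variance_components()] per trait column and appends
#' `h2 = v_g / (v_g + v_e)`.
#'
#' @param data Trait table with one row per plant (genotype x block).
#' @param traits Character vector of trait column names.
#' @inheritParams estimate_variance_components
#' @return A tibble with one row per trait: `trait`, `v_g`, `v_block`,
#'   `v_e`, `h2`, `n_genotypes`, `n_obs`.
#' @export
heritability <- function(data, traits, genotype = "genotype",
                         block = "block") {
  require_columns(data, traits, "data")
  purrr::map_dfr(traits, function(tr) {
    vc <- estimate_variance_components(data, tr, genotype = genotype,
                                       block = block)
    dplyr::mutate(vc, trait = tr,
                  h2 = broad_sense_heritability(.data$v_g, .data$v_e),
                  .before = 1)
  }) |>
    dplyr::relocate("trait", "v_g", "v_block", "v_e", "h2")
}

#' Pairwise Pearson correlations among traits
#'
#' Pearson product-moment correlation with two-sided p-values from the
#' t-distribution on `n - 2` degrees of freedom, computed on pairwise-
#' complete observations. Cells with fewer than `min_pairs` complete pairs
#' or with a zero-variance trait are reported as missing with a reason,
#' not dropped.
#'
#' @param data Trait table.
#' @param traits Character vector of trait columns to correlate.
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return A long tibble with `trait_i`, `trait_j`, `r`, `p`, `n`,
#'   `reason` covering every unordered pair (diagonal included, `r = 1`).
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + rnorm(10))
#' pearson_correlation_matrix(d, c("x", "y"))
#' @export
pearson_correlation_matrix <- function(data, traits, min_pairs = 3) {
  require_columns(data, traits, "data")
  pairs <- expand.grid(i = seq_along(traits), j = seq_along(traits))
  pairs <- pairs[pairs$i <= pairs$j, ]
  purrr::pmap_dfr(pairs, function(i, j) {
    xi <- data[[traits[i]]]; xj <- data[[traits[j]]]
    ok <- is.finite(xi) & is.finite(xj)
    n <- sum(ok)
    base <- tibble::tibble(trait_i = traits[i], trait_j = traits[j],
                           r = NA_real_, p = NA_real_, n = n,
                           reason = NA_character_)
    if (i == j) {
      base$r <- 1
      return(base)
    }
    if (n < min_pairs) {
      base$reason <- "too_few_pairs"
      return(base)
    }
    if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
      base$reason <- "zero_variance"
      return(base)
    }
    ct <- cor.test(xi[ok], xj[ok], method = "pearson")
    base$r <- unname(ct$estimate)
    base$p <- ct$p.value
    base
  })
}

#' Species comparison: type-III ANOVA and Tukey letter groups
#'
#' Compares a trait between species groups of unequal size. The species
#' effect is tested with type-III sums of squares (sum-to-zero contrasts,
#' via [car::Anova()]); pairwise differences use the Tukey-Kramer HSD at
#' `alpha`, compacted to letter groups by the insert-and-absorb algorithm
#' (groups sharing a letter are not significantly different). Letter
#' assignment order breaks ties by group sample size (largest first) then
#' name. Species with a single observation are dropped with a warning.
#'
#' @param data Trait table.
#' @param trait Name (string) of the trait column.
#' @param group Name of the species-group column (default
#'   `"species_group"`).
#' @param alpha Family-wise significance level for the HSD (default 0.05).
#' @return A list of class `species_anova` with `anova` (term-level
#'   tibble), `letters` (per-species tibble with `n`, `mean`, `letters`)
#'   and `tukey` (pairwise tibble with differences and adjusted p).
#' @export
species_anova_tukey <- function(data, trait, group = "species_group",
                                alpha = 0.05) {
  require_columns(data, c(trait, group), "data")
  df <- data.frame(y = data[[trait]], g = factor(data[[group]]))
  df <- df[is.finite(df$y), ]
  counts <- table(df$g)
  if (any(counts < 2)) {
    dropped <- names(counts)[counts < 2]
    warn(paste0("Dropping group(s) with fewer than 2 observations: ",
                paste(dropped, collapse = ", ")))
    df <- df[!df$g %in% dropped, ]
    df$g <- droplevels(df$g)
    counts <- table(df$g)
  }
  if (nlevels(df$g) < 2) {
    abort("Need at least two groups with two or more observations.",
          class = "stemseason_nonestimable_error")
  }
  fit <- lm(y ~ g, data = df,
            contrasts = list(g = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  anova_tbl <- tibble::tibble(
    term = c("species", "residuals"),
    sumsq = a3[c("g", "Residuals"), "Sum Sq"],
    df = a3[c("g", "Residuals"), "Df"],
    statistic = a3[c("g", "Residuals"), "F value"],
    p_value = a3[c("g", "Residuals"), "Pr(>F)"]
  )
  hsd <- TukeyHSD(aov(y ~ g, data = df), conf.level = 1 - alpha)$g
  cmp <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tukey_tbl <- tibble::tibble(
    group_1 = vapply(cmp, `[`, "", 1),
    group_2 = vapply(cmp, `[`, "", 2),
    diff = hsd[, "diff"],
    p_adj = hsd[, "p adj"]
  )
  lvls <- names(sort(counts, decreasing = TRUE))
  # stable sort: size descending, ties by name
  lvls <- lvls[order(-counts[lvls], lvls)]
  sig <- tukey_tbl[tukey_tbl$p_adj < alpha, , drop = FALSE]
  letters_map <- compact_letter_display(
    lvls, Map(c, sig$group_1, sig$group_2)
  )
  means <- tapply(df$y, df$g, mean)
  letters_tbl <- tibble::tibble(
    !!group := names(counts),
    n = as.integer(counts),
    mean = as.numeric(means[names(counts)]),
    letters = unname(letters_map[names(counts)])
  )
  out <- list(anova = anova_tbl, letters = letters_tbl, tukey = tukey_tbl,
              trait = trait, alpha = alpha)
  class(out) <- "species_anova"
  out
}

# insert-and-absorb compact letter display
# groups: ordered vector of group names (assignment order)
# sig_pairs: list of length-2 vectors, significantly different pairs
compact_letter_display <- function(groups, sig_pairs) {
  cols <- list(groups) # each column: set of groups sharing a letter
  for (pr in sig_pairs) {
    i <- 1L
    while (i <= length(cols)) {
      if (all(pr %in% cols[[i]])) {
        col <- cols[[i]]
        cols[[i]] <- setdiff(col, pr[1])
        cols <- append(cols, list(setdiff(col, pr[2])), after = i)
        # absorb: drop any column contained in another
        keep <- rep(TRUE, length(cols))
        for (k in seq_along(cols)) {
          for (l in seq_along(cols)) {
            if (k != l && keep[l] &&
                all(cols[[k]] %in% cols[[l]]) &&
                (length(cols[[k]]) < length(cols[[l]]) || k > l)) {
              keep[k] <- FALSE
              break
            }
          }
        }
        cols <- cols[keep]
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  labels <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) {
      labels[g] <- paste0(labels[g], letters[k])
    }
  }
  labels
}

#' @export
print.species_anova <- function(x, ...) {
  cat("Species comparison for trait `", x$trait, "`\n", sep = "")
  cat("Type-III ANOVA:\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  cat("\nTukey HSD letter groups (alpha = ", x$alpha, "):\n", sep = "")
  print(as.data.frame(x$letters), row.names = FALSE)
  invisible(x)
}

#' @rdname species_anova_tukey
#' @param x A `species_anova` object.
#' @param ... Unused.
#' @method tidy species_anova
#' @export
tidy.species_anova <- function(x, ...) x$anova

#' @rdname species_anova_tukey
#' @method glance species_anova
#' @export
glance.species_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$anova$statistic[1],
    p_value = x$anova$p_value[1],
    df_species = x$anova$df[1],
    df_residual = x$anova$df[2],
    n_groups = nrow(x$letters)
  )
}
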