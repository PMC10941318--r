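# A fast spec for unit-level fits.
quick_spec <- function(..., seed = 1L) {
  zib_model_spec(..., chains = 2, iterations = 600, warmup = 250,
                 seed = seed)
}

test_that("the design matrix uses treatment coding with the stated baseline",
{
  df <- data.frame(
    focal_id = sprintf("F%d", 1:8), partner_id = sprintf("P%d", 1:8),
    sri = runif(8),
    relationship = rep(c("other_adults", "parents", "siblings", "peers"),
                       2),
    overlap = runif(8), focal_age_days = rnorm(8))
  spec <- quick_spec(fixed_terms = c("relationship", "overlap",
                                     "focal_age_days"),
                     interactions = list(c("relationship",
                                           "focal_age_days")))
  des <- build_design(df, spec)
  expect_true("relationshipparents" %in% des$terms)
  expect_false(any(grepl("other_adults", des$terms)))
  # 1 intercept + 3 dummies + 2 mains + 3 interaction columns
  expect_equal(ncol(des$X), 9)
  # no interactions -> main-effect columns only
  des0 <- build_design(df, quick_spec(fixed_terms = c("overlap")))
  expect_equal(des0$terms, c("(Intercept)", "overlap"))
  expect_error(build_design(df[, -5], spec), "overlap")
  # index maps address the right levels
  expect_equal(length(des$focal_levels), 8)
  expect_equal(des$mem1,
               match(df$focal_id, sort(unique(c(df$focal_id,
                                                df$partner_id)))))
})

test_that("fits are reproducible and recover a planted covariate effect", {
  sim <- simulate_zib_data(n_birds = 30, n_dyads = 350,
                           beta = c("(Intercept)" = -2, overlap = log(2)),
                           seed = 5)
  spec <- quick_spec(fixed_terms = "overlap", seed = 11)
  fit <- suppressWarnings(fit_zib_mm(sim$dyad_table, spec))
  fit2 <- suppressWarnings(fit_zib_mm(sim$dyad_table, spec))
  expect_identical(fit$combined, fit2$combined)
  expect_equal(nrow(fit$combined),
               spec$chains * (spec$iterations - spec$warmup))
  s <- summarize_odds_ratios(fit, "overlap")
  expect_gt(s$or_mean, 1.2)
  expect_lt(s$or_mean, 3.5)
  expect_true(all(c("b_(Intercept)", "b_overlap", "phi", "sigma_a",
                    "sigma_m", "zi_(Intercept)") %in%
                    colnames(fit$combined)))
  expect_true(all(fit$rhat >= 1 | is.na(fit$rhat)))
})

test_that("the two MCMC engines agree on a shared fixture", {
  skip_if_not_installed("rjags")
  sim <- simulate_zib_data(n_birds = 25, n_dyads = 250,
                           beta = c("(Intercept)" = -1.5,
                                    overlap = log(2)),
                           pi = 0.25, seed = 8)
  spec <- zib_model_spec(fixed_terms = "overlap", chains = 2,
                         iterations = 1200, warmup = 500, seed = 21)
  fa <- suppressWarnings(fit_zib_mm(sim$dyad_table, spec))
  fj <- suppressWarnings(fit_zib_mm(sim$dyad_table, spec,
                                    engine = "jags"))
  for (p in c("b_(Intercept)", "b_overlap", "phi", "zi_(Intercept)")) {
    ma <- mean(fa$combined[, p])
    mj <- mean(fj$combined[, p])
    tol <- 3 * sqrt(sd(fa$combined[, p])^2 / fa$ess[p] +
                      sd(fj$combined[, p])^2 / max(fj$ess[p], 20)) + 0.05
    expect_lt(abs(ma - mj), max(tol, 0.12 * abs(mj) + 0.05))
  }
})

test_that("an all-zero response concentrates the zero-inflation near 1", {
  df <- data.frame(focal_id = rep(sprintf("F%d", 1:10), 5),
                   partner_id = rep(sprintf("F%d", c(2:10, 1)), 5),
                   sri = 0, overlap = runif(50))
  fit <- suppressWarnings(fit_zib_mm(df, quick_spec(fixed_terms =
                                                      "overlap")))
  pi_draws <- plogis(fit$combined[, "zi_(Intercept)"])
  expect_gt(mean(pi_draws), 0.9)
})

test_that("responses of exactly 1 are handled by both mapping options", {
  df <- data.frame(focal_id = rep(sprintf("F%d", 1:10), 4),
                   partner_id = rep(sprintf("F%d", c(2:10, 1)), 4),
                   sri = rep(c(1, 0.4, 0, 0.7), 10),
                   overlap = runif(40))
  for (h in c("epsilon", "compress")) {
    fit <- suppressWarnings(
      fit_zib_mm(df, quick_spec(fixed_terms = "overlap",
                                zero_one_handling = h)))
    expect_s3_class(fit, "zib_fit")
  }
  df$sri[1] <- 1.2
  expect_error(fit_zib_mm(df, quick_spec(fixed_terms = "overlap")),
               "\\[0, 1\\]")
})

test_that("odds-ratio summaries follow the CI-excludes-1 rule", {
  fake <- structure(list(
    combined = cbind(`b_(Intercept)` = rep(0, 400),
                     b_zero = rep(0, 400),
                     b_two = rep(log(2), 400),
                     b_mixed = c(rep(-0.1, 200), rep(0.1, 200))),
    design = list(terms = c("(Intercept)", "zero", "two", "mixed"))),
    class = "zib_fit")
  s <- summarize_odds_ratios(fake)
  expect_equal(s$or_mean[s$term == "zero"], 1)
  expect_equal(s$ci_low[s$term == "zero"], 1)
  expect_equal(s$ci_high[s$term == "zero"], 1)
  expect_false(s$significant[s$term == "zero"])
  expect_equal(s$or_mean[s$term == "two"], 2)
  expect_true(s$significant[s$term == "two"])
  expect_false(s$significant[s$term == "mixed"])
  expect_error(summarize_odds_ratios(fake, "nope"), "unknown")
  # percentile summaries match a sorting oracle on stored draws
  set.seed(3)
  dr <- rnorm(1000, 0.2, 0.4)
  fake2 <- structure(list(combined = cbind(b_x = dr),
                          design = list(terms = "x")),
                     class = "zib_fit")
  s2 <- summarize_odds_ratios(fake2, "x")
  sorted <- sort(exp(dr))
  # the 2.5th percentile leaves at most 2.5% of draws strictly below it
  expect_lte(mean(sorted < s2$ci_low), 0.025)
  expect_gte(mean(sorted <= s2$ci_low), 0.025)
  expect_lte(mean(sorted < s2$ci_high), 0.975)
  expect_gte(mean(sorted <= s2$ci_high), 0.975)
  expect_equal(s2$or_mean, mean(exp(dr)))
})

test_that("posterior predictive replication brackets self-generated data", {
  sim <- simulate_zib_data(n_birds = 30, n_dyads = 400,
                           beta = c("(Intercept)" = -2, overlap = log(2)),
                           pi = 0.3, seed = 13)
  fit <- suppressWarnings(fit_zib_mm(sim$dyad_table,
                                     quick_spec(fixed_terms = "overlap",
                                                seed = 17)))
  ppc <- posterior_predictive_check(fit, n_rep = 150, seed = 4)
  expect_equal(ppc$n_rep, 150)
  expect_equal(length(ppc$zero_fraction$replicated), 150)
  expect_gt(ppc$zero_fraction$quantile, 0.025)
  expect_lt(ppc$zero_fraction$quantile, 0.975)
  expect_gt(ppc$mean_nonzero$quantile, 0.025)
  expect_lt(ppc$mean_nonzero$quantile, 0.975)
  ppc2 <- posterior_predictive_check(fit, n_rep = 150, seed = 4)
  expect_identical(ppc$zero_fraction$replicated,
                   ppc2$zero_fraction$replicated)
})

test_that("the dyad-intercept alternative random structure fits", {
  sim <- simulate_zib_data(n_birds = 20, n_dyads = 200,
                           beta = c("(Intercept)" = -1.5,
                                    overlap = log(2)), seed = 23)
  spec <- quick_spec(fixed_terms = "overlap",
                     random_structure = list(dyad_intercept = TRUE))
  fit <- suppressWarnings(fit_zib_mm(sim$dyad_table, spec))
  expect_true("sigma_d" %in% colnames(fit$combined))
  expect_true(any(grepl("^d\\[", colnames(fit$combined))))
})
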