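test_that("standardize z-scores over analyzed rows and is idempotent", {
  run <- default_run()
  trials <- simulate_responses(run$tab, run$lists, response_model(), 4L, seed = 3L)
  trials$sv_raw <- ifelse(is.na(trials$sim_vision_z), NA,
                          3 + 2 * trials$sim_vision_z)
  z1 <- standardize(trials, "sv_raw")
  lure <- lure_rows(z1)
  expect_equal(mean(z1$sv_raw[lure]), 0, tolerance = 1e-10)
  expect_equal(sd(z1$sv_raw[lure]), 1, tolerance = 1e-10)
  expect_true(all(is.na(z1$sv_raw[!lure])))

  z2 <- standardize(z1, "sv_raw")
  expect_equal(z2$sv_raw, z1$sv_raw, tolerance = 1e-10)

  # balanced repeated design: equals unique-item standardization broadcast,
  # exactly so after the Bessel factor relating the K*n-row and n-value SDs
  uni <- z1$sv_raw[lure][!duplicated(z1$item_id[lure])]
  raw_uni <- trials$sv_raw[lure][!duplicated(trials$item_id[lure])]
  n <- length(raw_uni)
  K <- sum(lure) / n
  bessel <- sqrt((K * n - 1) / (K * (n - 1)))
  expect_equal(uni / bessel, (raw_uni - mean(raw_uni)) / sd(raw_uni),
               tolerance = 1e-10)
  expect_equal(uni, (raw_uni - mean(raw_uni)) / sd(raw_uni), tolerance = 5e-3)

  trials$const <- 1
  expect_error(standardize(trials, "const"), class = "drm_degenerate_error")
  expect_error(standardize(trials, "no_such"), class = "drm_precondition_error")
})

test_that("the crossed-intercept GLMM degenerates to plain logistic regression", {
  run <- default_run()
  zero_re <- response_model(sd_participant = 0, sd_list = 0)
  trials <- simulate_responses(run$tab, run$lists, zero_re, 12L, seed = 41L)
  fit <- suppressWarnings(
    fit_glmm(trials, glmm_spec(fixed_terms = c("sim_vision_z", "sim_language_z"))))
  lure <- trials[trials$role != "target", ]
  oracle <- stats::glm(response ~ sim_vision_z + sim_language_z,
                       data = lure, family = stats::binomial())
  expect_equal(unname(fit$terms$b), unname(coef(oracle)), tolerance = 0.02)
  expect_identical(fit$n_obs, nrow(lure))
  # AIC identity holds and n_params counts fixed effects + variance components
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_identical(fit$n_params, 5L)
  expect_named(fit$variance_components, c("participant_id", "list_id"),
               ignore.order = TRUE)
})

test_that("fit_glmm recovers known coefficients in simulation", {
  run <- default_run()
  truth <- response_model(beta_vision = 0.9, beta_language = 0.4)
  bs <- vapply(1:5, function(s) {
    trials <- simulate_responses(run$tab, run$lists, truth, 30L, seed = 700L + s)
    fit <- fit_glmm(trials, glmm_spec(fixed_terms = c("sim_vision_z", "sim_language_z")))
    c(fit$terms$b[fit$terms$term == "sim_vision_z"],
      fit$terms$b[fit$terms$term == "sim_language_z"])
  }, numeric(2))
  mc_se <- apply(bs, 1, sd) / sqrt(ncol(bs))
  expect_lt(abs(mean(bs[1, ]) - 0.9), 3 * mc_se[1] + 0.02)
  expect_lt(abs(mean(bs[2, ]) - 0.4), 3 * mc_se[2] + 0.02)
})

test_that("complete separation raises a diagnostic error", {
  toy <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), 5),
    list_id = rep(1:2, each = 5),
    role = "lure_close",
    x = c(-5, -4, -3, -2, -1, 1, 2, 3, 4, 5),
    response = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_error(suppressWarnings(fit_glmm(toy, glmm_spec(fixed_terms = "x"))),
               class = "drm_separation_error")
})

test_that("fit_glmm validates its inputs", {
  toy <- toy_trials()
  toy$response[1] <- 2
  expect_error(fit_glmm(toy, glmm_spec(fixed_terms = "sim_vision_z")),
               class = "drm_precondition_error")
  toy2 <- toy_trials()
  expect_error(fit_glmm(toy2, glmm_spec(fixed_terms = "sim_vision_z")),
               class = "drm_precondition_error")  # single participant level
})

test_that("hierarchical comparison reproduces the Akaike-weight algebra", {
  mk <- function(aic, loglik, k, n = 100L) {
    list(aic = aic, loglik = loglik, n_params = k, n_obs = n)
  }
  # identical AICs -> even weights, evidence ratio 1
  even <- compare_hierarchical(mk(100, -48, 2), mk(100, -47, 3))
  expect_equal(unname(even$akaike_weights), c(0.5, 0.5))
  expect_equal(even$evidence_ratio, 1)
  expect_equal(sum(even$akaike_weights), 1)

  # dAIC = 2 -> evidence ratio e (~2.7)
  two <- compare_hierarchical(mk(102, -49, 2), mk(100, -46, 3))
  expect_equal(two$delta_aic, 2)
  expect_equal(two$evidence_ratio, exp(1))
  expect_equal(round(two$evidence_ratio, 1), 2.7)

  # LRT chi2 9.39 adding one parameter -> dAIC 7.39, winner weight .976
  ll0 <- -200
  ll1 <- ll0 + 9.39 / 2
  cmp <- compare_hierarchical(mk(2 * 5 - 2 * ll0, ll0, 5L),
                              mk(2 * 6 - 2 * ll1, ll1, 6L))
  expect_equal(cmp$delta_aic, 7.39)
  expect_equal(cmp$lrt_chi2, 9.39)
  expect_identical(cmp$lrt_df, 1L)
  expect_equal(unname(cmp$akaike_weights["test"]),
               exp(3.695) / (1 + exp(3.695)))
  expect_equal(round(unname(cmp$akaike_weights["test"]), 3), 0.976)
  # evidence ratio equals exp(dAIC / 2) for a pair, cross-checked both ways
  expect_equal(cmp$evidence_ratio, exp(cmp$delta_aic / 2))

  expect_error(compare_hierarchical(mk(10, -3, 3), mk(9, -2, 3)),
               class = "drm_comparison_error")
  expect_error(compare_hierarchical(mk(10, -3, 2, n = 50L), mk(9, -2, 3, n = 60L)),
               class = "drm_comparison_error")
})

test_that("odds_ratio_ci reproduces published effect summaries from (b, z)", {
  # image task: language and vision slopes of the two-predictor model
  e1_lang <- odds_ratio_ci(0.210, 3.074)
  expect_equal(round(e1_lang$or_, 2), 1.23)
  expect_equal(round(e1_lang$ci_low, 2), 1.08)
  expect_equal(round(e1_lang$ci_high, 2), 1.41)
  expect_lt(abs(odds_ratio_ci(2.046, 17.577)$or_ - 7.73), 0.01)

  # word task
  expect_equal(round(odds_ratio_ci(0.748, 12.244)$or_, 2), 2.11)
  expect_equal(round(odds_ratio_ci(0.350, 5.117)$or_, 2), 1.42)

  # b = 0: OR 1 with a log-symmetric interval
  null <- odds_ratio_ci(0, 2)  # z kept nonzero by convention b/se
  expect_equal(null$or_, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)
  expect_error(odds_ratio_ci(0.3, 0), class = "drm_degenerate_error")
})

test_that("VIF matches its closed form and flags only real collinearity", {
  withr::with_seed(30, {
    n <- 400L
    a <- rnorm(n)
    b_orth <- rnorm(n)
    r <- 0.5
    b_cor <- r * scale(a)[, 1] + sqrt(1 - r^2) * scale(rnorm(n))[, 1]
    tab <- tibble::tibble(a = a, b = b_orth, c = b_cor)
  })
  # two predictors: both VIFs equal 1 / (1 - r^2) exactly
  v2 <- vif(tab, c("a", "c"))
  r_obs <- cor(tab$a, tab$c)
  expect_equal(unname(v2$vif), rep(1 / (1 - r_obs^2), 2), tolerance = 1e-10)
  expect_false(v2$any_flagged)  # ~4/3 at r ~ .5, far below 5

  v_orth <- vif(tibble::tibble(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1)),
                c("a", "b"))
  expect_equal(unname(v_orth$vif), c(1, 1), tolerance = 1e-12)

  tab$dup <- 2 * tab$a
  expect_error(vif(tab, c("a", "dup")), class = "drm_degenerate_error")
  expect_error(vif(tab, "a"), class = "drm_precondition_error")

  # independent cross-check against the standard automotive implementation
  if (requireNamespace("car", quietly = TRUE)) {
    withr::with_seed(8, tab$y <- rnorm(nrow(tab)))
    ref <- car::vif(lm(y ~ a + b + c, data = tab))
    v3 <- vif(tab, c("a", "b", "c"))
    expect_equal(unname(v3$vif), unname(ref[c("a", "b", "c")]), tolerance = 1e-8)
  }
})

test_that("the interaction test equals a manual two-fit comparison", {
  run <- default_run()
  trials <- simulate_responses(run$tab, run$lists, response_model(), 10L, seed = 55L)
  spec <- glmm_spec(fixed_terms = c("sim_vision_z", "sim_language_z"))
  res <- test_interaction(trials, spec)

  manual_main <- fit_glmm(trials, spec)
  inter_spec <- glmm_spec(fixed_terms = c("sim_vision_z", "sim_language_z",
                                          "sim_vision_z:sim_language_z"))
  manual_inter <- fit_glmm(trials, inter_spec)
  manual_cmp <- compare_hierarchical(manual_main, manual_inter)
  expect_equal(res$comparison$delta_aic, manual_cmp$delta_aic, tolerance = 1e-8)
  expect_equal(res$comparison$lrt_chi2, manual_cmp$lrt_chi2, tolerance = 1e-8)
  expect_identical(res$interaction$n_params, 6L)

  expect_error(test_interaction(trials, glmm_spec(fixed_terms = "sim_vision_z")),
               class = "drm_precondition_error")
})

test_that("interaction comparison has no appetite for a null term and detects a real one", {
  run <- default_run()
  spec <- glmm_spec(fixed_terms = c("sim_vision_z", "sim_language_z"))

  # null interaction: dAIC favouring the interaction model stays below 2
  null_delta <- vapply(1:4, function(s) {
    trials <- simulate_responses(run$tab, run$lists, response_model(), 15L,
                                 seed = 800L + s)
    test_interaction(trials, spec)$comparison$delta_aic
  }, numeric(1))
  expect_lt(median(null_delta), 2)

  # strong interaction: regenerate lure responses with a product-term effect
  detected <- vapply(1:4, function(s) {
    trials <- simulate_responses(run$tab, run$lists, response_model(), 15L,
                                 seed = 900L + s)
    lure <- trials$role != "target"
    eta <- -1.7 + 2.046 * trials$sim_vision_z[lure] +
      0.210 * trials$sim_language_z[lure] +
      1.0 * trials$sim_vision_z[lure] * trials$sim_language_z[lure]
    withr::with_seed(900L + s,
      trials$response[lure] <- stats::rbinom(sum(lure), 1L, stats::plogis(eta)))
    # responses regenerated without random effects: variance components sit
    # on the boundary, so the fit legitimately warns about singularity
    suppressWarnings(test_interaction(trials, spec)$comparison$delta_aic > 2)
  }, logical(1))
  expect_gte(mean(detected), 0.75)
})
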