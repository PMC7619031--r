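#' Standardize predictor columns
#'
#' Replaces each named column by its z-score, with mean and SD computed
#' over the analyzed observation rows — the lure rows when the table has a
#' `role` column (targets never enter the recognition GLMM), all rows
#' otherwise. Standardized values on non-analyzed rows are set to `NA`.
#' In the balanced repeated design this is algebraically identical to
#' standardizing over the unique item values and broadcasting.
#'
#' @param table trial-table data frame.
#' @param columns names of numeric columns to standardize.
#' @return the table with the named columns replaced by z-scores.
#' @export
standardize <- function(table, columns) {
  rows <- lure_rows(table)
  for (col in columns) {
    if (!col %in% names(table)) {
      stop_drm("drm_precondition_error", "no column '%s' in table", col)
    }
    x <- table[[col]][rows]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop_drm("drm_degenerate_error",
               "column '%s' is constant over analyzed rows", col)
    }
    z <- rep(NA_real_, nrow(table))
    z[rows] <- (x - mean(x)) / s
    table[[col]] <- z
  }
  table
}

#' Specify a recognition GLMM
#'
#' @param response name of the binary response column (0 = "new",
#'   1 = "old").
#' @param fixed_terms character vector of fixed-effect column names, in
#'   order; a product term may be written `"a:b"`. Empty vector gives an
#'   intercept-only model.
#' @param random_intercepts grouping-factor column names for crossed
#'   random intercepts (default participant and list).
#' @return a `glmm_spec` list.
#' @export
glmm_spec <- function(response = "response", fixed_terms,
                      random_intercepts = c("participant_id", "list_id")) {
  if (length(random_intercepts) < 1L) {
    stop_drm("drm_precondition_error", "at least one grouping factor required")
  }
  structure(list(response = response, fixed_terms = as.character(fixed_terms),
                 random_intercepts = as.character(random_intercepts)),
            class = "glmm_spec")
}

glmm_formula <- function(spec) {
  fixed <- if (length(spec$fixed_terms) == 0L) "1"
           else paste(spec$fixed_terms, collapse = " + ")
  re <- paste(sprintf("(1 | %s)", spec$random_intercepts), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", fixed, "+", re))
}

#' Fit a binomial GLMM with crossed random intercepts
#'
#' Logit-link Bernoulli model with Gaussian random intercepts for each
#' grouping factor, estimated by Laplace-approximated maximum likelihood
#' (`lme4::glmer`). Analyzed rows are the lure rows when the table has a
#' `role` column. Wald z and p values are reported per fixed term, as is
#' the usual AIC bookkeeping (`n_params` counts fixed effects plus
#' variance components). Non-convergence is flagged, never silent;
#' apparent complete separation (diverging slope with huge SE) raises a
#' diagnostic error.
#'
#' @param table trial-table data frame with the response, predictors and
#'   grouping factors.
#' @param spec a [glmm_spec()].
#' @return a `glmm_fit` list: `terms` (tibble with `term`, `b`, `se`,
#'   `z`, `p`), `variance_components` (named vector of random-intercept
#'   variances), `loglik`, `n_params`, `aic`, `n_obs`, `converged`, and
#'   the underlying `model` object.
#' @export
fit_glmm <- function(table, spec) {
  data <- as.data.frame(table)[lure_rows(table), , drop = FALSE]
  y <- data[[spec$response]]
  if (is.null(y) || !all(y %in% c(0, 1))) {
    stop_drm("drm_precondition_error",
             "response '%s' must be coded 0/1", spec$response)
  }
  for (g in spec$random_intercepts) {
    if (length(unique(data[[g]])) < 2L) {
      stop_drm("drm_precondition_error",
               "grouping factor '%s' needs >= 2 levels", g)
    }
  }
  messages <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(glmm_formula(spec), data = data, family = stats::binomial()),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  cf <- summary(fit)$coefficients
  terms <- tibble::tibble(
    term = rownames(cf), b = cf[, "Estimate"], se = cf[, "Std. Error"],
    z = cf[, "z value"], p = cf[, "Pr(>|z|)"])
  slopes <- terms[terms$term != "(Intercept)", , drop = FALSE]
  if (nrow(slopes) > 0L && any(abs(slopes$b) > 15 & slopes$se > 50)) {
    stop_drm("drm_separation_error",
             "apparent complete separation: term '%s' diverges (b = %.1f, se = %.1f)",
             slopes$term[which.max(abs(slopes$b))],
             max(abs(slopes$b)), max(slopes$se))
  }

  ll <- logLik(fit)
  converged <- length(messages) == 0L &&
    isTRUE(fit@optinfo$conv$opt == 0) &&
    length(fit@optinfo$conv$lme4) == 0L
  if (!converged) {
    warning(sprintf("fit_glmm: convergence not clean (%s)",
                    paste(unique(messages), collapse = "; ")), call. = FALSE)
  }
  vc <- lme4::VarCorr(fit)
  structure(list(
    terms = terms,
    variance_components = vapply(vc, function(m) as.numeric(m[1L, 1L]), numeric(1L)),
    loglik = as.numeric(ll),
    n_params = attr(ll, "df"),
    aic = AIC(fit),
    n_obs = nrow(data),
    converged = converged,
    model = fit), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit: %d obs, logLik %.2f, AIC %.1f, %d params%s>\n",
              x$n_obs, x$loglik, x$aic, x$n_params,
              if (x$converged) "" else ", NOT converged"))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Hierarchical model comparison by AIC
#'
#' Compares a baseline model with a test model that nests it (same data,
#' more parameters): AIC difference, Akaike weights
#' (`w_i = exp(-delta_i / 2)` normalized), evidence ratio (larger weight
#' over smaller — for two models `exp(|dAIC| / 2)`), and the
#' likelihood-ratio chi-square with its degrees of freedom and p value.
#' A `delta_aic` of 2 corresponds to an evidence ratio of `e ~ 2.7` in
#' favour of the lower-AIC model.
#'
#' @param base,test `glmm_fit` objects (or any lists with `aic`,
#'   `loglik`, `n_params`, `n_obs`); `test` must nest `base`.
#' @return a `model_comparison` list: `delta_aic`
#'   (`aic_base - aic_test`), `akaike_weights` (named, base/test, sums to
#'   1), `evidence_ratio`, `lrt_chi2`, `lrt_df`, `lrt_p`.
#' @export
compare_hierarchical <- function(base, test) {
  if (base$n_obs != test$n_obs) {
    stop_drm("drm_comparison_error",
             "models fit to different data (n = %d vs %d)", base$n_obs, test$n_obs)
  }
  df <- test$n_params - base$n_params
  if (df < 1L) {
    stop_drm("drm_comparison_error",
             "test model must add >= 1 parameter (base %d, test %d)",
             base$n_params, test$n_params)
  }
  aics <- c(base = base$aic, test = test$aic)
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  chi2 <- max(0, 2 * (test$loglik - base$loglik))
  list(delta_aic = unname(aics["base"] - aics["test"]),
       akaike_weights = w,
       evidence_ratio = max(w) / min(w),
       lrt_chi2 = chi2,
       lrt_df = df,
       lrt_p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Odds ratio with Wald confidence interval
#'
#' Recovers the standard error as `|b / z|`, then reports
#' `OR = exp(b)` with bounds `exp(b +/- q * se)`, `q` the two-sided
#' normal quantile at `level`.
#'
#' @param b log-odds estimate.
#' @param z Wald z statistic (`b / se`, nonzero).
#' @param level confidence level (default .95).
#' @return list with `or_`, `ci_low`, `ci_high`, `level`.
#' @export
odds_ratio_ci <- function(b, z, level = 0.95) {
  if (z == 0) {
    stop_drm("drm_degenerate_error", "z = 0: standard error is undefined")
  }
  se <- abs(b / z)
  q <- qnorm(1 - (1 - level) / 2)
  list(or_ = exp(b), ci_low = exp(b - q * se), ci_high = exp(b + q * se),
       level = level)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from an ordinary least-squares regression of
#' predictor `j` on the remaining predictors over the analyzed (lure)
#' rows. With exactly two predictors both VIFs equal `1 / (1 - r^2)`.
#'
#' @param table trial-table data frame.
#' @param predictors names of >= 2 numeric predictor columns.
#' @param flag_threshold VIF above which a predictor is flagged
#'   (default 5, the conventional collinearity alarm).
#' @return a `collinearity_report` list: `vif` (named vector),
#'   `flag_threshold`, `any_flagged`.
#' @export
vif <- function(table, predictors, flag_threshold = 5) {
  if (length(predictors) < 2L) {
    stop_drm("drm_precondition_error", "need >= 2 predictors")
  }
  data <- as.data.frame(table)[lure_rows(table), predictors, drop = FALSE]
  data <- data[complete.cases(data), , drop = FALSE]
  vals <- vapply(predictors, function(pj) {
    if (sd(data[[pj]]) == 0) {
      stop_drm("drm_degenerate_error", "predictor '%s' is constant", pj)
    }
    fml <- stats::as.formula(paste(pj, "~", paste(setdiff(predictors, pj),
                                                  collapse = " + ")))
    # a perfect fit is caught right below; silence summary.lm's note about it
    r2 <- suppressWarnings(summary(lm(fml, data = data))$r.squared)
    if (r2 >= 1 - 1e-12) {
      stop_drm("drm_degenerate_error",
               "predictor '%s' is perfectly collinear (infinite VIF)", pj)
    }
    1 / (1 - r2)
  }, numeric(1L))
  list(vif = vals, flag_threshold = flag_threshold,
       any_flagged = any(vals > flag_threshold))
}

#' Test the similarity-by-similarity interaction
#'
#' Fits the two-predictor main-effects model and the model adding their
#' product term (built from the standardized columns), and returns the
#' hierarchical comparison. An interaction would signal superadditive
#' effects of visual and linguistic similarity on false recognition.
#'
#' @param table trial-table data frame.
#' @param spec a [glmm_spec()] whose `fixed_terms` are exactly the two
#'   similarity predictors.
#' @return list with `main` and `interaction` (`glmm_fit`s) and
#'   `comparison` (a [compare_hierarchical()] result).
#' @export
test_interaction <- function(table, spec) {
  if (length(spec$fixed_terms) != 2L) {
    stop_drm("drm_precondition_error",
             "spec must have exactly the two similarity predictors")
  }
  main <- fit_glmm(table, spec)
  inter_spec <- spec
  inter_spec$fixed_terms <- c(spec$fixed_terms,
                              paste(spec$fixed_terms, collapse = ":"))
  interaction <- fit_glmm(table, inter_spec)
  list(main = main, interaction = interaction,
       comparison = compare_hierarchical(main, interaction))
}

#' Serialize a fit or comparison to JSON-ready lists
#'
#' @param fit a `glmm_fit`.
#' @return plain list safe for `jsonlite::write_json(auto_unbox = TRUE)`.
#' @keywords internal
fit_summary <- function(fit) {
  list(terms = lapply(seq_len(nrow(fit$terms)), function(i) {
         as.list(fit$terms[i, ])
       }),
       variance_components = as.list(fit$variance_components),
       loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
       n_obs = fit$n_obs, converged = fit$converged)
}
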