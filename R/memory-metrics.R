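#' Nonparametric sensitivity index A'
#'
#' The standard nonparametric signal-detection sensitivity measure
#' (Pollack-Norman, in the signed generalization of Stanislaw & Todorov):
#' for hit rate `h` and false-alarm rate `fa`,
#' `A' = 0.5 + sign(h - fa) * ((h - fa)^2 + |h - fa|) /
#' (4 * max(h, fa) - 4 * h * fa)`, with `A' = 0.5` when `h = fa`
#' (including the 0,0 and 1,1 corners). 0.5 is chance discrimination,
#' 1 is perfect.
#'
#' @param h,fa hit and false-alarm rates in `[0, 1]` (vectorized).
#' @return values in `[0, 1]`.
#' @examples
#' a_prime(1, 0)        # 1
#' a_prime(0.72, 0.17)  # ~0.857
#' @export
a_prime <- function(h, fa) {
  if (any(h < 0 | h > 1 | fa < 0 | fa > 1, na.rm = TRUE)) {
    stop_drm("drm_precondition_error", "rates must lie in [0, 1]")
  }
  d <- h - fa
  denom <- 4 * pmax(h, fa) - 4 * h * fa
  out <- ifelse(d == 0, 0.5, 0.5 + sign(d) * (d^2 + abs(d)) / denom)
  out[is.na(h) | is.na(fa)] <- NA_real_
  out
}

#' Per-participant recognition descriptives
#'
#' For every participant x category cell: `p_hit` (mean endorsement of
#' target rows), `p_fa` (mean endorsement of lure rows), and [a_prime()].
#' Cells missing either targets or lures are emitted with `NA` and
#' counted in a message. Aggregates are across-participant means and SDs
#' per category — means of per-participant A', not A' of mean rates (the
#' two differ by Jensen's inequality; only the former matches
#' participant-level descriptive tables).
#'
#' @param table trial-table data frame with `participant_id`, `category`,
#'   `role`, `response`.
#' @return list with `by_participant` (tibble: `participant_id`,
#'   `category`, `p_hit`, `p_fa`, `a_prime`) and `by_category` (tibble:
#'   `category`, `n`, mean/SD of each measure).
#' @export
recognition_summary <- function(table) {
  needed <- c("participant_id", "category", "role", "response")
  if (!all(needed %in% names(table))) {
    stop_drm("drm_precondition_error", "table lacks column(s): %s",
             paste(setdiff(needed, names(table)), collapse = ", "))
  }
  is_target <- table$role == "target"
  is_lure <- table$role %in% LURE_ROLES
  if (!any(is_target) || !any(is_lure)) {
    stop_drm("drm_precondition_error", "table needs both target and lure rows")
  }
  cells <- unique(table[, c("participant_id", "category")])
  cells <- cells[order(cells$participant_id, cells$category), ]
  rate <- function(keep, p, cat) {
    r <- table$response[keep & table$participant_id == p & table$category == cat]
    if (length(r) == 0L) NA_real_ else mean(r)
  }
  p_hit <- mapply(rate, p = cells$participant_id, cat = cells$category,
                  MoreArgs = list(keep = is_target))
  p_fa <- mapply(rate, p = cells$participant_id, cat = cells$category,
                 MoreArgs = list(keep = is_lure))
  n_missing <- sum(is.na(p_hit) | is.na(p_fa))
  if (n_missing > 0L) {
    message(sprintf(
      "recognition_summary: %d participant x category cell(s) lack targets or lures; emitted as NA",
      n_missing))
  }
  by_participant <- tibble::tibble(
    participant_id = cells$participant_id, category = cells$category,
    p_hit = unname(p_hit), p_fa = unname(p_fa),
    a_prime = a_prime(unname(p_hit), unname(p_fa)))

  agg <- lapply(split(by_participant, by_participant$category), function(g) {
    tibble::tibble(
      category = g$category[1L], n = sum(complete.cases(g[, c("p_hit", "p_fa")])),
      p_hit_mean = mean(g$p_hit, na.rm = TRUE), p_hit_sd = sd(g$p_hit, na.rm = TRUE),
      p_fa_mean = mean(g$p_fa, na.rm = TRUE), p_fa_sd = sd(g$p_fa, na.rm = TRUE),
      a_prime_mean = mean(g$a_prime, na.rm = TRUE),
      a_prime_sd = sd(g$a_prime, na.rm = TRUE))
  })
  list(by_participant = by_participant, by_category = do.call(rbind, agg))
}

#' Are false alarms above zero?
#'
#' One-sample Wilcoxon signed-rank test of per-participant false-alarm
#' rates in one category against zero (one-sided, greater). The
#' signed-rank test is used because rates are bounded and typically
#' skewed; it is exact for `n <= 25` when no rate is tied at zero. When
#' every rate is zero the test is vacuous and `p = 1` is returned.
#'
#' @param summary a [recognition_summary()] result.
#' @param category category label to test.
#' @param min_n minimum participants with a non-missing rate (default 5).
#' @return list with `statistic` (signed-rank V), `p`, `n`.
#' @export
fa_above_zero_test <- function(summary, category, min_n = 5L) {
  bp <- summary$by_participant
  x <- bp$p_fa[bp$category == category & !is.na(bp$p_fa)]
  if (length(x) < min_n) {
    stop_drm("drm_precondition_error",
             "only %d participant(s) with a false-alarm rate in '%s' (need >= %d)",
             length(x), category, min_n)
  }
  if (all(x == 0)) {
    return(list(statistic = 0, p = 1, n = length(x)))
  }
  wt <- suppressWarnings(
    wilcox.test(x, mu = 0, alternative = "greater",
                exact = length(x) <= 25L && !any(x == 0)))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(x))
}

#' Exclude non-compliant participants
#'
#' Removes every trial of participants whose go/no-go accuracy during the
#' distractor task fell below `min_accuracy` (strictly: accuracy exactly
#' at the cutoff is retained). Retained rows pass through unaltered.
#'
#' @param table trial-table data frame with `participant_id` and
#'   `gonogo_accuracy`.
#' @param min_accuracy exclusion cutoff (default 0.60).
#' @param quiet suppress the exclusion-count message.
#' @return list with `table` (surviving rows) and `excluded` (character
#'   vector of excluded participant ids).
#' @export
compliance_filter <- function(table, min_accuracy = 0.60, quiet = FALSE) {
  if (!all(c("participant_id", "gonogo_accuracy") %in% names(table))) {
    stop_drm("drm_precondition_error",
             "table lacks participant_id / gonogo_accuracy")
  }
  acc <- tapply(table$gonogo_accuracy, table$participant_id, function(a) a[1L])
  excluded <- names(acc)[acc < min_accuracy]
  kept <- table[!table$participant_id %in% excluded, , drop = FALSE]
  if (!quiet) {
    message(sprintf(
      "compliance_filter: excluded %d of %d participants (accuracy < %g%%); %d rows retained",
      length(excluded), length(acc), 100 * min_accuracy, nrow(kept)))
  }
  if (length(excluded) == length(acc)) {
    warning("compliance_filter: every participant was excluded", call. = FALSE)
  }
  list(table = kept, excluded = excluded)
}

#' Write a category-level summary table
#'
#' Tab-delimited table mirroring the standard descriptive layout:
#' category, N, then mean (SD) of pHit, pFA and A'.
#'
#' @param summary a [recognition_summary()] result.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_summary_table <- function(summary, path) {
  bc <- summary$by_category
  fmt <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  out <- data.frame(
    category = bc$category, N = bc$n,
    pHit = fmt(bc$p_hit_mean, bc$p_hit_sd),
    pFA = fmt(bc$p_fa_mean, bc$p_fa_sd),
    A_prime = fmt(bc$a_prime_mean, bc$a_prime_sd))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
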