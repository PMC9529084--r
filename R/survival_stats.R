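#' Assign samples to high/low expression groups by percentile cutoffs
#'
#' Samples strictly above the `high_cut` empirical percentile of the values
#' are labelled `"high"`, samples strictly below the `low_cut` percentile
#' `"low"`, and the remainder `"excluded"` — the custom-cutoff convention of
#' GEPIA2-style survival screens (defaults keep the top and bottom quarters
#' and drop the middle half). When `high_cut == low_cut` the split is a
#' two-way cut with no exclusion: ties at the cut go to `"low"`.
#'
#' @param values named numeric vector of per-sample expression.
#' @param high_cut,low_cut percentile cutoffs in \[0, 1\],
#'   `low_cut <= high_cut`.
#' @return named character vector over \{"high", "low", "excluded"\}.
#' @export
assign_groups <- function(values, high_cut = 0.75, low_cut = 0.25) {
  stopifnot(length(values) >= 4, low_cut >= 0, high_cut <= 1,
            low_cut <= high_cut)
  if (length(unique(values)) == 1) {
    stop("cannot split constant expression values into groups",
         call. = FALSE)
  }
  q_high <- stats::quantile(values, high_cut, names = FALSE)
  out <- rep("excluded", length(values))
  names(out) <- names(values)
  if (high_cut == low_cut) {
    out[values > q_high] <- "high"
    out[values <= q_high] <- "low"
    return(out)
  }
  q_low <- stats::quantile(values, low_cut, names = FALSE)
  out[values > q_high] <- "high"
  out[values < q_low] <- "low"
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square (1 df) over the
#' pooled event times of the `"high"` and `"low"` groups, with the
#' hypergeometric variance handling tied event times. Samples labelled
#' `"excluded"` are ignored. With no observed events in either group the
#' test is undefined and `p = 1` is returned with a warning.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = death observed, 0 = censored).
#' @param groups group labels from [assign_groups()] (or any vector over
#'   high/low/excluded), aligned with `times`.
#' @return list with elements `statistic` (chi-square), `p`, `n_high`,
#'   `n_low`.
#' @export
logrank_test <- function(times, events, groups) {
  keep <- groups %in% c("high", "low")
  times <- times[keep]; events <- events[keep]; groups <- groups[keep]
  if (!any(groups == "high") || !any(groups == "low")) {
    stop("both the high and the low group must be non-empty", call. = FALSE)
  }
  n_high <- sum(groups == "high"); n_low <- sum(groups == "low")
  if (sum(events) == 0) {
    warning("no events in either group; log-rank p set to 1", call. = FALSE)
    return(list(statistic = 0, p = 1, n_high = n_high, n_low = n_low))
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups, rho = 0)
  stat <- fit$chisq
  list(statistic = as.numeric(stat),
       p = as.numeric(stats::pchisq(stat, df = 1, lower.tail = FALSE)),
       n_high = n_high, n_low = n_low)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron approximation for tied event
#' times. For a binary high/low group the covariate is coded high = 1, so
#' `hazard_ratio > 1` means the high-expression group dies faster. Reports
#' the Wald 95% confidence interval and p-value. Non-convergence or an
#' infinite coefficient (complete separation) yields a flagged result with
#' missing CI rather than an error.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @param covariate numeric covariate, or a group labelling over
#'   high/low/excluded (excluded samples are dropped).
#' @return one-row data frame with columns `hazard_ratio`, `hr_ci_low`,
#'   `hr_ci_high`, `p_value`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(times, events, covariate) {
  if (is.character(covariate) || is.factor(covariate)) {
    covariate <- as.character(covariate)
    keep <- covariate %in% c("high", "low")
    times <- times[keep]; events <- events[keep]
    covariate <- as.numeric(covariate[keep] == "high")
  }
  flagged <- function(n, n_events) {
    data.frame(hazard_ratio = NA_real_, hr_ci_low = NA_real_,
               hr_ci_high = NA_real_, p_value = NA_real_,
               n = n, n_events = n_events, converged = FALSE)
  }
  n <- length(times); n_events <- sum(events)
  if (n_events < 2 || length(unique(covariate)) < 2) {
    return(flagged(n, n_events))
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "efron"),
    warning = function(w) w, error = function(e) e)
  if (inherits(fit, "condition")) return(flagged(n, n_events))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  if (!is.finite(beta) || !is.finite(se)) return(flagged(n, n_events))
  data.frame(hazard_ratio = exp(beta),
             hr_ci_low = exp(beta - stats::qnorm(0.975) * se),
             hr_ci_high = exp(beta + stats::qnorm(0.975) * se),
             p_value = 2 * stats::pnorm(-abs(beta / se)),
             n = n, n_events = n_events, converged = TRUE)
}

#' Per-level subgroup Cox hazard ratios
#'
#' Fits [cox_univariate()] separately within each level of a stratifying
#' label (race or gender), reporting one hazard ratio per level — the
#' subgroup presentation used for per-race and per-gender survival tables.
#' A level is evaluable only if each expression group contributes at least
#' two events within it; otherwise a not-evaluable record is returned.
#'
#' @param times,events follow-up data aligned with `groups`.
#' @param groups high/low/excluded labels from [assign_groups()].
#' @param stratifier character vector of subgroup labels (`NA` rows are
#'   dropped).
#' @return data frame with one row per stratifier level: `subgroup`,
#'   `evaluable`, and the [cox_univariate()] columns.
#' @export
cox_subgroup <- function(times, events, groups, stratifier) {
  stratifier <- as.character(stratifier)
  keep <- !is.na(stratifier) & groups %in% c("high", "low")
  times <- times[keep]; events <- events[keep]
  groups <- groups[keep]; stratifier <- stratifier[keep]
  levels <- sort(unique(stratifier))
  rows <- lapply(levels, function(lv) {
    in_lv <- stratifier == lv
    ev_high <- sum(events[in_lv & groups == "high"])
    ev_low <- sum(events[in_lv & groups == "low"])
    if (ev_high < 2 || ev_low < 2) {
      res <- data.frame(hazard_ratio = NA_real_, hr_ci_low = NA_real_,
                        hr_ci_high = NA_real_, p_value = NA_real_,
                        n = sum(in_lv), n_events = ev_high + ev_low,
                        converged = FALSE)
      return(cbind(subgroup = lv, evaluable = FALSE, res))
    }
    res <- cox_univariate(times[in_lv], events[in_lv], groups[in_lv])
    cbind(subgroup = lv, evaluable = res$converged, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of cancers affected
#'
#' The breadth statistic `100 * k / n`, reported to two decimals: the
#' percentage of the analysed cancer types in which a gene is significantly
#' affected (in expression or survival).
#'
#' @param k number of cancers significantly affected, `0 <= k <= n`.
#' @param n total number of cancers analysed, `> 0`.
#' @return the percentage, rounded to 2 decimals.
#' @examples
#' percent_affected(17, 52)  # 32.69
#' percent_affected(23, 52)  # 44.23
#' @export
percent_affected <- function(k, n) {
  stopifnot(n > 0, k >= 0)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  round(100 * k / n, 2)
}
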