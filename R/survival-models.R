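#' Cox proportional-hazards model with Efron tie handling
#'
#' Fits `survival::coxph(ties = "efron")` on the named covariates. By default
#' continuous covariates are standardized to unit SD on the training records
#' (binary covariates are left alone), so each reported hazard ratio is the
#' risk multiplier per SD increase of that covariate; the stored scaling is
#' reapplied verbatim by [prognostic_index()].
#'
#' @param records tibble with `time_months` (> 0), `event` (0/1), and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param standardize standardize continuous covariates to unit SD
#'   (default `TRUE`).
#' @param tag optional model tag (e.g. `"clinical"`, `"connectome"`,
#'   `"pattern"`, `"combined"`).
#' @return An object of class `klse_cox`: the `survival::coxph` fit, the
#'   coefficient table with Wald 95% CIs, training `center`/`scale`,
#'   `c_index` on the training records, and `tag`.
#' @export
fit_cox <- function(records, covariates, standardize = TRUE, tag = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("time_months", "event", covariates)
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(records$time_months <= 0)) abort("`time_months` must be > 0.")
  if (sum(records$event) < 1L) abort("need at least 1 event.")
  x <- records[covariates]
  bad <- names(x)[!vapply(x, function(v) all(is.finite(v)), TRUE)]
  if (length(bad) > 0L) {
    abort(sprintf("non-finite covariate(s): %s", paste(bad, collapse = ", ")))
  }
  continuous <- vapply(x, function(v) length(unique(v)) > 2L, TRUE)
  center <- vapply(x, function(v) 0, numeric(1))
  scale <- vapply(x, function(v) 1, numeric(1))
  if (standardize) {
    center[continuous] <- vapply(x[continuous], mean, numeric(1))
    s <- vapply(x[continuous], sd, numeric(1))
    s[s == 0] <- 1
    scale[continuous] <- s
  }
  xs <- as.data.frame(purrr::map2(x, seq_along(x), function(v, i) {
    (v - center[i]) / scale[i]
  }))
  df <- cbind(xs, time_months = records$time_months, event = records$event)
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(is.na(coef(fit)))) {
    abort(sprintf(
      "rank-deficient design: coefficient(s) %s not estimable (collinear covariates?).",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  sm <- summary(fit)
  coefs <- tibble(
    term = covariates,
    estimate = unname(coef(fit)),
    hazard_ratio = unname(exp(coef(fit))),
    std_error = unname(sm$coefficients[, "se(coef)"]),
    conf_low = unname(exp(coef(fit) - qnorm(0.975) * sm$coefficients[, "se(coef)"])),
    conf_high = unname(exp(coef(fit) + qnorm(0.975) * sm$coefficients[, "se(coef)"])),
    p_value = unname(sm$coefficients[, "Pr(>|z|)"])
  )
  obj <- structure(
    list(fit = fit, coefficients = coefs, center = center, scale = scale,
         covariates = covariates, standardize = standardize, tag = tag,
         n = nrow(records), n_events = sum(records$event)),
    class = "klse_cox"
  )
  obj$c_index <- concordance_index(
    prognostic_index(obj, records), records$time_months, records$event
  )
  obj
}

#' @export
print.klse_cox <- function(x, ...) {
  cat(sprintf(
    "<klse_cox>%s %d covariates, n = %d (%d events), training C-index = %.3f\n",
    if (is.null(x$tag)) "" else paste0(" [", x$tag, "]"),
    length(x$covariates), x$n, x$n_events, x$c_index
  ))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy klse_cox
#' @export
tidy.klse_cox <- function(x, ...) x$coefficients

#' @method glance klse_cox
#' @export
glance.klse_cox <- function(x, ...) {
  tibble(tag = x$tag %||% NA_character_, n = x$n, n_events = x$n_events,
         c_index = x$c_index)
}

#' Prognostic index (Cox linear predictor)
#'
#' `PI = sum(beta * standardized covariate)` using the model's training
#' standardization, so test-set subjects are scored on the training scale.
#'
#' @param fit a [fit_cox()] model.
#' @param records tibble carrying the model's covariates.
#' @return A numeric vector of prognostic indices.
#' @export
prognostic_index <- function(fit, records) {
  stopifnot(inherits(fit, "klse_cox"), is.data.frame(records))
  missing <- setdiff(fit$covariates, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("records lack covariate(s): %s", paste(missing, collapse = ", ")))
  }
  beta <- coef(fit$fit)
  out <- rep(0, nrow(records))
  for (i in seq_along(fit$covariates)) {
    v <- fit$covariates[i]
    out <- out + beta[[i]] * (records[[v]] - fit$center[[v]]) / fit$scale[[v]]
  }
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs whose prognostic-index ordering
#' matches their event-time ordering. A pair `(i, j)` is comparable when
#' `t_i < t_j` and subject `i` had the event (censoring makes later orderings
#' ambiguous; such pairs are excluded, Harrell-style). Ties in the index
#' count 1/2.
#'
#' @param pi numeric prognostic indices (higher = higher risk).
#' @param time event/censoring times.
#' @param event 0/1 event indicators.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(pi, time, event) {
  n <- length(pi)
  stopifnot(length(time) == n, length(event) == n)
  # comparable: t_i < t_j with event_i = 1
  cmp <- outer(time, time, "<") & (event == 1L)
  diag(cmp) <- FALSE
  n_cmp <- sum(cmp)
  if (n_cmp == 0L) abort("no comparable pairs.")
  gt <- outer(pi, pi, ">")[cmp]
  eq <- outer(pi, pi, "==")[cmp]
  (sum(gt) + 0.5 * sum(eq)) / n_cmp
}

#' Kaplan-Meier risk stratification by prognostic index
#'
#' Splits subjects into equally sized low- and high-risk strata at the median
#' prognostic index (ties go to low-risk), estimates a Kaplan-Meier curve per
#' stratum, tests the difference with a log-rank test, and reports the
#' high-vs-low hazard ratio from a one-covariate Cox model on the stratum
#' indicator.
#'
#' @param pi numeric prognostic indices.
#' @param records tibble with `time_months` and `event`.
#' @return An object of class `klse_km`: `survfit` curves, `logrank_chisq`,
#'   `logrank_p`, `hazard_ratio` with `conf_low`/`conf_high`, and the
#'   stratified data.
#' @export
km_stratified <- function(pi, records) {
  stopifnot(is.data.frame(records), length(pi) == nrow(records))
  med <- median(pi)
  risk <- factor(ifelse(pi > med, "high", "low"), levels = c("low", "high"))
  if (any(table(risk) < 2L)) abort("each risk stratum needs >= 2 subjects.")
  df <- data.frame(time_months = records$time_months, event = records$event,
                   risk = risk)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ risk, data = df)
  sd_ <- survival::survdiff(survival::Surv(time_months, event) ~ risk, data = df)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time_months, event) ~ risk, data = df,
                        ties = "efron")
  se <- sqrt(diag(cx$var))[1]
  structure(
    list(
      survfit = sf,
      logrank_chisq = unname(sd_$chisq),
      logrank_p = p,
      hazard_ratio = unname(exp(coef(cx)[1])),
      conf_low = unname(exp(coef(cx)[1] - qnorm(0.975) * se)),
      conf_high = unname(exp(coef(cx)[1] + qnorm(0.975) * se)),
      data = as_tibble(df)
    ),
    class = "klse_km"
  )
}

#' @export
print.klse_km <- function(x, ...) {
  cat(sprintf(
    "<klse_km> high vs low risk: HR = %.2f [%.2f, %.2f], log-rank p = %.3g\n",
    x$hazard_ratio, x$conf_low, x$conf_high, x$logrank_p
  ))
  invisible(x)
}

#' @method glance klse_km
#' @export
glance.klse_km <- function(x, ...) {
  tibble(hazard_ratio = x$hazard_ratio, conf_low = x$conf_low,
         conf_high = x$conf_high, logrank_chisq = x$logrank_chisq,
         logrank_p = x$logrank_p)
}
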