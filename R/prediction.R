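#' Fit the metabolic connectome expression (MCE) model
#'
#' L1-penalized (LASSO) logistic regression of group membership on the
#' network property table. Features are standardized internally on the
#' training rows (the stored centers/scales are reapplied verbatim at
#' scoring time, so the test set never leaks into the standardization);
#' the penalty is chosen by seeded k-fold cross-validated deviance, with the
#' sparser `lambda.1se` rule by default.
#'
#' @param features tibble of training subjects: an optional `subject_id`
#'   column plus numeric property columns.
#' @param labels binary outcome (factor, logical, or 0/1), length
#'   `nrow(features)`; the second level / 1 is the positive (converting)
#'   class.
#' @param nfolds cross-validation folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @param rule `"lambda.1se"` (default, sparser) or `"lambda.min"`.
#' @param refit if `TRUE`, refit an unpenalized logistic model on the
#'   selected features and use its coefficients.
#' @return An object of class `klse_mce`: nonzero `coef` (named), `intercept`,
#'   per-feature `center`/`scale` for the selected features, `lambda`,
#'   `rule`, `seed`.
#' @export
fit_mce <- function(features, labels, nfolds = 10L, seed = 1L,
                    rule = c("lambda.1se", "lambda.min"), refit = FALSE) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(features))
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2L) abort("`labels` must contain exactly 2 classes.")
  if (length(y) != nrow(features)) abort("`labels` length must match `features` rows.")
  if (nrow(features) < 20L) abort("need at least 20 training subjects.")
  x <- as.matrix(features[vapply(features, is.numeric, TRUE)])
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1  # constant features carry no signal; avoid 0/0
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  foldid <- withr::with_seed(as.integer(seed), sample(rep_len(seq_len(nfolds), length(y))))
  cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = FALSE)
  lambda <- if (rule == "lambda.1se") cvfit$lambda.1se else cvfit$lambda.min
  cf <- as.matrix(coef(cvfit, s = lambda))
  beta <- cf[-1, 1]
  intercept <- cf[1, 1]
  selected <- names(beta)[beta != 0]
  if (refit && length(selected) > 0L) {
    df <- as.data.frame(xs[, selected, drop = FALSE])
    df$.y <- y
    gf <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    intercept <- unname(coef(gf)[1])
    beta_sel <- coef(gf)[-1]
    names(beta_sel) <- selected
  } else {
    beta_sel <- beta[selected]
  }
  structure(
    list(
      coef = beta_sel,
      intercept = intercept,
      center = center[selected],
      scale = scale[selected],
      lambda = lambda,
      rule = rule,
      refit = refit,
      seed = as.integer(seed),
      n_train = length(y)
    ),
    class = "klse_mce"
  )
}

#' @export
print.klse_mce <- function(x, ...) {
  cat(sprintf(
    "<klse_mce> %d selected propert%s (rule %s, lambda %.4g, n = %d)\n",
    length(x$coef), if (length(x$coef) == 1) "y" else "ies",
    x$rule, x$lambda, x$n_train
  ))
  invisible(x)
}

#' @method tidy klse_mce
#' @export
tidy.klse_mce <- function(x, ...) {
  tibble(feature = names(x$coef), coefficient = unname(x$coef))
}

#' @method glance klse_mce
#' @export
glance.klse_mce <- function(x, ...) {
  tibble(n_selected = length(x$coef), lambda = x$lambda, rule = x$rule,
         n_train = x$n_train)
}

#' Score subjects with an MCE model
#'
#' `intercept + sum(coef * standardized feature)`, with the training-set
#' standardization applied. Features the model did not select are ignored.
#'
#' @param model a [fit_mce()] model.
#' @param features tibble containing at least the model's selected features.
#' @return A numeric vector of scores (named by `subject_id` when present).
#' @export
mce_score <- function(model, features) {
  stopifnot(inherits(model, "klse_mce"), is.data.frame(features))
  missing <- setdiff(names(model$coef), names(features))
  if (length(missing) > 0L) {
    abort(sprintf("feature(s) missing from table: %s", paste(missing, collapse = ", ")))
  }
  out <- rep(model$intercept, nrow(features))
  for (f in names(model$coef)) {
    z <- (features[[f]] - model$center[[f]]) / model$scale[[f]]
    out <- out + model$coef[[f]] * z
  }
  if ("subject_id" %in% names(features)) names(out) <- features$subject_id
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted 1/2.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels; the second factor level / 1 / `TRUE` is
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2L) abort("`labels` must contain exactly 2 classes.")
  if (length(scores) != length(y)) abort("`scores` and `labels` lengths differ.")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
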