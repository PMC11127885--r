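# Two-group linear discriminant analysis from first principles: pooled
# within-group covariance, Fisher direction, unit within-group variance
# scaling, sign convention (group 1 positive), Gaussian posteriors on LD1.

#' Predictor set of a reference model
#'
#' Model 1 (high- vs low-input farming) uses five traits; model 2 (input level
#' in semi-arid settings) drops flowering period; model 3 (high vs low soil
#' disturbance) uses vegetative propagation and flowering period only.
#' Predictors are returned in the canonical column order.
#'
#' @param model Model id, 1, 2 or 3.
#' @return Character vector of predictor names.
#' @export
weed_predictors <- function(model) {
  sets <- list(`1` = c("SLA", "ARNODE", "LOGCANH", "LOGCAND", "FLOWPER"),
               `2` = c("SLA", "ARNODE", "LOGCANH", "LOGCAND"),
               `3` = c("VEGPROP", "FLOWPER"))
  if (!as.character(model) %in% names(sets))
    stop("model must be 1, 2 or 3", call. = FALSE)
  intersect(TRAIT_ORDER, sets[[as.character(model)]])
}

#' Validate a modern-survey model dataset
#'
#' One row per surveyed modern field: `group` (1 or 2), `location` and the
#' model's predictor columns (averaged trait values for the field). Both
#' groups must be non-empty with at least p + 2 fields each (p predictors),
#' and no predictor value may be missing.
#'
#' @param df Data frame with `group`, optional `location`, and predictors.
#' @param model Model id (1, 2 or 3) declaring the expected predictor set, or
#'   a character vector naming a custom predictor set (for ad-hoc two-group
#'   discriminants outside the three reference models).
#' @return The validated data frame (class `weed_model_data`, attributes
#'   `model` and `predictors`), predictor columns in canonical order.
#' @export
as_model_data <- function(df, model) {
  predictors <- if (is.character(model)) model else weed_predictors(model)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"group" %in% names(df))
    stop("model data needs a `group` column (1/2)", call. = FALSE)
  miss <- setdiff(predictors, names(df))
  if (length(miss))
    stop("model ", model, " data is missing predictor columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$group <- as.integer(df$group)
  if (!all(df$group %in% c(1L, 2L)))
    stop("`group` must contain only 1 and 2", call. = FALSE)
  if (!"location" %in% names(df)) df$location <- "unknown"
  n1 <- sum(df$group == 1L); n2 <- sum(df$group == 2L)
  p <- length(predictors)
  if (n1 < p + 2L || n2 < p + 2L)
    stop("each group needs at least p + 2 = ", p + 2L,
         " fields (got ", n1, " and ", n2, ")", call. = FALSE)
  for (tr in predictors) {
    df[[tr]] <- as.numeric(df[[tr]])
    if (anyNA(df[[tr]]))
      stop("missing values in predictor ", tr, call. = FALSE)
  }
  df <- df[, c("group", "location", predictors)]
  structure(df, model = model, predictors = predictors,
            class = c("weed_model_data", "data.frame"))
}

#' Load a reference model dataset
#'
#' Reads a model-data CSV (`group,location,<predictor columns>`). The builtin
#' ids `"synthetic1"`, `"synthetic2"`, `"synthetic3"` resolve to small
#' synthetic stand-in datasets packaged under `inst/extdata/` — these emulate
#' the schema and statistical structure of the published survey data but are
#' simulated, clearly labelled as such, and carry no ecological meaning. To
#' use the published survey data, export it to CSV in this schema and pass the
#' path.
#'
#' @param source File path, or one of `"synthetic1"`, `"synthetic2"`,
#'   `"synthetic3"`.
#' @param model Model id; defaults to the digit in a builtin id, otherwise
#'   required.
#' @return A `weed_model_data` data frame (see [as_model_data()]).
#' @export
load_model_data <- function(source, model = NULL) {
  if (grepl("^synthetic[123]$", source)) {
    k <- as.integer(sub("synthetic", "", source))
    if (is.null(model)) model <- k
    if (model != k)
      stop("builtin '", source, "' is a model ", k, " dataset", call. = FALSE)
    source <- system.file("extdata", paste0("synthetic_model", k, ".csv"),
                          package = "weedclass", mustWork = TRUE)
  }
  if (is.null(model))
    stop("`model` is required when loading from a file path", call. = FALSE)
  as_model_data(utils::read.csv(source, stringsAsFactors = FALSE), model)
}

#' Fit the two-group linear discriminant
#'
#' Computes the discriminant from first principles. With group means
#' \eqn{m_1, m_2} and pooled within-group covariance
#' \eqn{S = [(n_1-1)S_1 + (n_2-1)S_2] / (n_1+n_2-2)}, the discriminant
#' direction is \eqn{w = S^{-1}(m_1 - m_2)}, rescaled so the pooled
#' within-group variance of the score is 1 (\eqn{w^T S w = 1}). The constant
#' maps the prior-weighted grand mean to score 0. The sign is then enforced so
#' group 1 scores positive (flip \eqn{w} and the constant if the group 1
#' centroid is negative) — discriminant signs are arbitrary, and fixing them
#' keeps plots comparable across software. Standardised coefficients are the
#' unstandardised ones multiplied by each predictor's pooled within-group SD.
#'
#' @param model_data A `weed_model_data` data frame (see [as_model_data()] /
#'   [load_model_data()]).
#' @param equal_priors If `TRUE`, use priors (0.5, 0.5); default is the
#'   training group proportions.
#' @return Object of class `wlda`: coefficients (`coef_unstd`, `coef_std`),
#'   `constant`, centroids, priors, pooled covariance, group means and sizes,
#'   per-field training scores, and the model id.
#' @export
wlda_fit <- function(model_data, equal_priors = FALSE) {
  if (!inherits(model_data, "weed_model_data"))
    stop("fit expects a `weed_model_data` object; see as_model_data()",
         call. = FALSE)
  model <- attr(model_data, "model")
  predictors <- attr(model_data, "predictors")
  X <- as.matrix(model_data[, predictors, drop = FALSE])
  g <- model_data$group
  n1 <- sum(g == 1L); n2 <- sum(g == 2L); p <- ncol(X)
  m1 <- colMeans(X[g == 1L, , drop = FALSE])
  m2 <- colMeans(X[g == 2L, , drop = FALSE])
  S1 <- stats::cov(X[g == 1L, , drop = FALSE])
  S2 <- stats::cov(X[g == 2L, , drop = FALSE])
  S <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)

  w <- tryCatch(solve(S, m1 - m2), error = function(e)
    stop("pooled within-group covariance is singular; remove a redundant ",
         "or constant predictor (", conditionMessage(e), ")", call. = FALSE))
  w <- w / sqrt(drop(t(w) %*% S %*% w))  # unit pooled within-group variance

  priors <- if (equal_priors) c(0.5, 0.5) else c(n1, n2) / (n1 + n2)
  grand <- priors[1L] * m1 + priors[2L] * m2
  const <- -drop(crossprod(w, grand))
  c1 <- drop(crossprod(w, m1)) + const
  if (c1 < 0) {  # sign convention: group 1 positive
    w <- -w
    const <- -const
    c1 <- -c1
  }
  c2 <- drop(crossprod(w, m2)) + const
  scores <- drop(X %*% w) + const

  structure(list(
    model = model, predictors = predictors,
    coef_unstd = stats::setNames(w, predictors),
    coef_std = stats::setNames(w * sqrt(diag(S)), predictors),
    constant = const,
    centroid_1 = c1, centroid_2 = c2,
    priors = stats::setNames(priors, c("1", "2")),
    pooled_cov = S, group_means = rbind(`1` = m1, `2` = m2),
    n1 = n1, n2 = n2,
    training = data.frame(group = g, location = model_data$location,
                          LD1 = scores, stringsAsFactors = FALSE)),
    class = "wlda")
}

#' @export
print.wlda <- function(x, ...) {
  cat("<wlda> two-group linear discriminant, model", x$model, "\n")
  cat("predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("n1 =", x$n1, " n2 =", x$n2,
      " priors =", paste(signif(x$priors, 4), collapse = "/"), "\n")
  cat("centroids: group 1", signif(x$centroid_1, 5),
      "| group 2", signif(x$centroid_2, 5), "\n")
  cat("coefficients (unstandardised):\n")
  print(signif(x$coef_unstd, 5))
  invisible(x)
}

#' Classify sample trait profiles against a fitted discriminant
#'
#' Scores each sample on the discriminant axis and assigns posterior
#' probabilities by the two-group Gaussian rule with pooled covariance, which
#' collapses to one dimension on LD1: with centroids \eqn{c_1 > 0 > c_2} and
#' priors \eqn{\pi_1, \pi_2},
#' \deqn{\log\frac{p_1}{p_2} = \log\frac{\pi_1}{\pi_2} +
#'   LD1\,(c_1 - c_2) - \frac{c_1^2 - c_2^2}{2}.}
#' Class 1 is assigned when \eqn{p_1 > 0.5}; an exact tie goes to class 2 (the
#' second, low-input/low-disturbance group). The standardised score is
#' computed independently through pooled-within-SD-scaled predictors and the
#' standardised coefficients; both routes provably agree.
#'
#' @param fit A `wlda` object from [wlda_fit()].
#' @param profiles A `sample_profiles` data frame from [organise()], or any
#'   data frame with a `sample` column (optional) and the model's predictor
#'   columns, non-missing.
#' @return Data frame of class `weed_classification`: `sample`, `LD1_unstd`,
#'   `LD1_std`, `class`, `prob1`, `prob2`; the fitted model is attached as
#'   attribute `fit`.
#' @export
weed_classify <- function(fit, profiles) {
  stopifnot(inherits(fit, "wlda"))
  profiles <- as.data.frame(profiles)
  miss <- setdiff(fit$predictors, names(profiles))
  if (length(miss))
    stop("profiles are missing predictor columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- if ("sample" %in% names(profiles)) as.character(profiles$sample)
         else as.character(seq_len(nrow(profiles)))
  X <- as.matrix(profiles[, fit$predictors, drop = FALSE])
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    stop("missing predictor values: ",
         paste(sprintf("%s/%s", ids[idx[, 1L]],
                       fit$predictors[idx[, 2L]]), collapse = ", "),
         call. = FALSE)
  }
  ld_unstd <- drop(X %*% fit$coef_unstd) + fit$constant

  # standardised route: centre at the prior-weighted grand mean, scale by
  # pooled within-group SDs, apply the standardised coefficients
  grand <- drop(fit$priors[1L] * fit$group_means[1L, ] +
                fit$priors[2L] * fit$group_means[2L, ])
  sds <- sqrt(diag(fit$pooled_cov))
  Z <- sweep(sweep(X, 2L, grand, "-"), 2L, sds, "/")
  ld_std <- drop(Z %*% fit$coef_std)

  c1 <- fit$centroid_1; c2 <- fit$centroid_2
  logodds <- log(fit$priors[1L] / fit$priors[2L]) +
    ld_unstd * (c1 - c2) - (c1^2 - c2^2) / 2
  prob1 <- stats::plogis(logodds)
  cls <- ifelse(prob1 > 0.5, 1L, 2L)  # tie (prob1 == 0.5) -> class 2

  structure(data.frame(sample = ids, LD1_unstd = ld_unstd, LD1_std = ld_std,
                       class = cls, prob1 = prob1, prob2 = 1 - prob1,
                       stringsAsFactors = FALSE, row.names = NULL),
            fit = fit, class = c("weed_classification", "data.frame"))
}

#' Write a classification result CSV
#'
#' Columns: `sample,LD1_unstd,LD1_std,class,prob1,prob2`.
#'
#' @param results A `weed_classification` data frame.
#' @param path Output file path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results)[, c("sample", "LD1_unstd",
                                              "LD1_std", "class",
                                              "prob1", "prob2")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
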