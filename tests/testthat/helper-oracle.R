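# Independent brute-force oracle: full p-dimensional two-group Gaussian Bayes
# rule with pooled covariance, computed via Mahalanobis distances — a
# different code path from the package's one-dimensional collapse onto LD1.

bayes_oracle <- function(model_data, newdata, equal_priors = FALSE) {
  predictors <- attr(model_data, "predictors")
  X <- as.matrix(model_data[, predictors, drop = FALSE])
  g <- model_data$group
  n1 <- sum(g == 1); n2 <- sum(g == 2)
  m1 <- colMeans(X[g == 1, , drop = FALSE])
  m2 <- colMeans(X[g == 2, , drop = FALSE])
  S <- ((n1 - 1) * cov(X[g == 1, , drop = FALSE]) +
        (n2 - 1) * cov(X[g == 2, , drop = FALSE])) / (n1 + n2 - 2)
  pri <- if (equal_priors) c(0.5, 0.5) else c(n1, n2) / (n1 + n2)
  Xn <- as.matrix(newdata[, predictors, drop = FALSE])
  d1 <- mahalanobis(Xn, m1, S)
  d2 <- mahalanobis(Xn, m2, S)
  l1 <- -d1 / 2 + log(pri[1]); l2 <- -d2 / 2 + log(pri[2])
  prob1 <- 1 / (1 + exp(l2 - l1))
  list(class = ifelse(prob1 > 0.5, 1L, 2L), prob1 = prob1)
}

# closed-form Fisher direction, recomputed independently of wlda_fit
fisher_direction <- function(model_data) {
  predictors <- attr(model_data, "predictors")
  X <- as.matrix(model_data[, predictors, drop = FALSE])
  g <- model_data$group
  n1 <- sum(g == 1); n2 <- sum(g == 2)
  m1 <- colMeans(X[g == 1, , drop = FALSE])
  m2 <- colMeans(X[g == 2, , drop = FALSE])
  S <- ((n1 - 1) * cov(X[g == 1, , drop = FALSE]) +
        (n2 - 1) * cov(X[g == 2, , drop = FALSE])) / (n1 + n2 - 2)
  solve(S, m1 - m2)
}

angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(abs(ca), -1), 1)) * 180 / pi
}
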