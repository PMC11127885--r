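# two-group linear discriminant: fit geometry, classification, invariances

test_that("fit recovers the closed-form Fisher direction and scaling", {
  set.seed(101)
  inst <- random_instance(p = 3)
  fit <- wlda_fit(inst$md)
  w0 <- fisher_direction(inst$md)              # independent recomputation
  # proportional, up to the enforced sign
  expect_lt(angle_deg(fit$coef_unstd, w0), 1e-6)
  # unit pooled within-group variance of LD1
  X <- as.matrix(inst$md[, attr(inst$md, "predictors")])
  g <- inst$md$group
  s <- drop(X %*% fit$coef_unstd)
  pooled_var <- (sum((s[g == 1] - mean(s[g == 1]))^2) +
                 sum((s[g == 2] - mean(s[g == 2]))^2)) / (length(s) - 2)
  expect_equal(pooled_var, 1, tolerance = 1e-10)
  # prior-weighted grand mean maps to 0; sign convention holds
  pri <- fit$priors
  expect_equal(pri[["1"]] * fit$centroid_1 + pri[["2"]] * fit$centroid_2, 0,
               tolerance = 1e-10)
  expect_gt(fit$centroid_1, 0)
  expect_lt(fit$centroid_2, 0)
  # standardised coefficients are unstandardised times pooled SDs
  expect_equal(unname(fit$coef_std),
               unname(fit$coef_unstd * sqrt(diag(fit$pooled_cov))))
})

test_that("univariate symmetric groups give symmetric centroids", {
  set.seed(7)
  x1 <- rnorm(30, 4); x2 <- rnorm(30, 0)
  md <- as_model_data(data.frame(group = rep(1:2, each = 30),
                                 X1 = c(x1, x2)), model = "X1")
  fit <- wlda_fit(md)
  expect_gt(fit$coef_unstd[["X1"]], 0)  # points toward group 1's higher mean
  expect_equal(fit$centroid_1, -fit$centroid_2, tolerance = 1e-10)
})

test_that("duplicating every field is invariant up to the d.o.f. factor", {
  # replication leaves means and scatter untouched but rescales the unbiased
  # pooled covariance by (N - 2)/(N - 1); with unit within-group variance
  # scaling, every score therefore grows by exactly sqrt((N-1)/(N-2)) and
  # nothing else changes: same direction, same classes
  set.seed(11)
  inst <- random_instance(p = 2)
  fit1 <- wlda_fit(inst$md)
  doubled <- as_model_data(rbind(as.data.frame(inst$md),
                                 as.data.frame(inst$md)),
                           model = attr(inst$md, "predictors"))
  fit2 <- wlda_fit(doubled)
  N <- inst$n1 + inst$n2
  k <- sqrt((N - 1) / (N - 2))
  expect_lt(angle_deg(fit2$coef_unstd, fit1$coef_unstd), 1e-9)
  expect_equal(fit2$centroid_1, k * fit1$centroid_1, tolerance = 1e-9)
  expect_equal(fit2$centroid_2, k * fit1$centroid_2, tolerance = 1e-9)
  expect_identical(weed_classify(fit2, inst$test)$class,
                   weed_classify(fit1, inst$test)$class)
})

test_that("identity pooled covariance aligns w with the mean difference", {
  # orthonormal design: pooled covariance is exactly the identity, group
  # mean difference is exactly (1, 0)
  base <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * sqrt(3) / 2
  g1 <- sweep(base, 2, c(0.5, 0), "+")
  g2 <- sweep(base, 2, c(-0.5, 0), "+")
  md <- as_model_data(data.frame(group = rep(1:2, each = 4),
                                 X1 = c(g1[, 1], g2[, 1]),
                                 X2 = c(g1[, 2], g2[, 2])),
                      model = c("X1", "X2"))
  fit <- wlda_fit(md)
  expect_equal(fit$pooled_cov, diag(2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(fit$coef_unstd[["X2"]], 0, tolerance = 1e-12)
  expect_gt(fit$coef_unstd[["X1"]], 0)
})

test_that("degenerate model data is rejected with actionable errors", {
  set.seed(3)
  inst <- random_instance(p = 2)
  df <- as.data.frame(inst$md)
  expect_error(as_model_data(df[df$group == 1, ], c("X1", "X2")),
               "p \\+ 2")
  df$X2 <- df$X1                      # perfectly collinear
  md <- as_model_data(df, c("X1", "X2"))
  expect_error(wlda_fit(md), "singular")
})

test_that("classification matches hand-computable boundary cases", {
  set.seed(21)
  inst <- random_instance(p = 3)
  fit <- wlda_fit(inst$md, equal_priors = TRUE)
  S <- fit$pooled_cov
  w <- fit$coef_unstd
  grand <- drop(0.5 * fit$group_means[1, ] + 0.5 * fit$group_means[2, ])
  # a profile scoring exactly at centroid_1 -> class 1 decisively
  at_c1 <- grand + drop(S %*% w) * fit$centroid_1
  r1 <- weed_classify(fit, as.data.frame(t(at_c1)))
  expect_equal(r1$LD1_unstd, fit$centroid_1, tolerance = 1e-9)
  expect_gt(r1$prob1, 0.5)
  expect_identical(r1$class, 1L)
  # the midpoint of the centroids (equal priors) is the 50/50 boundary,
  # and the exact tie resolves to class 2
  mid <- grand + drop(S %*% w) * (fit$centroid_1 + fit$centroid_2) / 2
  r0 <- weed_classify(fit, as.data.frame(t(mid)))
  expect_equal(r0$prob1, 0.5, tolerance = 1e-9)
  expect_identical(r0$class, 2L)
})

test_that("posteriors and classes match the brute-force Bayes oracle", {
  set.seed(55)
  for (i in 1:50) {
    inst <- random_instance()
    eq <- i %% 2 == 0
    fit <- wlda_fit(inst$md, equal_priors = eq)
    got <- weed_classify(fit, inst$test)
    want <- bayes_oracle(inst$md, inst$test, equal_priors = eq)
    expect_identical(got$class, want$class)
    expect_equal(got$prob1, want$prob1, tolerance = 1e-8)
  }
})

test_that("classification agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(77)
  inst <- random_instance(p = 4)
  fit <- wlda_fit(inst$md)
  got <- weed_classify(fit, inst$test)
  ref <- MASS::lda(as.matrix(inst$md[, attr(inst$md, "predictors")]),
                   grouping = inst$md$group)
  pred <- predict(ref, as.matrix(inst$test))
  expect_identical(got$class, as.integer(as.character(pred$class)))
  expect_equal(got$prob1, unname(pred$posterior[, "1"]), tolerance = 1e-8)
  # scores agree up to the (arbitrary) sign and degrees-of-freedom scale
  expect_gt(abs(cor(got$LD1_unstd, pred$x[, 1])), 1 - 1e-10)
})

test_that("standardised and unstandardised routes agree", {
  set.seed(88)
  inst <- random_instance()
  fit <- wlda_fit(inst$md)
  got <- weed_classify(fit, inst$test)
  expect_equal(got$LD1_std, got$LD1_unstd, tolerance = 1e-9)
  expect_equal(got$prob1 + got$prob2, rep(1, nrow(got)), tolerance = 1e-12)
})

test_that("rescaling a predictor leaves scores and classes unchanged", {
  set.seed(99)
  for (i in 1:10) {
    inst <- random_instance()
    fit <- wlda_fit(inst$md)
    base <- weed_classify(fit, inst$test)
    sc <- runif(inst$p, 0.1, 10)
    df <- as.data.frame(inst$md)
    te <- inst$test
    for (j in seq_len(inst$p)) {
      nm <- paste0("X", j)
      df[[nm]] <- df[[nm]] * sc[j]
      te[[nm]] <- te[[nm]] * sc[j]
    }
    fit2 <- wlda_fit(as_model_data(df, attr(inst$md, "predictors")))
    got <- weed_classify(fit2, te)
    expect_equal(got$LD1_unstd, base$LD1_unstd, tolerance = 1e-9)
    expect_equal(got$prob1, base$prob1, tolerance = 1e-9)
    expect_identical(got$class, base$class)
    # unstandardised coefficients scale inversely, standardised ones don't
    expect_equal(unname(fit2$coef_unstd * sc), unname(fit$coef_unstd),
                 tolerance = 1e-9)
    expect_equal(fit2$coef_std, fit$coef_std, tolerance = 1e-9)
  }
})

test_that("swapping group labels flips scores and classes coherently", {
  set.seed(123)
  for (i in 1:10) {
    inst <- random_instance()
    fit <- wlda_fit(inst$md)
    base <- weed_classify(fit, inst$test)
    df <- as.data.frame(inst$md)
    df$group <- 3L - df$group
    fit2 <- wlda_fit(as_model_data(df, attr(inst$md, "predictors")))
    got <- weed_classify(fit2, inst$test)
    expect_equal(got$LD1_unstd, -base$LD1_unstd, tolerance = 1e-9)
    expect_equal(got$prob1, base$prob2, tolerance = 1e-9)
    expect_identical(got$class, 3L - base$class)
  }
})

test_that("missing predictors are reported by sample and trait", {
  set.seed(5)
  inst <- random_instance(p = 2)
  fit <- wlda_fit(inst$md)
  te <- inst$test
  te$sample <- paste0("smp", seq_len(nrow(te)))
  te$X2[3] <- NA
  expect_error(weed_classify(fit, te), "smp3/X2")
  expect_error(weed_classify(fit, te[, "X1", drop = FALSE]), "X2")
})

test_that("builtin synthetic model datasets load and validate", {
  for (k in 1:3) {
    md <- load_model_data(paste0("synthetic", k))
    expect_s3_class(md, "weed_model_data")
    expect_identical(attr(md, "predictors"), weed_predictors(k))
    expect_setequal(unique(md$group), c(1L, 2L))
    if (k > 1) expect_gte(length(unique(md$location)), 2L)
    expect_silent(wlda_fit(md))
  }
  expect_error(load_model_data("synthetic1", model = 2), "model 1")
  # a file with only one group is rejected
  p <- withr::local_tempfile(fileext = ".csv")
  md1 <- as.data.frame(load_model_data("synthetic2"))
  utils::write.csv(md1[md1$group == 1, ], p, row.names = FALSE)
  expect_error(load_model_data(p, model = 2), "p \\+ 2")
})
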