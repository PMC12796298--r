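fake_features <- function(amplitude, delta, rho,
                          subject = "s1", isi = 0L, group = "HC") {
  data.frame(
    subject_id = subject, session_id = paste0(subject, "_s1"), group = group,
    isi_ms = isi, amplitude_uv = amplitude, delta = delta, rho = rho,
    stringsAsFactors = FALSE
  )
}

test_that("collinear predictors put all variance on PC1", {
  x <- c(1, 2, 3, 4, 5)
  res <- standardize_and_pc1(fake_features(x, 2 * x, 3 * x))
  expect_equal(res$variance_explained, 1, tolerance = 1e-12)
  expect_equal(sum(res$loadings^2), 1, tolerance = 1e-12)
  expect_gte(res$loadings["amplitude_uv"], 0)
})

test_that("independent predictors approach the isotropic 1/3 share", {
  set.seed(51)
  n <- 30000
  res <- standardize_and_pc1(fake_features(rnorm(n), rnorm(n), rnorm(n)))
  expect_lt(abs(res$variance_explained - 1 / 3), 0.02)
})

test_that("PC1 scores are centred and sign-anchored to MEP amplitude", {
  set.seed(52)
  n <- 500
  a <- rnorm(n)
  res <- standardize_and_pc1(fake_features(a, a + rnorm(n, sd = 0.3),
                                           a + rnorm(n, sd = 0.3)))
  expect_equal(mean(res$scores), 0, tolerance = 1e-10)
  expect_gte(res$loadings["amplitude_uv"], 0)
  # scores correlate positively with amplitude under the sign convention
  expect_gt(stats::cor(res$scores, a), 0)
})

test_that("degenerate PCA inputs raise named errors", {
  expect_error(standardize_and_pc1(fake_features(1:5, rep(1, 5), 1:5)), "delta")
  expect_error(standardize_and_pc1(fake_features(1, 1, 1)), ">= 3 rows")
})

test_that("PC1 aggregation is per subject x ISI with integrity checks", {
  agg <- aggregate_pc1(c(-1, 1), c("s1", "s1"), c(4L, 4L), c("HC", "HC"))
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$pc1, 0)

  feats <- annotate_metrics(generate_cohort(cohort_config(seed = 53L)))
  pca <- standardize_and_pc1(feats)
  agg_full <- aggregate_pc1(pca$scores, feats$subject_id, feats$isi_ms, feats$group)
  expect_equal(nrow(agg_full), 43L * 7L)

  expect_error(
    aggregate_pc1(c(0, 0), c("s1", "s1"), c(0L, 4L), c("HC", "MDD")),
    "inconsistent group"
  )
})

sim_aggregated <- function(n = 300, beta0 = 0.44, beta1 = 0.3) {
  isi <- rep(c(0L, 4L, 5L, 8L, 10L, 15L, 20L), length.out = n)
  pc1 <- rnorm(n)
  y <- rbinom(n, 1L, plogis(beta0 + beta1 * pc1))
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)), isi_ms = isi,
    group = ifelse(y == 1L, "MDD", "HC"), pc1 = pc1,
    stringsAsFactors = FALSE
  )
}

test_that("boundary GLMM fits collapse to ordinary logistic regression", {
  # search deterministically for a replicate whose variance estimates hit
  # the boundary (true variances are zero, so most do)
  found <- FALSE
  for (seed in 61:80) {
    set.seed(seed)
    agg <- sim_aggregated()
    res <- fit_glmm(agg)
    if (res$var_intercept < 1e-10 && res$var_slope < 1e-10) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_true(res$boundary)
  glm_fit <- stats::glm(I(group == "MDD") ~ pc1, data = agg, family = stats::binomial())
  expect_equal(res$beta0, unname(stats::coef(glm_fit)[1]), tolerance = 1e-6)
  expect_equal(res$beta1, unname(stats::coef(glm_fit)[2]), tolerance = 1e-6)
})

test_that("GLMM reports information criteria and Wald inference", {
  set.seed(62)
  res <- fit_glmm(sim_aggregated(n = 280))
  expect_gt(res$bic, res$aic) # log(280) penalty exceeds 2 per parameter
  expect_equal(res$n_obs, 280L)
  expect_equal(res$z1, res$beta1 / res$se1, tolerance = 1e-9)
  expect_true(res$p1 >= 0 && res$p1 <= 1)
})

test_that("GLMM input contracts are enforced and separation is flagged", {
  agg <- sim_aggregated(n = 60)
  agg$group <- "MDD"
  expect_error(fit_glmm(agg), "both outcome classes")
  expect_error(fit_glmm(sim_aggregated(n = 40)[1, ]), "ISI levels|both outcome")

  set.seed(63)
  sep <- sim_aggregated(n = 80)
  sep$group <- ifelse(sep$pc1 > 0, "MDD", "HC") # perfectly separable
  res <- fit_glmm(sep)
  expect_true(res$separation || !res$converged)
})

test_that("the full PC-GLMM analysis recovers a positive excitability effect", {
  feats <- small_features(seed = 64L)
  res <- pc_glmm_analysis(feats)
  expect_equal(nrow(res$aggregated), res$glmm$n_obs)
  expect_gt(res$glmm$beta1, 0) # MDD simulated as hyper-excitable
  expect_gt(res$pca$variance_explained, 1 / 3)
})
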