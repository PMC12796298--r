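#' First principal component of standardized (MEP, delta, rho)
#'
#' The three predictors are strongly collinear (delta and rho are ratios of
#' the same amplitude), so their shared variance is collapsed into the first
#' principal component of the z-scored columns before regression. The
#' eigenvector sign is fixed so the loading on MEP amplitude is
#' non-negative, making the downstream slope's sign interpretable (higher
#' amplitude/excitability pushes the score up).
#'
#' @param features Feature table with `amplitude_uv`, `delta`, `rho`.
#' @return An object of class `pc1_result`: list with `loadings` (named
#'   3-vector, unit norm), `variance_explained` (largest eigenvalue share)
#'   and `scores` (per-row PC1 values, mean 0).
#' @export
standardize_and_pc1 <- function(features) {
  check_stim_table(features, require = c("amplitude_uv", "delta", "rho"))
  if (nrow(features) < 3L) stop_param("need >= 3 rows for PCA")
  m <- as.matrix(features[c("amplitude_uv", "delta", "rho")])
  if (anyNA(m)) stop_param("predictors contain missing values")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    stop_param("zero-variance column(s): ",
               paste(colnames(m)[sds == 0], collapse = ", "))
  }
  pca <- prcomp(m, center = TRUE, scale. = TRUE)
  load1 <- pca$rotation[, 1L]
  scores <- pca$x[, 1L]
  if (load1["amplitude_uv"] < 0) {
    load1 <- -load1
    scores <- -scores
  }
  structure(
    list(
      loadings = load1,
      variance_explained = unname(pca$sdev[1L]^2 / sum(pca$sdev^2)),
      scores = unname(scores)
    ),
    class = "pc1_result"
  )
}

#' @export
print.pc1_result <- function(x, ...) {
  cat(sprintf("PC1 of standardized (MEP, delta, rho): %.1f%% of variance\n",
              100 * x$variance_explained))
  print(round(x$loadings, 4))
  invisible(x)
}

#' Average PC1 scores within subject x ISI
#'
#' @param scores Per-row PC1 scores (from [standardize_and_pc1()]).
#' @param subject_id,isi_ms,group Aligned vectors from the same feature table.
#' @return Data.frame with one row per subject x ISI: `subject_id`,
#'   `isi_ms`, `group`, `pc1`.
#' @export
aggregate_pc1 <- function(scores, subject_id, isi_ms, group) {
  n <- length(scores)
  if (length(subject_id) != n || length(isi_ms) != n || length(group) != n) {
    stop_param("`scores`, `subject_id`, `isi_ms` and `group` must be aligned")
  }
  lab <- tapply(group, subject_id, function(g) length(unique(g)))
  if (any(lab > 1L)) {
    stop_param("inconsistent group labels within subject(s): ",
               paste(names(lab)[lab > 1L], collapse = ", "))
  }
  d <- data.frame(pc1 = scores, subject_id = subject_id,
                  isi_ms = isi_ms, group = group, stringsAsFactors = FALSE)
  out <- aggregate(pc1 ~ subject_id + isi_ms + group, data = d, FUN = mean)
  out <- out[c("subject_id", "isi_ms", "group", "pc1")]
  out <- out[order(out$subject_id, out$isi_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mixed-effects logistic model of diagnostic status
#'
#' Fits, by maximum likelihood (Laplace approximation, via
#' [lme4::glmer()]),
#'
#' \deqn{\mathrm{logit}\,P(y_{ij} = \mathrm{MDD}) =
#'   \beta_0 + \beta_1 \mathrm{PC}^{(1)}_{ij} + b_{0j} + b_{1j}
#'   \mathrm{PC}^{(1)}_{ij}}
#'
#' where j indexes ISI levels: a random intercept and an (independent)
#' random slope per ISI let the effect of the excitability component vary
#' across stimulation conditions. Variance estimates on the boundary
#' (zero) are reported with a `boundary` flag rather than an error —
#' a boundary fit collapses to ordinary logistic regression.
#'
#' @param aggregated Output of [aggregate_pc1()] (columns `pc1`, `isi_ms`,
#'   `group`).
#' @param positive Group label modelled as the event (default `"MDD"`).
#' @return An object of class `glmm_result`: fixed effects (`beta0`,
#'   `beta1`) with standard errors, Wald z and p-values, random-effect
#'   variances (`var_intercept`, `var_slope`), `aic`, `bic`, `n_obs`,
#'   `boundary` and `converged` flags, and the underlying `fit`.
#' @export
fit_glmm <- function(aggregated, positive = "MDD") {
  check_stim_table(aggregated, require = c("pc1", "isi_ms", "group"))
  if (length(unique(aggregated$isi_ms)) < 2L) stop_param("need >= 2 ISI levels")
  y <- as.integer(aggregated$group == positive)
  if (length(unique(y)) < 2L) stop_param("both outcome classes must be present")
  d <- data.frame(y = y, pc1 = aggregated$pc1,
                  isi = factor(aggregated$isi_ms))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(y ~ pc1 + (1 | isi) + (0 + pc1 | isi),
                  data = d, family = stats::binomial())
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # the PIRLS inner loop diverges under (quasi-)complete separation;
    # report the boundary logistic fit with a non-convergence flag
    glm_fit <- suppressWarnings(
      stats::glm(y ~ pc1, data = d, family = stats::binomial())
    )
    co <- summary(glm_fit)$coefficients
    colnames(co) <- c("Estimate", "Std. Error", "z value", "Pr(>|z|)")
    return(structure(
      list(
        beta0 = co["(Intercept)", "Estimate"], beta1 = co["pc1", "Estimate"],
        se0 = co["(Intercept)", "Std. Error"], se1 = co["pc1", "Std. Error"],
        z0 = co["(Intercept)", "z value"], z1 = co["pc1", "z value"],
        p0 = co["(Intercept)", "Pr(>|z|)"], p1 = co["pc1", "Pr(>|z|)"],
        var_intercept = 0, var_slope = 0,
        aic = stats::AIC(glm_fit), bic = stats::BIC(glm_fit),
        n_obs = nrow(d), boundary = TRUE,
        converged = FALSE, separation = TRUE, fit = glm_fit
      ),
      class = "glmm_result"
    ))
  }
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$var1 == "(Intercept)"][1]
  var_slp <- vc$vcov[vc$var1 == "pc1"][1]
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  separation <- any(abs(co[, "Estimate"]) > 15) || any(co[, "Std. Error"] > 50)
  structure(
    list(
      beta0 = co["(Intercept)", "Estimate"], beta1 = co["pc1", "Estimate"],
      se0 = co["(Intercept)", "Std. Error"], se1 = co["pc1", "Std. Error"],
      z0 = co["(Intercept)", "z value"], z1 = co["pc1", "z value"],
      p0 = co["(Intercept)", "Pr(>|z|)"], p1 = co["pc1", "Pr(>|z|)"],
      var_intercept = var_int, var_slope = var_slp,
      aic = stats::AIC(fit), bic = stats::BIC(fit),
      n_obs = nrow(d),
      boundary = (var_int < 1e-8) || (var_slp < 1e-8),
      converged = converged && !separation,
      separation = separation,
      fit = fit
    ),
    class = "glmm_result"
  )
}

#' @export
print.glmm_result <- function(x, ...) {
  cat("Mixed-effects logistic model of diagnostic status\n")
  cat(sprintf("  intercept  %.4f (SE %.4f, z = %.2f, p = %.4g)\n",
              x$beta0, x$se0, x$z0, x$p0))
  cat(sprintf("  PC1 slope  %.4f (SE %.4f, z = %.2f, p = %.4g)\n",
              x$beta1, x$se1, x$z1, x$p1))
  cat(sprintf("  random-effect variances (ISI): intercept %.3g, slope %.3g%s\n",
              x$var_intercept, x$var_slope,
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  AIC %.1f, BIC %.1f, n = %d\n", x$aic, x$bic, x$n_obs))
  if (!x$converged) cat("  WARNING: fit flagged as non-converged/separated\n")
  invisible(x)
}

#' Convenience wrapper: PCA, aggregation and GLMM in one call
#'
#' @param features Feature table.
#' @param positive Event label for the logistic model.
#' @return A list with `pca` ([standardize_and_pc1()] result), `aggregated`
#'   table and `glmm` ([fit_glmm()] result).
#' @export
pc_glmm_analysis <- function(features, positive = "MDD") {
  pca <- standardize_and_pc1(features)
  agg <- aggregate_pc1(pca$scores, features$subject_id,
                       features$isi_ms, features$group)
  list(pca = pca, aggregated = agg, glmm = fit_glmm(agg, positive = positive))
}
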