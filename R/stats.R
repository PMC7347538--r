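# Cross-variant statistical layer: one-way ANOVA, gamma GLM (log link)
# with a Wald chi-square test, affinity-density regression, and the
# chain-length argmax of the density curve.

#' One-way ANOVA across variant groups
#'
#' Classic fixed-effects one-way analysis of variance: F = MS(between) /
#' MS(within) with k - 1 and N - k degrees of freedom, assuming normal
#' within-group distributions.
#'
#' @param groups list of two or more numeric vectors, each with at least
#'   two values; names become group labels.
#' @return A [StatsResult-class] (`statistic` = F, `df` = c(k-1, N-k)).
#' @examples
#' anovaOneway(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
anovaOneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  tab <- stats::anova(stats::lm(y ~ g))
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(f)) { f <- 0; p <- 1 }  # zero residual variance, equal means
  new("StatsResult", test = "oneway_anova", statistic = f,
      df = c(tab$Df[1], tab$Df[2]), p.value = p, groups = names(groups))
}

#' Gamma GLM with log link and Wald chi-square test
#'
#' Models strictly positive, right-skewed responses (cluster ion channel
#' densities) as gamma-distributed with a log link between the linear
#' predictor and the mean: `E[y | group g] = exp(beta0 + beta_g)`. The fit
#' is by iteratively reweighted least squares ([stats::glm()]); the Wald
#' chi-square statistic `W = beta' V^-1 beta` over the group contrasts
#' tests the null that all group effects are zero, with the coefficient
#' covariance scaled by the Pearson chi-square dispersion estimate from
#' the final IRLS step.
#'
#' @param values strictly positive numeric responses.
#' @param group_labels group membership, same length as `values`; at
#'   least two groups.
#' @param max_iter IRLS iteration cap.
#' @return A [StatsResult-class] (`statistic` = Wald chi-square, `df` =
#'   k-1, `estimate` = fitted coefficients on the log scale plus the
#'   dispersion).
#' @export
gammaGlmLogLink <- function(values, group_labels, max_iter = 50L) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("gamma GLM requires strictly positive values")
  g <- factor(group_labels)
  if (nlevels(g) < 2L)
    stop("need at least two groups (single-group call is degenerate)")
  if (length(values) != length(g)) stop("values and labels differ in length")
  fit <- stats::glm(values ~ g, family = stats::Gamma(link = "log"),
                    control = stats::glm.control(maxit = max_iter))
  if (!fit$converged)
    stop("IRLS did not converge within ", max_iter, " iterations ",
         "(deviance ", format(fit$deviance), ")")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  V <- summary(fit, dispersion = disp)$cov.scaled
  beta <- stats::coef(fit)
  idx <- seq_along(beta)[-1]  # group contrasts
  W <- drop(t(beta[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% beta[idx])
  df <- length(idx)
  est <- c(beta, dispersion = disp)
  new("StatsResult", test = "gamma_glm_wald", statistic = W, df = df,
      p.value = stats::pchisq(W, df, lower.tail = FALSE), estimate = est,
      groups = levels(g))
}

#' Affinity-density regression across variants
#'
#' Ordinary least squares of the mean cluster signal intensity on the
#' scaffold-binding free energy over variants with chain length at least
#' `min_chain_length` (the regime where recruitment thermodynamics, not
#' steric hindrance, governs cluster density). Variants without a measured
#' binding energy are excluded; the reversed-sequence control can be
#' excluded with `include_reversed = FALSE`.
#'
#' @param summaries data.frame from [summarizeVariant()] (needs
#'   `chain_length`, `intensity_mean`, `binding_energy`, optionally
#'   `reversed`).
#' @param min_chain_length smallest chain length included (default 61).
#' @param include_reversed keep the reversed-chain control (default TRUE).
#' @return A [StatsResult-class] with `estimate["slope"]`,
#'   `["intercept"]`, `["r.squared"]`, and `["n"]`.
#' @examples
#' s <- kvPresets()
#' s$intensity_mean <- s$cluster_intensity
#' affinityDensityRegression(s)
#' @export
affinityDensityRegression <- function(summaries, min_chain_length = 61L,
                                      include_reversed = TRUE) {
  d <- summaries[!is.na(summaries$binding_energy) &
                 summaries$chain_length >= min_chain_length, , drop = FALSE]
  if (!include_reversed && "reversed" %in% names(d))
    d <- d[!d$reversed %in% TRUE, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least three variants with binding energies ",
         "(got ", nrow(d), ")")
  fit <- stats::lm(intensity_mean ~ binding_energy, data = d)
  sm <- summary(fit)
  new("StatsResult", test = "affinity_density_ols",
      statistic = NA_real_, df = fit$df.residual, p.value = NA_real_,
      estimate = c(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r.squared = sm$r.squared, n = nrow(d)),
      groups = as.character(d$name))
}

#' Chain length at the density maximum
#'
#' The chain length whose variant attains the maximal mean cluster signal
#' intensity: the apex of the bell-shaped density-versus-chain-length
#' dependence. Ties go to the shorter chain.
#'
#' @param summaries data.frame with `chain_length` and `intensity_mean`;
#'   at least three variants.
#' @return integer chain length (amino acids).
#' @export
bellCurveArgmax <- function(summaries) {
  if (nrow(summaries) < 3L) stop("need at least three variants")
  m <- max(summaries$intensity_mean)
  cand <- summaries$chain_length[summaries$intensity_mean == m]
  as.integer(min(cand))
}
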