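#' Regression models for spurt-level growth outcomes
#'
#' Three models over the [build_model_table()] rows, each with the linear
#' predictor `Spurt + AoA + Frequency(log) + Length`: a quasi-binomial
#' logit-link GLM for each proportional outcome (degree gain, saturation
#' gain), and a zero-inflated negative binomial regression for the rounded
#' average weighted degree, whose zeros come from spurts with an empty
#' neighbourhood.  Spurt and AoA enter as categorical factors with
#' treatment contrasts against level 1, so coefficients read as "Spurt 2",
#' "AoA 3", ... relative to the first level.
#'
#' @name growth_models
NULL

model_frame_from_table <- function(table, dv_col) {
  stopifnot(inherits(table, "data.frame"))
  d <- data.frame(
    dv = table[[dv_col]],
    Spurt = factor(table$spurt),
    AoA = factor(table$aoa),
    Frequency = table$freq_log,
    Length = table$length
  )
  d[!is.na(d$dv), , drop = FALSE]
}

# binomial-style log-likelihood for proportion outcomes: the quasi-binomial
# fit has no true likelihood, so McFadden's R2 is computed on the analogous
# Bernoulli kernel sum(y log mu + (1-y) log(1-mu))
bernoulli_kernel_ll <- function(y, mu) sum(y * log(mu) + (1 - y) * log(1 - mu))

#' McFadden pseudo-R² of a proportional-outcome fit
#'
#' `1 - ll_model / ll_null` on the Bernoulli likelihood kernel evaluated at
#' the fitted and the intercept-only means.  0 for the null model itself,
#' non-decreasing as covariates are added.
#'
#' @param y observed proportions in (0, 1)
#' @param mu fitted means
#' @return numeric in \[0, 1\] for nested fits
#' @export
mcfadden_r2 <- function(y, mu) {
  ll_m <- bernoulli_kernel_ll(y, mu)
  ll_0 <- bernoulli_kernel_ll(y, rep(mean(y), length(y)))
  1 - ll_m / ll_0
}

# Cohen-threshold labels for standardized odds ratios, applied symmetrically
# through the reciprocal for ORs below 1
or_effect_label <- function(or) {
  m <- pmax(or, 1 / or)
  cut(m, c(-Inf, 1.68, 3.47, 6.71, Inf),
      labels = c("Very small", "Small", "Medium", "Large"))
}

standardized_odds_ratios <- function(formula, data, family) {
  d <- data
  for (v in c("Frequency", "Length"))
    if (stats::sd(d[[v]]) > 0) d[[v]] <- as.numeric(scale(d[[v]]))
  fit <- stats::glm(formula, family = family, data = d)
  or <- exp(stats::coef(fit))
  data.frame(term = names(or), std_odds_ratio = unname(or),
             effect_size = or_effect_label(unname(or)),
             stringsAsFactors = FALSE)
}

#' Fit a quasi-binomial GLM for a proportional growth outcome
#'
#' `DV ~ Spurt + AoA + Frequency + Length`, family quasibinomial with logit
#' link, on the Smithson-Verkuilen transformed proportion.  Returns the
#' coefficient table with dispersion, variance-inflation factors, McFadden's
#' pseudo-R² (computed on the Bernoulli kernel), and standardized odds
#' ratios (continuous covariates scaled to unit SD).
#'
#' @param table a `spurt_model_table` (or compatible data.frame)
#' @param dv `"degree_gain"` or `"saturation_gain"`
#' @return object of class `phonogrow_glm`
#' @export
fit_proportional_model <- function(table,
                                   dv = c("degree_gain", "saturation_gain")) {
  dv <- match.arg(dv)
  col <- paste0("sv_", dv)
  if (!col %in% names(table))
    stop("table lacks column ", col, "; build it with build_model_table()")
  d <- model_frame_from_table(table, col)
  if (any(d$dv <= 0 | d$dv >= 1))
    stop("DV must lie strictly in (0, 1); apply sv_transform first")
  if (stats::sd(d$dv) == 0) stop("constant DV; nothing to fit")
  form <- dv ~ Spurt + AoA + Frequency + Length
  # single-level factors (e.g. one AoA stage in a small fixture) are dropped
  keep <- c("Spurt", "AoA")[vapply(d[c("Spurt", "AoA")], nlevels,
                                   integer(1L)) > 1L]
  form <- stats::reformulate(c(keep, "Frequency", "Length"), response = "dv")
  fit <- stats::glm(form, family = stats::quasibinomial(link = "logit"),
                    data = d)
  if (!fit$converged) warning("quasi-binomial fit did not converge")
  coefs <- summary(fit)$coefficients
  vifs <- if (length(attr(stats::terms(form), "term.labels")) >= 2L)
    car::vif(fit) else NULL
  structure(
    list(fit = fit, dv = dv, n = nrow(d),
         formula = form,
         coefficients = coefs,
         dispersion = summary(fit)$dispersion,
         vif = vifs,
         mcfadden_r2 = mcfadden_r2(d$dv, stats::fitted(fit)),
         odds_ratios = standardized_odds_ratios(
           form, d, stats::quasibinomial(link = "logit"))),
    class = "phonogrow_glm"
  )
}

#' @export
print.phonogrow_glm <- function(x, ...) {
  cat("Quasi-binomial GLM for proportional", x$dv,
      " (n =", x$n, ")\n")
  cat(deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, digits = 3)
  cat("\nDispersion:", round(x$dispersion, 3),
      "  McFadden R2:", round(x$mcfadden_r2, 3), "\n")
  invisible(x)
}

#' @export
summary.phonogrow_glm <- function(object, ...) {
  print(object)
  if (!is.null(object$vif)) {
    cat("\nVariance inflation factors:\n"); print(object$vif)
  }
  cat("\nStandardized odds ratios:\n")
  print(object$odds_ratios, row.names = FALSE)
  invisible(object)
}

#' @export
coef.phonogrow_glm <- function(object, ...) stats::coef(object$fit)

#' Fit the zero-inflated negative binomial model for weighted degree
#'
#' `wd_new_int ~ Spurt + AoA + Frequency + Length` in both the count
#' (negative binomial, log link) and the zero-inflation (binomial, logit
#' link) components.  The DV must be the non-negative integer rounded
#' average weighted degree; its zeros are spurts at which the word's
#' neighbourhood is still empty.
#'
#' @param table a `spurt_model_table` (or compatible data.frame with a
#'   `wd_new_int` column)
#' @param zi_formula right-hand side of the zero-inflation component
#'   (default: same predictors as the count component)
#' @return object of class `phonogrow_zinb` with `count_coefficients` and
#'   `zero_coefficients` tables
#' @export
fit_zinb_model <- function(table, zi_formula = NULL) {
  if (!"wd_new_int" %in% names(table)) stop("table lacks wd_new_int")
  d <- model_frame_from_table(table, "wd_new_int")
  if (any(d$dv < 0) || any(d$dv != round(d$dv)))
    stop("DV must be non-negative integers (rounded average weighted degree)")
  keep <- c("Spurt", "AoA")[vapply(d[c("Spurt", "AoA")], nlevels,
                                   integer(1L)) > 1L]
  rhs <- c(keep, "Frequency", "Length")
  form <- stats::reformulate(rhs, response = "dv")
  zif <- zi_formula %||% stats::reformulate(rhs)
  fit <- glmmTMB::glmmTMB(form, ziformula = zif,
                          family = glmmTMB::nbinom2, data = d)
  conv <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  if (!conv)
    warning("zero-inflated fit did not fully converge; ",
            "inspect $fit diagnostics (degenerate zero-inflation cells ",
            "can produce huge standard errors)")
  sm <- summary(fit)
  structure(
    list(fit = fit, n = nrow(d), formula = form, zi_formula = zif,
         converged = conv,
         count_coefficients = sm$coefficients$cond,
         zero_coefficients = sm$coefficients$zi,
         theta = glmmTMB::sigma(fit)),
    class = "phonogrow_zinb"
  )
}

#' @export
print.phonogrow_zinb <- function(x, ...) {
  cat("Zero-inflated negative binomial model (n =", x$n, ")\n")
  cat("Count component (negbin, log link):\n")
  stats::printCoefmat(x$count_coefficients, digits = 3)
  cat("\nZero-inflation component (binomial, logit link):\n")
  stats::printCoefmat(x$zero_coefficients, digits = 3)
  cat("\nTheta:", round(x$theta, 3),
      if (!x$converged) "  [convergence warning]" else "", "\n")
  invisible(x)
}

#' @export
summary.phonogrow_zinb <- function(object, ...) print(object)

#' @export
coef.phonogrow_zinb <- function(object, ...) glmmTMB::fixef(object$fit)

#' Pairwise spurt contrasts on the response scale
#'
#' Estimated marginal means for the Spurt factor, averaged over AoA (and
#' the continuous covariates at their means), re-gridded to the response
#' scale, with all pairwise differences and Tukey-adjusted p-values
#' (multivariate-t family-wise correction over the spurt pairs).
#'
#' @param fit a `phonogrow_glm` or `phonogrow_zinb`
#' @return data.frame with `contrast`, `estimate`, `se`, `z_ratio`,
#'   `p_value`
#' @export
pairwise_spurt_contrasts <- function(fit) {
  obj <- if (inherits(fit, "phonogrow_glm")) fit$fit
         else if (inherits(fit, "phonogrow_zinb")) fit$fit
         else stop("need a phonogrow_glm or phonogrow_zinb fit")
  if (!"Spurt" %in% all.vars(fit$formula)) stop("model contains no Spurt term")
  em <- if (inherits(fit, "phonogrow_zinb"))
    emmeans::emmeans(obj, "Spurt", component = "cond")
  else emmeans::emmeans(obj, "Spurt")
  prs <- summary(graphics::pairs(emmeans::regrid(em), adjust = "tukey"),
                 infer = c(FALSE, TRUE))
  data.frame(contrast = as.character(prs$contrast),
             estimate = prs$estimate,
             se = prs$SE,
             z_ratio = prs$estimate / prs$SE,
             p_value = prs$p.value,
             stringsAsFactors = FALSE)
}
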