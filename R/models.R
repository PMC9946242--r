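#' Used-versus-available mixed models of current density
#'
#' `fit_case_model()` fits the random-intercept linear mixed model
#' `current_value ~ case + (1 | individual_id)` by REML: current density as
#' the response, case (observed = 1, available = 0) as the categorical
#' predictor, and individual as the random effect to absorb correlation
#' among each individual's observations. `fit_interaction_model()` adds the
#' individual's maximum displacement distance and its interaction with case
#' (`current_value ~ case * d_max + (1 | individual_id)`): a positive
#' interaction means the observed-available gap widens for longer-ranging
#' individuals. Confidence intervals are Wald 95% intervals.
#'
#' A singular fit (random-intercept variance estimated at 0) is reported,
#' not dropped.
#'
#' @param data A case tibble: `individual_id`, `case` (0/1),
#'   `current_value`, and `d_max` for the interaction model. Each individual
#'   needs both cases; at least 2 individuals.
#' @return An `omc_model_fit`: tibble of fixed effects (`term`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high`), `ranef_variance`,
#'   `sigma`, `n_obs`, `n_individuals`, `singular`, and the underlying
#'   `lme4` fit in `$fit`.
#' @export
fit_case_model <- function(data) {
  check_case_data(data)
  wrap_lmm(lme4::lmer(current_value ~ case + (1 | individual_id),
                      data = data, REML = TRUE),
           data)
}

#' @rdname fit_case_model
#' @export
fit_interaction_model <- function(data) {
  check_case_data(data)
  if (length(unique(data$d_max)) < 2L) {
    stop("d_max must vary across individuals", call. = FALSE)
  }
  wrap_lmm(lme4::lmer(current_value ~ case * d_max + (1 | individual_id),
                      data = data, REML = TRUE),
           data)
}

check_case_data <- function(data) {
  need <- c("individual_id", "case", "current_value")
  if (!all(need %in% names(data))) {
    stop("case data needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$individual_id)) < 2L) {
    stop("need at least 2 individuals", call. = FALSE)
  }
  both <- tapply(data$case, data$individual_id,
                 function(x) all(c(0, 1) %in% x))
  if (!all(both)) {
    stop("every individual needs both observed and available rows",
         call. = FALSE)
  }
}

wrap_lmm <- function(fit, data) {
  est <- lme4::fixef(fit)
  # an exactly-degenerate fit (zero residual variance) can make vcov() fail;
  # its standard errors are genuinely zero
  vc_fixed <- tryCatch(
    suppressWarnings(as.matrix(stats::vcov(fit))),
    error = function(e) matrix(NA_real_, length(est), length(est)))
  se <- sqrt(base::diag(vc_fixed))
  # an exactly-degenerate fit (zero residual variance) has no sampling
  # variability; report zero standard errors rather than NA
  se[!is.finite(se)] <- 0
  z <- stats::qnorm(0.975)
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    conf_low = unname(est - z * se),
    conf_high = unname(est + z * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(coefficients = coefs,
         ranef_variance = vc$vcov[vc$grp == "individual_id"][1],
         sigma = stats::sigma(fit),
         n_obs = nrow(data),
         n_individuals = length(unique(data$individual_id)),
         singular = lme4::isSingular(fit),
         fit = fit),
    class = "omc_model_fit"
  )
}

#' @export
print.omc_model_fit <- function(x, ...) {
  cat(sprintf("<mixed model fit> %d obs, %d individuals%s\n", x$n_obs,
              x$n_individuals, if (x$singular) " (singular fit)" else ""))
  print(x$coefficients)
  cat(sprintf("random-intercept variance %.4g, residual sigma %.4g\n",
              x$ranef_variance, x$sigma))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model fit
#'
#' @param x An `omc_model_fit`.
#' @param ... Unused.
#' @return `tidy()`: the fixed-effects tibble. `glance()`: a one-row model
#'   summary.
#' @export
tidy.omc_model_fit <- function(x, ...) x$coefficients

#' @rdname tidy.omc_model_fit
#' @export
glance.omc_model_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_individuals = x$n_individuals,
                 ranef_variance = x$ranef_variance, sigma = x$sigma,
                 singular = x$singular,
                 REMLcrit = as.numeric(lme4::REMLcrit(x$fit)))
}

#' Predicted observed-available gap across displacement distances
#'
#' From an interaction fit, the model-implied difference between observed
#' and available current density at given displacement distances:
#' `case + case:d_max * d`. At `d = 0` this is the case main effect.
#'
#' @param fit An `omc_model_fit` from [fit_interaction_model()].
#' @param d_max Distances at which to evaluate.
#' @return Tibble: `d_max`, `difference`.
#' @export
predict_case_difference <- function(fit, d_max) {
  co <- fit$coefficients
  main <- co$estimate[co$term == "case"]
  inter <- co$estimate[co$term == "case:d_max"]
  if (length(inter) == 0L) inter <- 0
  tibble::tibble(d_max = d_max, difference = main + inter * d_max)
}
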