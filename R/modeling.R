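#' Mixed-model specification
#'
#' The three model families of the analysis, all with word frequency as a
#' treatment-coded categorical fixed effect (high-frequency reference, so
#' the coefficient estimates low minus high: positive is the canonical
#' frequency effect) and crossed random intercepts for subjects and items
#' (no slopes):
#' \describe{
#'   \item{`lmm_identity`}{linear mixed model on raw durations (ms).}
#'   \item{`lmm_log`}{linear mixed model on natural-log durations.}
#'   \item{`glmm_gamma`}{generalized linear mixed model with a Gamma
#'     response and identity link, i.e. skewed durations modeled without
#'     transformation.}
#' }
#'
#' @param family one of `"lmm_identity"`, `"lmm_log"`, `"glmm_gamma"`.
#' @param significance_alpha two-sided Wald significance level.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("lmm_identity", "lmm_log", "glmm_gamma"),
                       significance_alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(significance_alpha > 0, significance_alpha < 1)
  structure(list(family = family, significance_alpha = significance_alpha),
            class = "model_spec")
}

#' Fit one frequency-effect mixed model
#'
#' Fits the requested family on the observation table and reports the
#' frequency-effect coefficient, its Wald statistic and two-sided normal
#' p-value, a convergence flag, and the effect back-transformed to a
#' comparable millisecond scale (see [back_transform()]).  Optimizer
#' failures, convergence warnings, and singular (non-positive-definite)
#' variance estimates are recorded in `converged`, never raised; genuine
#' input violations (a single condition, fewer than two levels of a
#' random factor) are errors.
#'
#' The Gamma model is fitted with `lme4::glmer(..., nAGQ = 0)`; the
#' contract is the estimate/SE/convergence flag, not the optimizer.
#'
#' @param obs observation table from [extract_sfd()].
#' @param spec a [model_spec()].
#' @return an object of class `model_result` with fields `family`,
#'   `beta_freq`, `se_beta`, `stat`, `p_value`, `significant`,
#'   `converged`, `n_obs`, `intercept`, `effect_ms`.
#' @export
fit_model <- function(obs, spec) {
  stopifnot(inherits(spec, "model_spec"))
  obs <- as.data.table(obs)
  if (length(unique(obs$condition)) < 2L)
    stop("both frequency conditions must be present")
  if (length(unique(obs$subject_id)) < 2L || length(unique(obs$item_id)) < 2L)
    stop("need at least 2 levels of each random factor (subjects, items)")
  d <- data.frame(
    y = obs$sfd_ms,
    condition = factor(obs$condition, levels = c("high", "low")),
    subject = factor(obs$subject_id),
    item = factor(obs$item_id))

  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      switch(spec$family,
             lmm_identity = lme4::lmer(
               y ~ condition + (1 | subject) + (1 | item), data = d,
               control = lme4::lmerControl(calc.derivs = FALSE)),
             lmm_log = lme4::lmer(
               log(y) ~ condition + (1 | subject) + (1 | item), data = d,
               control = lme4::lmerControl(calc.derivs = FALSE)),
             glmm_gamma = lme4::glmer(
               y ~ condition + (1 | subject) + (1 | item), data = d,
               family = stats::Gamma(link = "identity"), nAGQ = 0L)),
      error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  res <- list(family = spec$family, beta_freq = NA_real_, se_beta = NA_real_,
              stat = NA_real_, p_value = NA_real_, significant = FALSE,
              converged = FALSE, n_obs = nrow(d), intercept = NA_real_,
              effect_ms = NA_real_, alpha = spec$significance_alpha,
              messages = warns)
  if (!inherits(fit, "condition")) {
    fe <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    res$intercept <- unname(fe[["(Intercept)"]])
    res$beta_freq <- unname(fe[["conditionlow"]])
    res$se_beta <- sqrt(vc["conditionlow", "conditionlow"])
    res$stat <- res$beta_freq / res$se_beta
    res$p_value <- 2 * pnorm(-abs(res$stat))
    conv_warn <- any(grepl("converge|Hessian|unable to evaluate", warns,
                           ignore.case = TRUE))
    singular <- isTRUE(lme4::isSingular(fit, tol = 1e-5))
    opt_ok <- is.null(fit@optinfo$conv$lme4$code) ||
      fit@optinfo$conv$lme4$code >= 0
    res$converged <- !conv_warn && !singular && opt_ok &&
      is.finite(res$beta_freq) && is.finite(res$se_beta) && res$se_beta > 0
  } else {
    res$messages <- c(warns, conditionMessage(fit))
  }
  res$significant <- isTRUE(res$converged) && !is.na(res$p_value) &&
    res$p_value < spec$significance_alpha
  res <- structure(res, class = "model_result")
  res$effect_ms <- back_transform(res)
  res
}

#' Back-transform a frequency-effect coefficient to milliseconds
#'
#' Identity-scale families report their coefficient unchanged; the log
#' model's effect is evaluated at the fixed-effect scale,
#' `exp(intercept + beta) - exp(intercept)` (no variance correction, a
#' stated simplification).  Undefined (`NA`) for non-converged fits.
#'
#' @param result a `model_result` from [fit_model()].
#' @return effect size in ms, or `NA` if not converged.
#' @export
back_transform <- function(result) {
  stopifnot(inherits(result, "model_result"))
  if (!isTRUE(result$converged)) return(NA_real_)
  switch(result$family,
         lmm_identity = result$beta_freq,
         glmm_gamma = result$beta_freq,
         lmm_log = exp(result$intercept + result$beta_freq) - exp(result$intercept))
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf(paste0("<model_result> %s: beta = %.3f (SE %.3f), z = %.2f, ",
                     "p = %.4g, effect = %.2f ms, converged = %s\n"),
              x$family, x$beta_freq, x$se_beta, x$stat, x$p_value,
              x$effect_ms, x$converged))
  invisible(x)
}
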