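# S3 methods for ward_glmm fits

#' @export
print.ward_glmm <- function(x, ...) {
  cat("Random-intercept binomial GLMM (adaptive Gauss-Hermite,",
      x$nAGQ, "nodes)\n")
  cat("  ", paste(deparse(x$formula), collapse = " "), "\n")
  cat(sprintf("  n = %d observations, %d groups; logLik = %.3f\n",
              x$n_obs, x$n_groups, x$loglik))
  cat(sprintf("  random-intercept SD = %.4f%s\n", x$sigma_b,
              if (x$boundary) " (boundary)" else ""))
  print(round(x$beta, 4))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
summary.ward_glmm <- function(object, ...) {
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p_value,
               `2.5 %` = object$ci[, "lower"],
               `97.5 %` = object$ci[, "upper"])
  structure(list(fit = object, coefficients = tab),
            class = "summary.ward_glmm")
}

#' @export
print.summary.ward_glmm <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Random-intercept binomial GLMM (adaptive Gauss-Hermite,",
      f$nAGQ, "nodes)\n")
  cat("  ", paste(deparse(f$formula), collapse = " "), "\n\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nRandom intercept (per %s): SD = %.4f%s\n", f$group_var,
              f$sigma_b, if (f$boundary) " (boundary)" else ""))
  cat(sprintf("logLik = %.4f, deviance = %.4f, n = %d, groups = %d\n",
              f$loglik, f$deviance, f$n_obs, f$n_groups))
  if (!f$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.ward_glmm <- function(object, ...) object$beta

#' @export
vcov.ward_glmm <- function(object, ...) object$vcov

#' @export
logLik.ward_glmm <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 1L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
confint.ward_glmm <- function(object, parm, level = 0.95, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.ward_glmm <- function(object, ...) {
  plogis(drop(object$X %*% object$beta) +
           object$ranef[as.character(object$group)])
}

#' Predict from a ward_glmm
#'
#' @param object a `ward_glmm`.
#' @param newdata optional data.frame; the fitted design is reused when
#'   omitted.
#' @param type `"link"` (log-odds) or `"response"` (probability).
#' @param re `"conditional"` adds the estimated group intercept (zero for
#'   unseen groups); `"population"` sets it to zero.
#' @param ... unused.
#' @export
predict.ward_glmm <- function(object, newdata = NULL,
                              type = c("link", "response"),
                              re = c("conditional", "population"), ...) {
  type <- match.arg(type)
  re <- match.arg(re)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$beta)
    g <- as.character(object$group)
  } else {
    tt <- delete.response(object$terms)
    mf <- model.frame(tt, newdata, xlev = object$xlevels)
    X <- model.matrix(tt, mf)
    eta <- drop(X %*% object$beta[colnames(X)])
    g <- as.character(newdata[[object$group_var]])
  }
  if (re == "conditional") {
    bi <- object$ranef[g]
    bi[is.na(bi)] <- 0
    eta <- eta + unname(bi)
  }
  if (type == "response") plogis(eta) else eta
}

#' @export
residuals.ward_glmm <- function(object,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  y <- object$y
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu)))
  )
}

#' @export
simulate.ward_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta0 <- drop(object$X %*% object$beta)
  gi <- as.integer(object$group)
  out <- as.data.frame(replicate(nsim, {
    b <- rnorm(object$n_groups, 0, object$sigma_b)
    rbinom(object$n_obs, 1L, plogis(eta0 + b[gi]))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ward_glmm <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  stats::qqnorm(x$ranef, main = "Random intercepts", ...)
  stats::qqline(x$ranef)
  mu <- fitted(x)
  plot(mu, residuals(x, "pearson"), xlab = "fitted probability",
       ylab = "Pearson residual", main = "Residuals")
  abline(h = 0, lty = 2)
  invisible(x)
}

#' Likelihood-ratio (ANOVA) test of nested GLMMs
#'
#' Compares a nested and a full fit by the chi-square likelihood-ratio test,
#' mirroring the ANOVA gating used when deciding whether an added term earns
#' its complexity. Both fits must use exactly the same rows; the nested
#' model's fixed terms must be a subset of the full model's. If the full
#' model's likelihood falls below the nested one's (a failed inner
#' optimization), the full model is refitted from the nested solution before
#' testing.
#'
#' @param nested,full `ward_glmm` fits.
#' @param alpha significance level for the keep/drop verdict (default 0.05).
#' @return Object of class `ward_lrt`: `delta_deviance`, `delta_df`,
#'   `p_value`, `keep`, plus the two deviances.
#' @export
lrt <- function(nested, full, alpha = 0.05) {
  stopifnot(inherits(nested, "ward_glmm"), inherits(full, "ward_glmm"))
  tn <- colnames(nested$X); tf <- colnames(full$X)
  if (length(tn) > length(tf)) {
    tmp <- nested; nested <- full; full <- tmp
    tn <- colnames(nested$X); tf <- colnames(full$X)
  }
  if (!all(tn %in% tf))
    stop("models are not nested: ",
         paste(setdiff(tn, tf), collapse = ", "), " missing from full model")
  if (nested$n_obs != full$n_obs ||
      !isTRUE(all.equal(sort(nested$y), sort(full$y))) ||
      !identical(as.character(sort(unique(nested$group))),
                 as.character(sort(unique(full$group)))))
    stop("fits use different rows; refit both on the common row set")
  dd <- nested$deviance - full$deviance
  if (dd < -1e-6) {
    # full optimum worse than the nested one: restart from the nested fit
    start <- setNames(numeric(length(tf)), tf)
    start[tn] <- nested$beta
    refit <- fit_glmm(full$formula, full$model_data, nAGQ = full$nAGQ,
                      start = c(start, nested$log_sigma))
    if (refit$loglik > full$loglik) full <- refit
    dd <- nested$deviance - full$deviance
  }
  dd <- max(dd, 0)
  ddf <- length(tf) - length(tn)
  p <- if (ddf == 0L) 1 else pchisq(dd, ddf, lower.tail = FALSE)
  structure(list(delta_deviance = dd, delta_df = ddf, p_value = p,
                 keep = p < alpha, alpha = alpha,
                 deviance_nested = nested$deviance,
                 deviance_full = full$deviance),
            class = "ward_lrt")
}

#' @export
print.ward_lrt <- function(x, ...) {
  cat(sprintf(
    "LRT: delta deviance = %.4f on %d df, p = %s -> %s (alpha = %g)\n",
    x$delta_deviance, x$delta_df, format.pval(x$p_value, digits = 3),
    if (x$keep) "keep" else "drop", x$alpha))
  invisible(x)
}

#' @export
anova.ward_glmm <- function(object, ..., alpha = 0.05) {
  others <- Filter(function(o) inherits(o, "ward_glmm"), list(...))
  if (length(others) != 1L)
    stop("anova() for ward_glmm compares exactly two nested fits")
  lrt(object, others[[1L]], alpha = alpha)
}

#' Odds ratio for a fitted term
#'
#' Exponentiates a coefficient and its Wald confidence bounds: the
#' multiplicative change in the odds of the outcome per unit (for
#' standardized features, per SD) increase of the term.
#'
#' @param fit a `ward_glmm`.
#' @param term coefficient name as in `coef(fit)`.
#' @return Named numeric: `or`, `lower`, `upper`.
#' @examples
#' # exp(0.68) ~ 1.97: odds almost double per SD
#' @export
odds_ratio <- function(fit, term) {
  if (!term %in% names(fit$beta)) stop("unknown term: ", term)
  c(or = unname(exp(fit$beta[term])),
    lower = unname(exp(fit$ci[term, "lower"])),
    upper = unname(exp(fit$ci[term, "upper"])))
}
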