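# Random-intercept binomial GLMM fitted by maximizing the marginal
# likelihood, with the per-group integral over the Gaussian intercept
# approximated by adaptive Gauss-Hermite quadrature (default 25 nodes;
# 1 node is the Laplace approximation). Estimation is fully deterministic:
# fixed effects start at the plain logistic fit, the intercept SD at 1, and
# a quasi-Newton search runs on (beta, log sigma_b).

.gh_cache <- new.env(parent = emptyenv())

# Gauss-Hermite nodes/weights for weight exp(-x^2) (Golub-Welsch on the
# symmetric tridiagonal Jacobi matrix; deterministic)
gh_rule <- function(K) {
  key <- as.character(K)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  if (K == 1L) {
    r <- list(x = 0, w = sqrt(pi))
  } else {
    J <- matrix(0, K, K)
    off <- sqrt(seq_len(K - 1) / 2)
    J[cbind(1:(K - 1), 2:K)] <- off
    J[cbind(2:K, 1:(K - 1))] <- off
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    r <- list(x = e$values[ord],
              w = sqrt(pi) * (e$vectors[1, ord])^2)
  }
  .gh_cache[[key]] <- r
  r
}

# parse "outcome ~ fixed + (1 | group)" into fixed formula + grouping factor
.parse_glmm_formula <- function(formula) {
  txt <- paste(deparse(formula), collapse = " ")
  m <- regmatches(txt, regexpr("\\(\\s*1\\s*\\|\\s*[^)]+\\)", txt))
  if (!length(m))
    stop("formula must contain a random-intercept term (1 | group)")
  gvar <- trimws(sub("^\\(\\s*1\\s*\\|\\s*", "", sub("\\)$", "", m)))
  fixed_txt <- gsub("\\+?\\s*\\(\\s*1\\s*\\|\\s*[^)]+\\)", "", txt)
  fixed_txt <- sub("~\\s*\\+", "~", fixed_txt)
  fixed_txt <- sub("~\\s*$", "~ 1", fixed_txt)
  list(fixed = as.formula(fixed_txt), group = gvar)
}

#' Fit a random-intercept binomial GLMM
#'
#' Fits `outcome ~ fixed terms + (1 | group)` with a logit link by direct
#' maximization of the marginal likelihood; the intractable per-group
#' integral over the Gaussian random intercept is evaluated with adaptive
#' Gauss-Hermite quadrature centred at each group's conditional mode.
#' Inference on the fixed effects is Wald-based (matching the conventions of
#' the usual mixed-model summaries); the 95% CI is `estimate +/- 1.96 * SE`.
#'
#' @param formula e.g. `verbal ~ z_sound_sd + time_group + maj_room_group +
#'   (1 | patient_id)`. Exactly one random-intercept term is supported; an
#'   intercept is always included.
#' @param data data.frame; rows with missing values in any used variable are
#'   dropped listwise.
#' @param nAGQ number of quadrature nodes (default 25; 1 = Laplace).
#' @param start optional `c(beta, log_sigma)` start values.
#' @return Object of class `ward_glmm` with methods `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `logLik`, `fitted`, `predict`, `residuals`,
#'   `simulate`, `plot` and `anova` (likelihood-ratio test, see [lrt()]).
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rep(1:10, each = 20), x = rnorm(200))
#' d$y <- rbinom(200, 1, plogis(0.5 * d$x + rep(rnorm(10), each = 20)))
#' fit <- fit_glmm(y ~ x + (1 | g), d)
#' summary(fit)
#' @export
fit_glmm <- function(formula, data, nAGQ = 25L, start = NULL) {
  pf <- .parse_glmm_formula(formula)
  vars <- unique(c(all.vars(pf$fixed), pf$group))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variables not found in data: ", paste(miss, collapse = ", "))
  dat <- as.data.frame(data)[, vars, drop = FALSE]
  keep <- complete.cases(dat)
  dat <- droplevels(dat[keep, , drop = FALSE])

  tt <- terms(pf$fixed, data = dat)
  if (attr(tt, "intercept") != 1L) stop("the intercept cannot be removed")
  mf <- model.frame(tt, dat)
  y <- model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; the model cannot be fitted")
  X <- model.matrix(tt, mf)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design is rank deficient: ",
         paste(colnames(X), collapse = ", "))
  grp <- factor(dat[[pf$group]])
  if (nlevels(grp) < 2L) stop("need at least 2 groups for a random intercept")

  ord <- order(as.integer(grp))
  X <- X[ord, , drop = FALSE]
  y <- as.numeric(y[ord])
  grp <- grp[ord]
  grp_start <- c(0L, cumsum(tabulate(as.integer(grp), nlevels(grp))))
  p <- ncol(X)
  gh <- gh_rule(nAGQ)

  nll <- function(theta) {
    ls <- theta[p + 1L]
    pen <- 0
    if (ls < -8) { pen <- (ls + 8)^2 * 100; theta[p + 1L] <- -8 }
    if (ls > 4) { pen <- (ls - 4)^2 * 100; theta[p + 1L] <- 4 }
    .agq_nll(theta, X, y, grp_start, gh$x, gh$w) + pen
  }

  if (is.null(start)) {
    g0 <- suppressWarnings(glm.fit(X, y, family = binomial()))
    beta0 <- g0$coefficients
    beta0[is.na(beta0)] <- 0
    start <- c(beta0, 0)
  }
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt <- optim(opt$par, nll, method = "BFGS",  # polish from the optimum
               control = list(maxit = 1000, reltol = 1e-14))
  theta <- opt$par
  boundary <- theta[p + 1L] <= -7.9
  converged <- opt$convergence == 0L && max(abs(theta[1:p])) < 15

  H <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V) && !is.null(H))
    V <- tryCatch({
      Vb <- solve(H[1:p, 1:p, drop = FALSE])
      V <- matrix(NA_real_, p + 1L, p + 1L)
      V[1:p, 1:p] <- Vb
      V
    }, error = function(e) NULL)
  if (is.null(V)) {
    converged <- FALSE
    V <- matrix(NA_real_, p + 1L, p + 1L)
  }
  se <- sqrt(pmax(diag(V)[1:p], 0))
  beta <- setNames(theta[1:p], colnames(X))
  se <- setNames(se, colnames(X))
  zval <- beta / se
  loglik <- -nll(theta)

  structure(list(
    call = match.call(),
    formula = formula,
    fixed_formula = pf$fixed,
    terms = tt,
    xlevels = stats::.getXlevels(tt, mf),
    group_var = pf$group,
    beta = beta,
    se = se,
    z = zval,
    p_value = 2 * pnorm(-abs(zval)),
    ci = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
    vcov = V[1:p, 1:p, drop = FALSE],
    sigma_b = exp(theta[p + 1L]),
    log_sigma = theta[p + 1L],
    loglik = loglik,
    deviance = -2 * loglik,
    n_obs = length(y),
    n_groups = nlevels(grp),
    nAGQ = as.integer(nAGQ),
    converged = converged,
    boundary = boundary,
    X = X, y = y, group = grp, model_data = dat,
    ranef = setNames(as.numeric(.agq_modes(theta, X, y, grp_start)),
                     levels(grp))
  ), class = "ward_glmm")
}

# marginal log-likelihood at given parameters (used by tests against the
# dense-integration oracle)
glmm_loglik_at <- function(fit, beta = fit$beta, log_sigma = fit$log_sigma,
                           nAGQ = fit$nAGQ) {
  grp_start <- c(0L, cumsum(tabulate(as.integer(fit$group),
                                     nlevels(fit$group))))
  gh <- gh_rule(nAGQ)
  -.agq_nll(c(beta, log_sigma), fit$X, fit$y, grp_start, gh$x, gh$w)
}
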