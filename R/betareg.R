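#' Prepare a bounded response for beta regression
#'
#' Response indices on `[-1, 1]` cannot enter a beta likelihood directly:
#' the boundary cases (-1 and +1, species absent from one treatment) are
#' removed, and the remainder is mapped by `y -> (y + 1) / 2` onto the open
#' unit interval.
#'
#' @param r_values numeric vector in `[-1, 1]`, NA = undefined.
#' @param epsilon tolerance for detecting boundary values.
#' @param min_cases minimum remaining cases below which the preparation is
#'   refused.
#' @return list: `y` (transformed responses), `keep` (logical index into the
#'   input), `n_dropped_boundary`, `n_dropped_undefined`.
#' @export
prepare_beta_response <- function(r_values, epsilon = 1e-8,
                                  min_cases = 10L) {
  defined <- !is.na(r_values)
  boundary <- defined & (abs(abs(r_values) - 1) <= epsilon)
  keep <- defined & !boundary
  if (sum(keep) < min_cases)
    stop(sprintf(
      "beta regression refused: only %d usable case(s) after dropping %d undefined and %d boundary value(s); need at least %d",
      sum(keep), sum(!defined), sum(boundary), min_cases))
  list(y = (r_values[keep] + 1) / 2, keep = keep,
       n_dropped_boundary = sum(boundary),
       n_dropped_undefined = sum(!defined))
}

# Negative log-likelihood and analytic gradient of the mean/precision
# parameterized beta regression: logit(mu) = b0 + b1 x, shapes (mu*phi,
# (1-mu)*phi), phi on the log scale.
beta_nll <- function(theta, x, y) {
  eta <- theta[1] + theta[2] * x
  mu <- plogis(eta)
  phi <- exp(theta[3])
  -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

beta_ngr <- function(theta, x, y) {
  eta <- theta[1] + theta[2] * x
  mu <- plogis(eta)
  phi <- exp(theta[3])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dl_deta <- phi * (ystar - mustar) * mu * (1 - mu)
  dl_dphi <- digamma(phi) - mu * digamma(mu * phi) -
    (1 - mu) * digamma((1 - mu) * phi) + mu * log(y) + (1 - mu) * log1p(-y)
  -c(sum(dl_deta), sum(dl_deta * x), phi * sum(dl_dphi))
}

#' Beta regression by maximum likelihood
#'
#' Fits `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with `logit(mu_i) = b0 +
#' b1 x_i`, maximizing the likelihood over `(b0, b1, log phi)` by BFGS with
#' analytic gradients.  Standard errors come from the inverse observed
#' information at the optimum; the slope is tested by a two-sided Wald z
#' test; the pseudo R-squared is the squared Pearson correlation between
#' `logit(y)` and the fitted linear predictor.
#'
#' @param x numeric predictor with nonzero variance.
#' @param y responses strictly inside (0, 1).
#' @param min_cases minimum number of observations required.
#' @return object of class `beta_reg` with `coefficients` (intercept,
#'   slope), `phi`, `se`, `z`, `p_value`, `pseudo_r2`, `loglik`, `n_used`,
#'   plus the data and optimizer diagnostics.
#' @export
beta_reg <- function(x, y, min_cases = 10L) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  if (length(y) < min_cases)
    stop("beta regression needs at least ", min_cases, " cases")
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly inside (0, 1)")
  if (!all(is.finite(x)) || sd(x) == 0)
    stop("predictor must be finite with nonzero variance")

  # start: logit-scale least squares, phi from residual variance
  z <- qlogis(y)
  b <- coef(lm(z ~ x))
  mu0 <- plogis(b[1] + b[2] * x)
  v <- mean((y - mu0)^2)
  phi0 <- max(2, mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1)
  theta0 <- unname(c(b[1], b[2], log(phi0)))

  fit <- optim(theta0, beta_nll, beta_ngr, x = x, y = y, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12), hessian = TRUE)
  if (fit$convergence != 0)
    stop(sprintf(
      "beta regression did not converge (code %d) at theta = (%s), |grad| = %.3g",
      fit$convergence, paste(signif(fit$par, 6), collapse = ", "),
      sqrt(sum(beta_ngr(fit$par, x, y)^2))))

  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 3) else
    unname(sqrt(pmax(diag(vc), 0)))
  eta <- fit$par[1] + fit$par[2] * x
  zstat <- fit$par[2] / se[2]
  structure(list(
    coefficients = c(intercept = unname(fit$par[1]),
                     slope = unname(fit$par[2])),
    phi = unname(exp(fit$par[3])),
    se = c(intercept = se[1], slope = se[2]),
    z = unname(zstat),
    p_value = unname(2 * pnorm(-abs(zstat))),
    pseudo_r2 = unname(cor(qlogis(y), eta)^2),
    loglik = -fit$value,
    n_used = length(y),
    x = x, y = y, vcov = vc
  ), class = "beta_reg")
}

#' @export
coef.beta_reg <- function(object, ...) object$coefficients

#' @export
logLik.beta_reg <- function(object, ...) {
  structure(object$loglik, df = 3, nobs = object$n_used, class = "logLik")
}

#' @rdname beta_reg
#' @param object,newx a fitted `beta_reg` and predictor values.
#' @param type `"response"` (mean scale) or `"link"`.
#' @param ... unused.
#' @export
predict.beta_reg <- function(object, newx = object$x,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- object$coefficients[1] + object$coefficients[2] * newx
  if (type == "link") unname(eta) else unname(plogis(eta))
}

#' @export
simulate.beta_reg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  replicate(nsim, rbeta(length(mu), mu * object$phi, (1 - mu) * object$phi),
            simplify = FALSE)
}

#' @export
residuals.beta_reg <- function(object, ...) {
  mu <- predict(object)
  (object$y - mu) / sqrt(mu * (1 - mu) / (1 + object$phi))
}

#' @export
print.beta_reg <- function(x, ...) {
  cat("Beta regression (logit link, ML)\n")
  cat(sprintf("  logit(mu) = %.4g %+.4g x,  phi = %.4g\n",
              x$coefficients[1], x$coefficients[2], x$phi))
  cat(sprintf("  slope z = %.3f, p = %.4g, pseudo-R2 = %.3f, n = %d\n",
              x$z, x$p_value, x$pseudo_r2, x$n_used))
  invisible(x)
}

#' @export
summary.beta_reg <- function(object, ...) {
  tab <- cbind(Estimate = c(object$coefficients, phi = object$phi),
               `Std. Error` = c(object$se, NA),
               `z value` = c(object$coefficients / object$se, NA),
               `Pr(>|z|)` = c(2 * pnorm(-abs(object$coefficients /
                                               object$se)), NA))
  structure(list(coefficients = tab, pseudo_r2 = object$pseudo_r2,
                 loglik = object$loglik, n = object$n_used),
            class = "summary.beta_reg")
}

#' @export
print.summary.beta_reg <- function(x, ...) {
  printCoefmat(x$coefficients, na.print = "")
  cat(sprintf("log-likelihood %.4f, pseudo-R2 %.3f, n = %d\n",
              x$loglik, x$pseudo_r2, x$n))
  invisible(x)
}

# the species-level predictor battery: GP and GR at all six incubation
# conditions, the two response indices, niche breadth, and occupation and
# proportion at each constant temperature (25 predictors).
species_predictors <- function() {
  sfx <- condition_suffix(GERM_CONDITIONS)
  c(paste0("gp_", sfx), paste0("gr_", sfx), "r_alt", "r_wc", "btn",
    paste0("o_", CONSTANT_TEMPS), paste0("p_", CONSTANT_TEMPS))
}

#' Species-level beta regressions of the fertilization response
#'
#' Regresses the transformed fertilization response `(R_f + 1) / 2`
#' (boundary species removed) on each germination index in turn.  Species
#' with an undefined predictor are dropped per fit; per-fit failures are
#' recorded and do not abort the battery.
#'
#' @param responses output of [abundance_response()].
#' @param profiles a `germ_profiles` data.frame.
#' @param config a [germ_config()].
#' @return data.frame, one row per predictor: coefficients, `phi`, standard
#'   errors, `z_slope`, `p_slope`, `pseudo_r2`, `n_used`,
#'   `n_dropped_boundary`, and `error` (NA when the fit succeeded).
#' @export
fit_species_regressions <- function(responses, profiles,
                                    config = germ_config()) {
  stopifnot(all(responses$species_id %in% profiles$species_id))
  prep <- prepare_beta_response(responses$r_f, config$boundary_epsilon,
                                config$min_beta_cases)
  ids <- responses$species_id[prep$keep]
  y <- prep$y
  pred_rows <- match(ids, profiles$species_id)

  rows <- lapply(species_predictors(), function(v) {
    out <- data.frame(predictor = v, intercept = NA_real_, slope = NA_real_,
                      phi = NA_real_, se_intercept = NA_real_,
                      se_slope = NA_real_, z_slope = NA_real_,
                      p_slope = NA_real_, pseudo_r2 = NA_real_,
                      n_used = NA_integer_,
                      n_dropped_boundary = prep$n_dropped_boundary,
                      error = NA_character_, stringsAsFactors = FALSE)
    x <- profiles[[v]][pred_rows]
    ok <- !is.na(x)
    f <- tryCatch(beta_reg(x[ok], y[ok], min_cases = config$min_beta_cases),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      out$error <- f
    } else {
      out$intercept <- f$coefficients[1]; out$slope <- f$coefficients[2]
      out$phi <- f$phi
      out$se_intercept <- f$se[1]; out$se_slope <- f$se[2]
      out$z_slope <- f$z; out$p_slope <- f$p_value
      out$pseudo_r2 <- f$pseudo_r2; out$n_used <- f$n_used
    }
    out
  })
  do.call(rbind, rows)
}
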