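#' Gaussian linear mixed model with a block random intercept
#'
#' Fits `y = X beta + b_block + e`, `b ~ N(0, sigma2_block)`,
#' `e ~ N(0, sigma2_resid)`, by maximum likelihood (not REML, so
#' likelihood-ratio tests between nested fixed-effect structures are
#' valid).  For a given variance ratio `lambda = sigma2_block /
#' sigma2_resid` the GLS coefficients and the profiled log-likelihood are
#' closed-form; `lambda` is optimized by a one-dimensional search on the
#' log scale, with the boundary `lambda = 0` (ordinary least squares)
#' always considered.
#'
#' @param formula fixed-effects formula, e.g. `y ~ temperature * n_level`.
#' @param data data.frame holding the response, fixed factors and block
#'   labels.
#' @param block name of the block column (default `"block_id"`).
#' @return object of class `lmm_block`: `coefficients`, `sigma2_block`,
#'   `sigma2_resid`, `loglik` (ML), `n_obs`, `n_fixed` (fixed-effect
#'   parameter count), `formula`, `fitted`, `data`.
#' @export
lmm_block <- function(formula, data, block = "block_id") {
  stopifnot(block %in% names(data))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  ok <- stats::complete.cases(mf) & !is.na(data[[block]])
  mf <- mf[ok, , drop = FALSE]
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  g <- factor(data[[block]][ok])
  Z <- model.matrix(~ g - 1)
  n <- length(y)

  profiled <- function(log_lambda) {
    lambda <- exp(log_lambda)
    V <- diag(n) + lambda * tcrossprod(Z)
    cV <- chol(V)
    Xw <- backsolve(cV, X, transpose = TRUE)
    yw <- backsolve(cV, y, transpose = TRUE)
    fit <- lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ll <- -n / 2 * log(2 * pi * sigma2) - sum(log(diag(cV))) - n / 2
    list(ll = ll, beta = fit$coefficients, sigma2 = sigma2, lambda = lambda)
  }

  opt <- optimize(function(l) profiled(l)$ll, c(-15, 15), maximum = TRUE,
                  tol = 1e-9)
  best <- profiled(opt$maximum)
  at0 <- profiled(-Inf)   # lambda = 0: ordinary least squares
  if (at0$ll >= best$ll) { best <- at0; best$lambda <- 0 }

  structure(list(
    coefficients = best$beta,
    sigma2_block = best$lambda * best$sigma2,
    sigma2_resid = best$sigma2,
    loglik = best$ll,
    n_obs = n,
    n_fixed = ncol(X),
    formula = formula,
    fitted = drop(X %*% best$beta),
    residuals = y - drop(X %*% best$beta),
    block = g,
    data = data
  ), class = "lmm_block")
}

#' @export
coef.lmm_block <- function(object, ...) object$coefficients

#' @export
logLik.lmm_block <- function(object, ...) {
  structure(object$loglik, df = object$n_fixed + 2, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.lmm_block <- function(object, ...) object$fitted

#' @export
residuals.lmm_block <- function(object, ...) object$residuals

#' @export
print.lmm_block <- function(x, ...) {
  cat("Linear mixed model (block random intercept, ML)\n")
  cat("  fixed:", deparse(x$formula), "\n")
  cat(sprintf("  sigma2_block = %.4g, sigma2_resid = %.4g, logLik = %.3f, n = %d\n",
              x$sigma2_block, x$sigma2_resid, x$loglik, x$n_obs))
  invisible(x)
}

#' @export
summary.lmm_block <- function(object, ...) {
  cat("Fixed effects:\n")
  print(object$coefficients)
  print(object)
  invisible(object)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' `chi2 = 2 (l_full - l_reduced)` (clipped at zero) on as many degrees of
#' freedom as the fixed-effect parameter-count difference, referred to the
#' chi-squared upper tail.  Both fits must be ML fits of the same data.
#'
#' @param full,reduced `lmm_block` fits, `reduced` nested in `full`.
#' @return data.frame: `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_block"), inherits(reduced, "lmm_block"))
  if (full$n_obs != reduced$n_obs)
    stop("fits use different numbers of observations")
  df <- full$n_fixed - reduced$n_fixed
  if (df < 0) stop("'full' has fewer fixed-effect parameters than 'reduced'")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  data.frame(chi2 = chi2, df = df, p = p)
}

#' Tukey HSD comparisons with compact letter display
#'
#' All pairwise comparisons of group means with the studentized-range
#' statistic (Tukey-Kramer for unequal group sizes), using the pooled
#' within-group residual variance.  Levels that do not differ at the
#' configured alpha share a letter.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of treatment levels, each with at
#'   least 2 observations.
#' @param alpha family-wise significance level.
#' @param resid_var,resid_df optional error variance and its degrees of
#'   freedom from a surrounding model fit; defaults to the one-way pooled
#'   within-group variance.
#' @return list: `letters` (named character, one entry per level), `means`,
#'   `p_values` (matrix of pairwise Tukey p-values).
#' @export
tukey_groups <- function(values, groups, alpha = 0.05,
                         resid_var = NULL, resid_df = NULL) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  ni <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 levels")
  if (any(ni < 2)) stop("every level needs at least 2 observations, level ",
                        names(ni)[ni < 2][1], " has ", min(ni))
  k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  if (is.null(resid_var)) {
    resid_df <- length(values) - k
    resid_var <- sum(tapply(values, groups, function(v)
      sum((v - mean(v))^2))) / resid_df
  }
  pmat <- matrix(1, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se <- sqrt(resid_var / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- if (se > 0) abs(means[i] - means[j]) / se else
      if (means[i] == means[j]) 0 else Inf
    pmat[i, j] <- pmat[j, i] <- ptukey(q, k, resid_df, lower.tail = FALSE)
  }
  sig <- pmat < alpha
  list(letters = compact_letters(sig, order(-means)), means = means,
       p_values = pmat)
}

# Insert-and-absorb compact letter display: maintain letter sets such that
# every non-significant pair shares a set and no significant pair does.
compact_letters <- function(sig, ordering = seq_len(nrow(sig))) {
  lv <- rownames(sig)
  k <- length(lv)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        sets[[length(sets) + 1L]] <- setdiff(sets[[s]], i)
        sets[[s]] <- setdiff(sets[[s]], j)
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(sets[[a]] %in% sets[[b]]) &&
          (length(sets[[a]]) < length(sets[[b]]) || a > b)) keep[a] <- FALSE
    }
    sets <- sets[keep]
  }
  # stable letter order: sets sorted by the best-ranked member they contain
  rank_of <- match(seq_len(k), ordering)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), numeric(1)))]
  out <- setNames(rep("", k), lv)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}

#' Community-level mixed-model tests
#'
#' Likelihood-ratio tests of the fertilization gradient (and, for the
#' temperature-resolved CWM responses, of temperature and the interaction)
#' on community summaries, with block as random intercept.  Terms are
#' tested by comparing nested ML fits: interaction against main effects,
#' each main effect against the model with the other main effect only, and
#' for single-factor responses fertilization against the intercept.
#'
#' @param summaries a `community_summary` data.frame.
#' @param fd optional output of [fd_all()], tested the same way as the
#'   single-factor responses.
#' @return data.frame: `response`, `term`, `chi2`, `df`, `p`.
#' @export
community_tests <- function(summaries, fd = NULL) {
  rows <- list()
  # temperature-resolved responses: stack the five temperatures long
  for (fam in c("gp", "gr")) {
    long <- do.call(rbind, lapply(CONSTANT_TEMPS, function(tp) {
      data.frame(block_id = summaries$block_id, n_level = summaries$n_level,
                 temperature = factor(tp, levels = CONSTANT_TEMPS),
                 y = summaries[[paste0("cwm_", fam, "_", tp)]],
                 stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$y), , drop = FALSE]
    full <- lmm_block(y ~ temperature * n_level, long)
    main <- lmm_block(y ~ temperature + n_level, long)
    tem <- lmm_block(y ~ n_level, long)
    fer <- lmm_block(y ~ temperature, long)
    resp <- paste0("cwm_", fam)
    rows[[length(rows) + 1L]] <- cbind(response = resp, term = "temperature",
                                       lrt(main, tem))
    rows[[length(rows) + 1L]] <- cbind(response = resp, term = "fertilization",
                                       lrt(main, fer))
    rows[[length(rows) + 1L]] <- cbind(response = resp,
                                       term = "temperature:fertilization",
                                       lrt(full, main))
  }
  single <- c(cwm_btn = "cwm_btn", cwm_r_alt = "cwm_r_alt",
              cwm_r_wc = "cwm_r_wc")
  dat <- summaries
  if (!is.null(fd)) {
    dat <- merge(summaries, fd, by = c("block_id", "n_level"))
    single <- c(single, fric = "fric", feve = "feve", fdiv = "fdiv")
  }
  for (resp in names(single)) {
    d <- data.frame(block_id = dat$block_id, n_level = dat$n_level,
                    y = dat[[single[[resp]]]])
    d <- d[!is.na(d$y), , drop = FALSE]
    full <- lmm_block(y ~ n_level, d)
    null <- lmm_block(y ~ 1, d)
    rows[[length(rows) + 1L]] <- cbind(response = resp,
                                       term = "fertilization",
                                       lrt(full, null))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
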