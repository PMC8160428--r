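gen_block_data <- function(n_blocks, reps, beta = c(2, 1, -1, 0.5),
                           sb = 1, se = 1, seed = 1) {
  set.seed(seed)
  levels <- c("N0", "N1", "N2", "N3")
  d <- expand.grid(block_id = sprintf("b%02d", seq_len(n_blocks)),
                   n_level = levels, rep = seq_len(reps),
                   stringsAsFactors = FALSE)
  X <- model.matrix(~ n_level, d)
  b <- rnorm(n_blocks, 0, sb)
  d$y <- drop(X %*% beta) + b[match(d$block_id, unique(d$block_id))] +
    rnorm(nrow(d), 0, se)
  d
}

test_that("without block variance the fit collapses to least squares", {
  d <- gen_block_data(6, 3, sb = 0, seed = 4)
  # remove any sampled block signal entirely so lambda-hat = 0
  d$y <- d$y - ave(d$y, d$block_id) + mean(d$y)
  fit <- lmm_block(y ~ n_level, d)
  ols <- lm(y ~ n_level, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma2_block, 0, tolerance = 1e-8)
})

test_that("adding a constant to the response only shifts the intercept", {
  d <- gen_block_data(8, 2, seed = 5)
  f1 <- lmm_block(y ~ n_level, d)
  d2 <- d; d2$y <- d2$y + 10
  f2 <- lmm_block(y ~ n_level, d2)
  expect_equal(unname(coef(f2)["(Intercept)"]),
               unname(coef(f1)["(Intercept)"] + 10), tolerance = 1e-6)
  expect_equal(unname(coef(f2)[-1]), unname(coef(f1)[-1]),
               tolerance = 1e-6)
  expect_equal(f2$sigma2_block, f1$sigma2_block, tolerance = 1e-6)
})

test_that("variance components are recovered in a large balanced design", {
  d <- gen_block_data(50, 10, sb = 2, se = 1, seed = 6)  # variances 4 and 1
  fit <- lmm_block(y ~ n_level, d)
  expect_lt(abs(fit$sigma2_block - 4) / 4, 0.3)
  expect_lt(abs(fit$sigma2_resid - 1) / 1, 0.3)
})

test_that("the profiled fit agrees with lme4 maximum likelihood", {
  set.seed(9)
  d <- gen_block_data(7, 3, sb = 0.8, se = 0.6, seed = 9)
  d <- d[-sample(nrow(d), 11), ]  # unbalanced
  fit <- lmm_block(y ~ n_level, d)
  ref <- lme4::lmer(y ~ n_level + (1 | block_id), d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_block, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-3)
})

test_that("profiling equals direct joint optimization of all parameters", {
  set.seed(30)
  for (i in 1:5) {
    d <- gen_block_data(sample(5:9, 1), sample(2:3, 1),
                        sb = runif(1, 0.2, 2), se = runif(1, 0.5, 1.5),
                        seed = 100 + i)
    fit <- lmm_block(y ~ n_level, d)
    X <- model.matrix(~ n_level, d)
    Z <- model.matrix(~ factor(d$block_id) - 1)
    nll <- function(th) {
      beta <- th[seq_len(ncol(X))]
      V <- exp(th[ncol(X) + 1]) * tcrossprod(Z) +
        exp(th[ncol(X) + 2]) * diag(nrow(X))
      r <- d$y - drop(X %*% beta)
      0.5 * (determinant(V)$modulus + sum(r * solve(V, r)) +
               nrow(X) * log(2 * pi))
    }
    direct <- optim(c(coef(fit), log(max(fit$sigma2_block, 1e-4)),
                      log(fit$sigma2_resid)) + 0.05,
                    nll, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
    expect_lt(abs(fit$loglik - (-direct$value)), 1e-6)
  }
})

test_that("likelihood-ratio tests report the factorial degrees of freedom", {
  cfg <- sim_config(n_species = 12, rng_seed = 61)
  study <- simulate_study(cfg)
  prof <- build_profiles(study$trials)
  cwm <- summarize_communities(study$quadrats, prof)
  tests <- community_tests(cwm)
  gp <- tests[tests$response == "cwm_gp", ]
  expect_equal(gp$df[gp$term == "temperature"], 4)
  expect_equal(gp$df[gp$term == "fertilization"], 3)
  expect_equal(gp$df[gp$term == "temperature:fertilization"], 12)
  expect_true(all(tests$chi2 >= 0))
  expect_true(all(tests$p > 0 & tests$p <= 1))

  # identical fits: zero statistic, p = 1
  d <- gen_block_data(5, 2, seed = 3)
  f <- lmm_block(y ~ n_level, d)
  self <- lrt(f, f)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  expect_error(lrt(lmm_block(y ~ 1, d), f), "fewer fixed-effect")
})

test_that("Tukey letters separate what differs and merge what does not", {
  d <- data.frame(y = rep(c(0, 0, 0, 0), each = 5),
                  g = rep(c("N0", "N1", "N2", "N3"), each = 5))
  d$y <- d$y + rep(c(0.01, -0.01, 0.02, -0.02, 0), 4)  # identical groups
  tk <- tukey_groups(d$y, d$g)
  expect_true(all(tk$letters == tk$letters[1]))

  set.seed(2)
  d2 <- data.frame(y = c(rnorm(5, 0, 1), rnorm(5, 10, 1)),
                   g = rep(c("lo", "hi"), each = 5))
  tk2 <- tukey_groups(d2$y, d2$g)
  expect_false(any(strsplit(tk2$letters[["lo"]], "")[[1]] %in%
                     strsplit(tk2$letters[["hi"]], "")[[1]]))

  # three clearly separated groups get three distinct letters
  d3 <- data.frame(y = c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1),
                         rnorm(5, 10, 0.1)),
                   g = rep(c("a0", "b5", "c10"), each = 5))
  tk3 <- tukey_groups(d3$y, d3$g)
  expect_equal(length(unique(tk3$letters)), 3)
  expect_error(tukey_groups(1:3, c("a", "a", "b")), "at least 2")
})
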