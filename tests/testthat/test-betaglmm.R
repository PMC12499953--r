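test_that("model specs enforce structural rules", {
  expect_error(model_spec("none", interaction = TRUE), "interaction")
  base <- model_spec("none")
  expect_false("measure" %in% base$listener_re)   # dropped automatically
  full <- model_spec("m1", interaction = TRUE)
  expect_setequal(full$fixed,
                  c("intercept", "target", "measure", "target:measure"))
})

test_that("beta log-density matches closed forms and dbeta", {
  expect_equal(beta_logpdf(0.3, 0.5, 2), 0)         # Beta(1,1) is uniform
  expect_equal(beta_logpdf(0.4, 0.5, 6), beta_logpdf(0.6, 0.5, 6))
  ys <- with_seed(1, stats::runif(50, 0.01, 0.99))
  for (pars in list(c(0.37, 11), c(0.62, 3.3), c(0.9, 40))) {
    expect_equal(beta_logpdf(ys, pars[1], pars[2]),
                 stats::dbeta(ys, pars[1] * pars[2],
                              (1 - pars[1]) * pars[2], log = TRUE),
                 tolerance = 1e-12)
  }
  expect_error(beta_logpdf(0, 0.5, 2), "strictly inside")
  expect_error(beta_logpdf(0.5, 0.5, -1), "phi")
})

test_that("beta density integrates to one", {
  pairs <- with_seed(4, cbind(stats::runif(5, 0.05, 0.95),
                              stats::runif(5, 0.5, 40)))
  for (r in seq_len(nrow(pairs))) {
    v <- stats::integrate(function(y) {
      exp(beta_logpdf(y, pairs[r, 1], pairs[r, 2]))
    }, 0, 1, rel.tol = 1e-10)$value
    expect_equal(v, 1, tolerance = 1e-8)
  }
})

test_that("vanishing random effects recover the fixed-effects likelihood", {
  d <- make_rating_data(6, 20, rating_truth(n_listeners = 6,
                                            listener_sds = c(0, 0, 0),
                                            stimulus_sd = 0), seed = 3)
  beta <- c(0.8, -0.5, -1.0); phi <- 9
  lap <- marginal_loglik(model_spec("m1"), d,
                         list(beta = beta,
                              Sigma_listener = diag(1e-12, 3),
                              sigma_stimulus = 1e-8, phi = phi))
  X <- cbind(1, d$target, d$m1)
  direct <- sum(beta_logpdf(d$value_open, stats::plogis(X %*% beta), phi))
  expect_equal(lap, direct, tolerance = 1e-6)
})

test_that("one observation: Laplace matches 1-D quadrature near the Gaussian limit", {
  d1 <- data.frame(listener_id = "L1", token_id = "t1", target = 1,
                   value_open = 0.62)
  s <- 0.05
  lap <- marginal_loglik(model_spec("none", listener_re = "intercept"), d1,
                         list(beta = c(0.2, -0.3),
                              Sigma_listener = matrix(s^2, 1, 1),
                              sigma_stimulus = s, phi = 10))
  # listener and stimulus intercepts are confounded for a single rating:
  # their sum is Gaussian with variance 2 s^2, so the marginal is a 1-D
  # integral evaluated by adaptive quadrature
  sig <- s * sqrt(2)
  ora <- log(stats::integrate(function(z) {
    vapply(z, function(zz) {
      exp(beta_logpdf(0.62, stats::plogis(0.2 - 0.3 + sig * zz), 10))
    }, numeric(1)) * stats::dnorm(z)
  }, -10, 10, rel.tol = 1e-12)$value)
  expect_equal(lap, ora, tolerance = 1e-4)
})

test_that("Laplace agrees with 15-node adaptive Gauss-Hermite at study-like load", {
  # one-random-effect models at the per-listener rating load of the target
  # design (hundreds of ratings per listener)
  for (s in 1:3) {
    J <- 6; nper <- 536
    d <- with_seed(600 + s, {
      dd <- data.frame(listener_id = rep(sprintf("L%02d", 1:J), each = nper),
                       token_id = paste0("t", seq_len(J * nper)),
                       target = stats::rbinom(J * nper, 1, 0.5))
      u <- stats::rnorm(J, 0, 0.3)
      mu <- stats::plogis(0.5 - 0.7 * dd$target +
                            u[as.integer(factor(dd$listener_id))])
      dd$value_open <- pmin(1 - 1e-9,
                            pmax(1e-9, stats::rbeta(J * nper, mu * 10,
                                                    (1 - mu) * 10)))
      dd
    })
    beta <- c(0.5, -0.7)
    lap <- marginal_loglik(model_spec("none", listener_re = "intercept",
                                      stimulus_re = FALSE), d,
                           list(beta = beta,
                                Sigma_listener = matrix(0.09, 1, 1),
                                phi = 10))
    agq <- agq_loglik_intercept(d, beta, 0.3, 10)
    expect_lt(abs(lap - agq), 1e-3)
  }
})

test_that("Laplace agrees with importance-sampled marginal on crossed data", {
  J <- 5; K <- 20
  d <- with_seed(77, {
    dd <- expand.grid(listener_id = sprintf("L%02d", 1:J),
                      token_id = sprintf("t%02d", 1:K),
                      stringsAsFactors = FALSE)
    tk <- data.frame(token_id = sprintf("t%02d", 1:K),
                     target = stats::rbinom(K, 1, 0.5))
    dd <- merge(dd, tk)
    ul <- stats::rnorm(J, 0, 0.3); uk <- stats::rnorm(K, 0, 0.3)
    mu <- stats::plogis(0.3 - 0.5 * dd$target +
                          ul[as.integer(factor(dd$listener_id))] +
                          uk[as.integer(factor(dd$token_id))])
    dd$value_open <- pmin(1 - 1e-9,
                          pmax(1e-9, stats::rbeta(nrow(dd), mu * 10,
                                                  (1 - mu) * 10)))
    dd
  })
  beta <- c(0.3, -0.5)
  lap <- marginal_loglik(model_spec("none", listener_re = "intercept"), d,
                         list(beta = beta,
                              Sigma_listener = matrix(0.09, 1, 1),
                              sigma_stimulus = 0.3, phi = 10))
  mc <- is_loglik_crossed(d, beta, 0.3, 0.3, 10, n_samples = 1e5)
  expect_lt(abs(lap - mc), 0.02 * abs(mc))
})

test_that("the analytic outer gradient matches finite differences", {
  d <- make_rating_data(6, 25, rating_truth(n_listeners = 6, phi = 8),
                        seed = 21)
  model <- sibspect:::build_model(model_spec("m1"), d)
  state <- new.env(); state$z <- numeric(model$m)
  f <- function(th) sibspect:::neg_marginal(model, th, state)
  th <- with_seed(5, c(stats::rnorm(3, 0, 0.4), stats::rnorm(6, -1, 0.3),
                       -1, 2.1))
  ga <- sibspect:::neg_marginal_grad(model, th, state)$grad
  gn <- vapply(seq_along(th), function(r) {
    h <- 1e-6 * max(1, abs(th[r]))
    tp <- th; tp[r] <- tp[r] + h
    tm <- th; tm[r] <- tm[r] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / (1 + abs(gn))), 5e-4)
})

test_that("a fixed-effects-only fit recovers a known target effect", {
  n <- 2000
  d <- with_seed(4, {
    target <- stats::rbinom(n, 1, 0.5)
    mu <- stats::plogis(0.5 - 1.2 * target)
    data.frame(listener_id = "L1", token_id = paste0("t", 1:n),
               target = target,
               value_open = pmin(1 - 1e-9,
                                 pmax(1e-9, stats::rbeta(n, mu * 8,
                                                         (1 - mu) * 8))))
  })
  fit <- beta_glmm(model_spec("none", listener_re = character(0),
                              stimulus_re = FALSE), d)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["target"]] - (-1.2)), 0.1)
})

test_that("refitting identical data with the same seed is deterministic", {
  d <- make_rating_data(6, 20, seed = 9)
  f1 <- beta_glmm(model_spec("m1"), d, seed = 1)
  f2 <- beta_glmm(model_spec("m1"), d, seed = 1)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("shifting the measure by a constant moves only the intercept", {
  d <- make_rating_data(8, 30, seed = 13)
  f1 <- beta_glmm(model_spec("m1"), d, seed = 1)
  d2 <- d; d2$m1 <- d2$m1 + 0.5
  f2 <- beta_glmm(model_spec("m1"), d2, seed = 1)
  expect_lt(abs(f1$coefficients[["measure"]] - f2$coefficients[["measure"]]),
            1e-3)
  expect_lt(abs(f1$coefficients[["target"]] - f2$coefficients[["target"]]),
            1e-3)
  expect_lt(abs((f1$coefficients[["intercept"]] -
                   f2$coefficients[["intercept"]]) -
                  0.5 * f2$coefficients[["measure"]]), 5e-3)
})

test_that("likelihood-ratio tests respect nesting, clipping and identity", {
  d <- make_rating_data(6, 20, seed = 15)
  main <- beta_glmm(model_spec("m1"), d, seed = 1)
  intr <- beta_glmm(model_spec("m1", interaction = TRUE), d, seed = 1)
  base <- beta_glmm(model_spec("none"), d, seed = 1)
  self <- lr_test(main, main)
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)
  lt <- lr_test(intr, main)
  expect_gte(lt$chisq, 0)
  expect_equal(lt$df, 1L)
  lb <- lr_test(main, base)
  expect_equal(lb$df, main$n_params - base$n_params)
  expect_error(lr_test(base, main), "not nested")
  # AIC identity: full preferred by AIC iff chisq > 2 df
  expect_equal(intr$aic < main$aic, lt$chisq > 2 * lt$df)
})

test_that("AIC is 2k - 2 logLik and the logLik method carries df", {
  d <- make_rating_data(5, 15, seed = 19)
  fit <- beta_glmm(model_spec("m1"), d, seed = 1)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), fit$n_params)
  expect_equal(AIC(fit), fit$aic)
})

test_that("fits agree with an independent implementation (glmmTMB)", {
  d <- make_rating_data(15, 60, rating_truth(n_listeners = 15), seed = 31)
  ours <- beta_glmm(model_spec("m1"), d, seed = 1, se = TRUE)
  tmb <- glmmTMB::glmmTMB(
    value_open ~ target + m1 + (1 + target + m1 | listener_id) +
      (1 | token_id),
    data = d, family = glmmTMB::beta_family(link = "logit"))
  expect_equal(ours$loglik, as.numeric(stats::logLik(tmb)), tolerance = 0.02)
  bt <- glmmTMB::fixef(tmb)$cond
  expect_equal(unname(ours$coefficients),
               unname(bt[c("(Intercept)", "target", "m1")]),
               tolerance = 0.02)
  expect_equal(ours$phi, glmmTMB::sigma(tmb), tolerance = 0.02)
  se_tmb <- summary(tmb)$coefficients$cond[, "Std. Error"]
  expect_equal(unname(ours$se), unname(se_tmb), tolerance = 0.15)
  # identical parameter count convention for this model family
  expect_equal(fit_df <- attr(stats::logLik(tmb), "df"), ours$n_params)
})
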