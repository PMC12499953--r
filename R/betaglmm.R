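#' Specify a beta mixed-effects model of VAS ratings
#'
#' The response is a rating in (0, 1); the mean follows a logit link with
#' fixed effects for the target phoneme (1 = /s/, 0 = /sh/), optionally one
#' scaled acoustic measure and their interaction. Random effects are crossed:
#' a by-listener vector (any of intercept, target slope, measure slope, with
#' a fully correlated covariance) and a by-stimulus intercept. The precision
#' `phi` is constant (no dispersion submodel).
#'
#' @param measure Name of the scaled acoustic predictor column (`"m1"`,
#'   `"fm_3_7"`, `"fm_3_8"`, `"fm_3_9"`) or `"none"` for the baseline
#'   (target-only) model.
#' @param interaction Include the target-by-measure interaction (requires a
#'   measure).
#' @param listener_re Character subset of `c("intercept", "target",
#'   "measure")`; `"measure"` is dropped automatically when `measure =
#'   "none"`.
#' @param stimulus_re Include a by-stimulus random intercept.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(measure = "none", interaction = FALSE,
                       listener_re = c("intercept", "target", "measure"),
                       stimulus_re = TRUE) {
  measure <- as.character(measure)
  listener_re <- if (length(listener_re)) {
    match.arg(listener_re, c("intercept", "target", "measure"),
              several.ok = TRUE)
  } else {
    character(0)
  }
  if (measure == "none") {
    if (interaction) {
      stop("model_spec: interaction requires a measure", call. = FALSE)
    }
    listener_re <- setdiff(listener_re, "measure")
  }
  fixed <- c("intercept", "target",
             if (measure != "none") "measure",
             if (interaction) "target:measure")
  structure(list(measure = measure, interaction = interaction,
                 fixed = fixed, listener_re = listener_re,
                 stimulus_re = isTRUE(stimulus_re)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: fixed = %s; listener RE = %s; stimulus RE = %s>\n",
              paste(x$fixed, collapse = " + "),
              if (length(x$listener_re)) paste(x$listener_re, collapse = " + ") else "none",
              if (x$stimulus_re) "intercept" else "none"))
  invisible(x)
}

#' Log-density of the mean-precision beta distribution
#'
#' `Beta(mu * phi, (1 - mu) * phi)` evaluated at `y`, all arguments in the
#' open unit interval (`phi > 0`). Boundary responses must be compressed
#' first (see [squeeze_boundaries()]).
#'
#' @param y Response in (0, 1).
#' @param mu Mean in (0, 1).
#' @param phi Precision (> 0).
#' @return Log-density (vectorized).
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) {
    stop("beta_logpdf: y must lie strictly inside (0, 1); squeeze boundaries first",
         call. = FALSE)
  }
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0)) {
    stop("beta_logpdf: need 0 < mu < 1 and phi > 0", call. = FALSE)
  }
  a <- mu * phi
  b <- (1 - mu) * phi
  lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * log(y) + (b - 1) * log1p(-y)
}

## ---- internal model structure ---------------------------------------------

## Assemble the design objects shared by every likelihood evaluation: y,
## dense X, the listener random-effect covariate matrix Tl with its index
## vector, and the stimulus index vector. The inner solver receives these
## directly and exploits the crossed block structure of the joint Hessian.
build_model <- function(spec, data) {
  need <- c("value_open", "target", "listener_id", "token_id",
            if (spec$measure != "none") spec$measure)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop(sprintf("beta_glmm: missing column(s) in data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  y <- data$value_open
  if (any(y <= 0 | y >= 1)) {
    stop("beta_glmm: responses must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- length(y)
  meas <- if (spec$measure != "none") data[[spec$measure]] else NULL

  X <- cbind(intercept = rep(1, n), target = data$target)
  if (spec$measure != "none") X <- cbind(X, measure = meas)
  if (spec$interaction) X <- cbind(X, `target:measure` = data$target * meas)

  term_col <- function(term) switch(term,
    intercept = rep(1, n), target = data$target, measure = meas)
  q <- length(spec$listener_re)
  listener <- factor(data$listener_id)
  stimulus <- factor(data$token_id)
  J <- if (q > 0) nlevels(listener) else 0L
  jidx <- if (q > 0) as.integer(listener) else integer(n)
  K <- if (spec$stimulus_re) nlevels(stimulus) else 0L
  kidx <- if (spec$stimulus_re) as.integer(stimulus) else integer(n)
  Tl <- if (q > 0) {
    matrix(unlist(lapply(spec$listener_re, term_col)), nrow = n)
  } else {
    matrix(0, n, 0)
  }

  nlam <- q * (q + 1) / 2
  m <- J * q + K
  ## diagonal positions of Lambda within the column-major lower triangle
  lam_diag <- if (q > 0) cumsum(c(1, if (q >= 2) seq(q, 2))) else integer(0)

  p <- ncol(X)
  list(y = y, X = X, Tl = Tl, jidx = jidx, kidx = kidx, spec = spec,
       n = n, p = p, q = q, nlam = nlam, J = J, K = K, m = m,
       lam_diag = lam_diag,
       listener_levels = levels(listener), stimulus_levels = levels(stimulus),
       n_params = p + nlam + spec$stimulus_re + 1L)
}

## theta layout: [beta (p)] [lam (nlam; diagonal entries on log scale)]
## [log sigma_w (if stimulus_re)] [log phi]
theta_split <- function(model, theta) {
  p <- model$p; nlam <- model$nlam; q <- model$q
  beta <- theta[seq_len(p)]
  lam <- if (nlam > 0) theta[p + seq_len(nlam)] else numeric(0)
  if (nlam > 0) lam[model$lam_diag] <- exp(lam[model$lam_diag])
  Lambda <- matrix(0, q, q)
  if (q > 0) Lambda[lower.tri(Lambda, diag = TRUE)] <- lam
  pos <- p + nlam
  sigma_w <- if (model$spec$stimulus_re) exp(theta[pos + 1]) else 0
  phi <- exp(theta[length(theta)])
  list(beta = beta, lam = lam, Lambda = Lambda, sigma_w = sigma_w, phi = phi)
}

## One evaluation of the negative Laplace marginal log-likelihood.
## `state` is an environment carrying the warm-start mode between calls.
neg_marginal <- function(model, theta, state) {
  pars <- theta_split(model, theta)
  if (pars$phi <= 0 || !all(is.finite(theta))) return(1e10)
  eta_fixed <- as.numeric(model$X %*% pars$beta)
  res <- .laplace_inner(model$y, eta_fixed, model$Tl, model$jidx,
                        model$kidx, pars$Lambda, pars$sigma_w, pars$phi,
                        state$z, model$X)
  if (is.finite(res$nll) && model$m > 0L) state$z <- res$z
  res$nll
}

## Analytic gradient of the negative Laplace objective wrt theta, via the
## adjoint of the log-determinant term; the raw C++ gradient (wrt beta, the
## Lambda entries, sigma_w, phi) gets the log-scale chain rule applied here.
neg_marginal_grad <- function(model, theta, state) {
  pars <- theta_split(model, theta)
  if (pars$phi <= 0 || !all(is.finite(theta))) {
    return(list(nll = 1e10, grad = rep(0, length(theta))))
  }
  eta_fixed <- as.numeric(model$X %*% pars$beta)
  res <- .laplace_inner(model$y, eta_fixed, model$Tl, model$jidx,
                        model$kidx, pars$Lambda, pars$sigma_w, pars$phi,
                        state$z, model$X, want_grad = TRUE)
  if (is.finite(res$nll) && model$m > 0L) state$z <- res$z
  g <- as.numeric(res$grad)
  p <- model$p
  if (model$m == 0L) {
    ## fixed-effects-only: raw gradient is (beta, phi)
    grad <- c(g[seq_len(p)], g[p + 1L] * pars$phi)
    return(list(nll = res$nll, grad = grad))
  }
  if (model$nlam > 0) {
    lam_idx <- p + seq_len(model$nlam)
    g[lam_idx][model$lam_diag] <-
      g[lam_idx][model$lam_diag] * pars$lam[model$lam_diag]
  }
  pos <- p + model$nlam
  if (model$spec$stimulus_re) {
    g[pos + 1L] <- g[pos + 1L] * pars$sigma_w
    pos <- pos + 1L
  }
  g[pos + 1L] <- g[pos + 1L] * pars$phi
  list(nll = res$nll, grad = g)
}

#' Laplace-approximate marginal log-likelihood at fixed parameters
#'
#' Evaluates the marginal log-likelihood of a beta mixed-effects model at a
#' given parameter value, integrating the crossed random effects out with a
#' Laplace approximation (joint mode via damped Newton, then a Gaussian
#' correction from the sparse joint Hessian). Useful for likelihood
#' diagnostics and for comparison against quadrature at small sizes.
#'
#' @param spec A [model_spec()].
#' @param data Analysis data frame (see [beta_glmm()]).
#' @param params List with `beta` (fixed effects, in the order
#'   intercept/target/measure/interaction), `Sigma_listener` (q x q
#'   covariance of the listener effects; may be omitted when the spec has no
#'   listener terms), `sigma_stimulus` (stimulus intercept SD) and `phi`.
#' @return The approximate marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(spec, data, params) {
  model <- build_model(spec, data)
  theta <- params_to_theta(model, params)
  state <- new.env(parent = emptyenv())
  state$z <- numeric(model$m)
  -neg_marginal(model, theta, state)
}

params_to_theta <- function(model, params) {
  beta <- params$beta
  if (length(beta) != model$p) {
    stop(sprintf("expected %d fixed effects, got %d", model$p, length(beta)),
         call. = FALSE)
  }
  lam_raw <- numeric(model$nlam)
  if (model$q > 0) {
    Sig <- params$Sigma_listener
    if (is.null(Sig)) stop("params$Sigma_listener required", call. = FALSE)
    Sig <- as.matrix(Sig)
    L <- t(chol(Sig + diag(1e-12, model$q)))
    lam_raw <- L[lower.tri(L, diag = TRUE)]   # column-major lower triangle
    lam_raw[model$lam_diag] <- log(pmax(lam_raw[model$lam_diag], 1e-12))
  }
  c(beta, lam_raw,
    if (model$spec$stimulus_re) log(max(params$sigma_stimulus, 1e-12)),
    log(params$phi))
}

## ---- fitting ---------------------------------------------------------------

#' Control parameters for [beta_glmm()]
#'
#' @param n_starts Number of seeded starting points; a short pre-search is
#'   run from each and the best is polished to convergence.
#' @param presearch_iter Outer iterations allotted to each pre-search.
#' @param iter_max Outer iterations for the polishing run.
#' @param inner_tol Gradient tolerance of the inner Newton mode-finder.
#' @param grad_tol Outer gradient max-norm below which the fit is declared
#'   converged. The outer gradient is analytic (adjoint differentiation of
#'   the Laplace objective), but its consistency with the computed objective
#'   is limited by the inner solver's numerical floor, which scales with the
#'   magnitude of the log-likelihood; the default is an absolute 1e-2
#'   (log-likelihood units per unit parameter).
#' @param fd_h Relative step for finite-difference gradient checks.
#' @param rel_tol Relative convergence tolerance of the outer optimizer.
#' @return List of control values.
#' @export
glmm_control <- function(n_starts = 3L, presearch_iter = 15L, iter_max = 300L,
                         inner_tol = 1e-8, grad_tol = 1e-2, fd_h = 1e-6,
                         rel_tol = 1e-10) {
  list(n_starts = n_starts, presearch_iter = presearch_iter,
       iter_max = iter_max, inner_tol = inner_tol, grad_tol = grad_tol,
       fd_h = fd_h, rel_tol = rel_tol)
}

## Fixed-effects-only beta regression (exact likelihood, analytic gradient);
## used for starting values and as the degenerate no-random-effects fit.
fit_fixed_beta <- function(y, X, beta0 = NULL, logphi0 = log(5)) {
  if (is.null(beta0)) {
    beta0 <- stats::lm.fit(X, stats::qlogis(pmin(1 - 1e-6, pmax(1e-6, y))))$coefficients
    beta0[!is.finite(beta0)] <- 0
  }
  obj <- function(par) {
    beta <- par[-length(par)]; phi <- exp(par[length(par)])
    eta <- as.numeric(X %*% beta)
    d <- .beta_eta_derivs(y, eta, phi)
    -d$ll
  }
  grad <- function(par) {
    beta <- par[-length(par)]; phi <- exp(par[length(par)])
    eta <- pmin(35, pmax(-35, as.numeric(X %*% beta)))
    mu <- stats::plogis(eta)
    a <- mu * phi; b <- (1 - mu) * phi
    d1 <- phi * mu * (1 - mu) * (log(y) - log1p(-y) - digamma(a) + digamma(b))
    dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
      mu * log(y) + (1 - mu) * log1p(-y)
    -c(as.numeric(crossprod(X, d1)), phi * sum(dphi))
  }
  res <- stats::nlminb(c(beta0, logphi0), obj, grad,
                       control = list(iter.max = 200))
  list(beta = res$par[-length(res$par)],
       logphi = res$par[length(res$par)],
       loglik = -res$objective)
}

## Forward-difference outer gradient with warm-started inner solves.
fd_gradient <- function(f, theta, f0, h_rel) {
  g <- numeric(length(theta))
  for (r in seq_along(theta)) {
    h <- h_rel * max(1, abs(theta[r]))
    th <- theta; th[r] <- th[r] + h
    g[r] <- (f(th) - f0) / h
  }
  g
}

#' Fit a beta mixed-effects regression by Laplace-approximate ML
#'
#' Maximizes the Laplace-approximate marginal likelihood over the fixed
#' effects, the Cholesky factor of the listener covariance, the stimulus
#' intercept SD and the log precision, using a quasi-Newton outer optimizer
#' with finite-difference gradients and warm-started inner Newton solves.
#' Several seeded starting points are pre-searched briefly and the best is
#' polished to convergence; refitting with the same data and seed is
#' deterministic.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with columns `value_open` (response in (0, 1)),
#'   `target` (0/1), `listener_id`, `token_id`, and the scaled measure column
#'   named by the spec.
#' @param control A [glmm_control()].
#' @param seed Seed for the start-point jitter.
#' @param se Compute standard errors from a finite-difference Hessian.
#' @return An object of class `beta_glmm` with elements `coefficients`,
#'   `se`, `Sigma_listener`, `sigma_stimulus`, `phi`, `loglik`, `n_params`,
#'   `aic`, `converged`, `gradient_norm`, `spec`, `theta`, and the model
#'   dimensions.
#' @export
beta_glmm <- function(spec, data, control = glmm_control(), seed = 1L,
                      se = FALSE) {
  model <- build_model(spec, data)
  state <- new.env(parent = emptyenv())
  state$z <- numeric(model$m)
  state$last_theta <- NULL
  f <- function(theta) {
    v <- neg_marginal(model, theta, state)
    state$last_theta <- theta
    state$last_f <- v
    v
  }

  ## smart start: exact fixed-effects fit, moderate random-effect SDs
  fx <- fit_fixed_beta(model$y, model$X)
  theta0 <- numeric(model$p + model$nlam + model$spec$stimulus_re + 1L)
  theta0[seq_len(model$p)] <- fx$beta
  if (model$nlam > 0) {
    lam0 <- numeric(model$nlam)
    lam0[model$lam_diag] <- log(0.3)
    theta0[model$p + seq_len(model$nlam)] <- lam0
  }
  if (model$spec$stimulus_re) theta0[model$p + model$nlam + 1L] <- log(0.3)
  theta0[length(theta0)] <- fx$logphi

  starts <- list(theta0)
  if (control$n_starts > 1L) {
    jitter <- with_local_seed(seed, {
      lapply(seq_len(control$n_starts - 1L), function(s) {
        th <- theta0
        th[seq_len(model$p)] <- th[seq_len(model$p)] +
          stats::rnorm(model$p, sd = 0.25)
        if (model$nlam > 0) {
          th[model$p + seq_len(model$nlam)] <-
            th[model$p + seq_len(model$nlam)] + stats::rnorm(model$nlam, sd = 0.5)
        }
        th[length(th)] <- th[length(th)] + stats::rnorm(1, sd = 0.3)
        th
      })
    })
    starts <- c(starts, jitter)
  }

  grad_fn <- function(theta) neg_marginal_grad(model, theta, state)$grad

  pre <- lapply(starts, function(th) {
    state$z <- numeric(model$m)
    if (length(starts) == 1L) return(list(par = th, objective = f(th)))
    stats::nlminb(th, f, grad_fn,
                  control = list(iter.max = control$presearch_iter,
                                 eval.max = 10L * control$presearch_iter,
                                 rel.tol = control$rel_tol))
  })
  best <- which.min(vapply(pre, function(r) r$objective, numeric(1)))
  theta <- pre[[best]]$par
  ## polish to convergence; a quasi-Newton restart with fresh curvature
  ## memory is cheap and often shaves the last order of magnitude off the
  ## gradient norm
  for (round in 1:3) {
    opt <- stats::nlminb(theta, f, grad_fn,
                         control = list(iter.max = control$iter_max,
                                        eval.max = 4L * control$iter_max,
                                        rel.tol = control$rel_tol))
    theta <- opt$par
    final <- neg_marginal_grad(model, theta, state)
    gradient_norm <- max(abs(final$grad))
    if (gradient_norm < control$grad_tol) break
  }
  nll <- final$nll
  pars <- theta_split(model, theta)

  Sigma_listener <- NULL
  if (model$q > 0) {
    L <- matrix(0, model$q, model$q)
    L[lower.tri(L, diag = TRUE)] <- pars$lam
    Sigma_listener <- L %*% t(L)
    dimnames(Sigma_listener) <- list(model$spec$listener_re,
                                     model$spec$listener_re)
  }

  fit <- structure(list(
    spec = spec,
    coefficients = stats::setNames(pars$beta, colnames(model$X)),
    se = NULL, vcov_theta = NULL,
    Sigma_listener = Sigma_listener,
    sigma_stimulus = if (model$spec$stimulus_re) pars$sigma_w else NA_real_,
    phi = pars$phi,
    loglik = -nll,
    n_params = model$n_params,
    aic = 2 * model$n_params + 2 * nll,
    converged = gradient_norm < control$grad_tol,
    gradient_norm = gradient_norm,
    theta = theta,
    n = model$n, n_listeners = model$J, n_stimuli = model$K,
    z_hat = state$z,
    control = control, seed = seed
  ), class = "beta_glmm")

  if (se) {
    H <- fd_hessian_from_grad(function(th) neg_marginal_grad(model, th, state)$grad,
                              theta, h = 1e-5)
    V <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[seq_len(model$p)] > 0)) {
      fit$vcov_theta <- V
      fit$se <- stats::setNames(sqrt(diag(V)[seq_len(model$p)]),
                                colnames(model$X))
    }
  }
  fit
}

## Central differences of an (analytic) gradient function; symmetrized.
fd_hessian_from_grad <- function(grad_fn, theta, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  hs <- h * pmax(1, abs(theta))
  for (r in seq_len(k)) {
    tp <- theta; tp[r] <- tp[r] + hs[r]
    tm <- theta; tm[r] <- tm[r] - hs[r]
    H[, r] <- (grad_fn(tp) - grad_fn(tm)) / (2 * hs[r])
  }
  (H + t(H)) / 2
}

#' @export
print.beta_glmm <- function(x, ...) {
  cat(sprintf("Beta mixed-effects model (Laplace ML)%s\n",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  n = %d ratings, %d listeners, %d stimuli\n",
              x$n, x$n_listeners, x$n_stimuli))
  cat("  fixed effects (logit scale):\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf("    %-16s %8.4f%s\n", nm, x$coefficients[[nm]],
                if (!is.null(x$se)) sprintf("  (SE %.4f)", x$se[[nm]]) else ""))
  }
  if (!is.null(x$Sigma_listener)) {
    cat(sprintf("  listener RE SDs: %s\n",
                paste(sprintf("%.3f", sqrt(diag(x$Sigma_listener))),
                      collapse = ", ")))
  }
  if (is.finite(x$sigma_stimulus)) {
    cat(sprintf("  stimulus intercept SD: %.3f\n", x$sigma_stimulus))
  }
  cat(sprintf("  phi = %.2f, logLik = %.2f, k = %d, AIC = %.2f\n",
              x$phi, x$loglik, x$n_params, x$aic))
  invisible(x)
}

#' @export
logLik.beta_glmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
coef.beta_glmm <- function(object, ...) object$coefficients

#' Likelihood-ratio test of two nested beta mixed-effects fits
#'
#' @param full,reduced `beta_glmm` fits of the same data, `reduced` nested in
#'   `full` (fixed terms and listener random-effect terms are subsets).
#' @return List of class `lrt_result`: `chisq` (clipped at 0), `df`,
#'   `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "beta_glmm"), inherits(reduced, "beta_glmm"))
  if (full$n != reduced$n) {
    stop("lr_test: fits are not on the same data (different n)", call. = FALSE)
  }
  nested <- all(reduced$spec$fixed %in% full$spec$fixed) &&
    all(reduced$spec$listener_re %in% full$spec$listener_re) &&
    reduced$n_params <= full$n_params &&
    (reduced$spec$measure %in% c("none", full$spec$measure))
  if (!nested) {
    stop("lr_test: 'reduced' is not nested in 'full'", call. = FALSE)
  }
  df <- full$n_params - reduced$n_params
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df >= 1) stats::pchisq(chisq, df, lower.tail = FALSE) else
    as.numeric(chisq <= 0)   # identical nests: chisq 0, p 1
  structure(list(chisq = chisq, df = df, p_value = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square[df=%d] = %.3f, p = %.4g\n",
              x$df, x$chisq, x$p_value))
  invisible(x)
}
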