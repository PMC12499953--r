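# Shared fixtures and independent oracles for the mixed-model tests.

# Analysis-shaped data simulated from the generative beta GLMM with a
# uniform scaled measure; returns the table beta_glmm() expects.
make_rating_data <- function(J, K, truth = rating_truth(n_listeners = J),
                             seed = 1, measure = "m1") {
  tok <- with_seed(seed, {
    data.frame(token_id = sprintf("t%03d", seq_len(K)),
               target = stats::rbinom(K, 1, 0.5),
               x = stats::runif(K))
  })
  names(tok)[names(tok) == "x"] <- measure
  ratings <- simulate_ratings(tok, truth, driving = measure, seed = seed)
  d <- merge(ratings, tok, by = "token_id")
  d$value_open <- squeeze_boundaries(d$value)
  d
}

# Full synthetic pipeline up to the modeling table: corpus, measurement,
# screening-free scaling, simulated ratings driven by `driving` (a truth
# column or a scaled measured column).
small_analysis_table <- function(seed, driving = "resonance_scaled",
                                 n_tokens = 50, n_listeners = 8,
                                 truth = rating_truth(n_listeners = n_listeners)) {
  corp <- synth_corpus(n_tokens, seed = seed)
  m <- measure_tokens(corp$tokens)
  tok <- corp$truth
  tok$resonance_scaled <- minmax_scale(tok$resonance_hz)$scaled
  scaled <- scale_measures(m)$data
  tok <- merge(tok, scaled[, c("token_id", "m1", "fm_3_7", "fm_3_8",
                               "fm_3_9")], by = "token_id")
  ratings <- simulate_ratings(tok, truth, driving = driving, seed = seed)
  d <- merge(ratings, tok[, c("token_id", "target", "m1", "fm_3_7",
                              "fm_3_8", "fm_3_9")], by = "token_id")
  d$value_open <- squeeze_boundaries(d$value)
  d
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Adaptive 15-node Gauss-Hermite marginal log-likelihood for a model with a
# single by-listener random intercept (no stimulus effect). Independent of
# the package's Laplace path: plain R, per-listener 1-D integrals.
agq_loglik_intercept <- function(d, beta, sigma, phi, nodes = 15) {
  gh <- pracma::gaussHermite(nodes)
  X <- cbind(1, d$target)
  eta0 <- as.numeric(X %*% beta)
  total <- 0
  for (j in unique(d$listener_id)) {
    sel <- d$listener_id == j
    Lj <- function(z) {
      sum(beta_logpdf(d$value_open[sel], stats::plogis(eta0[sel] + sigma * z),
                      phi)) - z^2 / 2 - log(2 * pi) / 2
    }
    zh <- stats::optimize(function(z) -Lj(z), c(-10, 10))$minimum
    h <- -(Lj(zh + 1e-4) - 2 * Lj(zh) + Lj(zh - 1e-4)) / 1e-8
    sh <- 1 / sqrt(h)
    lw <- vapply(seq_along(gh$x), function(k) {
      Lj(zh + sqrt(2) * sh * gh$x[k]) + gh$x[k]^2 + log(gh$w[k])
    }, numeric(1))
    total <- total + log(sum(exp(lw - max(lw)))) + max(lw) + log(sqrt(2) * sh)
  }
  total
}

# Importance-sampled marginal log-likelihood for a crossed intercept-only
# model (listener + stimulus random intercepts), using a Gaussian proposal
# centred at the joint mode found by a plain-R Newton iteration. All dense R
# linear algebra, independent of the C++ path.
is_loglik_crossed <- function(d, beta, sigma_l, sigma_w, phi,
                              n_samples = 1e5, seed = 42) {
  X <- cbind(1, d$target)
  eta0 <- as.numeric(X %*% beta)
  jf <- factor(d$listener_id); kf <- factor(d$token_id)
  J <- nlevels(jf); K <- nlevels(kf)
  m <- J + K
  M <- matrix(0, nrow(d), m)
  M[cbind(seq_len(nrow(d)), as.integer(jf))] <- sigma_l
  M[cbind(seq_len(nrow(d)), J + as.integer(kf))] <- sigma_w
  loglik_z <- function(z) {
    sum(beta_logpdf(d$value_open, stats::plogis(eta0 + as.numeric(M %*% z)),
                    phi))
  }
  z <- numeric(m)
  for (it in 1:50) {
    dv <- sibspect:::.beta_eta_derivs(d$value_open,
                                      eta0 + as.numeric(M %*% z), phi)
    gr <- -as.numeric(crossprod(M, as.numeric(dv$d1))) + z
    if (max(abs(gr)) < 1e-10) break
    W <- as.numeric(-dv$d2); W[W <= 0] <- 1e-10
    G <- crossprod(M * sqrt(W)); diag(G) <- diag(G) + 1
    z <- z - solve(G, gr)
  }
  dv <- sibspect:::.beta_eta_derivs(d$value_open,
                                    eta0 + as.numeric(M %*% z), phi)
  W <- as.numeric(-dv$d2); W[W < 0] <- 0
  G <- crossprod(M * sqrt(W)); diag(G) <- diag(G) + 1
  Gi <- solve(G)
  L <- t(chol(Gi))
  with_seed(seed, {
    Zs <- matrix(stats::rnorm(n_samples * m), m, n_samples)
    zs <- z + L %*% Zs
    lw <- vapply(seq_len(n_samples), function(s) {
      zz <- zs[, s]
      loglik_z(zz) - sum(zz^2) / 2 - m / 2 * log(2 * pi) -
        (-sum(Zs[, s]^2) / 2 - m / 2 * log(2 * pi) -
           sum(log(diag(L))))
    }, numeric(1))
    mx <- max(lw)
    mx + log(mean(exp(lw - mx)))
  })
}
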