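#' Parameters of one mixed continuous/binary estimation
#'
#' The latent seizure state of estimation `n` follows an AR(1) process
#' `x_k = rho * x_{k-1} + eta_k`, `eta_k ~ N(0, var_eta)`. It is observed
#' through a continuous Gaussian channel `v_k = alpha + beta * x_k +
#' eps_k`, `eps_k ~ N(0, var_eps)`, and a binary Bernoulli channel
#' `lambda_k ~ Bernoulli(p_k)` with `p_k = logistic(mu + x_k)`.
#'
#' @param rho forgetting rate, `0 < rho < 1`.
#' @param alpha continuous-feature baseline (dB).
#' @param beta continuous-feature gain per unit of seizure state.
#' @param var_eta process-noise variance (> 0).
#' @param var_eps continuous measurement-noise variance (> 0).
#' @param mu Bernoulli offset; `logistic(mu)` is the seizure probability
#'   at the resting state `x = 0` (see [mu_from_chance()]).
#' @return An object of class `"mixed_params"`.
#' @export
mixed_params <- function(rho, alpha, beta, var_eta, var_eps, mu) {
  stopifnot(is.finite(rho), rho > 0, rho < 1,
            is.finite(alpha), is.finite(beta), is.finite(mu),
            is.finite(var_eta), var_eta > 0,
            is.finite(var_eps), var_eps > 0)
  structure(list(rho = rho, alpha = alpha, beta = beta,
                 var_eta = var_eta, var_eps = var_eps, mu = mu),
            class = "mixed_params")
}

#' @export
print.mixed_params <- function(x, ...) {
  cat(sprintf(
    "<mixed_params> rho=%.4f alpha=%.3f beta=%.3f var_eta=%.4g var_eps=%.4g mu=%.3f\n",
    x$rho, x$alpha, x$beta, x$var_eta, x$var_eps, x$mu))
  invisible(x)
}

#' Bernoulli offset from chance probability
#'
#' `mu = log(p_chance / (1 - p_chance))`, so that the logistic observation
#' model yields exactly `p_chance` at the resting state `x = 0`. The
#' chance probability is the fraction of the combined training and
#' validation duration labeled as seizure.
#'
#' @param p_chance probability in (0, 1), exclusive.
#' @return The logit of `p_chance`.
#' @export
mu_from_chance <- function(p_chance) {
  if (!is.numeric(p_chance) || length(p_chance) != 1 ||
      !is.finite(p_chance) || p_chance <= 0 || p_chance >= 1)
    stop("p_chance must lie strictly inside (0, 1)")
  stats::qlogis(p_chance)
}

#' Seizure probability from the latent state
#'
#' Overflow-safe logistic transform `exp(mu + x) / (1 + exp(mu + x))`,
#' clamped into the open interval (0, 1).
#'
#' @param mu Bernoulli offset.
#' @param x latent state value(s).
#' @return Probabilities strictly inside (0, 1).
#' @export
logistic_prob <- function(mu, x) {
  eps <- .Machine$double.eps
  pmin(pmax(stats::plogis(mu + x), eps), 1 - eps)
}

#' Simulate from the mixed observation model
#'
#' Draws a latent AR(1) trajectory started from its stationary
#' distribution `N(0, var_eta / (1 - rho^2))` (unless `x0` is forced) and
#' the paired continuous and binary observations.
#'
#' @param params a [mixed_params()].
#' @param K number of steps.
#' @param seed integer seed (the caller's RNG state is restored).
#' @param x0 optional fixed initial state overriding the stationary draw.
#' @return List with numeric vectors `x`, `v` and integer vector `lambda`.
#' @export
simulate_mixed <- function(params, K, seed = NULL, x0 = NULL) {
  stopifnot(K >= 1)
  with_seed(seed, {
    x <- numeric(K)
    xp <- if (is.null(x0))
      rnorm(1, 0, sqrt(params$var_eta / (1 - params$rho^2))) else x0
    eta <- rnorm(K, 0, sqrt(params$var_eta))
    for (k in seq_len(K)) {
      xp <- params$rho * xp + eta[k]
      x[k] <- xp
    }
    v <- params$alpha + params$beta * x + rnorm(K, 0, sqrt(params$var_eps))
    lambda <- rbinom(K, 1, logistic_prob(params$mu, x))
    list(x = x, v = v, lambda = lambda)
  })
}

#' Causal forward mixed filter
#'
#' One-step-ahead prediction `x_{k|k-1} = rho x_{k-1|k-1}`,
#' `var_{k|k-1} = rho^2 var_{k-1|k-1} + var_eta`, followed by the
#' posterior-mode update: `x_{k|k}` solves
#' `x = x_{k|k-1} + var_{k|k-1} [ (beta/var_eps)(v_k - alpha - beta x) +
#' (lambda_k - logistic(mu + x)) ]` (Newton-Raphson with a bisection
#' fallback; the equation has a unique root), and
#' `var_{k|k} = [1/var_{k|k-1} + beta^2/var_eps + p(1-p)]^-1` with `p`
#' evaluated at the mode. Strictly causal: no future sample influences
#' step `k`.
#'
#' @param v continuous observation series (dB scale).
#' @param lambda binary observation series (0/1), same length as `v`.
#' @param params a [mixed_params()].
#' @param x0,var0 initial state mean and variance; defaults are 0 and the
#'   stationary variance `var_eta / (1 - rho^2)`.
#' @return An object of class `"estimation_track"` with vectors `x_pred`,
#'   `var_pred`, `x_filt`, `var_filt`, `p`.
#' @export
forward_filter <- function(v, lambda, params, x0 = 0,
                           var0 = params$var_eta / (1 - params$rho^2)) {
  stopifnot(length(v) == length(lambda), length(v) >= 1,
            all(lambda %in% c(0, 1)))
  out <- mixed_forward_cpp(as.numeric(v), as.numeric(lambda),
                           params$rho, params$alpha, params$beta,
                           params$var_eta, params$var_eps, params$mu,
                           x0, var0)
  structure(out, class = "estimation_track")
}

#' @export
print.estimation_track <- function(x, ...) {
  cat(sprintf("<estimation_track> %d steps, final x=%.3f (var %.3g), p=%.3f\n",
              length(x$x_filt), tail(x$x_filt, 1), tail(x$var_filt, 1),
              tail(x$p, 1)))
  invisible(x)
}

#' Fixed-interval smoother for a mixed-filter track
#'
#' RTS-form backward pass over the forward-filter output:
#' `x_{k|K} = x_{k|k} + s_k (x_{k+1|K} - x_{k+1|k})` with
#' `s_k = rho var_{k|k} / var_{k+1|k}` and the matching variance
#' recursion. Used only inside EM on training data; it is not causal.
#'
#' @param track an [forward_filter()] result.
#' @param params the [mixed_params()] used to produce it.
#' @return List with `x_smooth`, `var_smooth` and the smoothing `gain`
#'   sequence (`gain[k] = s_k`; the lag-one smoothed covariance is
#'   `gain[k] * var_smooth[k+1]`).
#' @export
mixed_smooth <- function(track, params) {
  mixed_smooth_cpp(track$x_filt, track$var_filt,
                   track$x_pred, track$var_pred, params$rho)
}

# Gaussian part of the expected complete-data log-likelihood under the
# posterior moments (m, M = m^2 + var, W = lag-one second moment). The
# Bernoulli term is independent of the M-step parameters (mu is pinned)
# and cancels from per-iteration comparisons.
q_gaussian <- function(theta, v, m, M, W) {
  K <- length(v)
  trans <- M[-1] - 2 * theta$rho * W + theta$rho^2 * M[-K]
  obs <- (v - theta$alpha - theta$beta * m)^2 + theta$beta^2 * (M - m^2)
  -0.5 * (K - 1) * log(2 * pi * theta$var_eta) -
    sum(trans) / (2 * theta$var_eta) -
    0.5 * K * log(2 * pi * theta$var_eps) -
    sum(obs) / (2 * theta$var_eps)
}

#' EM parameter estimation for one mixed estimation
#'
#' Alternates an E-step (forward filter plus fixed-interval smoother,
#' Gaussian approximation at the posterior mode) with closed-form M-step
#' updates of `rho`, `alpha`, `beta`, `var_eta` and `var_eps` from the
#' smoothed first and second moments. The Bernoulli offset `mu` is pinned
#' at `mu_from_chance(p_chance)` throughout and never re-estimated. The
#' gain `beta` is constrained positive (the joint sign of `(beta, x)` is
#' not identifiable from the Gaussian channel); its sign is flipped at the
#' end of an M-step if needed.
#'
#' @param v,lambda observation series as in [forward_filter()].
#' @param p_chance chance probability pinning `mu`.
#' @param init optional initial [mixed_params()]; default `rho = 0.9`,
#'   `alpha = mean(v)`, `beta = 1`, `var_eps = var(v)/2`, `var_eta = 0.1`.
#' @param tol relative-change stopping tolerance (default `1e-4`).
#' @param max_iter maximum EM iterations (default 200).
#' @return List of class `"mixed_fit"`: `params` (fitted
#'   [mixed_params()]), `track` (final [forward_filter()] output),
#'   `n_iter`, and `q_steps` — a data frame with the Gaussian part of the
#'   expected complete-data log-likelihood before (`q_old`) and after
#'   (`q_new`) each M-step under that iteration's posterior moments.
#' @export
em_fit_mixed <- function(v, lambda, p_chance, init = NULL, tol = 1e-4,
                         max_iter = 200) {
  v <- as.numeric(v); lambda <- as.numeric(lambda)
  stopifnot(length(v) == length(lambda), length(v) >= 3)
  mu <- mu_from_chance(p_chance)
  if (is.null(init))
    init <- mixed_params(rho = 0.9, alpha = mean(v), beta = 1,
                         var_eta = 0.1,
                         var_eps = max(stats::var(v) / 2, 1e-8), mu = mu)
  theta <- init
  theta$mu <- mu
  K <- length(v)
  q_old <- numeric(0); q_new <- numeric(0)
  n_iter <- 0

  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    track <- forward_filter(v, lambda, theta)
    sm <- mixed_smooth(track, theta)
    m <- sm$x_smooth
    M <- m^2 + sm$var_smooth
    W <- m[-K] * m[-1] + sm$gain[-K] * sm$var_smooth[-1]

    rho_new <- sum(W) / sum(M[-K])
    rho_new <- min(max(rho_new, 1e-6), 1 - 1e-6)
    var_eta_new <- sum(M[-1] - 2 * rho_new * W + rho_new^2 * M[-K]) / (K - 1)
    den <- K * sum(M) - sum(m)^2
    beta_new <- (K * sum(v * m) - sum(v) * sum(m)) / den
    if (beta_new < 0) beta_new <- -beta_new
    alpha_new <- (sum(v) - beta_new * sum(m)) / K
    var_eps_new <- sum((v - alpha_new - beta_new * m)^2 +
                         beta_new^2 * sm$var_smooth) / K
    var_eta_new <- max(var_eta_new, 1e-12)
    var_eps_new <- max(var_eps_new, 1e-12)

    new <- list(rho = rho_new, alpha = alpha_new, beta = beta_new,
                var_eta = var_eta_new, var_eps = var_eps_new, mu = mu)
    if (!all(vapply(new, is.finite, logical(1))))
      stop("EM diverged (non-finite parameter) at iteration ", iter)
    q_old[iter] <- q_gaussian(theta, v, m, M, W)
    q_new[iter] <- q_gaussian(new, v, m, M, W)

    rel <- max(abs(unlist(new[1:5]) - unlist(theta[1:5])) /
                 (abs(unlist(theta[1:5])) + 1e-8))
    theta <- structure(new, class = "mixed_params")
    if (rel < tol) break
  }

  structure(list(params = theta,
                 track = forward_filter(v, lambda, theta),
                 n_iter = n_iter,
                 q_steps = data.frame(q_old = q_old, q_new = q_new)),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> converged in %d EM iteration(s)\n", x$n_iter))
  print(x$params)
  invisible(x)
}
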