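#' Parameters of the combined-state model
#'
#' The scalar combined seizure state evolves as `z_k = A z_{k-1} +
#' omega_k`, `omega_k ~ N(0, var_omega)`, and the stacked vector of the N
#' per-estimation filtered states is observed as `x_k = B + C z_k +
#' nu_k`, `nu_k ~ N(0, cov_nu)`.
#'
#' @param A state transition scalar (stable defaults have `|A| < 1`).
#' @param B bias vector of length N.
#' @param C measurement gain vector of length N.
#' @param var_omega process-noise variance (> 0).
#' @param cov_nu measurement-noise covariance: an N x N symmetric
#'   positive-definite matrix, or a length-N vector taken as its diagonal.
#' @return An object of class `"combiner_params"`.
#' @export
combiner_params <- function(A, B, C, var_omega, cov_nu) {
  B <- as.numeric(B); C <- as.numeric(C)
  N <- length(B)
  stopifnot(length(C) == N, is.finite(A), var_omega > 0)
  if (is.vector(cov_nu) && !is.matrix(cov_nu)) {
    stopifnot(length(cov_nu) %in% c(1L, N))
    cov_nu <- diag(rep(as.numeric(cov_nu), length.out = N), N)
  }
  cov_nu <- as.matrix(cov_nu)
  stopifnot(nrow(cov_nu) == N, ncol(cov_nu) == N)
  if (max(abs(cov_nu - t(cov_nu))) > 1e-8 * max(abs(cov_nu), 1))
    stop("cov_nu must be symmetric")
  cov_nu <- (cov_nu + t(cov_nu)) / 2
  ev <- min(eigen(cov_nu, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("cov_nu must be positive definite")
  structure(list(A = A, B = B, C = C, var_omega = var_omega,
                 cov_nu = cov_nu, N = N),
            class = "combiner_params")
}

#' @export
print.combiner_params <- function(x, ...) {
  cat(sprintf("<combiner_params> N=%d, A=%.4f, var_omega=%.4g\n",
              x$N, x$A, x$var_omega))
  cat("  B:", paste(sprintf("%.3f", x$B), collapse = " "), "\n")
  cat("  C:", paste(sprintf("%.3f", x$C), collapse = " "), "\n")
  invisible(x)
}

stationary_var <- function(A, Q) if (abs(A) < 1) Q / (1 - A^2) else 1

#' Simulate from the combined-state model
#'
#' @param params a [combiner_params()].
#' @param K number of steps.
#' @param seed integer seed (the caller's RNG state is restored).
#' @param z0 optional fixed initial state; default draws from the
#'   stationary distribution (variance `var_omega / (1 - A^2)` for
#'   `|A| < 1`, else 1).
#' @return List with `z` (length K) and `X` (N x K observation matrix).
#' @export
simulate_combined <- function(params, K, seed = NULL, z0 = NULL) {
  stopifnot(K >= 1)
  with_seed(seed, {
    zp <- if (is.null(z0))
      rnorm(1, 0, sqrt(stationary_var(params$A, params$var_omega))) else z0
    z <- numeric(K)
    om <- rnorm(K, 0, sqrt(params$var_omega))
    for (k in seq_len(K)) {
      zp <- params$A * zp + om[k]
      z[k] <- zp
    }
    L <- t(chol(params$cov_nu))
    noise <- L %*% matrix(rnorm(params$N * K), params$N, K)
    X <- params$B + outer(params$C, z) + noise
    list(z = z, X = X)
  })
}

#' Square-root Kalman filter for the combined state
#'
#' Standard Kalman predict/update carried entirely in square-root
#' (Cholesky-factor) form. Each measurement update triangularizes the
#' stacked pre-array `[L_R, C s_pred; 0, s_pred]` by QR, with the sign
#' convention that the post-array factor has a non-negative diagonal, so
#' the reconstructed state-error covariance is symmetric non-negative by
#' construction even when `cov_nu` is badly conditioned. Algebraically
#' equivalent to the covariance-form filter.
#'
#' @param X N x K matrix of per-estimation state tracks (one row per
#'   estimation).
#' @param params a [combiner_params()].
#' @param z0,var0 prior mean and variance of the first state; defaults 0
#'   and the stationary variance.
#' @return An object of class `"combined_track"` with `z_filt`, `z_pred`
#'   and `sqrt_cov` (the per-step scalar factor `s_k`, `Sigma_k = s_k^2`).
#' @export
sqrt_kalman_filter <- function(X, params, z0 = 0,
                               var0 = stationary_var(params$A, params$var_omega)) {
  X <- as.matrix(X)
  N <- params$N
  if (nrow(X) != N)
    stop("X must have one row per estimation (expected ", N, ")")
  K <- ncol(X)
  L_R <- tryCatch(t(chol(params$cov_nu)),
                  error = function(e) stop("cov_nu is not positive definite"))
  z_filt <- numeric(K); z_pred <- numeric(K); s_filt <- numeric(K)
  zp <- z0; sp <- sqrt(var0)
  for (k in seq_len(K)) {
    if (k > 1) {
      zp <- params$A * z_filt[k - 1]
      # scalar-state prediction in factor form
      sp <- sqrt((params$A * s_filt[k - 1])^2 + params$var_omega)
    }
    z_pred[k] <- zp
    pre <- rbind(cbind(L_R, params$C * sp),
                 c(rep(0, N), sp))
    post <- t(qr.R(qr(t(pre))))
    sgn <- sign(diag(post)); sgn[sgn == 0] <- 1
    post <- sweep(post, 2, sgn, `*`)
    L_S <- post[1:N, 1:N, drop = FALSE]
    G <- post[N + 1, 1:N]
    e <- X[, k] - params$B - params$C * zp
    z_filt[k] <- zp + sum(G * forwardsolve(L_S, e))
    s_filt[k] <- abs(post[N + 1, N + 1])
  }
  structure(list(z_filt = z_filt, z_pred = z_pred, sqrt_cov = s_filt),
            class = "combined_track")
}

#' @export
print.combined_track <- function(x, ...) {
  cat(sprintf("<combined_track> %d steps, final z=%.3f (sd %.3g)\n",
              length(x$z_filt), tail(x$z_filt, 1), tail(x$sqrt_cov, 1)))
  invisible(x)
}

# Exact scalar-state Kalman filter in information form. The innovation
# covariance is handled by Woodbury/determinant-lemma identities so the
# per-step cost does not involve an N x N solve. Returns filtered and
# predicted moments plus the exact innovations log-likelihood.
kalman_scalar <- function(X, params, z1_mean = 0, P1 = NULL) {
  A <- params$A; B <- params$B; C <- params$C
  Q <- params$var_omega; R <- params$cov_nu
  N <- params$N; K <- ncol(X)
  if (is.null(P1)) P1 <- stationary_var(A, Q)
  L_R <- t(chol(R))
  E0 <- X - B                                  # N x K
  W <- forwardsolve(L_R, E0)                   # L^-1 (x - B)
  Rc <- forwardsolve(L_R, C)
  cRc <- sum(Rc^2)                             # C' R^-1 C
  U <- as.numeric(crossprod(Rc, W))            # C' R^-1 (x_k - B)
  eRe <- colSums(W^2)
  logdetR <- 2 * sum(log(diag(L_R)))

  P_pred <- numeric(K); P_filt <- numeric(K)
  z_pred <- numeric(K); z_filt <- numeric(K)
  pp <- P1
  for (k in seq_len(K)) {
    if (k > 1) pp <- A^2 * P_filt[k - 1] + Q
    P_pred[k] <- pp
    P_filt[k] <- 1 / (1 / pp + cRc)
  }
  zp <- z1_mean
  for (k in seq_len(K)) {
    if (k > 1) zp <- A * z_filt[k - 1]
    z_pred[k] <- zp
    z_filt[k] <- P_filt[k] * (zp / P_pred[k] + U[k])
  }
  # innovations likelihood: e'S^-1 e and log|S| via the scalar-state identities
  cRe <- U - cRc * z_pred
  quad <- eRe - 2 * z_pred * U + cRc * z_pred^2 -
    P_pred * cRe^2 / (1 + P_pred * cRc)
  logdetS <- logdetR + log1p(P_pred * cRc)
  ll <- -0.5 * sum(N * log(2 * pi) + logdetS + quad)
  list(z_pred = z_pred, P_pred = P_pred, z_filt = z_filt, P_filt = P_filt,
       loglik = ll)
}

# RTS smoother for the scalar-state filter output.
rts_scalar <- function(kf, A) {
  K <- length(kf$z_filt)
  z_sm <- numeric(K); V_sm <- numeric(K); gain <- rep(NA_real_, K)
  z_sm[K] <- kf$z_filt[K]; V_sm[K] <- kf$P_filt[K]
  for (k in rev(seq_len(K - 1))) {
    s <- A * kf$P_filt[k] / kf$P_pred[k + 1]
    z_sm[k] <- kf$z_filt[k] + s * (z_sm[k + 1] - kf$z_pred[k + 1])
    V_sm[k] <- kf$P_filt[k] + s^2 * (V_sm[k + 1] - kf$P_pred[k + 1])
    gain[k] <- s
  }
  list(z_smooth = z_sm, var_smooth = V_sm, gain = gain)
}

#' Linear-Gaussian EM for the combiner parameters
#'
#' Estimates `(A, B, C, var_omega, cov_nu)` by exact linear-Gaussian EM:
#' the E-step runs the (algebraically exact) Kalman filter and RTS
#' smoother, the M-step updates all five blocks in closed form from the
#' smoothed moments. The exact innovations log-likelihood is
#' non-decreasing at every iteration.
#'
#' Identifiability: `(C, z)` are jointly scale- and sign-unidentifiable,
#' so after each M-step the model is rescaled to the convention
#' `||C||_2 = sqrt(N)` with `sum(C) >= 0` (a likelihood-invariant
#' reparameterization). The prior variance of the first state is frozen
#' at its value under the initial parameters (rescaled with the
#' convention), which keeps the EM ascent exact.
#'
#' @param X N x K matrix of estimation tracks.
#' @param init optional initial [combiner_params()]; the default uses
#'   `A = 0.9`, `B` = row means, `C` = the first principal direction of
#'   the row-centered data (scaled to the convention), a diagonal
#'   residual-variance `cov_nu`, and `var_omega = 0.1`.
#' @param tol relative-change stopping tolerance (default `1e-4`).
#' @param max_iter maximum EM iterations (default 200).
#' @param diagonal_cov if `TRUE`, constrain `cov_nu` to be diagonal.
#' @return List of class `"combiner_fit"`: `params`, `loglik` (exact
#'   log-likelihood at the start of each iteration, plus the final fit),
#'   `n_iter`, `z_smooth`.
#' @export
em_fit_combiner <- function(X, init = NULL, tol = 1e-4, max_iter = 200,
                            diagonal_cov = FALSE) {
  X <- as.matrix(X)
  N <- nrow(X); K <- ncol(X)
  if (K <= N) stop("need more time steps than estimations (K > N)")
  if (is.null(init)) {
    B0 <- rowMeans(X)
    Xc <- X - B0
    C0 <- svd(Xc, nu = 1, nv = 0)$u[, 1]
    C0 <- C0 * sqrt(N) / sqrt(sum(C0^2))
    if (sum(C0) < 0) C0 <- -C0
    resid_var <- pmax(apply(Xc, 1, stats::var) / 2, 1e-6)
    init <- combiner_params(A = 0.9, B = B0, C = C0, var_omega = 0.1,
                            cov_nu = resid_var)
  }
  theta <- init
  P1 <- stationary_var(theta$A, theta$var_omega)
  ll <- numeric(0)

  for (iter in seq_len(max_iter)) {
    kf <- kalman_scalar(X, theta, z1_mean = 0, P1 = P1)
    if (!is.finite(kf$loglik))
      stop("combiner EM produced a non-finite likelihood at iteration ", iter)
    ll[iter] <- kf$loglik
    sm <- rts_scalar(kf, theta$A)
    m <- sm$z_smooth
    M <- m^2 + sm$var_smooth
    W <- m[-K] * m[-1] + sm$gain[-K] * sm$var_smooth[-1]

    A_new <- sum(W) / sum(M[-K])
    if (abs(A_new) >= 1) A_new <- sign(A_new) * (1 - 1e-6)
    Q_new <- sum(M[-1] - 2 * A_new * W + A_new^2 * M[-K]) / (K - 1)
    sm_sum <- sum(m); sM <- sum(M)
    den <- sM - sm_sum^2 / K
    C_new <- (as.numeric(X %*% m) - rowSums(X) * sm_sum / K) / den
    B_new <- rowMeans(X) - C_new * mean(m)
    Ec <- X - B_new - outer(C_new, m)
    R_new <- (tcrossprod(Ec) + sum(sm$var_smooth) * tcrossprod(C_new)) / K
    R_new <- (R_new + t(R_new)) / 2
    if (diagonal_cov) R_new <- diag(diag(R_new), N)

    # likelihood-invariant rescale to the identifiability convention
    sc <- sqrt(sum(C_new^2)) / sqrt(N)
    if (sc > 0) {
      C_new <- C_new / sc
      Q_new <- Q_new * sc^2
      P1_new <- P1 * sc^2
    } else P1_new <- P1
    if (sum(C_new) < 0 ||
        (abs(sum(C_new)) < 1e-12 && C_new[which.max(abs(C_new))] < 0))
      C_new <- -C_new
    Q_new <- max(Q_new, 1e-12)

    old_vec <- c(theta$A, theta$B, theta$C, theta$var_omega, diag(theta$cov_nu))
    new_vec <- c(A_new, B_new, C_new, Q_new, diag(R_new))
    theta <- combiner_params(A_new, B_new, C_new, Q_new, R_new)
    P1 <- P1_new
    if (max(abs(new_vec - old_vec) / (abs(old_vec) + 1e-8)) < tol) break
  }
  kf <- kalman_scalar(X, theta, z1_mean = 0, P1 = P1)
  ll <- c(ll, kf$loglik)
  sm <- rts_scalar(kf, theta$A)
  structure(list(params = theta, loglik = ll, n_iter = length(ll) - 1,
                 z_smooth = sm$z_smooth, prior_var = P1),
            class = "combiner_fit")
}

#' @export
print.combiner_fit <- function(x, ...) {
  cat(sprintf("<combiner_fit> %d EM iteration(s), final loglik %.2f\n",
              x$n_iter, tail(x$loglik, 1)))
  print(x$params)
  invisible(x)
}
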