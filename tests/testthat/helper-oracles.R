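# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths they validate: the DFT is
# summed term by term, the Kalman/RTS/EM oracles use the textbook
# covariance-form recursions, and the posterior mode is found by dense
# grid search.

# band power by direct DFT-bin summation (no fft())
oracle_band_power <- function(x, fs, f_lo, f_hi) {
  L <- length(x)
  t <- 0:(L - 1)
  total <- 0
  for (j in 0:(L - 1)) {
    f <- j * fs / L
    if (f <= fs / 2 && f >= f_lo && f < f_hi) {
      re <- sum(x * cos(2 * pi * j * t / L))
      im <- -sum(x * sin(2 * pi * j * t / L))
      total <- total + re^2 + im^2
    }
  }
  total
}

# argmax over a dense grid of the one-step posterior of the mixed filter
oracle_grid_mode <- function(x_pred, var_pred, v, lam, alpha, beta,
                             var_eps, mu, lo = -10, hi = 10, by = 1e-4) {
  x <- seq(lo, hi, by = by)
  lp <- -(x - x_pred)^2 / (2 * var_pred) -
    (v - alpha - beta * x)^2 / (2 * var_eps) +
    lam * (mu + x) - log1p(exp(mu + x))
  x[which.max(lp)]
}

# textbook scalar linear-Gaussian Kalman filter (covariance form)
oracle_kf_lg <- function(y, rho, alpha, beta, var_eta, var_eps, x0, var0) {
  K <- length(y)
  xp <- vp <- xf <- vf <- numeric(K)
  mx <- x0; Px <- var0
  for (k in seq_len(K)) {
    mx <- rho * mx; Px <- rho^2 * Px + var_eta
    xp[k] <- mx; vp[k] <- Px
    S <- beta^2 * Px + var_eps
    G <- Px * beta / S
    mx <- mx + G * (y[k] - alpha - beta * mx)
    Px <- (1 - G * beta) * Px
    xf[k] <- mx; vf[k] <- Px
  }
  list(x_pred = xp, var_pred = vp, x_filt = xf, var_filt = vf)
}

oracle_rts_lg <- function(kf, rho) {
  K <- length(kf$x_filt)
  xs <- numeric(K); vs <- numeric(K); gain <- rep(NA_real_, K)
  xs[K] <- kf$x_filt[K]; vs[K] <- kf$var_filt[K]
  for (k in rev(seq_len(K - 1))) {
    s <- rho * kf$var_filt[k] / kf$var_pred[k + 1]
    xs[k] <- kf$x_filt[k] + s * (xs[k + 1] - kf$x_pred[k + 1])
    vs[k] <- kf$var_filt[k] + s^2 * (vs[k + 1] - kf$var_pred[k + 1])
    gain[k] <- s
  }
  list(x_smooth = xs, var_smooth = vs, gain = gain)
}

# textbook linear-Gaussian EM (Shumway-Stoffer closed forms) mirroring the
# package's conventions: x0 = 0 fixed, stationary prior variance under the
# current parameters, transition sums over k = 2..K, beta kept positive.
oracle_em_lg <- function(y, rho, alpha, beta, var_eta, var_eps, n_iter) {
  K <- length(y)
  for (i in seq_len(n_iter)) {
    kf <- oracle_kf_lg(y, rho, alpha, beta, var_eta, var_eps,
                       0, var_eta / (1 - rho^2))
    sm <- oracle_rts_lg(kf, rho)
    m <- sm$x_smooth
    M <- m^2 + sm$var_smooth
    W <- m[-K] * m[-1] + sm$gain[-K] * sm$var_smooth[-1]
    rho <- min(max(sum(W) / sum(M[-K]), 1e-6), 1 - 1e-6)
    var_eta <- max(sum(M[-1] - 2 * rho * W + rho^2 * M[-K]) / (K - 1), 1e-12)
    den <- K * sum(M) - sum(m)^2
    beta <- (K * sum(y * m) - sum(y) * sum(m)) / den
    if (beta < 0) beta <- -beta
    alpha <- (sum(y) - beta * sum(m)) / K
    var_eps <- max(sum((y - alpha - beta * m)^2 +
                         beta^2 * sm$var_smooth) / K, 1e-12)
  }
  list(rho = rho, alpha = alpha, beta = beta, var_eta = var_eta,
       var_eps = var_eps)
}

# textbook covariance-form Kalman filter for the scalar-state / vector-
# observation combiner model
oracle_kf_vec <- function(X, A, B, C, Q, R, z0, P0) {
  K <- ncol(X); N <- nrow(X)
  zf <- numeric(K); Pf <- numeric(K)
  mz <- z0; Pz <- P0
  for (k in seq_len(K)) {
    if (k > 1) { mz <- A * zf[k - 1]; Pz <- A^2 * Pf[k - 1] + Q }
    S <- Pz * tcrossprod(C) + R
    G <- Pz * solve(S, C)
    e <- X[, k] - B - C * mz
    zf[k] <- mz + sum(G * e)
    Pf[k] <- Pz - Pz * sum(G * C)
  }
  list(z_filt = zf, P_filt = Pf)
}

# exhaustive first-iteration wrapper selection (uses the package's own LDA
# and F1, enumerating instead of greedy bookkeeping)
oracle_exhaustive_first <- function(train, val) {
  score_pool <- function(pool_tr, pool_va, extra_tr = NULL, extra_va = NULL) {
    f1s <- vapply(names(pool_tr), function(id) {
      m <- suppressWarnings(
        fit_lda(cbind(extra_tr, pool_tr[[id]]$values), train$labels))
      f1_score(predict(m, cbind(extra_va, pool_va[[id]]$values)), val$labels)
    }, numeric(1))
    names(which.max(f1s))  # ties: first index, same as the tie-break rule
  }
  cont <- score_pool(train$cont, val$cont)
  ctr <- matrix(train$cont[[cont]]$values, ncol = 1)
  cva <- matrix(val$cont[[cont]]$values, ncol = 1)
  bin <- score_pool(train$bin, val$bin, ctr, cva)
  c(cont = cont, bin = bin)
}

# cost-weighted empirical risk of a 1-D threshold rule (grid search)
oracle_best_threshold <- function(x, labels, cost_miss, cost_fa) {
  cand <- sort(unique(x))
  thr <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
           cand[length(cand)] + 1)
  risk <- vapply(thr, function(t) {
    pred <- as.integer(x > t)
    cost_miss * sum(pred == 0 & labels == 1) +
      cost_fa * sum(pred == 1 & labels == 0)
  }, numeric(1))
  thr[which.min(risk)]
}
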