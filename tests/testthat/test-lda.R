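test_that("F1 matches hand arithmetic and its edge conventions", {
  expect_equal(f1_score(c(0, 1, 1), c(0, 1, 1)), 1)
  # precision 0.5, recall 0.5: TP=1, FP=1, FN=1
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  # TP=3, FP=1, FN=2 -> 2*0.45/1.35
  expect_equal(f1_score(c(1, 1, 1, 1, 0, 0, 0),
                        c(1, 1, 1, 0, 1, 1, 0)), 2 * 0.45 / 1.35,
               tolerance = 1e-12)
  expect_equal(f1_score(c(0, 0), c(1, 1)), 0)  # precision+recall undefined
})

test_that("equal-cost balanced 1-D LDA puts the threshold at the class-mean midpoint", {
  with_seed(41, {
    x <- c(rnorm(500, 0), rnorm(500, 10))
    lab <- rep(c(0L, 1L), each = 500)
    m <- fit_lda(matrix(x, ncol = 1), lab, cost_ratio = 1)
    thr <- -m$bias / m$weight
    mid <- (mean(x[lab == 0]) + mean(x[lab == 1])) / 2
    expect_equal(thr, mid, tolerance = 1e-8)
    expect_error(fit_lda(matrix(x, ncol = 1), rep(1L, 1000)), "both classes")
  })
})

test_that("doubling the seizure cost lowers the threshold, matching the grid-risk oracle", {
  with_seed(42, {
    x <- c(rnorm(400, 0), rnorm(400, 10))
    lab <- rep(c(0L, 1L), each = 400)
    m1 <- fit_lda(matrix(x, ncol = 1), lab, cost_ratio = 1)
    m2 <- fit_lda(matrix(x, ncol = 1), lab, cost_ratio = 2)
    thr1 <- -m1$bias / m1$weight
    thr2 <- -m2$bias / m2$weight
    expect_lt(thr2, thr1)
    expect_lt(thr2, 5 + 0.3)
    # the cost-weighted empirical-risk minimizer moves the same way
    o1 <- oracle_best_threshold(x, lab, 1, 1)
    o2 <- oracle_best_threshold(x, lab, 2, 1)
    expect_lte(o2, o1)
    expect_lt(abs(thr2 - o2), 1)
  })
})

test_that("fit_lda direction agrees with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  with_seed(43, {
    n <- 400
    lab <- rbinom(n, 1, 0.3)
    X <- matrix(rnorm(n * 3), n, 3)
    X[lab == 1, ] <- X[lab == 1, ] + matrix(rep(c(1, 2, -1), each = sum(lab)),
                                            ncol = 3)
    ours <- fit_lda(X, lab, cost_ratio = 1)
    ref <- MASS::lda(X, grouping = lab)
    cosine <- sum(ours$weight * ref$scaling) /
      sqrt(sum(ours$weight^2) * sum(ref$scaling^2))
    expect_gt(abs(cosine), 1 - 1e-6)
  })
})

test_that("LDA predictions are invariant to affine rescaling of a feature column", {
  with_seed(44, {
    n <- 300
    lab <- rep(c(0L, 1L), length.out = n)
    X <- matrix(rnorm(n * 2), n, 2) + lab * 2
    m <- fit_lda(X, lab)
    X2 <- X; X2[, 1] <- X2[, 1] * 37.5 - 11
    m2 <- fit_lda(X2, lab)
    expect_equal(predict(m, X), predict(m2, X2), tolerance = 1e-8)
  })
})

test_that("degenerate and singular fits are handled with warnings, not failures", {
  lab <- rep(c(0L, 1L), each = 20)
  expect_warning(m <- fit_lda(matrix(5, 40, 1), lab), "degenerate")
  expect_identical(predict(m, matrix(5, 40, 1)), rep(0L, 40))
  # duplicated column -> singular pooled covariance
  with_seed(45, {
    x <- rnorm(40) + lab
    expect_warning(ms <- fit_lda(cbind(x, x), lab), "singular|degenerate")
    expect_true(all(is.finite(ms$weight)))
  })
})

test_that("binarization reproduces a label-valued feature and separates two Gaussians", {
  with_seed(46, {
    g <- make_gaussian_feature(5000, p_pos = 0.2, mean0 = 0, mean1 = 10,
                               sd = 1, seed = 46)
    out <- binarize_feature(g$values, g$labels)
    expect_true(all(out$series$values %in% c(0, 1)))
    expect_gte(mean(out$series$values == g$labels), 0.99)

    # a label-valued feature is constant within classes: ridge path + warning
    expect_warning(ident <- binarize_feature(as.numeric(g$labels), g$labels),
                   "degenerate")
    expect_identical(as.integer(ident$series$values), g$labels)

    expect_warning(cz <- binarize_feature(rep(1, 100),
                                          rep(c(0L, 1L), 50)), "degenerate")
    expect_identical(cz$series$values, rep(0, 100))
  })
})

test_that("greedy wrapper matches exhaustive first-iteration search on random pools", {
  for (seed in 1:5) {
    with_seed(seed + 100, {
      n <- 400
      lab_tr <- rbinom(n, 1, 0.25)
      lab_va <- rbinom(n, 1, 0.25)
    })
    qual <- with_seed(seed + 200, runif(8, 0, 0.9))
    train <- list(cont = make_pools(400, lab_tr, qual, seed + 300),
                  bin = make_pools(400, lab_tr, rev(qual), seed + 400),
                  labels = lab_tr)
    val <- list(cont = make_pools(400, lab_va, qual, seed + 500),
                bin = make_pools(400, lab_va, rev(qual), seed + 600),
                labels = lab_va)
    sel <- wrapper_select(train, val, N = 1)
    ex <- oracle_exhaustive_first(train, val)
    expect_identical(sel$pairs$cont_id[1], unname(ex["cont"]))
    expect_identical(sel$pairs$bin_id[1], unname(ex["bin"]))
  }
})

test_that("forced single-candidate pools and perfect features behave as expected", {
  n <- 200
  lab <- rep(c(0L, 1L), each = n / 2)
  perfect <- feature_series(as.numeric(lab), "CH1", "Delta", "power", 1)
  noise <- feature_series(runif(n), "CH2", "Delta", "power", 1)

  one <- list(cont = list(`CH1|Delta|db` = perfect),
              bin = list(`CH2|Delta|power` = noise), labels = lab)
  sel <- wrapper_select(one, one, N = 1)
  expect_identical(sel$pairs$cont_id, "CH1|Delta|db")
  expect_identical(sel$pairs$bin_id, "CH2|Delta|power")

  multi <- list(cont = list(`CH1|Delta|db` = noise, `CH2|Theta|db` = perfect),
                bin = list(`CH1|Delta|power` = noise,
                           `CH2|Theta|power` = perfect),
                labels = lab)
  sel2 <- wrapper_select(multi, multi, N = 1)
  expect_identical(sel2$pairs$cont_id[1], "CH2|Theta|db")
  expect_equal(sel2$f1_trajectory[1], 1)
})

test_that("selected features are removed from their pools (no reselection)", {
  n <- 200
  lab <- rep(c(0L, 1L), each = n / 2)
  mk <- function(q, ch) feature_series(q * lab + with_seed(ch, runif(n)),
                                       paste0("CH", ch), "Delta", "power", 1)
  pools <- list(cont = list(a = mk(3, 1), b = mk(2, 2), c = mk(1, 3)),
                bin = list(d = mk(3, 4), e = mk(2, 5), f = mk(1, 6)),
                labels = lab)
  sel <- wrapper_select(pools, pools, N = 3)
  expect_equal(nrow(sel$pairs), 3)
  expect_false(any(duplicated(sel$pairs$cont_id)))
  expect_false(any(duplicated(sel$pairs$bin_id)))
})
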