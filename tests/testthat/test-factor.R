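test_that("profile extraction matches the equicorrelation closed form", {
  n <- 5000
  for (r in c(0.3, 0.6889)) {
    R <- matrix(r, 3, 3); diag(R) <- 1
    Z <- exact_cor_data(n, R, seed = 1)
    pr <- extract_profile(as.data.frame(Z))
    expect_equal(pr$variance_explained, 100 * (1 + 2 * r) / 3,
                 tolerance = 1e-8)
  }
  # exactly uncorrelated columns: one third each
  Z0 <- exact_cor_data(n, diag(3), seed = 2)
  expect_equal(extract_profile(Z0)$variance_explained, 100 / 3,
               tolerance = 1e-8)
  # perfectly collinear columns: all the variance
  z <- rnorm(500)
  expect_equal(extract_profile(cbind(z, 2 * z, -z))$variance_explained, 100)
})

test_that("profile scores are standardized with positive loadings", {
  set.seed(2)
  Y <- matrix(rnorm(600), 200, 3) %*% chol(matrix(c(1, .5, .5, .5, 1, .5,
                                                    .5, .5, 1), 3))
  pr <- extract_profile(Y)
  s <- pr$factor_scores[, 1]
  expect_lt(abs(mean(s)), 1e-8)
  expect_equal(var(s), 1, tolerance = 1e-8)
  expect_true(all(pr$loadings > 0))
  expect_error(extract_profile(Y[, 1:2]), "3 indicator")
})

test_that("eigenvalues of a correlation matrix preserve the trace", {
  set.seed(3)
  Y <- matrix(rnorm(300 * 11), 300, 11)
  efa <- efa_stressors(Y)
  expect_equal(sum(efa$eigenvalues), 11, tolerance = 1e-10)
})

test_that("EFA recovers the 7/4 stressor block assignment", {
  set.seed(4)
  n <- 1000
  blocks <- rep(1:2, c(7, 4))
  hits <- 0L
  for (rep in 1:20) {
    f <- matrix(rnorm(n * 2), n, 2)
    L <- matrix(0, 11, 2); L[cbind(1:11, blocks)] <- 0.6
    Y <- f %*% t(L) + matrix(rnorm(n * 11), n, 11) * sqrt(1 - 0.36)
    colnames(Y) <- c(stressor_domains()$socioeconomic,
                     stressor_domains()$personal)
    efa <- efa_stressors(Y)
    expect_identical(efa$n_factors, 2L)
    a <- efa$assignment
    ok <- (all(a[1:7] == a[1]) && all(a[8:11] == a[8]) && a[1] != a[8])
    hits <- hits + ok
  }
  expect_identical(hits, 20L)
})

test_that("EFA variance explained is scale invariant and rotation keeps
          per-indicator communality", {
  set.seed(5)
  n <- 400
  f <- matrix(rnorm(n * 2), n, 2)
  L <- matrix(0, 11, 2); L[cbind(1:11, rep(1:2, c(7, 4)))] <- 0.6
  Y <- f %*% t(L) + matrix(rnorm(n * 11), n, 11) * 0.8
  efa1 <- efa_stressors(Y)
  efa2 <- efa_stressors(sweep(Y, 2, c(1:11), "*"))
  expect_equal(efa1$variance_explained, efa2$variance_explained)
  # rotation preserves each row's sum of squared loadings
  raw <- eigen(cor(Y), symmetric = TRUE)
  Lraw <- raw$vectors[, 1:2] %*% diag(sqrt(raw$values[1:2]))
  expect_equal(rowSums(efa1$loadings^2), rowSums(Lraw^2),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("identity correlation input degenerates the auto rule, reported", {
  n <- 11
  Y <- diag(n)[rep(1:n, 30), ] + matrix(rnorm(30 * n * n, sd = 1), 30 * n, n)
  # force an exactly-identity correlation via whitening
  set.seed(6)
  Z <- matrix(rnorm(5000 * 11), 5000, 11)
  Z <- scale(Z %*% solve(chol(cov(Z))))
  efa <- efa_stressors(Z)
  expect_true(efa$auto_degenerate)
  expect_equal(efa$eigenvalues, rep(1, 11), tolerance = 1e-6)
})

test_that("varimax rotation is orthogonal and increases the criterion", {
  # 2x2 oracle: brute-force grid over rotation angles
  L <- matrix(c(.7, .7, .7, -.7), 2, 2)
  rot <- varimax_rotate(L, normalize = FALSE)
  grid <- sapply(seq(0, pi / 2, length.out = 20001), function(a) {
    G <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    varimax_criterion(L %*% G)
  })
  expect_gte(varimax_criterion(rot$loadings) + 1e-10, max(grid))
  expect_gte(varimax_criterion(rot$loadings), varimax_criterion(L))
  # rotated to the axes: one near-zero entry per row
  expect_equal(sort(abs(as.numeric(rot$loadings))),
               c(0, 0, sqrt(2) * .7, sqrt(2) * .7), tolerance = 1e-4)
  expect_equal(crossprod(rot$rotmat), diag(2), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("varimax agrees with an independent implementation on regular
          problems", {
  set.seed(10)
  for (i in 1:10) {
    M <- matrix(rnorm(11 * sample(2:4, 1)), 11)
    ours <- varimax_rotate(M, normalize = FALSE)
    ref <- stats::varimax(M, normalize = FALSE, eps = 1e-14)
    expect_gte(varimax_criterion(ours$loadings) + 1e-10,
               varimax_criterion(M %*% ref$rotmat))
  }
  set.seed(11)
  M <- matrix(rnorm(22), 11, 2)
  ours <- varimax_rotate(M)
  ref <- stats::varimax(M, normalize = TRUE, eps = 1e-14)
  expect_equal(abs(ours$loadings), abs(M %*% ref$rotmat),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("varimax leaves a simple-structure matrix unchanged", {
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- c(.8, .7, .6); L[4:6, 2] <- c(.75, .65, .55)
  rot <- varimax_rotate(L, normalize = FALSE)
  # up to column sign/permutation
  agree <- min(max(abs(abs(rot$loadings) - L)),
               max(abs(abs(rot$loadings[, 2:1]) - L)))
  expect_lt(agree, 1e-6)
  expect_error(varimax_rotate(L[, 1, drop = FALSE]), "2 factors")
})

test_that("quartile descriptives reproduce known patterns", {
  set.seed(7)
  n <- 400
  profile <- rnorm(n)
  dat <- data.frame(
    same = profile,                       # strictly increasing means
    const = rep(2, n),                    # degenerate
    indep = rnorm(n),
    cat = factor(sample(c("a", "b"), n, replace = TRUE))
  )
  qd <- quartile_descriptives(dat, profile)
  expect_equal(as.integer(table(qd$quartile)), rep(100L, 4))
  tab <- qd$table
  same_means <- as.numeric(sub(" .*", "", tab[tab$variable == "same",
                                              paste0("Q", 1:4)]))
  expect_true(all(diff(same_means) > 0))
  expect_identical(tab$test[tab$variable == "const"], "none (constant)")
  expect_true(is.na(tab$p_value[tab$variable == "const"]))
  expect_identical(unique(tab$test[tab$variable == "cat"]), "chi-square")
})

test_that("quartile split sends boundary ties to the lower quartile", {
  x <- c(1, 1, 1, 2, 3, 4, 5, 6)  # Q1 = 1.0 with ties at the boundary
  qd <- quartile_descriptives(data.frame(v = x), x)
  expect_identical(as.integer(qd$quartile[1:3]), rep(1L, 3))
})

test_that("ANOVA p-values are uniform when a variable is independent of
          the profile", {
  set.seed(8)
  ps <- replicate(1000, {
    prof <- rnorm(60)
    v <- rnorm(60)
    qd <- quartile_descriptives(data.frame(v = v), prof)
    qd$table$p_value[1]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
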