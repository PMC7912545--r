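test_that("VIF screening identifies and removes collinear columns", {
  set.seed(1)
  X <- cbind(x1 = rnorm(100), x2 = rnorm(100))
  vs <- vif_screen(X, threshold = 4)
  expect_true(all(vs$vif < 1.2))           # near-orthogonal columns
  expect_equal(nrow(vs$removed), 0)

  dupe <- cbind(X, x3 = X[, "x1"])
  vs2 <- vif_screen(dupe, threshold = 4)
  expect_equal(nrow(vs2$removed), 1)
  expect_true(is.infinite(vs2$removed$vif[1]))
  expect_length(vs2$retained, 2)

  near <- cbind(X, x3 = X[, "x1"] + X[, "x2"] + rnorm(100, sd = 1e-3))
  first_vifs <- vapply(1:3, function(j) {
    r2 <- summary(stats::lm(near[, j] ~ near[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(which.max(first_vifs), 3L)  # x3 carries the largest VIF
  expect_equal(vif_screen(near, threshold = 4)$removed$column[1], "x3")
})

test_that("PCA screen flags only low-loading columns and is report-only", {
  # identity correlation: loadings are unit-scaled, everything retained
  set.seed(2)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  ps <- pca_screen(X, loading_threshold = 0.5)
  expect_length(ps$flagged, 0)
  expect_equal(ps$retained, c("a", "b", "c"))
  expect_length(pca_screen(X, loading_threshold = 0)$flagged, 0)

  # dominant 2-factor structure plus a pure-noise column
  set.seed(3)
  f1 <- rnorm(300); f2 <- rnorm(300)
  Y <- cbind(y1 = f1 + rnorm(300, sd = .2), y2 = f1 + rnorm(300, sd = .2),
             y3 = f2 + rnorm(300, sd = .2), y4 = f2 + rnorm(300, sd = .2),
             noise = rnorm(300))
  ps2 <- pca_screen(Y, loading_threshold = 0.5)
  expect_equal(names(which.min(ps2$max_abs_loading)), "noise")
  expect_equal(pca_screen(Y, loading_threshold = 0.5,
                          action = "remove")$retained,
               c("y1", "y2", "y3", "y4"))
})

test_that("stepwise selection ranks discriminating variables first", {
  sg <- sim_groups(shift = 3, p = 2, seed = 4)
  X <- cbind(sg$X, noise1 = rnorm(nrow(sg$X)), noise2 = rnorm(nrow(sg$X)))
  sw <- stepwise_select(X, sg$groups)
  expect_equal(sort(sw$selected[1:2]), c("v1", "v2"))
  expect_true(all(diff(sw$steps$wilks) <= 0))   # lambda decreases per step
  expect_error(stepwise_select(X, sg$groups, f_to_enter = Inf),
               "no variable passes")
  # univariate rank table orders by F
  expect_equal(sw$univariate$variable[sw$univariate$rank <= 2][1:2],
               c("v1", "v2"))
})

test_that("informative variables enter before noise across seeds", {
  wins <- 0
  for (s in 1:20) {
    sg <- sim_groups(n_per = c(40, 40, 40), shift = 2, p = 2, seed = s)
    set.seed(1000 + s)
    X <- cbind(sg$X, n1 = rnorm(120), n2 = rnorm(120), n3 = rnorm(120))
    sw <- stepwise_select(X, sg$groups)
    k <- match(c("v1", "v2"), sw$selected)
    wins <- wins + (!anyNA(k) && max(k) == 2)
  }
  expect_gte(wins, 18)
})

test_that("canonical solution matches an explicit scatter-matrix oracle", {
  sg <- sim_groups(seed = 6)
  model <- fit_cda(sg$X, sg$groups)

  # oracle: explicit elementwise scatter construction + generalized eigen
  X <- sg$X; grp <- sg$groups
  gm <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X)); B <- matrix(0, ncol(X), ncol(X))
  for (g in unique(grp)) {
    Xg <- X[grp == g, , drop = FALSE]
    mg <- colMeans(Xg)
    for (r in seq_len(nrow(Xg)))
      W <- W + tcrossprod(Xg[r, ] - mg)
    B <- B + nrow(Xg) * tcrossprod(mg - gm)
  }
  ev <- eigen(solve(W) %*% B)
  lam <- sort(Re(ev$values), decreasing = TRUE)[seq_along(model$eigenvalues)]
  expect_equal(model$eigenvalues, lam, tolerance = 1e-8)

  # identities tying eigenvalues, correlations and Wilks together
  expect_equal(model$canonical_correlations^2,
               model$eigenvalues / (1 + model$eigenvalues),
               tolerance = 1e-12)
  expect_equal(model$wilks$wilks[1], prod(1 / (1 + model$eigenvalues)),
               tolerance = 1e-12)
  expect_equal(sum(model$explained_variance), 1)
  expect_equal(model$pillai$V, sum(model$canonical_correlations^2),
               tolerance = 1e-12)

  # scores: unit pooled within-group variance, weighted grand mean zero
  sc <- territorial_coordinates(model)
  obs <- sc[!sc$is_centroid, ]
  within_var <- vapply(c("CF1", "CF2"), function(cf) {
    res <- obs[[cf]] - ave(obs[[cf]], obs$group)
    sum(res^2) / (nrow(obs) - length(unique(obs$group)))
  }, numeric(1))
  expect_equal(unname(within_var), c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(colMeans(obs[c("CF1", "CF2")]))), 1e-10)
  cents <- sc[sc$is_centroid, ]
  agg <- aggregate(obs[c("CF1", "CF2")], list(group = obs$group), mean)
  expect_equal(cents[order(cents$group), c("CF1", "CF2")],
               agg[order(agg$group), c("CF1", "CF2")],
               ignore_attr = TRUE)
})

test_that("degenerate groups and singular scatter are handled", {
  set.seed(7)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  same <- rep(c("g1", "g2"), each = 50)
  m <- fit_cda(X[c(1:50, 1:50), ], same)   # two identical groups
  expect_lt(m$eigenvalues[1], 1e-10)
  expect_lt(m$canonical_correlations[1], 1e-5)
  Xs <- cbind(X, c = X[, 1])
  expect_error(fit_cda(Xs, same), "singular")
})

test_that("Mahalanobis distances equal canonical centroid distances", {
  sg <- sim_groups(seed = 8)
  model <- fit_cda(sg$X, sg$groups)
  D2 <- mahalanobis_between(model)
  expect_true(isSymmetric(D2))
  expect_equal(unname(diag(D2)), rep(0, 3))
  cd <- as.matrix(stats::dist(model$centroids))^2
  expect_equal(D2, cd[rownames(D2), colnames(D2)], tolerance = 1e-10)

  # hand-computable case: identity covariance, centroids (0,0) and (3,4)
  set.seed(9)
  base <- matrix(rnorm(4000), 2000, 2)
  base <- base %*% solve(chol(stats::cov(base)))  # exactly unit covariance
  base <- scale(base, scale = FALSE)
  Y <- rbind(base, sweep(base, 2, c(-3, -4)))
  gy <- rep(c("p", "q"), each = 2000)
  m2 <- fit_cda(Y, gy)
  expect_equal(mahalanobis_between(m2)["p", "q"], 25, tolerance = 1e-6)
})

test_that("classification is invariant to affine rescaling of inputs", {
  sg <- sim_groups(seed = 10)
  m1 <- fit_cda(sg$X, sg$groups)
  Xr <- sg$X
  Xr[, 1] <- 100 * Xr[, 1] - 7
  m2 <- fit_cda(Xr, sg$groups)
  expect_equal(classify_loocv(m1)$confusion, classify_loocv(m2)$confusion)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
})

test_that("LOOCV downdating equals a literal refit and matches MASS::lda", {
  skip_if_not_installed("MASS")
  sg <- sim_groups(n_per = c(25, 20, 15), shift = 2.5, p = 3, seed = 11)
  model <- fit_cda(sg$X, sg$groups)
  cl <- classify_loocv(model)

  # literal refit per fold
  lev <- model$groups
  naive <- character(nrow(sg$X))
  for (i in seq_len(nrow(sg$X))) {
    mi <- fit_cda(sg$X[-i, ], sg$groups[-i])
    naive[i] <- peddiv:::classify_linear(sg$X[i, , drop = FALSE],
                                         mi$group_means, mi$pooled_cov,
                                         mi$priors)
  }
  cv_tab <- table(actual = factor(sg$groups, lev),
                  predicted = factor(naive, lev))
  expect_equal(cl$confusion_loocv, cv_tab)

  # resubstitution rule agrees with the reference implementation
  ld <- MASS::lda(sg$X, grouping = sg$groups)
  expect_equal(as.character(stats::predict(ld)$class),
               peddiv:::classify_linear(sg$X, model$group_means,
                                        model$pooled_cov, model$priors))

  # eigenvalue route agrees with lda's singular values:
  # lambda = svd^2 (g - 1)/(n - g)
  n <- length(sg$groups); g <- length(lev)
  expect_equal(model$eigenvalues, ld$svd^2 * (g - 1) / (n - g),
               tolerance = 1e-8)
})

test_that("LOOCV is no better than resubstitution on average", {
  diffs <- numeric(20)
  for (s in 1:20) {
    sg <- sim_groups(n_per = c(30, 25, 20), shift = 1.5, p = 3, seed = s)
    cl <- classify_loocv(fit_cda(sg$X, sg$groups))
    diffs[s] <- cl$hit_ratio - cl$hit_ratio_loocv
  }
  expect_gte(mean(diffs), 0)
})

test_that("well-separated groups are almost perfectly cross-validated", {
  hits <- 0
  for (s in 1:20) {
    sg <- sim_groups(n_per = c(40, 35, 30), shift = 6, p = 3, seed = 600 + s)
    cl <- classify_loocv(fit_cda(sg$X, sg$groups))
    hits <- hits + (cl$hit_ratio_loocv > 0.95)
  }
  expect_gte(hits, 18)
})

test_that("Press' Q reproduces its closed form and critical value", {
  pq <- press_q(207100, 197026, 3)
  expect_equal(round(pq$Q, 2), 355961.14)
  expect_true(pq$significant)
  expect_equal(press_q(100, 100, 2)$Q, 100)
  expect_equal(round(press_q(1, 1, 2)$critical, 2), 6.63)
})

test_that("the pedigree feature table is complete and grouped", {
  cfgA <- sim_config(n_founders_per_breed = 12, n_generations = 3, seed = 61)
  cfgB <- sim_config(n_founders_per_breed = 12, n_generations = 3, seed = 62)
  ped <- simulate_composite(cfgA, cfgB, composite_scheme_5050(n = 12),
                            seed = 63)
  ft <- feature_table(ped)
  expect_false(anyNA(ft[setdiff(names(ft), "group")]))
  expect_setequal(unique(ft$group), c("A", "B", "COMP"))
  expect_equal(nrow(ft), nrow(ped))
  # alpha column reproduces its defining identity per breed
  F <- inbreeding(ped)
  b <- ft$group == "A"
  Cb <- mean_coancestry(ped, ped$id[b], F)
  expect_equal(ft$alpha[b], 1 - (1 - F[b]) / (1 - Cb), ignore_attr = TRUE)
})
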