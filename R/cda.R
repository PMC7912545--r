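#' Assemble the per-individual diversity feature table
#'
#' Builds the observation matrix for breed discrimination: one row per
#' reference animal, columns the pedigree diversity parameters - inbreeding
#' F (%), average relatedness AR (%), genetic conservation index GCI, the
#' individual non-random-mating term alpha_i = 1 - (1 - F_i)/(1 - C_breed)
#' (C_breed the mean coancestry of the animal's breed), maximum, complete
#' and equivalent generation numbers, and number of offspring - with the
#' breed as the grouping factor. F and equivalent generations are carried
#' for the multicollinearity screen and are typically removed by it.
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to focal set, else all records).
#' @param group_col Column of `ped` providing the grouping label.
#' @return Data frame with attribute `group` naming the grouping column.
#' @export
feature_table <- function(ped, reference = NULL, group_col = "breed") {
  idx <- focal_indices(ped, reference)
  F <- inbreeding(ped)
  AR <- average_relatedness(ped, F)
  gp <- generation_profiles(ped)
  gci <- genetic_conservation_index(ped, ped$id[idx])
  grp <- as.character(ped[[group_col]][idx])
  if (anyNA(grp)) stop("missing group label for some reference animals")
  # per-breed mean coancestry for the individual alpha term
  alpha <- numeric(length(idx))
  for (b in unique(grp)) {
    sel <- grp == b
    Cb <- mean_coancestry(ped, ped$id[idx][sel], F)
    alpha[sel] <- 1 - (1 - F[idx][sel]) / (1 - Cb)
  }
  off <- tabulate(c(ped$sire_idx, ped$dam_idx), nbins = nrow(ped))
  out <- data.frame(
    F_pct = 100 * unname(F[idx]),
    AR_pct = 100 * unname(AR[idx]),
    GCI = unname(gci),
    alpha = alpha,
    max_generations = gp$max_generations[idx],
    complete_generations = gp$complete_generations[idx],
    equivalent_generations = gp$equivalent_generations[idx],
    offspring_n = off[idx],
    group = grp,
    stringsAsFactors = FALSE)
  attr(out, "group") <- "group"
  out
}

# numeric predictor matrix: drops the group column of a feature table
numeric_matrix <- function(X) {
  gcol <- attr(X, "group")
  if (is.null(gcol) && is.data.frame(X) && "group" %in% names(X))
    gcol <- "group"
  if (is.data.frame(X) && !is.null(gcol) && gcol %in% names(X))
    X <- X[setdiff(names(X), gcol)]
  M <- as.matrix(X)
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("missing cells in the feature table")
  M
}

split_xy <- function(X, groups = NULL) {
  if (is.null(groups)) {
    gcol <- attr(X, "group")
    if (is.null(gcol) && is.data.frame(X) && "group" %in% names(X))
      gcol <- "group"
    if (is.null(gcol) || !gcol %in% names(X))
      stop("supply `groups` or a feature table with a group column")
    groups <- X[[gcol]]
    X <- X[setdiff(names(X), gcol)]
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing cells in the feature table")
  list(X = X, groups = as.character(groups))
}

#' Variance-inflation-factor screen
#'
#' Regresses each column on all others; VIF = 1/(1 - R^2). Columns are
#' removed iteratively, largest VIF first (perfectly collinear columns have
#' infinite VIF and go first), until every remaining column passes the
#' threshold.
#'
#' @param X Feature table (group column ignored) or numeric matrix.
#' @param threshold Maximum tolerated VIF.
#' @return List of class `vif_screen`: `retained`, `removed` (with the VIF
#'   at removal) and `vif` (final VIFs of retained columns).
#' @export
vif_screen <- function(X, threshold = 4) {
  M <- numeric_matrix(X)
  if (ncol(M) < 2) stop("need at least two columns")
  removed <- data.frame(column = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    vifs <- vapply(seq_len(ncol(M)), function(j) {
      fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), M[, j])
      rss <- sum(fit$residuals^2)
      tss <- sum((M[, j] - mean(M[, j]))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    names(vifs) <- colnames(M)
    if (all(vifs <= threshold) || ncol(M) <= 2) break
    worst <- which.max(vifs)
    removed <- rbind(removed, data.frame(column = colnames(M)[worst],
                                         vif = vifs[[worst]]))
    M <- M[, -worst, drop = FALSE]
  }
  structure(list(retained = colnames(M), removed = removed, vif = vifs),
            class = "vif_screen")
}

#' Principal-component loading screen
#'
#' PCA on the standardized columns; a column whose maximum absolute loading
#' (eigenvector scaled by the component standard deviation) over the
#' retained components (eigenvalue >= 1) falls below the threshold is
#' flagged. By default the screen only reports; set `action = "remove"` to
#' drop flagged columns.
#'
#' @param X Feature table or numeric matrix.
#' @param loading_threshold Minimum acceptable maximum |loading|.
#' @param action `"report"` (default) or `"remove"`.
#' @return List of class `pca_screen`: `loadings`, `max_abs_loading`,
#'   `flagged`, `retained`.
#' @export
pca_screen <- function(X, loading_threshold = 0.5,
                       action = c("report", "remove")) {
  action <- match.arg(action)
  M <- scale(numeric_matrix(X))
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  keep <- which(pc$sdev^2 >= 1)
  if (!length(keep)) keep <- 1L
  load <- pc$rotation[, keep, drop = FALSE] %*% diag(pc$sdev[keep],
                                                     length(keep))
  colnames(load) <- paste0("PC", keep)
  maxl <- apply(abs(load), 1, max)
  flagged <- names(maxl)[maxl < loading_threshold]
  retained <- if (action == "remove") setdiff(colnames(M), flagged)
              else colnames(M)
  structure(list(loadings = load, max_abs_loading = maxl,
                 flagged = flagged, retained = retained),
            class = "pca_screen")
}

# Wilks' lambda of a variable subset: det(W)/det(T)
wilks_lambda <- function(X, groups, cols) {
  M <- X[, cols, drop = FALSE]
  Tm <- stats::cov(M) * (nrow(M) - 1)
  W <- matrix(0, ncol(M), ncol(M))
  for (g in unique(groups)) {
    Mg <- M[groups == g, , drop = FALSE]
    if (nrow(Mg) > 1) W <- W + stats::cov(Mg) * (nrow(Mg) - 1)
  }
  det(W) / det(Tm)
}

#' Forward stepwise variable selection by Wilks' lambda
#'
#' At each step the variable that most reduces the overall Wilks' lambda is
#' added, provided its partial F-to-enter meets the threshold. Also returns
#' the univariate tests of equality of group means (one-way Wilks and F per
#' variable) as a discriminating-power rank table.
#'
#' @param X Feature table or numeric matrix.
#' @param groups Group labels (taken from the feature table if `NULL`).
#' @param f_to_enter Minimum partial F for a variable to enter.
#' @return List of class `stepwise_selection`: `selected` (ordered),
#'   `steps` (variable, Wilks after entry, partial F), and `univariate`
#'   (per-variable one-way Wilks, F and rank).
#' @export
stepwise_select <- function(X, groups = NULL, f_to_enter = 3.84) {
  xy <- split_xy(X, groups)
  M <- xy$X; grp <- xy$groups
  g <- length(unique(grp)); n <- nrow(M)
  if (g < 2) stop("need at least two groups")

  uni <- do.call(rbind, lapply(colnames(M), function(v) {
    lam <- wilks_lambda(M, grp, v)
    Fv <- (1 - lam) / lam * (n - g) / (g - 1)
    data.frame(variable = v, wilks = lam, F = Fv,
               stringsAsFactors = FALSE)
  }))
  uni$rank <- rank(-uni$F, ties.method = "min")

  selected <- character(0)
  steps <- data.frame(variable = character(0), wilks = numeric(0),
                      partial_F = numeric(0), stringsAsFactors = FALSE)
  lam_old <- 1
  repeat {
    candidates <- setdiff(colnames(M), selected)
    if (!length(candidates)) break
    lam_new <- vapply(candidates, function(v)
      wilks_lambda(M, grp, c(selected, v)), numeric(1))
    p <- length(selected)
    partF <- (lam_old / lam_new - 1) * (n - g - p) / (g - 1)
    best <- which.max(partF)
    if (partF[best] < f_to_enter) break
    selected <- c(selected, candidates[best])
    steps <- rbind(steps, data.frame(variable = candidates[best],
                                     wilks = lam_new[[best]],
                                     partial_F = partF[[best]]))
    lam_old <- lam_new[[best]]
  }
  if (!length(selected))
    stop("no variable passes the F-to-enter threshold at step 1")
  structure(list(selected = selected, steps = steps, univariate = uni),
            class = "stepwise_selection")
}

#' Fit a canonical discriminant analysis
#'
#' Eigen-decomposition of the within-group-scatter inverse times the
#' between-group scatter, solved through a symmetric whitening of the
#' within matrix. Canonical axes are scaled so the pooled within-group
#' variance of the scores is 1; scores are centred on the grand mean. The
#' model reports eigenvalues, canonical correlations Rc = sqrt(l/(1+l)),
#' explained-variance shares, Wilks' lambda for each residual root set with
#' Bartlett's chi-square, Pillai's trace with its F approximation,
#' standardized coefficients (raw coefficients times pooled within-group
#' SDs), discriminant loadings (pooled within-group correlations of each
#' variable with each score), group centroids and priors. Dimensions with
#' Rc >= 0.30 are flagged meaningful.
#'
#' @param X Feature table (screened columns) or numeric matrix.
#' @param groups Group labels (taken from the feature table if `NULL`).
#' @param priors `"from_group_sizes"` or `"equal"`.
#' @return An object of class `cda_model`.
#' @export
fit_cda <- function(X, groups = NULL,
                    priors = c("from_group_sizes", "equal")) {
  priors <- match.arg(priors)
  xy <- split_xy(X, groups)
  M <- xy$X; grp <- factor(xy$groups)
  n <- nrow(M); p <- ncol(M); g <- nlevels(grp)
  if (g < 2) stop("need at least two groups")
  if (min(table(grp)) <= p)
    warning("smallest group (", min(table(grp)),
            ") does not exceed the number of predictors (", p, ")")
  gm <- colMeans(M)
  means <- rowsum(M, grp) / as.vector(table(grp))
  W <- matrix(0, p, p, dimnames = list(colnames(M), colnames(M)))
  for (lev in levels(grp)) {
    Mg <- M[grp == lev, , drop = FALSE]
    if (nrow(Mg) > 1) W <- W + stats::cov(Mg) * (nrow(Mg) - 1)
  }
  Tm <- stats::cov(M) * (n - 1)
  B <- Tm - W
  sdw <- sqrt(diag(W) / (n - g))
  zero <- which(sdw < 1e-12 * max(sdw))
  if (length(zero))
    stop("within-group scatter singular; offending column(s): ",
         paste(colnames(M)[zero], collapse = ", "))
  R <- tryCatch(chol(W), error = function(e)
    stop("within-group scatter singular (not positive definite)"))
  Rin <- backsolve(R, diag(p))
  K <- crossprod(Rin, B %*% Rin)
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  m <- min(p, g - 1)
  lambda <- pmax(ev$values[seq_len(m)], 0)
  V <- Rin %*% ev$vectors[, seq_len(m), drop = FALSE]
  # scale: pooled within-group variance of each score = 1
  Cw <- W / (n - g)
  sc <- sqrt(colSums(V * (Cw %*% V)))
  V <- sweep(V, 2, sc, "/")
  dimnames(V) <- list(colnames(M), paste0("CF", seq_len(m)))

  Rc <- sqrt(lambda / (1 + lambda))
  expl <- if (sum(lambda) > 0) lambda / sum(lambda) else rep(0, m)
  # Wilks for root sets k+1..m with Bartlett chi-square
  wilks <- vapply(0:(m - 1), function(k)
    prod(1 / (1 + lambda[(k + 1):m])), numeric(1))
  chisq <- -(n - 1 - (p + g) / 2) * log(wilks)
  df <- vapply(0:(m - 1), function(k) (p - k) * (g - 1 - k), numeric(1))
  wilks_tab <- data.frame(functions = paste0(seq_len(m), " through ", m),
                          wilks = wilks, chisq = chisq, df = df,
                          p_value = stats::pchisq(chisq, df,
                                                  lower.tail = FALSE))

  Vp <- sum(Rc^2)
  s <- m
  m1 <- (abs(p - g + 1) - 1) / 2
  n1 <- (n - g - p - 1) / 2
  pillai_F <- ((2 * n1 + s + 1) / (2 * m1 + s + 1)) * Vp / (s - Vp)
  pillai_df1 <- s * (2 * m1 + s + 1)
  pillai_df2 <- s * (2 * n1 + s + 1)

  scores <- sweep(M, 2, gm) %*% V
  centroids <- rowsum(scores, grp) / as.vector(table(grp))
  std_coef <- V * sdw
  # scores have unit pooled within-group variance, so the within-group
  # correlation of variable j with a score is cov_w(x_j, score)/sd_w(j)
  loadings <- diag(1 / sdw, p) %*% Cw %*% V
  rownames(loadings) <- colnames(M)
  colnames(loadings) <- colnames(V)

  pri <- if (priors == "equal") rep(1 / g, g)
         else as.vector(table(grp)) / n
  names(pri) <- levels(grp)

  structure(list(
    variables = colnames(M), groups = levels(grp),
    n = n, p = p, g = g,
    eigenvalues = lambda, canonical_correlations = Rc,
    explained_variance = expl, meaningful = Rc >= 0.30,
    wilks = wilks_tab,
    pillai = list(V = Vp, F = pillai_F, df1 = pillai_df1,
                  df2 = pillai_df2,
                  p_value = stats::pf(pillai_F, pillai_df1, pillai_df2,
                                      lower.tail = FALSE)),
    raw_coefficients = V, standardized_coefficients = std_coef,
    loadings = loadings, centroids = centroids,
    grand_mean = gm, group_means = means, pooled_cov = Cw,
    priors = pri, prior_spec = priors,
    X = M, group_labels = as.character(grp)),
    class = "cda_model")
}

#' @export
print.cda_model <- function(x, ...) {
  cat("Canonical discriminant analysis:", x$p, "variables,", x$g,
      "groups,", x$n, "observations\n")
  tab <- data.frame(eigenvalue = x$eigenvalues,
                    canonical_correlation = x$canonical_correlations,
                    pct_variance = 100 * x$explained_variance,
                    meaningful = x$meaningful)
  rownames(tab) <- paste0("CF", seq_along(x$eigenvalues))
  print(tab)
  cat("Wilks' lambda (all functions):", format(x$wilks$wilks[1]),
      " Pillai's trace:", format(x$pillai$V), "\n")
  invisible(x)
}

#' Squared Mahalanobis distances between group centroids
#'
#' D2_ij = (m_i - m_j)' S^-1 (m_i - m_j) with S the pooled within-group
#' covariance; identical to the squared Euclidean distance between
#' centroids in the full canonical space.
#'
#' @param model A fitted `cda_model`.
#' @return Symmetric matrix of squared distances.
#' @export
mahalanobis_between <- function(model) {
  mm <- model$group_means
  Sinv <- solve(model$pooled_cov)
  g <- nrow(mm)
  D2 <- matrix(0, g, g, dimnames = list(rownames(mm), rownames(mm)))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    d <- mm[i, ] - mm[j, ]
    D2[i, j] <- drop(t(d) %*% Sinv %*% d)
  }
  D2
}

# linear classification of rows of M given group means, pooled covariance
# and priors
classify_linear <- function(M, means, Cw, priors) {
  Sinv <- solve(Cw)
  G <- nrow(means)
  disc <- matrix(0, nrow(M), G)
  for (k in seq_len(G)) {
    mu <- means[k, ]
    disc[, k] <- M %*% (Sinv %*% mu) -
      0.5 * drop(t(mu) %*% Sinv %*% mu) + log(priors[k])
  }
  rownames(means)[max.col(disc, ties.method = "first")]
}

#' Press' Q statistic
#'
#' Q = (N - nK)^2 / (N (K - 1)) for N cases, n correctly classified and K
#' groups; compared against the chi-square(1) critical value 6.63 at the
#' 0.01 level.
#'
#' @param N Number of cases.
#' @param n_correct Number classified correctly.
#' @param K Number of groups.
#' @return List with `Q`, `critical` and `significant`.
#' @export
press_q <- function(N, n_correct, K) {
  Q <- (N - n_correct * K)^2 / (N * (K - 1))
  crit <- stats::qchisq(0.99, df = 1)
  list(Q = Q, critical = crit, significant = Q > crit)
}

#' Classification and leave-one-out cross-validation
#'
#' Linear (pooled-covariance) classification with the model's priors:
#' resubstitution and exact leave-one-out confusion matrices, hit ratios
#' and Press' Q on the cross-validated assignments. The leave-one-out refit
#' uses the exact downdating identities for the group mean and pooled
#' scatter, so it equals a literal refit excluding each case.
#'
#' @param model A fitted `cda_model` (carries its training data).
#' @return List of class `cda_classification`: `confusion`,
#'   `confusion_loocv`, `hit_ratio`, `hit_ratio_loocv`, `per_group_pct`
#'   (LOOCV percent correct by group) and `press_q`.
#' @export
classify_loocv <- function(model) {
  M <- model$X; grp <- model$group_labels
  lev <- model$groups
  n <- nrow(M); G <- length(lev)
  counts <- table(factor(grp, levels = lev))
  pred <- classify_linear(M, model$group_means, model$pooled_cov,
                          model$priors)
  confusion <- table(actual = factor(grp, lev), predicted = factor(pred, lev))

  W <- model$pooled_cov * (n - G)
  pred_cv <- character(n)
  for (i in seq_len(n)) {
    gi <- grp[i]
    ng <- counts[[gi]]
    if (ng == 1) stop("group ", gi, " absent from a training fold")
    mu <- model$group_means[gi, ]
    d <- M[i, ] - mu
    mu_i <- (ng * mu - M[i, ]) / (ng - 1)
    W_i <- W - (ng / (ng - 1)) * tcrossprod(d)
    means_i <- model$group_means
    means_i[gi, ] <- mu_i
    counts_i <- counts; counts_i[gi] <- ng - 1
    pri <- if (model$prior_spec == "equal") rep(1 / G, G)
           else as.vector(counts_i) / (n - 1)
    names(pri) <- lev
    Cw_i <- W_i / (n - 1 - G)
    pred_cv[i] <- classify_linear(M[i, , drop = FALSE], means_i, Cw_i, pri)
  }
  confusion_cv <- table(actual = factor(grp, lev),
                        predicted = factor(pred_cv, lev))
  n_correct <- sum(diag(confusion_cv))
  structure(list(
    confusion = confusion, confusion_loocv = confusion_cv,
    hit_ratio = sum(diag(confusion)) / n,
    hit_ratio_loocv = n_correct / n,
    per_group_pct = 100 * diag(confusion_cv) / as.vector(counts),
    press_q = press_q(n, n_correct, G)),
    class = "cda_classification")
}

#' Per-individual canonical scores for territorial plotting
#'
#' Scores of every observation on the canonical functions, with the group
#' centroids appended as flagged rows; suitable for plotting a territorial
#' map externally.
#'
#' @param model A fitted `cda_model`.
#' @param X Optional new observations (defaults to the training data).
#' @param groups Labels for `X` when supplied.
#' @return Data frame with canonical-function columns, `group` and
#'   `is_centroid`.
#' @export
territorial_coordinates <- function(model, X = NULL, groups = NULL) {
  if (is.null(X)) {
    M <- model$X; grp <- model$group_labels
  } else {
    xy <- split_xy(X, groups)
    M <- xy$X[, model$variables, drop = FALSE]; grp <- xy$groups
  }
  scores <- sweep(M, 2, model$grand_mean) %*% model$raw_coefficients
  cent <- rowsum(scores, grp) / as.vector(table(factor(grp)))
  out <- data.frame(scores, group = grp, is_centroid = FALSE,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(cent, group = rownames(cent),
                               is_centroid = TRUE,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
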