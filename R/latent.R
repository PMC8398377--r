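#' Principal component analysis of an abundance matrix
#'
#' Unsupervised decomposition for qualitative inspection of group
#' separation. Columns are mean-centered and, by default, scaled to unit
#' variance (autoscaling, the untargeted-metabolomics norm). Component signs
#' are fixed by convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param x imputed-stage [abundance_matrix()] or plain numeric matrix
#'   (samples x metabolites).
#' @param n_components number of components to keep (default full rank).
#' @param scaling `"unit_variance"` or `"center_only"`.
#' @return a `pca_model`: `scores`, `loadings`,
#'   `explained_variance_fraction`, `center`, `scale`, `scaling`.
#' @export
fit_pca <- function(x, n_components = NULL,
                    scaling = c("unit_variance", "center_only")) {
  scaling <- match.arg(scaling)
  vals <- unclass(x)
  if (anyNA(vals)) stop("fit_pca requires a complete (imputed) matrix")
  rank_max <- min(nrow(vals) - 1L, ncol(vals))
  if (is.null(n_components)) n_components <- rank_max
  if (n_components > rank_max)
    stop("n_components exceeds min(samples - 1, metabolites)")
  if (scaling == "unit_variance") {
    sds <- apply(vals, 2, stats::sd)
    const <- colnames(vals)[sds == 0]
    if (length(const))
      stop("constant metabolite(s) cannot be unit-variance scaled: ",
           paste(const, collapse = ", "))
  }
  fit <- stats::prcomp(vals, center = TRUE,
                       scale. = (scaling == "unit_variance"))
  k <- n_components
  flip <- vapply(seq_len(k), function(j) {
    l <- fit$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(fit$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(fit$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  ev <- fit$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = (ev / sum(ev))[seq_len(k)],
                 center = fit$center,
                 scale = if (scaling == "unit_variance") fit$scale else NULL,
                 scaling = scaling),
            class = "pca_model")
}

# internal: center/scale X and 0/1-code y for the latent models; returns the
# preprocessed matrices plus the transform needed to apply it to new data
latent_prepare <- function(X, labels, scaling) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  if (min(table(labels)) < 3) stop("each class needs at least 3 samples")
  y01 <- as.numeric(labels == levels(labels)[2])
  center <- colMeans(X)
  Xc <- X - rep(center, each = nrow(X))
  scale <- if (scaling == "unit_variance") {
    s <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
    if (any(s == 0))
      stop("constant metabolite(s) cannot be unit-variance scaled: ",
           paste(colnames(X)[s == 0], collapse = ", "))
    s
  } else rep(1, ncol(X))
  Xs <- Xc / rep(scale, each = nrow(X))
  list(X = Xs, y = y01 - mean(y01), y01 = y01, y_mean = mean(y01),
       center = center, scale = scale, levels = levels(labels))
}

# internal: core O-PLS fit on an already centered/scaled X and centered y.
# Iteratively extracts components of X-variation orthogonal to y, deflates
# X, then fits the single predictive PLS component on the filtered matrix.
opls_core <- function(X, y, n_orthogonal) {
  p <- ncol(X)
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  if (n_orthogonal > 0) {
    for (k in seq_len(n_orthogonal)) {
      w <- drop(crossprod(Xd, y))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) stop("X carries no covariance with y; cannot fit")
      w <- w / nw
      t <- drop(Xd %*% w)
      pload <- drop(crossprod(Xd, t)) / sum(t^2)
      w_o <- pload - drop(crossprod(w, pload)) * w
      nwo <- sqrt(sum(w_o^2))
      if (nwo < 1e-12)
        stop("requested orthogonal components exceed the y-orthogonal rank of X")
      w_o <- w_o / nwo
      t_o <- drop(Xd %*% w_o)
      p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    }
  }
  w <- drop(crossprod(Xd, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("X carries no covariance with y; cannot fit")
  w <- w / nw
  t <- drop(Xd %*% w)
  pload <- drop(crossprod(Xd, t)) / sum(t^2)
  c_coef <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = pload, c = c_coef,
       w_ortho = W_o, p_ortho = P_o, t_ortho = T_o, X_filtered = Xd)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis for two classes:
#' variation in X uncorrelated with the class vector is captured in 0..K
#' orthogonal components and removed, then a single predictive PLS component
#' is fit on the filtered matrix. With `n_orthogonal = 0` the model is
#' exactly a one-component PLS1-DA. Class coding is 0/1, centered;
#' predictions are thresholded at the midpoint for class calls.
#'
#' @param X samples x metabolites matrix (rows of the imputed matrix for the
#'   two groups of a contrast).
#' @param labels two-level factor (or coercible) of class memberships.
#' @param n_orthogonal number of orthogonal components (>= 0).
#' @param scaling `"unit_variance"` (default) or `"center_only"`.
#' @return an `oplsda_model` with predictive weights/scores/loadings,
#'   orthogonal components, `r2x`, `r2y`, `vip`, and the preprocessing
#'   record needed by [predict.oplsda_model()].
#' @export
fit_oplsda <- function(X, labels, n_orthogonal = 0,
                       scaling = c("unit_variance", "center_only")) {
  scaling <- match.arg(scaling)
  prep <- latent_prepare(X, labels, scaling)
  if (n_orthogonal > min(nrow(prep$X) - 2L, ncol(prep$X) - 1L))
    stop("n_orthogonal exceeds the usable rank of X")
  core <- opls_core(prep$X, prep$y, n_orthogonal)
  yhat <- core$t * core$c
  r2y <- 1 - sum((prep$y - yhat)^2) / sum(prep$y^2)
  ssx <- sum(prep$X^2)
  ssx_model <- sum(tcrossprod(core$t, core$p)^2) +
    (if (ncol(core$t_ortho)) sum((core$t_ortho %*% t(core$p_ortho))^2) else 0)
  model <- structure(list(
    w = core$w, t = core$t, p = core$p, c = core$c,
    w_ortho = core$w_ortho, p_ortho = core$p_ortho, t_ortho = core$t_ortho,
    n_orthogonal = n_orthogonal,
    r2x = ssx_model / ssx, r2y = r2y,
    center = prep$center, scale = prep$scale, scaling = scaling,
    y_mean = prep$y_mean, levels = prep$levels,
    metabolite_ids = colnames(as.matrix(X))
  ), class = "oplsda_model")
  model$vip <- vip_scores(model)
  model
}

#' Predict from an OPLS-DA model
#'
#' Applies the training centering/scaling, strips the orthogonal components
#' sequentially, and projects onto the predictive component.
#'
#' @param object an `oplsda_model`.
#' @param newdata samples x metabolites matrix with the training columns.
#' @param ... unused.
#' @return list with `y_score` (numeric prediction on the 0/1 scale),
#'   `class` (thresholded at 0.5), `t_pred` (predictive scores).
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$metabolite_ids, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  if (object$n_orthogonal > 0) {
    for (k in seq_len(object$n_orthogonal)) {
      t_o <- drop(Xs %*% object$w_ortho[, k])
      Xs <- Xs - tcrossprod(t_o, object$p_ortho[, k])
    }
  }
  t_pred <- drop(Xs %*% object$w)
  y_score <- t_pred * object$c + object$y_mean
  list(y_score = y_score,
       class = object$levels[(y_score > 0.5) + 1L],
       t_pred = t_pred)
}

#' VIP scores of an OPLS-DA model
#'
#' Variable importance in projection computed from the predictive component
#' (the component carrying class separation): with a single predictive
#' component VIP reduces to `sqrt(M) * |w_j| / ||w||`, so the squared VIPs
#' average exactly 1 over the M metabolites. Metabolites with VIP > 1
#' contribute more than an average variable to the discrimination.
#'
#' @param model a fitted `oplsda_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  w <- model$w
  m <- length(w)
  vip <- sqrt(m) * abs(w) / sqrt(sum(w^2))
  names(vip) <- model$metabolite_ids
  vip
}

# internal: deterministic stratified fold assignment.  Samples of each class
# are ordered by row name (so assignment is invariant to row order) and
# dealt into folds after a seeded shuffle.
make_folds <- function(labels, ids, n_folds, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n_folds >= n) {                       # leave-one-out: one fold each
    return(order(order(ids)))
  }
  fold <- integer(n)
  set.seed(seed)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    idx <- idx[order(ids[idx])]
    idx <- idx[sample(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# internal: resolve the fold count rule: 10-fold when the smaller class has
# at least 10 members, else 5-fold, else leave-one-out
resolve_folds <- function(labels, folds) {
  n_min <- min(table(labels))
  if (!identical(folds, "auto")) return(as.integer(folds))
  if (n_min >= 10) 10L else if (n_min >= 5) 5L else length(labels)
}

#' Cross-validated predictive ability (Q2) of an OPLS-DA model
#'
#' Stratified k-fold cross-validation: each fold is held out, the model
#' (including centering/scaling) is refit on the remainder, and held-out
#' class values are predicted. `q2 = 1 - PRESS/TSS` where PRESS sums squared
#' out-of-fold errors of the centered class vector and TSS is its total
#' centered sum of squares. Ten folds are used when the smaller class has at
#' least 10 members, five when it has at least 5, otherwise leave-one-out.
#'
#' @param X samples x metabolites matrix.
#' @param labels two-level class vector.
#' @param n_orthogonal orthogonal components per refit.
#' @param folds `"auto"` (the rule above) or an explicit fold count.
#' @param seed integer seed controlling the fold assignment.
#' @param scaling passed to [fit_oplsda()].
#' @return list: `q2`, `press`, `tss`, `predictions` (out-of-fold y-scores,
#'   sample order), `fold` assignment, `n_folds`.
#' @export
cross_validate <- function(X, labels, n_orthogonal = 0, folds = "auto",
                           seed = 1L, scaling = "unit_variance") {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  n_folds <- resolve_folds(labels, folds)
  if (n_folds > length(labels)) n_folds <- length(labels)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("row%04d", seq_len(nrow(X)))
  fold <- make_folds(labels, ids, n_folds, seed)
  # a training split must contain both classes; fall back to leave-one-out
  ok <- all(vapply(seq_len(n_folds), function(f)
    nlevels(droplevels(labels[fold != f])) == 2, logical(1)))
  if (!ok) {
    warning("fold scheme left a single-class training split; using leave-one-out")
    n_folds <- length(labels)
    fold <- make_folds(labels, ids, n_folds, seed)
  }
  y01 <- as.numeric(labels == levels(labels)[2])
  pred <- numeric(length(labels))
  for (f in sort(unique(fold))) {
    train <- fold != f
    fit <- fit_oplsda(X[train, , drop = FALSE], labels[train],
                      n_orthogonal = n_orthogonal, scaling = scaling)
    pred[!train] <- predict(fit, X[!train, , drop = FALSE])$y_score
  }
  yc <- y01 - mean(y01)
  press <- sum((y01 - pred)^2)
  tss <- sum(yc^2)
  list(q2 = 1 - press / tss, press = press, tss = tss,
       predictions = pred, fold = fold, n_folds = n_folds)
}

#' Choose the number of orthogonal components
#'
#' Starts at zero and adds orthogonal components while the cross-validated
#' Q2 improves by more than `tol`, up to `k_max`.
#'
#' @param X samples x metabolites matrix.
#' @param labels two-level class vector.
#' @param k_max maximum orthogonal components (default 3).
#' @param folds,seed,scaling passed to [cross_validate()].
#' @param tol minimum Q2 improvement to accept a component (default 0.01).
#' @return the chosen count (integer).
#' @export
choose_n_orthogonal <- function(X, labels, k_max = 3, folds = "auto",
                                seed = 1L, scaling = "unit_variance",
                                tol = 0.01) {
  if (k_max <= 0) return(0L)
  best_k <- 0L
  best_q2 <- cross_validate(X, labels, 0, folds, seed, scaling)$q2
  rank_cap <- min(nrow(as.matrix(X)) - 3L, ncol(as.matrix(X)) - 1L)
  for (k in seq_len(min(k_max, max(rank_cap, 0L)))) {
    q2 <- tryCatch(cross_validate(X, labels, k, folds, seed, scaling)$q2,
                   error = function(e) -Inf)
    if (q2 > best_q2 + tol) {
      best_k <- k
      best_q2 <- q2
    } else break
  }
  best_k
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F-test comparing the cross-validated prediction residuals against the
#' residuals of the intercept-only predictor (the class mean), in the style
#' of the SIMCA CV-ANOVA construction. Degrees of freedom: the model is
#' charged one df per component (1 predictive + K orthogonal), so
#' `F = ((TSS - PRESS)/A) / (PRESS/(n - 1 - A))` with `A = 1 + K`; when the
#' cross-validated model does not improve on the intercept (PRESS >= TSS)
#' the statistic is floored at zero and p = 1. A PRESS of zero is reported
#' at the capped statistic and flagged degenerate.
#'
#' @param cv result of [cross_validate()].
#' @param labels the class vector the model was validated on.
#' @param n_orthogonal orthogonal component count of the model.
#' @return list: `f_stat`, `df1`, `df2`, `p_value`, `degenerate`.
#' @export
cv_anova <- function(cv, labels, n_orthogonal = 0) {
  n <- length(cv$predictions)
  a <- 1 + n_orthogonal
  df2 <- n - 1 - a
  if (df2 <= 0) stop("too few samples for CV-ANOVA with this many components")
  press_floor <- 1e-12 * cv$tss
  degenerate <- cv$press < press_floor
  f <- max(0, (cv$tss - cv$press) / a) / (max(cv$press, press_floor) / df2)
  list(f_stat = f, df1 = a, df2 = df2,
       p_value = stats::pf(f, a, df2, lower.tail = FALSE),
       degenerate = degenerate)
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model under random permutations of the class labels, using
#' the same fold rule for each permuted Q2, and reports add-one permutation
#' p-values for both R2Y and Q2: `p = (1 + #{permuted >= observed}) /
#' (1 + n_permutations)`. A permutation that reproduces the original labels
#' still counts toward the numerator.
#'
#' @param X samples x metabolites matrix.
#' @param labels two-level class vector.
#' @param n_orthogonal orthogonal components.
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed (drives both folds and permutations).
#' @param folds,scaling passed to the fitting routines.
#' @return list: `p_r2y`, `p_q2`, `observed` (r2y, q2), `null_r2y`,
#'   `null_q2`.
#' @export
permutation_test <- function(X, labels, n_orthogonal = 0,
                             n_permutations = 100, seed = 1L,
                             folds = "auto", scaling = "unit_variance") {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  X <- as.matrix(X)
  labels <- as.factor(labels)
  obs_fit <- fit_oplsda(X, labels, n_orthogonal, scaling)
  obs_cv <- cross_validate(X, labels, n_orthogonal, folds, seed, scaling)
  null_r2y <- null_q2 <- numeric(n_permutations)
  set.seed(seed + 1L)
  perms <- replicate(n_permutations, sample(length(labels)), simplify = FALSE)
  for (i in seq_len(n_permutations)) {
    lp <- labels[perms[[i]]]
    null_r2y[i] <- tryCatch(
      fit_oplsda(X, lp, n_orthogonal, scaling)$r2y, error = function(e) NA_real_)
    null_q2[i] <- tryCatch(
      cross_validate(X, lp, n_orthogonal, folds, seed, scaling)$q2,
      error = function(e) NA_real_)
  }
  p_of <- function(null, obs) {
    (1 + sum(null >= obs, na.rm = TRUE)) / (1 + n_permutations)
  }
  list(p_r2y = p_of(null_r2y, obs_fit$r2y),
       p_q2 = p_of(null_q2, obs_cv$q2),
       observed = c(r2y = obs_fit$r2y, q2 = obs_cv$q2),
       null_r2y = null_r2y, null_q2 = null_q2)
}

#' Fit and validate an OPLS-DA model for one contrast
#'
#' Convenience wrapper: chooses the orthogonal component count, fits the
#' model, cross-validates, and runs CV-ANOVA and the permutation test. A
#' model is called validated when the Q2 permutation p-value is below
#' `alpha` and Q2 is positive.
#'
#' @param X samples x metabolites matrix.
#' @param labels two-level class vector.
#' @param n_orthogonal `"auto"` (default) or an explicit count.
#' @param n_permutations permutations for the label test (default 100).
#' @param folds `"auto"` or an explicit count.
#' @param seed integer seed.
#' @param scaling `"unit_variance"` or `"center_only"`.
#' @param alpha validation level for the permutation p-value (default 0.05).
#' @return an `oplsda_validation` list: `model`, `cv`, `cv_anova`,
#'   `permutation`, `n_orthogonal`, `validated`.
#' @export
validate_oplsda <- function(X, labels, n_orthogonal = "auto",
                            n_permutations = 100, folds = "auto", seed = 1L,
                            scaling = "unit_variance", alpha = 0.05) {
  if (identical(n_orthogonal, "auto"))
    n_orthogonal <- choose_n_orthogonal(X, labels, folds = folds, seed = seed,
                                        scaling = scaling)
  model <- fit_oplsda(X, labels, n_orthogonal, scaling)
  cv <- cross_validate(X, labels, n_orthogonal, folds, seed, scaling)
  ca <- cv_anova(cv, labels, n_orthogonal)
  perm <- permutation_test(X, labels, n_orthogonal, n_permutations, seed,
                           folds, scaling)
  structure(list(model = model, cv = cv, cv_anova = ca, permutation = perm,
                 n_orthogonal = n_orthogonal,
                 validated = perm$p_q2 < alpha && cv$q2 > 0),
            class = "oplsda_validation")
}
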