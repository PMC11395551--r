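# From-scratch NIPALS chemometrics core: PCA, PLS1/PLS2, OPLS-DA,
# VIP, cross-validated Q2, permutation validation, CV-ANOVA.

# squared relative score change at convergence: 1e-24 gives ~1e-12 relative
# precision, tight enough to compare against SVD/eigen oracles at 1e-8
NIPALS_TOL <- 1e-24
NIPALS_MAXIT <- 5000L

#' Column scaling for latent-variable models
#'
#' Mean-centers every column and divides by the column standard deviation
#' (`unit_variance`, the usual autoscaling), its square root (`pareto`) or
#' nothing (`center_only`). Constant columns get scale 1 and are flagged so
#' they cannot blow up to NaN.
#'
#' @param X numeric matrix (observations x variables).
#' @param mode scaling mode.
#' @return list of class `"scaled_matrix"`: `values, column_means,
#'   column_scales, scaling_mode, constant`.
#' @export
autoscale <- function(X, mode = c("unit_variance", "pareto", "center_only")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  constant <- s == 0 | is.na(s)
  if (any(constant)) {
    ak_log("WARN", "%d constant column(s) scaled by 1", sum(constant))
  }
  scales <- switch(mode,
    unit_variance = ifelse(constant, 1, s),
    pareto = ifelse(constant, 1, sqrt(s)),
    center_only = rep(1, ncol(X))
  )
  vals <- sweep(sweep(X, 2, mu, "-"), 2, scales, "/")
  structure(
    list(values = vals, column_means = mu, column_scales = scales,
         scaling_mode = mode, constant = constant),
    class = "scaled_matrix"
  )
}

#' Invert an [autoscale()] transform
#' @param scaled a `scaled_matrix`.
#' @param values optional matrix in scaled units (defaults to the stored one).
#' @return matrix on the original scale.
#' @export
descale <- function(scaled, values = scaled$values) {
  sweep(sweep(values, 2, scaled$column_scales, "*"), 2, scaled$column_means, "+")
}

# fix component sign so the largest-|.| loading entry is positive
fix_sign <- function(t, p, ...) {
  flip <- sign(p[which.max(abs(p))])
  if (flip == 0) flip <- 1
  lapply(c(list(t = t * flip, p = p * flip), lapply(list(...), function(v) v * flip)),
         identity)
}

#' PCA by NIPALS iteration
#'
#' Extracts `k` principal components by the NIPALS power iteration with
#' deflation. Scores are mutually orthogonal; each component's sign is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param X_scaled a `scaled_matrix` or a pre-scaled numeric matrix.
#' @param k number of components, `k <= min(dim(X))`.
#' @return latent model list: `kind, T, P, explained_per_component, R2X`.
#' @export
pca_fit <- function(X_scaled, k) {
  X <- if (inherits(X_scaled, "scaled_matrix")) X_scaled$values else as.matrix(X_scaled)
  stopifnot(k >= 1, k <= min(dim(X)))
  ss_tot <- sum(X^2)
  Tm <- matrix(0, nrow(X), k)
  Pm <- matrix(0, ncol(X), k)
  expl <- numeric(k)
  for (a in seq_len(k)) {
    if (sum(X^2) < 1e-12 * max(ss_tot, 1)) {
      ak_log("WARN", "PCA component %d: residual matrix is rank-deficient; zero component", a)
      break
    }
    t <- X[, which.max(colSums(X^2))]
    for (it in seq_len(NIPALS_MAXIT)) {
      p <- crossprod(X, t)[, 1] / sum(t^2)
      p <- p / sqrt(sum(p^2))
      t_new <- (X %*% p)[, 1]
      if (sum((t_new - t)^2) < NIPALS_TOL * sum(t_new^2)) { t <- t_new; break }
      t <- t_new
      if (it == NIPALS_MAXIT) {
        stop(sprintf("PCA NIPALS failed to converge for component %d", a), call. = FALSE)
      }
    }
    sp <- fix_sign(t, p)
    t <- sp$t; p <- sp$p
    Tm[, a] <- t
    Pm[, a] <- p
    expl[a] <- sum(t^2) / ss_tot
    X <- X - tcrossprod(t, p)
  }
  structure(
    list(kind = "pca", T = Tm, P = Pm,
         explained_per_component = expl, R2X = sum(expl)),
    class = "latent_model"
  )
}

#' PLS regression by NIPALS (PLS1/PLS2)
#'
#' Fits `n_components` PLS components with X- and Y-deflation. With a single
#' Y column this reduces to PLS1. `B` holds the regression coefficients on
#' the scaled data so that `X %*% B` reproduces the fitted Y.
#'
#' @param X_scaled,Y_scaled `scaled_matrix` objects or pre-scaled matrices.
#' @param n_components number of latent components.
#' @return latent model list: `kind, T, P, W, C, U, B, R2X, R2Y,
#'   explained_y_per_component, ssy_per_component, n_components`.
#' @export
pls_fit <- function(X_scaled, Y_scaled, n_components) {
  X <- if (inherits(X_scaled, "scaled_matrix")) X_scaled$values else as.matrix(X_scaled)
  Y <- if (inherits(Y_scaled, "scaled_matrix")) Y_scaled$values else as.matrix(Y_scaled)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  stopifnot(nrow(X) == nrow(Y), n_components >= 1)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ssx_tot <- sum(X^2); ssy_tot <- sum(Y^2)

  Tm <- matrix(0, n, n_components); Um <- matrix(0, n, n_components)
  Wm <- matrix(0, p, n_components); Pm <- matrix(0, p, n_components)
  Cm <- matrix(0, q, n_components)
  ssy_comp <- numeric(n_components)
  ssx_comp <- numeric(n_components)
  a_used <- 0L

  if (ssy_tot < 1e-12) {
    # degenerate: nothing to explain, zero model
    return(structure(
      list(kind = "pls", T = Tm[, 0, drop = FALSE], P = Pm[, 0, drop = FALSE],
           W = Wm[, 0, drop = FALSE], C = Cm[, 0, drop = FALSE],
           U = Um[, 0, drop = FALSE], B = matrix(0, p, q),
           R2X = 0, R2Y = 0, explained_y_per_component = numeric(0),
           ssy_per_component = numeric(0), n_components = 0L),
      class = "latent_model"
    ))
  }

  for (a in seq_len(n_components)) {
    if (sum(Y^2) < 1e-10 * ssy_tot || sum(X^2) < 1e-10 * max(ssx_tot, 1)) break
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(NIPALS_MAXIT)) {
      w <- crossprod(X, u)[, 1] / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t <- (X %*% w)[, 1]
      cvec <- crossprod(Y, t)[, 1] / sum(t^2)
      u <- (Y %*% cvec)[, 1] / sum(cvec^2)
      if (sum((t - t_old)^2) < NIPALS_TOL * sum(t^2)) break
      t_old <- t
      if (it == NIPALS_MAXIT) {
        stop(sprintf("PLS NIPALS inner loop failed to converge for component %d", a),
             call. = FALSE)
      }
    }
    pvec <- crossprod(X, t)[, 1] / sum(t^2)
    sp <- fix_sign(t, pvec, w = w)
    t <- sp$t; pvec <- sp$p; w <- sp$w
    cvec <- crossprod(Y, t)[, 1] / sum(t^2)

    a_used <- a
    Tm[, a] <- t; Um[, a] <- u
    Wm[, a] <- w; Pm[, a] <- pvec; Cm[, a] <- cvec
    ssx_comp[a] <- sum(tcrossprod(t, pvec)^2)
    ssy_comp[a] <- sum(t^2) * sum(cvec^2)
    X <- X - tcrossprod(t, pvec)
    Y <- Y - tcrossprod(t, cvec)
  }
  idx <- seq_len(a_used)
  Tm <- Tm[, idx, drop = FALSE]; Um <- Um[, idx, drop = FALSE]
  Wm <- Wm[, idx, drop = FALSE]; Pm <- Pm[, idx, drop = FALSE]
  Cm <- Cm[, idx, drop = FALSE]
  B <- if (a_used > 0) {
    Wm %*% solve(crossprod(Pm, Wm), t(Cm))
  } else matrix(0, p, q)
  structure(
    list(kind = "pls", T = Tm, P = Pm, W = Wm, C = Cm, U = Um, B = B,
         R2X = sum(ssx_comp) / ssx_tot,
         R2Y = 1 - sum(Y^2) / ssy_tot,
         explained_y_per_component = ssy_comp[idx] / ssy_tot,
         ssy_per_component = ssy_comp[idx],
         n_components = a_used),
    class = "latent_model"
  )
}

#' Predict scaled responses from a PLS model
#' @param model a `latent_model` of kind pls.
#' @param X_new matrix in the same scaled units the model was fit on.
#' @return matrix of predicted scaled responses.
#' @export
pls_predict <- function(model, X_new) {
  as.matrix(X_new) %*% model$B
}

# ---- OPLS-DA ----------------------------------------------------------------

# one pass of orthogonal-component extraction; returns updated X and component
osc_component <- function(X, y) {
  w <- crossprod(X, y)[, 1]
  nw0 <- sqrt(sum(w^2))
  if (!is.finite(nw0) || nw0 < 1e-300) return(NULL)
  w <- w / nw0
  t <- (X %*% w)[, 1]
  p <- crossprod(X, t)[, 1] / sum(t^2)
  w_o <- p - sum(w * p) * w
  nw <- sqrt(sum(w_o^2))
  if (nw < 1e-12) return(NULL)  # no orthogonal variation left
  w_o <- w_o / nw
  t_o <- (X %*% w_o)[, 1]
  p_o <- crossprod(X, t_o)[, 1] / sum(t_o^2)
  list(X = X - tcrossprod(t_o, p_o), w_orth = w_o, t_orth = t_o, p_orth = p_o)
}

opls_core <- function(X, y_c, n_orth) {
  p <- ncol(X)
  W_o <- matrix(0, p, 0); P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xf <- X
  for (k in seq_len(n_orth)) {
    oc <- osc_component(Xf, y_c)
    if (is.null(oc)) break
    Xf <- oc$X
    W_o <- cbind(W_o, oc$w_orth); P_o <- cbind(P_o, oc$p_orth)
    T_o <- cbind(T_o, oc$t_orth)
  }
  # final single predictive component on the filtered matrix; a fold whose
  # training split carries no class contrast degenerates to the zero model
  w <- crossprod(Xf, y_c)[, 1]
  nw <- sqrt(sum(w^2))
  if (!is.finite(nw) || nw < 1e-300) {
    p_dim <- ncol(X)
    return(list(w = rep(0, p_dim), t = rep(0, nrow(X)), p = rep(0, p_dim),
                c = 0, W_orth = W_o, P_orth = P_o, T_orth = T_o,
                X_filtered = Xf))
  }
  w <- w / nw
  t <- (Xf %*% w)[, 1]
  pv <- crossprod(Xf, t)[, 1] / sum(t^2)
  cc <- sum(y_c * t) / sum(t^2)
  list(w = w, t = t, p = pv, c = cc, W_orth = W_o, P_orth = P_o, T_orth = T_o,
       X_filtered = Xf)
}

opls_predict_core <- function(core, X_new) {
  Xf <- as.matrix(X_new)
  n_o <- ncol(core$W_orth)
  for (k in seq_len(n_o)) {
    t_o <- (Xf %*% core$W_orth[, k])[, 1]
    Xf <- Xf - tcrossprod(t_o, core$P_orth[, k])
  }
  (Xf %*% core$w)[, 1] * core$c
}

venetian_folds <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L

# cross-validated predictions of an OPLS (or 0-component null) model;
# y is the raw 0/1 indicator, X already scaled
opls_cv_press <- function(X, y01, n_orth, folds) {
  n <- length(y01)
  fold <- venetian_folds(n, folds)
  pred <- numeric(n)
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (length(unique(y01[tr])) < 2) {
      ak_log("WARN", "CV fold %d: a class is absent from the training split", f)
    }
    # recenter both blocks on the training split
    mu_x <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, mu_x)
    y_tr_c <- y01[tr] - mean(y01[tr])
    core <- opls_core(Xtr, y_tr_c, n_orth)
    Xte <- sweep(X[te, , drop = FALSE], 2, mu_x)
    pred[te] <- opls_predict_core(core, Xte) + mean(y01[tr])
  }
  pred
}

#' OPLS-DA: orthogonal PLS discriminant analysis for two classes
#'
#' Encodes the two classes as a centered 0/1 indicator, strips `n_orth`
#' Y-orthogonal components from X, then fits a single predictive PLS
#' component on the filtered matrix. With `n_orth = "auto"`, orthogonal
#' components are added while cross-validated Q2 improves (at most 3).
#'
#' @param X_scaled `scaled_matrix` or pre-scaled matrix.
#' @param class_labels factor/character/numeric with exactly 2 levels.
#' @param n_orth number of orthogonal components, or `"auto"`.
#' @param cv_folds folds for the venetian-blind Q2 (and the `"auto"` search).
#' @return latent model list: `kind, T, P, W, C, B, T_orth, P_orth, W_orth,
#'   n_orth, R2X, R2X_orth, R2Y, Q2, y, classes`.
#' @export
opls_da_fit <- function(X_scaled, class_labels, n_orth = "auto", cv_folds = 7) {
  X <- if (inherits(X_scaled, "scaled_matrix")) X_scaled$values else as.matrix(X_scaled)
  cls <- as.factor(class_labels)
  if (nlevels(cls) != 2) stop("OPLS-DA needs exactly 2 classes", call. = FALSE)
  if (min(table(cls)) < 2) {
    ak_log("WARN", "a class has < 2 observations; cross-validation folds degenerate")
  }
  y01 <- as.numeric(cls == levels(cls)[2])
  y_c <- y01 - mean(y01)
  folds <- min(cv_folds, nrow(X))

  if (identical(n_orth, "auto")) {
    best_q2 <- -Inf; n_orth <- 0L
    for (k in 0:3) {
      pred <- opls_cv_press(X, y01, k, folds)
      q2_k <- 1 - sum((y01 - pred)^2) / sum((y01 - mean(y01))^2)
      if (q2_k > best_q2 + 1e-10) { best_q2 <- q2_k; n_orth <- k } else break
    }
  }

  core <- opls_core(X, y_c, n_orth)
  sp <- fix_sign(core$t, core$p, w = core$w)
  tvec <- sp$t; pvec <- sp$p; wvec <- sp$w
  cc <- sum(y_c * tvec) / sum(tvec^2)

  fitted_c <- tvec * cc
  r2y <- 1 - sum((y_c - fitted_c)^2) / sum(y_c^2)
  ssx_tot <- sum(X^2)
  r2x_pred <- sum(tcrossprod(tvec, pvec)^2) / ssx_tot
  r2x_orth <- if (ncol(core$T_orth) > 0) {
    sum(vapply(seq_len(ncol(core$T_orth)), function(k) {
      sum(tcrossprod(core$T_orth[, k], core$P_orth[, k])^2)
    }, numeric(1))) / ssx_tot
  } else 0

  pred_cv <- opls_cv_press(X, y01, ncol(core$W_orth), folds)
  q2 <- 1 - sum((y01 - pred_cv)^2) / sum((y01 - mean(y01))^2)

  structure(
    list(kind = "opls_da",
         T = matrix(tvec, ncol = 1), P = matrix(pvec, ncol = 1),
         W = matrix(wvec, ncol = 1), C = matrix(cc, 1, 1),
         B = matrix(wvec * cc, ncol = 1),
         T_orth = core$T_orth, P_orth = core$P_orth, W_orth = core$W_orth,
         n_orth = ncol(core$W_orth),
         ssy_per_component = sum(tvec^2) * cc^2,
         R2X = r2x_pred + r2x_orth, R2X_pred = r2x_pred, R2X_orth = r2x_orth,
         R2Y = r2y, Q2 = q2,
         y = y_c, y01 = y01, classes = levels(cls), cv_folds = folds),
    class = "latent_model"
  )
}

#' Cross-validated Q2 per cumulative component
#'
#' Venetian-blind cross-validation: observation i goes to fold
#' `((i - 1) mod folds) + 1`, deterministic in the row order. For each fold
#' the model is refit on the remaining rows (responses re-centered on the
#' training split) and held-out rows predicted; Q2_A = 1 - PRESS_A / SS.
#'
#' @param X_scaled,Y_scaled scaled matrices (see [autoscale()]).
#' @param n_components maximum number of PLS components.
#' @param folds number of folds (>= 2, <= n).
#' @return numeric vector `Q2[a]`, one entry per cumulative component count.
#' @export
q2_cross_validation <- function(X_scaled, Y_scaled, n_components, folds = 7) {
  X <- if (inherits(X_scaled, "scaled_matrix")) X_scaled$values else as.matrix(X_scaled)
  Y <- if (inherits(Y_scaled, "scaled_matrix")) Y_scaled$values else as.matrix(Y_scaled)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  n <- nrow(X)
  stopifnot(folds >= 2, folds <= n)
  fold <- venetian_folds(n, folds)
  press <- matrix(0, length(unique(fold)), n_components)
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    mu_x <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, mu_x)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, mu_x)
    Ytr_mu <- colMeans(Y[tr, , drop = FALSE])
    Ytr <- sweep(Y[tr, , drop = FALSE], 2, Ytr_mu)
    for (a in seq_len(n_components)) {
      m <- pls_fit(Xtr, Ytr, a)
      pred <- sweep(pls_predict(m, Xte), 2, Ytr_mu, "+")
      press[f, a] <- sum((Y[!tr, , drop = FALSE] - pred)^2)
    }
  }
  1 - colSums(press) / ss
}

#' Variable importance in projection (VIP)
#'
#' Standard PLS-VIP over the predictive components:
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ).
#' For OPLS models only the predictive component enters by default.
#'
#' @param model a fitted PLS-family `latent_model`.
#' @return numeric vector of VIP scores (mean of squares = 1).
#' @export
vip <- function(model) {
  if (!model$kind %in% c("pls", "opls_da", "plsr")) {
    stop("VIP needs a PLS-family model", call. = FALSE)
  }
  W <- model$W
  ssy <- model$ssy_per_component
  if (length(ssy) == 0 || sum(ssy) <= 0) stop("model explains no Y variance", call. = FALSE)
  p <- nrow(W)
  wn2 <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  v <- sqrt(p * (wn2 %*% ssy)[, 1] / sum(ssy))
  setNames(v, rownames(W))
}

#' Permutation (label-scrambling) validation of a supervised model
#'
#' Refits the OPLS-DA model `n` times under uniformly permuted class labels.
#' The p-value is (1 + #{Q2_perm >= Q2_obs}) / (n + 1). The regression
#' intercepts of permuted R2Y and Q2 on the |correlation| between permuted
#' and original labels summarize the classical validation plot.
#'
#' @param X_scaled scaled predictor matrix.
#' @param class_labels two-class labels.
#' @param n number of permutations.
#' @param n_orth orthogonal components for every refit (default: as selected
#'   on the observed labels).
#' @param cv_folds CV folds for Q2.
#' @return list: `observed` model, `permuted` tibble
#'   (`cor_abs, R2Y, Q2`), `r2y_intercept, q2_intercept, p_value, n`.
#' @export
permutation_test <- function(X_scaled, class_labels, n = 200,
                             n_orth = NULL, cv_folds = 7) {
  X <- if (inherits(X_scaled, "scaled_matrix")) X_scaled$values else as.matrix(X_scaled)
  obs <- opls_da_fit(X, class_labels,
                     n_orth = if (is.null(n_orth)) "auto" else n_orth,
                     cv_folds = cv_folds)
  k_orth <- obs$n_orth
  y <- obs$y01
  r2y_p <- numeric(n); q2_p <- numeric(n); cor_p <- numeric(n)
  for (i in seq_len(n)) {
    y_perm <- sample(y)
    m <- opls_da_fit(X, y_perm, n_orth = k_orth, cv_folds = cv_folds)
    r2y_p[i] <- m$R2Y; q2_p[i] <- m$Q2
    cr <- suppressWarnings(cor(y_perm, y))
    cor_p[i] <- if (is.na(cr)) 0 else abs(cr)
  }
  fit_int <- function(v) unname(coef(stats::lm(v ~ cor_p))[1])
  list(
    observed = obs,
    permuted = tibble(cor_abs = cor_p, R2Y = r2y_p, Q2 = q2_p),
    r2y_intercept = fit_int(r2y_p),
    q2_intercept = fit_int(q2_p),
    p_value = (1 + sum(q2_p >= obs$Q2)) / (n + 1),
    n = n
  )
}

#' CV-ANOVA: F-test of cross-validated residuals against the mean-only null
#'
#' PRESS-ratio construction: F is the ratio of the mean squared
#' cross-validated residual of the null (training-mean predictor) to that of
#' the model, F = (PRESS0/df1) / (PRESS/df2) with df1 = n - 1 and
#' df2 = n - 1 - A, A the number of fitted latent components; the p-value
#' comes from the F distribution at (df1, df2).
#'
#' @param resid_null cross-validated residuals of the mean-only predictor.
#' @param resid_model cross-validated residuals of the fitted model.
#' @param n_components total latent components of the model (predictive +
#'   orthogonal).
#' @return list `F, df1, df2, p_value, press_null, press_model`.
#' @export
cv_anova <- function(resid_null, resid_model, n_components) {
  n <- length(resid_null)
  stopifnot(length(resid_model) == n)
  press0 <- sum(resid_null^2)
  press1 <- sum(resid_model^2)
  df1 <- n - 1
  df2 <- n - 1 - n_components
  if (df2 <= 0) stop("too few observations for CV-ANOVA degrees of freedom", call. = FALSE)
  if (press1 == 0) {
    ak_log("WARN", "CV-ANOVA: zero model residuals; F reported as Inf")
    return(list(F = Inf, df1 = df1, df2 = df2, p_value = 0,
                press_null = press0, press_model = press1))
  }
  Fv <- (press0 / df1) / (press1 / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       press_null = press0, press_model = press1)
}

#' CV-ANOVA for a fitted OPLS-DA model
#'
#' Recomputes the model's venetian-blind cross-validated predictions and the
#' null (training-fold mean) predictions, then applies [cv_anova()].
#'
#' @param model a fitted `opls_da` model.
#' @param X_scaled the scaled matrix the model was fit on.
#' @return see [cv_anova()].
#' @export
cv_anova_opls <- function(model, X_scaled) {
  X <- if (inherits(X_scaled, "scaled_matrix")) X_scaled$values else as.matrix(X_scaled)
  y <- model$y01
  folds <- model$cv_folds
  fold <- venetian_folds(length(y), folds)
  pred_model <- opls_cv_press(X, y, model$n_orth, folds)
  pred_null <- numeric(length(y))
  for (f in sort(unique(fold))) {
    pred_null[fold == f] <- mean(y[fold != f])
  }
  cv_anova(y - pred_null, y - pred_model, n_components = 1 + model$n_orth)
}
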