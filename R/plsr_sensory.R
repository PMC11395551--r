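# PLSR linking key-compound concentrations to sensory attributes,
# with correlation loadings and jack-knife coefficient significance.

#' PLSR of sensory attributes on key-compound concentrations
#'
#' Fits a two-factor PLS2 model of the sensory attribute block on the
#' compound concentration block (both autoscaled) and computes correlation
#' loadings: the Pearson correlation of every original X and Y column with
#' the two factor score vectors. Points lie inside the unit (100% explained
#' variance) circle; the inner circle at radius sqrt(0.5) marks 50%.
#'
#' @param X matrix of compound concentrations (rows = sample x replicate).
#' @param Y matrix of sensory attribute scores aligned to the rows of `X`.
#' @param n_components number of PLS factors (default 2, for the biplot).
#' @param scaling scaling mode for both blocks.
#' @return list of class `"plsr_sensory"`: `model` (latent model),
#'   `correlation_loadings` tibble (`variable, block, r1, r2`),
#'   `inner_radius, outer_radius, explained_x, explained_y`,
#'   plus the scaled blocks for downstream jack-knifing.
#' @export
plsr_sensory <- function(X, Y, n_components = 2,
                         scaling = c("unit_variance", "pareto", "center_only")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 3) stop("PLSR needs at least 3 observations", call. = FALSE)
  stopifnot(nrow(X) == nrow(Y))
  Xs <- autoscale(X, scaling)
  Ys <- autoscale(Y, scaling)
  model <- pls_fit(Xs, Ys, n_components)
  model$kind <- "plsr"
  rownames(model$W) <- colnames(X)

  corr_with <- function(M, block) {
    r1 <- apply(M, 2, function(col) safe_cor(col, model$T[, 1]))
    r2 <- if (ncol(model$T) >= 2) {
      apply(M, 2, function(col) safe_cor(col, model$T[, 2]))
    } else rep(0, ncol(M))
    tibble(variable = colnames(M), block = block, r1 = r1, r2 = r2)
  }
  cl <- dplyr::bind_rows(corr_with(X, "compound"), corr_with(Y, "attribute"))

  ssx <- sum(Xs$values^2); ssy <- sum(Ys$values^2)
  structure(
    list(model = model,
         correlation_loadings = cl,
         inner_radius = sqrt(0.5), outer_radius = 1,
         explained_x = model$R2X, explained_y = model$R2Y,
         X_scaled = Xs, Y_scaled = Ys),
    class = "plsr_sensory"
  )
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Jack-knife significance of PLS regression coefficients
#'
#' Martens-style uncertainty: the model is refit with each observation left
#' out, and the coefficient uncertainty is
#' u_jk = sqrt( sum_i g * (b_(-i) - b)^2 ) with g = (n-1)/n. A coefficient is
#' significant when |b| > u_jk * t_(1 - alpha/2, n-1).
#'
#' @param fit a [plsr_sensory()] result (or list with `X_scaled, Y_scaled,
#'   model`).
#' @param alpha two-sided significance level.
#' @return tibble `variable, attribute, coefficient, uncertainty, t_ratio,
#'   significant`.
#' @export
jackknife_significance <- function(fit, alpha = 0.05) {
  X <- fit$X_scaled$values
  Y <- fit$Y_scaled$values
  n <- nrow(X)
  if (n < 3) stop("jack-knife needs at least 3 observations", call. = FALSE)
  A <- fit$model$n_components
  B <- fit$model$B
  g <- (n - 1) / n
  acc <- matrix(0, nrow(B), ncol(B))
  for (i in seq_len(n)) {
    m_i <- tryCatch(
      pls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], A),
      error = function(e) {
        stop(sprintf("jack-knife refit failed leaving out observation %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
    Bi <- m_i$B
    if (ncol(Bi) != ncol(B) || nrow(Bi) != nrow(B)) {
      stop(sprintf("jack-knife refit degenerate leaving out observation %d", i),
           call. = FALSE)
    }
    acc <- acc + g * (Bi - B)^2
  }
  u <- sqrt(acc)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  xn <- colnames(X); if (is.null(xn)) xn <- paste0("x", seq_len(nrow(B)))
  yn <- colnames(Y); if (is.null(yn)) yn <- paste0("y", seq_len(ncol(B)))
  out <- expand.grid(variable = xn, attribute = yn,
                     stringsAsFactors = FALSE)
  out$coefficient <- as.vector(B)
  out$uncertainty <- as.vector(u)
  out$t_ratio <- ifelse(out$uncertainty > 0, abs(out$coefficient) / out$uncertainty,
                        ifelse(abs(out$coefficient) > 0, Inf, 0))
  out$significant <- out$t_ratio > tcrit
  as_tibble(out)
}
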