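#' Cross-validated deviance for one penalty pair
#'
#' Splits samples into `folds` parts by seeded shuffling, fits the model on
#' each training set and accumulates the Gaussian deviance (held-out residual
#' sum of squares) on the left-out samples. Burden columns that are constant
#' within a training fold are dropped for that fold with a warning.
#'
#' @param X a `collapsed_design` or matrix.
#' @param Y phenotype matrix.
#' @param spec a [model_spec()] (its penalties are overridden).
#' @param lambda_G,lambda_P penalty pair to evaluate.
#' @param folds number of CV folds (>= 2).
#' @param cv_seed seed for the fold assignment (independent of the fit /
#'   permutation streams).
#' @param blocks per-pathway column indices (with matrix `X`).
#' @return mean held-out deviance across folds.
#' @export
cv_deviance <- function(X, Y, spec = model_spec(), lambda_G, lambda_P,
                        folds = 3, cv_seed = 1L, blocks = NULL) {
  d <- resolve_design(X, blocks)
  Y <- as.matrix(Y)
  N <- nrow(Y)
  stopifnot(folds >= 2, folds <= N)
  fold_id <- cv_folds(N, folds, cv_seed)
  spec$lambda_G <- lambda_G
  spec$lambda_P <- lambda_P
  dev <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- d$X[!test, , drop = FALSE]
    sds <- apply(Xtr, 2, stats::sd)
    keep <- sds > 0
    blocks_f <- d$blocks
    if (!all(keep)) {
      warning("fold ", f, ": dropping ", sum(!keep), " constant burden column(s)")
      remap <- cumsum(keep)
      blocks_f <- lapply(d$blocks, function(idx) remap[idx[keep[idx]]])
      blocks_f <- blocks_f[vapply(blocks_f, length, integer(1)) > 0]
    }
    Xtr <- Xtr[, keep, drop = FALSE]
    fit <- suppressWarnings(
      fit_model(Xtr, Y[!test, , drop = FALSE], spec, blocks = blocks_f)
    )
    Xte <- d$X[test, keep, drop = FALSE]
    Fte <- latent_from_w(Xte, fit$W, fit$blocks)
    pred <- sweep(Fte %*% fit$B, 2, fit$b0, `+`)
    dev[f] <- sum((Y[test, , drop = FALSE] - pred)^2)
  }
  mean(dev)
}

cv_folds <- function(N, folds, cv_seed) {
  set.seed(cv_seed)
  sample(rep(seq_len(folds), length.out = N))
}

#' Penalty grid constructor
#'
#' Default: six log10-spaced points from 1e1 to 1e6 on each axis
#' (36 cells), evaluated with 3-fold CV.
#' @param lambda_G,lambda_P candidate values for each axis.
#' @param folds CV folds.
#' @return list of class `penalty_grid`.
#' @export
penalty_grid <- function(lambda_G = 10^(1:6), lambda_P = 10^(1:6), folds = 3) {
  stopifnot(all(lambda_G > 0), all(lambda_P > 0), folds >= 2)
  structure(list(lambda_G = sort(lambda_G), lambda_P = sort(lambda_P),
                 folds = folds),
            class = "penalty_grid")
}

#' Select ridge penalties by k-fold cross-validation
#'
#' Evaluates mean held-out deviance on the two-dimensional grid and returns
#' the arg-min cell. Ties are broken toward more regularization
#' (lexicographically larger `lambda_P`, then `lambda_G`).
#'
#' @inheritParams cv_deviance
#' @param grid a [penalty_grid()].
#' @return list with `lambda_G`, `lambda_P`, `deviance` (full grid
#'   data.frame) and the selected cell's mean deviance.
#' @export
select_penalties <- function(X, Y, spec = model_spec(), grid = penalty_grid(),
                             cv_seed = 1L, blocks = NULL) {
  cells <- expand.grid(lambda_G = grid$lambda_G, lambda_P = grid$lambda_P,
                       KEEP.OUT.ATTRS = FALSE)
  cells$deviance <- vapply(seq_len(nrow(cells)), function(i) {
    cv_deviance(X, Y, spec, cells$lambda_G[i], cells$lambda_P[i],
                folds = grid$folds, cv_seed = cv_seed, blocks = blocks)
  }, numeric(1))
  if (any(!is.finite(cells$deviance))) {
    stop("non-finite CV deviance for some grid cells")
  }
  # arg-min; ties -> larger lambda_P, then larger lambda_G
  ord <- order(cells$deviance, -cells$lambda_P, -cells$lambda_G)
  best <- cells[ord[1], ]
  list(lambda_G = best$lambda_G, lambda_P = best$lambda_P,
       deviance = cells, min_deviance = best$deviance)
}
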