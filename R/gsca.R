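#' Model specification for the hierarchical component fit
#'
#' @param lambda_G ridge penalty on gene weights (>= 0).
#' @param lambda_P ridge penalty on pathway-to-phenotype coefficients (>= 0).
#' @param tol convergence tolerance on the summed L1 change of all weights
#'   and coefficients between iterations (default 1e-5).
#' @param max_iter iteration cap (default 500).
#' @param seed integer seed for the random weight initialization.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(lambda_G = 0, lambda_P = 0, tol = 1e-5,
                       max_iter = 500, seed = 1L) {
  stopifnot(lambda_G >= 0, lambda_P >= 0, tol > 0, max_iter >= 1)
  structure(list(lambda_G = lambda_G, lambda_P = lambda_P, tol = tol,
                 max_iter = max_iter, seed = as.integer(seed)),
            class = "model_spec")
}

# resolve X/blocks from a collapsed_design or a plain matrix + blocks list
resolve_design <- function(X, blocks = NULL) {
  if (inherits(X, "collapsed_design")) {
    list(X = X$X, blocks = X$blocks)
  } else {
    if (is.null(blocks)) stop("blocks must be supplied for a plain matrix design")
    list(X = as.matrix(X), blocks = blocks)
  }
}

#' Random initial gene weights
#'
#' Draws each weight from Uniform(-1, 1) and rescales every pathway block so
#' that the implied latent score satisfies the scaling constraint
#' `sum_i f_ik^2 = N`.
#'
#' @param X design (a `collapsed_design` or matrix).
#' @param blocks per-pathway column index list (if `X` is a matrix).
#' @param seed integer seed.
#' @return numeric weight vector (one entry per design column), block-scaled.
#' @export
init_weights <- function(X, blocks = NULL, seed = 1L) {
  d <- resolve_design(X, blocks)
  set.seed(seed)
  w <- stats::runif(ncol(d$X), -1, 1)
  compute_latent_scores(d$X, w, d$blocks)$w
}

#' Latent pathway scores under the scaling constraint
#'
#' Computes `f_k = X_k w_k`, rescaled by `sqrt(N)/||X_k w_k||` so that
#' `diag(F'F) = N I`. The rescale factor is folded back into the returned
#' weights, so `X_k %*% w_k` reproduces `F[, k]` exactly.
#'
#' @param X design matrix (or `collapsed_design`).
#' @param w weight vector.
#' @param blocks per-pathway column index list.
#' @return list with `F` (N x K), `w` (rescaled weights), `s` (per-pathway
#'   rescale factors applied).
#' @export
compute_latent_scores <- function(X, w, blocks = NULL) {
  d <- resolve_design(X, blocks)
  X <- d$X; blocks <- d$blocks
  N <- nrow(X); K <- length(blocks)
  F_ <- matrix(0, N, K, dimnames = list(rownames(X), names(blocks)))
  s <- numeric(K)
  for (k in seq_len(K)) {
    idx <- blocks[[k]]
    v <- X[, idx, drop = FALSE] %*% w[idx]
    nv <- sqrt(sum(v^2))
    if (nv == 0) {
      stop("degenerate pathway block ", names(blocks)[k],
           ": X_k w_k has zero norm (collinear or zero weights)")
    }
    s[k] <- sqrt(N) / nv
    F_[, k] <- v * s[k]
    w[idx] <- w[idx] * s[k]
  }
  list(F = F_, w = w, s = s)
}

#' Ridge update of pathway-to-phenotype coefficients
#'
#' Solves the penalized normal equations for `B` given latent scores `F`:
#' Q independent ridge regressions of each phenotype on the K scores (plus
#' optional unpenalized covariates). Intercepts are estimated but never
#' penalized; phenotypes are column-centered internally.
#'
#' @param F N x K latent score matrix.
#' @param Y N x Q phenotype matrix.
#' @param lambda_P ridge penalty.
#' @param C optional N x L covariate matrix (unpenalized).
#' @return list with `B` (K x Q), `b0` (length-Q intercepts), `G`
#'   (L x Q covariate coefficients or NULL).
#' @export
update_coefficients <- function(F, Y, lambda_P = 0, C = NULL) {
  Y <- as.matrix(Y); F <- as.matrix(F)
  K <- ncol(F); Q <- ncol(Y)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  if (is.null(C)) {
    A <- crossprod(F) + diag(lambda_P, K)
    rhs <- crossprod(F, Yc)
    B <- tryCatch(solve(A, rhs), error = function(e) {
      stop("singular coefficient system; try lambda_P > 0 (", conditionMessage(e), ")")
    })
    list(B = matrix(B, K, Q, dimnames = list(colnames(F), colnames(Y))),
         b0 = ybar, G = NULL)
  } else {
    C <- as.matrix(C)
    cbar <- colMeans(C)
    Cc <- sweep(C, 2, cbar)
    Z <- cbind(F, Cc)
    pen <- diag(c(rep(lambda_P, K), rep(0, ncol(C))))
    A <- crossprod(Z) + pen
    coefs <- tryCatch(solve(A, crossprod(Z, Yc)), error = function(e) {
      stop("singular coefficient system; try lambda_P > 0 (", conditionMessage(e), ")")
    })
    B <- coefs[seq_len(K), , drop = FALSE]
    G <- coefs[-seq_len(K), , drop = FALSE]
    list(B = B, b0 = ybar - as.numeric(crossprod(G, cbar)), G = G)
  }
}

#' Ridge update of gene weights
#'
#' Builds the stacked design whose column for the (pathway k, gene t) pair is
#' the stack over observations (i, q) of `beta_kq * x_ikt` (gene weights only
#' influence their own pathway's score), solves the penalized normal
#' equations, then renormalizes each pathway block to the scaling constraint
#' and rescales the matching row of `B` so fitted values are unchanged.
#'
#' @param X design matrix (or `collapsed_design`).
#' @param B current K x Q coefficients.
#' @param Y N x Q phenotype matrix (intercept/covariate contribution already
#'   removed; internally column-centered).
#' @param lambda_G ridge penalty on weights.
#' @param blocks per-pathway column index list.
#' @param w_prev previous weights: retained for any pathway whose
#'   coefficient row is numerically zero (unidentifiable block, flagged).
#' @return list with `w` (normalized weights), `B` (rescaled), `F`,
#'   `flagged` (names of unidentifiable pathways).
#' @export
update_weights <- function(X, B, Y, lambda_G = 0, blocks = NULL, w_prev = NULL) {
  d <- resolve_design(X, blocks)
  X <- d$X; blocks <- d$blocks
  Y <- as.matrix(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  P <- ncol(X)
  col_pathway <- integer(P)
  for (k in seq_along(blocks)) col_pathway[blocks[[k]]] <- k
  Bx <- B[col_pathway, , drop = FALSE]            # P x Q expanded coefficients
  XtX <- crossprod(X)
  XtY <- crossprod(X, Yc)
  A <- XtX * tcrossprod(Bx) + diag(lambda_G, P)
  rhs <- rowSums(Bx * XtY)
  w <- tryCatch(as.numeric(solve(A, rhs)), error = function(e) {
    stop("singular weight system; try lambda_G > 0 (", conditionMessage(e), ")")
  })
  flagged <- character(0)
  for (k in seq_along(blocks)) {
    if (max(abs(B[k, ])) < 1e-12) {
      flagged <- c(flagged, names(blocks)[k])
      if (!is.null(w_prev)) w[blocks[[k]]] <- w_prev[blocks[[k]]]
      else w[blocks[[k]]] <- 1
    }
  }
  ls <- compute_latent_scores(X, w, blocks)
  B_new <- B / ls$s   # row k scaled by 1/s_k keeps B'F fixed
  list(w = ls$w, B = B_new, F = ls$F, flagged = flagged)
}

#' Residual covariance after convergence
#'
#' `Sigma = E'E / N` with `E` the N x Q residual matrix (MLE divisor N).
#' @param Y N x Q phenotypes.
#' @param F N x K latent scores.
#' @param B K x Q coefficients.
#' @param b0 intercepts (default column means of `Y`).
#' @return Q x Q symmetric PSD matrix.
#' @export
estimate_residual_cov <- function(Y, F, B, b0 = colMeans(as.matrix(Y))) {
  Y <- as.matrix(Y)
  E <- sweep(Y, 2, b0) - as.matrix(F) %*% B
  S <- crossprod(E) / nrow(Y)
  (S + t(S)) / 2
}

#' Penalized least-squares criterion
#'
#' `sum_i ||Y_i - b0 - B'F_i||^2 + lambda_G ||w||^2 + lambda_P ||B||^2`
#' (intercepts unpenalized). Used as a convergence diagnostic.
#' @inheritParams estimate_residual_cov
#' @param w weight vector.
#' @param X design (matrix or `collapsed_design`); only needed to recompute
#'   `F` if `F` is missing.
#' @param lambda_G,lambda_P penalties.
#' @param blocks per-pathway column indices (with matrix `X`).
#' @return scalar criterion value.
#' @export
penalized_objective <- function(w, B, Y, X, lambda_G = 0, lambda_P = 0,
                                blocks = NULL, b0 = colMeans(as.matrix(Y))) {
  d <- resolve_design(X, blocks)
  F_ <- matrix(0, nrow(d$X), length(d$blocks))
  for (k in seq_along(d$blocks)) {
    idx <- d$blocks[[k]]
    F_[, k] <- d$X[, idx, drop = FALSE] %*% w[idx]
  }
  E <- sweep(as.matrix(Y), 2, b0) - F_ %*% B
  sum(E^2) + lambda_G * sum(w^2) + lambda_P * sum(B^2)
}

# ---- sufficient-statistics core -------------------------------------------
#
# The alternating least-squares iteration only ever needs X'X (P x P),
# X'Yc (P x Q), Yc'Yc (Q x Q) and N. Permutation inference refits the model
# thousands of times, so the core runs on these statistics; one fit costs
# O(P^2 Q) per iteration regardless of N.

fit_gsca_stats <- function(XtX, XtY, YtY, N, blocks, lambda_G, lambda_P,
                           w0, tol = 1e-5, max_iter = 500, relax = 1) {
  P <- nrow(XtX); Q <- ncol(XtY); K <- length(blocks)
  col_pathway <- integer(P)
  for (k in seq_len(K)) col_pathway[blocks[[k]]] <- k
  widx <- cbind(seq_len(P), col_pathway)   # positions of w in the P x K map
  IP <- diag(lambda_G, P)
  IK <- diag(lambda_P, K)
  Pmat <- matrix(0, P, K); Pmat[widx] <- 1   # block membership indicator

  # block-diagonal weight map Wm (P x K): F'F = Wm' XtX Wm, F'Y = Wm' XtY
  cross_F <- function(w) {
    Wm <- matrix(0, P, K)
    Wm[widx] <- w
    XW <- XtX %*% Wm
    list(FtF = crossprod(Wm, XW), FtY = crossprod(Wm, XtY), XW = XW, Wm = Wm)
  }
  normalize_w <- function(w) {
    Wm <- matrix(0, P, K)
    Wm[widx] <- w
    nsq <- colSums(Wm * (XtX %*% Wm))
    if (any(nsq <= 0)) {
      stop("degenerate pathway block ", names(blocks)[which(nsq <= 0)[1]])
    }
    s <- sqrt(N / nsq)
    list(w = w * s[col_pathway], s = s)
  }

  nw <- normalize_w(w0)
  w <- nw$w
  B <- matrix(0, K, Q)
  trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  flagged <- character(0)

  while (it < max_iter) {
    it <- it + 1L
    w_old <- w; B_old <- B
    cf <- cross_F(w)
    B <- solve(cf$FtF + IK, cf$FtY)
    # W-step on the stacked system: A = X'X .* (Bx Bx'), rhs = rowSums(Bx * X'Y)
    Bx <- B[col_pathway, , drop = FALSE]
    A <- XtX * tcrossprod(Bx) + IP
    rhs <- rowSums(Bx * XtY)
    w_new <- as.numeric(solve(A, rhs))
    rowabs <- rowSums(abs(B))
    if (any(rowabs < 1e-12)) {
      dead <- which(rowabs < 1e-12)
      flagged <- unique(c(flagged, names(blocks)[dead]))
      keepmask <- col_pathway %in% dead
      w_new[keepmask] <- w[keepmask]
    }
    nw <- normalize_w(w_new)
    w_n <- nw$w
    B <- B / nw$s
    # align each block's sign with the previous iterate (the solution is
    # sign-indeterminate per block; alignment prevents flip cycles)
    dots <- as.numeric(crossprod(Pmat, w_n * w))
    if (any(dots < 0)) {
      sgn <- ifelse(dots < 0, -1, 1)
      w_n <- w_n * sgn[col_pathway]
      B <- B * sgn
    }
    # mild relaxation: damps rotational limit cycles of the update map in
    # the near-null regime (fixed points are unchanged)
    if (relax < 1) {
      w_n <- relax * w_n + (1 - relax) * w
      nw2 <- normalize_w(w_n)
      w_n <- nw2$w
      B <- B / nw2$s
    }
    w <- w_n
    delta <- sum(abs(w - w_old)) + sum(abs(B - B_old))
    trace[it] <- delta
    if (delta < tol) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(it)]

  # sign convention applied once at the end (flipping inside the loop can
  # oscillate when a block's weight sum sits near zero): each block's weight
  # sum positive, ties broken by the first nonzero weight
  bsum <- as.numeric(crossprod(Pmat, w))
  zero <- bsum == 0
  if (any(zero)) {
    for (k in which(zero)) {
      wk <- w[col_pathway == k]
      bsum[k] <- wk[which(wk != 0)[1]]
    }
  }
  flip <- !is.na(bsum) & bsum < 0
  if (any(flip)) {
    sgn <- ifelse(flip, -1, 1)
    w <- w * sgn[col_pathway]
    B <- B * sgn
  }

  cf <- cross_F(w)
  Sigma <- (YtY - crossprod(cf$FtY, B) - crossprod(B, cf$FtY) +
            t(B) %*% cf$FtF %*% B) / N
  Sigma <- (Sigma + t(Sigma)) / 2
  list(w = w, B = B, FtF = cf$FtF, FtY = cf$FtY, Sigma = Sigma,
       iterations = it, converged = converged, trace = trace,
       flagged = flagged)
}

#' Fit the hierarchical pathway component model
#'
#' Alternates the coefficient update and the weight update under the scaling
#' constraint `diag(F'F) = N I` until the summed L1 change of all parameters
#' drops below `spec$tol` (default 1e-5) or `spec$max_iter` is reached.
#' Pathway block signs are fixed so each block's weight sum is positive.
#' The residual covariance is estimated once after convergence.
#'
#' @param X a `collapsed_design`, or numeric matrix with `blocks`.
#' @param Y N x Q numeric phenotype matrix (a vector is treated as Q = 1).
#' @param spec a [model_spec()].
#' @param blocks per-pathway column index list (when `X` is a matrix).
#' @param C optional covariate matrix (unpenalized direct predictors of
#'   every phenotype).
#' @param w0 optional initial weights (default: seeded random init).
#' @return object of class `gsca_fit`: `W` (named weight vector), `B`
#'   (K x Q), `b0`, `F` (N x K), `Sigma` (Q x Q), `trace`, `converged`,
#'   `iterations`, plus bookkeeping (`blocks`, penalties).
#' @export
fit_model <- function(X, Y, spec = model_spec(), blocks = NULL, C = NULL,
                      w0 = NULL) {
  d <- resolve_design(X, blocks)
  Y <- as.matrix(Y)
  if (nrow(d$X) != nrow(Y)) stop("X and Y row counts differ")
  N <- nrow(Y); Q <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("pheno", seq_len(Q))
  if (is.null(w0)) w0 <- init_weights(d$X, d$blocks, seed = spec$seed)

  if (is.null(C)) {
    ybar <- colMeans(Y)
    Yc <- sweep(Y, 2, ybar)
    res <- fit_gsca_stats(crossprod(d$X), crossprod(d$X, Yc), crossprod(Yc),
                          N, d$blocks, spec$lambda_G, spec$lambda_P, w0,
                          tol = spec$tol, max_iter = spec$max_iter)
    b0 <- ybar; G <- NULL
    F_ <- latent_from_w(d$X, res$w, d$blocks)
  } else {
    # covariate path: full-matrix alternation (covariates re-estimated in
    # every coefficient step, their contribution removed before the W step)
    C <- as.matrix(C)
    w <- compute_latent_scores(d$X, w0, d$blocks)$w
    B <- matrix(0, length(d$blocks), Q); G <- matrix(0, ncol(C), Q)
    b0 <- colMeans(Y)
    trace <- numeric(0); converged <- FALSE; it <- 0L
    repeat {
      it <- it + 1L
      w_old <- w; B_old <- B
      F_ <- latent_from_w(d$X, w, d$blocks)
      up <- update_coefficients(F_, Y, spec$lambda_P, C = C)
      B <- up$B; G <- up$G; b0 <- up$b0
      Yadj <- Y - C %*% G
      uw <- update_weights(d$X, B, Yadj, spec$lambda_G, d$blocks, w_prev = w)
      w <- uw$w; B <- uw$B
      delta <- sum(abs(w - w_old)) + sum(abs(B - B_old))
      trace <- c(trace, delta)
      if (delta < spec$tol) { converged <- TRUE; break }
      if (it >= spec$max_iter) break
    }
    # sign convention once at the end (see fit_gsca_stats)
    for (k in seq_along(d$blocks)) {
      idx <- d$blocks[[k]]
      if (sum(w[idx]) < 0) { w[idx] <- -w[idx]; B[k, ] <- -B[k, ] }
    }
    F_ <- latent_from_w(d$X, w, d$blocks)
    Sigma <- estimate_residual_cov(Y - C %*% G, F_, B)
    res <- list(w = w, B = B, Sigma = Sigma, iterations = it,
                converged = converged, trace = trace, flagged = character(0))
  }

  if (!res$converged) {
    warning("model did not converge in ", res$iterations,
            " iterations (last delta ", signif(utils::tail(res$trace, 1), 3), ")")
  }
  K <- length(d$blocks)
  dimnames(res$B) <- list(names(d$blocks), colnames(Y))
  names(res$w) <- colnames(d$X)
  structure(list(W = res$w, B = res$B, b0 = b0, G = G, F = F_,
                 Sigma = res$Sigma, trace = res$trace,
                 converged = res$converged, iterations = res$iterations,
                 flagged = res$flagged, blocks = d$blocks,
                 lambda_G = spec$lambda_G, lambda_P = spec$lambda_P,
                 N = N, Q = Q, K = K),
            class = "gsca_fit")
}

latent_from_w <- function(X, w, blocks) {
  F_ <- matrix(0, nrow(X), length(blocks),
               dimnames = list(rownames(X), names(blocks)))
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    F_[, k] <- X[, idx, drop = FALSE] %*% w[idx]
  }
  F_
}

#' @export
print.gsca_fit <- function(x, ...) {
  cat(sprintf("gsca_fit: K=%d pathways, Q=%d phenotypes, N=%d samples\n",
              x$K, x$Q, x$N))
  cat(sprintf("  lambda_G=%g lambda_P=%g | %s after %d iterations\n",
              x$lambda_G, x$lambda_P,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Gene-level effects implied by a fit
#'
#' The effect of gene t (in pathway k) on phenotype q decomposes exactly as
#' `w_tk * beta_kq`.
#' @param fit a `gsca_fit`.
#' @return matrix (one row per design column) of per-phenotype gene effects.
#' @export
gene_effects <- function(fit) {
  P <- length(fit$W)
  col_pathway <- integer(P)
  for (k in seq_along(fit$blocks)) col_pathway[fit$blocks[[k]]] <- k
  eff <- fit$W * fit$B[col_pathway, , drop = FALSE]
  rownames(eff) <- names(fit$W)
  eff
}
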