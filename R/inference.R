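#' Empirical permutation p-value
#'
#' Add-one estimator `p = (1 + #{j: null_j >= obs}) / (1 + J)`. Coefficient
#' tests are two-sided (absolute values compared); statistics that are
#' already non-negative (e.g. a Wald quadratic form) are compared directly
#' with `two_sided = FALSE`.
#'
#' @param observed scalar observed statistic.
#' @param null numeric vector of J null statistics.
#' @param two_sided compare absolute values (default TRUE).
#' @return p-value in `[1/(J+1), 1]`.
#' @export
empirical_pvalue <- function(observed, null, two_sided = TRUE) {
  J <- length(null)
  stopifnot(J >= 1)
  if (two_sided) {
    observed <- abs(observed)
    null <- abs(null)
  }
  (1 + sum(null >= observed)) / (1 + J)
}

#' Fisher combination of independent p-values
#'
#' `Psi = -2 sum(log p)` referred to chi-square with 2Q degrees of freedom.
#' @param p vector of p-values in (0, 1]. Zeros are clamped to `p_floor`
#'   (the permutation lower bound) with a warning.
#' @param p_floor clamp value for zero inputs.
#' @return list with `psi` and `p` (combined).
#' @export
fisher_combine <- function(p, p_floor = .Machine$double.xmin) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-value(s) clamped to ", signif(p_floor, 3),
            " before Fisher combination")
    p[p == 0] <- p_floor
  }
  psi <- -2 * sum(log(p))
  list(psi = psi, p = stats::pchisq(psi, df = 2 * length(p), lower.tail = FALSE))
}

# Kost cubic approximation to cov(-2 log P_i, -2 log P_j) for correlated
# normal test statistics
kost_cov_poly <- function(rho) {
  3.263 * rho + 0.71 * rho^2 + 0.027 * rho^3
}

#' Kost/Brown combination of dependent p-values
#'
#' Brown's moment-matched chi-square with the covariance of `-2 log P`
#' approximated by the cubic `3.263 rho + 0.71 rho^2 + 0.027 rho^3`:
#' with `E = 2Q` and `Var = 4Q + 2 sum_{i<j} K(rho_ij)`, the scale is
#' `c = Var / (2E)`, the rescaled degrees of freedom `2d = 2 E^2 / Var`,
#' and the combined p-value is the chi-square survival of `Psi / c` at
#' `2d` degrees of freedom. With all `rho = 0` this is exactly Fisher's
#' method; with `Q = 2`, `rho = 1` and equal inputs it returns the input.
#'
#' @param p vector of Q p-values in (0, 1].
#' @param rho Q x Q correlation matrix of the coefficient estimates.
#' @param p_floor clamp for zero p-values.
#' @return list with `psi`, `c`, `d`, `df` (= 2d), `p`.
#' @export
kost_combine <- function(p, rho, p_floor = .Machine$double.xmin) {
  Q <- length(p)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == Q, ncol(rho) == Q)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric")
  if (any(abs(diag(rho) - 1) > 1e-8)) stop("rho must have unit diagonal")
  if (any(rho < -1 - 1e-8 | rho > 1 + 1e-8)) stop("rho entries must lie in [-1, 1]")
  if (any(p == 0)) {
    warning("zero p-value(s) clamped to ", signif(p_floor, 3))
    p[p == 0] <- p_floor
  }
  psi <- -2 * sum(log(p))
  E <- 2 * Q
  off <- rho[upper.tri(rho)]
  v <- 4 * Q + 2 * sum(kost_cov_poly(off))
  if (v <= 0) stop("invalid correlation input: matched variance <= 0")
  cc <- v / (2 * E)
  d <- E^2 / v
  list(psi = psi, c = cc, d = d, df = 2 * d,
       p = stats::pchisq(psi / cc, df = 2 * d, lower.tail = FALSE))
}

#' Correlation of pathway coefficients across permutations
#'
#' Pearson correlation of the J permutation draws of
#' `(beta_k1, ..., beta_kQ)`; this is the empirical dependence plugged into
#' the Kost combination.
#' @param null a `permutation_null` (or J x Q matrix of draws for one
#'   pathway).
#' @param k pathway index (ignored when a matrix is passed).
#' @return Q x Q correlation matrix (clipped to `[-1, 1]`, unit diagonal).
#' @export
coef_correlation <- function(null, k = 1) {
  draws <- if (is.matrix(null)) null else null$betas[, k, , drop = TRUE]
  draws <- as.matrix(draws)
  if (nrow(draws) < 10) stop("need J >= 10 permutations to estimate coefficient correlation")
  if (any(apply(draws, 2, stats::sd) == 0)) {
    stop("zero-variance coefficient series; correlation undefined")
  }
  r <- stats::cor(draws)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Wald-type joint statistic for one pathway
#'
#' `T = beta' cov^{-1} beta`, tested against its permutation null. A
#' near-singular covariance is ridge-regularized by `1e-10 * mean(diag)`
#' (flagged via warning); a covariance still singular after regularization
#' errors.
#' @param beta_k length-Q coefficient vector.
#' @param cov_k Q x Q covariance of the estimates.
#' @return non-negative scalar.
#' @export
wald_statistic <- function(beta_k, cov_k) {
  cov_k <- as.matrix(cov_k)
  sol <- tryCatch(solve(cov_k, beta_k), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular coefficient covariance; ridge-regularizing")
    cov_k <- cov_k + diag(1e-10 * mean(diag(cov_k)), nrow(cov_k))
    sol <- tryCatch(solve(cov_k, beta_k), error = function(e) {
      stop("coefficient covariance singular even after regularization")
    })
  }
  as.numeric(crossprod(beta_k, sol))
}

#' Analytic covariance of the ridge coefficient estimates
#'
#' The ridge sandwich in Kronecker form,
#' `(F'F + lambda_P I)^{-1} F'F (F'F + lambda_P I)^{-1} (x) Sigma`.
#' The Q x Q block for pathway k is `A_kk * Sigma` with `A` the K x K
#' sandwich; `pathway_blocks = TRUE` returns the list of those blocks.
#'
#' @param F N x K latent scores (or a K x K `FtF` via `FtF =`).
#' @param lambda_P ridge penalty used in the fit.
#' @param Sigma Q x Q residual covariance.
#' @param FtF optional precomputed `F'F`.
#' @param pathway_blocks return per-pathway Q x Q blocks (default) instead
#'   of the full KQ x KQ Kronecker matrix.
#' @return list of K covariance blocks, or the full Kronecker matrix.
#' @export
coef_covariance_analytic <- function(F = NULL, lambda_P = 0, Sigma,
                                     FtF = NULL, pathway_blocks = TRUE) {
  if (is.null(FtF)) FtF <- crossprod(as.matrix(F))
  K <- nrow(FtF)
  Minv <- solve(FtF + diag(lambda_P, K))
  A <- Minv %*% FtF %*% Minv
  Sigma <- as.matrix(Sigma)
  if (pathway_blocks) {
    lapply(seq_len(K), function(k) A[k, k] * Sigma)
  } else {
    A %x% Sigma
  }
}

#' Westfall-Young maxT adjusted p-values
#'
#' Free step-down maxT: observed statistics are ranked ascending; within each
#' permutation the statistics are reordered by that ranking and replaced by
#' their cumulative maximum, so each hypothesis is compared against the
#' maximum over itself and all less-significant hypotheses. The adjusted
#' p-value is `(1 + sum_j I_jk) / (1 + J)` with
#' `I_jk = [obs_k < cummax_jk]`, and monotonicity is enforced along the
#' significance ranking. Statistics must be oriented so larger = more
#' significant. With K = 1 this reduces to the empirical p-value.
#'
#' @param T_obs length-K observed statistics.
#' @param T_null J x K matrix of permutation statistics.
#' @return length-K adjusted p-values (input order).
#' @export
westfall_young_adjust <- function(T_obs, T_null) {
  T_null <- as.matrix(T_null)
  K <- length(T_obs)
  stopifnot(ncol(T_null) == K)
  J <- nrow(T_null)
  ord <- order(T_obs)                       # ascending significance
  Tn <- T_null[, ord, drop = FALSE]
  cm <- t(apply(Tn, 1, cummax))             # J x K cumulative maxima
  if (K == 1) cm <- matrix(Tn, J, 1)
  obs_sorted <- T_obs[ord]
  exceed <- sweep(cm, 2, obs_sorted, `>`)   # I_jk
  p_sorted <- (1 + colSums(exceed)) / (1 + J)
  # monotone: less-significant hypotheses get p at least that of more
  # significant ones (cumulative max from the top of the ranking down)
  p_sorted <- rev(cummax(rev(p_sorted)))
  p <- numeric(K)
  p[ord] <- p_sorted
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up: `q_(i) = min_{j >= i} p_(j) * K / j`, capped at 1, mapped back
#' to the input order.
#' @param p vector of p-values.
#' @return q-values of the same length/order.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  K <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * K / seq_len(K)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(K)
  q[ord] <- q_sorted
  q
}

#' Permutation null distributions for pathway and gene statistics
#'
#' For each of J permutations the rows of `Y` are shuffled jointly (all Q
#' phenotype columns together, so the cross-phenotype correlation is
#' preserved while the genotype-phenotype link is broken) and the model is
#' refitted at the fixed penalties. Per permutation the pathway coefficient
#' matrix, the Wald statistics (analytic covariance from that fit) and the
#' gene-level effects are recorded. Covariates stay aligned with `X`.
#'
#' @param X a `collapsed_design` or matrix.
#' @param Y phenotype matrix.
#' @param spec a [model_spec()] carrying the (tuned) penalties.
#' @param J number of permutations (default 5000).
#' @param perm_seed seed of the permutation stream.
#' @param blocks per-pathway column indices (with matrix `X`).
#' @param progress print a dot every 500 permutations.
#' @return object of class `permutation_null` with `betas` (J x K x Q),
#'   `wald` (J x K), `gene_eff` (J x P x Q), `converged` (logical J),
#'   `J`, `seed`.
#' @export
permutation_null <- function(X, Y, spec = model_spec(), J = 5000,
                             perm_seed = 1L, blocks = NULL, progress = FALSE) {
  d <- resolve_design(X, blocks)
  Y <- as.matrix(Y)
  N <- nrow(Y); Q <- ncol(Y); K <- length(d$blocks); P <- ncol(d$X)
  stopifnot(J >= 1)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  XtX <- crossprod(d$X)
  Xt <- t(d$X)
  YtY_base <- crossprod(Yc)   # row permutation leaves Y'Y unchanged
  w0 <- init_weights(d$X, d$blocks, seed = spec$seed)

  betas <- array(NA_real_, c(J, K, Q))
  wald <- matrix(NA_real_, J, K)
  gene_eff <- array(NA_real_, c(J, P, Q))
  conv <- logical(J)
  col_pathway <- integer(P)
  for (k in seq_len(K)) col_pathway[d$blocks[[k]]] <- k

  set.seed(perm_seed)
  perms <- replicate(J, sample.int(N), simplify = FALSE)

  for (j in seq_len(J)) {
    Yp <- Yc[perms[[j]], , drop = FALSE]
    XtYp <- Xt %*% Yp
    fitj <- fit_gsca_stats(XtX, XtYp, YtY_base, N, d$blocks,
                           spec$lambda_G, spec$lambda_P, w0,
                           tol = spec$tol, max_iter = spec$max_iter)
    betas[j, , ] <- fitj$B
    gene_eff[j, , ] <- fitj$w * fitj$B[col_pathway, , drop = FALSE]
    # T_k = beta_k' (A_kk Sigma)^{-1} beta_k with A the ridge sandwich
    Minv <- solve(fitj$FtF + diag(spec$lambda_P, K))
    a_kk <- diag(Minv %*% fitj$FtF %*% Minv)
    Sinv <- solve(fitj$Sigma)
    wald[j, ] <- rowSums((fitj$B %*% Sinv) * fitj$B) / a_kk
    conv[j] <- fitj$converged
    if (progress && j %% 500 == 0) cat(".")
  }
  fail <- mean(!conv)
  if (fail > 0.05) {
    stop(sprintf("%.1f%% of permutation fits failed to converge; aborting", 100 * fail))
  }
  structure(list(betas = betas, wald = wald, gene_eff = gene_eff,
                 converged = conv, J = J, seed = perm_seed,
                 pathways = names(d$blocks), genes = colnames(d$X)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: J=%d permutations, %d pathways, %d genes (%.1f%% converged)\n",
              x$J, dim(x$betas)[2], dim(x$gene_eff)[2], 100 * mean(x$converged)))
  invisible(x)
}

# within-null empirical p for every draw: p_j = (1 + #{l: |x_l| >= |x_j|})/(1+J)
null_internal_p <- function(x) {
  J <- length(x)
  r <- rank(abs(x), ties.method = "min")
  (J - r + 2) / (J + 1)
}

#' Full pathway / gene inference
#'
#' Fits the observed model, builds the permutation null, and assembles:
#' per-phenotype empirical coefficient p-values, the Kost-combined joint
#' p-value (`p_kost`), the Wald-type joint p-value (`p_wald`, permutation
#' calibrated), Westfall-Young adjusted p-values for both joint tests, BH
#' q-values for both, and gene-level effects with per-phenotype p-values.
#'
#' @inheritParams permutation_null
#' @param C optional covariates (held fixed under permutation).
#' @param cov_method `"analytic"` (ridge sandwich, default) or
#'   `"permutation"` (sample covariance of the permutation coefficient
#'   draws) for the Wald covariance.
#' @return list of class `pathway_inference` with data.frames `pathways`
#'   and `genes`, plus `fit` and `null`.
#' @export
run_inference <- function(X, Y, spec = model_spec(), J = 5000,
                          perm_seed = 1L, blocks = NULL, C = NULL,
                          cov_method = c("analytic", "permutation"),
                          progress = FALSE) {
  cov_method <- match.arg(cov_method)
  d <- resolve_design(X, blocks)
  Y <- as.matrix(Y)
  K <- length(d$blocks); Q <- ncol(Y); P <- ncol(d$X)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("pheno", seq_len(Q))

  fit <- fit_model(d$X, Y, spec, blocks = d$blocks, C = C)
  Yperm <- if (is.null(C)) Y else Y - C %*% fit$G
  null <- permutation_null(d$X, Yperm, spec, J = J, perm_seed = perm_seed,
                           blocks = d$blocks, progress = progress)

  # per-phenotype empirical p-values for pathway coefficients
  p_coef <- matrix(NA_real_, K, Q, dimnames = list(names(d$blocks), colnames(Y)))
  for (k in seq_len(K)) for (q in seq_len(Q)) {
    p_coef[k, q] <- empirical_pvalue(fit$B[k, q], null$betas[, k, q])
  }

  # Kost joint p (with per-permutation analogue for WY adjustment)
  rho_list <- lapply(seq_len(K), function(k) {
    if (Q == 1) matrix(1, 1, 1) else coef_correlation(null, k)
  })
  kost <- lapply(seq_len(K), function(k) kost_combine(p_coef[k, ], rho_list[[k]]))
  p_kost <- vapply(kost, `[[`, numeric(1), "p")
  # per-permutation Kost statistic Psi/c from within-null p-values
  kost_stat_null <- matrix(NA_real_, null$J, K)
  kost_stat_obs <- numeric(K)
  for (k in seq_len(K)) {
    pn <- vapply(seq_len(Q), function(q) null_internal_p(null$betas[, k, q]),
                 numeric(null$J))
    pn <- matrix(pn, null$J, Q)
    kost_stat_null[, k] <- -2 * rowSums(log(pn)) / kost[[k]]$c
    kost_stat_obs[k] <- kost[[k]]$psi / kost[[k]]$c
  }

  # Wald joint statistic, permutation calibrated
  if (cov_method == "analytic") {
    covs <- coef_covariance_analytic(F = fit$F, lambda_P = spec$lambda_P,
                                     Sigma = fit$Sigma)
  } else {
    covs <- lapply(seq_len(K), function(k) {
      stats::cov(matrix(null$betas[, k, ], null$J, Q))
    })
  }
  T_obs <- vapply(seq_len(K), function(k) wald_statistic(fit$B[k, ], covs[[k]]),
                  numeric(1))
  T_null <- if (cov_method == "analytic") null$wald else {
    tn <- matrix(NA_real_, null$J, K)
    for (k in seq_len(K)) {
      bk <- matrix(null$betas[, k, ], null$J, Q)
      tn[, k] <- vapply(seq_len(null$J),
                        function(j) wald_statistic(bk[j, ], covs[[k]]), numeric(1))
    }
    tn
  }
  p_wald <- vapply(seq_len(K), function(k) {
    empirical_pvalue(T_obs[k], T_null[, k], two_sided = FALSE)
  }, numeric(1))

  p_wy_wald <- westfall_young_adjust(T_obs, T_null)
  p_wy_kost <- westfall_young_adjust(kost_stat_obs, kost_stat_null)
  q_wald <- bh_qvalues(p_wald)
  q_kost <- bh_qvalues(p_kost)

  n_genes <- vapply(d$blocks, length, integer(1))
  n_variants <- if (inherits(X, "collapsed_design")) {
    vapply(d$blocks, function(idx) sum(X$m[idx]), integer(1))
  } else rep(NA_integer_, K)
  pathways <- data.frame(pathway = names(d$blocks), n_genes = n_genes,
                         n_variants = n_variants, row.names = NULL)
  for (q in seq_len(Q)) pathways[[paste0("beta_", colnames(Y)[q])]] <- fit$B[, q]
  for (q in seq_len(Q)) pathways[[paste0("p_", colnames(Y)[q])]] <- p_coef[, q]
  pathways$p_kost <- p_kost
  pathways$p_wald <- p_wald
  pathways$p_wy_kost <- p_wy_kost
  pathways$p_wy_wald <- p_wy_wald
  pathways$q_bh_kost <- q_kost
  pathways$q_bh_wald <- q_wald

  eff <- gene_effects(fit)
  col_pathway <- integer(P)
  for (k in seq_len(K)) col_pathway[d$blocks[[k]]] <- k
  genes <- data.frame(
    gene = if (inherits(X, "collapsed_design")) X$gene else colnames(d$X),
    pathway = names(d$blocks)[col_pathway], row.names = NULL)
  for (q in seq_len(Q)) genes[[paste0("effect_", colnames(Y)[q])]] <- eff[, q]
  for (q in seq_len(Q)) {
    genes[[paste0("p_", colnames(Y)[q])]] <- vapply(seq_len(P), function(t) {
      empirical_pvalue(eff[t, q], null$gene_eff[, t, q])
    }, numeric(1))
  }

  structure(list(pathways = pathways, genes = genes, fit = fit, null = null,
                 T_obs = T_obs, rho = rho_list),
            class = "pathway_inference")
}

#' @export
print.pathway_inference <- function(x, ...) {
  cat("pathway_inference:", nrow(x$pathways), "pathways,",
      nrow(x$genes), "genes, J =", x$null$J, "permutations\n")
  print(utils::head(x$pathways[order(x$pathways$p_wald), ], 10))
  invisible(x)
}
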