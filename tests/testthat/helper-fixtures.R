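# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# tiny genotype matrix with explicit counts
make_geno <- function(counts, chrom = "1", pos = NULL) {
  counts <- as.matrix(counts)
  if (is.null(pos)) pos <- seq_len(ncol(counts)) * 100L
  genotype_matrix(
    counts,
    samples = sprintf("S%02d", seq_len(nrow(counts))),
    variants = data.frame(id = sprintf("v%02d", seq_len(ncol(counts))),
                          chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE)
  )
}

# standardized random design with K pathway blocks of T genes each
make_design <- function(N = 50, K = 2, T_k = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(N * K * T_k), N, K * T_k)
  X <- scale(X)
  colnames(X) <- paste0("g", seq_len(ncol(X)))
  blocks <- split(seq_len(K * T_k), rep(seq_len(K), each = T_k))
  names(blocks) <- paste0("PW", seq_len(K))
  list(X = unclass(X), blocks = blocks)
}

# brute-force stacked-system oracles for the two ALS updates ----------------

# B-update oracle: build R = I_Q (x) F (stacking phenotype-major) and solve
# the penalized normal equations directly.
oracle_update_B <- function(F, Yc, lambda_P) {
  K <- ncol(F); Q <- ncol(Yc); N <- nrow(F)
  R <- kronecker(diag(Q), F)
  pen <- diag(lambda_P, K * Q)
  vecB <- solve(crossprod(R) + pen, crossprod(R, as.numeric(Yc)))
  matrix(vecB, K, Q)
}

# W-update oracle: explicit stacked design whose column (k,t) is the stack
# over (i,q) of beta_kq * x_ikt.
oracle_update_w <- function(X, B, Yc, lambda_G, blocks) {
  N <- nrow(X); Q <- ncol(Yc); P <- ncol(X)
  col_pathway <- integer(P)
  for (k in seq_along(blocks)) col_pathway[blocks[[k]]] <- k
  Phi <- do.call(rbind, lapply(seq_len(Q), function(q) {
    sweep(X, 2, B[col_pathway, q], `*`)
  }))
  as.numeric(solve(crossprod(Phi) + diag(lambda_G, P),
                   crossprod(Phi, as.numeric(Yc))))
}

# a small simulated dataset + design for end-to-end tests
make_sim <- function(N = 150, K = 3, T_k = 3, beta = 0, H1 = 1, w = 0.1,
                     rho = 0.25, Q = 2, seed = 11, vpg = 6) {
  sc <- scenario_config(N = N, K = K, T_k = T_k, variants_per_gene = vpg,
                        H1 = H1, w = w, beta = beta, rho = rho, Q = Q)
  ds <- simulate_dataset(sc, seed = seed)
  list(ds = ds, design = design_from_simulation(ds))
}
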