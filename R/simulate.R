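#' Simulation scenario configuration
#'
#' Describes one synthetic-data condition: a hierarchy of `K` pathways with
#' `T_k` genes each and `variants_per_gene` rare variants per gene, sample
#' size `N`, and phenotypes driven by the first pathway only. The full-scale
#' world is N = 1000, K = 10, T_k = 10, Q = 2 with effect grids
#' `H1 in {1, 2, 5}`, `w in {0.1, 0.2}`, `beta in {0.1, 0.15, 0.2}`,
#' `rho in {0, 0.25, 0.5}`; scaled-down defaults for routine runs are
#' N = 400, K = 5, T_k = 5.
#'
#' @param N sample count.
#' @param K pathway count.
#' @param T_k genes per pathway.
#' @param variants_per_gene rare variants per gene (a 1 Kbp gene in a
#'   sequencing study typically yields on the order of ten rare sites).
#' @param maf_range log-uniform MAF spectrum bounds (within (0, 0.05]).
#' @param H1 number of causal genes in the first (causal) pathway.
#' @param w gene-level effect, identical across the H1 causal genes.
#' @param beta pathway-level effect per phenotype (scalar recycled to Q).
#' @param rho residual compound-symmetry correlation between phenotypes.
#' @param Q phenotype count.
#' @param constraint normalize the causal latent score to sum of squares N
#'   (the generating model's scaling constraint); `FALSE` gives the
#'   unconstrained variant where raw burden scale carries through.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(N = 1000, K = 10, T_k = 10, variants_per_gene = 10,
                            maf_range = c(5e-4, 0.01), H1 = 1, w = 0.1,
                            beta = 0.1, rho = 0, Q = 2, constraint = TRUE) {
  stopifnot(N >= 1, K >= 1, T_k >= 1, variants_per_gene >= 1,
            H1 >= 0, H1 <= T_k, rho >= -1, rho <= 1, Q >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.05,
            maf_range[1] <= maf_range[2])
  beta <- rep_len(beta, Q)
  structure(list(N = N, K = K, T_k = T_k,
                 variants_per_gene = variants_per_gene,
                 maf_range = maf_range, H1 = H1, w = w, beta = beta,
                 rho = rho, Q = Q, constraint = constraint),
            class = "scenario_config")
}

#' Draw a pool of rare-variant MAFs
#'
#' i.i.d. log-uniform on `maf_range` (default `[5e-4, 0.01]`), emulating the
#' rare tail of a site-frequency spectrum.
#' @param n_variants pool size.
#' @param maf_range bounds within (0, 0.05].
#' @param seed integer seed.
#' @return numeric MAF vector.
#' @export
gen_variant_pool <- function(n_variants, maf_range = c(5e-4, 0.01), seed = 1L) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.05)
  set.seed(seed)
  exp(stats::runif(n_variants, log(maf_range[1]), log(maf_range[2])))
}

#' Draw genotypes at given MAFs
#'
#' Hardy-Weinberg sampling: `g_ij ~ Binomial(2, MAF_j)`. Columns that come
#' out monomorphic are regenerated once and dropped (with their MAF) if
#' still monomorphic.
#' @param mafs per-variant MAFs.
#' @param N samples.
#' @param seed integer seed.
#' @return list with `counts` (N x J' matrix), `mafs` (retained MAFs) and
#'   `kept` (indices of the input MAF vector that survived).
#' @export
gen_genotypes <- function(mafs, N, seed = 1L) {
  stopifnot(N >= 1)
  set.seed(seed)
  J <- length(mafs)
  counts <- matrix(stats::rbinom(N * J, 2, rep(mafs, each = N)), N, J)
  mono <- colSums(counts) == 0 | colSums(counts) == 2 * N
  if (any(mono)) {
    for (j in which(mono)) counts[, j] <- stats::rbinom(N, 2, mafs[j])
    mono <- colSums(counts) == 0 | colSums(counts) == 2 * N
  }
  kept <- which(!mono)
  list(counts = counts[, kept, drop = FALSE], mafs = mafs[kept], kept = kept)
}

#' Variant effect size from its frequency
#'
#' `gamma = |log10(MAF)|`: rarer variants carry larger per-allele effects.
#' @param maf MAF in (0, 0.5].
#' @return effect size(s).
#' @export
variant_effect <- function(maf) {
  if (any(maf <= 0)) stop("variant_effect: maf must be > 0")
  abs(log10(maf))
}

#' Generate one simulated dataset
#'
#' Builds the genotype matrix, the pathway/gene hierarchy (disjoint genes
#' across pathways), and phenotypes from the generating model: only the
#' first pathway is causal; its latent score is the weighted sum over the
#' `H1` causal genes of variant-effect-weighted allele counts, optionally
#' normalized to the scaling constraint, and residuals are multivariate
#' normal with unit variances and compound-symmetry correlation `rho`.
#'
#' @param scenario a [scenario_config()].
#' @param seed integer seed (drives variant pool, genotypes and noise).
#' @return list of class `simulated_dataset`: `genotypes`
#'   ([genotype_matrix()]), `pathways` (`pathway_db`), `gene_map` (gene ->
#'   variant indices), `Y`, `mafs`, `causal_pathway`, `causal_genes`,
#'   `scenario`.
#' @export
simulate_dataset <- function(scenario = scenario_config(), seed = 1L) {
  sc <- scenario
  n_genes <- sc$K * sc$T_k
  J <- n_genes * sc$variants_per_gene
  mafs <- gen_variant_pool(J, sc$maf_range, seed = seed)
  gg <- gen_genotypes(mafs, sc$N, seed = seed + 1L)
  J_eff <- ncol(gg$counts)
  gene_of_variant <- rep(seq_len(n_genes), each = sc$variants_per_gene)[gg$kept]
  samples <- sprintf("S%04d", seq_len(sc$N))
  genes <- sprintf("G%03d", seq_len(n_genes))
  variants <- data.frame(id = sprintf("v%05d", seq_len(J_eff)),
                         chrom = "1", pos = seq_len(J_eff),
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(gg$counts, samples, variants)
  gene_map <- split(seq_len(J_eff), genes[gene_of_variant])
  gene_map <- gene_map[genes[genes %in% names(gene_map)]]
  pw <- split(genes, rep(seq_len(sc$K), each = sc$T_k))
  names(pw) <- sprintf("PW%02d", seq_len(sc$K))
  pathways <- pathway_db(pw)
  causal_genes <- genes[seq_len(sc$H1)]
  Y <- gen_phenotypes(g, gene_map, gg$mafs, sc, seed = seed + 2L)
  structure(list(genotypes = g, pathways = pathways, gene_map = gene_map,
                 Y = Y, mafs = gg$mafs, causal_pathway = "PW01",
                 causal_genes = causal_genes, scenario = sc),
            class = "simulated_dataset")
}

#' Generate phenotypes from genotypes under the causal model
#'
#' @param g a [genotype_matrix()].
#' @param gene_map gene -> variant column indices (genes ordered; the first
#'   `H1` genes of the first pathway are causal).
#' @param mafs per-variant MAFs (for the `|log10 MAF|` effects).
#' @param scenario a [scenario_config()].
#' @param seed seed for the residual draw.
#' @return N x Q phenotype matrix with sample rownames.
#' @export
gen_phenotypes <- function(g, gene_map, mafs, scenario, seed = 1L) {
  sc <- scenario
  N <- nrow(g$counts)
  if (sc$H1 == 0 && any(sc$beta != 0)) {
    stop("H1 = 0 with nonzero beta: no causal genes to carry the effect")
  }
  f <- numeric(N)
  if (sc$H1 > 0 && any(sc$beta != 0)) {
    for (t in seq_len(sc$H1)) {
      idx <- gene_map[[t]]
      gamma <- variant_effect(mafs[idx])
      f <- f + sc$w * as.numeric(g$counts[, idx, drop = FALSE] %*% gamma)
    }
    f <- f - mean(f)
    if (sc$constraint) {
      ssq <- sum(f^2)
      if (ssq == 0) stop("causal latent score is constant; cannot normalize")
      f <- f * sqrt(N / ssq)
    }
  }
  Sig <- matrix(sc$rho, sc$Q, sc$Q); diag(Sig) <- 1
  set.seed(seed)
  eps <- matrix(stats::rnorm(N * sc$Q), N, sc$Q) %*% chol(Sig)
  Y <- outer(f, sc$beta) + eps
  rownames(Y) <- g$samples
  colnames(Y) <- paste0("pheno", seq_len(sc$Q))
  Y
}

#' Burden design straight from a simulated dataset
#'
#' Collapses the simulated genotypes into the pathway-by-gene design with
#' unit variant weights (the generator already encodes frequency effects),
#' standardized columns.
#' @param ds a `simulated_dataset`.
#' @return a `collapsed_design`.
#' @export
design_from_simulation <- function(ds) {
  collapse_to_design(ds$genotypes, ds$gene_map, ds$pathways,
                     weights = rep(1, ncol(ds$genotypes$counts)))
}

#' Export a simulated dataset as plain-text analysis inputs
#'
#' Writes genotype TSV, phenotype TSV, gene-map TSV (1-based) and a GMT, the
#' formats the fitting command reads, so the simulator doubles as an
#' end-to-end pipeline fixture generator.
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named vector of file paths.
#' @export
export_simulated_dataset <- function(ds, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotypes = file.path(dir, paste0(prefix, "_geno.tsv")),
    phenotypes = file.path(dir, paste0(prefix, "_pheno.tsv")),
    genes = file.path(dir, paste0(prefix, "_genes.tsv")),
    gmt = file.path(dir, paste0(prefix, ".gmt"))
  )
  counts <- ds$genotypes$counts
  colnames(counts) <- paste(ds$genotypes$variants$chrom,
                            ds$genotypes$variants$pos, sep = ":")
  gt <- data.frame(sample = ds$genotypes$samples, counts, check.names = FALSE)
  utils::write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- data.frame(sample = rownames(ds$Y), ds$Y, check.names = FALSE)
  utils::write.table(ph, paths["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gm <- do.call(rbind, lapply(names(ds$gene_map), function(gname) {
    idx <- ds$gene_map[[gname]]
    data.frame(gene = gname, chrom = "1",
               start = min(ds$genotypes$variants$pos[idx]),
               end = max(ds$genotypes$variants$pos[idx]))
  }))
  utils::write.table(gm, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt_lines <- vapply(names(ds$pathways), function(p) {
    paste(c(p, "simulated", ds$pathways[[p]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, paths["gmt"])
  paths
}

#' Type-I-error experiment on null data
#'
#' Generates `replicates` null datasets (all beta = 0), runs the full
#' permutation inference on each at fixed penalties, and reports the
#' fraction of null-pathway p-values below each alpha for every test
#' (per-phenotype coefficient tests, the Kost combination and the Wald
#' joint test), with Monte-Carlo standard errors, plus a Q-Q table of
#' sorted p-values against uniform quantiles.
#'
#' @param scenario a [scenario_config()] (its beta is forced to 0).
#' @param lambda_G,lambda_P fixed penalties (CV is skipped in experiments).
#' @param replicates number of simulated datasets.
#' @param J permutations per dataset.
#' @param alphas significance levels to evaluate.
#' @param seed master seed; per-replicate data/permutation seeds derive
#'   from it.
#' @param progress print one dot per 20 replicates.
#' @return list with `rates` (data.frame test/alpha/rate/mc_se), `pvalues`
#'   (matrix, replicates*K rows x tests) and `qq` (per-test sorted p vs
#'   uniform quantiles).
#' @export
run_type1_experiment <- function(scenario = scenario_config(N = 400, K = 5, T_k = 5),
                                 lambda_G = 100, lambda_P = 100,
                                 replicates = 200, J = 300,
                                 alphas = c(0.01, 0.05), seed = 1L,
                                 progress = FALSE) {
  seed <- as.integer(seed %% 50000L)   # derived seeds must stay < 2^31
  sc <- scenario
  sc$beta <- rep(0, sc$Q)
  spec <- model_spec(lambda_G = lambda_G, lambda_P = lambda_P, seed = seed)
  tests <- c(paste0("p_pheno", seq_len(sc$Q)), "p_kost", "p_wald")
  pvals <- vector("list", replicates)
  failed <- 0L
  for (r in seq_len(replicates)) {
    ds <- simulate_dataset(sc, seed = seed * 10000L + r * 7L)
    des <- design_from_simulation(ds)
    inf <- tryCatch(
      suppressWarnings(run_inference(des, ds$Y, spec, J = J,
                                     perm_seed = seed * 20000L + r * 11L)),
      error = function(e) NULL)
    if (is.null(inf)) { failed <- failed + 1L; next }   # >5% perm failures
    pw <- inf$pathways
    pm <- cbind(as.matrix(pw[, paste0("p_pheno", seq_len(sc$Q))]),
                p_kost = pw$p_kost, p_wald = pw$p_wald)
    pvals[[r]] <- pm
    if (progress && r %% 20 == 0) cat(".")
  }
  if (failed > 0) {
    warning(failed, " of ", replicates,
            " replicates aborted (permutation non-convergence) and were excluded")
  }
  P <- do.call(rbind, pvals)
  colnames(P) <- tests
  rates <- do.call(rbind, lapply(alphas, function(a) {
    rate <- colMeans(P < a)
    data.frame(test = tests, alpha = a, rate = as.numeric(rate),
               mc_se = sqrt(rate * (1 - rate) / nrow(P)), row.names = NULL)
  }))
  n <- nrow(P)
  qq <- data.frame(uniform = stats::ppoints(n),
                   apply(P, 2, sort), check.names = FALSE)
  list(rates = rates, pvalues = P, qq = qq,
       config = list(scenario = sc, lambda_G = lambda_G, lambda_P = lambda_P,
                     replicates = replicates, J = J, seed = seed))
}

#' Power experiment over a scenario grid
#'
#' For each scenario: simulate, fit, test, BH-adjust the Wald and Kost joint
#' p-values across the K pathways, and record whether the causal (first)
#' pathway's q-value falls below `q_threshold`. With `univariate = TRUE`
#' the identical datasets are additionally analyzed with the first phenotype
#' only, giving the multivariate-vs-univariate power contrast.
#'
#' @param scenarios list of [scenario_config()]s (or a single one).
#' @param lambda_G,lambda_P fixed penalties.
#' @param replicates replicates per scenario.
#' @param J permutations per replicate.
#' @param q_threshold significance threshold on the BH q-value.
#' @param univariate also run the Q = 1 comparator on the same data.
#' @param seed master seed.
#' @param progress print one dot per 20 replicates.
#' @return data.frame, one row per scenario: power for the Wald and Kost
#'   joint tests (and `power_*_uni` univariate counterparts when requested),
#'   Monte-Carlo SE, the number of completed replicates and the number of
#'   replicates aborted for permutation non-convergence.
#' @export
run_power_experiment <- function(scenarios, lambda_G = 100, lambda_P = 100,
                                 replicates = 200, J = 300,
                                 q_threshold = 0.05, univariate = FALSE,
                                 seed = 1L, progress = FALSE) {
  seed <- as.integer(seed %% 50000L)   # derived seeds must stay < 2^31
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  out <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    spec <- model_spec(lambda_G = lambda_G, lambda_P = lambda_P, seed = seed)
    hits_w <- hits_k <- logical(0)
    hits_w_uni <- hits_k_uni <- logical(0)
    failed <- 0L
    for (r in seq_len(replicates)) {
      ds <- simulate_dataset(sc, seed = seed * 10000L + s * 1000L + r * 7L)
      des <- design_from_simulation(ds)
      pseed <- seed * 20000L + s * 1000L + r * 11L
      res <- tryCatch(suppressWarnings({
        inf <- run_inference(des, ds$Y, spec, J = J, perm_seed = pseed)
        inf1 <- if (univariate) {
          run_inference(des, ds$Y[, 1, drop = FALSE], spec, J = J,
                        perm_seed = pseed)
        }
        list(inf = inf, inf1 = inf1)
      }), error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      ci <- which(res$inf$pathways$pathway == ds$causal_pathway)
      hits_w <- c(hits_w, res$inf$pathways$q_bh_wald[ci] < q_threshold)
      hits_k <- c(hits_k, res$inf$pathways$q_bh_kost[ci] < q_threshold)
      if (univariate) {
        hits_w_uni <- c(hits_w_uni, res$inf1$pathways$q_bh_wald[ci] < q_threshold)
        hits_k_uni <- c(hits_k_uni, res$inf1$pathways$q_bh_kost[ci] < q_threshold)
      }
      if (progress && r %% 20 == 0) cat(".")
    }
    if (failed > 0) {
      warning("scenario ", s, ": ", failed, " of ", replicates,
              " replicates aborted (permutation non-convergence), excluded")
    }
    n_ok <- length(hits_w)
    row <- data.frame(scenario = s, H1 = sc$H1, w = sc$w, beta = sc$beta[1],
                      rho = sc$rho, Q = sc$Q, N = sc$N,
                      power_wald = mean(hits_w), power_kost = mean(hits_k),
                      mc_se_wald = sqrt(mean(hits_w) * (1 - mean(hits_w)) / n_ok),
                      replicates = n_ok, failed = failed)
    if (univariate) {
      row$power_wald_uni <- mean(hits_w_uni)
      row$power_kost_uni <- mean(hits_k_uni)
    }
    out[[s]] <- row
  }
  do.call(rbind, out)
}

#' Monte-Carlo recovery of the dependent-Fisher covariance polynomial
#'
#' Draws bivariate standard-normal pairs at each correlation on `rho_grid`,
#' converts both coordinates to one-sided survival p-values
#' `P = Phi(-z)` (the setting in which the dependent-Fisher covariance
#' approximation is defined; two-sided p-values discard the sign of the
#' statistic and give a much flatter, nearly even-in-rho curve), estimates
#' `cov(-2 log P_1, -2 log P_2)`, and fits a cubic through the origin. The
#' linear coefficient of that cubic is the quantity approximated by the
#' published constant 3.263.
#'
#' @param n pairs per grid point (>= 1e5 recommended).
#' @param rho_grid correlations to evaluate.
#' @param seed integer seed.
#' @return list with `coefficients` (linear, quadratic, cubic), `table`
#'   (rho, estimated covariance).
#' @export
kost_polynomial_mc <- function(n = 1e6, rho_grid = seq(0, 1, by = 0.1),
                               seed = 1L) {
  set.seed(seed)
  est <- vapply(rho_grid, function(rho) {
    z1 <- stats::rnorm(n)
    if (rho == 1) {
      z2 <- z1
    } else {
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    x1 <- -2 * stats::pnorm(-z1, log.p = TRUE)
    x2 <- -2 * stats::pnorm(-z2, log.p = TRUE)
    stats::cov(x1, x2)
  }, numeric(1))
  fit <- stats::lm(est ~ 0 + rho_grid + I(rho_grid^2) + I(rho_grid^3))
  co <- unname(stats::coef(fit))
  list(coefficients = c(linear = co[1], quadratic = co[2], cubic = co[3]),
       table = data.frame(rho = rho_grid, cov = est))
}
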