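#' Construct a genotype matrix object
#'
#' Container for minor-allele counts of `N` samples at `J` variants. Entries
#' are 0, 1, 2 or `NA` (missing call). Variant metadata travels with the
#' matrix so downstream QC and gene mapping can address variants by position.
#'
#' @param counts integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers (row order).
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based) and
#'   optionally `ref`, `alt`; one row per column of `counts`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, samples, variants) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype counts must be 0, 1, 2 or NA; offending entries at rows ",
         paste(utils::head(unique(which(bad, arr.ind = TRUE)[, 1]), 5), collapse = ", "))
  }
  if (length(samples) != nrow(counts)) stop("length(samples) != nrow(counts)")
  if (nrow(variants) != ncol(counts)) stop("nrow(variants) != ncol(counts)")
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)))
  rownames(counts) <- samples
  colnames(counts) <- variants$id
  structure(list(counts = counts, samples = as.character(samples),
                 variants = as.data.frame(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Read genotypes from TSV or VCF
#'
#' The TSV layout is `sample<TAB>var1<TAB>...` with integer allele counts.
#' VCF parsing (diploid GT fields) is delegated to the VariantAnnotation
#' package. In both formats counts are re-polarized so that they count the
#' *minor* allele: any variant whose counted-allele frequency exceeds 0.5 is
#' flipped (`g -> 2 - g`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  g <- switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path)
  )
  polarize_minor(g)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("genotype TSV needs a sample column plus >=1 variant column")
  samples <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "double")
  bad_rows <- which(apply(counts, 1, function(r) any(!is.na(r) & !(r %in% c(0, 1, 2)))))
  nonnum <- which(apply(tab[, -1, drop = FALSE], 1,
                        function(r) any(!is.na(r) & is.na(suppressWarnings(as.numeric(r))))))
  bad_rows <- sort(unique(c(bad_rows, nonnum)))
  if (length(bad_rows)) {
    stop("malformed genotype value(s) in ", path, " at data line(s) ",
         paste(utils::head(bad_rows, 5), collapse = ", "),
         " (header is line 1, so file line ", bad_rows[1] + 1, ")")
  }
  ids <- colnames(counts)
  # ids of the form "chrom:pos" (or "chrom:pos:name") carry coordinates
  coord <- grepl("^[^:]+:[0-9]+(:.*)?$", ids)
  variants <- data.frame(id = ids, chrom = NA_character_, pos = NA_integer_,
                         stringsAsFactors = FALSE)
  if (all(coord)) {
    parts <- strsplit(ids, ":")
    variants$chrom <- vapply(parts, `[`, character(1), 1)
    variants$pos <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  genotype_matrix(counts, samples, variants)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  counts <- apply(gt, c(1, 2), gt_to_count)
  counts <- t(counts)  # samples x variants
  ids <- rownames(gt)
  variants <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    stringsAsFactors = FALSE
  )
  genotype_matrix(counts, colnames(gt), variants)
}

gt_to_count <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2) stop("non-diploid genotype '", gt, "' (ploidy != 2)")
  if (any(alleles == ".")) return(NA_real_)
  sum(as.integer(alleles) > 0)
}

#' Re-polarize counts to the minor allele
#'
#' Variants whose counted-allele frequency exceeds 0.5 are flipped so counts
#' always refer to the minor allele. Idempotent.
#' @param g a [genotype_matrix()].
#' @return a [genotype_matrix()] with all counted-allele frequencies <= 0.5.
#' @export
polarize_minor <- function(g) {
  f <- colMeans(g$counts, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) g$counts[, flip] <- 2 - g$counts[, flip]
  g
}

#' Per-variant minor allele frequency
#'
#' `MAF_j = min(f, 1 - f)` with `f = sum(counts_j) / (2 * n_nonmissing)`.
#' Variants with no non-missing call get `NA` (flagged, undefined).
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of MAFs in `[0, 0.5]` (or `NA`).
#' @export
compute_maf <- function(g) {
  n_ok <- colSums(!is.na(g$counts))
  f <- colSums(g$counts, na.rm = TRUE) / (2 * n_ok)
  maf <- pmin(f, 1 - f)
  maf[n_ok == 0] <- NA_real_
  unname(maf)
}

#' Hardy-Weinberg equilibrium goodness-of-fit p-value
#'
#' 1-df chi-square test of observed genotype counts against expectations at
#' the estimated allele frequency. Monomorphic sites return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom., het., minor hom.).
#' @return p-value in (0, 1].
#' @export
hwe_pvalue <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("hwe_pvalue: total genotype count must be >= 1")
  p <- (2 * n_aa + n_Aa) / (2 * n)   # minor allele frequency
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' QC filter for rare-variant analysis
#'
#' Retains variants with call rate >= `call_rate_min`, HWE p >= `hwe_min_p`,
#' MAF < `maf_max` and minor-allele count > `mac_min` (strict, matching the
#' conventional "MAC > 2" phrasing). Defaults follow standard
#' sequencing-study QC: 0.95 / 1e-5 / 0.05 / 2.
#'
#' @param g a [genotype_matrix()].
#' @param call_rate_min minimum fraction of non-missing calls.
#' @param hwe_min_p minimum HWE p-value.
#' @param maf_max exclusive upper MAF bound (rare-variant threshold).
#' @param mac_min exclusive lower minor-allele-count bound.
#' @param verbose print per-criterion removal counts.
#' @return filtered [genotype_matrix()] with attribute `"qc_removed"`, a
#'   named vector of counts failing each criterion.
#' @export
qc_filter_variants <- function(g, call_rate_min = 0.95, hwe_min_p = 1e-5,
                               maf_max = 0.05, mac_min = 2, verbose = FALSE) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_min_p >= 0, hwe_min_p <= 1,
            maf_max > 0, maf_max <= 0.5, mac_min >= 0)
  cr <- colMeans(!is.na(g$counts))
  maf <- compute_maf(g)
  n_ok <- colSums(!is.na(g$counts))
  mac <- pmin(colSums(g$counts, na.rm = TRUE),
              2 * n_ok - colSums(g$counts, na.rm = TRUE))
  hwe <- vapply(seq_len(ncol(g$counts)), function(j) {
    cj <- g$counts[, j]
    hwe_pvalue(sum(cj == 0, na.rm = TRUE), sum(cj == 1, na.rm = TRUE),
               sum(cj == 2, na.rm = TRUE))
  }, numeric(1))
  fail_cr  <- cr < call_rate_min
  fail_hwe <- hwe < hwe_min_p
  fail_maf <- is.na(maf) | maf >= maf_max
  fail_mac <- mac <= mac_min
  removed <- c(call_rate = sum(fail_cr), hwe = sum(fail_hwe),
               maf = sum(fail_maf), mac = sum(fail_mac))
  keep <- !(fail_cr | fail_hwe | fail_maf | fail_mac)
  if (!any(keep)) {
    stop("no variants survive QC; review thresholds (call_rate_min=",
         call_rate_min, ", hwe_min_p=", hwe_min_p, ", maf_max=", maf_max,
         ", mac_min=", mac_min, ")")
  }
  if (verbose) {
    message(sprintf("QC: removed %d (call rate), %d (HWE), %d (MAF), %d (MAC); %d/%d retained",
                    removed[1], removed[2], removed[3], removed[4],
                    sum(keep), length(keep)))
  }
  out <- genotype_matrix(g$counts[, keep, drop = FALSE], g$samples,
                         g$variants[keep, , drop = FALSE])
  attr(out, "qc_removed") <- removed
  out
}

#' Variant weights for burden collapsing
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param scheme `"none"` (unit weights), `"beta"` (Beta-density weights,
#'   defaults shape (1, 25), the standard heavy up-weighting of the rarest
#'   variants) or `"madsen_browning"` (`1/sqrt(maf*(1-maf))`).
#' @param a,b Beta shape parameters (used when `scheme = "beta"`).
#' @return numeric vector of weights.
#' @export
variant_weight <- function(maf, scheme = c("none", "beta", "madsen_browning"),
                           a = 1, b = 25) {
  scheme <- match.arg(scheme)
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5)) {
    stop("variant_weight: maf must be in [0, 0.5]")
  }
  switch(scheme,
    none = rep(1, length(maf)),
    beta = stats::dbeta(maf, a, b),
    madsen_browning = {
      if (any(maf == 0)) stop("madsen_browning weight undefined at maf = 0")
      1 / sqrt(maf * (1 - maf))
    }
  )
}

#' Read a gene coordinate map
#'
#' Accepts either a 1-based inclusive TSV (`gene<TAB>chrom<TAB>start<TAB>end`,
#' header optional) or BED (0-based half-open, converted on read). Duplicate
#' gene symbols (e.g. transcript-level rows) are merged to the union of their
#' ranges per chromosome.
#'
#' @param path file path.
#' @param format `"tsv"` or `"bed"`.
#' @return data.frame of class `gene_range_map` with columns
#'   `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_map <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene map file not found: ", path)
  first <- readLines(path, n = 1)
  if (format == "tsv") {
    has_header <- grepl("gene", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
    tab <- utils::read.table(path, header = has_header, sep = "\t",
                             stringsAsFactors = FALSE)
    names(tab)[1:4] <- c("gene", "chrom", "start", "end")
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    tab <- data.frame(gene = tab[[4]], chrom = tab[[1]],
                      start = tab[[2]] + 1L, end = tab[[3]],
                      stringsAsFactors = FALSE)
  }
  gene_range_map(tab)
}

#' @rdname read_gene_map
#' @param tab data.frame with columns gene, chrom, start, end (1-based).
#' @export
gene_range_map <- function(tab) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(tab)))
  if (any(tab$start > tab$end)) stop("gene range with start > end")
  # union of ranges per (gene, chrom): mirrors merging transcript rows
  key <- paste(tab$gene, tab$chrom, sep = "\r")
  merged <- do.call(rbind, lapply(split(tab, key), function(d) {
    data.frame(gene = d$gene[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  class(merged) <- c("gene_range_map", "data.frame")
  merged
}

#' Read pathway gene sets in GMT format
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a pathway are dropped; empty pathways are removed.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `pathway_db`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3) return(NULL)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], character(1))
  sets <- sets[!vapply(sets, is.null, logical(1))]
  sets <- sets[vapply(sets, length, integer(1)) >= 1]
  if (!length(sets)) stop("no usable pathways in ", path)
  structure(sets, class = "pathway_db")
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors.
#' @export
pathway_db <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  sets <- sets[vapply(sets, length, integer(1)) >= 1]
  structure(sets, class = "pathway_db")
}

#' Read a phenotype table
#'
#' TSV with header `sample<TAB>pheno1...phenoQ`, numeric phenotype columns.
#' @param path file path.
#' @return numeric matrix with sample rownames.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  y <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(y) <- "double"
  rownames(y) <- as.character(tab[[1]])
  y
}

#' Map variants to genes with flanking regions
#'
#' A variant at position `p` maps to a gene iff
#' `start - flank_bp <= p <= end + flank_bp` (1-based inclusive). A variant
#' may map to multiple overlapping genes.
#'
#' @param g a [genotype_matrix()] with chrom/pos metadata.
#' @param genes a `gene_range_map`.
#' @param flank_bp flank added on both sides (default 10000).
#' @return named list: for each gene symbol, integer indices of mapped
#'   variant columns (genes with no variants omitted).
#' @export
map_variants_to_genes <- function(g, genes, flank_bp = 10000) {
  v <- g$variants
  if (any(is.na(v$chrom)) || any(is.na(v$pos))) {
    stop("variant chrom/pos metadata required for gene mapping")
  }
  norm_chr <- function(x) sub("^chr", "", as.character(x))
  vchr <- norm_chr(v$chrom)
  gchr <- norm_chr(genes$chrom)
  mapping <- lapply(seq_len(nrow(genes)), function(i) {
    which(vchr == gchr[i] &
          v$pos >= genes$start[i] - flank_bp &
          v$pos <= genes$end[i] + flank_bp)
  })
  names(mapping) <- genes$gene
  mapping <- mapping[vapply(mapping, length, integer(1)) > 0]
  if (!length(mapping)) stop("no variant maps to any gene (check chromosome naming / flank)")
  mapping
}

#' Collapse rare variants into a pathway-by-gene burden design
#'
#' Builds the N x sum(T_k) design of gene-level burden scores
#' `x_ikt = sum_{j in M_kt} w_j * g_ij`, one column per (pathway, gene) pair.
#' A gene shared by several pathways contributes one column per pathway (the
#' model's unit is the pathway-gene pair). Missing genotypes are imputed to
#' the expected count `2 * MAF` before summation. Columns are standardized
#' (mean 0, unit sample variance); constant columns are dropped with a
#' warning, and pathways left without genes are removed.
#'
#' @param g a [genotype_matrix()].
#' @param gene_map named list gene -> variant column indices
#'   (from [map_variants_to_genes()]).
#' @param pathways a `pathway_db`.
#' @param weights per-variant weights (length `ncol(g$counts)`); default unit.
#' @param standardize standardize columns (default TRUE; the penalized fit
#'   requires comparable column scales).
#' @return object of class `collapsed_design`: list with `X` (standardized
#'   matrix), `pathway`, `gene` (per column), `blocks` (per-pathway column
#'   index list), `m` (variants per column), `members` (variant ids per
#'   column), `center`, `scale`.
#' @export
collapse_to_design <- function(g, gene_map, pathways, weights = NULL,
                               standardize = TRUE) {
  if (is.null(weights)) weights <- rep(1, ncol(g$counts))
  stopifnot(length(weights) == ncol(g$counts))
  counts <- g$counts
  if (anyNA(counts)) {
    maf <- compute_maf(g)
    for (j in which(colSums(is.na(counts)) > 0)) {
      counts[is.na(counts[, j]), j] <- 2 * maf[j]
    }
  }
  cols <- list(); pw <- character(); gn <- character()
  m <- integer(); members <- list()
  for (k in names(pathways)) {
    genes_k <- intersect(pathways[[k]], names(gene_map))
    for (t in genes_k) {
      idx <- gene_map[[t]]
      x <- counts[, idx, drop = FALSE] %*% weights[idx]
      cols[[length(cols) + 1L]] <- as.numeric(x)
      pw <- c(pw, k); gn <- c(gn, t)
      m <- c(m, length(idx))
      members[[length(members) + 1L]] <- g$variants$id[idx]
    }
  }
  if (!length(cols)) stop("no (pathway, gene) pair has mapped variants")
  X <- do.call(cbind, cols)
  rownames(X) <- g$samples
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant burden column(s) dropped: ",
            paste(utils::head(paste(pw[!keep], gn[!keep], sep = ":"), 5), collapse = ", "))
    X <- X[, keep, drop = FALSE]
    pw <- pw[keep]; gn <- gn[keep]; m <- m[keep]; members <- members[keep]
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (standardize) X <- scale(X, center = ctr, scale = scl)
  colnames(X) <- paste(pw, gn, sep = "|")
  blocks <- split(seq_along(pw), factor(pw, levels = unique(pw)))
  structure(list(X = unclass(X)[, , drop = FALSE], pathway = pw, gene = gn,
                 blocks = blocks, m = m, members = members,
                 center = ctr, scale = scl, standardized = standardize),
            class = "collapsed_design")
}

#' @export
print.collapsed_design <- function(x, ...) {
  cat(sprintf("collapsed_design: %d samples x %d (pathway, gene) columns, %d pathways\n",
              nrow(x$X), ncol(x$X), length(x$blocks)))
  invisible(x)
}

#' Align genotype and phenotype samples
#'
#' @param g a [genotype_matrix()].
#' @param Y phenotype matrix with sample rownames.
#' @return list of the two objects restricted and reordered to the common
#'   samples; errors listing unmatched ids if the sets differ.
#' @export
align_samples <- function(g, Y) {
  common <- intersect(g$samples, rownames(Y))
  miss_g <- setdiff(rownames(Y), g$samples)
  miss_y <- setdiff(g$samples, rownames(Y))
  if (length(miss_g) || length(miss_y)) {
    stop("sample id mismatch; missing from genotypes: ",
         paste(utils::head(miss_g, 5), collapse = ", "),
         "; missing from phenotypes: ",
         paste(utils::head(miss_y, 5), collapse = ", "))
  }
  idx <- match(common, g$samples)
  g2 <- genotype_matrix(g$counts[idx, , drop = FALSE], common, g$variants)
  list(genotypes = g2, phenotypes = Y[common, , drop = FALSE])
}
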