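# Population-genetic statistics: per-sample inbreeding coefficients,
# per-locus minor allele frequency and Weir-Cockerham theta, and
# relatedness clusters derived from principal components.

#' Per-sample inbreeding coefficient F_IS
#'
#' For sample i, `F_IS_i = 1 - Ho_i / He_i` where `Ho_i` is the fraction of
#' heterozygous loci and `He_i` the mean over loci of the unbiased
#' expected heterozygosity `2*p*q*n/(n-1)` computed from allele
#' frequencies of the sample's own population, with n the number of
#' sampled alleles (twice the population sample count) so the estimator
#' is unbiased under Hardy-Weinberg. Loci monomorphic within the
#' population (He = 0) carry no information about heterozygote deficit
#' and are excluded from both means. Samples from populations of size 1
#' get `NA`.
#'
#' @param genotable a complete-case `genotype_table`.
#' @return data.frame with columns `sample_id`, `population`, `fis`.
#' @export
sample_fis <- function(genotable) {
  g <- genotable$genotypes
  if (anyNA(g)) stop("sample_fis requires complete-case genotypes")
  pops <- genotable$samples$population
  fis <- rep(NA_real_, nrow(g))
  for (pop in unique(pops)) {
    rows <- which(pops == pop)
    n <- length(rows)
    if (n < 2) next     # F_IS undefined for singleton populations
    p <- colMeans(g[rows, , drop = FALSE]) / 2
    he <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
    poly <- he > 0
    if (!any(poly)) next
    he_bar <- mean(he[poly])
    het <- g[rows, poly, drop = FALSE] == 1
    ho <- rowMeans(het)
    fis[rows] <- 1 - ho / he_bar
  }
  data.frame(sample_id = genotable$samples$sample_id,
             population = pops, fis = fis, stringsAsFactors = FALSE)
}

#' Weir-Cockerham theta per locus
#'
#' The 1984 variance-component estimator of F_ST across populations,
#' computed per biallelic locus from genotype counts. May be slightly
#' negative at undifferentiated loci.
#'
#' @param genotable a complete-case `genotype_table` (populations taken
#'   from the sample metadata).
#' @param snps optional SNP selection (ids or indices); default all.
#' @return numeric vector of theta values (named by snp_id).
#' @export
wc_fst <- function(genotable, snps = NULL) {
  g <- genotable$genotypes
  if (!is.null(snps)) {
    jdx <- if (is.character(snps)) match(snps, genotable$snps$snp_id) else snps
    g <- g[, jdx, drop = FALSE]
  }
  pops <- genotable$samples$population
  upops <- unique(pops)
  r <- length(upops)
  if (r < 2) stop("wc_fst needs at least 2 populations")
  ni <- vapply(upops, function(pp) sum(pops == pp), numeric(1))
  # per-pop allele frequency and heterozygote fraction, loci in columns
  pmat <- t(vapply(upops, function(pp)
    colMeans(g[pops == pp, , drop = FALSE]) / 2, numeric(ncol(g))))
  hmat <- t(vapply(upops, function(pp)
    colMeans(g[pops == pp, , drop = FALSE] == 1), numeric(ncol(g))))
  if (ncol(g) == 1) { pmat <- matrix(pmat, ncol = 1); hmat <- matrix(hmat, ncol = 1) }
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(ni * pmat) / (r * nbar)
  s2 <- colSums(ni * (pmat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * hmat) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[a + b + cc == 0] <- 0    # monomorphic overall: no differentiation
  names(theta) <- colnames(g)
  theta
}

# per-SNP centered genotypes scaled by sqrt(2p(1-p)); constant SNPs error
scale_genotypes <- function(g) {
  p <- colMeans(g) / 2
  v <- colMeans(g^2) - colMeans(g)^2
  if (any(p == 0 | p == 1 | v == 0))
    stop("constant SNP column encountered; filter genotypes first")
  sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
}

# PCA on samples of the scaled genotype matrix: scores (n x K) and
# orthonormal basis U used for the per-SNP regressions
genotype_pca <- function(g, K) {
  if (K >= nrow(g)) stop("need fewer PCs than samples")
  gs <- scale_genotypes(g)
  sv <- svd(gs, nu = min(nrow(g), 50), nv = 0)
  list(u = sv$u[, seq_len(K), drop = FALSE],
       d = sv$d,
       scores = sweep(sv$u[, seq_len(K), drop = FALSE], 2,
                      sv$d[seq_len(K)], "*"),
       scaled = gs)
}

#' Relatedness clusters from principal components
#'
#' k-means on the first `K_pcs` principal-component scores of the scaled
#' genotype matrix, mirroring the use of multivariate structure as a
#' categorical relatedness correction. Deterministic for a fixed seed;
#' cluster labels are renumbered by order of first appearance so equal
#' partitions always get equal labels.
#'
#' @param genotable a complete-case `genotype_table`.
#' @param K_pcs number of principal components (default 3).
#' @param n_clusters number of clusters (panel default 7; use 6 for the
#'   North American panel).
#' @param seed integer seed.
#' @param nstart k-means restarts (default 25).
#' @return integer vector of cluster labels, named by sample_id.
#' @export
relatedness_clusters <- function(genotable, K_pcs = 3, n_clusters = 7,
                                 seed = 1L, nstart = 25) {
  g <- genotable$genotypes
  if (n_clusters == 1)
    return(setNames(rep(1L, nrow(g)), genotable$samples$sample_id))
  pca <- genotype_pca(g, K_pcs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  km <- kmeans(pca$scores, centers = n_clusters, nstart = nstart,
               iter.max = 100)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  labels <- km$cluster
  relabel <- match(labels, unique(labels))
  setNames(as.integer(relabel), genotable$samples$sample_id)
}

#' Per-locus statistics: MAF, Weir-Cockerham theta, heterozygotes by cluster
#'
#' @param genotable a complete-case `genotype_table`.
#' @param clusters integer cluster label per sample (see
#'   [relatedness_clusters()]); default one cluster.
#' @return A list with `stats` (data.frame `snp_id`, `maf`, `fst`) and
#'   `het_by_cluster` (long data.frame `snp_id`, `cluster_id`,
#'   `het_count`, `n_samples`). Per SNP, cluster heterozygote counts sum
#'   to the SNP's total heterozygote count.
#' @export
locus_stats <- function(genotable, clusters = NULL) {
  g <- genotable$genotypes
  if (is.null(clusters)) clusters <- rep(1L, nrow(g))
  maf <- global_maf(genotable)
  fst <- wc_fst(genotable)
  ucl <- sort(unique(clusters))
  hb <- do.call(rbind, lapply(ucl, function(cl) {
    rows <- clusters == cl
    data.frame(snp_id = genotable$snps$snp_id,
               cluster_id = cl,
               het_count = colSums(g[rows, , drop = FALSE] == 1),
               n_samples = sum(rows),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(stats = data.frame(snp_id = genotable$snps$snp_id,
                          maf = maf, fst = as.numeric(fst),
                          row.names = NULL, stringsAsFactors = FALSE),
       het_by_cluster = hb)
}
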