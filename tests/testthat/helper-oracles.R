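# Shared fixture builders and independent oracles. Every oracle here is
# coded independently of the package's own computation paths.

# quick genotype_table from a samples x SNPs matrix
make_gt <- function(g, populations, lineage = "A", chrom = NULL, pos = NULL) {
  g <- as.matrix(g)
  if (is.null(chrom)) chrom <- rep("chr1", ncol(g))
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 100L
  genotype_table(
    g,
    data.frame(snp_id = sprintf("s%03d", seq_len(ncol(g))),
               chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("i%03d", seq_len(nrow(g))),
               population = populations, lineage = lineage,
               stringsAsFactors = FALSE))
}

# iid genotypes with no population structure (null model), MAF-safe
make_null_gt <- function(n_samples, n_snps, n_pops, seed,
                         q_range = c(0.1, 0.9)) {
  set.seed(seed)
  q <- runif(n_snps, q_range[1], q_range[2])
  g <- matrix(rbinom(n_samples * n_snps, 2, rep(q, each = n_samples)),
              nrow = n_samples)
  maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  keep <- maf >= 0.05
  pops <- rep(sprintf("p%02d", seq_len(n_pops)),
              each = ceiling(n_samples / n_pops))[seq_len(n_samples)]
  make_gt(g[, keep, drop = FALSE], pops)
}

# O(n*m) brute-force nearest-TE oracle: for each SNP, scan every TE on its
# chromosome; distance 0 inside, else gap to the nearer edge; ties by
# lowest start then te_id; strand-aware sense
oracle_nearest <- function(chrom, pos, catalog, sense_mode = "strand") {
  n <- length(pos)
  out <- data.frame(te_id = rep("<no_te>", n),
                    superfamily = rep("<no_te>", n),
                    distance_bp = rep(NA_integer_, n),
                    sense = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sel <- catalog$chrom == chrom[i]
    if (!any(sel)) next
    st <- catalog$start[sel]; en <- catalog$end[sel]
    d <- ifelse(pos[i] >= st & pos[i] <= en, 0,
                pmin(abs(pos[i] - st), abs(pos[i] - en)))
    ord <- order(d, st, catalog$te_id[sel])
    b <- ord[1]
    idx <- which(sel)[b]
    out$te_id[i] <- catalog$te_id[idx]
    out$superfamily[i] <- catalog$superfamily[idx]
    out$distance_bp[i] <- as.integer(d[b])
    strand <- catalog$strand[idx]
    if (d[b] == 0) out$sense[i] <- "within"
    else {
      after <- pos[i] > catalog$end[idx]
      flip <- sense_mode == "strand" && strand == "-"
      out$sense[i] <- if (xor(after, flip)) "downstream" else "upstream"
    }
  }
  out
}

# Newton-Raphson (Fisher scoring) maximization of the binomial cloglog
# log-likelihood, independent of stats::glm
oracle_cloglog_fit <- function(X, y, n, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(1 - exp(-exp(eta)), 1e-12), 1 - 1e-12)
    dmu <- exp(eta - exp(eta))
    score <- drop(t(X) %*% (dmu * (y - n * mu) / (mu * (1 - mu))))
    W <- n * dmu^2 / (mu * (1 - mu))
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# beta-binomial cell probability by numerical integration of the binomial
# likelihood against the beta density (independent of any lgamma algebra)
oracle_bb_loglik <- function(k, n, p, alpha, beta) {
  ll <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(beta)) {
      u <- exp(-(alpha[i] + beta[j]))
      a <- p[i] * u; b <- (1 - p[i]) * u
      f <- function(x) dbinom(k[i, j], n[i, j], x) * dbeta(x, a, b)
      v <- integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value
      ll <- ll + log(v)
    }
  }
  ll
}

# exact hypergeometric upper-tail by explicit summation of lchoose terms
oracle_hyper_tail <- function(a, m, K, N) {
  j <- seq(a, min(m, K))
  if (length(j) == 0 || a > min(m, K)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, m - j) - lchoose(N, m)))
}

# Weir-Cockerham (1984) theta for one biallelic locus, coded directly from
# the variance components (independent of the package's vectorized path)
oracle_wc_theta <- function(p_i, h_i, n_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# random TE catalog for property tests
random_catalog <- function(n_te, chroms = c("chr1", "chr2"), L = 1e5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_te == 0)
    return(te_catalog(character(), character(), integer(), integer(),
                      character(), character()))
  start <- sample.int(L - 500, n_te, replace = TRUE)
  te_catalog(sprintf("t%04d", sample(n_te)), sample(chroms, n_te, TRUE),
             start, start + sample(50:500, n_te, TRUE),
             sample(c("+", "-", "unknown"), n_te, TRUE),
             sample(c("Copia", "Gypsy", "CACTA"), n_te, TRUE))
}
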