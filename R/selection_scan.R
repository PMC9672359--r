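# Selection-scan module: PCA-Mahalanobis outlier scan, Bayesian F_ST
# decomposition (locus alpha / population beta) by reversible-jump MCMC,
# classification into balancing / divergent / neutral, and the
# balancing-vs-purifying discrimination rule.

#' MCMC settings for the F_ST decomposition
#'
#' Desk-scale defaults: 10 pilot runs of 1,000 sweeps for proposal tuning,
#' 5,000 burn-in sweeps, 25,000 sampling sweeps thinned by 10. The prior
#' odds of 10 favour the neutral (alpha excluded) model.
#'
#' @param pilot_runs,pilot_length proposal-tuning rounds and their length.
#' @param burnin burn-in sweeps.
#' @param n_iter sampling sweeps.
#' @param thin thinning interval.
#' @param prior_odds prior odds for neutrality (P(neutral)/P(selected)).
#' @param alpha_prior_sd sd of the N(0, sd) slab on alpha.
#' @param beta_prior_mean,beta_prior_sd normal prior on beta.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(pilot_runs = 10, pilot_length = 1000,
                          burnin = 5000, n_iter = 25000, thin = 10,
                          prior_odds = 10, alpha_prior_sd = 1,
                          beta_prior_mean = -1, beta_prior_sd = 1.8) {
  structure(list(pilot_runs = pilot_runs, pilot_length = pilot_length,
                 burnin = burnin, n_iter = n_iter, thin = thin,
                 prior_odds = prior_odds, alpha_prior_sd = alpha_prior_sd,
                 beta_prior_mean = beta_prior_mean,
                 beta_prior_sd = beta_prior_sd),
            class = "mcmc_settings")
}

#' Per-population allele counts
#'
#' @param genotable a complete-case `genotype_table`.
#' @return list with integer matrices `k` (alternate-allele counts, SNPs x
#'   populations) and `n` (sampled alleles).
#' @export
allele_counts <- function(genotable) {
  g <- genotable$genotypes
  pops <- genotable$samples$population
  upops <- unique(pops)
  k <- vapply(upops, function(pp)
    as.integer(colSums(g[pops == pp, , drop = FALSE])), integer(ncol(g)))
  n <- vapply(upops, function(pp)
    rep(2L * sum(pops == pp), ncol(g)), integer(ncol(g)))
  if (ncol(g) == 1) { k <- matrix(k, nrow = 1); n <- matrix(n, nrow = 1) }
  dimnames(k) <- dimnames(n) <- list(genotable$snps$snp_id, upops)
  list(k = k, n = n)
}

#' Beta-binomial log-likelihood of an allele-count table
#'
#' Full log-likelihood (binomial coefficients included) of counts `k` out
#' of `n` under the F_ST decomposition model with ancestral frequencies
#' `p`, locus effects `alpha` and population effects `beta`:
#' `F_ST(i,j) = plogis(alpha_i + beta_j)` and counts beta-binomial with
#' mean `p_i` and overdispersion `F_ST(i,j)`.
#'
#' @param k,n integer matrices (loci x populations).
#' @param p ancestral allele frequency per locus.
#' @param alpha locus effect per locus.
#' @param beta population effect per population.
#' @return scalar log-likelihood.
#' @export
beta_binomial_loglik <- function(k, n, p, alpha, beta) {
  bb_loglik_cpp(as.matrix(k), as.matrix(n), as.numeric(p),
                as.numeric(alpha), as.numeric(beta))
}

# split-chain potential scale reduction (Gelman-Rubin on the two halves)
split_psr <- function(chain) {
  m <- nrow(chain)
  h <- floor(m / 2)
  if (h < 2) return(rep(NA_real_, ncol(chain)))
  apply(chain, 2, function(x) {
    a <- x[seq_len(h)]
    b <- x[(m - h + 1):m]
    W <- (stats::var(a) + stats::var(b)) / 2
    if (W <= 0) return(1)
    B <- h * stats::var(c(mean(a), mean(b)))
    varplus <- (h - 1) / h * W + B / h
    sqrt(varplus / W)
  })
}

#' Bayesian F_ST decomposition by reversible-jump MCMC
#'
#' Decomposes per-locus, per-population F_ST into locus-specific effects
#' (alpha; negative values point to balancing or purifying selection) and
#' population-specific effects (beta), with a reversible-jump move that
#' toggles each locus's alpha in and out of the model. Evidence for
#' selection at a locus is the log10 posterior odds of inclusion; outliers
#' are loci exceeding `log10_po_threshold` within the Bayesian FDR
#' selection (mean posterior probability of neutrality of the selected set
#' kept below `fdr`).
#'
#' @param genotable a complete-case `genotype_table`, or a list with
#'   allele-count matrices `k` and `n` (loci x populations).
#' @param settings an [mcmc_settings()].
#' @param log10_po_threshold log10 posterior-odds cutoff (default 0.5).
#' @param fdr Bayesian false discovery rate (default 0.05).
#' @return list with `loci` (data.frame: `snp_id`, `post_incl`,
#'   `log10_PO`, `alpha_mean`, `alpha_cond`, `selected_fdr`,
#'   `is_outlier`), `beta` (data.frame per population), and `diagnostics`
#'   (split-chain PSR per beta, acceptance rates, settings). A PSR above
#'   1.1 on any beta triggers a warning.
#' @export
fst_decomposition_mcmc <- function(genotable, settings = mcmc_settings(),
                                   log10_po_threshold = 0.5, fdr = 0.05) {
  if (inherits(genotable, "genotype_table")) {
    ac <- allele_counts(genotable)
  } else {
    ac <- genotable
    stopifnot(all(c("k", "n") %in% names(ac)))
  }
  if (ncol(ac$k) < 2) stop("need at least 2 populations")
  fit <- bayescan_mcmc_cpp(ac$k, ac$n,
                           settings$pilot_runs, settings$pilot_length,
                           settings$burnin, settings$n_iter, settings$thin,
                           settings$prior_odds, settings$alpha_prior_sd,
                           settings$beta_prior_mean, settings$beta_prior_sd)
  S <- fit$n_recorded
  pin <- pmin(pmax(fit$post_incl, 1 / (2 * S)), 1 - 1 / (2 * S))
  log10_po <- log10(pin / (1 - pin))
  # Bayesian FDR: grow the selected set in decreasing posterior-inclusion
  # order while its mean neutrality probability stays below fdr
  ord <- order(fit$post_incl, decreasing = TRUE)
  qloc <- cumsum(1 - fit$post_incl[ord]) / seq_along(ord)
  nsel <- if (any(qloc <= fdr)) max(which(qloc <= fdr)) else 0
  selected <- logical(length(ord))
  if (nsel > 0) selected[ord[seq_len(nsel)]] <- TRUE
  snp_ids <- rownames(ac$k)
  if (is.null(snp_ids)) snp_ids <- paste0("locus_", seq_len(nrow(ac$k)))
  loci <- data.frame(snp_id = snp_ids,
                     post_incl = fit$post_incl,
                     log10_PO = log10_po,
                     alpha_mean = fit$alpha_mean,
                     alpha_cond = fit$alpha_cond,
                     selected_fdr = selected,
                     is_outlier = selected & log10_po > log10_po_threshold,
                     stringsAsFactors = FALSE)
  psr <- split_psr(fit$beta_chain)
  if (any(psr > 1.1, na.rm = TRUE))
    warning("split-chain PSR > 1.1 on beta; consider longer chains")
  pops <- colnames(ac$k)
  if (is.null(pops)) pops <- paste0("pop_", seq_len(ncol(ac$k)))
  list(loci = loci,
       beta = data.frame(population = pops, beta_mean = fit$beta_mean,
                         psr = psr, accept_rate = fit$beta_accept,
                         stringsAsFactors = FALSE),
       diagnostics = list(psr_beta = psr,
                          p_accept = fit$p_accept,
                          n_recorded = S,
                          settings = settings))
}

#' PCA-Mahalanobis genome scan
#'
#' Centers and scales genotypes per SNP by `sqrt(2p(1-p))`, extracts the
#' first `K` principal components of the sample structure, regresses every
#' SNP on the K component score vectors, and combines the K regression
#' z-scores into a squared Mahalanobis distance using a robust (MCD)
#' covariance estimate. Distances are rescaled by the genomic inflation
#' factor (median d-squared over the chi-squared K median) before
#' conversion to p-values; q-values are Benjamini-Hochberg.
#'
#' @param genotable a complete-case, filtered `genotype_table`.
#' @param K number of principal components (default 3).
#' @return list with `snps` (data.frame: `snp_id`, `mahalanobis_d2`,
#'   `p_value`, `q_value`), `scores` (samples x K), `zscores` (SNPs x K)
#'   and `gif` (the inflation factor).
#' @export
pca_scan <- function(genotable, K = 3) {
  g <- genotable$genotypes
  if (K < 1) stop("K must be >= 1")
  pca <- genotype_pca(g, K)
  u <- pca$u                     # orthonormal regressors (n x K)
  gs <- pca$scaled               # n x SNPs
  n <- nrow(gs)
  bt <- crossprod(u, gs)         # K x SNPs coefficients (orthonormal basis)
  rss <- colSums(gs^2) - colSums(bt^2)
  dfree <- max(n - K - 1, 1)
  sigma <- sqrt(pmax(rss, 0) / dfree)
  sigma[sigma == 0] <- .Machine$double.eps
  z <- t(bt) / sigma             # SNPs x K z-scores
  if (K == 1) {
    ctr <- median(z)
    s2 <- mad(z)^2
    d2 <- (z - ctr)^2 / s2
    d2 <- as.numeric(d2)
  } else {
    rob <- MASS::cov.rob(z, method = "mcd")
    d2 <- stats::mahalanobis(z, rob$center, rob$cov)
  }
  gif <- median(d2) / qchisq(0.5, df = K)
  pval <- pchisq(d2 / gif, df = K, lower.tail = FALSE)
  qval <- p.adjust(pval, method = "BH")
  list(snps = data.frame(snp_id = genotable$snps$snp_id,
                         mahalanobis_d2 = d2, p_value = pval,
                         q_value = qval, stringsAsFactors = FALSE),
       scores = pca$scores, zscores = z, gif = gif)
}

#' Classify SNPs into balancing / divergent / neutral
#'
#' Combines the two scan arms. Balancing: a significant locus effect
#' (MCMC outlier) with negative alpha. Divergent: a significant locus
#' effect with positive alpha, or (in `"combined"` mode) a PCA-scan
#' outlier (`q < q_threshold`) whose Weir-Cockerham theta lies above the
#' SNP-set median. Everything else is neutral. `"bayescan-only"` restricts
#' calls to the MCMC arm.
#'
#' @param pca_result output of [pca_scan()].
#' @param mcmc_result output of [fst_decomposition_mcmc()].
#' @param stats per-locus stats data.frame (needs `snp_id`, `fst`), see
#'   [locus_stats()].
#' @param q_threshold PCA-arm q-value cutoff (default 0.01).
#' @param mode `"combined"` (default) or `"bayescan-only"`.
#' @return data.frame of selection calls: `snp_id`, `mahalanobis_d2`,
#'   `q_value`, `alpha`, `log10_PO`, `class`, `purifying_candidate`
#'   (initialised FALSE; see [purifying_rule()]).
#' @export
classify_selection <- function(pca_result, mcmc_result, stats,
                               q_threshold = 0.01,
                               mode = c("combined", "bayescan-only")) {
  mode <- match.arg(mode)
  pc <- pca_result$snps
  mc <- mcmc_result$loci
  stopifnot(identical(pc$snp_id, mc$snp_id))
  fst <- stats$fst[match(pc$snp_id, stats$snp_id)]
  bal <- mc$is_outlier & mc$alpha_mean < 0
  div <- mc$is_outlier & mc$alpha_mean > 0
  if (mode == "combined") {
    pca_div <- pc$q_value < q_threshold & fst > median(fst, na.rm = TRUE)
    div <- div | (pca_div & !bal)
  }
  cls <- ifelse(bal, "balancing", ifelse(div, "divergent", "neutral"))
  data.frame(snp_id = pc$snp_id,
             mahalanobis_d2 = pc$mahalanobis_d2,
             q_value = pc$q_value,
             alpha = mc$alpha_mean,
             log10_PO = mc$log10_PO,
             class = cls,
             purifying_candidate = FALSE,
             stringsAsFactors = FALSE)
}

#' Discriminate purifying-selection candidates among negative-alpha SNPs
#'
#' Among SNPs called balancing (negative alpha with significant locus
#' effect), flags candidates of purifying selection: (i) the SNP's minor
#' allele frequency must lie below the median MAF of neutral-class SNPs,
#' and (ii) at the group level, negative-alpha SNPs must show lower median
#' MAF at 0-fold (non-synonymous) than at 4-fold (synonymous) sites. A SNP
#' is flagged iff (i) holds and ((ii) holds or the SNP itself is 0-fold
#' with MAF below the 4-fold median). With `per_snp = TRUE`, condition
#' (ii) is evaluated per SNP only (the SNP must be 0-fold with MAF below
#' the 4-fold median). Without any fold annotation the decision falls back
#' to condition (i) alone, with a warning. Positive-alpha and neutral SNPs
#' are never flagged; unflagged negative-alpha SNPs stay balancing.
#'
#' @param calls selection calls from [classify_selection()].
#' @param stats per-locus stats (needs `snp_id`, `maf`).
#' @param codon_fold data.frame `chrom`, `pos`, `fold` or a vector of fold
#'   labels aligned with `calls` (values `0-fold`, `4-fold`, `none`), or
#'   NULL.
#' @param snps SNP coordinate table (`snp_id`, `chrom`, `pos`), required
#'   when `codon_fold` is a coordinate table.
#' @param per_snp evaluate condition (ii) per SNP instead of group level.
#' @return `calls` with `purifying_candidate` filled in.
#' @export
purifying_rule <- function(calls, stats, codon_fold = NULL, snps = NULL,
                           per_snp = FALSE) {
  maf <- stats$maf[match(calls$snp_id, stats$snp_id)]
  fold <- rep(NA_character_, nrow(calls))
  if (!is.null(codon_fold)) {
    if (is.data.frame(codon_fold)) {
      if (is.null(snps)) stop("snps table required to match codon_fold coordinates")
      key_cf <- paste(codon_fold$chrom, codon_fold$pos)
      key_snp <- paste(snps$chrom, snps$pos)[match(calls$snp_id, snps$snp_id)]
      fold <- codon_fold$fold[match(key_snp, key_cf)]
    } else fold <- as.character(codon_fold)
  }
  neg <- calls$class == "balancing" & calls$alpha < 0
  neutral_med <- median(maf[calls$class == "neutral"], na.rm = TRUE)
  cond1 <- neg & !is.na(maf) & maf < neutral_med

  have_fold <- !is.na(fold) & fold %in% c("0-fold", "4-fold")
  flags <- rep(FALSE, nrow(calls))
  if (!any(neg)) { calls$purifying_candidate <- flags; return(calls) }
  if (!any(have_fold & neg)) {
    warning("no codon-fold annotation among negative-alpha SNPs; ",
            "purifying candidacy decided on allele frequency alone")
    flags <- cond1
  } else {
    med0 <- median(maf[neg & fold == "0-fold"], na.rm = TRUE)
    med4 <- median(maf[neg & fold == "4-fold"], na.rm = TRUE)
    cond2_group <- is.finite(med0) && is.finite(med4) && med0 < med4
    snp_is_low0 <- !is.na(fold) & fold == "0-fold" & is.finite(med4) & maf < med4
    if (per_snp) flags <- cond1 & snp_is_low0
    else flags <- cond1 & (cond2_group | snp_is_low0)
  }
  calls$purifying_candidate <- flags
  calls
}
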