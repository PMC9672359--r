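# Selection scans: beta-binomial likelihood against an integration oracle,
# RJ-MCMC determinism and monotonicity, PCA-scan calibration, the
# classification rule, and the purifying-selection discrimination rule.

short_chain <- function() mcmc_settings(pilot_runs = 2, pilot_length = 200,
                                        burnin = 500, n_iter = 2000, thin = 5)

test_that("the beta-binomial log-likelihood matches numerical integration", {
  k <- matrix(c(3L, 9L, 0L, 17L), nrow = 2)
  n <- matrix(c(20L, 20L, 18L, 22L), nrow = 2)
  p <- c(0.3, 0.62)
  alpha <- c(0.4, -1.1)
  beta <- c(-1.5, -0.2)
  expect_equal(beta_binomial_loglik(k, n, p, alpha, beta),
               oracle_bb_loglik(k, n, p, alpha, beta), tolerance = 1e-8)
  # alpha = 0 for all loci: F_ST depends on the population only
  f <- function(a, b) 1 / (1 + exp(-(a + b)))
  expect_equal(f(0, beta[1]), f(0, beta[1]))
  ll0 <- beta_binomial_loglik(k, n, p, c(0, 0), beta)
  expect_equal(ll0, oracle_bb_loglik(k, n, p, c(0, 0), beta),
               tolerance = 1e-8)
})

test_that("identical seeds give identical MCMC results", {
  gt <- make_null_gt(40, 120, 4, seed = 71)
  set.seed(3)
  a <- fst_decomposition_mcmc(gt, short_chain())
  set.seed(3)
  b <- fst_decomposition_mcmc(gt, short_chain())
  expect_identical(a$loci, b$loci)
  expect_identical(a$beta$beta_mean, b$beta$beta_mean)
})

test_that("posterior-mean alpha increases with across-population spread", {
  # same global frequency, growing differentiation for locus 1
  set.seed(8)
  base_k <- matrix(rbinom(80 * 4, 40, 0.5), ncol = 4)
  n <- matrix(40L, nrow = nrow(base_k) + 1, ncol = 4)
  alphas <- vapply(c(0, 0.25, 0.45), function(spread) {
    k1 <- as.integer(round(40 * c(0.5 - spread, 0.5 + spread,
                                  0.5 - spread, 0.5 + spread)))
    k <- rbind(k1, base_k)
    set.seed(12)
    fit <- fst_decomposition_mcmc(list(k = k, n = n), short_chain())
    fit$loci$alpha_mean[1]
  }, numeric(1))
  expect_true(alphas[3] > alphas[1])
  expect_true(alphas[3] > 0.5)            # strongly divergent locus
})

test_that("the PCA scan is calibrated on structureless data", {
  gt <- make_null_gt(50, 1500, 5, seed = 19)
  res <- pca_scan(gt, K = 3)
  expect_gt(res$gif, 0.8)
  expect_lt(res$gif, 1.2)
  expect_lt(mean(res$snps$q_value < 0.01), 0.02)
  expect_true(all(res$snps$p_value >= 0 & res$snps$p_value <= 1))
})

test_that("constant SNP columns are rejected by the scan", {
  g <- cbind(c(1, 1, 1, 1), c(0, 1, 2, 1))
  expect_error(pca_scan(make_gt(g, rep("p1", 4)), K = 1), "constant")
})

fake_scan <- function(q, alpha, log10_po, is_outlier, fst) {
  ids <- sprintf("s%03d", seq_along(q))
  list(pca = list(snps = data.frame(snp_id = ids, mahalanobis_d2 = 1,
                                    p_value = q, q_value = q,
                                    stringsAsFactors = FALSE)),
       mcmc = list(loci = data.frame(snp_id = ids, post_incl = 0.5,
                                     log10_PO = log10_po,
                                     alpha_mean = alpha, alpha_cond = alpha,
                                     selected_fdr = is_outlier,
                                     is_outlier = is_outlier,
                                     stringsAsFactors = FALSE)),
       stats = data.frame(snp_id = ids, maf = 0.2, fst = fst,
                          stringsAsFactors = FALSE))
}

test_that("classification follows the balancing / divergent / neutral rule", {
  # 1: strong negative-alpha outlier; 2: below all thresholds; 3: PCA-arm
  # divergent (high theta, q tiny) despite weak posterior odds; 4: filler
  fx <- fake_scan(q = c(0.5, 0.5, 0.001, 0.9),
                  alpha = c(-0.8, 0.1, 0.5, 0),
                  log10_po = c(1.2, -0.3, 0.2, -1),
                  is_outlier = c(TRUE, FALSE, FALSE, FALSE),
                  fst = c(0.05, 0.02, 0.9, 0.01))
  calls <- classify_selection(fx$pca, fx$mcmc, fx$stats)
  expect_equal(calls$class, c("balancing", "neutral", "divergent", "neutral"))
  # bayescan-only mode drops the PCA arm
  calls2 <- classify_selection(fx$pca, fx$mcmc, fx$stats,
                               mode = "bayescan-only")
  expect_equal(calls2$class, c("balancing", "neutral", "neutral", "neutral"))
})

test_that("the purifying rule matches hand evaluation on all branches", {
  ids <- sprintf("s%03d", 1:8)
  calls <- data.frame(
    snp_id = ids,
    mahalanobis_d2 = 1, q_value = 0.5,
    alpha = c(-0.8, -0.6, -0.9, -0.5, 0.7, 0, -0.7, -0.4),
    log10_PO = 1,
    class = c("balancing", "balancing", "balancing", "balancing",
              "divergent", "neutral", "balancing", "balancing"),
    purifying_candidate = FALSE, stringsAsFactors = FALSE)
  stats <- data.frame(snp_id = ids,
                      maf = c(0.45, 0.06, 0.08, 0.10, 0.05, 0.22, 0.18, 0.09))
  fold <- c("4-fold", "0-fold", "0-fold", "4-fold", "0-fold", "none",
            "4-fold", "none")
  # neutral MAF median is the single neutral SNP: 0.22
  # negative-alpha group: 0-fold medians {0.06, 0.08} -> 0.07;
  # 4-fold {0.45, 0.10, 0.18} -> 0.18; group condition (ii) holds
  out <- purifying_rule(calls, stats, fold)
  want <- c(FALSE,  # (i) fails: 0.45 > 0.22
            TRUE,   # (i) and group (ii) hold
            TRUE,
            TRUE,   # 4-fold SNP, flagged via group-level (ii)
            FALSE,  # positive alpha: never
            FALSE,  # neutral: never
            TRUE,   # (i) holds, group (ii) holds
            TRUE)   # no fold annotation for the SNP, group (ii) carries it
  expect_identical(out$purifying_candidate, want)

  # per-SNP variant: only 0-fold SNPs below the 4-fold median qualify
  out2 <- purifying_rule(calls, stats, fold, per_snp = TRUE)
  want2 <- c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_identical(out2$purifying_candidate, want2)

  # no fold annotation at all: condition (i) alone, with a warning
  expect_warning(out3 <- purifying_rule(calls, stats, rep("none", 8)),
                 "allele frequency alone")
  expect_identical(out3$purifying_candidate,
                   calls$class == "balancing" & stats$maf < 0.22)
})

test_that("coordinate-table codon-fold input joins on chrom and pos", {
  ids <- c("a", "b")
  calls <- data.frame(snp_id = ids, mahalanobis_d2 = 1, q_value = 0.5,
                      alpha = c(-1, -1), log10_PO = 1,
                      class = c("balancing", "balancing"),
                      purifying_candidate = FALSE, stringsAsFactors = FALSE)
  calls <- rbind(calls,
                 data.frame(snp_id = "n", mahalanobis_d2 = 1, q_value = 0.5,
                            alpha = 0, log10_PO = 0, class = "neutral",
                            purifying_candidate = FALSE))
  stats <- data.frame(snp_id = c(ids, "n"), maf = c(0.05, 0.30, 0.25))
  snps <- data.frame(snp_id = c(ids, "n"), chrom = "chr1",
                     pos = c(10L, 20L, 30L))
  cf <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                   fold = c("0-fold", "4-fold", "none"))
  out <- purifying_rule(calls, stats, cf, snps = snps)
  expect_true(out$purifying_candidate[1])    # 0-fold below 4-fold median
  expect_false(out$purifying_candidate[2])
  expect_false(out$purifying_candidate[3])
})
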