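# Cross-lineage profiles and correlation, Fisher enrichment against the
# hypergeometric oracle, and the essentiality ANOVA.

mk_ctx <- function(superfamily, sense, ids = NULL) {
  n <- length(superfamily)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  data.frame(snp_id = ids, chrom = "chr1", pos = seq_len(n) * 10L,
             te_id = "te", superfamily = superfamily,
             distance_bp = 100L, sense = sense, stringsAsFactors = FALSE)
}

mk_calls <- function(class, ids = NULL) {
  n <- length(class)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  data.frame(snp_id = ids, mahalanobis_d2 = 1, q_value = 0.5, alpha = 0,
             log10_PO = 0, class = class, purifying_candidate = FALSE,
             stringsAsFactors = FALSE)
}

test_that("outlier proportions are per-stratum ratios, empty strata omitted", {
  ctx <- mk_ctx(rep("Copia", 10), rep("downstream", 10))
  calls <- mk_calls(c(rep("balancing", 3), rep("neutral", 7)))
  pr <- outlier_profiles(ctx, calls)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$prop_balancing, 0.3)
  expect_equal(pr$prop_divergent, 0)
  expect_false(pr$low_confidence)
  expect_false("upstream" %in% pr$sense)    # zero-SNP stratum omitted
  # min_n flags small strata; "within" SNPs are not profiled
  ctx2 <- mk_ctx(c("Gypsy", "Gypsy", "Gypsy"),
                 c("upstream", "upstream", "within"))
  pr2 <- outlier_profiles(ctx2, mk_calls(rep("divergent", 3)))
  expect_equal(pr2$n_snps, 2)
  expect_true(pr2$low_confidence)
})

test_that("profiles on a planted fixture match the planted class rates", {
  sc <- simulation_config(seed = 81, n_snps = 3000, n_pops = 4,
                          n_samples_per_pop = 6, fis_pop = 0.2)
  sim <- simulate_genotypes(sc, simulate_te_landscape(sc))
  tr <- sim$truth$snps
  calls <- mk_calls(ifelse(tr$class %in% c("balancing", "divergent"),
                           tr$class, "neutral"), ids = tr$snp_id)
  ctx <- tr[, c("snp_id", "chrom", "pos", "te_id", "superfamily",
                "distance_bp", "sense")]
  pr <- outlier_profiles(ctx, calls, min_n = 20)
  big <- pr[!pr$low_confidence, ]
  p_bal <- sc$class_props["balancing"]
  se <- sqrt(p_bal * (1 - p_bal) / big$n_snps)
  expect_gt(mean(abs(big$prop_balancing - p_bal) <= 3 * se), 0.95)
})

test_that("cross-lineage correlation: identity, frozen toy, symmetry", {
  pr <- data.frame(superfamily = c("A", "B", "C", "D"), sense = "upstream",
                   n_snps = 10, prop_balancing = c(0.1, 0.2, 0.3, 0.4),
                   prop_divergent = c(0.4, 0.3, 0.3, 0.1),
                   low_confidence = FALSE, stringsAsFactors = FALSE)
  same <- cross_lineage_correlation(pr, pr)
  expect_equal(same$r, c(1, 1))
  # second lineage swaps the two proportion columns: r computed on the
  # 4-point toy (0.1,0.4),(0.2,0.3),(0.3,0.3),(0.4,0.1), frozen from an
  # independent arithmetic oracle
  pr2 <- pr
  pr2$prop_balancing <- pr$prop_divergent
  pr2$prop_divergent <- pr$prop_balancing
  mixed <- cross_lineage_correlation(pr, pr2)
  expect_equal(mixed$r[mixed$type == "balancing"], -0.923380516876639,
               tolerance = 1e-12)
  # symmetry in lineages and invariance to row order
  rev_order <- pr2[c(3, 1, 4, 2), ]
  m2 <- cross_lineage_correlation(rev_order, pr)
  expect_equal(sort(m2$r), sort(mixed$r))
})

test_that("shared outliers are matched by position across lineages", {
  snps_a <- data.frame(snp_id = c("a1", "a2", "a3"), chrom = "chr1",
                       pos = c(100L, 200L, 300L))
  snps_b <- data.frame(snp_id = c("b1", "b2", "b3"), chrom = "chr1",
                       pos = c(100L, 250L, 300L))
  calls_a <- mk_calls(c("balancing", "balancing", "divergent"),
                      ids = snps_a$snp_id)
  calls_b <- mk_calls(c("balancing", "balancing", "divergent"),
                      ids = snps_b$snp_id)
  sh <- shared_outlier_counts(calls_a, calls_b, snps_a, snps_b)
  expect_equal(sh$n_shared[sh$type == "balancing"], 1)
  expect_equal(sh$n_shared[sh$type == "divergent"], 1)
})

test_that("Fisher enrichment equals the hypergeometric oracle", {
  # toy mirroring a 14-of-17 foreground split against a constructed
  # background universe of 186 genes, 17 of them annotated... term carried
  # by 14 fg + 3 bg-only genes
  snp_gene <- data.frame(snp_id = sprintf("s%03d", 1:186),
                         gene_id = sprintf("g%03d", 1:186))
  fg <- sprintf("s%03d", 1:17)
  bg <- sprintf("s%03d", 1:186)
  gene_go <- data.frame(gene_id = c(sprintf("g%03d", 1:14),
                                    sprintf("g%03d", 18:20)),
                        go_term = "GO:0000001", stringsAsFactors = FALSE)
  res <- fisher_enrichment(fg, bg, snp_gene, gene_go)
  expect_equal(res$fg_with_term, 14)
  expect_equal(res$bg_with_term, 17)
  expect_equal(res$p, oracle_hyper_tail(14, 17, 17, 186), tolerance = 1e-12)
  # closed form: all 3 term members in a foreground of 3 from 100
  sg2 <- data.frame(snp_id = sprintf("s%03d", 1:100),
                    gene_id = sprintf("g%03d", 1:100))
  gg2 <- data.frame(gene_id = sprintf("g%03d", 1:3), go_term = "GO:1")
  res2 <- fisher_enrichment(sprintf("s%03d", 1:3), sprintf("s%03d", 1:100),
                            sg2, gg2)
  expect_equal(res2$p, 1 / choose(100, 3), tolerance = 1e-12)
})

test_that("duplicate SNPs in one gene do not pseudo-replicate", {
  snp_gene <- data.frame(snp_id = sprintf("s%02d", 1:20),
                         gene_id = c(rep("g1", 5), sprintf("g%02d", 2:16)))
  gene_go <- data.frame(gene_id = c("g1", "g02", "g03"), go_term = "GO:7")
  res_multi <- fisher_enrichment(sprintf("s%02d", 1:6), sprintf("s%02d", 1:20),
                                 snp_gene, gene_go)
  # foreground genes: g1 (via 5 SNPs) and g02 -> 2 genes, both with term
  expect_equal(res_multi$fg_size, 2)
  expect_equal(res_multi$fg_with_term, 2)
  # terms with < 2 foreground genes are skipped
  gg_small <- data.frame(gene_id = "g03", go_term = "GO:8")
  expect_equal(nrow(fisher_enrichment(sprintf("s%02d", 1:6),
                                      sprintf("s%02d", 1:20),
                                      snp_gene, gg_small)), 0)
})

test_that("uniform foregrounds are not called enriched", {
  set.seed(901)
  genes <- sprintf("g%03d", 1:150)
  snp_gene <- data.frame(snp_id = sprintf("s%03d", 1:150), gene_id = genes)
  gene_go <- do.call(rbind, lapply(sprintf("GO:%02d", 1:12), function(t)
    data.frame(gene_id = sample(genes, 25), go_term = t)))
  hits <- 0
  for (r in 1:40) {
    fg <- sample(snp_gene$snp_id, 20)
    res <- fisher_enrichment(fg, snp_gene$snp_id, snp_gene, gene_go)
    if (nrow(res) && min(res$q) < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 40, 0.10)
})

test_that("essentiality ANOVA: null F, balanced-toy arithmetic, planted shift", {
  # identical group means -> F ~ 0, p ~ 1
  ctx <- mk_ctx(rep("Copia", 12), rep(c("upstream", "downstream"), 6))
  calls <- mk_calls(rep(c("neutral", "balancing", "divergent"), each = 4))
  sg <- data.frame(snp_id = ctx$snp_id, gene_id = sprintf("g%02d", 1:12))
  # every class-by-sense cell holds {2, 4}: identical means, residual
  # spread only
  ess <- data.frame(gene_id = sg$gene_id,
                    family_copy_number = rep(c(2L, 4L, 4L, 2L), 3),
                    ka_ks = 0.5)
  an <- essentiality_anova(ess, calls, ctx, sg, log_transform = FALSE)
  expect_true(all(an$copy_number$F_value[1:3] < 1e-10, na.rm = TRUE))
  expect_true(all(an$copy_number$p[1:3] > 0.999, na.rm = TRUE))
  expect_true(all(an$ka_ks$F_value[1:3] == 0, na.rm = TRUE))  # constant

  # balanced 2x3 with integer responses: F from hand-computed sums of squares
  cls <- rep(rep(c("neutral", "balancing", "divergent"), each = 4), 2)
  sns <- rep(c("upstream", "downstream"), each = 12)
  ctx2 <- mk_ctx(rep("Copia", 24), sns)
  calls2 <- mk_calls(cls)
  sg2 <- data.frame(snp_id = ctx2$snp_id, gene_id = sprintf("g%02d", 1:24))
  y <- c(1, 2, 2, 3,  4, 5, 5, 6,  2, 2, 3, 3,
         2, 3, 3, 4,  6, 7, 7, 8,  3, 3, 4, 4)
  ess2 <- data.frame(gene_id = sg2$gene_id, family_copy_number = 2L,
                     ka_ks = y)
  an2 <- essentiality_anova(ess2, calls2, ctx2, sg2, log_transform = FALSE)
  # oracle: balanced two-way ANOVA sums of squares computed directly
  d <- data.frame(y = y, cls = cls, sns = sns)
  cell <- tapply(d$y, list(d$cls, d$sns), mean)
  gm <- mean(y)
  ss_cls <- 8 * sum((rowMeans(cell) - gm)^2)
  ss_sns <- 12 * sum((colMeans(cell) - gm)^2)
  ss_int <- 4 * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") + gm)^2)
  ss_res <- sum((y - cell[cbind(d$cls, d$sns)])^2)
  f_cls <- (ss_cls / 2) / (ss_res / 18)
  f_sns <- (ss_sns / 1) / (ss_res / 18)
  f_int <- (ss_int / 2) / (ss_res / 18)
  tab <- an2$ka_ks
  expect_equal(tab$F_value[tab$term == "class"], f_cls, tolerance = 1e-10)
  expect_equal(tab$F_value[tab$term == "sense"], f_sns, tolerance = 1e-10)
  expect_equal(tab$F_value[tab$term == "class:sense"], f_int,
               tolerance = 1e-10)

  # planted shift: balancing-downstream single copy vs copy number 3
  set.seed(77)
  n <- 200
  cls3 <- sample(c("neutral", "balancing", "divergent"), n, replace = TRUE)
  sns3 <- sample(c("upstream", "downstream"), n, replace = TRUE)
  ctx3 <- mk_ctx(rep("Copia", n), sns3)
  calls3 <- mk_calls(cls3)
  sg3 <- data.frame(snp_id = ctx3$snp_id, gene_id = sprintf("g%03d", 1:n))
  shifted <- cls3 == "balancing" & sns3 == "downstream"
  ess3 <- data.frame(gene_id = sg3$gene_id,
                     family_copy_number = ifelse(shifted, 1L,
                                                 3L + rpois(n, 1)),
                     ka_ks = 0.4)
  an3 <- essentiality_anova(ess3, calls3, ctx3, sg3)
  expect_lt(min(an3$copy_number$p, na.rm = TRUE), 0.01)
})
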