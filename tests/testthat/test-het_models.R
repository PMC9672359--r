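# Heterozygosity models: cloglog fits against a Newton-Raphson oracle,
# the intercept closed form, Wald CI coverage, observation-table assembly,
# and the Model-0 TE-Effect procedure.

test_that("the intercept-only fit equals the cloglog closed form", {
  obs <- data.frame(snp_id = sprintf("s%d", 1:6), cluster_id = 1L,
                    het_count = c(2L, 5L, 1L, 4L, 3L, 0L), n_samples = 10L)
  fit <- fit_cloglog_binomial(obs, "1")
  pbar <- sum(obs$het_count) / sum(obs$n_samples)
  expect_equal(unname(fit$coefficients$estimate[1]),
               log(-log(1 - pbar)), tolerance = 1e-10)
})

test_that("cloglog coefficients match the Newton-Raphson oracle on fixed data", {
  datasets <- list(
    list(x = c(-1, -0.5, 0, 0.5, 1, 1.5), y = c(1L, 2L, 3L, 5L, 7L, 8L),
         n = rep(10L, 6)),
    list(x = c(0, 0, 1, 1, 2, 2, 3, 3), y = c(0L, 1L, 1L, 2L, 3L, 2L, 5L, 4L),
         n = rep(8L, 8)),
    list(x = c(-2, -1, 0, 1, 2), y = c(9L, 6L, 5L, 3L, 1L),
         n = c(12L, 12L, 12L, 12L, 12L)))
  for (d in datasets) {
    obs <- data.frame(snp_id = seq_along(d$x), cluster_id = 1L,
                      het_count = d$y, n_samples = d$n, x = d$x)
    fit <- fit_cloglog_binomial(obs, "x")
    want <- oracle_cloglog_fit(cbind(1, d$x), d$y, d$n)
    expect_equal(unname(fit$coefficients$estimate), unname(want),
                 tolerance = 1e-6)
  }
})

test_that("Wald 95% intervals cover known coefficients in >= 90% of replicates", {
  set.seed(515)
  b0 <- -1.2; b_down <- 0.5; b_dist <- 0
  hits_down <- 0; hits_dist <- 0
  R <- 200
  for (r in seq_len(R)) {
    nobs <- 60
    down <- rep(c(0, 1), length.out = nobs)
    dist <- runif(nobs, 0, 3)
    eta <- b0 + b_down * down + b_dist * dist
    mu <- 1 - exp(-exp(eta))
    n <- rep(12L, nobs)
    y <- rbinom(nobs, n, mu)
    obs <- data.frame(snp_id = seq_len(nobs), cluster_id = 1L,
                      het_count = y, n_samples = n,
                      down = down, dist = dist)
    fit <- suppressWarnings(fit_cloglog_binomial(obs, "down + dist"))
    cf <- fit$coefficients
    lo <- cf$estimate - 1.96 * cf$se
    hi <- cf$estimate + 1.96 * cf$se
    if (lo[2] <= b_down && b_down <= hi[2]) hits_down <- hits_down + 1
    if (lo[3] <= b_dist && b_dist <= hi[3]) hits_dist <- hits_dist + 1
  }
  expect_gte(hits_down / R, 0.90)
  expect_gte(hits_dist / R, 0.90)
})

test_that("nested models never have lower deviance than their extension", {
  set.seed(99)
  obs <- data.frame(snp_id = 1:40, cluster_id = rep(1:2, 20),
                    het_count = rbinom(40, 10, 0.3), n_samples = 10L,
                    x = rnorm(40), z = rnorm(40))
  f_small <- fit_cloglog_binomial(obs, "x")
  f_big <- fit_cloglog_binomial(obs, "x + z")
  expect_gte(deviance(f_small$fit), deviance(f_big$fit) - 1e-10)
})

sim_ladder_inputs <- function(seed, delta, n_snps = 1200) {
  sc <- simulation_config(seed = seed, n_snps = n_snps, n_pops = 4,
                          n_samples_per_pop = 10,
                          fis_pop = c(0.8, 0.8, 0, 0), delta_te = delta)
  cat_ <- simulate_te_landscape(sc)
  sim <- simulate_genotypes(sc, cat_)
  gtf <- filter_genotypes(sim$genotable)
  fis <- sample_fis(gtf)
  cl <- relatedness_clusters(gtf, K_pcs = 3, n_clusters = 2, seed = seed)
  ctx <- nearest_te(gtf$snps, cat_)
  list(gt = gtf, fis = fis, cl = cl, ctx = ctx, truth = sim$truth)
}

test_that("observation tables have one row per SNP-by-cluster cell", {
  inp <- sim_ladder_inputs(61, 0.6, n_snps = 300)
  obs <- build_observations(inp$gt, inp$ctx, inp$cl, inp$fis)
  n_ctx <- sum(inp$ctx$te_id != "<no_te>")
  expect_equal(nrow(obs), n_ctx * length(unique(inp$cl)))
  expect_true(all(obs$het_count <= obs$n_samples))
  expect_true(all(obs$n_samples > 0))
  # hand-assembled toy: 2 SNPs x 2 clusters
  g <- rbind(c(1, 0), c(1, 2), c(0, 1), c(2, 1))
  gt <- make_gt(g, c("p1", "p1", "p2", "p2"))
  ctx <- data.frame(snp_id = c("s001", "s002"), chrom = "chr1",
                    pos = c(100L, 200L), te_id = "te1", superfamily = "Copia",
                    distance_bp = c(10L, 20L),
                    sense = c("downstream", "upstream"),
                    stringsAsFactors = FALSE)
  cl <- setNames(c(1L, 1L, 2L, 2L), gt$samples$sample_id)
  fis <- data.frame(sample_id = gt$samples$sample_id, fis = c(0.1, 0.2, 0.3, 0.4))
  obs2 <- build_observations(gt, ctx, cl, fis)
  expect_equal(nrow(obs2), 4)
  cell <- obs2[obs2$snp_id == "s001" & obs2$cluster_id == 1, ]
  expect_equal(cell$het_count, 2L)       # samples 1 and 2 heterozygous
  expect_equal(cell$n_samples, 2L)
  expect_equal(cell$mean_fis, 0.15)
  expect_error(build_observations(gt, ctx, cl, fis, samples = rep(FALSE, 4)),
               "empty")
})

test_that("the Model-0 procedure recovers planted TE-Effect superfamilies", {
  inp <- sim_ladder_inputs(62, 0.6)
  ml <- suppressWarnings(model_ladder(inp$gt, inp$ctx, inp$cl, inp$fis))
  expect_true(all(c("Copia", "Harbinger") %in% ml$te_effect_set))
  expect_lt(ml$gate_p, 0.05)
  expect_true(all(c("0a", "0b", "1") %in% names(ml$fits)))
  expect_true(all(c("2a", "2b") %in% names(ml$skipped)))  # no calls given
  # Model 1 carries TE-Effect and sense terms
  expect_true(any(grepl("te_effect_group", ml$fits$`1`$coefficients$term)))
})

test_that("no TE effect is claimed when none is planted", {
  inp <- sim_ladder_inputs(63, 0)
  ml <- suppressWarnings(model_ladder(inp$gt, inp$ctx, inp$cl, inp$fis))
  expect_length(ml$te_effect_set, 0)
  expect_true("2a" %in% names(ml$skipped) || is.null(ml$fits$`2a`))
})

test_that("permuting superfamily labels destroys the TE-Effect signal", {
  recovered <- logical(4)
  for (s in seq_along(recovered)) {
    inp <- sim_ladder_inputs(70 + s, 0.6, n_snps = 800)
    set.seed(1000 + s)
    inp$ctx$superfamily <- sample(inp$ctx$superfamily)
    ml <- suppressWarnings(model_ladder(inp$gt, inp$ctx, inp$cl, inp$fis))
    recovered[s] <- all(c("Copia", "Harbinger") %in% ml$te_effect_set)
  }
  expect_false(any(recovered))
})

test_that("fixed and random cluster intercepts agree on the TE-Effect sign", {
  inp <- sim_ladder_inputs(64, 0.6, n_snps = 600)
  fisv <- inp$fis$fis[match(inp$gt$samples$sample_id, inp$fis$sample_id)]
  obs <- build_observations(inp$gt, inp$ctx, inp$cl, inp$fis,
                            te_effect_set = c("Copia", "Harbinger"),
                            samples = fisv > 0.6)
  fixed <- fit_cloglog_binomial(obs, "te_effect_group + sense")
  random <- fit_cloglog_binomial(obs, "te_effect_group + sense",
                                 cluster_handling = "random")
  cf <- function(f) f$coefficients$estimate[
    grepl("te_effect_groupH_TE", f$coefficients$term)]
  expect_gt(cf(fixed), 0)
  expect_equal(sign(cf(fixed)), sign(cf(random)))
})

test_that("Model 2a picks up the heterozygosity-inbreeding interaction inputs", {
  inp <- sim_ladder_inputs(65, 0.6)
  calls <- data.frame(snp_id = inp$gt$snps$snp_id,
                      class = inp$truth$snps$class[
                        match(inp$gt$snps$snp_id, inp$truth$snps$snp_id)],
                      stringsAsFactors = FALSE)
  calls$class[calls$class == "purifying"] <- "balancing"
  ml <- suppressWarnings(model_ladder(inp$gt, inp$ctx, inp$cl, inp$fis,
                                      calls = calls))
  expect_true(!is.null(ml$fits$`2a`))
  expect_true(!is.null(ml$fits$`2b`))
  expect_true(any(grepl("mean_fis", ml$fits$`2a`$coefficients$term)))
  # europe arm: low-F lineage with the same TE-Effect labels
  eu <- sim_ladder_inputs(66, 0)
  eu_fis <- eu$fis
  eu_fis$fis <- eu_fis$fis - 0.4          # centre the outcrossing gradient
  ml2 <- suppressWarnings(model_ladder(
    inp$gt, inp$ctx, inp$cl, inp$fis, calls = calls,
    europe = list(genotable = eu$gt, contexts = eu$ctx, clusters = eu$cl,
                  fis = eu_fis)))
  expect_true(any(grepl("^3_", names(ml2$fits))) ||
                any(grepl("^3", names(ml2$skipped))))
})
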