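# Synthetic-data module: genotype, TE-annotation, codon-fold, GO and
# essentiality fixtures with the statistical structure the analysis
# assumes, and planted ground truth for recovery tests.
#
# Genotypes are drawn directly from inbreeding-adjusted Hardy-Weinberg
# proportions rather than simulating generations of selfing: for a SNP
# with population allele frequency q and effective inbreeding F,
#   P(het)    = 2 q (1-q) (1 - F)
#   P(homALT) = q^2 + q (1-q) F
# F is the only quantity the downstream analysis consumes, so direct
# draws make the ground truth exact. SNPs downstream of a TE-effect
# superfamily and within `te_reach` bp get F_eff = max(0, F_pop -
# delta_te), the excess-heterozygosity effect mirroring the mutational
# reach of TEs (~3.5 kb). Negative F is clamped to the feasible range
# -min(q,1-q)/max(q,1-q) so all three genotype probabilities stay valid.

#' Simulation configuration
#'
#' Defaults emulate a typical mixed-mating study panel: 13
#' populations x 4 samples spanning a selfing-driven inbreeding gradient,
#' ~2,000 unlinked biallelic SNPs on two chromosomes, a TE landscape of 13
#' superfamilies, and planted neutral / balancing / divergent / purifying
#' loci. `sim_config_europe()` gives the outcrossing-lineage counterpart
#' (18 populations x 2-3 samples, F_IS in -0.64..-0.24).
#'
#' @param n_pops number of populations.
#' @param n_samples_per_pop samples per population (scalar or vector).
#' @param fis_pop per-population inbreeding level in \[-0.6, 0.95\]
#'   (recycled to `n_pops`).
#' @param n_snps number of SNPs.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param te_counts named vector: TEs per superfamily.
#' @param te_length_meanlog,te_length_sdlog log-normal TE length
#'   parameters (bp).
#' @param class_props named proportions for `neutral`, `balancing`,
#'   `divergent`, `purifying` (must sum to 1).
#' @param te_effect_superfamilies superfamilies whose downstream SNPs get
#'   the excess-heterozygosity effect.
#' @param delta_te excess-heterozygosity effect size (>= 0; subtracted
#'   from F_pop within reach).
#' @param te_reach reach of the TE effect in bp (default 3500).
#' @param baseline_af range of the baseline (neutral) ancestral allele
#'   frequency distribution, sampled uniformly.
#' @param neutral_dispersion across-population dispersion (F_ST-like) of
#'   neutral allele frequencies.
#' @param balancing_dispersion dispersion of balancing/purifying loci
#'   (small: low F_ST).
#' @param divergent_sd target across-population frequency SD of divergent
#'   loci (default 0.35).
#' @param purifying_maf_range global MAF range of purifying loci (their
#'   sites are tagged 0-fold).
#' @param fold_props codon-fold proportions for non-purifying SNPs.
#' @param lineage lineage label written into metadata.
#' @param plant_essentiality if TRUE, balancing-downstream genes are
#'   single-copy with low Ka/Ks (for power checks of the essentiality
#'   ANOVA).
#' @param go_enriched_term optional GO term planted at high rate in genes
#'   of `go_enriched_class` SNPs.
#' @param go_enriched_class planted-class carrier of the enriched term
#'   (default `"balancing"`).
#' @param seed integer seed (mandatory).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_pops = 13,
                              n_samples_per_pop = 4,
                              fis_pop = seq(0.9, -0.1, length.out = n_pops),
                              n_snps = 2000,
                              chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                              te_counts = setNames(rep(30L, 13), TE_SUPERFAMILIES),
                              te_length_meanlog = log(1500),
                              te_length_sdlog = 0.5,
                              class_props = c(neutral = 0.80, balancing = 0.08,
                                              divergent = 0.10, purifying = 0.02),
                              te_effect_superfamilies = c("Copia", "Harbinger"),
                              delta_te = 0.6,
                              te_reach = 3500,
                              baseline_af = c(0.1, 0.9),
                              neutral_dispersion = 0.05,
                              balancing_dispersion = 0.002,
                              divergent_sd = 0.35,
                              purifying_maf_range = c(0.05, 0.10),
                              fold_props = c("0-fold" = 0.10, "4-fold" = 0.15,
                                             none = 0.75),
                              lineage = "NorthAmerica",
                              plant_essentiality = FALSE,
                              go_enriched_term = NULL,
                              go_enriched_class = "balancing",
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(class_props) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (delta_te < 0) stop("delta_te must be >= 0")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  n_samples_per_pop <- rep_len(n_samples_per_pop, n_pops)
  fis_pop <- rep_len(fis_pop, n_pops)
  stopifnot(all(fis_pop >= -1), all(fis_pop <= 1))
  structure(list(n_pops = n_pops, n_samples_per_pop = n_samples_per_pop,
                 fis_pop = fis_pop, n_snps = n_snps,
                 chrom_lengths = chrom_lengths, te_counts = te_counts,
                 te_length_meanlog = te_length_meanlog,
                 te_length_sdlog = te_length_sdlog,
                 class_props = class_props,
                 te_effect_superfamilies = te_effect_superfamilies,
                 delta_te = delta_te, te_reach = te_reach,
                 baseline_af = baseline_af,
                 neutral_dispersion = neutral_dispersion,
                 balancing_dispersion = balancing_dispersion,
                 divergent_sd = divergent_sd,
                 purifying_maf_range = purifying_maf_range,
                 fold_props = fold_props, lineage = lineage,
                 plant_essentiality = plant_essentiality,
                 go_enriched_term = go_enriched_term,
                 go_enriched_class = go_enriched_class,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param ... overrides passed to [simulation_config()].
#' @export
sim_config_europe <- function(seed, ...) {
  defaults <- list(n_pops = 18, n_samples_per_pop = rep(c(2L, 3L), 9),
                   fis_pop = seq(-0.64, -0.24, length.out = 18),
                   lineage = "Europe", seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Simulate a TE landscape
#'
#' Places exactly `te_counts[s]` TEs of each superfamily uniformly on the
#' chromosomes (proportional to length), with log-normal lengths and
#' uniform strands. Overlaps are permitted (TE islands). Errors if the
#' expected TE footprint exceeds the genome.
#'
#' @param config a [simulation_config()].
#' @return A [te_catalog()].
#' @export
simulate_te_landscape <- function(config) {
  set.seed(config$seed)
  counts <- config$te_counts
  total <- sum(counts)
  if (total == 0)
    return(te_catalog(character(), character(), integer(), integer(),
                      character(), character()))
  lens <- pmax(100, round(rlnorm(total, config$te_length_meanlog,
                                 config$te_length_sdlog)))
  if (sum(lens) >= sum(config$chrom_lengths))
    stop("infeasible packing: TE footprint exceeds genome length")
  chroms <- sample(names(config$chrom_lengths), total, replace = TRUE,
                   prob = config$chrom_lengths)
  L <- config$chrom_lengths[chroms]
  if (any(lens >= L)) stop("infeasible packing: TE longer than chromosome")
  start <- floor(runif(total, 1, L - lens + 1))
  fam <- rep(names(counts), counts)
  ord <- order(chroms, start)
  te_catalog(sprintf("te_%05d", seq_len(total)),
             chroms[ord], start[ord], start[ord] + lens[ord] - 1,
             sample(c("+", "-"), total, replace = TRUE),
             fam[ord])
}

# independent brute-force nearest-TE annotation used to record ground
# truth (deliberately not the te_proximity query path)
brute_force_nearest <- function(chrom, pos, catalog,
                                sense_mode = "strand") {
  n <- length(pos)
  res <- data.frame(te_id = rep(NO_TE_SENTINEL, n),
                    superfamily = rep(NO_TE_SENTINEL, n),
                    distance_bp = rep(NA_integer_, n),
                    sense = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cand <- which(catalog$chrom == chrom[i])
    if (!length(cand)) next
    d <- ifelse(pos[i] >= catalog$start[cand] & pos[i] <= catalog$end[cand], 0L,
                pmin(abs(pos[i] - catalog$start[cand]),
                     abs(pos[i] - catalog$end[cand])))
    best <- cand[order(d, catalog$start[cand], catalog$te_id[cand])][1]
    dist <- if (pos[i] >= catalog$start[best] && pos[i] <= catalog$end[best]) 0L
            else min(abs(pos[i] - catalog$start[best]),
                     abs(pos[i] - catalog$end[best]))
    after <- pos[i] > catalog$end[best]
    minus <- sense_mode == "strand" && catalog$strand[best] == "-"
    sense <- if (dist == 0) "within"
             else if (xor(after, minus)) "downstream" else "upstream"
    res$te_id[i] <- catalog$te_id[best]
    res$superfamily[i] <- catalog$superfamily[best]
    res$distance_bp[i] <- as.integer(dist)
    res$sense[i] <- sense
  }
  res
}

#' Simulate genotypes with planted selection classes and a TE effect
#'
#' Draws per-population allele frequencies with class-specific
#' across-population dispersion (balancing: intermediate frequency, low
#' dispersion; divergent: high dispersion targeting `divergent_sd`;
#' purifying: low global MAF, tagged 0-fold), then genotypes from
#' inbreeding-adjusted Hardy-Weinberg proportions. SNPs downstream of a
#' TE-effect superfamily within `te_reach` bp get `F_eff = max(0, F_pop -
#' delta_te)`.
#'
#' @param config a [simulation_config()].
#' @param te_catalog a [te_catalog()] (see [simulate_te_landscape()]).
#' @return A list with elements `genotable` (complete-case
#'   `genotype_table`), `truth` (list: `snps` per-SNP planted class /
#'   distance / sense / TE-effect flag / below-filter flag, `pops`
#'   per-population true F, `te_effect_superfamilies`), and `annotations`
#'   (codon-fold, snp-gene, gene-GO and essentiality tables).
#' @export
simulate_genotypes <- function(config, te_catalog) {
  set.seed(config$seed + 1L)
  nsnp <- config$n_snps
  npop <- config$n_pops

  # SNP positions, unique per chromosome, count proportional to length
  alloc <- round(nsnp * config$chrom_lengths / sum(config$chrom_lengths))
  alloc[1] <- nsnp - sum(alloc[-1])
  chrom <- rep(names(config$chrom_lengths), alloc)
  pos <- unlist(lapply(seq_along(alloc), function(k)
    sort(sample.int(config$chrom_lengths[k], alloc[k]))), use.names = FALSE)
  snp_id <- sprintf("snp_%05d", seq_len(nsnp))

  class <- sample(names(config$class_props), nsnp, replace = TRUE,
                  prob = config$class_props)

  ctx <- brute_force_nearest(chrom, pos, te_catalog)
  te_effect <- !is.na(ctx$sense) & ctx$sense == "downstream" &
    ctx$superfamily %in% config$te_effect_superfamilies &
    ctx$distance_bp <= config$te_reach

  # ancestral frequency and across-population dispersion per class
  q0 <- numeric(nsnp)
  disp <- numeric(nsnp)
  i <- class == "neutral"
  q0[i] <- runif(sum(i), config$baseline_af[1], config$baseline_af[2])
  disp[i] <- config$neutral_dispersion
  i <- class == "balancing"
  q0[i] <- runif(sum(i), 0.45, 0.55)
  disp[i] <- config$balancing_dispersion
  i <- class == "divergent"
  q0[i] <- runif(sum(i), 0.3, 0.7)
  disp[i] <- pmin(0.8, config$divergent_sd^2 / (q0[i] * (1 - q0[i])))
  i <- class == "purifying"
  q0[i] <- runif(sum(i), config$purifying_maf_range[1],
                 config$purifying_maf_range[2])
  disp[i] <- config$balancing_dispersion

  # per-population frequencies: beta around q0 with dispersion c
  Q <- matrix(0, nrow = npop, ncol = nsnp)
  for (p in seq_len(npop)) {
    a <- q0 * (1 - disp) / disp
    b <- (1 - q0) * (1 - disp) / disp
    Q[p, ] <- rbeta(nsnp, a, b)
  }
  Q <- pmin(pmax(Q, 1e-6), 1 - 1e-6)

  pops <- sprintf("pop%02d", seq_len(npop))
  nper <- config$n_samples_per_pop
  total_n <- sum(nper)
  G <- matrix(0L, nrow = total_n, ncol = nsnp)
  row0 <- 0
  for (p in seq_len(npop)) {
    q <- Q[p, ]
    f <- ifelse(te_effect, pmax(0, config$fis_pop[p] - config$delta_te),
                config$fis_pop[p])
    f <- pmax(f, -pmin(q, 1 - q) / pmax(q, 1 - q))   # keep HW probs valid
    p2 <- q^2 + q * (1 - q) * f
    p1 <- 2 * q * (1 - q) * (1 - f)
    for (s in seq_len(nper[p])) {
      u <- runif(nsnp)
      G[row0 + s, ] <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
    }
    row0 <- row0 + nper[p]
  }

  samples <- data.frame(
    sample_id = sprintf("%s_s%02d", rep(pops, nper),
                        unlist(lapply(nper, seq_len))),
    population = rep(pops, nper),
    lineage = config$lineage, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  gt <- genotype_table(G, snps, samples)

  realized_af <- colMeans(G) / 2
  realized_maf <- pmin(realized_af, 1 - realized_af)

  # codon-fold annotation: purifying sites are 0-fold by construction
  fold <- sample(names(config$fold_props), nsnp, replace = TRUE,
                 prob = config$fold_props)
  fold[class == "purifying"] <- "0-fold"
  codon_fold <- data.frame(chrom = chrom, pos = as.integer(pos), fold = fold,
                           stringsAsFactors = FALSE)

  ann <- simulate_gene_annotations(config, snp_id, class, ctx)

  truth_snps <- data.frame(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos), class = class,
    te_id = ctx$te_id, superfamily = ctx$superfamily,
    distance_bp = ctx$distance_bp, sense = ctx$sense,
    te_effect = te_effect, ancestral_q = q0,
    below_filter = realized_maf < 0.05, stringsAsFactors = FALSE)
  truth_pops <- data.frame(population = pops, f_pop = config$fis_pop,
                           stringsAsFactors = FALSE)

  list(genotable = gt,
       truth = list(snps = truth_snps, pops = truth_pops,
                    te_effect_superfamilies = config$te_effect_superfamilies),
       annotations = c(list(codon_fold = codon_fold), ann))
}

# gene structure: runs of 1-3 consecutive SNPs share a gene; GO terms per
# gene from a fixed pool, optionally enriching one term in balancing genes
simulate_gene_annotations <- function(config, snp_id, class, ctx) {
  nsnp <- length(snp_id)
  sizes <- sample(1:3, nsnp, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  gene_of <- rep(seq_along(sizes), sizes)[seq_len(nsnp)]
  gene_id <- sprintf("gene_%04d", gene_of)
  snp_gene <- data.frame(snp_id = snp_id, gene_id = gene_id,
                         stringsAsFactors = FALSE)
  genes <- unique(gene_id)
  terms <- sprintf("GO:%07d", seq_len(40))
  gene_go <- do.call(rbind, lapply(genes, function(g) {
    k <- 1 + rpois(1, 1.5)
    data.frame(gene_id = g, go_term = sample(terms, min(k, length(terms))),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(config$go_enriched_term)) {
    bal_genes <- unique(gene_id[class == config$go_enriched_class])
    add <- bal_genes[runif(length(bal_genes)) < 0.8]
    base <- setdiff(genes, bal_genes)
    add_bg <- base[runif(length(base)) < 0.05]
    extra <- data.frame(gene_id = c(add, add_bg),
                        go_term = config$go_enriched_term,
                        stringsAsFactors = FALSE)
    gene_go <- unique(rbind(gene_go, extra))
  }
  gene_go <- gene_go[order(gene_go$gene_id, gene_go$go_term), ]
  rownames(gene_go) <- NULL

  if (config$plant_essentiality) {
    bal_down <- unique(gene_id[class == "balancing" &
                               !is.na(ctx$sense) & ctx$sense == "downstream"])
    is_bd <- genes %in% bal_down
    copy <- ifelse(is_bd, 1L, 3L + rpois(length(genes), 1))
    kaks <- ifelse(is_bd, rlnorm(length(genes), -2.0, 0.3),
                   rlnorm(length(genes), -0.8, 0.3))
  } else {
    copy <- 1L + rpois(length(genes), 2)
    kaks <- rlnorm(length(genes), -1.2, 0.5)
  }
  essentiality <- data.frame(gene_id = genes,
                             family_copy_number = as.integer(copy),
                             ka_ks = round(kaks, 4),
                             stringsAsFactors = FALSE)
  list(snp_gene = snp_gene, gene_go = gene_go,
       gene_essentiality = essentiality)
}

#' Write a simulated dataset to disk as standard formats
#'
#' Emits `genotypes.vcf`, `tes.gff3`, `metadata.tsv`, `codon_fold.tsv`,
#' `snp_gene.tsv`, `gene_go.tsv`, `gene_essentiality.tsv` and `truth.tsv`
#' into `dir`. Re-reading through the IO module reproduces the in-memory
#' objects; identical seeds give byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param genotable a `genotype_table`.
#' @param catalog a [te_catalog()].
#' @param truth the `truth` element of [simulate_genotypes()] output.
#' @param annotations the `annotations` element of [simulate_genotypes()]
#'   output (optional).
#' @return Invisibly, the named vector of paths written.
#' @export
emit_fixture <- function(dir, genotable, catalog, truth = NULL,
                         annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             gff = file.path(dir, "tes.gff3"),
             metadata = file.path(dir, "metadata.tsv"))
  write_genotypes_vcf(genotable, paths["vcf"])
  write_te_gff3(catalog, paths["gff"])
  md <- genotable$samples
  names(md)[names(md) == "sample_id"] <- "sample"
  write_output_tsv(md, paths["metadata"])
  if (!is.null(annotations)) {
    for (nm in names(annotations)) {
      paths[nm] <- file.path(dir, paste0(nm, ".tsv"))
      write_output_tsv(annotations[[nm]], paths[nm])
    }
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    write_output_tsv(truth$snps, paths["truth"])
    paths["truth_pops"] <- file.path(dir, "truth_pops.tsv")
    write_output_tsv(truth$pops, paths["truth_pops"])
  }
  invisible(paths)
}

#' Write a genotype table as a minimal VCF 4.2
#'
#' All records are biallelic A/T SNPs with unphased diploid GT fields.
#'
#' @param genotable a `genotype_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotable, path) {
  g <- genotable$genotypes
  gtchr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gtchr[is.na(g)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=tehet",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotable$samples$sample_id),
                    collapse = "\t"))
  body <- apply(cbind(genotable$snps$chrom, genotable$snps$pos,
                      genotable$snps$snp_id, "A", "T", ".", "PASS", ".",
                      "GT", t(gtchr)),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a TE catalog as GFF3
#'
#' @param catalog a [te_catalog()].
#' @param path output path.
#' @param superfamily_key attribute name for the superfamily (default
#'   `"superfamily"`).
#' @return Invisibly, `path`.
#' @export
write_te_gff3 <- function(catalog, path, superfamily_key = "superfamily") {
  strand <- ifelse(catalog$strand %in% c("+", "-"), catalog$strand, ".")
  lines <- sprintf("%s\ttehet\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=%s;%s=%s",
                   catalog$chrom, catalog$start, catalog$end, strand,
                   catalog$te_id, superfamily_key, catalog$superfamily)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
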