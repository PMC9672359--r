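# Cross-lineage comparison of per-superfamily outlier proportions, GO
# enrichment (Fisher's exact, classic per-term semantics) and
# gene-essentiality analysis of variance.

#' Per-superfamily outlier proportions by sense stratum
#'
#' For each TE superfamily and sense stratum (upstream / downstream), the
#' proportion of SNPs called balancing and divergent. Strata with no SNPs
#' are omitted; strata with fewer than `min_n` SNPs are flagged
#' low-confidence.
#'
#' @param contexts nearest-TE contexts ([nearest_te()]).
#' @param calls selection calls ([classify_selection()]).
#' @param min_n minimum stratum size for full confidence (default 5).
#' @return data.frame: `superfamily`, `sense`, `n_snps`,
#'   `prop_balancing`, `prop_divergent`, `low_confidence`.
#' @export
outlier_profiles <- function(contexts, calls, min_n = 5) {
  m <- merge(contexts[, c("snp_id", "superfamily", "sense")],
             calls[, c("snp_id", "class")], by = "snp_id")
  m <- m[!is.na(m$sense) & m$sense %in% c("upstream", "downstream") &
           m$superfamily != NO_TE_SENTINEL, ]
  if (nrow(m) == 0)
    return(data.frame(superfamily = character(), sense = character(),
                      n_snps = integer(), prop_balancing = numeric(),
                      prop_divergent = numeric(),
                      low_confidence = logical()))
  key <- interaction(m$superfamily, m$sense, drop = TRUE)
  agg <- do.call(rbind, lapply(split(m, key), function(d) data.frame(
    superfamily = d$superfamily[1], sense = d$sense[1],
    n_snps = nrow(d),
    prop_balancing = mean(d$class == "balancing"),
    prop_divergent = mean(d$class == "divergent"),
    stringsAsFactors = FALSE)))
  agg$low_confidence <- agg$n_snps < min_n
  agg <- agg[order(agg$superfamily, agg$sense), ]
  rownames(agg) <- NULL
  agg
}

#' Cross-lineage correlation of per-superfamily outlier proportions
#'
#' Pearson correlation, per sense stratum and selection type, of
#' superfamily-matched outlier proportions between two lineages.
#' Symmetric in the lineages and invariant to superfamily order.
#'
#' @param profiles_a,profiles_b outputs of [outlier_profiles()] for the
#'   two lineages.
#' @return data.frame: `sense`, `type`, `n_superfamilies`, `r`, `p`.
#' @export
cross_lineage_correlation <- function(profiles_a, profiles_b) {
  m <- merge(profiles_a, profiles_b, by = c("superfamily", "sense"),
             suffixes = c("_a", "_b"))
  out <- NULL
  for (s in unique(m$sense)) {
    for (type in c("balancing", "divergent")) {
      col <- paste0("prop_", type)
      d <- m[m$sense == s, ]
      if (nrow(d) < 3) next
      ct <- suppressWarnings(
        cor.test(d[[paste0(col, "_a")]], d[[paste0(col, "_b")]],
                 method = "pearson"))
      out <- rbind(out, data.frame(sense = s, type = type,
                                   n_superfamilies = nrow(d),
                                   r = unname(ct$estimate),
                                   p = ct$p.value,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Count SNPs sharing a selection signature between two lineages
#'
#' SNPs are matched by chromosome and position.
#'
#' @param calls_a,calls_b selection calls for the two lineages.
#' @param snps_a,snps_b SNP coordinate tables (`snp_id`, `chrom`, `pos`).
#' @return data.frame with shared balancing and divergent counts.
#' @export
shared_outlier_counts <- function(calls_a, calls_b, snps_a, snps_b) {
  key_a <- paste(snps_a$chrom, snps_a$pos)[match(calls_a$snp_id, snps_a$snp_id)]
  key_b <- paste(snps_b$chrom, snps_b$pos)[match(calls_b$snp_id, snps_b$snp_id)]
  shared <- function(type) {
    sum(key_a[calls_a$class == type] %in% key_b[calls_b$class == type])
  }
  data.frame(type = c("balancing", "divergent"),
             n_shared = c(shared("balancing"), shared("divergent")),
             stringsAsFactors = FALSE)
}

# one-sided hypergeometric overrepresentation p-value:
# P(X >= a) with a of K annotated among m drawn from N containing K
hyper_test_p <- function(a, m, K, N) {
  phyper(a - 1, K, N - K, m, lower.tail = FALSE)
}

#' GO-term enrichment by Fisher's exact test
#'
#' Classic per-term semantics: each term is tested independently for
#' overrepresentation in the foreground against the background universe
#' with a one-sided hypergeometric test, followed by Benjamini-Hochberg
#' correction. Testing is at gene level: SNPs are deduplicated to genes
#' first, so duplicate SNPs in a gene cannot pseudo-replicate. Terms with
#' fewer than 2 foreground genes are skipped. With `unit = "snp"`, SNPs
#' are the test unit instead.
#'
#' @param foreground_snps character vector of foreground SNP ids.
#' @param background_snps character vector of background (universe) SNP
#'   ids; the foreground is included in the universe.
#' @param snp_gene SNP-to-gene map (`snp_id`, `gene_id`).
#' @param gene_go gene-to-GO map (`gene_id`, `go_term`, pre-propagated).
#' @param unit `"gene"` (default) or `"snp"`.
#' @return data.frame per term: counts, odds ratio, one-sided `p`, BH `q`.
#' @export
fisher_enrichment <- function(foreground_snps, background_snps, snp_gene,
                              gene_go, unit = c("gene", "snp")) {
  unit <- match.arg(unit)
  universe_snps <- union(background_snps, foreground_snps)
  if (unit == "gene") {
    fg <- unique(snp_gene$gene_id[snp_gene$snp_id %in% foreground_snps])
    bg <- unique(snp_gene$gene_id[snp_gene$snp_id %in% universe_snps])
    ann <- split(gene_go$go_term, gene_go$gene_id)
    members <- function(term, set)
      sum(vapply(ann[set], function(tt) term %in% tt, logical(1)), na.rm = TRUE)
  } else {
    fg <- unique(intersect(foreground_snps, snp_gene$snp_id))
    bg <- unique(intersect(universe_snps, snp_gene$snp_id))
    s2t <- merge(snp_gene, gene_go, by = "gene_id")
    ann <- split(s2t$go_term, s2t$snp_id)
    members <- function(term, set)
      sum(vapply(ann[set], function(tt) term %in% tt, logical(1)), na.rm = TRUE)
  }
  bg <- union(bg, fg)
  terms <- sort(unique(gene_go$go_term))
  rows <- lapply(terms, function(term) {
    a <- members(term, fg)
    if (a < 2) return(NULL)
    K <- members(term, bg)
    m <- length(fg); N <- length(bg)
    orr <- (a / max(m - a, 0.5)) / (max(K - a, 0.5) / max(N - K - (m - a), 0.5))
    data.frame(term = term, fg_with_term = a, fg_size = m,
               bg_with_term = K, bg_size = N, odds_ratio = orr,
               p = hyper_test_p(a, m, K, N), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), fg_with_term = integer(),
                      fg_size = integer(), bg_with_term = integer(),
                      bg_size = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric()))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Gene-essentiality analysis of variance
#'
#' Tests whether gene-family copy number and Ka/Ks differ between
#' selection signatures (balancing / divergent / neutral) and orientation
#' relative to the nearest TE (upstream / downstream), by type-II two-way
#' ANOVA with interaction. Both responses are log1p-transformed by default
#' for variance stabilization. SNPs are deduplicated to genes; a gene's
#' selection class is the highest-priority class among its SNPs
#' (balancing > divergent > neutral) and its sense the first annotated.
#'
#' @param gene_essentiality table (`gene_id`, `family_copy_number`,
#'   `ka_ks`).
#' @param calls selection calls ([classify_selection()]).
#' @param contexts nearest-TE contexts ([nearest_te()]).
#' @param snp_gene SNP-to-gene map.
#' @param log_transform log1p-transform the responses (default TRUE).
#' @return list with `copy_number` and `ka_ks` ANOVA tables (term,
#'   sum_sq, df, F, p), plus `data` (the gene-level table).
#' @export
essentiality_anova <- function(gene_essentiality, calls, contexts, snp_gene,
                               log_transform = TRUE) {
  d <- merge(snp_gene, calls[, c("snp_id", "class")], by = "snp_id")
  d <- merge(d, contexts[, c("snp_id", "sense")], by = "snp_id")
  d <- d[!is.na(d$sense) & d$sense %in% c("upstream", "downstream"), ]
  prio <- c(balancing = 1, divergent = 2, neutral = 3)
  d <- d[order(d$gene_id, prio[d$class]), ]
  genes <- d[!duplicated(d$gene_id), c("gene_id", "class", "sense")]
  genes <- merge(genes, gene_essentiality, by = "gene_id")
  if (nrow(genes) < 6) stop("too few annotated genes for ANOVA")
  genes$class <- factor(genes$class, levels = c("neutral", "balancing",
                                                "divergent"))
  genes$sense <- factor(genes$sense, levels = c("upstream", "downstream"))
  resp <- function(x) if (log_transform) log1p(x) else x
  tab <- function(y) {
    terms <- c("class", "sense", "class:sense", "Residuals")
    if (var(y) < .Machine$double.eps) {
      # constant response: nothing to explain
      return(data.frame(term = terms, sum_sq = 0,
                        df = c(2, 1, 2, length(y) - 6),
                        F_value = c(0, 0, 0, NA), p = c(1, 1, 1, NA),
                        stringsAsFactors = FALSE))
    }
    fit <- lm(y ~ class * sense, data = genes)
    a <- car::Anova(fit, type = "II")
    data.frame(term = rownames(a), sum_sq = a[, "Sum Sq"], df = a[, "Df"],
               F_value = a[, "F value"], p = a[, "Pr(>F)"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(copy_number = tab(resp(genes$family_copy_number)),
       ka_ks = tab(resp(genes$ka_ks)),
       data = genes)
}
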