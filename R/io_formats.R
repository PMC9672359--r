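# IO module: genotype / TE-annotation / metadata readers and writers,
# plus the MAF + missingness filter applied to every loaded genotype table.
# All coordinates are 1-based inclusive, as on disk in VCF and GFF3; no
# internal conversion is ever performed.

#' Construct a genotype table
#'
#' Container for biallelic SNP genotypes with sample metadata. Genotypes
#' count copies of the alternate allele (0, 1, 2; `NA` = missing).
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param samples data.frame with columns `sample_id`, `population`,
#'   `lineage`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(genotypes, snps, samples) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(snps), is.data.frame(samples))
  req_snp <- c("snp_id", "chrom", "pos")
  req_sam <- c("sample_id", "population", "lineage")
  if (!all(req_snp %in% names(snps)))
    stop("snps must have columns: ", paste(req_snp, collapse = ", "))
  if (!all(req_sam %in% names(samples)))
    stop("samples must have columns: ", paste(req_sam, collapse = ", "))
  if (nrow(genotypes) != nrow(samples) || ncol(genotypes) != nrow(snps))
    stop("genotype matrix dimensions must be samples x SNPs")
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  if (anyNA(samples$population) || anyNA(samples$lineage))
    stop("every sample needs a population and lineage label")
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- snps$snp_id
  structure(list(genotypes = genotypes,
                 snps = as.data.frame(snps, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d SNPs, %d populations, %d lineage(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$samples$population)),
              length(unique(x$samples$lineage))))
  fr <- attr(x, "filter_report")
  if (!is.null(fr))
    cat(sprintf("  filter: %d input, %d retained, %d dropped (MAF), %d dropped (missingness), %d skipped (multiallelic)\n",
                fr$input, fr$retained, fr$dropped_maf, fr$dropped_missing,
                fr$skipped_multiallelic))
  invisible(x)
}

#' Number of samples / SNPs in a genotype table
#' @param gt a `genotype_table`.
#' @return integer count.
#' @export
n_samples <- function(gt) nrow(gt$genotypes)

#' @rdname n_samples
#' @export
n_snps <- function(gt) ncol(gt$genotypes)

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param samples logical/integer/character index into samples (optional).
#' @param snps logical/integer/character index into SNPs (optional).
#' @return A `genotype_table` restricted to the selection.
#' @export
subset_genotypes <- function(gt, samples = NULL, snps = NULL) {
  gmat <- gt$genotypes
  sam <- gt$samples
  snp <- gt$snps
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, sam$sample_id) else samples
    gmat <- gmat[idx, , drop = FALSE]
    sam <- sam[idx, , drop = FALSE]
  }
  if (!is.null(snps)) {
    jdx <- if (is.character(snps)) match(snps, snp$snp_id) else snps
    gmat <- gmat[, jdx, drop = FALSE]
    snp <- snp[jdx, , drop = FALSE]
  }
  genotype_table(gmat, droplevels(snp), droplevels(sam))
}

#' Global minor allele frequency per SNP
#'
#' Pooled over all samples (lineage-wide), as in the upstream SNP filtering.
#'
#' @param gt a `genotype_table`.
#' @return numeric vector of minor allele frequencies, one per SNP.
#' @export
global_maf <- function(gt) {
  af <- colMeans(gt$genotypes, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Filter a genotype table on missingness and minor allele frequency
#'
#' SNPs with any missing genotype are dropped first, then SNPs with global
#' minor allele frequency below `maf_min`. Counts are recorded in a filter
#' report (attribute `filter_report`); retained + dropped always equals the
#' input SNP count.
#'
#' @param gt a `genotype_table`.
#' @param maf_min minimum global minor allele frequency (default 0.05).
#' @param skipped_multiallelic count of multi-allelic records skipped at
#'   parse time, carried into the report.
#' @return Filtered `genotype_table` with a `filter_report` attribute.
#' @export
filter_genotypes <- function(gt, maf_min = 0.05, skipped_multiallelic = 0L) {
  input <- n_snps(gt)
  miss <- colSums(is.na(gt$genotypes)) > 0
  gt2 <- if (any(miss)) subset_genotypes(gt, snps = !miss) else gt
  maf <- global_maf(gt2)
  low <- maf < maf_min
  out <- if (any(low)) subset_genotypes(gt2, snps = !low) else gt2
  attr(out, "filter_report") <- list(
    input = input,
    retained = n_snps(out),
    dropped_missing = sum(miss),
    dropped_maf = sum(low),
    skipped_multiallelic = as.integer(skipped_multiallelic))
  out
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `population`, `lineage` (a header
#'   row is required; `sample_id` is accepted for `sample`).
#' @return data.frame with columns `sample_id`, `population`, `lineage`.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if ("sample" %in% names(md)) names(md)[names(md) == "sample"] <- "sample_id"
  req <- c("sample_id", "population", "lineage")
  if (!all(req %in% names(md)))
    stop("metadata must have columns sample, population, lineage")
  md[, req]
}

#' Read biallelic SNP genotypes from VCF or a genotype-matrix TSV
#'
#' Loads genotypes, attaches sample metadata, and applies the standard
#' quality filter: SNPs with any missing genotype or global minor allele
#' frequency below `maf_min` are dropped and counted in the filter report.
#' Multi-allelic VCF records are skipped with a warning.
#'
#' @param vcf_or_table path to a VCF 4.x file or a TSV genotype matrix
#'   (columns `snp_id`, `chrom`, `pos`, then one column per sample holding
#'   0/1/2 alternate-allele counts; `NA` = missing).
#' @param metadata_table path to the metadata TSV (see
#'   [read_sample_metadata()]) or an equivalent data.frame.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @param maf_min minimum global minor allele frequency (default 0.05).
#' @return A filtered `genotype_table` with a `filter_report` attribute.
#' @export
read_genotypes <- function(vcf_or_table, metadata_table,
                           format = c("auto", "vcf", "matrix"),
                           maf_min = 0.05) {
  format <- match.arg(format)
  if (!file.exists(vcf_or_table)) stop("no such file: ", vcf_or_table)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", vcf_or_table)) "vcf" else "matrix"
  md <- if (is.character(metadata_table)) read_sample_metadata(metadata_table)
        else {
          m <- as.data.frame(metadata_table)
          if ("sample" %in% names(m)) names(m)[names(m) == "sample"] <- "sample_id"
          m
        }
  parsed <- if (format == "vcf") parse_vcf_genotypes(vcf_or_table)
            else parse_matrix_genotypes(vcf_or_table)
  missing_md <- setdiff(parsed$sample_ids, md$sample_id)
  if (length(missing_md))
    stop("samples absent from metadata: ", paste(missing_md, collapse = ", "))
  samples <- md[match(parsed$sample_ids, md$sample_id), ]
  gt <- genotype_table(parsed$genotypes, parsed$snps, samples)
  filter_genotypes(gt, maf_min = maf_min,
                   skipped_multiallelic = parsed$skipped_multiallelic)
}

# VCF parsing (vcfR); biallelic records only, others skipped with a warning
parse_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  nskip <- sum(multi)
  if (nskip > 0)
    warning(nskip, " multi-allelic or ALT-less record(s) skipped")
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_chr))) gt_chr <- matrix(gt_chr, nrow = nrow(fix))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt_chr <- gt_chr[keep, , drop = FALSE]
  alleles <- gsub("[|/]", "", gt_chr)
  g <- matrix(NA_integer_, nrow = nrow(alleles), ncol = ncol(alleles))
  ok <- !is.na(alleles) & alleles %in% c("00", "01", "10", "11")
  g[ok] <- vapply(strsplit(alleles[ok], ""),
                  function(a) sum(a == "1"), integer(1))
  ids <- fix$ID
  if (is.null(ids)) ids <- rep(NA_character_, nrow(fix))
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  list(genotypes = t(g),
       snps = data.frame(snp_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         stringsAsFactors = FALSE),
       sample_ids = colnames(gt_chr),
       skipped_multiallelic = nskip)
}

parse_matrix_genotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("snp_id", "chrom", "pos")
  if (!all(req %in% names(tab)))
    stop("genotype matrix needs columns snp_id, chrom, pos")
  sample_cols <- setdiff(names(tab), req)
  g <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(g) <- "integer"
  list(genotypes = t(g),
       snps = tab[, req],
       sample_ids = sample_cols,
       skipped_multiallelic = 0L)
}

#' Construct a TE catalog
#'
#' @param te_id,chrom,start,end,strand,superfamily vectors of equal length;
#'   coordinates are 1-based inclusive, `strand` one of `"+"`, `"-"`,
#'   `"unknown"`.
#' @return data.frame of class `te_catalog`.
#' @export
te_catalog <- function(te_id, chrom, start, end, strand, superfamily) {
  strand <- as.character(strand)
  strand[!strand %in% c("+", "-")] <- "unknown"
  cat <- data.frame(te_id = as.character(te_id), chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = strand, superfamily = as.character(superfamily),
                    stringsAsFactors = FALSE)
  if (nrow(cat)) {
    if (any(cat$start > cat$end)) stop("TE intervals must have start <= end")
    if (any(is.na(cat$superfamily) | cat$superfamily == ""))
      stop("superfamily labels must be non-empty")
  }
  class(cat) <- c("te_catalog", "data.frame")
  cat
}

#' Read a TE annotation from GFF3
#'
#' Every record becomes one TE; overlapping records are retained (TE
#' islands). The superfamily is taken from the attribute named
#' `superfamily_key`; records without it get `"Unknown"`. Strand `.`/`?`
#' maps to `"unknown"`.
#'
#' @param gff3_path path to a GFF3 file.
#' @param superfamily_key name of the attribute carrying the superfamily
#'   (default `"superfamily"`; the annotation dialect varies).
#' @return A `te_catalog`.
#' @export
read_te_gff <- function(gff3_path, superfamily_key = "superfamily") {
  if (!file.exists(gff3_path)) stop("no such file: ", gff3_path)
  lines <- readLines(gff3_path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    stop("malformed GFF3 line ", bad, ": expected 9 tab-separated fields")
  }
  if (!any(body))
    return(te_catalog(character(), character(), integer(), integer(),
                      character(), character()))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  fam <- if (superfamily_key %in% names(mc)) as.character(mc[[superfamily_key]])
         else rep(NA_character_, length(gr))
  fam[is.na(fam) | fam == ""] <- "Unknown"
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("te_", seq_along(gr))[is.na(ids)]
  strand <- as.character(BiocGenerics::strand(gr))
  te_catalog(ids, as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr), BiocGenerics::end(gr), strand, fam)
}

#' Read per-site codon-fold annotation
#'
#' @param path TSV with columns `chrom`, `pos`, `fold` (values `0-fold`,
#'   `4-fold` or `none`).
#' @return data.frame with those columns.
#' @export
read_codon_fold <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "fold")
  if (!all(req %in% names(tab))) stop("codon-fold table needs chrom, pos, fold")
  if (!all(tab$fold %in% c("0-fold", "4-fold", "none")))
    stop("fold must be one of 0-fold, 4-fold, none")
  tab[, req]
}

#' Read SNP-to-gene and gene-to-GO mapping tables
#'
#' @param path TSV. For SNP-to-gene: columns `snp_id`, `gene_id`. For
#'   gene-to-GO: columns `gene_id`, `go_term` (one row per pair,
#'   pre-propagated).
#' @return data.frame.
#' @export
read_snp_gene_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(tab)))
    stop("snp-gene map needs snp_id, gene_id")
  tab[, c("snp_id", "gene_id")]
}

#' @rdname read_snp_gene_map
#' @export
read_gene_go_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_term") %in% names(tab)))
    stop("gene-GO map needs gene_id, go_term")
  tab[, c("gene_id", "go_term")]
}

#' Read gene-essentiality proxies
#'
#' @param path TSV with columns `gene_id`, `family_copy_number` (positive
#'   integer) and `ka_ks` (non-negative).
#' @return data.frame.
#' @export
read_gene_essentiality <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("gene_id", "family_copy_number", "ka_ks")
  if (!all(req %in% names(tab)))
    stop("essentiality table needs gene_id, family_copy_number, ka_ks")
  if (any(tab$family_copy_number < 1)) stop("family_copy_number must be >= 1")
  if (any(tab$ka_ks < 0)) stop("ka_ks must be >= 0")
  tab[, req]
}

#' Write / read pipeline output tables (exact round trip)
#'
#' Tab-separated, header row, no quoting or row names; `read_output_tsv`
#' re-reads what `write_output_tsv` wrote, reproducing the data.frame.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_output_tsv` returns the data.frame.
#' @export
write_output_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_output_tsv
#' @export
read_output_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects the analysis thresholds and settings. Defaults are the
#' pipeline's standard constants: F_IS splits at 0.6 (inbred vs outcrossed) and -0.3 (the
#' outcrossing-lineage contrast), outlier q-value 0.01, log10 posterior
#' odds 0.5, Bayesian FDR 0.05, K = 3 principal components.
#'
#' @param fis_split_inbred F_IS threshold separating predominantly selfing
#'   samples (default 0.6).
#' @param fis_split_outcross F_IS threshold splitting the outcrossing
#'   lineage (default -0.3).
#' @param q_threshold q-value cutoff for the PCA scan (default 0.01).
#' @param log10_po_threshold log10 posterior-odds cutoff (default 0.5).
#' @param fdr Bayesian false discovery rate (default 0.05).
#' @param n_pcs number of principal components (default 3).
#' @param n_clusters relatedness cluster count (default 7, the European
#'   panel structure; use 6 for the North American panel).
#' @param sense_mode `"strand"` (TE-strand-aware) or `"genomic"`.
#' @param mcmc_settings see [mcmc_settings()].
#' @param seed integer seed recorded in all outputs.
#' @param maf_min minimum global minor allele frequency (default 0.05).
#' @param superfamily_key GFF3 attribute holding the superfamily.
#' @param paths named list of input file paths (vcf, metadata, te_gff, and
#'   optionally codon_fold, snp_gene, gene_go, essentiality).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fis_split_inbred = 0.6,
                            fis_split_outcross = -0.3,
                            q_threshold = 0.01,
                            log10_po_threshold = 0.5,
                            fdr = 0.05,
                            n_pcs = 3,
                            n_clusters = 7,
                            sense_mode = c("strand", "genomic"),
                            mcmc_settings = tehet::mcmc_settings(),
                            seed = 1L,
                            maf_min = 0.05,
                            superfamily_key = "superfamily",
                            paths = list()) {
  sense_mode <- match.arg(sense_mode)
  stopifnot(q_threshold > 0, q_threshold < 1, fdr > 0, fdr < 1,
            n_pcs >= 1, n_clusters >= 1,
            fis_split_inbred >= -1, fis_split_inbred <= 1,
            fis_split_outcross >= -1, fis_split_outcross <= 1,
            maf_min >= 0, maf_min < 0.5)
  structure(list(fis_split_inbred = fis_split_inbred,
                 fis_split_outcross = fis_split_outcross,
                 q_threshold = q_threshold,
                 log10_po_threshold = log10_po_threshold,
                 fdr = fdr, n_pcs = n_pcs, n_clusters = n_clusters,
                 sense_mode = sense_mode, mcmc_settings = mcmc_settings,
                 seed = as.integer(seed), maf_min = maf_min,
                 superfamily_key = superfamily_key, paths = paths),
            class = "pipeline_config")
}
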