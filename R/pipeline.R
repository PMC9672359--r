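# End-to-end pipeline driver: runs every stage on one lineage's inputs and
# writes tab-separated result tables plus a machine-readable run log.

#' Run the full analysis pipeline
#'
#' Loads genotypes, metadata and the TE annotation named in
#' `config$paths`, then runs nearest-TE annotation, population-genetic
#' statistics, both selection scans, the heterozygosity model ladder and
#' the outlier profiles, writing each result as a TSV into `out_dir`
#' together with `run_log.json` (seed, package and R versions, stage
#' status, filter report). Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()]; `config$paths` must name `vcf`
#'   (or `matrix`), `metadata` and `te_gff`, and may name `codon_fold`,
#'   `snp_gene`, `gene_go`, `essentiality`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list(seed = config$seed,
              package_version = as.character(packageVersion("tehet")),
              r_version = R.version.string,
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = list())
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log$stages[[name]] <<- "ok"
    out
  }

  res$genotable <- stage("load", {
    p <- config$paths
    geno_path <- if (!is.null(p$vcf)) p$vcf else p$matrix
    if (is.null(geno_path) || is.null(p$metadata))
      stop("config$paths must provide vcf (or matrix) and metadata")
    read_genotypes(geno_path, p$metadata, maf_min = config$maf_min)
  })
  log$filter_report <- attr(res$genotable, "filter_report")
  res$catalog <- stage("load_te", {
    if (is.null(config$paths$te_gff)) stop("config$paths$te_gff missing")
    read_te_gff(config$paths$te_gff, config$superfamily_key)
  })

  res$te_context <- stage("annotate_te", {
    ann <- annotate_te_context(res$genotable, res$catalog,
                               sense_mode = config$sense_mode)
    write_output_tsv(ann$contexts, file.path(out_dir, "snp_te_context.tsv"))
    write_output_tsv(ann$summary, file.path(out_dir, "te_summary.tsv"))
    ann
  })

  res$popgen <- stage("popgen", {
    fis <- sample_fis(res$genotable)
    clusters <- relatedness_clusters(res$genotable, K_pcs = config$n_pcs,
                                     n_clusters = config$n_clusters,
                                     seed = config$seed)
    ls <- locus_stats(res$genotable, clusters)
    write_output_tsv(fis, file.path(out_dir, "sample_fis.tsv"))
    write_output_tsv(ls$stats, file.path(out_dir, "locus_stats.tsv"))
    write_output_tsv(ls$het_by_cluster,
                     file.path(out_dir, "het_by_cluster.tsv"))
    list(fis = fis, clusters = clusters, locus = ls)
  })

  res$scan <- stage("scan", {
    pca <- pca_scan(res$genotable, K = config$n_pcs)
    mc <- fst_decomposition_mcmc(res$genotable, config$mcmc_settings,
                                 config$log10_po_threshold, config$fdr)
    calls <- classify_selection(pca, mc, res$popgen$locus$stats,
                                q_threshold = config$q_threshold)
    fold <- NULL
    if (!is.null(config$paths$codon_fold))
      fold <- read_codon_fold(config$paths$codon_fold)
    calls <- if (!is.null(fold))
      purifying_rule(calls, res$popgen$locus$stats, fold,
                     snps = res$genotable$snps)
    else calls
    write_output_tsv(calls, file.path(out_dir, "selection_calls.tsv"))
    write_output_tsv(mc$beta, file.path(out_dir, "mcmc_populations.tsv"))
    list(pca = pca, mcmc = mc, calls = calls)
  })

  res$models <- stage("models", {
    ml <- model_ladder(res$genotable, res$te_context$contexts,
                       res$popgen$clusters, res$popgen$fis,
                       calls = res$scan$calls,
                       fis_split = config$fis_split_inbred,
                       fis_split_europe = config$fis_split_outcross)
    for (nm in names(ml$fits))
      write_output_tsv(ml$fits[[nm]]$coefficients,
                       file.path(out_dir, paste0("model_", nm, "_coefficients.tsv")))
    anodev <- do.call(rbind, lapply(names(ml$fits), function(nm) {
      a <- ml$fits[[nm]]$anodev
      if (is.null(a)) return(NULL)
      cbind(model = nm, a)
    }))
    if (!is.null(anodev))
      write_output_tsv(anodev, file.path(out_dir, "model_anodev.tsv"))
    write_output_tsv(
      data.frame(superfamily = sort(unique(res$te_context$contexts$superfamily)),
                 te_effect = sort(unique(res$te_context$contexts$superfamily)) %in%
                   ml$te_effect_set),
      file.path(out_dir, "te_effect_membership.tsv"))
    ml
  })

  res$profiles <- stage("profiles", {
    pr <- outlier_profiles(res$te_context$contexts, res$scan$calls)
    write_output_tsv(pr, file.path(out_dir, "outlier_profiles.tsv"))
    pr
  })

  if (!is.null(config$paths$snp_gene) && !is.null(config$paths$gene_go)) {
    res$enrichment <- stage("enrichment", {
      sg <- read_snp_gene_map(config$paths$snp_gene)
      gg <- read_gene_go_map(config$paths$gene_go)
      fg <- res$scan$calls$snp_id[res$scan$calls$class == "balancing"]
      bg <- res$scan$calls$snp_id
      enr <- fisher_enrichment(fg, bg, sg, gg)
      write_output_tsv(enr, file.path(out_dir, "enrichment_balancing.tsv"))
      enr
    })
    if (!is.null(config$paths$essentiality)) {
      res$essentiality <- stage("essentiality", {
        ess <- read_gene_essentiality(config$paths$essentiality)
        sg <- read_snp_gene_map(config$paths$snp_gene)
        an <- essentiality_anova(ess, res$scan$calls,
                                 res$te_context$contexts, sg)
        write_output_tsv(an$copy_number,
                         file.path(out_dir, "essentiality_copy_number_anova.tsv"))
        write_output_tsv(an$ka_ks,
                         file.path(out_dir, "essentiality_kaks_anova.tsv"))
        an
      })
    }
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(res)
}
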