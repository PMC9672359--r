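# Nearest-TE annotation: distance, orientation (sense) and superfamily of
# the TE closest to each SNP.
#
# Distance convention: 0 means the SNP lies within the TE (start <= pos <=
# end); otherwise the edge-to-position gap in bp, so a base adjacent to a
# TE edge is at distance 1. Ties are broken by lowest TE start, then
# lexicographic te_id, for determinism.
#
# Sense convention (default, TE-strand-aware): relative to the TE's own
# orientation — for a "+" TE, positions beyond `end` are downstream and
# before `start` upstream; for a "-" TE the reverse; TEs of unknown strand
# fall back to genomic forward orientation. `sense_mode = "genomic"`
# applies the forward convention to every TE.

#' Annotate SNPs with their nearest TE
#'
#' For every SNP, finds the nearest TE on the same chromosome and reports
#' its identity, superfamily, distance in bp and the SNP's orientation
#' relative to it (`within`, `upstream`, `downstream`). SNPs on
#' chromosomes without any TE receive a sentinel context (`te_id`
#' `"<no_te>"`, `NA` distance and sense) and are excluded from
#' TE-conditioned models downstream.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, or a
#'   `genotype_table`.
#' @param catalog a [te_catalog()].
#' @param sense_mode `"strand"` (default) or `"genomic"`.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `te_id`,
#'   `superfamily`, `distance_bp`, `sense`.
#' @export
nearest_te <- function(snps, catalog, sense_mode = c("strand", "genomic")) {
  sense_mode <- match.arg(sense_mode)
  if (inherits(snps, "genotype_table")) snps <- snps$snps
  out <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                    pos = as.integer(snps$pos),
                    te_id = NO_TE_SENTINEL, superfamily = NO_TE_SENTINEL,
                    distance_bp = NA_integer_, sense = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(catalog) == 0 || nrow(snps) == 0) return(out)

  for (ch in intersect(unique(out$chrom), unique(catalog$chrom))) {
    ti <- which(catalog$chrom == ch)
    si <- which(out$chrom == ch)
    st <- catalog$start[ti]; en <- catalog$end[ti]
    id <- catalog$te_id[ti]
    pos <- out$pos[si]
    # sorted edges give O(log m) gap queries; running max of ends over
    # start-sorted TEs detects containment despite overlapping intervals
    oe <- sort(en)
    os <- order(st)
    ss <- st[os]
    cummax_end <- cummax(en[os])
    n_before <- findInterval(pos, ss)                 # TEs with start <= pos
    contained <- n_before >= 1 & cummax_end[pmax(n_before, 1)] >= pos
    li <- findInterval(pos - 1L, oe)                  # largest end < pos
    left_d <- ifelse(li >= 1, pos - oe[pmax(li, 1)], Inf)
    ri <- n_before + 1L                               # smallest start > pos
    right_d <- ifelse(ri <= length(ss), ss[pmin(ri, length(ss))] - pos, Inf)
    for (k in seq_along(si)) {
      if (contained[k]) {
        d <- 0L
        cand <- which(st <= pos[k] & en >= pos[k])
      } else {
        d <- min(left_d[k], right_d[k])
        cand <- integer()
        if (left_d[k] == d) cand <- which(en == pos[k] - d)
        if (right_d[k] == d) cand <- c(cand, which(st == pos[k] + d))
      }
      best <- cand[order(st[cand], id[cand])][1]      # tie-break rule
      j <- ti[best]
      i <- si[k]
      out$te_id[i] <- catalog$te_id[j]
      out$superfamily[i] <- catalog$superfamily[j]
      out$distance_bp[i] <- as.integer(d)
      if (d == 0) out$sense[i] <- "within"
      else {
        after <- pos[k] > catalog$end[j]
        flip <- sense_mode == "strand" && catalog$strand[j] == "-"
        out$sense[i] <- if (xor(after, flip)) "downstream" else "upstream"
      }
    }
  }
  out
}

#' Annotate all SNPs of a genotype table and summarise per superfamily
#'
#' @param genotable a `genotype_table`.
#' @param catalog a [te_catalog()].
#' @param sense_mode `"strand"` or `"genomic"` (see [nearest_te()]).
#' @return A list with `contexts` (one row per SNP, see [nearest_te()]) and
#'   `summary` (per-superfamily SNP count and mean/min/max distance);
#'   summary counts sum to the SNP count.
#' @export
annotate_te_context <- function(genotable, catalog,
                                sense_mode = c("strand", "genomic")) {
  sense_mode <- match.arg(sense_mode)
  ctx <- nearest_te(genotable$snps, catalog, sense_mode = sense_mode)
  sf <- split(ctx$distance_bp, ctx$superfamily)
  summ <- data.frame(
    superfamily = names(sf),
    n_snps = vapply(sf, length, integer(1)),
    mean_distance_bp = vapply(sf, function(d) mean(d), numeric(1)),
    min_distance_bp = vapply(sf, function(d) suppressWarnings(min(d)), numeric(1)),
    max_distance_bp = vapply(sf, function(d) suppressWarnings(max(d)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(contexts = ctx, summary = summ)
}
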