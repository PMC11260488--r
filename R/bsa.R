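#' @section Bulk-segregant mapping:
#' F1 haploid segregants of an evolved x ancestral cross are phenotyped for
#' expression noise in replicate, classified as ancestral-like or
#' evolved-like, pooled (20 consistent segregants per bulk), and the pools
#' sequenced. Per site the SNP index is the fraction of reads carrying the
#' evolved-parent allele within one bulk; the delta-SNP index is the
#' evolved-bulk index minus the ancestral-bulk index. Sites need an index
#' above 0.3 in at least one bulk (spurious-SNP filter) and a delta above
#' 0.8 to be called causal; a fully penetrant causal locus gives delta = 1.
#' @name bsa
#' @keywords internal
NULL

#' Classify segregants from replicate noise phenotypes
#'
#' Per replicate, a segregant is evolved-like iff its Fano exceeds the
#' midpoint of the two parental reference values; the overall label requires
#' all replicates to agree, otherwise the segregant is `inconsistent` and
#' excluded from pooling. The midpoint rule is a configurable choice — the
#' bench classification is by eye against parental distributions.
#'
#' @param phenotypes Matrix (segregants x replicates) of Fano values, or the
#'   list returned by [gen_segregants()].
#' @param ancestral_ref,evolved_ref Parental reference Fano values
#'   (`evolved_ref > ancestral_ref`).
#' @return Data.frame: segregant, label ("ancestral-like", "evolved-like",
#'   "inconsistent"), consistent flag, plus the replicate values.
#' @export
classify_segregants <- function(phenotypes, ancestral_ref, evolved_ref) {
  if (is.list(phenotypes) && !is.null(phenotypes$phenotypes))
    phenotypes <- phenotypes$phenotypes
  phenotypes <- as.matrix(phenotypes)
  if (anyNA(phenotypes)) stop("missing replicate phenotype value(s)")
  if (!(evolved_ref > ancestral_ref))
    stop("evolved_ref must exceed ancestral_ref")
  mid <- (ancestral_ref + evolved_ref) / 2
  evo <- phenotypes > mid
  all_evo <- rowSums(evo) == ncol(phenotypes)
  all_anc <- rowSums(evo) == 0
  label <- ifelse(all_evo, "evolved-like",
                  ifelse(all_anc, "ancestral-like", "inconsistent"))
  out <- data.frame(segregant = seq_len(nrow(phenotypes)), label = label,
                    consistent = all_evo | all_anc,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(phenotypes))
}

#' Draw the two sequencing bulks
#'
#' Uniform seeded sampling without replacement of `pool_size` consistently
#' classified segregants per class.
#'
#' @param classified Output of [classify_segregants()].
#' @param pool_size Segregants per bulk (default 20).
#' @param seed Integer seed.
#' @return List with integer index vectors `evolved` and `ancestral`.
#' @export
build_pools <- function(classified, pool_size = 20, seed = 1) {
  set.seed(as.integer(seed))
  pick <- function(lbl) {
    cand <- classified$segregant[classified$label == lbl]
    if (length(cand) < pool_size)
      stop(sprintf("only %d consistent %s segregants; need %d",
                   length(cand), lbl, pool_size))
    sort(sample(cand, pool_size))
  }
  list(evolved = pick("evolved-like"), ancestral = pick("ancestral-like"))
}

#' Per-bulk SNP index
#'
#' alt / (ref + alt) per site and bulk. Sites with zero depth in either
#' bulk have an undefined index: they are dropped, and the drop count is
#' attached as attribute `n_dropped`.
#'
#' @param counts Bulk-count data.frame (schema of [pool_counts_table()]).
#' @return The data.frame with `snp_index_evolved` and
#'   `snp_index_ancestral` columns appended and undefined sites removed.
#' @export
snp_index <- function(counts) {
  need <- c("ref_count_evolved", "alt_count_evolved",
            "ref_count_ancestral", "alt_count_ancestral")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count column(s): ",
                         paste(miss, collapse = ", "))
  if (any(counts[need] < 0)) stop("negative read counts")
  de <- counts$ref_count_evolved + counts$alt_count_evolved
  da <- counts$ref_count_ancestral + counts$alt_count_ancestral
  ok <- de > 0 & da > 0
  out <- counts[ok, , drop = FALSE]
  out$snp_index_evolved <- out$alt_count_evolved /
    (out$ref_count_evolved + out$alt_count_evolved)
  out$snp_index_ancestral <- out$alt_count_ancestral /
    (out$ref_count_ancestral + out$alt_count_ancestral)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Delta-SNP index and causal-mutation filters
#'
#' delta = evolved index - ancestral index. A site passes the index filter
#' iff its SNP index is strictly above `min_index` in at least one bulk
#' (filters spurious SNPs from sequencing/alignment error); it is called
#' causal iff it passes and delta is strictly above `causal_threshold`.
#'
#' @param records Output of [snp_index()].
#' @param min_index Per-bulk index filter (default 0.3, strict `>`).
#' @param causal_threshold Delta threshold for a causal call (default 0.8,
#'   strict `>`).
#' @return The records with `delta_snp_index`, `passed_index_filter`, and
#'   `called_causal` columns appended.
#' @export
delta_and_filter <- function(records, min_index = 0.3,
                             causal_threshold = 0.8) {
  stopifnot(all(c("snp_index_evolved", "snp_index_ancestral") %in%
                  names(records)))
  records$delta_snp_index <- records$snp_index_evolved -
    records$snp_index_ancestral
  records$passed_index_filter <- records$snp_index_evolved > min_index |
    records$snp_index_ancestral > min_index
  records$called_causal <- records$passed_index_filter &
    records$delta_snp_index > causal_threshold
  records
}

#' Filter clone-sequencing variants
#'
#' Retains variants with coverage strictly above 30 reads and allele
#' frequency strictly above 0.5 — the hard filter applied to evolved-clone
#' whole-genome variant calls.
#'
#' @param variants Data.frame with `coverage` and `allele_frequency`
#'   columns.
#' @param min_coverage Coverage threshold (strict `>`, default 30).
#' @param min_af Allele-frequency threshold (strict `>`, default 0.5).
#' @return The retained rows.
#' @export
clone_variant_filter <- function(variants, min_coverage = 30,
                                 min_af = 0.5) {
  stopifnot(all(c("coverage", "allele_frequency") %in% names(variants)))
  if (any(variants$coverage < 0)) stop("negative coverage")
  variants[variants$coverage > min_coverage &
             variants$allele_frequency > min_af, , drop = FALSE]
}

#' Read two-bulk allele counts from a VCF with per-sample AD
#'
#' @param path VCF path (plain text or bgzipped).
#' @param evolved_bulk,ancestral_bulk Sample names of the two bulks.
#' @param multiallelic "skip" (default) drops multi-allelic sites,
#'   counting them in attribute `n_multiallelic`; "first" keeps the first
#'   alternate allele's depth.
#' @return Bulk-count data.frame in the [pool_counts_table()] schema
#'   (1-based positions preserved).
#' @export
read_bulk_vcf <- function(path, evolved_bulk, ancestral_bulk,
                          multiallelic = c("skip", "first")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c(evolved_bulk, ancestral_bulk))
    if (!s %in% colnames(ad)) stop("sample not in VCF: ", s)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  keep <- if (multiallelic == "skip") !multi else rep(TRUE, nrow(fix))
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    ref <- as.integer(vapply(parts, `[`, "", 1))
    alt <- as.integer(vapply(parts, `[`, "", 2))
    list(ref = ref, alt = alt)
  }
  e <- split_ad(ad[, evolved_bulk])
  a <- split_ad(ad[, ancestral_bulk])
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = sub(",.*", "", fix$ALT),
                    ref_count_evolved = e$ref, alt_count_evolved = e$alt,
                    ref_count_ancestral = a$ref,
                    alt_count_ancestral = a$alt,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Read two-bulk allele counts from TSV
#'
#' @param path TSV with header chrom, pos, ref, alt, ref_count_evolved,
#'   alt_count_evolved, ref_count_ancestral, alt_count_ancestral.
#' @return Bulk-count data.frame.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("chrom", "pos", "ref", "alt", "ref_count_evolved",
            "alt_count_evolved", "ref_count_ancestral",
            "alt_count_ancestral")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write SNP-index records to TSV
#'
#' @param records Output of [delta_and_filter()].
#' @param path Output path.
#' @export
write_snp_index <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write causal candidates as BED
#'
#' @param records Output of [delta_and_filter()].
#' @param path Output path. BED is 0-based half-open; 1-based positions are
#'   converted.
#' @export
write_causal_bed <- function(records, path) {
  cc <- records[records$called_causal, , drop = FALSE]
  bed <- data.frame(chrom = cc$chrom, start = cc$pos - 1L, end = cc$pos,
                    name = paste0(cc$ref, ">", cc$alt),
                    score = round(1000 * pmin(1, pmax(0, cc$delta_snp_index))))
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' End-to-end bulk-segregant mapping on a simulated cross
#'
#' Simulates the cross, classifies segregants against the parental Fano
#' references implied by the design, draws the two bulks, simulates pooled
#' sequencing of each, and computes SNP indices, delta, and causal calls.
#'
#' @param design A [cross_design()].
#' @param depth Reads per site per bulk.
#' @param error_rate Symmetric per-read error rate.
#' @param pool_size Segregants per bulk.
#' @param seed Run-level integer seed (stage seeds derived by fixed
#'   offsets).
#' @param min_index,causal_threshold Filter thresholds.
#' @return The [delta_and_filter()] record set, with the causal locus index
#'   attached as attribute `causal_locus`.
#' @export
bsa_map <- function(design, depth = 200, error_rate = 0, pool_size = 20,
                    seed = 1, min_index = 0.3, causal_threshold = 0.8) {
  cross <- gen_segregants(design, seed = derive_seed(seed, 11))
  cls <- classify_segregants(cross$phenotypes,
                             ancestral_ref = design$base_fano,
                             evolved_ref = design$base_fano +
                               design$phenotype_effect)
  pools <- build_pools(cls, pool_size = pool_size,
                       seed = derive_seed(seed, 12))
  reads_e <- gen_pool_reads(cross$genotypes[pools$evolved, , drop = FALSE],
                            depth, error_rate,
                            seed = derive_seed(seed, 13))
  reads_a <- gen_pool_reads(cross$genotypes[pools$ancestral, , drop = FALSE],
                            depth, error_rate,
                            seed = derive_seed(seed, 14))
  counts <- pool_counts_table(reads_e, reads_a, design$map_positions)
  rec <- delta_and_filter(snp_index(counts), min_index, causal_threshold)
  attr(rec, "causal_locus") <- design$causal_index
  rec
}
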