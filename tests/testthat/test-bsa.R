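test_that("segregant classification follows the replicate-consistency rule", {
  ph <- rbind(c(2.0, 2.1, 1.9),   # all above midpoint -> evolved-like
              c(1.0, 0.9, 1.1),   # all below -> ancestral-like
              c(2.0, 1.0, 2.0))   # disagreement -> inconsistent
  cls <- classify_segregants(ph, ancestral_ref = 1, evolved_ref = 2)
  expect_equal(cls$label, c("evolved-like", "ancestral-like", "inconsistent"))
  expect_equal(cls$consistent, c(TRUE, TRUE, FALSE))
  expect_error(classify_segregants(rbind(c(1, NA, 1)), 1, 2), "missing")
  expect_error(classify_segregants(ph, 2, 1), "exceed")
})

test_that("small phenotype noise yields mostly consistent, correctly-typed segregants", {
  des <- cross_design(n_segregants = 200, phenotype_noise_sd = 0.05,
                      phenotype_effect = 1)
  cross <- gen_segregants(des, seed = 1)
  cls <- classify_segregants(cross$phenotypes, 1, 2)
  expect_gte(mean(cls$consistent), 0.90)
  carriers <- cross$genotypes[, des$causal_index] == 1
  consistent_carriers <- cls$consistent & carriers
  expect_true(all(cls$label[consistent_carriers] == "evolved-like"))
})

test_that("pool construction is a seeded subset with informative failures", {
  ph <- rbind(matrix(2, 30, 3), matrix(1, 20, 3))
  cls <- classify_segregants(ph, 1, 2)
  p1 <- build_pools(cls, pool_size = 20, seed = 4)
  p2 <- build_pools(cls, pool_size = 20, seed = 4)
  expect_identical(p1, p2)
  expect_length(p1$evolved, 20)
  expect_true(all(cls$label[p1$evolved] == "evolved-like"))
  # exactly 20 consistent ancestral-like -> the pool is those 20
  expect_setequal(p1$ancestral, cls$segregant[cls$label == "ancestral-like"])
  ph0 <- matrix(2, 25, 3)  # zero ancestral-like
  expect_error(build_pools(classify_segregants(ph0, 1, 2), 20),
               "ancestral-like")
})

test_that("SNP index is alt/(ref+alt) with zero-depth sites dropped", {
  counts <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
                       ref_count_evolved = c(30, 0, 0),
                       alt_count_evolved = c(10, 200, 0),
                       ref_count_ancestral = c(30, 100, 10),
                       alt_count_ancestral = c(10, 100, 10))
  idx <- snp_index(counts)
  expect_equal(nrow(idx), 2)
  expect_equal(attr(idx, "n_dropped"), 1)
  expect_equal(idx$snp_index_evolved, c(0.25, 1.0))
  expect_error(snp_index(transform(counts, ref_count_evolved = -1)),
               "negative")
})

test_that("delta and the two filters follow the strict thresholds", {
  rec <- data.frame(snp_index_evolved = c(1.0, 0.25, 1.0, 0.3, 0.31),
                    snp_index_ancestral = c(0.0, 0.25, 0.25, 0.0, 0.0))
  out <- delta_and_filter(rec)
  expect_equal(out$delta_snp_index, c(1, 0, 0.75, 0.3, 0.31))
  # both indices at 0.3 fail the strict > 0.3 filter
  expect_equal(out$passed_index_filter, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # delta 0.75 passes the filter but misses the strict > 0.8 causal cut
  expect_equal(out$called_causal, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("clone variant filter applies strict coverage and frequency cuts", {
  v <- data.frame(chrom = "chr1", pos = 1:4,
                  coverage = c(31, 30, 100, 100),
                  allele_frequency = c(0.6, 0.9, 0.5, 0.51))
  out <- clone_variant_filter(v)
  expect_equal(out$pos, c(1, 4))  # 30 and 0.5 sit exactly on the cut: out
})

test_that("raising either threshold never adds a causal call", {
  set.seed(3)
  rec <- data.frame(snp_index_evolved = runif(200),
                    snp_index_ancestral = runif(200))
  base <- delta_and_filter(rec, 0.3, 0.8)
  for (mi in c(0.4, 0.5)) {
    expect_true(all(delta_and_filter(rec, mi, 0.8)$called_causal <=
                      base$called_causal))
  }
  for (ct in c(0.85, 0.95)) {
    expect_true(all(delta_and_filter(rec, 0.3, ct)$called_causal <=
                      base$called_causal))
  }
})

test_that("the causal locus is recovered as the unique causal call", {
  des <- cross_design(n_loci = 50, causal_index = 25, n_segregants = 100,
                      phenotype_noise_sd = 0.05)
  hits <- sapply(1:20, function(s) {
    rec <- bsa_map(des, depth = 200, error_rate = 0, seed = s)
    sum(rec$called_causal) == 1 &&
      which(rec$called_causal) == attr(rec, "causal_locus")
  })
  expect_gte(mean(hits), 0.95)
  # indices and deltas stay in their ranges
  rec <- bsa_map(des, depth = 200, error_rate = 0.005, seed = 99)
  expect_true(all(rec$snp_index_evolved >= 0 & rec$snp_index_evolved <= 1))
  expect_true(all(abs(rec$delta_snp_index) <= 1))
})

test_that("delta decays with map distance from the causal locus", {
  map <- data.frame(chrom = rep("chr1", 3), cM = c(0, 1, 50))
  des <- cross_design(n_loci = 3, causal_index = 1, map_positions = map,
                      n_segregants = 100, phenotype_noise_sd = 0)
  d <- rowMeans(sapply(1:20, function(s) {
    rec <- bsa_map(des, depth = 200, error_rate = 0, seed = s)
    rec$delta_snp_index
  }))
  expect_gt(d[2], d[3])  # 1 cM neighbour tracks the causal site more closely
})

test_that("bulk counts round-trip through TSV and parse from VCF AD fields", {
  des <- cross_design(n_loci = 5, causal_index = 3, n_segregants = 60,
                      map_positions = data.frame(chrom = paste0("chr", 1:5),
                                                 cM = 0),
                      phenotype_noise_sd = 0)
  rec <- bsa_map(des, depth = 100, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_snp_index(rec, tsv)
  back <- read_counts_tsv(tsv)
  expect_equal(back$alt_count_evolved, rec$alt_count_evolved)

  # minimal two-sample VCF with AD, one multi-allelic site
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tEB\tAB",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t1:10,190\t0:150,50",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT:AD\t0:100,100\t0:120,80",
    "chr2\t300\t.\tA\tT,G\t.\tPASS\t.\tGT:AD\t1:50,50,100\t0:80,20,100"),
    vcf)
  counts <- read_bulk_vcf(vcf, "EB", "AB")
  expect_equal(nrow(counts), 2)  # multi-allelic site skipped
  expect_equal(attr(counts, "n_multiallelic"), 1)
  expect_equal(counts$pos, c(100, 200))
  expect_equal(counts$alt_count_evolved, c(190, 100))
  idx <- delta_and_filter(snp_index(counts))
  expect_equal(idx$snp_index_evolved[1], 0.95)
  expect_equal(idx$snp_index_ancestral[1], 0.25)
  expect_equal(idx$delta_snp_index[1], 0.70)
  expect_error(read_bulk_vcf(vcf, "EB", "nope"), "not in VCF")

  bed <- withr::local_tempfile(fileext = ".bed")
  write_causal_bed(delta_and_filter(snp_index(
    data.frame(chrom = "chr4", pos = 500, ref = "A", alt = "T",
               ref_count_evolved = 0, alt_count_evolved = 100,
               ref_count_ancestral = 100, alt_count_ancestral = 0))), bed)
  row <- read.delim(bed, header = FALSE)
  expect_equal(row$V2, 499)  # 1-based VCF position to 0-based BED start
  expect_equal(row$V3, 500)
})
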