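test_that("VCF reading keeps biallelic SNPs only and preserves missing calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t1/1",   # tri-allelic
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t1/1",
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/0",    # indel
    "chr1\t500\t.\tT\tC\t.\tPASS\t.\tGT\t1|0\t0|0"),
    path)
  vt <- read_vcf(path)
  expect_equal(nrow(vt), 3)
  expect_equal(vt$pos, c(100L, 300L, 500L))
  expect_true(is.na(vt$s1[vt$pos == 300]))
  expect_equal(vt$s1[vt$pos == 500], 1L)
  expect_equal(attr(vt, "chrom_lengths"), c(chr1 = 10000))
})

test_that("write/read round-trip preserves coordinates, alleles and genotypes", {
  fx <- make_test_vt(n_sites = 200, miss_rate = 0.1, seed = 42)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(fx$vt, path)
  back <- read_vcf(path)
  for (col in c("chrom", "pos", "ref", "alt", vt_samples(fx$vt))) {
    expect_equal(back[[col]], fx$vt[[col]], info = col)
  }
})

test_that("site filters match per-site hand computation", {
  # 10 sites, 5 samples, hand-set genotypes
  g <- rbind(
    c(0L, 0L, 1L, 0L, 0L),   # maf 1/10
    c(0L, 1L, 1L, 0L, 0L),   # maf 2/10
    c(NA, 1L, 1L, 0L, 0L),   # miss 1/5, maf 2/8
    c(NA, NA, 1L, 0L, 0L),   # miss 2/5
    c(2L, 2L, 2L, 2L, 2L),   # maf 0
    c(2L, 2L, 2L, 2L, 1L),   # maf 1/10
    c(1L, 1L, 1L, 1L, 1L),   # maf 5/10
    c(0L, 0L, 0L, 0L, 0L),   # maf 0
    c(2L, 0L, 1L, 1L, 0L),   # maf 4/10
    c(NA, NA, NA, NA, NA))   # all missing
  vt <- variant_tbl(rep("chr1", 10), seq(100, 1000, 100), rep("A", 10),
                    rep("C", 10), g, paste0("s", 1:5))
  out <- apply_snp_filters(vt, max_missing_rate = 0.2, min_maf = 0.2)
  expect_equal(out$pos, c(200L, 300L, 700L, 900L))
  # identity settings keep everything except nothing
  expect_equal(nrow(apply_snp_filters(vt, 1, 0)), 10)
  # threshold is inclusive: maf exactly at the cut stays
  out2 <- apply_snp_filters(vt, 1, 0.1)
  expect_true(100L %in% out2$pos)   # maf 0.1 >= 0.1
  expect_false(500L %in% out2$pos)  # maf 0
})

test_that("allele frequencies equal the counting oracle and flag missing", {
  fx <- make_test_vt(n_sites = 20, miss_rate = 0.15, seed = 5)
  f <- allele_freqs(fx$vt, fx$pm, "wild")
  g <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == "wild"])
  for (s in seq_len(nrow(g))) {
    cp <- .copies(g[s, ])
    if (length(cp) == 0) {
      expect_true(is.na(f$p[s]))
      expect_equal(f$n[s], 0L)
    } else {
      expect_equal(f$p[s], mean(cp))
      expect_equal(f$n[s], length(cp))
    }
  }
  # forced arithmetic: genotypes 0,1,2 give p = 0.5 over 6 haplotypes
  vt <- variant_tbl("chr1", 1L, "A", "C", matrix(c(0L, 1L, 2L), 1),
                    paste0("s", 1:3))
  pm <- as_popmap(tibble::tibble(sample = paste0("s", 1:3), population = "x"))
  f1 <- allele_freqs(vt, pm, "x")
  expect_equal(f1$p, 0.5)
  expect_equal(f1$n, 6L)
  expect_error(allele_freqs(vt, pm, "nope"), "unknown population")
})

test_that("population-weighted frequencies recombine to the global frequency", {
  fx <- make_test_vt(n_sites = 30, miss_rate = 0.1, seed = 9)
  pops <- unique(fx$pm$population)
  fr <- lapply(pops, function(pp) allele_freqs(fx$vt, fx$pm, pp))
  num <- Reduce(`+`, lapply(fr, function(f) ifelse(f$n > 0, f$p * f$n, 0)))
  den <- Reduce(`+`, lapply(fr, function(f) f$n))
  fall <- allele_freqs(fx$vt, as_popmap(transform(fx$pm, population = "all")),
                       "all")
  expect_equal(num / den, fall$p, tolerance = 1e-12)
})

test_that("polarization follows the fixed-outgroup rule and is involution-safe", {
  g <- rbind(c(1L, 2L, 0L, 0L),   # outgroup fixed ref -> ancestral ref
             c(1L, 0L, 2L, 2L),   # outgroup fixed alt -> ancestral alt
             c(1L, 1L, 0L, 1L),   # outgroup het -> unusable
             c(1L, 1L, NA, NA))   # outgroup missing -> unusable
  vt <- variant_tbl(rep("chr1", 4), c(10L, 20L, 30L, 40L), rep("A", 4),
                    rep("G", 4), g, c("i1", "i2", "o1", "o2"))
  pm <- as_popmap(tibble::tibble(sample = c("i1", "i2", "o1", "o2"),
                                 population = c("in", "in", "out", "out"),
                                 role = c("ingroup", "ingroup", "outgroup",
                                          "outgroup")))
  pv <- polarize(vt, pm, "out")
  expect_equal(pv$ancestral, c("ref", "alt", NA, NA))
  expect_equal(pv$polarizable, c(TRUE, TRUE, FALSE, FALSE))
  # derived frequency flips where ancestral is the alt allele
  f <- allele_freqs(pv, pm, "in", derived = TRUE)
  expect_equal(f$p[1], 0.75)   # alt freq 3/4
  expect_equal(f$p[2], 0.75)   # alt freq 1/4, flipped
  expect_true(all(is.na(f$p[3:4])))
  expect_identical(polarize(pv, pm, "out")$ancestral, pv$ancestral)
})

test_that("window construction reproduces the enumerated sliding grid", {
  vt <- variant_tbl("chr1", c(1L, 249999L), c("A", "A"), c("C", "C"),
                    matrix(c(0L, 1L), 2, 1), "s1")
  w <- make_windows(vt, 1e5, 2e4, chrom_lengths = c(chr1 = 250000))
  expect_equal(nrow(w), 11)
  expect_equal(w$start, seq(1, 200001, by = 20000))
  expect_equal(w$end, pmin(w$start + 1e5 - 1, 250000))
  expect_true(all(w$end[1:8] == w$start[1:8] + 1e5 - 1))
  expect_equal(w$end[11], 250000)
})

test_that("non-overlapping windows partition SNPs exactly", {
  fx <- make_test_vt(n_sites = 80, seed = 3, chrom_len = 7300L)
  w <- make_windows(fx$vt, 1000, 1000)
  expect_equal(sum(w$n_snps), nrow(fx$vt))
  expect_true(max(w$end) >= max(fx$vt$pos))
  expect_true(all(diff(w$start) == 1000))
  # min_snps flags but does not drop
  w2 <- make_windows(fx$vt, 1000, 1000, min_snps = 1e6)
  expect_equal(nrow(w2), nrow(w))
  expect_true(all(w2$excluded))
})

test_that("popmap IO validates roles and survives a round-trip", {
  pm <- as_popmap(tibble::tibble(sample = c("a", "b"),
                                 population = c("x", "y"),
                                 role = c("ingroup", "outgroup")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  expect_equal(read_popmap(path), pm)
  expect_error(as_popmap(tibble::tibble(sample = c("a", "a"),
                                        population = c("x", "y"))),
               "exactly one population")
})

test_that("BED output converts to 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(tibble::tibble(chrom = "chr1", start = 101, end = 200), path)
  expect_equal(readLines(path), "chr1\t100\t200")
  rb <- read_bed(path)
  expect_equal(rb$start, 101)
  expect_equal(rb$end, 200)
})
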