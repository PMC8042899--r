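# build a polarized-frequency pattern table directly
pattern_tbl <- function(p1, p2, p3, pos = NULL, chrom = "chr1") {
  pos <- pos %||% seq_along(p1) * 10L
  tibble::tibble(chrom = chrom, pos = pos, p1 = p1, p2 = p2, p3 = p3,
                 abba = (1 - p1) * p2 * p3, baba = p1 * (1 - p2) * p3)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("site-pattern terms follow the frequency products", {
  fx <- make_test_vt(n_sites = 60, seed = 41)
  pat <- site_patterns(fx$vt, fx$pm, "wild", "domcn", "seasa", "outgroup")
  expect_true(all(pat$abba >= 0 & pat$abba <= 1))
  expect_equal(pat$abba, (1 - pat$p1) * pat$p2 * pat$p3, tolerance = 1e-15)
  # forced cases
  expect_equal(pattern_tbl(0, 1, 1)$abba, 1)
  expect_equal(pattern_tbl(0, 1, 1)$baba, 0)
  expect_equal(pattern_tbl(0.5, 0.5, 0)$abba, 0)   # p3 = 0 uninformative
  expect_equal(pattern_tbl(0.2, 0.8, 0.6)$abba, 0.384, tolerance = 1e-15)
  expect_equal(pattern_tbl(0.2, 0.8, 0.6)$baba, 0.024, tolerance = 1e-15)
  # overlapping P populations are rejected
  pm_bad <- fx$pm
  pm_bad$population[pm_bad$population == "domcn"] <- "wild"
  expect_error(site_patterns(fx$vt, pm_bad, "wild", "wild", "seasa",
                             "outgroup"), "share samples")
})

test_that("Patterson's D equals the term-by-term oracle on the 3-site fixture", {
  pat <- pattern_tbl(c(0.2, 0.5, 0.1), c(0.8, 0.5, 0.3), c(0.6, 0.9, 0.7),
                     pos = c(10L, 3000000L, 7000000L))
  d <- patterson_d(pat, block_size_bp = 2e6)
  expect_equal(d$estimate,
               oracle_d_stat(pat$p1, pat$p2, pat$p3), tolerance = 1e-12)
  # hand value: per-site products summed
  expect_equal(d$estimate, (0.798 - 0.298) / (0.798 + 0.298),
               tolerance = 1e-3)
})

test_that("D respects its symmetries and bounds", {
  set.seed(43)
  p1 <- runif(200); p2 <- runif(200); p3 <- runif(200)
  pat <- pattern_tbl(p1, p2, p3, pos = sort(sample.int(2e7, 200)))
  d <- patterson_d(pat)
  expect_true(abs(d$estimate) <= 1)
  swapped <- pattern_tbl(p2, p1, p3, pos = pat$pos)
  expect_equal(patterson_d(swapped)$estimate, -d$estimate, tolerance = 1e-12)
  # symmetric counts give D = 0
  sym <- pattern_tbl(c(0.2, 0.8), c(0.8, 0.2), c(0.5, 0.5),
                     pos = c(10L, 20L))
  expect_equal(patterson_d(sym, block_size_bp = 5L)$estimate, 0)
  # all-uninformative input is an error
  expect_error(patterson_d(pattern_tbl(c(0, 0), c(0, 0), c(0, 0))),
               "uninformative")
})

test_that("weighted block jackknife matches the closed form and recombines", {
  set.seed(47)
  p1 <- runif(300); p2 <- runif(300); p3 <- runif(300)
  pat <- pattern_tbl(p1, p2, p3, pos = sort(sample.int(3e7, 300)))
  d <- patterson_d(pat)
  blocks <- paste(pat$chrom, (pat$pos - 1) %/% 2e6)
  num_j <- rowsum(pat$abba - pat$baba, blocks)[, 1]
  den_j <- rowsum(pat$abba + pat$baba, blocks)[, 1]
  expect_equal(d$se, oracle_jackknife_se(num_j, den_j), tolerance = 1e-12)
  expect_equal(d$n_blocks, length(num_j))
  # recombining delete-one estimates with their weights restores D exactly
  W <- sum(den_j)
  recombined <- sum((W - den_j) * d$loo) / ((length(den_j) - 1) * W)
  expect_equal(recombined, d$estimate, tolerance = 1e-12)
  # identical per-block D means zero between-block variance
  pat2 <- pattern_tbl(rep(0.2, 4), rep(0.8, 4), rep(0.6, 4),
                      pos = c(1L, 2L, 4000001L, 4000002L))
  d2 <- patterson_d(pat2)
  expect_equal(d2$se, 0)
  expect_true(is.infinite(d2$z))
})

test_that("f3 matches the hand-summed oracle and its symmetries", {
  fx <- make_test_vt(n_sites = 20, miss_rate = 0.1, seed = 53)
  r_bc <- f3_test(fx$vt, fx$pm, "wild", "domcn", "seasa", block_size_bp = 300)
  r_cb <- f3_test(fx$vt, fx$pm, "wild", "seasa", "domcn", block_size_bp = 300)
  expect_equal(r_bc$estimate, r_cb$estimate, tolerance = 1e-12)
  # scalar oracle
  fa <- allele_freqs(fx$vt, fx$pm, "wild")
  fb <- allele_freqs(fx$vt, fx$pm, "domcn")
  fc <- allele_freqs(fx$vt, fx$pm, "seasa")
  tt <- c()
  for (s in seq_len(nrow(fx$vt))) {
    if (fa$n[s] < 2 || fb$n[s] < 1 || fc$n[s] < 1) next
    ha <- fa$p[s] * (1 - fa$p[s]) * fa$n[s] / (fa$n[s] - 1)
    tt <- c(tt, (fa$p[s] - fb$p[s]) * (fa$p[s] - fc$p[s]) - ha / fa$n[s])
  }
  expect_equal(r_bc$estimate, mean(tt), tolerance = 1e-12)
  # pA midway between distinct pB, pC gives a negative raw term
  expect_lt((0.5 - 0.2) * (0.5 - 0.8), 0)
})

test_that("fd window values follow the donor-proxy convention", {
  # two-site window: (0, 0.5, 1) and (0, 1, 0.5) -> num 1, den 2, fd 0.5
  pat <- pattern_tbl(c(0, 0), c(0.5, 1), c(1, 0.5), pos = c(10L, 20L))
  expect_equal(oracle_fd(pat$p1, pat$p2, pat$p3), 0.5)
  # p2 = p3 everywhere with positive numerator -> fd = 1
  expect_equal(oracle_fd(c(0, 0), c(0.7, 0.4), c(0.7, 0.4)), 1)
  # negative window D -> 0 by convention
  expect_equal(oracle_fd(c(0.9, 0.9), c(0.1, 0.1), c(0.8, 0.8)), 0)
  # fd_scan agrees with the oracle on simulated data, window by window
  fx <- make_test_vt(n_sites = 400, seed = 59, chrom_len = 40000L)
  fd <- fd_scan(fx$vt, fx$pm, "wild", "domcn", "seasa", "outgroup",
                size_bp = 10000, step_bp = 10000, min_snps = 1)
  pat <- site_patterns(fx$vt, fx$pm, "wild", "domcn", "seasa", "outgroup")
  for (i in seq_len(nrow(fd))) {
    inw <- pat$pos >= fd$start[i] & pat$pos <= fd$end[i]
    if (!any(inw)) next
    expect_equal(fd$fd[i], oracle_fd(pat$p1[inw], pat$p2[inw], pat$p3[inw]),
                 tolerance = 1e-12)
  }
  expect_true(all(fd$fd[!is.na(fd$fd)] <= 1 + 1e-9))
})

test_that("region calling merges, bookends and enforces the length floor", {
  base <- tibble::tibble(
    chrom = "chr1",
    start = seq(1, by = 20000, length.out = 30),
    end = seq(1, by = 20000, length.out = 30) + 99999,
    n_snps = 200L, excluded = FALSE, d_window = 0.1, fd = 0.1)
  # six consecutive passing windows spanning exactly 200 kb
  w <- base
  w$fd[6:11] <- 0.8
  reg <- call_introgressed_regions(w)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, w$start[6])
  expect_equal(reg$end, w$end[11])
  expect_equal(reg$end - reg$start + 1, 200000)
  expect_equal(reg$n_windows, 6L)
  expect_equal(reg$peak_fd, 0.8)
  # a single isolated passing window spans only 100 kb and is dropped
  w2 <- base; w2$fd[15] <- 0.9
  expect_equal(nrow(call_introgressed_regions(w2)), 0)
  # nothing above threshold: empty result
  expect_equal(nrow(call_introgressed_regions(base)), 0)
  # excluded windows cannot seed regions
  w3 <- base; w3$fd[6:11] <- 0.8; w3$excluded[6:11] <- TRUE
  expect_equal(nrow(call_introgressed_regions(w3)), 0)
  # two separated clusters stay two regions
  w4 <- base; w4$fd[c(1:6, 20:25)] <- 0.7
  expect_equal(nrow(call_introgressed_regions(w4)), 2)
})

test_that("planted introgression lowers recipient-donor dxy in the tract", {
  cfg <- scenario_config(chrom_lengths = c(chr1 = 3e6),
                         introgression = list(donor = "seasa",
                                              recipient = "domcn",
                                              chrom = "chr1",
                                              start = 1200001, end = 1600000,
                                              fraction = 0.8),
                         sweep = NULL, seed = 61)
  fx <- generate_fixture(cfg)
  ver <- verify_region(fx$truth$introgression, fx$vt, fx$popmap,
                       recipient = "domcn", donor_group = "seasa",
                       control_group = "wild")
  expect_lt(ver$donor_dxy, ver$donor_dxy_bg_mean)
  expect_lt(ver$donor_dxy_z, -1)
  # the same contrast against the non-donor control is much weaker
  expect_gt(ver$control_dxy_z, ver$donor_dxy_z)
})

test_that("mean tract fd does not decrease with the admixture fraction", {
  mean_tract_fd <- function(fraction) {
    cfg <- scenario_config(
      chrom_lengths = c(chr1 = 3e6),
      introgression = list(donor = "seasa", recipient = "domcn",
                           chrom = "chr1", start = 1200001, end = 1600000,
                           fraction = fraction),
      sweep = NULL, seed = 97)
    fx <- generate_fixture(cfg)
    fd <- fd_scan(fx$vt, fx$popmap, "wild", "domcn", "seasa", "outgroup")
    inw <- !fd$excluded & !is.na(fd$fd) & fd$start <= 1600000 &
      fd$end >= 1200001
    mean(fd$fd[inw])
  }
  fds <- vapply(c(0.25, 0.5, 0.75), mean_tract_fd, 0)
  expect_true(all(diff(fds) > -0.02))   # non-decreasing up to MC noise
  expect_gt(fds[3], fds[1])
})

test_that("gene flow between P2 and P3 raises D above its no-flow baseline", {
  # the fixed topology makes domcn and seasa sisters, so with P1 = wild the
  # no-flow D is already positive; migration must shift it further up
  base <- scenario_config()$model
  mig <- tibble::tibble(from = c("domcn", "seasa"), to = c("seasa", "domcn"),
                        m4n = 10, t_start = 0, t_end = base$t1)
  m_mig <- base; m_mig$migration <- mig
  d_of <- function(model) {
    ds <- simulate_dataset(model, c(wild = 16, domcn = 16, seasa = 16,
                                    outgroup = 8), n_loci = 60,
                           locus_bp = 5000)
    conv <- sim_to_variant_tbl(ds, locus_spacing_bp = 2e6)
    pat <- site_patterns(conv$vt, conv$popmap, "wild", "domcn", "seasa",
                         "outgroup")
    patterson_d(pat, block_weights = "uniform")$estimate
  }
  set.seed(87)
  pairs <- t(vapply(1:10, function(i) c(null = d_of(base), mig = d_of(m_mig)),
                    c(null = 0, mig = 0)))
  expect_gte(mean(pairs[, "mig"] > pairs[, "null"]), 0.9)
})
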