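win_all <- function(vt, len = NULL) {
  len <- len %||% max(vt$pos)
  tibble::tibble(chrom = vt$chrom[1], start = 1, end = len,
                 n_snps = nrow(vt), excluded = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("windowed theta-pi equals the pairwise-enumeration oracle", {
  fx <- make_test_vt(n_sites = 50, miss_rate = 0.1, seed = 11)
  w <- win_all(fx$vt, 5000)
  for (pp in c("wild", "seasa")) {
    got <- theta_pi_windows(fx$vt, fx$pm, pp, w)$theta_pi
    g <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == pp])
    expect_equal(got, oracle_pi_sum(g) / 5000, tolerance = 1e-12)
  }
  # forced case: one site, two haplotypes differing, 1000-bp window
  vt <- variant_tbl("chr1", 500L, "A", "C", matrix(1L, 1, 1), "s1")
  pm <- as_popmap(tibble::tibble(sample = "s1", population = "x"))
  w1 <- tibble::tibble(chrom = "chr1", start = 1, end = 1000,
                       n_snps = 1L, excluded = FALSE)
  expect_equal(theta_pi_windows(vt, pm, "x", w1)$theta_pi, 0.001)
  # empty window
  w0 <- tibble::tibble(chrom = "chr1", start = 2000, end = 3000,
                       n_snps = 0L, excluded = FALSE)
  expect_equal(theta_pi_windows(vt, pm, "x", w0)$theta_pi, 0)
})

test_that("Tajima's D matches the hand-evaluated textbook formula", {
  # n = 4 haplotypes (2 diploids), S = 3: genotypes chosen so each diploid
  # pair of allele copies is a known haplotype pair (all homozygous)
  hap <- cbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
  geno <- matrix(c(hap[, 1] + hap[, 2], hap[, 3] + hap[, 4]), ncol = 2)
  vt <- variant_tbl(rep("chr1", 3), c(10L, 20L, 30L), rep("A", 3),
                    rep("C", 3), geno, c("s1", "s2"))
  pm <- as_popmap(tibble::tibble(sample = c("s1", "s2"), population = "x"))
  got <- tajima_d_windows(vt, pm, "x", win_all(vt))$tajimas_d
  expect_equal(got, oracle_tajima_d(hap), tolerance = 1e-12)
  # S = 0 window is undefined, not zero
  w0 <- tibble::tibble(chrom = "chr1", start = 100, end = 200,
                       n_snps = 0L, excluded = FALSE)
  expect_true(is.na(tajima_d_windows(vt, pm, "x", w0)$tajimas_d))
})

test_that("Tajima's D is near zero under the neutral coalescent null", {
  set.seed(21)
  ds <- simulate_dataset(neutral_model(2e4), c(wild = 20), n_loci = 500,
                         locus_bp = 5000)
  d <- vapply(split(seq_along(ds$locus), ds$locus), function(ix) {
    h <- ds$haps[ix, , drop = FALSE]
    if (nrow(h) < 1) return(NA_real_)
    oracle_tajima_d(h)
  }, 0)
  d <- d[!is.na(d)]
  expect_gt(length(d), 300)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("dxy equals the cross-population enumeration oracle and is symmetric", {
  fx <- make_test_vt(n_sites = 30, miss_rate = 0.1, seed = 13)
  w <- win_all(fx$vt, 3000)
  ab <- dxy_windows(fx$vt, fx$pm, "wild", "domcn", w)$dxy
  ba <- dxy_windows(fx$vt, fx$pm, "domcn", "wild", w)$dxy
  expect_identical(ab, ba)
  ga <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == "wild"])
  gb <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == "domcn"])
  expect_equal(ab, oracle_dxy_sum(ga, gb) / 3000, tolerance = 1e-12)
  # five fixed differences in a 1000-bp window give dxy = 0.005
  g <- cbind(rep(0L, 5), rep(2L, 5))
  vt <- variant_tbl(rep("chr1", 5), seq(100L, 500L, 100L), rep("A", 5),
                    rep("C", 5), g, c("a1", "b1"))
  pm <- as_popmap(tibble::tibble(sample = c("a1", "b1"),
                                 population = c("A", "B")))
  w1 <- tibble::tibble(chrom = "chr1", start = 1, end = 1000, n_snps = 5L,
                       excluded = FALSE)
  expect_equal(dxy_windows(vt, pm, "A", "B", w1)$dxy, 0.005)
})

test_that("dxy of a population against itself relates to theta-pi", {
  # self-dxy = 2p(1-p) per site; theta-pi adds the n/(n-1) correction
  fx <- make_test_vt(n_sites = 40, seed = 17)
  w <- win_all(fx$vt, 4000)
  self <- dxy_windows(fx$vt, fx$pm, "wild", "wild", w)$dxy
  pi_w <- theta_pi_windows(fx$vt, fx$pm, "wild", w)$theta_pi
  n <- 2 * sum(fx$pm$population == "wild")
  expect_equal(self * n / (n - 1), pi_w, tolerance = 1e-12)
})

test_that("FST estimators match their per-site component oracles", {
  fx <- make_test_vt(n_sites = 25,
                     n_per_pop = c(wild = 5, domcn = 3, seasa = 2,
                                   outgroup = 2),
                     miss_rate = 0.12, seed = 19)
  w <- win_all(fx$vt, 2500)
  ga <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == "wild"])
  gb <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == "domcn"])
  wc <- fst_windows(fx$vt, fx$pm, "wild", "domcn", w)$fst
  expect_equal(wc, oracle_wc_fst(ga, gb), tolerance = 1e-12)
  hu <- fst_windows(fx$vt, fx$pm, "wild", "domcn", w,
                    estimator = "hudson")$fst
  expect_equal(hu, oracle_hudson_fst(ga, gb), tolerance = 1e-12)
  expect_error(fst_windows(fx$vt, fx$pm, "wild", "domcn", w,
                           estimator = "nonsense"))
})

test_that("FST hits its boundary values on degenerate configurations", {
  # fixed difference with equal sample sizes: FST = 1 for both estimators
  g <- cbind(rep(0L, 4), rep(0L, 4), rep(2L, 4), rep(2L, 4))
  vt <- variant_tbl(rep("chr1", 4), seq(10L, 40L, 10L), rep("A", 4),
                    rep("C", 4), g, c("a1", "a2", "b1", "b2"))
  pm <- as_popmap(tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                                 population = c("A", "A", "B", "B")))
  w <- win_all(vt)
  expect_equal(fst_windows(vt, pm, "A", "B", w)$fst, 1)
  expect_equal(fst_windows(vt, pm, "A", "B", w, estimator = "hudson")$fst, 1)
  # identical per-site frequency vectors, equal n: Hudson FST = 0 exactly
  g2 <- cbind(c(0L, 1L, 2L), c(2L, 1L, 0L), c(0L, 1L, 2L), c(2L, 1L, 0L))
  vt2 <- variant_tbl(rep("chr1", 3), c(10L, 20L, 30L), rep("A", 3),
                     rep("C", 3), g2, c("a1", "a2", "b1", "b2"))
  expect_equal(fst_windows(vt2, pm, "A", "B", win_all(vt2),
                           estimator = "hudson")$fst, 0)
})

test_that("diversity statistics ignore sample labels within populations", {
  fx <- make_test_vt(n_sites = 30, miss_rate = 0.1, seed = 23)
  w <- win_all(fx$vt, 3000)
  pm2 <- fx$pm
  wi <- which(pm2$population == "wild")
  pm2$sample[wi] <- pm2$sample[rev(wi)]     # permute labels inside wild
  expect_equal(theta_pi_windows(fx$vt, fx$pm, "wild", w)$theta_pi,
               theta_pi_windows(fx$vt, pm2, "wild", w)$theta_pi)
  expect_equal(dxy_windows(fx$vt, fx$pm, "wild", "domcn", w)$dxy,
               dxy_windows(fx$vt, pm2, "wild", "domcn", w)$dxy)
})

test_that("heterozygosity matches the tally oracle and its bounds", {
  fx <- make_test_vt(n_sites = 10, miss_rate = 0.1, seed = 29)
  h <- heterozygosity(fx$vt, fx$pm, "wild")
  g <- geno_matrix(fx$vt, fx$pm$sample[fx$pm$population == "wild"])
  ho <- mean(apply(g, 1, function(x) mean(x[!is.na(x)] == 1)))
  he <- mean(apply(g, 1, function(x) {
    cp <- .copies(x); p <- mean(cp)
    2 * p * (1 - p) * length(cp) / (length(cp) - 1)
  }))
  expect_equal(h$h_obs, ho, tolerance = 1e-12)
  expect_equal(h$h_exp, he, tolerance = 1e-12)
  # all-homozygous and all-het boundary cases
  g0 <- matrix(c(0L, 2L, 2L, 0L), 2)
  vt0 <- variant_tbl(rep("c", 2), c(1L, 2L), "A", "C", g0, c("x1", "x2"))
  pm0 <- as_popmap(tibble::tibble(sample = c("x1", "x2"), population = "p"))
  expect_equal(heterozygosity(vt0, pm0, "p")$h_obs, 0)
  g1 <- matrix(1L, 2, 2)
  vt1 <- variant_tbl(rep("c", 2), c(1L, 2L), "A", "C", g1, c("x1", "x2"))
  expect_equal(heterozygosity(vt1, pm0, "p")$h_obs, 1)
})

test_that("LD r2 matches hand formulas on constructed pairs", {
  # identical genotype columns: r2 = 1; orthogonal constructed columns: 0
  g <- cbind(c(0L, 1L, 2L, 0L, 1L, 2L),
             c(0L, 1L, 2L, 0L, 1L, 2L),
             c(0L, 2L, 1L, 2L, 1L, 0L))
  vt <- variant_tbl(rep("chr1", 3), c(100L, 200L, 300L), rep("A", 3),
                    rep("C", 3), t(g[, c(1, 2, 3)]),
                    paste0("s", 1:6))
  pm <- as_popmap(tibble::tibble(sample = paste0("s", 1:6), population = "x"))
  bins <- ld_decay(vt, pm, "x", max_dist_bp = 300, bin_width_bp = 300)
  # all three pairs fall in one bin; compute expected mean by hand
  r2_12 <- 1
  r2_13 <- cor(g[, 1], g[, 3])^2
  r2_23 <- cor(g[, 2], g[, 3])^2
  expect_equal(bins$mean_r2[1], mean(c(r2_12, r2_13, r2_23)),
               tolerance = 1e-12)
  expect_equal(bins$n_pairs[1], 3L)
})

test_that("phased LD equals the haplotype-frequency formula", {
  # 4 phased haplotypes AB, AB, aB, ab at two sites
  hap <- cbind(c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  vt <- variant_tbl(rep("chr1", 2), c(100L, 500L), rep("A", 2), rep("C", 2),
                    matrix(c(2L, 1L, 2L, 1L), 2), c("s1", "s2"))
  pm <- as_popmap(tibble::tibble(sample = c("s1", "s2"), population = "x"))
  bins <- ld_decay(vt, pm, "x", max_dist_bp = 1000, bin_width_bp = 1000,
                   haplotypes = hap)
  expect_equal(bins$mean_r2[1], oracle_hap_r2(hap[1, ], hap[2, ]),
               tolerance = 1e-12)
})

test_that("mean r2 declines with distance under linkage", {
  set.seed(31)
  ds <- simulate_recombined_locus(neutral_model(5e4), c(wild = 60),
                                  locus_bp = 3e5, crossover_rate = 3)
  conv <- sim_to_variant_tbl(ds)
  bins <- ld_decay(conv$vt, conv$popmap, "wild", max_dist_bp = 1.5e5,
                   bin_width_bp = 1.5e4)
  b <- dplyr::filter(bins, n_pairs >= 1000)
  ct <- suppressWarnings(
    cor.test(b$mean_r2, (b$dist_lo + b$dist_hi) / 2, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
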