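#' ABBA/BABA site-pattern terms
#'
#' For a four-population setting (((P1, P2), P3), O) on outgroup-polarized
#' derived-allele frequencies, computes per-site
#' `abba = (1-p1) p2 p3` and `baba = p1 (1-p2) p3` (the outgroup derived
#' frequency is 0 after polarization). Sites that cannot be polarized or
#' where any of the three ingroups is fully missing are excluded (their
#' count is attached as attribute `n_excluded`).
#'
#' @param vt A `variant_tbl`, polarized with [polarize()] (done on the fly
#'   when the `ancestral` column is absent).
#' @param pm Population map.
#' @param p1,p2,p3 Ingroup population labels (P3 the candidate introgressor).
#' @param outgroup Outgroup population label.
#' @return Tibble with `chrom`, `pos`, `p1`, `p2`, `p3`, `abba`, `baba`.
#' @export
site_patterns <- function(vt, pm, p1, p2, p3, outgroup) {
  pops <- c(p1, p2, p3)
  smp <- lapply(c(pops, outgroup), function(pp) pop_samples(pm, pp, vt_samples(vt)))
  if (anyDuplicated(unlist(smp[1:3])))
    stop("P1, P2 and P3 must not share samples")
  if (!"ancestral" %in% names(vt)) vt <- polarize(vt, pm, outgroup)
  f <- lapply(pops, function(pp) allele_freqs(vt, pm, pp, derived = TRUE))
  ok <- vt$polarizable & !is.na(f[[1]]$p) & !is.na(f[[2]]$p) & !is.na(f[[3]]$p)
  out <- tibble::tibble(chrom = vt$chrom[ok], pos = vt$pos[ok],
                        p1 = f[[1]]$p[ok], p2 = f[[2]]$p[ok], p3 = f[[3]]$p[ok])
  out$abba <- (1 - out$p1) * out$p2 * out$p3
  out$baba <- out$p1 * (1 - out$p2) * out$p3
  attr(out, "n_excluded") <- sum(!ok)
  out
}

# contiguous coordinate blocks per chromosome, last block truncated
block_id <- function(chrom, pos, block_size_bp) {
  paste(chrom, (pos - 1) %/% block_size_bp, sep = ":")
}

# Weighted delete-one-block jackknife (Busing et al. 1999) for a ratio
# estimator theta = sum(num) / sum(den) with block weights w_j = sum(den_j).
weighted_block_jackknife <- function(num_j, den_j, w_j = den_j) {
  keep <- w_j > 0
  num_j <- num_j[keep]; den_j <- den_j[keep]; w_j <- w_j[keep]
  g <- length(w_j)
  if (g < 2) stop("block jackknife needs at least 2 non-empty blocks")
  N <- sum(num_j); W <- sum(den_j); Wt <- sum(w_j)
  theta <- N / W
  loo <- (N - num_j) / (W - den_j)
  h <- Wt / w_j
  theta_j <- g * theta - sum((1 - w_j / Wt) * loo)
  tau <- h * theta - (h - 1) * loo
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(estimate = theta, se = sqrt(v), n_blocks = g,
       loo = loo, weights = w_j)
}

new_jackknife_est <- function(statistic, jk, block_size_bp, extra = list()) {
  z <- if (jk$se > 0) jk$estimate / jk$se else sign(jk$estimate) * Inf
  structure(c(list(statistic = statistic, estimate = jk$estimate, se = jk$se,
                   z = z, n_blocks = jk$n_blocks,
                   block_size_bp = block_size_bp,
                   loo = jk$loo, weights = jk$weights), extra),
            class = "jackknife_est")
}

#' @export
print.jackknife_est <- function(x, ...) {
  cat(sprintf("%s = %.6g  (SE %.4g, Z = %.3f; %d blocks of %g bp)\n",
              x$statistic, x$estimate, x$se, x$z, x$n_blocks,
              x$block_size_bp))
  invisible(x)
}

#' @export
tidy.jackknife_est <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, estimate = x$estimate,
                 std.error = x$se, z = x$z)
}

#' @export
glance.jackknife_est <- function(x, ...) {
  tibble::tibble(n_blocks = x$n_blocks, block_size_bp = x$block_size_bp)
}

#' Patterson's D with weighted block jackknife
#'
#' `D = sum(abba - baba) / sum(abba + baba)` over all usable sites; the
#' standard error comes from a weighted delete-one-block jackknife over
#' non-overlapping coordinate blocks (default 2 Mb, truncated at chromosome
#' ends), with block weight equal to its informative-site mass
#' `sum(abba + baba)`. `|Z| > 3` is the conventional strong-evidence
#' threshold for admixture.
#'
#' @param patterns Site-pattern tibble from [site_patterns()].
#' @param block_size_bp Jackknife block size in bp (default 2 Mb).
#' @param block_weights `"informative"` (default) weights each block by its
#'   informative-site mass, appropriate for contiguous genomic blocks
#'   containing many weakly correlated sites. `"uniform"` is the classic
#'   delete-one jackknife, appropriate when each block is a single
#'   independent locus whose sites share one genealogy (there the per-block
#'   ABBA-BABA excess scales with the block's mass, which violates the
#'   variance model behind mass weighting).
#' @return A `jackknife_est` (supports `tidy()`/`glance()`).
#' @export
patterson_d <- function(patterns, block_size_bp = 2e6,
                        block_weights = c("informative", "uniform")) {
  block_weights <- match.arg(block_weights)
  num <- patterns$abba - patterns$baba
  den <- patterns$abba + patterns$baba
  if (sum(den) == 0) stop("all sites uninformative: D undefined")
  b <- block_id(patterns$chrom, patterns$pos, block_size_bp)
  agg <- rowsum(cbind(num, den), b)
  w <- if (block_weights == "informative") agg[, 2] else
    as.numeric(agg[, 2] > 0)
  jk <- weighted_block_jackknife(agg[, 1], agg[, 2], w)
  new_jackknife_est("D", jk, block_size_bp)
}

#' Three-population f3 test
#'
#' `f3(A; B, C)` with the finite-sample correction for the target A:
#' per site `t = (pA - pB)(pA - pC) - hA / nA` with
#' `hA = pA (1 - pA) nA / (nA - 1)` and `nA` the non-missing haplotype
#' count. The estimate is the mean of `t` over usable sites; SE and Z come
#' from the weighted block jackknife with per-block site counts as weights.
#' Significantly negative values (conventionally `Z <= -2`) indicate that A
#' is admixed between sources related to B and C; the statistic is
#' symmetric in B and C.
#'
#' @param vt A `variant_tbl`.
#' @param pm Population map.
#' @param a Target population label.
#' @param b,c Source population labels.
#' @param block_size_bp Jackknife block size (default 2 Mb).
#' @return A `jackknife_est` with statistic `"f3"`.
#' @export
f3_test <- function(vt, pm, a, b, c, block_size_bp = 2e6) {
  fa <- allele_freqs(vt, pm, a)
  fb <- allele_freqs(vt, pm, b)
  fc <- allele_freqs(vt, pm, c)
  ok <- fa$n >= 2 & fb$n >= 1 & fc$n >= 1
  if (!any(ok)) stop("no site with >= 2 target haplotypes: f3 undefined")
  pa <- fa$p[ok]; na <- fa$n[ok]
  ha <- pa * (1 - pa) * na / (na - 1)
  t <- (pa - fb$p[ok]) * (pa - fc$p[ok]) - ha / na
  bl <- block_id(vt$chrom[ok], vt$pos[ok], block_size_bp)
  agg <- rowsum(cbind(t, 1), bl)
  jk <- weighted_block_jackknife(agg[, 1], agg[, 2])
  new_jackknife_est("f3", jk, block_size_bp,
                    extra = list(target = a, sources = c(b, c)))
}

#' Windowed fd introgression scan
#'
#' Martin et al.'s window-scale fd: per window,
#' `numerator = sum(abba - baba)` and `denominator` uses the per-site donor
#' proxy `pD = max(p2, p3)` substituted for both P2 and P3. `fd` is
#' `numerator / denominator` when the numerator is positive, else 0 (so
#' region calling is well defined); windows with fewer usable polarized
#' SNPs than `min_snps` are flagged `excluded`.
#'
#' @inheritParams site_patterns
#' @param size_bp,step_bp Window size and step (defaults 100 kb / 20 kb).
#' @param min_snps Minimum usable SNPs per window (default 100).
#' @param windows Optional window tibble; built with [make_windows()] from
#'   `vt` when omitted.
#' @param zero_negative If `FALSE`, windows with non-positive numerator get
#'   `NA` instead of 0.
#' @return Tibble of windows with `n_snps` (usable polarized sites),
#'   `excluded`, `d_window` and `fd`.
#' @export
fd_scan <- function(vt, pm, p1, p2, p3, outgroup,
                    size_bp = 1e5, step_bp = 2e4, min_snps = 100,
                    windows = NULL, zero_negative = TRUE) {
  if (is.null(windows)) windows <- make_windows(vt, size_bp, step_bp)
  pat <- site_patterns(vt, pm, p1, p2, p3, outgroup)
  pd <- pmax(pat$p2, pat$p3)
  abba_d <- (1 - pat$p1) * pd * pd
  baba_d <- pat$p1 * (1 - pd) * pd
  X <- cbind(pat$abba - pat$baba, pat$abba + pat$baba, abba_d - baba_d, 1)
  s <- window_sums(pat$chrom, pat$pos, windows, X)
  num <- s[, 1]; den_d <- s[, 3]
  d_win <- ifelse(s[, 2] > 0, num / s[, 2], NA_real_)
  fd <- dplyr::case_when(
    num <= 0 ~ if (zero_negative) 0 else NA_real_,
    den_d == 0 ~ NA_real_,
    TRUE ~ num / den_d)
  windows$n_snps <- as.integer(s[, 4])
  windows$excluded <- windows$n_snps < min_snps
  dplyr::mutate(windows, d_window = d_win, fd = fd)
}

#' Call introgressed regions from fd windows
#'
#' Windows passing the fd threshold (and not excluded) are merged when they
#' overlap or are bookended; merged spans shorter than `min_region_bp` are
#' dropped.
#'
#' @param fd_windows Output of [fd_scan()], coordinate-sorted.
#' @param fd_threshold Minimum window fd (default 0.5).
#' @param min_region_bp Minimum merged span (default 200 kb).
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_fd`, `mean_fd`.
#' @export
call_introgressed_regions <- function(fd_windows, fd_threshold = 0.5,
                                      min_region_bp = 2e5) {
  w <- dplyr::filter(fd_windows, !.data$excluded, !is.na(.data$fd),
                     .data$fd >= fd_threshold)
  if (!nrow(w)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_fd = numeric(), mean_fd = numeric()))
  }
  w <- dplyr::arrange(w, .data$chrom, .data$start)
  w$region <- merge_run_ids(w$chrom, w$start, w$end)
  reg <- dplyr::summarise(
    dplyr::group_by(w, .data$region),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    n_windows = dplyr::n(), peak_fd = max(.data$fd), mean_fd = mean(.data$fd),
    .groups = "drop")
  reg <- dplyr::filter(reg, .data$end - .data$start + 1 >= min_region_bp)
  dplyr::select(reg, -"region")
}

# assign run ids to sorted intervals, merging overlapping/bookended ones
merge_run_ids <- function(chrom, start, end) {
  id <- integer(length(chrom))
  rid <- 0L; cur_chrom <- ""; cur_end <- -Inf
  for (i in seq_along(chrom)) {
    if (chrom[i] != cur_chrom || start[i] > cur_end + 1) {
      rid <- rid + 1L; cur_chrom <- chrom[i]; cur_end <- end[i]
    } else {
      cur_end <- max(cur_end, end[i])
    }
    id[i] <- rid
  }
  id
}

#' Verify a candidate introgressed region with dxy and FST contrasts
#'
#' Gene flow reduces dxy between recipient and donor inside the introgressed
#' region, while shared ancestral polymorphism does not; FST shows the same
#' contrast. The region's dxy/FST against the donor and against a
#' non-donor control group are each compared with a genome background built
#' from all windows of the region's size.
#'
#' @param region One-row tibble (`chrom`, `start`, `end`).
#' @param vt A `variant_tbl`.
#' @param pm Population map.
#' @param recipient,donor_group,control_group Population labels.
#' @return One-row tibble: region coordinates plus, for each of
#'   donor/control, the region dxy and FST, background means/SDs and
#'   z-scores (`(region - bg_mean) / bg_sd`).
#' @export
verify_region <- function(region, vt, pm, recipient, donor_group,
                          control_group) {
  size <- region$end[1] - region$start[1] + 1
  bg <- make_windows(vt, size_bp = size, step_bp = size)
  rw <- tibble::tibble(chrom = region$chrom[1], start = region$start[1],
                       end = region$end[1], n_snps = NA_integer_,
                       excluded = FALSE)
  one <- function(other) {
    d_bg <- dxy_windows(vt, pm, recipient, other, bg)$dxy
    f_bg <- fst_windows(vt, pm, recipient, other, bg)$fst
    d_r <- dxy_windows(vt, pm, recipient, other, rw)$dxy
    f_r <- fst_windows(vt, pm, recipient, other, rw)$fst
    c(dxy = d_r, dxy_bg_mean = mean(d_bg, na.rm = TRUE),
      dxy_bg_sd = sd(d_bg, na.rm = TRUE),
      dxy_z = (d_r - mean(d_bg, na.rm = TRUE)) / sd(d_bg, na.rm = TRUE),
      fst = f_r, fst_bg_mean = mean(f_bg, na.rm = TRUE),
      fst_bg_sd = sd(f_bg, na.rm = TRUE),
      fst_z = (f_r - mean(f_bg, na.rm = TRUE)) / sd(f_bg, na.rm = TRUE))
  }
  don <- one(donor_group)
  ctl <- one(control_group)
  names(don) <- paste0("donor_", names(don))
  names(ctl) <- paste0("control_", names(ctl))
  dplyr::bind_cols(region[1, c("chrom", "start", "end")],
                   tibble::as_tibble(as.list(c(don, ctl))))
}

#' Genes overlapping regions
#'
#' Interval intersection (1 bp of overlap suffices) between regions and gene
#' spans.
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param genes Gene tibble from [read_gff_genes()].
#' @return Tibble of region-gene pairs (region coordinates + `gene_id`,
#'   `gene_start`, `gene_end`).
#' @export
region_genes <- function(regions, genes) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start <= regions$end[i] & genes$end >= regions$start[i]
    if (!any(hit)) return(tibble::tibble())
    dplyr::bind_cols(regions[rep(i, sum(hit)), c("chrom", "start", "end")],
                     tibble::tibble(gene_id = genes$gene_id[hit],
                                    gene_start = genes$start[hit],
                                    gene_end = genes$end[hit]))
  })
}
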