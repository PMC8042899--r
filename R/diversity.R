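# Per-site allele-count summaries for one population: alt count (ac),
# called haplotypes (an), het-genotype count (nhet), called individuals (nind).
pop_site_counts <- function(vt, pm, population) {
  g <- geno_matrix(vt, pop_samples(pm, population, vt_samples(vt)))
  called <- !is.na(g)
  list(ac = rowSums(g, na.rm = TRUE),
       an = 2L * rowSums(called),
       nhet = rowSums(g == 1L, na.rm = TRUE),
       nind = rowSums(called))
}

# Sum per-site columns of X over windows; sites assumed position-sorted
# within chromosome. Returns windows x cols matrix.
window_sums <- function(chrom, pos, windows, X) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(windows), ncol(X))
  for (cc in unique(windows$chrom)) {
    wi <- which(windows$chrom == cc)
    si <- which(chrom == cc)
    if (!length(si)) next
    p <- pos[si]
    cs <- apply(X[si, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, matrix(cs, ncol = ncol(X)))
    lo <- findInterval(windows$start[wi] - 1L, p)
    hi <- findInterval(windows$end[wi], p)
    out[wi, ] <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  out
}

# per-site nucleotide diversity 2p(1-p) * n/(n-1); 0 where n < 2
site_pi <- function(ac, an) {
  p <- ifelse(an > 0, ac / an, 0)
  ifelse(an >= 2, 2 * p * (1 - p) * an / (an - 1), 0)
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Per-site diversity `2p(1-p) n/(n-1)` summed over SNPs in each window and
#' divided by the window length in bp (non-variant positions are implicitly
#' monomorphic).
#'
#' @param vt A `variant_tbl`.
#' @param pm Population map.
#' @param population Population label.
#' @param windows Window tibble from [make_windows()].
#' @return `windows` with a `theta_pi` column (per bp).
#' @export
theta_pi_windows <- function(vt, pm, population, windows) {
  cnt <- pop_site_counts(vt, pm, population)
  s <- window_sums(vt$chrom, vt$pos, windows, site_pi(cnt$ac, cnt$an))
  dplyr::mutate(windows, theta_pi = s[, 1] / (.data$end - .data$start + 1))
}

tajima_constants <- function(n) {
  # n = number of sequences (haplotypes)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

modal_count <- function(x) {
  if (!length(x)) return(NA_integer_)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Windowed Tajima's D
#'
#' Standard Tajima (1989) D per window from the segregating-site count and
#' the mean-pairwise-difference sum. The normalizing constants use the
#' window's modal non-missing haplotype count; sites with a different count
#' contribute their own frequencies.
#'
#' @inheritParams theta_pi_windows
#' @return `windows` with columns `S` (segregating sites used) and
#'   `tajimas_d` (`NA` where `S = 0` or fewer than 3 haplotypes).
#' @export
tajima_d_windows <- function(vt, pm, population, windows) {
  cnt <- pop_site_counts(vt, pm, population)
  seg <- cnt$an >= 2 & cnt$ac > 0 & cnt$ac < cnt$an
  pi_s <- site_pi(cnt$ac, cnt$an)
  pi_s[!seg] <- 0
  sums <- window_sums(vt$chrom, vt$pos, windows, cbind(as.numeric(seg), pi_s))
  d <- rep(NA_real_, nrow(windows))
  pos_by <- split(seq_len(nrow(vt)), vt$chrom)
  for (i in seq_len(nrow(windows))) {
    si <- pos_by[[windows$chrom[i]]]
    if (is.null(si)) next
    inw <- si[vt$pos[si] >= windows$start[i] & vt$pos[si] <= windows$end[i]]
    inw <- inw[seg[inw]]
    S <- sums[i, 1]
    if (S < 1) next
    n <- modal_count(cnt$an[inw])
    if (is.na(n) || n < 3) next
    k <- tajima_constants(n)
    vd <- k$e1 * S + k$e2 * S * (S - 1)
    if (vd <= 0) next
    d[i] <- (sums[i, 2] - S / k$a1) / sqrt(vd)
  }
  dplyr::mutate(windows, S = as.integer(sums[, 1]), tajimas_d = d)
}

#' Windowed absolute divergence (dxy)
#'
#' Per-site `pA(1-pB) + pB(1-pA)` summed over SNPs and divided by window
#' length in bp; symmetric in the two populations. Sites where either
#' population is fully missing are skipped.
#'
#' @inheritParams theta_pi_windows
#' @param pop_a,pop_b Population labels.
#' @return `windows` with a `dxy` column (per bp).
#' @export
dxy_windows <- function(vt, pm, pop_a, pop_b, windows) {
  a <- pop_site_counts(vt, pm, pop_a)
  b <- pop_site_counts(vt, pm, pop_b)
  ok <- a$an > 0 & b$an > 0
  pa <- ifelse(ok, a$ac / pmax(a$an, 1), 0)
  pb <- ifelse(ok, b$ac / pmax(b$an, 1), 0)
  dsite <- ifelse(ok, pa * (1 - pb) + pb * (1 - pa), 0)
  s <- window_sums(vt$chrom, vt$pos, windows, dsite)
  dplyr::mutate(windows, dxy = s[, 1] / (.data$end - .data$start + 1))
}

# Weir & Cockerham (1984) variance components for two populations at one
# vectorized set of sites. Inputs per population: p (alt freq), n (called
# individuals), h (het fraction among called). Returns a, b, c vectors.
wc_components <- function(p1, n1, h1, p2, n2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Hudson FST numerator/denominator per site: the plain frequency form
# 1 - Hw/Hb, i.e. num = (p1-p2)^2, den = p1(1-p2) + p2(1-p1); identical
# frequency vectors therefore give exactly 0.
hudson_terms <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Windowed FST between two populations
#'
#' Weir & Cockerham (1984) variance components or Hudson's estimator, each
#' combined over the window as a ratio of sums (the weighted convention),
#' never a mean of per-site ratios. Negative windowed values are reported as
#' computed.
#'
#' @inheritParams dxy_windows
#' @param estimator `"weir-cockerham"` (default) or `"hudson"`.
#' @return `windows` with an `fst` column (`NA` where no usable site).
#' @export
fst_windows <- function(vt, pm, pop_a, pop_b, windows,
                        estimator = c("weir-cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  a <- pop_site_counts(vt, pm, pop_a)
  b <- pop_site_counts(vt, pm, pop_b)
  if (estimator == "weir-cockerham") {
    ok <- a$nind > 0 & b$nind > 0 & (a$nind + b$nind) > 2
    p1 <- a$ac / pmax(a$an, 1); p2 <- b$ac / pmax(b$an, 1)
    h1 <- a$nhet / pmax(a$nind, 1); h2 <- b$nhet / pmax(b$nind, 1)
    w <- wc_components(p1, a$nind, h1, p2, b$nind, h2)
    num <- ifelse(ok, w$a, 0)
    den <- ifelse(ok, w$a + w$b + w$c, 0)
  } else {
    ok <- a$an >= 2 & b$an >= 2
    p1 <- a$ac / pmax(a$an, 1); p2 <- b$ac / pmax(b$an, 1)
    h <- hudson_terms(p1, a$an, p2, b$an)
    num <- ifelse(ok, h$num, 0)
    den <- ifelse(ok, h$den, 0)
  }
  num[is.na(num)] <- 0; den[is.na(den)] <- 0
  s <- window_sums(vt$chrom, vt$pos, windows, cbind(num, den))
  dplyr::mutate(windows, fst = ifelse(s[, 2] != 0, s[, 1] / s[, 2], NA_real_))
}

#' Observed and expected heterozygosity per population
#'
#' `H_O` is the fraction of heterozygous genotypes among non-missing calls,
#' averaged over sites; `H_E` is `2p(1-p)` with the small-sample correction
#' `2n/(2n-1)` (2n = called haplotypes), averaged over sites.
#'
#' @param vt A `variant_tbl`.
#' @param pm Population map.
#' @param populations Populations to report (default: all ingroup).
#' @return Tibble with `population`, `n_sites`, `h_obs`, `h_exp`.
#' @export
heterozygosity <- function(vt, pm,
                           populations = unique(pm$population[pm$role == "ingroup"])) {
  purrr::map_dfr(populations, function(pp) {
    cnt <- pop_site_counts(vt, pm, pp)
    ok <- cnt$nind > 0
    ho <- mean(cnt$nhet[ok] / cnt$nind[ok])
    ok2 <- cnt$an >= 2
    p <- cnt$ac[ok2] / cnt$an[ok2]
    he <- mean(2 * p * (1 - p) * cnt$an[ok2] / (cnt$an[ok2] - 1))
    tibble::tibble(population = pp, n_sites = sum(ok), h_obs = ho, h_exp = he)
  })
}

#' Linkage-disequilibrium decay
#'
#' Mean r-squared between SNP pairs binned by physical distance. On unphased
#' genotypes (the default), r-squared is the squared correlation of the
#' 0/1/2 allele-count columns (composite LD); with `haplotypes` supplied,
#' the haplotype-frequency r-squared `D^2 / (p(1-p) q(1-q))` is computed,
#' which equals the squared correlation of the 0/1 haplotype columns.
#'
#' @inheritParams theta_pi_windows
#' @param max_dist_bp Maximum pair separation considered.
#' @param bin_width_bp Width of the distance bins.
#' @param haplotypes Optional 0/1 matrix (sites x haplotypes, rows matching
#'   `vt`) for phased mode.
#' @return Tibble of bins: `dist_lo`, `dist_hi` (bp, `[lo, hi)`), `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(vt, pm, population, max_dist_bp = 50000,
                     bin_width_bp = 1000, haplotypes = NULL) {
  g <- if (is.null(haplotypes)) {
    geno_matrix(vt, pop_samples(pm, population, vt_samples(vt)))
  } else {
    as.matrix(haplotypes)
  }
  mode(g) <- "numeric"
  nb <- ceiling(max_dist_bp / bin_width_bp)
  sum_r2 <- cnt <- numeric(nb)
  for (cc in unique(vt$chrom)) {
    si <- which(vt$chrom == cc)
    if (length(si) < 2) next
    p <- vt$pos[si]
    X <- g[si, , drop = FALSE]
    M <- !is.na(X)
    X0 <- X; X0[!M] <- 0
    m <- length(si)
    for (d in seq_len(m - 1)) {
      dist <- p[(1 + d):m] - p[1:(m - d)]
      if (min(dist) > max_dist_bp) break
      sel <- which(dist <= max_dist_bp)
      ia <- sel; ib <- sel + d
      W <- M[ia, , drop = FALSE] & M[ib, , drop = FALSE]
      n <- rowSums(W)
      Xa <- X0[ia, , drop = FALSE] * W; Xb <- X0[ib, , drop = FALSE] * W
      sx <- rowSums(Xa); sy <- rowSums(Xb)
      sxx <- rowSums(Xa^2); syy <- rowSums(Xb^2); sxy <- rowSums(Xa * Xb)
      vx <- n * sxx - sx^2; vy <- n * syy - sy^2
      ok <- vx > 0 & vy > 0
      r2 <- (n * sxy - sx * sy)^2 / (vx * vy)
      bin <- pmin(pmax(ceiling(dist[sel] / bin_width_bp), 1L), nb)
      keep <- ok & n >= 2
      if (!any(keep)) next
      tb <- rowsum(cbind(r2[keep], 1), bin[keep])
      idx <- as.integer(rownames(tb))
      sum_r2[idx] <- sum_r2[idx] + tb[, 1]
      cnt[idx] <- cnt[idx] + tb[, 2]
    }
  }
  tibble::tibble(dist_lo = (seq_len(nb) - 1) * bin_width_bp,
                 dist_hi = seq_len(nb) * bin_width_bp,
                 mean_r2 = ifelse(cnt > 0, sum_r2 / cnt, NA_real_),
                 n_pairs = as.integer(cnt))
}
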