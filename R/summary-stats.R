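# Tajima's D from a segregating-site count and the pairwise-diversity sum,
# with constants for n sequences; 0 is returned (imputation, documented)
# when the statistic is undefined (S = 0, n < 3, or degenerate variance).
tajima_d_value <- function(S, pi_sum, n, impute = NA_real_) {
  if (is.na(n) || S < 1 || n < 3) return(impute)
  k <- tajima_constants(n)
  vd <- k$e1 * S + k$e2 * S * (S - 1)
  if (vd <= 0) return(impute)
  (pi_sum - S / k$a1) / sqrt(vd)
}

# One definition of every summary statistic, shared by the simulated and
# empirical paths. `counts` is a named list (one entry per population) of
# per-site vectors ac / an / nhet / nind over a common site set.
summary_stat_vector <- function(counts, total_bp) {
  pops <- names(counts)
  seg <- lapply(counts, function(cn) cn$an >= 2 & cn$ac > 0 & cn$ac < cn$an)
  out <- c()
  pi_per_pop <- numeric(length(pops))
  names(pi_per_pop) <- pops
  for (pp in pops) {
    cn <- counts[[pp]]
    sg <- seg[[pp]]
    other_seg <- Reduce(`|`, seg[setdiff(pops, pp)], rep(FALSE, length(sg)))
    S <- sum(sg)
    pi_sum <- sum(site_pi(cn$ac, cn$an))
    pi_per_pop[pp] <- pi_sum / total_bp
    ok <- cn$an >= 2
    p <- cn$ac[ok] / cn$an[ok]
    he <- if (any(ok)) mean(2 * p * (1 - p) * cn$an[ok] / (cn$an[ok] - 1)) else 0
    st <- c(S = S,
            sing = sum(cn$ac == 1),
            privS = sum(sg & !other_seg),
            pi = pi_sum / total_bp,
            tajd = tajima_d_value(S, pi_sum, modal_count(cn$an[sg]), impute = 0),
            he = he)
    names(st) <- paste0(names(st), "_", pp)
    out <- c(out, st)
  }
  ac_all <- Reduce(`+`, lapply(counts, `[[`, "ac"))
  an_all <- Reduce(`+`, lapply(counts, `[[`, "an"))
  sg_all <- an_all >= 2 & ac_all > 0 & ac_all < an_all
  pi_all_sum <- sum(site_pi(ac_all, an_all))
  okA <- an_all >= 2
  pA <- ac_all[okA] / an_all[okA]
  heA <- if (any(okA)) mean(2 * pA * (1 - pA) * an_all[okA] / (an_all[okA] - 1)) else 0
  out <- c(out, S_all = sum(sg_all), pi_all = pi_all_sum / total_bp,
           tajd_all = tajima_d_value(sum(sg_all), pi_all_sum,
                                     modal_count(an_all[sg_all]), impute = 0),
           he_all = heA)
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1)) {
      for (j in seq(i + 1, length(pops))) {
        a <- counts[[i]]; b <- counts[[j]]
        okp <- a$nind > 0 & b$nind > 0 & (a$nind + b$nind) > 2
        p1 <- a$ac / pmax(a$an, 1); p2 <- b$ac / pmax(b$an, 1)
        w <- wc_components(p1, a$nind, a$nhet / pmax(a$nind, 1),
                           p2, b$nind, b$nhet / pmax(b$nind, 1))
        fst_num <- sum(w$a[okp]); fst_den <- sum((w$a + w$b + w$c)[okp])
        okd <- a$an > 0 & b$an > 0
        dxy <- sum((p1 * (1 - p2) + p2 * (1 - p1))[okd]) / total_bp
        st <- c(fst = if (fst_den != 0) fst_num / fst_den else 0,
                dxy = dxy,
                da = dxy - (pi_per_pop[[i]] + pi_per_pop[[j]]) / 2,
                sharedS = sum(seg[[i]] & seg[[j]]),
                fixed = sum(okd & abs(p1 - p2) == 1))
        names(st) <- paste0(names(st), "_", pops[i], "_", pops[j])
        out <- c(out, st)
      }
    }
  }
  out
}

#' Summary-statistic vector of a dataset
#'
#' A fixed-order named vector (37 statistics for three populations) used as
#' the ABC summary layer: per population S, derived singletons, private S,
#' theta-pi (per bp), Tajima's D and expected heterozygosity; the same four
#' pooled over populations; and per pair FST (Weir-Cockerham, ratio of
#' sums), dxy, net divergence da, shared polymorphic sites and fixed
#' differences. Undefined Tajima's D (S = 0) is imputed as 0 so vectors stay
#' finite for PLS. The same statistic definitions back both the simulated
#' and empirical paths.
#'
#' @param x A `sim_dataset` (haplotypes are paired into pseudo-diploids) or
#'   a `variant_tbl`.
#' @param ... Method arguments.
#' @return Named numeric vector.
#' @export
summarize_dataset <- function(x, ...) UseMethod("summarize_dataset")

#' @rdname summarize_dataset
#' @param populations Populations to include (default: the dataset's sampled
#'   demes / the map's ingroups).
#' @export
summarize_dataset.sim_dataset <- function(x, populations = NULL, ...) {
  pops <- populations %||% setdiff(unique(x$hap_pop), "outgroup")
  h1 <- seq(1, length(x$hap_pop), by = 2)
  geno <- x$haps[, h1, drop = FALSE] + x$haps[, h1 + 1, drop = FALSE]
  ind_pop <- x$hap_pop[h1]
  counts <- lapply(stats::setNames(pops, pops), function(pp) {
    g <- geno[, ind_pop == pp, drop = FALSE]
    list(ac = rowSums(g), an = rep(2L * ncol(g), nrow(g)),
         nhet = rowSums(g == 1L), nind = rep(ncol(g), nrow(g)))
  })
  summary_stat_vector(counts, x$total_bp)
}

#' @rdname summarize_dataset
#' @param pm Population map (variant-table method).
#' @param total_bp Sequence length represented by the table; defaults to the
#'   sum of the `chrom_lengths` attribute.
#' @export
summarize_dataset.variant_tbl <- function(x, pm, populations = NULL,
                                          total_bp = NULL, ...) {
  pops <- populations %||% unique(pm$population[pm$role == "ingroup"])
  if (is.null(total_bp)) {
    cl <- attr(x, "chrom_lengths")
    if (is.null(cl)) stop("total_bp required when the table has no contig lengths")
    total_bp <- sum(cl)
  }
  counts <- lapply(stats::setNames(pops, pops),
                   function(pp) pop_site_counts(x, pm, pp))
  summary_stat_vector(counts, total_bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
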