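#' Joint theta-pi-ratio / Z(FST) selective-sweep scan
#'
#' Contrasts a wild and a domestic group in sliding windows (default
#' 40 kb / 10 kb). For every usable window the scan reports
#' `log2_pi_ratio = log2(theta_pi_wild / theta_pi_dom)` and the
#' Z-transformed FST, `z_fst = (fst - mean) / sd` over included windows.
#' Outlier windows are those jointly above the empirical upper `1 - quantile`
#' tails of both scores, the thresholds being recomputed from the data at
#' hand. Windows where the domestic group has zero diversity cannot enter
#' the ratio distribution and are flagged `fixed_dom` instead of being given
#' a pseudo-count; windows below `min_snps` are excluded from both threshold
#' estimation and outlier calling. Tajima's D for both groups is reported
#' alongside but is not part of the outlier criterion.
#'
#' @param vt A `variant_tbl`.
#' @param pm Population map.
#' @param wild_pop,domestic_pop Population labels being contrasted.
#' @param size_bp,step_bp Window size and step (defaults 40 kb / 10 kb).
#' @param quantile_cut Outlier quantile (default 0.95, i.e. top 5%).
#' @param min_snps Minimum SNPs per window to be usable.
#' @param estimator FST estimator, see [fst_windows()].
#' @return A `sweep_scan` tibble: window coordinates, `n_snps`,
#'   `theta_pi_wild`, `theta_pi_dom`, `log2_pi_ratio`, `fst`, `z_fst`,
#'   `tajimas_d_wild`, `tajimas_d_dom`, `included`, `fixed_dom`, `outlier`;
#'   thresholds are attached as attributes `log2_ratio_cut` and `z_fst_cut`.
#' @export
sweep_scan <- function(vt, pm, wild_pop, domestic_pop,
                       size_bp = 4e4, step_bp = 1e4, quantile_cut = 0.95,
                       min_snps = 10, estimator = "weir-cockerham") {
  win <- make_windows(vt, size_bp, step_bp, min_snps = min_snps)
  pw <- theta_pi_windows(vt, pm, wild_pop, win)$theta_pi
  pd <- theta_pi_windows(vt, pm, domestic_pop, win)$theta_pi
  fst <- fst_windows(vt, pm, wild_pop, domestic_pop, win,
                     estimator = estimator)$fst
  tw <- tajima_d_windows(vt, pm, wild_pop, win)$tajimas_d
  td <- tajima_d_windows(vt, pm, domestic_pop, win)$tajimas_d
  win <- dplyr::mutate(win, theta_pi_wild = pw, theta_pi_dom = pd, fst = fst,
                       tajimas_d_wild = tw, tajimas_d_dom = td)
  sweep_call_outliers(win, quantile_cut = quantile_cut)
}

#' Call joint top-tail outliers on a sweep window table
#'
#' The quantile machinery behind [sweep_scan()], exposed so that window
#' tables with externally computed statistics can be re-thresholded. Input
#' needs columns `theta_pi_wild`, `theta_pi_dom`, `fst` and (optionally)
#' `excluded`.
#'
#' @param win Window tibble with the statistic columns above.
#' @param quantile_cut Joint outlier quantile (default 0.95).
#' @return The `sweep_scan` tibble documented in [sweep_scan()].
#' @export
sweep_call_outliers <- function(win, quantile_cut = 0.95) {
  if (!"excluded" %in% names(win)) win$excluded <- FALSE
  usable <- !win$excluded & !is.na(win$fst)
  if (sum(usable) < 20)
    stop("fewer than 20 usable windows: quantile thresholds are meaningless")
  pw <- win$theta_pi_wild; pd <- win$theta_pi_dom
  fixed_dom <- usable & pd == 0
  included <- usable & pd > 0
  lr <- ifelse(included, log2(pw / pd), NA_real_)
  mu <- mean(win$fst[included]); sg <- sd(win$fst[included])
  z <- ifelse(usable, if (sg > 0) (win$fst - mu) / sg else 0, NA_real_)
  lr_cut <- quantile(lr[included], quantile_cut, names = FALSE, na.rm = TRUE)
  z_cut <- quantile(z[included], quantile_cut, names = FALSE)
  out <- dplyr::mutate(win,
    log2_pi_ratio = lr, z_fst = z,
    included = included, fixed_dom = fixed_dom,
    outlier = included & !is.na(lr) & lr > lr_cut & z > z_cut)
  attr(out, "log2_ratio_cut") <- lr_cut
  attr(out, "z_fst_cut") <- z_cut
  attr(out, "quantile_cut") <- quantile_cut
  class(out) <- unique(c("sweep_scan", class(out)))
  out
}

#' Merge outlier windows into sweep regions and annotate genes
#'
#' Overlapping or bookended outlier windows are merged into candidate sweep
#' regions; genes whose span intersects a region by at least 1 bp are
#' listed.
#'
#' @param scan A `sweep_scan` tibble (or any window tibble with an
#'   `outlier` column).
#' @param genes Optional gene tibble from [read_gff_genes()].
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `max_z_fst`, `max_log2_pi_ratio`, and `genes` (comma-separated ids,
#'   when `genes` given).
#' @export
merge_and_annotate <- function(scan, genes = NULL) {
  w <- dplyr::arrange(dplyr::filter(scan, .data$outlier),
                      .data$chrom, .data$start)
  if (!nrow(w)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          max_z_fst = numeric(),
                          max_log2_pi_ratio = numeric()))
  }
  w$region <- merge_run_ids(w$chrom, w$start, w$end)
  reg <- dplyr::summarise(
    dplyr::group_by(w, .data$region),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    n_windows = dplyr::n(), max_z_fst = max(.data$z_fst),
    max_log2_pi_ratio = max(.data$log2_pi_ratio), .groups = "drop")
  reg <- dplyr::select(reg, -"region")
  if (!is.null(genes)) {
    reg$genes <- vapply(seq_len(nrow(reg)), function(i) {
      hit <- genes$chrom == reg$chrom[i] & genes$start <= reg$end[i] &
        genes$end >= reg$start[i]
      paste(genes$gene_id[hit], collapse = ",")
    }, character(1))
  }
  reg
}
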