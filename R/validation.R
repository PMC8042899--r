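# Calibration experiments: the self-checks a scan of this kind should pass
# before being believed on real data. Each returns per-replicate tibbles so
# rates and means can be recomputed downstream.

#' Null calibration of the D statistic
#'
#' Simulates the four-population tree with no migration, computes genome-wide
#' D with the 2-Mb weighted block jackknife for each replicate (independent
#' loci are spaced onto separate blocks), and returns the per-replicate
#' estimates. P1 and P2 are two subsamples of the domestic deme (mirroring
#' the common design in which one unadmixed domestic breed serves as P1
#' against the other domestic populations), so they are exchangeable and
#' E\[D\] = 0 exactly.
#' Under the null, |Z| > 3 should be rare.
#'
#' @param n_reps Number of replicate genomes.
#' @param n_loci,locus_bp Loci per replicate and locus length.
#' @param sample_sizes Haploid sample sizes per deme (outgroup included);
#'   the domestic sample is split evenly into P1 and P2.
#' @param model Demography; defaults to the fixture demography (which has
#'   no migration).
#' @param block_size_bp Jackknife block size.
#' @param seed Seed.
#' @return Tibble: `rep`, `d`, `se`, `z`.
#' @export
null_d_calibration <- function(n_reps = 200, n_loci = 100, locus_bp = 5000,
                               sample_sizes = c(domcn = 40, seasa = 20,
                                                outgroup = 8),
                               model = scenario_config()$model,
                               block_size_bp = 2e6, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    ds <- simulate_dataset(model, sample_sizes, n_loci = n_loci,
                           locus_bp = locus_bp)
    conv <- sim_to_variant_tbl(ds, locus_spacing_bp = block_size_bp)
    pm <- conv$popmap
    di <- which(pm$population == "domcn")
    pm$population[di[seq_len(floor(length(di) / 2))]] <- "domcn1"
    pat <- site_patterns(conv$vt, pm, "domcn1", "domcn", "seasa", "outgroup")
    # one locus per block: uniform block weights (see ?patterson_d)
    dj <- patterson_d(pat, block_size_bp = block_size_bp,
                      block_weights = "uniform")
    tibble::tibble(rep = r, d = dj$estimate, se = dj$se, z = dj$z)
  })
}

# single-chromosome recovery scenario shared by the two planted-signal
# calibrations; interval fixed at 2.0-2.4 Mb of a 5-Mb chromosome
recovery_cfg <- function(seed, kind = c("introgression", "sweep", "ils"),
                         fraction = 0.5) {
  kind <- match.arg(kind)
  base <- list(chrom = "chr1", start = 2000001, end = 2400000)
  model <- scenario_config()$model
  if (kind == "ils") {
    # shared ancestral polymorphism only: deep ancestral size, no plant
    model$ne[c("anc")] <- 10 * model$ne[["anc"]]
  }
  scenario_config(
    chrom_lengths = c(chr1 = 5e6),
    model = model,
    introgression = if (kind == "introgression")
      c(list(donor = "seasa", recipient = "domcn"), base,
        list(fraction = fraction)),
    sweep = if (kind == "sweep") c(base[c("chrom", "start", "end")],
                                   list(deme = "domcn", new_muts = 0.5)),
    seed = seed)
}

#' Planted-introgression recovery across seeds
#'
#' For each seed, plants a 400-kb donor tract (donor fraction as given) and
#' asks (i) whether the genome's maximum-fd window overlaps the truth tract
#' and (ii) whether recipient-donor dxy inside the tract falls below the
#' genome background mean. With `kind = "ils"`, no tract is planted and the
#' ancestral population is made 10x larger instead, so any apparent
#' dxy reduction at the probed interval reflects shared ancestry alone -
#' gene flow reduces dxy, incomplete lineage sorting does not.
#'
#' @param n_seeds Number of independent fixtures.
#' @param seed Base seed (fixture `i` uses `seed * 1000 + i`).
#' @param fraction Donor fraction for the planted tract.
#' @param kind `"introgression"` or `"ils"` (control).
#' @return Tibble: `seed`, `max_fd_hit`, `tract_dxy`, `bg_mean`, `bg_sd`,
#'   `dxy_z`, `dxy_below_bg`.
#' @export
introgression_recovery <- function(n_seeds = 20, seed = 1, fraction = 0.5,
                                   kind = c("introgression", "ils")) {
  kind <- match.arg(kind)
  truth <- tibble::tibble(chrom = "chr1", start = 2000001, end = 2400000)
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- recovery_cfg(seed * 1000 + i, kind = kind, fraction = fraction)
    fx <- generate_fixture(cfg)
    fd <- fd_scan(fx$vt, fx$popmap, "wild", "domcn", "seasa", "outgroup")
    ok <- !fd$excluded & !is.na(fd$fd)
    top <- fd[ok, ][which.max(fd$fd[ok]), ]
    hit <- top$start <= truth$end & top$end >= truth$start
    ver <- verify_region(truth, fx$vt, fx$popmap, recipient = "domcn",
                         donor_group = "seasa", control_group = "wild")
    tibble::tibble(seed = cfg$seed, max_fd_hit = hit,
                   tract_dxy = ver$donor_dxy, bg_mean = ver$donor_dxy_bg_mean,
                   bg_sd = ver$donor_dxy_bg_sd, dxy_z = ver$donor_dxy_z,
                   dxy_below_bg = ver$donor_dxy < ver$donor_dxy_bg_mean)
  })
}

#' Planted-sweep recovery and permutation false-positive rate
#'
#' For each seed, plants a homogenized 400-kb interval in the domestic group
#' and asks whether the joint top-5% rule flags a window overlapping it.
#' With `permuted = TRUE` the wild/domestic labels are shuffled before
#' scanning (no plant is visible to a label-randomized contrast), and the
#' joint outlier fraction estimates the false-positive rate.
#'
#' @param n_seeds Number of fixtures.
#' @param seed Base seed.
#' @param permuted Shuffle group labels before scanning.
#' @return Tibble: `seed`, `recovered`, `outlier_fraction`.
#' @export
sweep_recovery <- function(n_seeds = 20, seed = 1, permuted = FALSE) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- recovery_cfg(seed * 1000 + i, kind = "sweep")
    fx <- generate_fixture(cfg)
    pm <- fx$popmap
    if (permuted) {
      set.seed(cfg$seed + 7)
      grp <- pm$population %in% c("wild", "domcn")
      pm$population[grp] <- sample(pm$population[grp])
    }
    sc <- sweep_scan(fx$vt, pm, "wild", "domcn")
    hit <- any(sc$outlier & sc$start <= 2400000 & sc$end >= 2000001)
    tibble::tibble(seed = cfg$seed, recovered = hit,
                   outlier_fraction = mean(sc$outlier[sc$included]))
  })
}

#' Neutral-expectation check of the coalescent simulator
#'
#' Constant-size single deme: compares mean per-bp diversity with
#' `4 Ne mu`, the mean per-locus segregating-site count with
#' `theta a1 L`, and mean Tajima's D with 0, reporting Monte-Carlo
#' standard errors.
#'
#' @param ne Diploid size.
#' @param n_haps Haploid sample size.
#' @param n_loci,locus_bp Simulation scale.
#' @param mu Mutation rate.
#' @param seed Seed.
#' @return One-row tibble with observed values, expectations and MC SEs.
#' @export
simulator_neutrality <- function(ne = 2e4, n_haps = 10, n_loci = 2000,
                                 locus_bp = 5000, mu = 1.91e-9, seed = 1) {
  model <- demographic_model(ne = c(wild = ne, domcn = ne, seasa = ne,
                                    anc = ne), t1 = 100, t0 = 200, mu = mu)
  set.seed(seed)
  ds <- simulate_dataset(model, c(wild = n_haps), n_loci = n_loci,
                         locus_bp = locus_bp)
  theta <- 4 * ne * mu
  per_locus_pi <- vapply(seq_len(n_loci), function(l) {
    ix <- which(ds$locus == l)
    if (!length(ix)) return(0)
    p <- rowMeans(ds$haps[ix, , drop = FALSE])
    sum(2 * p * (1 - p) * n_haps / (n_haps - 1)) / locus_bp
  }, 0)
  S_per_locus <- tabulate(ds$locus, n_loci)
  tajd <- vapply(seq_len(n_loci), function(l) {
    ix <- which(ds$locus == l)
    if (length(ix) < 1) return(NA_real_)
    p <- rowMeans(ds$haps[ix, , drop = FALSE])
    pi_sum <- sum(2 * p * (1 - p) * n_haps / (n_haps - 1))
    tajima_d_value(length(ix), pi_sum, n_haps)
  }, 0)
  tajd <- tajd[!is.na(tajd)]
  a1 <- sum(1 / seq_len(n_haps - 1))
  tibble::tibble(
    pi_hat = mean(per_locus_pi), pi_expected = theta,
    pi_se = sd(per_locus_pi) / sqrt(n_loci),
    s_hat = mean(S_per_locus), s_expected = theta * a1 * locus_bp,
    s_se = sd(S_per_locus) / sqrt(n_loci),
    tajd_mean = mean(tajd), tajd_se = sd(tajd) / sqrt(length(tajd)),
    n_loci = n_loci)
}
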