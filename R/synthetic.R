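#' Configure a synthetic study-like scenario
#'
#' Describes the fixture the generator emulates: three diverged populations
#' (wild, Chinese-domestic `domcn`, Southeast/South-Asian `seasa`) plus an
#' outgroup, with duck-resequencing-panel group sizes (19/25/21/4
#' diploids), founding
#' bottlenecks in the two derived demes, an optional planted introgressed
#' tract copied from a donor into a subset of recipient haplotypes, and an
#' optional planted sweep (founder-haplotype homogenization). Default split
#' times follow demographic estimates for the duck system (t1 = 1700,
#' t0 = 3500 generations at one generation per year); sizes are chosen so that SNP density lands near
#' real resequencing panels (a few SNPs per kb), and the two derived demes
#' carry founding bottlenecks (severe for the Southeast/South-Asian deme,
#' mild for the domestic one) so that within-population diversity drops
#' below between-population divergence - the regime in which dxy-based
#' introgression verification is informative.
#'
#' @param n_wild,n_domcn,n_seasa,n_outgroup Diploid sample sizes.
#' @param chrom_lengths Named chromosome lengths in bp (default 2 x 5 Mb).
#' @param locus_bp Tiling locus length (independent genealogies laid end to
#'   end; default 5 kb).
#' @param model A [demographic_model()] with an outgroup join time.
#' @param introgression `NULL` or a list: `donor`, `recipient`, `chrom`,
#'   `start`, `end`, `fraction` (of recipient haplotypes replaced).
#' @param sweep `NULL` or a list: `deme`, `chrom`, `start`, `end`,
#'   `new_muts` (expected new mutations per haplotype after
#'   homogenization).
#' @param seed Integer seed fixing all randomness.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_wild = 19, n_domcn = 25, n_seasa = 21,
                            n_outgroup = 4,
                            chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                            locus_bp = 5000,
                            model = demographic_model(
                              ne = c(wild = 1e5, domcn = 5e4, seasa = 2e4,
                                     anc = 1e5, outgroup = 5e4),
                              t1 = 1700, t0 = 3500, t_outgroup = 5e5,
                              bottlenecks = tibble::tibble(
                                deme = c("domcn", "seasa"),
                                frac = c(0.05, 0.03),
                                t_start = c(1360, 850), t_end = 1700)),
                            introgression = list(donor = "seasa",
                                                 recipient = "domcn",
                                                 chrom = "chr1",
                                                 start = 2000001,
                                                 end = 2400000,
                                                 fraction = 0.5),
                            sweep = list(deme = "domcn", chrom = "chr2",
                                         start = 2000001, end = 2400000,
                                         new_muts = 0.5),
                            seed = 1) {
  check_interval <- function(iv) {
    if (is.null(iv)) return()
    stopifnot(iv$chrom %in% names(chrom_lengths),
              iv$start >= 1, iv$end <= chrom_lengths[[iv$chrom]],
              iv$end > iv$start)
  }
  check_interval(introgression)
  check_interval(sweep)
  if (!is.null(introgression))
    stopifnot(introgression$fraction >= 0, introgression$fraction <= 1)
  structure(list(n = c(wild = n_wild, domcn = n_domcn, seasa = n_seasa,
                       outgroup = n_outgroup),
                 chrom_lengths = chrom_lengths, locus_bp = locus_bp,
                 model = model, introgression = introgression,
                 sweep = sweep, seed = seed),
            class = "scenario_config")
}

#' Copy a donor tract into recipient haplotypes
#'
#' For the configured fraction of recipient haplotypes (chosen once at
#' random), genotype columns at sites inside the tract are replaced by the
#' values of randomly paired donor haplotypes; sites outside the tract are
#' untouched.
#'
#' @param haps 0/1 matrix, sites x haplotypes.
#' @param in_tract Logical vector flagging tract sites (rows).
#' @param hap_pop Deme label per haplotype (columns).
#' @param donor,recipient Deme labels.
#' @param fraction Fraction of recipient haplotypes replaced.
#' @return List: `haps` (modified matrix) and `carriers` (indices of
#'   replaced recipient haplotypes).
#' @export
plant_introgression <- function(haps, in_tract, hap_pop, donor, recipient,
                                fraction) {
  rec <- which(hap_pop == recipient)
  don <- which(hap_pop == donor)
  n_rep <- floor(fraction * length(rec))
  if (fraction > 0 && n_rep < 1)
    stop("fraction * n_recipient < 1: no haplotype to replace")
  if (n_rep == 0) return(list(haps = haps, carriers = integer(0)))
  carriers <- sample(rec, n_rep)
  src <- if (n_rep <= length(don)) sample(don, n_rep) else
    sample(don, n_rep, replace = TRUE)
  haps[in_tract, carriers] <- haps[in_tract, src]
  list(haps = haps, carriers = carriers)
}

#' Homogenize a deme's haplotypes over a sweep interval
#'
#' All target-deme haplotypes in the interval are replaced by one founder
#' haplotype; each haplotype then receives an independent Poisson number of
#' new derived singleton mutations at fresh positions inside the interval
#' (new rows are appended by the caller). Other demes are untouched.
#'
#' @inheritParams plant_introgression
#' @param deme Target deme label.
#' @param new_muts Expected new mutations per haplotype (Poisson mean).
#' @param interval_pos Positions (same scale as the matrix's row positions)
#'   available for new mutations.
#' @return List: `haps` (homogenized matrix), `new_sites` (tibble `pos` x
#'   `hap` of new singleton mutations to append).
#' @export
plant_sweep <- function(haps, in_tract, hap_pop, deme, new_muts,
                        interval_pos) {
  tgt <- which(hap_pop == deme)
  founder <- haps[in_tract, tgt[1]]
  haps[in_tract, tgt] <- founder
  new_sites <- tibble::tibble(pos = integer(0), hap = integer(0))
  if (new_muts > 0) {
    for (h in tgt) {
      k <- rpois(1, new_muts)
      if (k > 0) {
        new_sites <- dplyr::bind_rows(new_sites, tibble::tibble(
          pos = sample(interval_pos, min(k, length(interval_pos))), hap = h))
      }
    }
  }
  list(haps = haps, new_sites = new_sites)
}

#' Generate a full synthetic fixture
#'
#' Simulates genotypes under the scenario's demography, tiling independent
#' loci end to end along each chromosome, plants the configured
#' introgressed tract and sweep at the haplotype level, pairs haplotypes
#' into diploids and returns the variant table together with the population
#' map, a toy gene annotation (3-10 genes per chromosome, one straddling
#' each truth-interval boundary) and the truth set. Deterministic under the
#' config seed.
#'
#' @param cfg A [scenario_config()].
#' @return A `popflow_fixture` list: `vt`, `popmap`, `genes`, `truth`
#'   (tibbles `introgression` and `sweep`, plus `params`), `cfg`.
#' @export
generate_fixture <- function(cfg) {
  set.seed(cfg$seed)
  samp <- 2L * cfg$n                     # haploids
  per_chrom <- list()
  hap_pop <- NULL
  for (cc in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[cc]]
    n_loci <- ceiling(L / cfg$locus_bp)
    ds <- simulate_dataset(cfg$model, sample_sizes = samp,
                           n_loci = n_loci, locus_bp = cfg$locus_bp)
    hap_pop <- ds$hap_pop
    gpos <- (ds$locus - 1L) * cfg$locus_bp + ds$pos
    keep <- gpos <= L
    haps <- ds$haps[keep, , drop = FALSE]
    gpos <- gpos[keep]
    pl <- cfg$introgression
    if (!is.null(pl) && pl$chrom == cc) {
      res <- plant_introgression(haps, gpos >= pl$start & gpos <= pl$end,
                                 ds$hap_pop, pl$donor, pl$recipient,
                                 pl$fraction)
      haps <- res$haps
    }
    sw <- cfg$sweep
    if (!is.null(sw) && sw$chrom == cc) {
      in_iv <- gpos >= sw$start & gpos <= sw$end
      free_pos <- setdiff(seq(sw$start, sw$end), gpos[in_iv])
      res <- plant_sweep(haps, in_iv, ds$hap_pop, sw$deme, sw$new_muts,
                         free_pos)
      haps <- res$haps
      if (nrow(res$new_sites)) {
        ns <- dplyr::distinct(res$new_sites, .data$pos, .keep_all = TRUE)
        add <- matrix(0L, nrow(ns), ncol(haps))
        add[cbind(seq_len(nrow(ns)), ns$hap)] <- 1L
        haps <- rbind(haps, add)
        gpos <- c(gpos, ns$pos)
      }
    }
    o <- order(gpos)
    per_chrom[[cc]] <- list(haps = haps[o, , drop = FALSE], pos = gpos[o])
  }
  # assemble genotypes
  ids <- unlist(lapply(names(cfg$n), function(pp) {
    sprintf("%s_%02d", toupper(substr(pp, 1, 1)), seq_len(cfg$n[[pp]]))
  }))
  ind_pop <- rep(names(cfg$n), cfg$n)
  h1 <- seq(1, sum(samp), by = 2)
  geno <- do.call(rbind, lapply(per_chrom, function(x) {
    x$haps[, h1, drop = FALSE] + x$haps[, h1 + 1, drop = FALSE]
  }))
  colnames(geno) <- ids
  chrom <- rep(names(per_chrom), vapply(per_chrom, function(x) length(x$pos), 0L))
  pos <- unlist(lapply(per_chrom, `[[`, "pos"), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  vt <- variant_tbl(chrom, pos, ref, alt, geno, ids)
  attr(vt, "chrom_lengths") <- cfg$chrom_lengths
  pm <- as_popmap(tibble::tibble(
    sample = ids, population = ind_pop,
    role = ifelse(ind_pop == "outgroup", "outgroup", "ingroup")))
  truth <- list(
    introgression = if (is.null(cfg$introgression)) tibble::tibble() else
      tibble::as_tibble(cfg$introgression[c("chrom", "start", "end")]),
    sweep = if (is.null(cfg$sweep)) tibble::tibble() else
      tibble::as_tibble(cfg$sweep[c("chrom", "start", "end")]),
    params = list(ne = cfg$model$ne, t1 = cfg$model$t1, t0 = cfg$model$t0,
                  t_outgroup = cfg$model$t_outgroup, mu = cfg$model$mu))
  genes <- toy_genes(cfg)
  structure(list(vt = vt, popmap = pm, genes = genes, truth = truth,
                 cfg = cfg),
            class = "popflow_fixture")
}

# 3-10 genes per chromosome; one straddles each truth-interval boundary
toy_genes <- function(cfg) {
  gid <- 0
  purrr::map_dfr(names(cfg$chrom_lengths), function(cc) {
    L <- cfg$chrom_lengths[[cc]]
    n_genes <- sample(3:10, 1)
    starts <- sort(sample.int(L - 20000L, n_genes))
    g <- tibble::tibble(chrom = cc, start = starts,
                        end = pmin(starts + sample(2000:20000, n_genes,
                                                   replace = TRUE), L))
    for (iv in list(cfg$introgression, cfg$sweep)) {
      if (!is.null(iv) && iv$chrom == cc) {
        g <- dplyr::bind_rows(g, tibble::tibble(
          chrom = cc, start = max(1, iv$start - 5000), end = iv$start + 5000))
      }
    }
    g <- dplyr::arrange(g, .data$start)
    g$gene_id <- sprintf("gene%03d", gid + seq_len(nrow(g)))
    gid <<- gid + nrow(g)
    g
  })
}

#' Write a fixture to disk in standard formats
#'
#' Emits `fixture.vcf`, `popmap.tsv`, `genes.gff3`,
#' `truth_introgression.bed`, `truth_sweep.bed` and `truth_model.json`
#' (YAML fallback when jsonlite is unavailable).
#'
#' @param fx A `popflow_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(fx$vt, file.path(dir, "fixture.vcf"))
  write_popmap(fx$popmap, file.path(dir, "popmap.tsv"))
  gff <- c("##gff-version 3",
           sprintf("%s\tpopflow\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                   fx$genes$chrom, fx$genes$start, fx$genes$end,
                   fx$genes$gene_id))
  writeLines(gff, file.path(dir, "genes.gff3"))
  if (nrow(fx$truth$introgression))
    write_bed(fx$truth$introgression, file.path(dir, "truth_introgression.bed"))
  if (nrow(fx$truth$sweep))
    write_bed(fx$truth$sweep, file.path(dir, "truth_sweep.bed"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(fx$truth$params, file.path(dir, "truth_model.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fx$truth$params, file.path(dir, "truth_model.yaml"))
  }
  invisible(dir)
}

#' Recombined single-locus haplotypes for LD analyses
#'
#' Tiled independent loci carry no linkage across locus boundaries, so LD
#' decay is studied in a dedicated single-locus mode: several independent
#' genealogies ("pools") of the same samples are simulated over one locus,
#' and each output haplotype is assembled by walking along the locus and
#' jumping to a random haplotype of a random pool (within the same deme) at
#' Poisson crossover points. Sites separated by no crossover share one
#' genealogy, so r-squared decays roughly exponentially with distance - an
#' approximation to intra-locus recombination, documented as such.
#'
#' @param model A [demographic_model()].
#' @param sample_sizes Haploid sample sizes.
#' @param locus_bp Locus length.
#' @param crossover_rate Expected crossovers per haplotype over the locus.
#' @param n_pools Number of independent genealogies drawn from.
#' @param seed Optional seed.
#' @return A `sim_dataset` with recombined haplotypes (positions on the
#'   first pool's site grid).
#' @export
simulate_recombined_locus <- function(model, sample_sizes = c(wild = 40),
                                      locus_bp = 1e6, crossover_rate = 4,
                                      n_pools = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- simulate_dataset(model, sample_sizes, n_loci = n_pools,
                         locus_bp = locus_bp)
  n_hap <- ncol(ds$haps)
  by_pool <- split(seq_along(ds$locus), ds$locus)
  pools <- lapply(by_pool, function(ix) ds$haps[ix, , drop = FALSE])
  pos_p <- lapply(by_pool, function(ix) ds$pos[ix])
  pos <- pos_p[[1]]
  # index of the nearest pool-j site at or before each grid position
  idx <- lapply(pos_p, function(pp) pmax(findInterval(pos, pp), 1L))
  same_deme <- lapply(unique(ds$hap_pop),
                      function(d) which(ds$hap_pop == d))
  names(same_deme) <- unique(ds$hap_pop)
  out <- matrix(0L, length(pos), n_hap)
  for (h in seq_len(n_hap)) {
    mates <- same_deme[[ds$hap_pop[h]]]
    cuts <- sort(runif(rpois(1, crossover_rate), 0, locus_bp))
    seg_of_site <- findInterval(pos, cuts) + 1L
    for (s in seq_len(length(cuts) + 1L)) {
      in_seg <- seg_of_site == s
      if (!any(in_seg)) next
      p <- sample.int(length(pools), 1)
      cc <- if (length(mates) > 1) sample(mates, 1) else mates
      out[in_seg, h] <- pools[[p]][idx[[p]][in_seg], cc]
    }
  }
  ds$haps <- out
  ds$locus <- rep(1L, nrow(out))
  ds$pos <- pos
  ds$n_loci <- 1L
  ds$total_bp <- locus_bp
  ds
}
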