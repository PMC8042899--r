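#' Define a three-population-plus-outgroup demographic model
#'
#' Topology (backward in time): `domcn` and `seasa` merge at `t1`; their
#' ancestor merges with `wild` at `t0`; an optional outgroup merges at
#' `t_outgroup`. Each deme has a constant diploid size, optionally with a
#' bottleneck epoch; migration edges connect coexisting demes over stated
#' epochs. Times are in generations; rates are per generation.
#'
#' @param ne Named diploid sizes: `wild`, `domcn`, `seasa`, `anc` (ancestor
#'   of domcn+seasa and the root), optionally `outgroup`.
#' @param t1,t0 Split times in generations, `t1 < t0`.
#' @param t_outgroup Outgroup join time (generations), `> t0`; `NULL` for a
#'   three-deme model.
#' @param bottlenecks Tibble (`deme`, `frac`, `t_start`, `t_end`): the deme's
#'   size is multiplied by `frac` on the backward-time interval
#'   `[t_start, t_end]`.
#' @param migration Tibble (`from`, `to`, `m4n`, `t_start`, `t_end`): scaled
#'   backward migration `m4n = 4 N_from m` active on `[t_start, t_end]`
#'   (backward in time); converted internally to the per-generation lineage
#'   rate `m = m4n / (4 N_from)`.
#' @param mu Mutation rate per bp per generation (default 1.91e-9).
#' @param gen_time Generation time in years (default 1), used only when
#'   reporting times in years.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(ne = c(wild = 1e5, domcn = 5e4, seasa = 2e4,
                                     anc = 1e5),
                              t1 = 1700, t0 = 3500, t_outgroup = NULL,
                              bottlenecks = NULL, migration = NULL,
                              mu = 1.91e-9, gen_time = 1) {
  stopifnot(t1 < t0, all(ne > 0), mu > 0)
  if (!is.null(t_outgroup)) {
    stopifnot(t_outgroup > t0)
    if (is.na(ne["outgroup"])) ne["outgroup"] <- unname(ne["anc"])
  }
  if (!is.null(migration)) {
    migration <- tibble::as_tibble(migration)
    if (is.null(migration$t_start)) migration$t_start <- 0
    if (is.null(migration$t_end))
      migration$t_end <- ifelse(migration$from == "domcn" & migration$to == "seasa" |
                                  migration$from == "seasa" & migration$to == "domcn",
                                t1, t0)
    stopifnot(all(migration$m4n >= 0))
  }
  structure(list(ne = ne, t1 = t1, t0 = t0, t_outgroup = t_outgroup,
                 bottlenecks = bottlenecks, migration = migration,
                 mu = mu, gen_time = gen_time),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model: ((domcn, seasa)@", x$t1, ", wild)@", x$t0,
      if (!is.null(x$t_outgroup)) paste0(", outgroup@", x$t_outgroup),
      " generations\n", sep = "")
  cat("Ne:", paste(names(x$ne), round(x$ne), sep = "=", collapse = " "), "\n")
  if (!is.null(x$migration) && nrow(x$migration))
    cat("migration edges:", nrow(x$migration), "\n")
  invisible(x)
}

# deme order for the simulator
model_demes <- function(model) {
  c("wild", "domcn", "seasa", if (!is.null(model$t_outgroup)) "outgroup")
}

# Compile a demographic_model into simulator inputs: initial sizes,
# initial migration matrix, and a time-sorted event table.
compile_demography <- function(model) {
  demes <- model_demes(model)
  nd <- length(demes)
  di <- stats::setNames(seq_len(nd) - 1L, demes)   # 0-based
  sizes <- unname(model$ne[demes])
  mig0 <- matrix(0, nd, nd)
  ev <- list()
  add <- function(time, type, i, j = 0L, x = 0) {
    ev[[length(ev) + 1L]] <<- c(time = time, type = type, i = i, j = j, x = x)
  }
  if (!is.null(model$bottlenecks) && nrow(model$bottlenecks)) {
    for (r in seq_len(nrow(model$bottlenecks))) {
      b <- model$bottlenecks[r, ]
      i <- di[[b$deme]]
      add(b$t_start, 1L, i, x = model$ne[[b$deme]] * b$frac)
      add(b$t_end, 1L, i, x = model$ne[[b$deme]])
    }
  }
  if (!is.null(model$migration) && nrow(model$migration)) {
    for (r in seq_len(nrow(model$migration))) {
      mg <- model$migration[r, ]
      i <- di[[mg$from]]; j <- di[[mg$to]]
      m <- mg$m4n / (4 * model$ne[[mg$from]])
      if (mg$t_start <= 0) mig0[i + 1, j + 1] <- m
      else add(mg$t_start, 2L, i, j, m)
      add(mg$t_end, 2L, i, j, 0)
    }
  }
  add(model$t1, 0L, di[["seasa"]], di[["domcn"]])
  add(model$t1, 1L, di[["domcn"]], x = model$ne[["anc"]])
  add(model$t0, 0L, di[["domcn"]], di[["wild"]])
  add(model$t0, 1L, di[["wild"]], x = model$ne[["anc"]])
  if (!is.null(model$t_outgroup))
    add(model$t_outgroup, 0L, di[["outgroup"]], di[["wild"]])
  evm <- do.call(rbind, ev)
  o <- order(evm[, "time"], evm[, "type"] != 0)  # joins first at equal times
  events <- tibble::tibble(time = evm[o, "time"],
                           type = as.integer(evm[o, "type"]),
                           i = as.integer(evm[o, "i"]),
                           j = as.integer(evm[o, "j"]),
                           x = evm[o, "x"])
  list(demes = demes, sizes = sizes, mig0 = mig0, events = events)
}

#' Simulate independent loci under a demographic model
#'
#' Event-driven structured-coalescent simulation (continuous-time
#' approximation: coalescence rate `k(k-1)/(4 Ne)` per deme and generation,
#' lineage migration rate `m` per generation) with infinite-sites mutations
#' placed as Poisson(`mu * locus_bp` x branch length). Loci are independent
#' genealogies.
#'
#' @param model A [demographic_model()].
#' @param sample_sizes Named haploid sample sizes per sampled deme (even
#'   numbers pair cleanly into diploids), e.g. `c(wild = 20, domcn = 20,
#'   seasa = 20)`.
#' @param n_loci Number of independent loci.
#' @param locus_bp Locus length in bp.
#' @param seed Optional integer seed (forwarded to [set.seed()]).
#' @return A `sim_dataset`: list with `haps` (0/1 matrix, sites x
#'   haplotypes; 1 = derived), `locus` (locus index per site), `pos`
#'   (position within locus), `hap_pop` (deme label per haplotype),
#'   `n_loci`, `locus_bp`, `total_bp`.
#' @export
simulate_dataset <- function(model, sample_sizes = c(wild = 20, domcn = 20,
                                                     seasa = 20),
                             n_loci = 200, locus_bp = 5000, seed = NULL) {
  stopifnot(n_loci >= 1, all(sample_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  cmp <- compile_demography(model)
  ss <- integer(length(cmp$demes))
  names(ss) <- cmp$demes
  ss[names(sample_sizes)] <- as.integer(sample_sizes)
  if (any(!names(sample_sizes) %in% cmp$demes))
    stop("sample_sizes name not a model deme")
  G <- sim_loci_cpp(unname(ss), cmp$sizes, cmp$mig0, cmp$events,
                    model$mu, locus_bp, as.integer(n_loci))
  nsites <- vapply(G, ncol, 0L)
  hap_pop <- rep(cmp$demes, times = ss)
  haps <- do.call(rbind, lapply(G, t))   # sites x haplotypes
  if (is.null(haps)) haps <- matrix(0L, 0, sum(ss))
  pos <- unlist(lapply(nsites, function(s) {
    sort(sample.int(locus_bp, min(s, locus_bp)))
  }), use.names = FALSE)
  # infinite-sites collisions on the finite grid: drop surplus rows
  keep_rows <- unlist(lapply(nsites, function(s) {
    c(rep(TRUE, min(s, locus_bp)), rep(FALSE, max(0L, s - locus_bp)))
  }), use.names = FALSE)
  if (length(keep_rows) && !all(keep_rows)) haps <- haps[keep_rows, , drop = FALSE]
  structure(list(haps = haps,
                 locus = rep(seq_len(n_loci), pmin(nsites, locus_bp)),
                 pos = pos, hap_pop = hap_pop, n_loci = n_loci,
                 locus_bp = locus_bp, total_bp = n_loci * locus_bp),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", length(x$hap_pop), "haplotypes,", nrow(x$haps),
      "segregating sites over", x$n_loci, "x", x$locus_bp, "bp loci\n")
  invisible(x)
}

#' Convert simulated haplotypes into a variant table
#'
#' Haplotypes are paired in order into pseudo-diploid samples; loci are laid
#' end to end along one chromosome (locus `i` occupies
#' `[(i-1) locus_bp + 1, i locus_bp]`). The ancestral (0) allele is written
#' as REF, so the table is born polarized.
#'
#' @param ds A `sim_dataset` with even haploid sample sizes.
#' @param chrom Chromosome label for the output.
#' @param sample_prefix Prefix map for sample names (defaults to deme names).
#' @param locus_spacing_bp Distance between locus starts (default
#'   `locus_bp`, i.e. loci tiled end to end). Spacing of 2 Mb or more puts
#'   every independent locus on its own jackknife block.
#' @return A list: `vt` (the `variant_tbl`) and `popmap`.
#' @export
sim_to_variant_tbl <- function(ds, chrom = "chr1", sample_prefix = NULL,
                               locus_spacing_bp = ds$locus_bp) {
  pops <- unique(ds$hap_pop)
  stopifnot(all(table(ds$hap_pop) %% 2 == 0))
  geno <- ds$haps[, seq(1, ncol(ds$haps), by = 2), drop = FALSE] +
    ds$haps[, seq(2, ncol(ds$haps), by = 2), drop = FALSE]
  ind_pop <- ds$hap_pop[seq(1, length(ds$hap_pop), by = 2)]
  ids <- unlist(lapply(pops, function(pp) {
    n <- sum(ind_pop == pp)
    pre <- if (!is.null(sample_prefix)) sample_prefix[[pp]] else pp
    sprintf("%s_%02d", pre, seq_len(n))
  }))
  colnames(geno) <- ids
  gpos <- (ds$locus - 1L) * locus_spacing_bp + ds$pos
  o <- order(gpos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(gpos), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  vt <- variant_tbl(rep(chrom, length(gpos)), gpos[o], ref[o], alt[o],
                    geno[o, , drop = FALSE], ids)
  attr(vt, "chrom_lengths") <-
    stats::setNames(ds$n_loci * locus_spacing_bp, chrom)
  pm <- as_popmap(tibble::tibble(
    sample = ids, population = ind_pop,
    role = ifelse(ind_pop == "outgroup", "outgroup", "ingroup")))
  list(vt = vt, popmap = pm)
}
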