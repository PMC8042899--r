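# Small genotype fixtures built in code.

# Random variant table: three ingroup populations + outgroup, with optional
# missingness. Genotypes are iid per population with population-specific
# allele frequencies so statistics are non-trivial.
make_test_vt <- function(n_sites = 50, n_per_pop = c(wild = 4, domcn = 4,
                                                     seasa = 3, outgroup = 2),
                         miss_rate = 0, seed = 1, chrom = "chr1",
                         chrom_len = n_sites * 100L) {
  set.seed(seed)
  pops <- names(n_per_pop)
  geno <- NULL
  for (pp in pops) {
    p <- if (pp == "outgroup") rbinom(n_sites, 1, 0.5) * 0.95 + 0.025 else
      runif(n_sites, 0.05, 0.95)
    g <- matrix(rbinom(n_sites * n_per_pop[[pp]], 2, rep(p, n_per_pop[[pp]])),
                nrow = n_sites)
    geno <- cbind(geno, g)
  }
  if (miss_rate > 0) {
    geno[runif(length(geno)) < miss_rate] <- NA
  }
  ids <- unlist(lapply(pops, function(pp)
    sprintf("%s%02d", toupper(substr(pp, 1, 1)), seq_len(n_per_pop[[pp]]))))
  colnames(geno) <- ids
  vt <- variant_tbl(rep(chrom, n_sites),
                    sort(sample.int(chrom_len, n_sites)),
                    rep("A", n_sites), rep("G", n_sites), geno, ids)
  attr(vt, "chrom_lengths") <- stats::setNames(chrom_len, chrom)
  pm <- as_popmap(tibble::tibble(
    sample = ids,
    population = rep(pops, n_per_pop),
    role = ifelse(rep(pops, n_per_pop) == "outgroup", "outgroup", "ingroup")))
  list(vt = vt, pm = pm)
}

# a tiny neutral single-population model for simulator checks
neutral_model <- function(ne = 1e4) {
  demographic_model(ne = c(wild = ne, domcn = ne, seasa = ne, anc = ne),
                    t1 = 100, t0 = 200)
}
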