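#' Build a variant table
#'
#' A variant table is the substrate of every statistic in popflow: a tibble
#' with one row per biallelic SNP and columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, followed by one integer column per sample holding the
#' alternate-allele count of the diploid genotype (0, 1, 2, or `NA` for a
#' missing call).
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt Single-base reference / alternate alleles.
#' @param geno Integer matrix of alternate-allele counts, sites in rows,
#'   samples in columns (values 0/1/2/NA).
#' @param samples Sample identifiers; defaults to `colnames(geno)`.
#'
#' @return A `variant_tbl`: a tibble of sites by (coordinates + samples).
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2)
#' variant_tbl("chr1", c(100L, 200L), c("A", "C"), c("G", "T"), g,
#'             samples = c("s1", "s2", "s3"))
variant_tbl <- function(chrom, pos, ref, alt, geno, samples = colnames(geno)) {
  geno <- as.matrix(geno)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  chrom <- rep_len(chrom, nrow(geno))
  ref <- rep_len(ref, nrow(geno))
  alt <- rep_len(alt, nrow(geno))
  stopifnot(length(pos) == nrow(geno), length(samples) == ncol(geno))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  vt <- tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                       ref = as.character(ref), alt = as.character(alt))
  gt <- tibble::as_tibble(matrix(as.integer(geno), nrow = nrow(geno),
                                 dimnames = list(NULL, samples)))
  out <- dplyr::bind_cols(vt, gt)
  validate_variant_tbl(new_variant_tbl(out))
}

new_variant_tbl <- function(x) {
  class(x) <- unique(c("variant_tbl", class(x)))
  x
}

validate_variant_tbl <- function(vt) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(vt)))
  ok <- tapply(vt$pos, vt$chrom, function(p) all(diff(p) > 0))
  if (length(ok) && !all(unlist(ok)))
    stop("positions must be strictly increasing within each chromosome")
  vt
}

#' Sample identifiers of a variant table
#' @param vt A `variant_tbl`.
#' @return Character vector of sample ids (genotype column names).
#' @export
vt_samples <- function(vt) {
  setdiff(names(vt), c("chrom", "pos", "ref", "alt", "ancestral", "polarizable"))
}

#' Genotype matrix of a variant table
#' @param vt A `variant_tbl`.
#' @param samples Optional subset of samples.
#' @return Integer matrix, sites x samples (0/1/2/NA alt-allele counts).
#' @export
geno_matrix <- function(vt, samples = vt_samples(vt)) {
  as.matrix(vt[, samples, drop = FALSE])
}

#' Read a sample-to-population map
#'
#' Two- or three-column TSV: `sample`, `population`, and optionally `role`
#' (`ingroup`/`outgroup`, defaulting to ingroup).
#'
#' @param path TSV path (header optional; detected from the first line).
#' @return Tibble with columns `sample`, `population`, `role`.
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^sample\\b", first)
  pm <- readr::read_tsv(path, col_names = has_header,
                        show_col_types = FALSE, progress = FALSE)
  if (!has_header) {
    names(pm) <- c("sample", "population", "role")[seq_len(ncol(pm))]
  }
  as_popmap(pm)
}

#' Coerce a data frame to a population map
#'
#' @param x Data frame with columns `sample`, `population` and optionally
#'   `role` (`"ingroup"` or `"outgroup"`).
#' @return A validated popmap tibble.
#' @export
as_popmap <- function(x) {
  pm <- tibble::as_tibble(x)
  stopifnot(all(c("sample", "population") %in% names(pm)))
  if (!"role" %in% names(pm)) pm$role <- "ingroup"
  pm$role[is.na(pm$role)] <- "ingroup"
  if (anyDuplicated(pm$sample))
    stop("each sample must be assigned exactly one population")
  if (!all(pm$role %in% c("ingroup", "outgroup")))
    stop("role must be 'ingroup' or 'outgroup'")
  pm[c("sample", "population", "role")]
}

#' Write a population map to TSV
#' @param pm Popmap tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  readr::write_tsv(as_popmap(pm), path, progress = FALSE)
  invisible(path)
}

pop_samples <- function(pm, population, samples = NULL) {
  if (!population %in% pm$population)
    stop("unknown population label: ", population)
  s <- pm$sample[pm$population == population]
  if (!is.null(samples)) s <- intersect(s, samples)
  if (!length(s)) stop("population ", population, " has no samples in table")
  s
}

#' Filter sites by missingness and minor-allele frequency
#'
#' Retains sites whose missing-genotype fraction is at most `max_missing_rate`
#' and whose minor-allele frequency, computed over non-missing calls across
#' all samples, is at least `min_maf`.
#'
#' @param vt A `variant_tbl`.
#' @param max_missing_rate Maximum tolerated fraction of missing genotypes
#'   per site, in `[0, 1]`.
#' @param min_maf Minimum minor-allele frequency, in `[0, 0.5]`.
#' @return The filtered `variant_tbl`.
#' @export
apply_snp_filters <- function(vt, max_missing_rate = 0.05, min_maf = 0.05) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  g <- geno_matrix(vt)
  n_mis <- rowSums(is.na(g))
  miss_rate <- n_mis / ncol(g)
  an <- 2L * (ncol(g) - n_mis)
  ac <- rowSums(g, na.rm = TRUE)
  p <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p, 1 - p)
  # sites with no called genotype have no defined MAF: they survive only
  # the trivial min_maf = 0 filter (keeps the identity property exact)
  maf[is.na(maf)] <- 0
  keep <- miss_rate <= max_missing_rate & maf >= min_maf
  vt[keep, , drop = FALSE]
}

#' Per-population alternate (or derived) allele frequencies
#'
#' @param vt A `variant_tbl` (optionally polarized, see [polarize()]).
#' @param pm Population map.
#' @param population Population label present in `pm`.
#' @param derived If `TRUE` and `vt` is polarized, report derived-allele
#'   frequencies (alt frequency flipped where the outgroup is fixed for alt).
#' @return Tibble with one row per site: `chrom`, `pos`, `p` (allele
#'   frequency; `NA` where the population is fully missing) and `n`
#'   (non-missing haplotype count; 0 when fully missing).
#' @export
allele_freqs <- function(vt, pm, population, derived = FALSE) {
  g <- geno_matrix(vt, pop_samples(pm, population, vt_samples(vt)))
  an <- 2L * rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  p <- ifelse(an > 0, ac / an, NA_real_)
  if (derived) {
    if (!"ancestral" %in% names(vt))
      stop("derived frequencies require a polarized table; run polarize()")
    flip <- vt$ancestral == "alt"
    p <- ifelse(flip, 1 - p, p)
    p[!vt$polarizable] <- NA_real_
  }
  tibble::tibble(chrom = vt$chrom, pos = vt$pos, p = p, n = as.integer(an))
}

#' Polarize alleles by an outgroup population
#'
#' Marks, for every site, which allele is ancestral: the allele fixed among
#' the outgroup's non-missing calls. Sites where the outgroup is polymorphic
#' or entirely missing are flagged unusable for polarized statistics
#' (`polarizable = FALSE`) rather than dropped.
#'
#' @param vt A `variant_tbl`.
#' @param pm Population map containing `outgroup`.
#' @param outgroup Outgroup population label.
#' @return The input table with two added columns: `ancestral`
#'   (`"ref"`/`"alt"`/`NA`) and `polarizable` (logical).
#' @export
polarize <- function(vt, pm, outgroup) {
  g <- geno_matrix(vt, pop_samples(pm, outgroup, vt_samples(vt)))
  an <- 2L * rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  anc <- dplyr::case_when(an > 0 & ac == 0 ~ "ref",
                          an > 0 & ac == an ~ "alt",
                          TRUE ~ NA_character_)
  vt$ancestral <- anc
  vt$polarizable <- !is.na(anc)
  vt
}

#' Sliding windows over chromosomes
#'
#' Windows are anchored at position 1 on each chromosome:
#' `[k*step + 1, k*step + size]`, truncated at the chromosome end. A trailing
#' truncated window is emitted while at least half of the window lies on the
#' chromosome; further truncated windows are added only as needed so that
#' every base up to the chromosome end is covered (which preserves the exact
#' tiling property when `step == size`).
#'
#' @param vt A `variant_tbl` (supplies per-chromosome SNPs and, by default,
#'   chromosome lengths as `max(pos)`).
#' @param size_bp,step_bp Window length and step in bp, `size_bp >= step_bp`.
#' @param min_snps Windows with fewer SNPs are flagged `excluded` (still
#'   emitted).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp);
#'   defaults to the `chrom_lengths` attribute set by [read_vcf()] from
#'   header contigs, else `max(pos)` per chromosome.
#' @return Tibble of windows: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_snps`, `excluded`.
#' @export
make_windows <- function(vt, size_bp, step_bp, min_snps = 0,
                         chrom_lengths = NULL) {
  stopifnot(size_bp >= step_bp, step_bp >= 1)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(vt, "chrom_lengths")
  chroms <- unique(vt$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc) max(vt$pos[vt$chrom == cc]),
                            numeric(1))
  }
  win <- purrr::map_dfr(chroms, function(cc) {
    L <- as.numeric(chrom_lengths[[cc]])
    starts <- numeric(0)
    k <- 0
    repeat {
      s <- k * step_bp + 1
      covered <- if (length(starts)) min(starts[length(starts)] + size_bp - 1, L) else 0
      if (s > L) break
      if (s <= L - floor(size_bp / 2) + 1 || covered < L) {
        starts <- c(starts, s)
      } else break
      k <- k + 1
    }
    tibble::tibble(chrom = cc, start = starts, end = pmin(starts + size_bp - 1, L))
  })
  pos_by <- split(vt$pos, vt$chrom)
  win$n_snps <- purrr::map2_int(win$chrom, seq_len(nrow(win)), function(cc, i) {
    p <- pos_by[[cc]]
    sum(p >= win$start[i] & p <= win$end[i])
  })
  win$excluded <- win$n_snps < min_snps
  win[c("chrom", "start", "end", "n_snps", "excluded")]
}

# index range [lo, hi] of sorted per-chromosome site positions per window;
# lo > hi means an empty window
window_site_index <- function(pos, starts, ends) {
  lo <- findInterval(starts - 1L, pos) + 1L
  hi <- findInterval(ends, pos)
  list(lo = lo, hi = hi)
}
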