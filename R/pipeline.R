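#' Default run configuration
#'
#' All analysis parameters with their conventional defaults: fd windows of
#' 100 kb at 20-kb steps with at least 100 SNPs, fd threshold 0.5 and
#' 200-kb minimum region; 2-Mb jackknife blocks with the |Z| > 3 (D) and
#' Z <= -2 (f3) conventions; sweep windows of 40 kb at 10-kb steps with the
#' top-5% joint rule; mutation rate 1.91e-9 per bp per generation and a
#' 1-year generation interval.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    fd = list(window = 1e5, step = 2e4, min_snps = 100, threshold = 0.5,
              min_region = 2e5),
    dstat = list(block_size = 2e6, z_threshold = 3),
    f3 = list(block_size = 2e6, z_threshold = -2),
    sweep = list(window = 4e4, step = 1e4, quantile = 0.95, min_snps = 10),
    demography = list(mu = 1.91e-9, generation_time = 1))
}

#' Read and validate a YAML run configuration
#'
#' User values override [default_run_config()]; unknown top-level keys are
#' an error naming the offending key. Input paths (`vcf`, `popmap`, `gff`)
#' and population assignments (`populations:` with `p1`/`p2`/`p3`/
#' `outgroup`/`wild`/`domestic` keys) are carried through untouched.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  allowed <- c(names(base), "vcf", "popmap", "gff", "populations", "out_dir")
  bad <- setdiff(names(user), allowed)
  if (length(bad)) stop("unknown configuration key: ", bad[1])
  for (k in intersect(names(user), names(base))) {
    if (is.list(base[[k]])) {
      bad2 <- setdiff(names(user[[k]]), names(base[[k]]))
      if (length(bad2)) stop("unknown configuration key: ", k, ".", bad2[1])
      base[[k]] <- utils::modifyList(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  for (k in setdiff(allowed, names(base))) base[[k]] <- user[[k]]
  if (is.null(base$popmap)) stop("configuration must name 'popmap'")
  if (is.null(base$vcf)) stop("configuration must name 'vcf'")
  base
}

#' Run the windowed scans described by a configuration
#'
#' Reads the VCF and population map, runs the fd introgression scan
#' (P1/P2/P3/outgroup from `populations`) and the sweep scan
#' (`wild`/`domestic`), writes TSV/BED outputs plus a reproducibility
#' manifest (config digest, seed, package version) into `out_dir`, and
#' returns the results invisibly.
#'
#' @param config Configuration list from [read_run_config()].
#' @return Invisibly, a list with `fd`, `regions`, `sweep`, `sweep_regions`.
#' @export
run_scans <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  vt <- read_vcf(config$vcf)
  pm <- read_popmap(config$popmap)
  pops <- config$populations
  genes <- if (!is.null(config$gff)) read_gff_genes(config$gff)
  fd <- fd_scan(vt, pm, pops$p1, pops$p2, pops$p3, pops$outgroup,
                size_bp = config$fd$window, step_bp = config$fd$step,
                min_snps = config$fd$min_snps)
  regions <- call_introgressed_regions(fd, config$fd$threshold,
                                       config$fd$min_region)
  sw <- sweep_scan(vt, pm, pops$wild, pops$domestic,
                   size_bp = config$sweep$window, step_bp = config$sweep$step,
                   quantile_cut = config$sweep$quantile,
                   min_snps = config$sweep$min_snps)
  swr <- merge_and_annotate(sw, genes)
  readr::write_tsv(fd, file.path(out_dir, "fd_windows.tsv"), progress = FALSE)
  if (nrow(regions))
    write_bed(regions, file.path(out_dir, "introgressed_regions.bed"))
  readr::write_tsv(tibble::as_tibble(sw), file.path(out_dir, "sweep_windows.tsv"),
                   progress = FALSE)
  if (nrow(swr))
    write_bed(swr, file.path(out_dir, "sweep_regions.bed"))
  manifest <- list(
    config_digest = digest_config(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("popflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(fd = fd, regions = regions, sweep = sw, sweep_regions = swr))
}

# order-independent content digest without external digest packages
digest_config <- function(config) {
  s <- yaml::as.yaml(config[order(names(config))])
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}
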