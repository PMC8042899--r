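#' Read a VCF into a variant table
#'
#' Keeps biallelic SNPs only (multi-allelic and indel records are dropped at
#' read time); genotypes are encoded as diploid alternate-allele counts with
#' missing calls preserved as `NA`. Only the GT field is used.
#'
#' @param path Path to an (uncompressed or gzipped) VCF 4.x file.
#' @param region_filter Optional tibble/data frame with `chrom`, `start`,
#'   `end`: only records inside one of the intervals are kept.
#' @return A `variant_tbl`. Chromosome lengths parsed from `##contig` header
#'   lines (when present) are attached as attribute `chrom_lengths`.
#' @export
read_vcf <- function(path, region_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    warning("no biallelic SNPs in ", path)
    return(empty_variant_tbl())
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gt_raw <- v@gt[snp, -1L, drop = FALSE]
  samples <- colnames(v@gt)[-1L]
  fix <- fix[snp, , drop = FALSE]
  if (!nrow(fix)) {
    warning("no biallelic SNPs in ", path)
    return(empty_variant_tbl())
  }
  # GT is the first (or only) colon-separated field
  gt <- sub(":.*$", "", gt_raw)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  colnames(code) <- samples
  vt <- variant_tbl(fix[, "CHROM"], as.integer(fix[, "POS"]),
                    ref[snp], alt[snp], code, samples)
  lens <- parse_contig_lengths(v@meta)
  if (length(lens)) attr(vt, "chrom_lengths") <- lens
  if (!is.null(region_filter)) {
    keep <- rep(FALSE, nrow(vt))
    for (i in seq_len(nrow(region_filter))) {
      keep <- keep | (vt$chrom == region_filter$chrom[i] &
                        vt$pos >= region_filter$start[i] &
                        vt$pos <= region_filter$end[i])
    }
    vt <- vt[keep, , drop = FALSE]
  }
  vt
}

empty_variant_tbl <- function() {
  new_variant_tbl(tibble::tibble(chrom = character(), pos = integer(),
                                 ref = character(), alt = character()))
}

parse_contig_lengths <- function(meta) {
  m <- meta[grepl("^##contig=", meta)]
  if (!length(m)) return(numeric(0))
  id <- sub(".*ID=([^,>]+).*", "\\1", m)
  ln <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", m)))
  stats::setNames(ln, id)[!is.na(ln)]
}

#' Write a variant table as VCF
#'
#' Minimal GT-only VCF 4.2 output, with `##contig` lines taken from the
#' table's `chrom_lengths` attribute (else `max(pos)` per chromosome).
#'
#' @param vt A `variant_tbl`.
#' @param path Output path (plain text).
#' @param chrom_lengths Optional named chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, chrom_lengths = attr(vt, "chrom_lengths")) {
  samples <- vt_samples(vt)
  chroms <- unique(vt$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc) max(vt$pos[vt$chrom == cc]),
                            numeric(1))
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  g <- geno_matrix(vt)
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[g == 0L] <- "0/0"
  gt[g == 1L] <- "0/1"
  gt[g == 2L] <- "1/1"
  body <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Restricted to `gene`-type features; uses rtracklayer when installed, else
#' a minimal reader for the seqid/start/end/ID subset this package needs.
#'
#' @param path GFF3 path.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3", feature.type = "gene")
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    return(tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr),
                          end = GenomicRanges::end(gr),
                          gene_id = as.character(id)))
  }
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 9 & vapply(f, `[`, "", 3) == "gene"]
  tibble::tibble(
    chrom = vapply(f, `[`, "", 1),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    gene_id = sub(".*(?:ID|Name)=([^;]+).*", "\\1", vapply(f, `[`, "", 9)))
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param x Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name` and `score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, format(x$start - 1L, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) {
    cols <- c(cols, list(x$name))
    if ("score" %in% names(x)) cols <- c(cols, list(x$score))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#' @param path BED3+ path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  tibble::tibble(chrom = as.character(b[[1]]), start = b[[2]] + 1L,
                 end = b[[3]])
}
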