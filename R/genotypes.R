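#' Genotype matrix container
#'
#' A `genotype_matrix` bundles a samples-by-SNPs dosage matrix (additive
#' 0/1/2 coding, `NA` as the dedicated missing sentinel) with per-SNP
#' metadata: position, the gene whose span contains the SNP (if any), the
#' region class flags (`exonic`: inside an exon interval; `tf_span`:
#' anywhere in the span of a transcription-factor gene, introns included),
#' minor-allele frequency and missingness computed from non-missing calls.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns, values
#'   in {0, 1, 2, NA}.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (and optionally
#'   `source_gene`, `exonic`, `tf_span`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps) {
  stopifnot(is.matrix(dosage), nrow(snps) == ncol(dosage))
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    abort("dosages must be 0, 1, 2 or NA", class = "transppi_invalid_parameter")
  }
  colnames(dosage) <- snps$snp_id
  snps$maf <- snp_maf(dosage)
  snps$missingness <- colMeans(is.na(dosage))
  structure(list(dosage = dosage, snps = snps,
                 samples = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

# Minor-allele frequency per SNP column from non-missing calls only.
snp_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

# Attach source gene and region-class flags by locating each SNP inside
# gene spans (1-based closed intervals; exon boundary positions are exonic).
annotate_snps <- function(snps, annotation) {
  hit <- purrr::map(seq_len(nrow(snps)), function(i) {
    j <- which(annotation$chrom == snps$chrom[i] &
               annotation$start <= snps$pos[i] &
               annotation$end >= snps$pos[i])
    if (length(j)) j[1] else NA_integer_
  })
  hit <- unlist(hit)
  snps$source_gene <- ifelse(is.na(hit), NA_character_,
                             annotation$gene_id[hit])
  snps$tf_span <- !is.na(hit) & annotation$is_tf[pmax(hit, 1L)]
  snps$tf_span[is.na(hit)] <- FALSE
  snps$exonic <- purrr::map2_lgl(hit, snps$pos, function(j, p) {
    if (is.na(j)) return(FALSE)
    position_in_exon(p, annotation$exons[[j]])
  })
  snps
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Places `snps_per_gene` SNPs uniformly inside every gene span and draws
#' dosages as Binomial(2, maf) per SNP, with the allele frequency drawn
#' uniformly from `maf_range`. Entries are then masked missing
#' independently at `missing_rate`. No linkage disequilibrium is
#' simulated.
#'
#' @param n_samples Number of samples.
#' @param annotation Gene annotation tibble ([generate_annotation()]).
#' @param snps_per_gene SNPs placed inside each gene span.
#' @param maf_range Allele-frequency window `(lo, hi)` with
#'   `0 < lo <= hi < 0.5`.
#' @param missing_rate Per-entry probability of a missing call.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
generate_genotypes <- function(n_samples, annotation, snps_per_gene = 3,
                               maf_range = c(0.1, 0.49),
                               missing_rate = 0.02, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 3)
  snps_per_gene <- check_count(snps_per_gene, "snps_per_gene")
  check_prob(missing_rate, "missing_rate")
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[2] >= 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must satisfy 0 < lo <= hi < 0.5",
          class = "transppi_invalid_parameter")
  }

  with_seed(seed, {
    n_snps <- nrow(annotation) * snps_per_gene
    pos <- integer(0); chrom <- character(0)
    for (i in seq_len(nrow(annotation))) {
      pos <- c(pos, sort(sample(seq(annotation$start[i], annotation$end[i]),
                                snps_per_gene)))
      chrom <- c(chrom, rep(annotation$chrom[i], snps_per_gene))
    }
    snps <- tibble::tibble(snp_id = sprintf("rs%05d", seq_len(n_snps)),
                           chrom = chrom, pos = pos)
    snps <- annotate_snps(snps, annotation)

    maf <- runif(n_snps, maf_range[1], maf_range[2])
    dosage <- vapply(maf, function(p) rbinom(n_samples, 2L, p),
                     numeric(n_samples))
    if (missing_rate > 0) {
      dosage[runif(length(dosage)) < missing_rate] <- NA
    }
    rownames(dosage) <- sprintf("S%03d", seq_len(n_samples))
    genotype_matrix(dosage, snps)
  })
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the standard marker filters with strict inequalities: SNPs are
#' kept when minor-allele frequency exceeds `maf_min` and per-SNP
#' missingness is below `snp_missing_max`; afterwards samples with
#' missingness at or above `sample_missing_max` (computed over the
#' retained SNPs) are dropped, and per-SNP statistics are recomputed on
#' the retained samples. SNP filtering always precedes sample filtering.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Keep SNPs with maf strictly above this value.
#' @param snp_missing_max Keep SNPs with missingness strictly below this.
#' @param sample_missing_max Keep samples with missingness strictly below.
#' @return A filtered `genotype_matrix`; the filter report (counts removed
#'   at each step) is attached as attribute `"filter_report"`.
#' @export
filter_genotypes <- function(G, maf_min = 0.05, snp_missing_max = 0.1,
                             sample_missing_max = 0.1) {
  stopifnot(inherits(G, "genotype_matrix"))
  maf <- snp_maf(G$dosage)
  miss <- colMeans(is.na(G$dosage))
  keep_snp <- !is.na(maf) & maf > maf_min & miss < snp_missing_max
  d <- G$dosage[, keep_snp, drop = FALSE]

  smiss <- rowMeans(is.na(d))
  keep_sample <- smiss < sample_missing_max
  d <- d[keep_sample, , drop = FALSE]

  if (ncol(d) == 0) {
    warn("all SNPs removed by QC filters")
  }
  out <- genotype_matrix(d, G$snps[keep_snp, , drop = FALSE])
  attr(out, "filter_report") <- list(
    snps_removed = sum(!keep_snp),
    samples_removed = sum(!keep_sample),
    snps_kept = ncol(d), samples_kept = nrow(d))
  out
}

#' Write / read genotypes as a minimal VCF
#'
#' Only biallelic records with a GT-only FORMAT are supported; genotypes
#' are written unphased (`0/0`, `0/1`, `1/1`, `./.`). Multi-allelic ALT
#' fields are rejected on read.
#'
#' @param G A [genotype_matrix()].
#' @param path File path.
#' @param annotation Optional annotation used to re-derive region classes
#'   on read.
#' @return `write_genotypes_vcf()` returns `path` invisibly;
#'   `read_genotypes()` returns a `genotype_matrix`.
#' @export
write_genotypes_vcf <- function(G, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(G$dosage)), function(j) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(G$snps$chrom[j], G$snps$pos[j], G$snps$snp_id[j], "A", "G",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @param format `"vcf_minimal"` or `"tsv"`.
#' @export
read_genotypes <- function(path, format = c("vcf_minimal", "tsv"),
                           annotation = NULL) {
  format <- match.arg(format)
  if (format == "tsv") return(read_genotypes_tsv(path, annotation))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "#CHROM") {
    abort(sprintf("%s: line 1 is not a VCF column header", path),
          class = "transppi_parse_error")
  }
  samples <- header[-(1:9)]
  recs <- strsplit(lines[-1], "\t", fixed = TRUE)
  parse_gt <- function(g) {
    switch(g, "0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "./." = NA_real_,
           abort(sprintf("unsupported GT field '%s'", g),
                 class = "transppi_parse_error"))
  }
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = length(recs),
                   dimnames = list(samples, NULL))
  meta <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    f <- recs[[k]]
    if (grepl(",", f[5], fixed = TRUE)) {
      abort(sprintf("%s: record %d (%s) is multi-allelic", path, k, f[3]),
            class = "transppi_multiallelic_error")
    }
    dosage[, k] <- vapply(f[-(1:9)], parse_gt, numeric(1))
    meta[[k]] <- tibble::tibble(snp_id = f[3], chrom = f[1],
                                pos = as.integer(f[2]))
  }
  snps <- dplyr::bind_rows(meta)
  if (!is.null(annotation)) snps <- annotate_snps(snps, annotation)
  genotype_matrix(dosage, snps)
}

#' Write / read genotypes as a SNP-rows TSV
#'
#' One row per SNP (`snp_id`, `chrom`, `pos`, then one dosage column per
#' sample; missing as `NA`), so positional metadata round-trips.
#'
#' @inheritParams write_genotypes_vcf
#' @export
write_genotypes_tsv <- function(G, path) {
  out <- dplyr::bind_cols(
    G$snps[, c("snp_id", "chrom", "pos")],
    tibble::as_tibble(t(G$dosage)))
  readr::write_tsv(out, path)
  invisible(path)
}

read_genotypes_tsv <- function(path, annotation = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("snp_id", "chrom", "pos") %in% names(raw))) {
    abort(sprintf("%s: expected snp_id/chrom/pos leading columns", path),
          class = "transppi_parse_error")
  }
  samples <- setdiff(names(raw), c("snp_id", "chrom", "pos"))
  dosage <- t(as.matrix(raw[, samples]))
  rownames(dosage) <- samples
  snps <- raw[, c("snp_id", "chrom", "pos")]
  if (!is.null(annotation)) snps <- annotate_snps(snps, annotation)
  genotype_matrix(dosage, snps)
}
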