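#' Generate a synthetic gene annotation
#'
#' Lays out `n_genes` genes round-robin across chromosomes with
#' non-overlapping spans, random exon structures and a fixed fraction of
#' genes flagged as transcription factors. All coordinates are 1-based and
#' intervals are closed; a position equal to an exon boundary lies inside
#' the exon.
#'
#' Intergenic gaps are drawn between 50 kb and 900 kb, so immediately
#' adjacent genes are within the 1 Mb cis window while genes two or more
#' slots apart on the same chromosome are in mutual trans range.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_chromosomes Number of chromosomes to distribute genes over.
#' @param tf_fraction Fraction of genes flagged as transcription factors;
#'   exactly `floor(tf_fraction * n_genes)` genes are flagged.
#' @param exon_count_range Length-two integer vector, inclusive range of
#'   exons per gene.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `is_tf` and a list-column `exons` of two-column
#'   matrices (start, end).
#' @export
generate_annotation <- function(n_genes, n_chromosomes = 4,
                                tf_fraction = 0.2,
                                exon_count_range = c(3L, 8L),
                                seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  check_prob(tf_fraction, "tf_fraction")
  if (length(exon_count_range) != 2 || any(exon_count_range < 1) ||
      exon_count_range[1] > exon_count_range[2]) {
    abort("`exon_count_range` must be an increasing pair of positive counts",
          class = "transppi_invalid_parameter")
  }

  with_seed(seed, {
    gene_id <- sprintf("G%04d", seq_len(n_genes))
    chrom <- paste0("chr", ((seq_len(n_genes) - 1L) %% n_chromosomes) + 1L)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    len <- round(runif(n_genes, 5e3, 3e4))
    n_exons <- sample(seq(exon_count_range[1], exon_count_range[2]),
                      n_genes, replace = TRUE)

    # lay genes per chromosome with gaps in (50kb, 900kb)
    start <- integer(n_genes)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos <- 1e4
      for (i in idx) {
        start[i] <- round(pos)
        pos <- pos + len[i] + runif(1, 5e4, 9e5)
      }
    }
    end <- start + len - 1L

    exons <- purrr::pmap(list(start, end, n_exons), function(s, e, k) {
      # split the span into 2k+1 alternating segments, exons on the evens
      cuts <- sort(sample(seq(s + 1, e - 1), 2L * k - 2L))
      bounds <- matrix(c(s, cuts, e), ncol = 2, byrow = TRUE)
      ex <- bounds[seq(1, nrow(bounds), by = 2), , drop = FALSE]
      colnames(ex) <- c("start", "end")
      ex
    })

    n_tf <- floor(tf_fraction * n_genes)
    is_tf <- rep(FALSE, n_genes)
    if (n_tf > 0) is_tf[sample.int(n_genes, n_tf)] <- TRUE

    tibble::tibble(gene_id = gene_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, is_tf = is_tf, exons = exons)
  })
}

#' Write / read a BED-like annotation table
#'
#' The on-disk format is a tab-separated table with 1-based closed
#' coordinates: `chrom, start, end, gene_id, strand, exon_starts,
#' exon_sizes, is_tf`, where `exon_starts`/`exon_sizes` are comma-joined
#' integers (absolute starts).
#'
#' @param annotation Annotation tibble as from [generate_annotation()].
#' @param path Output file.
#' @return `write_annotation()` returns `path` invisibly;
#'   `read_annotation()` returns the annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  out <- tibble::tibble(
    chrom = annotation$chrom,
    start = annotation$start,
    end = annotation$end,
    gene_id = annotation$gene_id,
    strand = annotation$strand,
    exon_starts = purrr::map_chr(annotation$exons,
                                 ~ paste(.x[, "start"], collapse = ",")),
    exon_sizes = purrr::map_chr(annotation$exons,
                                ~ paste(.x[, "end"] - .x[, "start"] + 1L,
                                        collapse = ",")),
    is_tf = as.integer(annotation$is_tf)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           exon_starts = readr::col_character(),
                           exon_sizes = readr::col_character(),
                           .default = readr::col_guess()))
  needed <- c("chrom", "start", "end", "gene_id", "strand",
              "exon_starts", "exon_sizes", "is_tf")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("annotation file %s is missing columns: %s", path,
                  paste(setdiff(needed, names(raw)), collapse = ", ")),
          class = "transppi_parse_error")
  }
  exons <- purrr::map2(raw$exon_starts, raw$exon_sizes, function(st, sz) {
    s <- as.integer(strsplit(st, ",")[[1]])
    w <- as.integer(strsplit(sz, ",")[[1]])
    ex <- cbind(start = s, end = s + w - 1L)
    ex
  })
  tibble::tibble(gene_id = raw$gene_id, chrom = raw$chrom,
                 start = as.integer(raw$start), end = as.integer(raw$end),
                 strand = raw$strand, is_tf = as.logical(raw$is_tf),
                 exons = exons)
}

# TRUE where position lies inside any exon of the gene (closed intervals)
position_in_exon <- function(pos, exons) {
  any(pos >= exons[, "start"] & pos <= exons[, "end"])
}
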