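#' Single-marker linear-regression association test
#'
#' Ordinary least squares of expression on additive dosage, with a
#' two-sided t-test on the slope. Samples with a missing dosage or
#' expression value are dropped pairwise.
#'
#' @param dosages Numeric vector of dosages (0/1/2, `NA` = missing).
#' @param expression Numeric vector of expression values, same length.
#' @return One-row tibble `(beta, se, t, p, n_used)`; `beta` is in
#'   expression units per dosage unit.
#' @export
test_association <- function(dosages, expression) {
  ok <- !is.na(dosages) & !is.na(expression)
  x <- dosages[ok]; y <- expression[ok]
  n <- length(x)
  if (n < 3) {
    abort(sprintf("only %d paired non-missing observations (need >= 3)", n),
          class = "transppi_insufficient_data")
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    abort("dosage has zero variance; association undefined",
          class = "transppi_undefined_test")
  }
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (x - mean(x))
  df <- n - 2
  se <- sqrt(sum(resid^2) / df / sxx)
  t <- if (se == 0) sign(beta) * Inf else beta / se
  p <- 2 * pt(-abs(t), df)
  tibble::tibble(beta = beta, se = se, t = t, p = p, n_used = n)
}

# Relation of a SNP position to a candidate target gene span.
# Returns "trans_diff_chrom", "trans_same_chrom_far", or NA (not trans).
trans_relation <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                           gene_end) {
  dplyr::case_when(
    snp_chrom != gene_chrom ~ "trans_diff_chrom",
    snp_pos < gene_start & gene_start - snp_pos >= 1e6 ~
      "trans_same_chrom_far",
    snp_pos > gene_end & snp_pos - gene_end >= 1e6 ~
      "trans_same_chrom_far",
    TRUE ~ NA_character_
  )
}

#' Trans association scan
#'
#' Tests every SNP of the requested region class against every gene's
#' expression by linear regression, keeping associations at
#' `p <= p_threshold` whose target is in trans with respect to the SNP:
#' on a different chromosome, or on the same chromosome with at least
#' 1 Mb between the SNP position and the nearest target-gene span
#' boundary. The SNP's own source gene is never reported as a target.
#'
#' @param G A filtered [genotype_matrix()].
#' @param E Expression matrix (samples x genes), samples aligned with `G`.
#' @param annotation Gene annotation tibble.
#' @param region_class `"exonic"` (SNPs inside exon intervals) or
#'   `"tf_span"` (SNPs anywhere in a TF gene span, introns included).
#' @param p_threshold Association p-value cutoff.
#' @return Tibble of source-target pairs, one row per (eSNP, target):
#'   `esnp_id, source_gene, target_gene, chrom, pos, beta, se, t, p,
#'   n_used, relation`, sorted by ascending p (ties by eSNP then target
#'   id).
#' @export
scan_trans <- function(G, E, annotation,
                       region_class = c("exonic", "tf_span"),
                       p_threshold = 1e-6) {
  region_class <- match.arg(region_class)
  stopifnot(inherits(G, "genotype_matrix"))
  if (!identical(rownames(E), G$samples)) {
    E <- E[G$samples, , drop = FALSE]
  }
  keep <- if (region_class == "exonic") G$snps$exonic else G$snps$tf_span
  keep[is.na(keep)] <- FALSE
  snps <- G$snps[keep, , drop = FALSE]
  if (nrow(snps) == 0) return(empty_pair_table())

  genes <- colnames(E)
  ann <- annotation[match(genes, annotation$gene_id), , drop = FALSE]

  res <- purrr::map(seq_len(nrow(snps)), function(i) {
    x <- G$dosage[, snps$snp_id[i]]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3) return(NULL)
    xs <- x[ok] - mean(x[ok])
    sxx <- sum(xs^2)
    if (sxx == 0) return(NULL)
    Y <- E[ok, , drop = FALSE]
    Yc <- sweep(Y, 2, colMeans(Y))
    sxy <- as.vector(crossprod(Yc, xs))
    syy <- colSums(Yc^2)
    beta <- sxy / sxx
    df <- n - 2
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / df / sxx)
    t <- ifelse(se == 0, sign(beta) * Inf, beta / se)
    p <- 2 * pt(-abs(t), df)

    hit <- which(p <= p_threshold)
    if (!length(hit)) return(NULL)
    rel <- trans_relation(snps$chrom[i], snps$pos[i], ann$chrom[hit],
                          ann$start[hit], ann$end[hit])
    same_gene <- !is.na(snps$source_gene[i]) &
      genes[hit] == snps$source_gene[i]
    ok_hit <- !is.na(rel) & !same_gene
    if (!any(ok_hit)) return(NULL)
    hit <- hit[ok_hit]
    tibble::tibble(esnp_id = snps$snp_id[i],
                   source_gene = snps$source_gene[i],
                   target_gene = genes[hit],
                   chrom = snps$chrom[i], pos = snps$pos[i],
                   beta = beta[hit], se = se[hit], t = t[hit],
                   p = p[hit], n_used = n,
                   relation = rel[ok_hit])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty_pair_table())
  dplyr::arrange(out, .data$p, .data$esnp_id, .data$target_gene)
}

empty_pair_table <- function() {
  tibble::tibble(esnp_id = character(0), source_gene = character(0),
                 target_gene = character(0), chrom = character(0),
                 pos = integer(0), beta = numeric(0), se = numeric(0),
                 t = numeric(0), p = numeric(0), n_used = integer(0),
                 relation = character(0))
}

#' Cis effect of an eSNP on its source gene
#'
#' The p-value of [test_association()] between the eSNP's dosages and the
#' expression of its own source gene, used to detect mild cis effects
#' beneath the genome-wide threshold.
#'
#' @param esnp_id SNP identifier present in `G`.
#' @param source_gene Gene identifier present in `E`.
#' @param G A [genotype_matrix()].
#' @param E Expression matrix (samples x genes).
#' @return A single p-value.
#' @export
cis_effect_test <- function(esnp_id, source_gene, G, E) {
  if (!source_gene %in% colnames(E)) {
    abort(sprintf("source gene %s absent from expression matrix",
                  source_gene), class = "transppi_invalid_parameter")
  }
  test_association(G$dosage[, esnp_id], E[G$samples, source_gene])$p
}

#' Reduce a scan to the best eSNP per source-target pair
#'
#' Keeps, for every unique (source, target) gene pair, the eSNP with the
#' smallest association p-value; ties are broken by the lexicographically
#' smallest SNP id. Unique-entity counts are attached as the `"counts"`
#' attribute.
#'
#' @param pairs Scan output ([scan_trans()]).
#' @return Tibble with one row per unique pair; attribute `counts` holds
#'   `n_records, n_unique_pairs, n_esnps, n_sources, n_targets`.
#' @export
best_esnp_per_pair <- function(pairs) {
  if (nrow(pairs) == 0) {
    abort("empty pair table", class = "transppi_invalid_parameter")
  }
  out <- pairs |>
    dplyr::arrange(.data$p, .data$esnp_id) |>
    dplyr::distinct(.data$source_gene, .data$target_gene,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$p, .data$esnp_id, .data$target_gene)
  attr(out, "counts") <- list(
    n_records = nrow(pairs),
    n_unique_pairs = nrow(out),
    n_esnps = dplyr::n_distinct(pairs$esnp_id),
    n_sources = dplyr::n_distinct(pairs$source_gene),
    n_targets = dplyr::n_distinct(pairs$target_gene))
  out
}

#' Chromosome-relation bookkeeping for a pair table
#'
#' @param pairs A pair table with a `relation` column.
#' @return Tibble `(relation, n, percent)` with percentages of the total.
#' @export
relation_summary <- function(pairs) {
  pairs |>
    dplyr::count(.data$relation, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
}
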