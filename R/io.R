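#' Write / read an expression matrix as TSV
#'
#' On disk the table has one row per gene: a `gene_id` column followed
#' by one column per sample; in memory the matrix is samples x genes.
#'
#' @param E Numeric matrix, samples x genes.
#' @param path File path.
#' @export
write_expression <- function(E, path) {
  out <- dplyr::bind_cols(tibble::tibble(gene_id = colnames(E)),
                          tibble::as_tibble(t(E)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(raw)[1] != "gene_id") {
    abort(sprintf("%s: first column must be gene_id", path),
          class = "transppi_parse_error")
  }
  if (!all(vapply(raw[-1], is.numeric, logical(1)))) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1] + 1
    abort(sprintf("%s: column %d is not numeric", path, bad),
          class = "transppi_parse_error")
  }
  E <- t(as.matrix(raw[, -1]))
  colnames(E) <- raw$gene_id
  if (any(!is.finite(E))) {
    abort(sprintf("%s: non-finite expression values", path),
          class = "transppi_parse_error")
  }
  E
}

#' @rdname load_network
#' @export
read_edge_list <- function(path) load_network(path)

#' Write pair tables / partitions / distance triplets
#'
#' Small text writers for the remaining result types: pair tables as
#' TSV, a partition as `(node, cluster)` TSV, and a distance matrix in
#' sparse triplet form `(from, to, distance)` over the upper triangle.
#'
#' @param x Object to write.
#' @param path File path.
#' @export
write_pairs <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
write_partition <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(unclass(x)[c("node", "cluster")]),
                   path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
write_distance_triplets <- function(x, path) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(from = rownames(x)[idx[, 1]],
                                  to = colnames(x)[idx[, 2]],
                                  distance = x[idx]), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Builds (and validates) the configuration list consumed by
#' [run_pipeline()]. All randomness in a run flows from `seed`; every
#' stage derives an independent sub-seed from it. The configuration
#' round-trips losslessly through JSON via [write_config()] /
#' [read_config()].
#'
#' @param seed Master seed.
#' @param n_samples,n_genes,n_chromosomes,n_clusters Fixture dimensions.
#' @param p_in,p_out,ppi_degree_heterogeneity Planted-partition edge
#'   probabilities and degree-correction sdlog.
#' @param snps_per_gene,maf_range,missing_rate Genotype parameters.
#' @param tf_fraction Fraction of genes flagged TF.
#' @param n_exon_sources,n_tf_sources,targets_per_tf,n_background Planted
#'   effect counts.
#' @param cis_beta,trans_beta,background_scale,min_causal_maf,proximal_radius,noise_sd
#'   Planted effect parameters.
#' @param maf_min,snp_missing_max,sample_missing_max QC thresholds.
#' @param p_threshold Association p-value cutoff for the trans scans.
#' @param n_perm Permutations for the trend null.
#' @param n_null_pairs Random pairs for co-occurrence / binding nulls.
#' @param n_tf_sets Permuted TF pair sets for the multiplicity test.
#' @param fdr Enrichment FDR threshold.
#' @param alpha Nominal cis significance level.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, n_samples = 50, n_genes = 200,
                       n_chromosomes = 4, n_clusters = 4, p_in = 0.3,
                       p_out = 0.01, ppi_degree_heterogeneity = 0.75,
                       snps_per_gene = 3,
                       maf_range = c(0.1, 0.49), missing_rate = 0.02,
                       tf_fraction = 0.2, n_exon_sources = 12,
                       n_tf_sources = 4, targets_per_tf = 3,
                       n_background = 40,
                       cis_beta = 1.5, trans_beta = 1.5,
                       background_scale = 0.55, min_causal_maf = 0.3,
                       proximal_radius = 1,
                       noise_sd = 1, maf_min = 0.05, snp_missing_max = 0.1,
                       sample_missing_max = 0.1, p_threshold = 1e-6,
                       n_perm = 1000, n_null_pairs = 2000,
                       n_tf_sets = 1000, fdr = 0.05, alpha = 0.05) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  check_prob(cfg$fdr, "fdr"); check_prob(cfg$alpha, "alpha")
  check_prob(cfg$p_threshold, "p_threshold")
  check_prob(cfg$missing_rate, "missing_rate")
  check_count(cfg$n_samples, "n_samples", 3)
  check_count(cfg$n_genes, "n_genes", 2)
  check_count(cfg$n_perm, "n_perm")
  invisible(cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}
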