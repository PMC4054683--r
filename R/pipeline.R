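#' Simulate a complete planted study
#'
#' Generates every input the analysis consumes — annotation, a
#' community-structured interaction network keyed to the genes, HWE
#' genotypes, a planted effect plan, expression driven by the plan,
#' cluster-aligned gene sets and a synthetic binding-pair table — from a
#' single master seed.
#'
#' @param config A [run_config()].
#' @return List with `annotation`, `network`, `genotypes`, `plan`,
#'   `expression`, `partition` (Louvain on the simulated network),
#'   `gene_sets`, `binding_pairs`, `config`.
#' @export
simulate_study <- function(config = run_config()) {
  s <- function(tag) derive_seed(config$seed, tag)
  annotation <- generate_annotation(
    config$n_genes, config$n_chromosomes, config$tf_fraction,
    seed = s("annotation"))
  network <- generate_ppi_network(
    n_clusters = config$n_clusters, p_in = config$p_in,
    p_out = config$p_out, seed = s("network"),
    nodes = annotation$gene_id,
    degree_heterogeneity = config$ppi_degree_heterogeneity)
  genotypes <- generate_genotypes(
    config$n_samples, annotation, config$snps_per_gene,
    config$maf_range, config$missing_rate, seed = s("genotypes"))
  plan <- plant_effects(
    annotation, network, genotypes,
    n_exon_sources = config$n_exon_sources,
    n_tf_sources = config$n_tf_sources,
    targets_per_tf = config$targets_per_tf,
    cis_beta = config$cis_beta, trans_beta = config$trans_beta,
    proximal_radius = config$proximal_radius,
    n_background = config$n_background,
    background_scale = config$background_scale,
    min_causal_maf = config$min_causal_maf, seed = s("plan"))
  expression <- generate_expression(
    genotypes, plan, annotation, config$noise_sd, seed = s("expression"))
  partition <- louvain_clusters(network, seed = s("louvain"))
  gene_sets <- generate_gene_sets(annotation, partition,
                                  seed = s("gene_sets"))
  binding_pairs <- generate_binding_pairs(plan, annotation,
                                          include_fraction = 1,
                                          decoy_fraction = 0.5,
                                          seed = s("binding"))
  list(annotation = annotation, network = network, genotypes = genotypes,
       plan = plan, expression = expression, partition = partition,
       gene_sets = gene_sets, binding_pairs = binding_pairs,
       config = config)
}

#' Run the full trans-eSNP / network analysis
#'
#' Executes the complete pipeline on a study (simulated via
#' [simulate_study()] or assembled from files): genotype QC, exon and TF
#' trans scans, network topology, cumulative threshold trends with a
#' permutation null, Louvain clustering, and the enrichment battery
#' (cis-effect binomial test, co-expression comparison, cluster
#' co-occurrence, TF target multiplicity, unit enrichment, binding
#' membership, path-annotation content). When `out_dir` is given, all
#' result tables plus a JSON manifest are written there; outputs are
#' bit-identical across runs of the same configuration.
#'
#' @param study A study list as from [simulate_study()].
#' @param out_dir Optional output directory (created if needed).
#' @return A `trans_run` list with all stage results.
#' @export
run_pipeline <- function(study, out_dir = NULL) {
  cfg <- study$config
  s <- function(tag) derive_seed(cfg$seed, tag)
  stage <- "qc"
  res <- list(config = cfg)
  tryCatch({
    G <- filter_genotypes(study$genotypes, cfg$maf_min,
                          cfg$snp_missing_max, cfg$sample_missing_max)
    res$genotypes <- G

    stage <- "association"
    E <- study$expression[G$samples, , drop = FALSE]
    res$exon_pairs <- scan_trans(G, E, study$annotation, "exonic",
                                 cfg$p_threshold)
    res$tf_pairs <- scan_trans(G, E, study$annotation, "tf_span",
                               cfg$p_threshold)
    res$exon_best <- if (nrow(res$exon_pairs))
      best_esnp_per_pair(res$exon_pairs) else res$exon_pairs
    res$tf_best <- if (nrow(res$tf_pairs))
      best_esnp_per_pair(res$tf_pairs) else res$tf_pairs
    res$relation <- relation_summary(res$exon_pairs)

    stage <- "topology"
    res$distances <- all_pairs_distances(study$network)
    res$partition <- louvain_clusters(study$network, seed = s("louvain"))

    stage <- "threshold_scan"
    if (nrow(res$exon_best) >= 2) {
      res$profile <- cumulative_property_profile(res$exon_best,
                                                 res$distances,
                                                 study$network)
      res$trend_null <- permuted_trend_distribution(
        attr(res$profile, "pairs"), study$network, res$distances,
        n_perm = cfg$n_perm, seed = s("trend"))
      res$trend <- trend_significance(res$profile, res$trend_null)
    }

    stage <- "enrichment"
    # cis-effect enrichment over unique exon sources
    if (nrow(res$exon_best)) {
      src <- res$exon_best |>
        dplyr::arrange(.data$p, .data$esnp_id) |>
        dplyr::distinct(.data$source_gene, .keep_all = TRUE)
      cis_p <- vapply(seq_len(nrow(src)), function(i) {
        cis_effect_test(src$esnp_id[i], src$source_gene[i], G, E)
      }, numeric(1))
      res$cis <- list(k_nominal = sum(cis_p < cfg$alpha),
                      n_sources = nrow(src),
                      p = binomial_cis_enrichment(sum(cis_p < cfg$alpha),
                                                  nrow(src), cfg$alpha))
      res$coexpression <- coexpression_comparison(res$exon_best, E,
                                                  seed = s("coexpr"))
    }

    null_pairs <- sample_network_pairs(study$network, cfg$n_null_pairs,
                                       seed = s("null_pairs"))
    if (nrow(res$tf_best)) {
      res$tf_cooccurrence <- cluster_cooccurrence(res$tf_best,
                                                  res$partition, null_pairs)
      tf_sets <- sample_permuted_tf_sets(res$tf_pairs, cfg$n_tf_sets,
                                         seed = s("tf_sets"))
      res$tf_multiplicity <- tf_multiplicity_test(res$tf_pairs, tf_sets)
      res$units <- tf_units(res$tf_best)
      res$unit_enrichment <- unit_enrichment(res$units, study$gene_sets,
                                             cfg$fdr)
      if (!is.null(study$binding_pairs)) {
        res$binding <- binding_membership_enrichment(
          res$tf_best, tf_sets[[1]], study$binding_pairs)
      }
    }
    if (nrow(res$exon_best)) {
      res$exon_cooccurrence <- cluster_cooccurrence(res$exon_best,
                                                    res$partition,
                                                    null_pairs)
      res$paths <- connected_paths(study$network, res$exon_best)
      if (length(res$paths) >= 2) {
        pool <- connected_paths(study$network, null_pairs)
        lens <- vapply(res$paths, function(p) p$length, integer(1))
        sets <- try(sample_length_matched_paths(pool, lens,
                                                n_sets = min(cfg$n_tf_sets,
                                                             500),
                                                seed = s("path_sets")),
                    silent = TRUE)
        if (!inherits(sets, "try-error")) {
          res$path_enrichment <- path_category_enrichment(
            res$paths, sets, study$gene_sets)
        }
      }
    }
    res$summary <- summarise_run(res, study)
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), class = "transppi_stage_error",
          parent = e)
  })

  class(res) <- "trans_run"
  if (!is.null(out_dir)) write_run(res, study, out_dir)
  res
}

# TF units (one TF source with all its distinct targets) from a pair table
tf_units <- function(tf_pairs) {
  tf_pairs |>
    dplyr::group_by(tf_source = .data$source_gene) |>
    dplyr::summarise(targets = list(unique(.data$target_gene)))
}

# canonical shortest paths for the same-component pairs of a pair table
connected_paths <- function(network, pairs) {
  pr <- normalise_pairs(pairs)
  nodes <- igraph::V(network)$name
  comp <- igraph::components(network)$membership
  out <- list()
  for (i in seq_len(nrow(pr))) {
    s <- pr$source[i]; t <- pr$target[i]
    if (!(s %in% nodes) || !(t %in% nodes)) next
    if (comp[[s]] != comp[[t]]) next
    out[[length(out) + 1]] <- shortest_path(network, s, t)
  }
  out
}

summarise_run <- function(res, study) {
  planted <- planned_pairs(study$plan)
  strong <- planted[planted$type == "exon", ]
  found <- paste(res$exon_pairs$source_gene, res$exon_pairs$target_gene)
  recovery <- mean(paste(strong$source_gene, strong$target_gene) %in% found)
  tibble::tibble(
    n_exon_records = nrow(res$exon_pairs),
    n_exon_pairs = nrow(res$exon_best),
    n_tf_pairs = nrow(res$tf_best),
    exon_recovery = recovery,
    pct_diff_chrom = if (nrow(res$relation)) {
      sum(res$relation$percent[res$relation$relation == "trans_diff_chrom"])
    } else NA_real_,
    r_distance = if (!is.null(res$profile))
      attr(res$profile, "spearman_r")[["mean_distance"]] else NA_real_,
    r_target_degree = if (!is.null(res$profile))
      attr(res$profile, "spearman_r")[["mean_target_degree"]] else NA_real_,
    cis_enrichment_p = if (!is.null(res$cis)) res$cis$p else NA_real_,
    coexpression_p = if (!is.null(res$coexpression))
      res$coexpression$wilcoxon_p else NA_real_,
    tf_cooccurrence_p = if (!is.null(res$tf_cooccurrence))
      res$tf_cooccurrence$fisher_p else NA_real_,
    units_enriched = if (!is.null(res$unit_enrichment))
      res$unit_enrichment$n_enriched else NA_integer_,
    modularity_q = attr(res$partition, "modularity_q"))
}

write_run <- function(res, study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_annotation(study$annotation, fp("annotation.tsv"))
  write_edge_list(study$network, fp("network.tsv"))
  write_pairs(res$exon_pairs, fp("exon_pairs.tsv"))
  write_pairs(res$tf_pairs, fp("tf_pairs.tsv"))
  write_partition(res$partition, fp("clusters.tsv"))
  if (!is.null(res$profile)) {
    readr::write_tsv(tibble::as_tibble(unclass(res$profile))[
      c("threshold", "n_pairs", "mean_distance", "mean_source_degree",
        "mean_target_degree")], fp("trend_profile.tsv"))
    readr::write_tsv(res$trend, fp("trend_significance.tsv"))
  }
  readr::write_tsv(res$summary, fp("summary.tsv"))
  manifest <- list(package = "transppi",
                   version = as.character(utils::packageVersion("transppi")),
                   config = unclass(res$config))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.trans_run <- function(x, ...) {
  cat("<trans_run>\n")
  print(x$summary)
  invisible(x)
}
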