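#' Fisher's exact test on a 2x2 table
#'
#' Thin, argument-checked wrapper around the exact hypergeometric test
#' for the table `rbind(c(a, b), c(c, d))`, where row 1 is the focal
#' group (e.g. real pairs: hits / misses) and row 2 the background.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param sided `"greater"` (enrichment of `a`) or `"two"`.
#' @return List `(odds_ratio, p)`.
#' @export
fisher_2x2 <- function(a, b, c, d, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("cell counts must be non-negative integers",
          class = "transppi_invalid_parameter")
  }
  ft <- fisher.test(matrix(counts, nrow = 2, byrow = TRUE),
                    alternative = if (sided == "two") "two.sided" else
                      "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Binomial enrichment of nominal cis effects
#'
#' Under the null that each unique source gene shows a nominal
#' (`p < alpha`) cis association by chance alone, the number of such
#' sources is Binomial(`n_sources`, `alpha`). Returns the strict upper
#' tail `P(X > k_nominal)`.
#'
#' @param k_nominal Observed number of sources with a nominal cis effect.
#' @param n_sources Number of unique source genes tested.
#' @param alpha Nominal significance level.
#' @return Upper-tail probability.
#' @export
binomial_cis_enrichment <- function(k_nominal, n_sources, alpha = 0.05) {
  k_nominal <- check_count(k_nominal, "k_nominal", min = 0)
  n_sources <- check_count(n_sources, "n_sources", min = 1)
  check_prob(alpha, "alpha")
  if (k_nominal > n_sources) {
    abort("`k_nominal` cannot exceed `n_sources`",
          class = "transppi_invalid_parameter")
  }
  pbinom(k_nominal, n_sources, alpha, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment with BH-FDR
#'
#' For each category, the upper-tail hypergeometric probability of
#' observing at least the overlap between the query and the category
#' within the background, with Benjamini-Hochberg q-values across all
#' tested categories. Categories overlapping the query below
#' `min_overlap` are excluded before testing.
#'
#' @param query Character vector of genes (subset of the background).
#' @param collection A `gene_set_collection`.
#' @param min_overlap Minimum query-category overlap to test.
#' @param fdr_threshold Used only to flag `significant` rows.
#' @return Tibble `(category, overlap, set_size, query_size,
#'   background_size, p, q, significant)`, sorted by p.
#' @export
hypergeometric_enrichment <- function(query, collection, min_overlap = 1,
                                      fdr_threshold = 0.05) {
  bg <- collection$background
  if (!length(bg)) {
    abort("empty background", class = "transppi_invalid_parameter")
  }
  query <- unique(intersect(query, bg))
  res <- purrr::imap_dfr(collection$categories, function(set, nm) {
    k <- length(intersect(query, set))
    if (k < min_overlap) return(NULL)
    # P(X >= k), X ~ Hypergeom(white = |set|, black = |bg|-|set|, n = |query|)
    p <- phyper(k - 1, length(set), length(bg) - length(set),
                length(query), lower.tail = FALSE)
    tibble::tibble(category = nm, overlap = k, set_size = length(set),
                   query_size = length(query),
                   background_size = length(bg), p = p)
  })
  if (nrow(res) == 0) return(dplyr::mutate(
    tibble::tibble(category = character(0), overlap = integer(0),
                   set_size = integer(0), query_size = integer(0),
                   background_size = integer(0), p = numeric(0)),
    q = numeric(0), significant = logical(0)))
  res$q <- benjamini_hochberg(res$p)
  res$significant <- res$q < fdr_threshold
  dplyr::arrange(res, .data$p, .data$category)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order, each capped at 1.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "transppi_invalid_parameter")
  }
  p.adjust(p_values, method = "BH")
}

#' Functional enrichment of TF regulatory units
#'
#' A unit is a TF source together with its trans targets, tested as a
#' single gene set against the collection. Only units with at least two
#' genes are tested; following the convention for annotation support, a
#' unit counts as enriched when some category overlaps it in two or more
#' genes at `FDR < fdr_threshold`.
#'
#' @param units Tibble `(tf_source, targets)` with `targets` a
#'   list-column, or an `effect_plan` (its TF entries are used).
#' @param collection A `gene_set_collection`.
#' @param fdr_threshold FDR cutoff for calling a unit enriched.
#' @return List with `per_unit` (named list of enrichment tables),
#'   `n_units`, `n_enriched`.
#' @export
unit_enrichment <- function(units, collection, fdr_threshold = 0.05) {
  if (inherits(units, "effect_plan")) {
    pp <- planned_pairs(units)
    pp <- pp[pp$type == "tf", ]
    units <- pp |>
      dplyr::group_by(tf_source = .data$source_gene) |>
      dplyr::summarise(targets = list(.data$target_gene))
  }
  per_unit <- list()
  enriched <- logical(0)
  for (i in seq_len(nrow(units))) {
    genes <- unique(c(units$tf_source[i], units$targets[[i]]))
    if (length(genes) < 2) next
    tab <- hypergeometric_enrichment(genes, collection, min_overlap = 2,
                                     fdr_threshold = fdr_threshold)
    per_unit[[units$tf_source[i]]] <- tab
    enriched <- c(enriched, any(tab$significant))
  }
  list(per_unit = per_unit, n_units = length(per_unit),
       n_enriched = sum(enriched))
}

#' Source-target co-expression versus the background distribution
#'
#' Spearman |r| between each source-target expression pair compared, by
#' two-sided Wilcoxon rank-sum test, with |r| over background gene
#' pairs (all pairs by default, or a random subsample for large gene
#' sets).
#'
#' @param pairs Pair table with `source_gene`/`target_gene`.
#' @param E Expression matrix (samples x genes).
#' @param max_background Cap on the number of background pairs (sampled
#'   deterministically when exceeded).
#' @param seed Seed for background subsampling.
#' @return List `(wilcoxon_p, median_abs_r_real, median_abs_r_background,
#'   real_r, background_r)`.
#' @export
coexpression_comparison <- function(pairs, E, max_background = 20000,
                                    seed = 1L) {
  pr <- normalise_pairs(pairs)
  pr <- pr[pr$source %in% colnames(E) & pr$target %in% colnames(E), ]
  if (nrow(pr) < 1) {
    abort("no pairs with expression data", class = "transppi_invalid_parameter")
  }
  real_r <- vapply(seq_len(nrow(pr)), function(i) {
    suppressWarnings(cor(E[, pr$source[i]], E[, pr$target[i]],
                         method = "spearman"))
  }, numeric(1))

  genes <- colnames(E)
  all_pairs <- utils::combn(length(genes), 2)
  if (ncol(all_pairs) > max_background) {
    keep <- with_seed(derive_seed(seed, "coexpr_bg"),
                      sample.int(ncol(all_pairs), max_background))
    all_pairs <- all_pairs[, keep, drop = FALSE]
  }
  R <- suppressWarnings(cor(E, method = "spearman"))
  bg_r <- R[cbind(all_pairs[1, ], all_pairs[2, ])]

  wp <- suppressWarnings(
    wilcox.test(abs(real_r), abs(bg_r), alternative = "two.sided")$p.value)
  list(wilcoxon_p = wp,
       median_abs_r_real = median(abs(real_r)),
       median_abs_r_background = median(abs(bg_r)),
       real_r = real_r, background_r = bg_r)
}

#' One-sided comparison of trans versus cis effect sizes
#'
#' Wilcoxon rank-sum test of the alternative that trans |beta| values
#' are stochastically larger than cis |beta| values.
#'
#' @param trans_betas,cis_betas Numeric vectors of absolute effect sizes.
#' @return p-value.
#' @export
effect_size_comparison <- function(trans_betas, cis_betas) {
  if (!length(trans_betas) || !length(cis_betas)) {
    abort("both effect-size vectors must be non-empty",
          class = "transppi_invalid_parameter")
  }
  suppressWarnings(
    wilcox.test(abs(trans_betas), abs(cis_betas),
                alternative = "greater")$p.value)
}

#' Cluster co-occurrence of source-target pairs
#'
#' Counts how many real pairs have source and target in the same network
#' cluster, compares against the same count in a null pair set by
#' one-sided Fisher's exact test (enrichment of co-occurrence in the
#' real pairs).
#'
#' @param pairs Real pair table.
#' @param partition A `ppi_partition` or tibble `(node, cluster)`.
#' @param null_pairs A `random_pair_set` (e.g. from
#'   [sample_network_pairs()]).
#' @param sided Passed to [fisher_2x2()].
#' @return List `(real_k, real_n, null_k, null_n, odds_ratio, fisher_p)`.
#' @export
cluster_cooccurrence <- function(pairs, partition, null_pairs,
                                 sided = "greater") {
  memb <- stats::setNames(partition$cluster, partition$node)
  same_cluster <- function(p) {
    p <- normalise_pairs(p)
    on <- p$source %in% names(memb) & p$target %in% names(memb)
    p <- p[on, , drop = FALSE]
    c(k = sum(memb[p$source] == memb[p$target]), n = nrow(p))
  }
  re <- same_cluster(pairs)
  nu <- same_cluster(null_pairs)
  ft <- fisher_2x2(re["k"], re["n"] - re["k"], nu["k"], nu["n"] - nu["k"],
                   sided = sided)
  list(real_k = unname(re["k"]), real_n = unname(re["n"]),
       null_k = unname(nu["k"]), null_n = unname(nu["n"]),
       odds_ratio = ft$odds_ratio, fisher_p = ft$p)
}

#' Membership of TF source-target pairs in a binding database
#'
#' Restricts both the real and the permuted pairs to those whose TF
#' source appears in the database at all, counts exact (TF, target)
#' membership in each group and compares the two rates by one-sided
#' Fisher's exact test.
#'
#' @param real_tf_pairs,null_tf_pairs Pair tables (`source`/`target` or
#'   `source_gene`/`target_gene` columns).
#' @param binding_db Tibble `(tf_gene, target_gene)`.
#' @return List `(real_k, real_n, null_k, null_n, odds_ratio, fisher_p)`.
#' @export
binding_membership_enrichment <- function(real_tf_pairs, null_tf_pairs,
                                          binding_db) {
  if (is.null(binding_db) || nrow(binding_db) == 0) {
    abort("binding database is empty", class = "transppi_feasibility_error")
  }
  db_key <- paste(binding_db$tf_gene, binding_db$target_gene)
  db_tfs <- unique(binding_db$tf_gene)
  tally <- function(p) {
    p <- normalise_pairs(p)
    p <- p[p$source %in% db_tfs, , drop = FALSE]
    c(k = sum(paste(p$source, p$target) %in% db_key), n = nrow(p))
  }
  re <- tally(real_tf_pairs)
  nu <- tally(null_tf_pairs)
  ft <- fisher_2x2(re["k"], re["n"] - re["k"], nu["k"], nu["n"] - nu["k"])
  list(real_k = unname(re["k"]), real_n = unname(re["n"]),
       null_k = unname(nu["k"]), null_n = unname(nu["n"]),
       odds_ratio = ft$odds_ratio, fisher_p = ft$p)
}

#' Empirical annotation-content tests on shortest-path sets
#'
#' For every category, two statistics are computed on the real paths and
#' on each length-matched permuted set: the number of category genes
#' appearing along the paths (counted with repetition across paths) and
#' the number of paths containing at least one category gene. The
#' empirical p-value is the fraction of permuted sets achieving an equal
#' or greater value ("ties count"). Path gene content includes the
#' endpoints by default.
#'
#' @param real_paths List of `path_record` objects.
#' @param permuted_sets List of permuted path lists
#'   ([sample_length_matched_paths()]).
#' @param collection A `gene_set_collection`.
#' @param include_endpoints Include source/target genes in the content.
#' @return Tibble `(category, gene_count, path_count, gene_count_emp_p,
#'   path_count_emp_p)`.
#' @export
path_category_enrichment <- function(real_paths, permuted_sets, collection,
                                     include_endpoints = TRUE) {
  path_genes <- function(p) {
    if (include_endpoints) p$nodes else p$intermediates
  }
  content_stats <- function(paths, set) {
    per_path <- vapply(paths, function(p) {
      sum(path_genes(p) %in% set)
    }, numeric(1))
    c(gene_count = sum(per_path), path_count = sum(per_path >= 1))
  }
  purrr::imap_dfr(collection$categories, function(set, nm) {
    if (!length(intersect(set, collection$background))) {
      warn(sprintf("category %s absent from background; skipped", nm))
      return(NULL)
    }
    real <- content_stats(real_paths, set)
    null <- vapply(permuted_sets, content_stats, numeric(2), set = set)
    tibble::tibble(
      category = nm,
      gene_count = real[["gene_count"]],
      path_count = real[["path_count"]],
      gene_count_emp_p = mean(null["gene_count", ] >= real[["gene_count"]]),
      path_count_emp_p = mean(null["path_count", ] >= real[["path_count"]]))
  })
}

#' Positional bias of eSNPs within their host transcripts
#'
#' Two complementary tests against the background SNP set: (i) a
#' one-sided Fisher test of eSNPs falling in *middle* exons versus
#' first/last exons (genes with a single exon are excluded; with two
#' exons only first/last bins exist; exon order is strand-aware); and
#' (ii) a Wilcoxon rank-sum test on the strand-aware fractional position
#' of the SNP within the concatenated exonic sequence (alternative:
#' eSNPs lie farther down the transcript).
#'
#' @param esnp_snps,background_snps Tibbles with `chrom`, `pos` and
#'   `source_gene` columns (exonic SNPs only).
#' @param annotation Gene annotation tibble.
#' @return List `(exon_bin_fisher_p, exon_bin_table,
#'   transcript_position_wilcoxon_p, esnp_positions,
#'   background_positions)`.
#' @export
positional_bias_test <- function(esnp_snps, background_snps, annotation) {
  ann_idx <- stats::setNames(seq_len(nrow(annotation)), annotation$gene_id)

  classify <- function(snps) {
    bins <- character(nrow(snps)); frac <- rep(NA_real_, nrow(snps))
    for (i in seq_len(nrow(snps))) {
      j <- ann_idx[[snps$source_gene[i]]]
      ex <- annotation$exons[[j]]
      k <- which(snps$pos[i] >= ex[, "start"] & snps$pos[i] <= ex[, "end"])
      if (!length(k)) { bins[i] <- NA_character_; next }
      ne <- nrow(ex)
      # strand-aware exon rank: exon 1 is 5'-most
      rank <- if (annotation$strand[j] == "+") k else ne - k + 1
      bins[i] <- if (ne < 2) NA_character_ else
        if (rank == 1) "first" else if (rank == ne) "last" else "middle"
      # fractional position along concatenated exons, strand-aware
      w <- ex[, "end"] - ex[, "start"] + 1
      before <- if (annotation$strand[j] == "+") {
        sum(w[seq_len(k - 1)]) + (snps$pos[i] - ex[k, "start"])
      } else {
        sum(w[-seq_len(k)]) + (ex[k, "end"] - snps$pos[i])
      }
      frac[i] <- (before + 1) / sum(w)
    }
    list(bins = bins, frac = frac)
  }

  es <- classify(esnp_snps)
  bg <- classify(background_snps)
  tab <- c(a = sum(es$bins == "middle", na.rm = TRUE),
           b = sum(es$bins %in% c("first", "last")),
           c = sum(bg$bins == "middle", na.rm = TRUE),
           d = sum(bg$bins %in% c("first", "last")))
  fp <- fisher_2x2(tab["a"], tab["b"], tab["c"], tab["d"])$p
  wp <- suppressWarnings(
    wilcox.test(es$frac, bg$frac, alternative = "greater")$p.value)
  list(exon_bin_fisher_p = fp,
       exon_bin_table = unname(tab),
       transcript_position_wilcoxon_p = wp,
       esnp_positions = es$frac, background_positions = bg$frac)
}
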