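#' Edge-switching random source-target pairs
#'
#' Draws `n` pairs by picking a source from the observed source multiset
#' and, independently, a target from the observed target multiset, so
#' each marginal distribution is preserved in expectation while the
#' pairing is destroyed. With `unique = TRUE`, duplicated (source,
#' target) combinations and source = target draws are rejected and
#' resampled.
#'
#' @param real_sources,real_targets Character vectors (multisets) of the
#'   observed sources and targets.
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @param unique Reject duplicate pairs and self-pairs.
#' @return A `random_pair_set`: tibble `(source, target)` with attributes
#'   `scheme` and `seed`.
#' @export
sample_random_pairs <- function(real_sources, real_targets, n, seed = 1L,
                                unique = FALSE) {
  n <- check_count(n, "n")
  if (!length(real_sources) || !length(real_targets)) {
    abort("source/target multisets must be non-empty",
          class = "transppi_invalid_parameter")
  }
  if (unique) {
    n_distinct <- sum(outer(unique(real_sources), unique(real_targets),
                            `!=`))
    if (n > n_distinct) {
      abort(sprintf("requested %d unique pairs but only %d are possible",
                    n, n_distinct), class = "transppi_feasibility_error")
    }
  }
  with_seed(seed, {
    out <- tibble::tibble(source = character(0), target = character(0))
    repeat {
      m <- n - nrow(out)
      if (m <= 0) break
      cand <- tibble::tibble(
        source = sample(real_sources, m, replace = TRUE),
        target = sample(real_targets, m, replace = TRUE))
      if (unique) {
        cand <- cand[cand$source != cand$target, , drop = FALSE]
        out <- dplyr::distinct(dplyr::bind_rows(out, cand))
      } else {
        out <- dplyr::bind_rows(out, cand)
      }
    }
    structure(out, scheme = if (unique) "edge_switching_unique" else
      "edge_switching", seed = seed, class = c("random_pair_set",
                                               class(out)))
  })
}

#' Uniform random unique node pairs from a network
#'
#' `n` distinct unordered pairs of distinct nodes, uniform over the
#' network's node set.
#'
#' @param network `igraph` graph with >= 2 nodes.
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return A `random_pair_set` tibble `(source, target)`.
#' @export
sample_network_pairs <- function(network, n, seed = 1L) {
  n <- check_count(n, "n")
  nodes <- igraph::V(network)$name
  if (length(nodes) < 2) {
    abort("need >= 2 network nodes", class = "transppi_invalid_parameter")
  }
  if (n > choose(length(nodes), 2)) {
    abort("more unique pairs requested than exist",
          class = "transppi_feasibility_error")
  }
  with_seed(seed, {
    m <- draw_unique_pairs(nodes, n)
    structure(tibble::tibble(source = m[, 1], target = m[, 2]),
              scheme = "network_uniform", seed = seed,
              class = c("random_pair_set", "tbl_df", "tbl", "data.frame"))
  })
}

#' Permuted sets of TF source-target pairs
#'
#' `n_sets` edge-switching draws, each of the same size as the observed
#' TF pair list, used as the null for the target-multiplicity test.
#'
#' @param real_tf_pairs Tibble with `source`/`target` columns (or
#'   `source_gene`/`target_gene`).
#' @param n_sets Number of permuted sets.
#' @param seed Integer seed; each set uses an independent derived
#'   sub-seed.
#' @return List of `random_pair_set` tibbles.
#' @export
sample_permuted_tf_sets <- function(real_tf_pairs, n_sets = 1000,
                                    seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets")
  pr <- normalise_pairs(real_tf_pairs)
  lapply(seq_len(n_sets), function(b) {
    sample_random_pairs(pr$source, pr$target, nrow(pr),
                        seed = derive_seed(seed, "tf_sets", b))
  })
}

normalise_pairs <- function(pairs) {
  if (all(c("source", "target") %in% names(pairs))) {
    tibble::tibble(source = pairs$source, target = pairs$target)
  } else if (all(c("source_gene", "target_gene") %in% names(pairs))) {
    tibble::tibble(source = pairs$source_gene, target = pairs$target_gene)
  } else {
    abort("pair table needs source/target columns",
          class = "transppi_invalid_parameter")
  }
}

#' Target-multiplicity test for TF sources
#'
#' Statistic: the number of source genes with two or more distinct
#' targets. The empirical p-value is the fraction of permuted sets whose
#' statistic is at least the observed one; a Wilcoxon rank-sum test
#' additionally compares the per-source target-count distribution in the
#' real data against the pooled permuted sets. The raw per-source count
#' vectors are returned so alternative multiplicity statistics can be
#' derived directly.
#'
#' @param real_tf_pairs Observed TF source-target pairs.
#' @param permuted_sets List from [sample_permuted_tf_sets()].
#' @return List with `statistic`, `empirical_p`, `wilcoxon_p`,
#'   `real_counts` (per-source distinct-target counts) and
#'   `null_statistics`.
#' @export
tf_multiplicity_test <- function(real_tf_pairs, permuted_sets) {
  if (!length(permuted_sets)) {
    abort("no permuted sets supplied", class = "transppi_invalid_parameter")
  }
  multi <- function(p) {
    cnt <- tapply(p$target, p$source, function(x) length(unique(x)))
    as.integer(cnt)
  }
  real <- multi(normalise_pairs(real_tf_pairs))
  null_counts <- lapply(permuted_sets, function(s) multi(normalise_pairs(s)))
  stat <- sum(real >= 2)
  null_stats <- vapply(null_counts, function(x) sum(x >= 2), integer(1))
  wp <- suppressWarnings(
    wilcox.test(real, unlist(null_counts), alternative = "greater")$p.value)
  list(statistic = stat,
       empirical_p = mean(null_stats >= stat),
       wilcoxon_p = wp,
       real_counts = real,
       null_statistics = null_stats)
}

#' Length-matched permuted shortest-path sets
#'
#' Draws `n_sets` subsets from a pool of permuted paths such that every
#' subset reproduces the exact length multiset of the real paths. Draws
#' are without replacement within a set and independent across sets.
#'
#' @param path_pool List of `path_record` objects (the permuted pool).
#' @param real_lengths Integer vector: lengths of the real paths.
#' @param n_sets Number of permuted sets.
#' @param seed Integer seed.
#' @return List of lists of `path_record`s.
#' @export
sample_length_matched_paths <- function(path_pool, real_lengths,
                                        n_sets = 1000, seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets")
  pool_len <- vapply(path_pool, function(p) p$length, integer(1))
  need <- table(real_lengths)
  have <- table(pool_len)
  for (len in names(need)) {
    if (is.na(have[len]) || have[len] < need[len]) {
      abort(sprintf(
        "path pool has %d path(s) of length %s but %d are required",
        ifelse(is.na(have[len]), 0L, have[len]), len, need[len]),
        class = "transppi_feasibility_error")
    }
  }
  by_len <- split(seq_along(path_pool), pool_len)
  with_seed(derive_seed(seed, "path_sets"), {
    lapply(seq_len(n_sets), function(b) {
      idx <- unlist(lapply(names(need), function(len) {
        pool <- by_len[[len]]
        pool[sample.int(length(pool), need[[len]])]
      }), use.names = FALSE)
      path_pool[idx]
    })
  })
}
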