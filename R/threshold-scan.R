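#' Cumulative topological trend profile across association thresholds
#'
#' Orders on-network source-target pairs by ascending association
#' p-value and, for every prefix of that list (i.e. every threshold at
#' which one more on-network pair enters), reports the running mean of
#' the pair's network distance and of the source and target degrees.
#' Each cumulative mean is then summarised by its Spearman rank
#' correlation with the prefix threshold, expressed as `-log10(p)` of
#' the last pair included.
#'
#' @param pairs Pair table ([scan_trans()] output or compatible); pairs
#'   whose source or target is off the network are dropped.
#' @param distances Distance matrix from [all_pairs_distances()].
#' @param network The `igraph` graph the distances were computed on.
#' @return A `trend_profile`: tibble `(threshold, n_pairs, mean_distance,
#'   mean_source_degree, mean_target_degree)` with attributes
#'   `spearman_r` (named vector), `degenerate` (properties with zero
#'   variance, reported as r = 0) and `pairs` (the on-network pairs
#'   used, in order).
#' @export
cumulative_property_profile <- function(pairs, distances, network) {
  nodes <- igraph::V(network)$name
  on <- pairs$source_gene %in% nodes & pairs$target_gene %in% nodes &
    !is.na(pairs$source_gene)
  pairs <- dplyr::arrange(pairs[on, , drop = FALSE], .data$p,
                          .data$esnp_id, .data$target_gene)
  if (nrow(pairs) < 2) {
    abort("fewer than 2 on-network pairs; trend undefined",
          class = "transppi_trend_undefined")
  }
  deg <- igraph::degree(network)
  d <- distances[cbind(pairs$source_gene, pairs$target_gene)]
  sdeg <- unname(deg[pairs$source_gene])
  tdeg <- unname(deg[pairs$target_gene])
  k <- seq_len(nrow(pairs))
  prof <- tibble::tibble(
    threshold = -log10(pairs$p),
    n_pairs = k,
    mean_distance = cumsum(d) / k,
    mean_source_degree = cumsum(sdeg) / k,
    mean_target_degree = cumsum(tdeg) / k)

  props <- c("mean_distance", "mean_source_degree", "mean_target_degree")
  degenerate <- character(0)
  r <- vapply(props, function(pp) {
    y <- prof[[pp]]
    if (stats::sd(y) == 0 || stats::sd(prof$threshold) == 0) {
      degenerate <<- c(degenerate, pp)
      return(0)
    }
    suppressWarnings(cor(prof$threshold, y, method = "spearman"))
  }, numeric(1))

  attr(prof, "spearman_r") <- r
  attr(prof, "degenerate") <- degenerate
  attr(prof, "pairs") <- pairs
  class(prof) <- c("trend_profile", class(prof))
  prof
}

#' @export
tidy.trend_profile <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.trend_profile <- function(x, ...) {
  r <- attr(x, "spearman_r")
  tibble::tibble(r_distance = r[["mean_distance"]],
                 r_source_degree = r[["mean_source_degree"]],
                 r_target_degree = r[["mean_target_degree"]],
                 n_pairs = nrow(x))
}

#' Null distribution of trend correlations from permuted pairs
#'
#' Repeats the cumulative-profile construction on random source-target
#' node pairs: each permutation draws as many pairs as the real data
#' (uniformly over network nodes, or by edge-switching from the real
#' source/target multisets), assigns them the real pairs' p-value
#' ordering, and records the same Spearman trend correlation per
#' property.
#'
#' @param real_pairs The on-network pair table (its p-values and size
#'   define the prefix structure).
#' @param network `igraph` graph.
#' @param distances Matrix from [all_pairs_distances()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param scheme `"network_uniform"` (arbitrary node pairs) or
#'   `"edge_switching"` (resample from the real source and target
#'   multisets).
#' @return Named list (per property) of `permutation_null` objects, each
#'   with `statistics`, `n_perm`, `seed`.
#' @export
permuted_trend_distribution <- function(real_pairs, network, distances,
                                        n_perm = 1000, seed = 1L,
                                        scheme = c("network_uniform",
                                                   "edge_switching")) {
  scheme <- match.arg(scheme)
  n_perm <- check_count(n_perm, "n_perm")
  nodes <- igraph::V(network)$name
  on <- real_pairs$source_gene %in% nodes & real_pairs$target_gene %in% nodes
  real_pairs <- real_pairs[on, , drop = FALSE]
  n_pairs <- nrow(real_pairs)
  if (length(nodes) < 2 || n_pairs < 2) {
    abort("need >= 2 network nodes and >= 2 pairs",
          class = "transppi_invalid_parameter")
  }
  deg <- igraph::degree(network)
  thr <- -log10(sort(real_pairs$p))
  k <- seq_len(n_pairs)

  stats_mat <- with_seed(derive_seed(seed, "trend_null"), {
    vapply(seq_len(n_perm), function(b) {
      if (scheme == "network_uniform") {
        ps <- draw_unique_pairs(nodes, n_pairs)
      } else {
        ps <- cbind(sample(real_pairs$source_gene, n_pairs, replace = TRUE),
                    sample(real_pairs$target_gene, n_pairs, replace = TRUE))
      }
      d <- distances[ps]
      sd_ <- deg[ps[, 1]]; td <- deg[ps[, 2]]
      vapply(list(d, sd_, td), function(y) {
        cm <- cumsum(y) / k
        if (stats::sd(cm) == 0) return(0)
        suppressWarnings(cor(thr, cm, method = "spearman"))
      }, numeric(1))
    }, numeric(3))
  })
  props <- c("mean_distance", "mean_source_degree", "mean_target_degree")
  stats::setNames(lapply(1:3, function(i) {
    structure(list(statistics = stats_mat[i, ], n_perm = n_perm,
                   seed = seed), class = "permutation_null")
  }), props)
}

# n distinct unordered node pairs, uniform, no self-pairs
draw_unique_pairs <- function(nodes, n) {
  seen <- character(0)
  out <- matrix(character(0), ncol = 2)
  while (nrow(out) < n) {
    a <- sample(nodes, n - nrow(out), replace = TRUE)
    b <- sample(nodes, n - nrow(out), replace = TRUE)
    ok <- a != b
    key <- paste(pmin(a, b), pmax(a, b))
    ok <- ok & !duplicated(key) & !(key %in% seen)
    seen <- c(seen, key[ok])
    out <- rbind(out, cbind(a[ok], b[ok]))
  }
  out
}

#' Empirical p-value against a permutation null
#'
#' Fraction of permuted statistics strictly beyond the observed value in
#' the stated direction; may legitimately return 0 when no permutation
#' exceeds the observation.
#'
#' @param real_stat Observed statistic.
#' @param null A `permutation_null` (or bare numeric vector).
#' @param direction `"greater"`: count permuted > real; `"less"`: count
#'   permuted < real.
#' @return A probability in `[0, 1]`.
#' @export
empirical_p <- function(real_stat, null,
                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  s <- if (is.list(null)) null$statistics else null
  if (length(s) < 1) {
    abort("empty permutation null", class = "transppi_invalid_parameter")
  }
  if (direction == "greater") mean(s > real_stat) else mean(s < real_stat)
}

#' Trend significance summary
#'
#' Combines a [cumulative_property_profile()] with its permutation null.
#' The signed test direction is property-specific (distance: the signal
#' is a more negative correlation; degrees: more positive); the raw
#' "permuted r > real r" convention is reported alongside.
#'
#' @param profile A `trend_profile`.
#' @param nulls Output of [permuted_trend_distribution()].
#' @return Tibble `(property, spearman_r, direction, empirical_p,
#'   empirical_p_greater, n_perm)`.
#' @export
trend_significance <- function(profile, nulls) {
  r <- attr(profile, "spearman_r")
  dirs <- c(mean_distance = "less", mean_source_degree = "greater",
            mean_target_degree = "greater")
  purrr::map_dfr(names(nulls), function(pp) {
    tibble::tibble(
      property = pp, spearman_r = r[[pp]], direction = dirs[[pp]],
      empirical_p = empirical_p(r[[pp]], nulls[[pp]], dirs[[pp]]),
      empirical_p_greater = empirical_p(r[[pp]], nulls[[pp]], "greater"),
      n_perm = nulls[[pp]]$n_perm)
  })
}

#' Plot a trend profile
#'
#' Cumulative topological means against the association threshold
#' (`-log10 p`), one panel per property.
#'
#' @param object A `trend_profile`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.trend_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass(object)),
                              dplyr::starts_with("mean_"),
                              names_to = "property", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value)) +
    ggplot2::geom_point(shape = 3) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(-log[10](association~italic(P))),
                  y = "cumulative mean")
  p
}
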