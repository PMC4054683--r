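#' Generate a gene-set collection aligned to a network partition
#'
#' Produces one category per cluster of the partition (the
#' "cluster-aligned" sets, emulating functional annotation that tracks
#' network modules) plus `n_random_sets` random categories drawn without
#' replacement from the background. The background is the full gene
#' universe of the annotation.
#'
#' @param annotation Gene annotation tibble.
#' @param partition A `ppi_partition` ([louvain_clusters()]) or tibble
#'   `(node, cluster)`.
#' @param n_random_sets Number of additional random categories.
#' @param random_set_size Size of each random category.
#' @param seed Integer seed.
#' @return A `gene_set_collection`: list with `categories` (named list of
#'   character vectors) and `background` (character vector).
#' @export
generate_gene_sets <- function(annotation, partition, n_random_sets = 5,
                               random_set_size = 15, seed = 1L) {
  if (is.null(partition) || nrow(partition) == 0) {
    abort("`partition` is empty", class = "transppi_invalid_parameter")
  }
  background <- annotation$gene_id
  cl <- split(partition$node, partition$cluster)
  categories <- stats::setNames(
    lapply(cl, function(g) intersect(g, background)),
    paste0("cluster_", names(cl)))
  with_seed(seed, {
    for (i in seq_len(n_random_sets)) {
      categories[[sprintf("random_%02d", i)]] <-
        sample(background, min(random_set_size, length(background)))
    }
    gene_set_collection(categories, background)
  })
}

#' Gene-set collection container
#'
#' @param categories Named list of character vectors (each a subset of
#'   `background`).
#' @param background Character vector, the gene universe.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(categories, background) {
  if (is.null(names(categories)) || anyDuplicated(names(categories))) {
    abort("category names must be unique and non-empty",
          class = "transppi_invalid_parameter")
  }
  categories <- lapply(categories, function(g) unique(intersect(g, background)))
  structure(list(categories = categories, background = unique(background)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d categories over %d background genes\n",
              length(x$categories), length(x$background)))
  invisible(x)
}

#' Write / read gene sets in GMT format
#'
#' Standard GMT: one tab-separated line per category, `name`,
#' `description`, then member genes. The background on read defaults to
#' the union of all categories unless supplied.
#'
#' @param collection A `gene_set_collection`.
#' @param path File path.
#' @param background Optional explicit background for `read_gmt()`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$categories), function(nm) {
    paste(c(nm, "na", collection$categories[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort(sprintf("%s: line %d has fewer than 3 fields", path, short[1]),
          class = "transppi_parse_error")
  }
  categories <- stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                                vapply(parts, `[[`, character(1), 1))
  if (is.null(background)) background <- unique(unlist(categories))
  gene_set_collection(categories, background)
}
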