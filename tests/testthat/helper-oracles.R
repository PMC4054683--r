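# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances via Floyd-Warshall, exact tests via
# choose() enumeration, modularity via the literal double sum.

# Floyd-Warshall all-pairs shortest paths on an igraph graph (unit weights)
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n,
              dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  D[el] <- 1; D[el[, 2:1, drop = FALSE]] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# P(X >= k) for X ~ Hypergeometric(K white, N - K black, n draws)
hyper_tail_enum <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# one-sided (greater) Fisher p for table (a, b // c, d) by enumeration
fisher_greater_enum <- function(a, b, c, d) {
  hyper_tail_enum(a, a + b, a + b + c + d, a + c)
}

# strict binomial upper tail P(X > k) by term-wise enumeration
binom_tail_enum <- function(k, n, p) {
  if (k >= n) return(0)
  xs <- (k + 1):n
  sum(choose(n, xs) * p^xs * (1 - p)^(n - xs))
}

# exact one-sided (x > y) rank-sum p by full enumeration of group labels
wilcox_greater_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  stat <- sum(rank(pooled)[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mean(stats >= stat)
}

# Newman-Girvan modularity by the literal double sum over node pairs
modularity_enum <- function(g, membership) {
  m <- igraph::ecount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- igraph::degree(g)
  nodes <- igraph::V(g)$name
  q <- 0
  for (i in nodes) for (j in nodes) {
    if (membership[[i]] == membership[[j]]) {
      q <- q + A[i, j] - deg[[i]] * deg[[j]] / (2 * m)
    }
  }
  q / (2 * m)
}

# small random graph helper
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

# Standard planted fixture, built once and reused across test files.
standard_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- transppi::simulate_study(
      transppi::run_config(seed = 1L))
    cache
  }
})

standard_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressMessages(
      transppi::run_pipeline(standard_study()))
    cache
  }
})

# tiny hand-built annotation: helper for coordinate-convention tests
toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 2100000L, 1000L),
    end = c(6999L, 2104999L, 5999L),
    strand = c("+", "-", "+"),
    is_tf = c(FALSE, FALSE, TRUE),
    exons = list(
      cbind(start = c(1000L, 3000L, 5000L), end = c(1999L, 3999L, 6999L)),
      cbind(start = c(2100000L, 2103000L), end = c(2100999L, 2104999L)),
      cbind(start = 1000L, end = 5999L)))
}
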