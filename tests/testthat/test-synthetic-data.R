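test_that("annotation generator respects counts, placement and determinism", {
  ann <- generate_annotation(10, n_chromosomes = 3, tf_fraction = 0.2,
                             seed = 1)
  expect_equal(sum(ann$is_tf), 2) # floor(0.2 * 10)
  expect_equal(nrow(ann), 10)
  # spans are valid and exons sorted, non-overlapping, inside the span
  for (i in seq_len(nrow(ann))) {
    ex <- ann$exons[[i]]
    expect_true(ann$start[i] <= ann$end[i])
    expect_true(all(ex[, "start"] <= ex[, "end"]))
    expect_true(all(ex[, "start"] >= ann$start[i] & ex[, "end"] <= ann$end[i]))
    if (nrow(ex) > 1) {
      expect_true(all(diff(ex[, "start"]) > 0))
      expect_true(all(ex[-1, "start"] > ex[-nrow(ex), "end"]))
    }
  }
  # genes on the same chromosome never overlap
  by_chr <- split(ann, ann$chrom)
  for (sub in by_chr) {
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }

  two <- generate_annotation(2, n_chromosomes = 2, seed = 3)
  expect_equal(length(unique(two$chrom)), 2)

  expect_identical(generate_annotation(25, seed = 9),
                   generate_annotation(25, seed = 9))
  expect_error(generate_annotation(1), class = "transppi_invalid_parameter")
  expect_error(generate_annotation(10, tf_fraction = 1.5),
               class = "transppi_invalid_parameter")
})

test_that("annotation round-trips through the BED-like format", {
  ann <- generate_annotation(12, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$start, ann$start)
  expect_equal(back$is_tf, ann$is_tf)
  for (i in seq_len(nrow(ann))) {
    expect_equal(unname(back$exons[[i]]), unname(ann$exons[[i]]))
  }
})

test_that("planted-partition generator matches its generating model", {
  # p_in = 1, p_out = 0: disjoint cliques, one per block
  g <- generate_ppi_network(12, n_clusters = 3, p_in = 1, p_out = 1e-9,
                            seed = 2)
  comp <- igraph::components(g)
  expect_equal(comp$no, 3)
  expect_equal(igraph::ecount(g), 3 * choose(4, 2))

  # expected edge count within 3 binomial standard deviations
  n <- 100; k <- 4; p_in <- 0.3; p_out <- 0.01
  within_pairs <- k * choose(n / k, 2)
  cross_pairs <- choose(n, 2) - within_pairs
  mu <- within_pairs * p_in + cross_pairs * p_out
  sdv <- sqrt(within_pairs * p_in * (1 - p_in) +
              cross_pairs * p_out * (1 - p_out))
  ec <- vapply(1:20, function(s) {
    igraph::ecount(generate_ppi_network(n, k, p_in, p_out, seed = s))
  }, numeric(1))
  expect_true(all(abs(ec - mu) < 3 * sdv + 1e-9))

  expect_error(generate_ppi_network(10, 2, p_in = 1.2, p_out = 0),
               class = "transppi_invalid_parameter")
  expect_error(generate_ppi_network(10, 2, p_in = 0.1, p_out = 0.2),
               class = "transppi_invalid_parameter")
})

test_that("Louvain recovers planted blocks (ARI > 0.9)", {
  skip_if_not_installed("mclust")
  g <- generate_ppi_network(100, n_clusters = 4, p_in = 0.3, p_out = 0.01,
                            seed = 7)
  cl <- louvain_clusters(g, seed = 1)
  ari <- mclust::adjustedRandIndex(cl$cluster, igraph::V(g)$block)
  expect_gt(ari, 0.9)
})

test_that("genotype generator follows HWE binomial sampling", {
  ann <- generate_annotation(20, seed = 5)
  G <- generate_genotypes(60, ann, snps_per_gene = 2, missing_rate = 0,
                          seed = 5)
  expect_false(anyNA(G$dosage))
  expect_true(all(G$dosage %in% 0:2))

  # per-SNP mean dosage within 3 sd of 2 * maf under Binomial(2, maf)
  Gm <- generate_genotypes(500, ann, snps_per_gene = 2,
                           maf_range = c(0.45, 0.49), missing_rate = 0,
                           seed = 6)
  p_hat <- colMeans(Gm$dosage) / 2
  # loosest bound: every SNP's allele frequency in (0.45, 0.49) +- 3 se
  se <- sqrt(0.5 * 0.5 / (2 * 500))
  expect_true(all(p_hat > 0.45 - 3 * se & p_hat < 0.49 + 3 * se))

  Gmiss <- generate_genotypes(50, ann, missing_rate = 0.1, seed = 7)
  expect_gt(mean(is.na(Gmiss$dosage)), 0.05)
  expect_lt(mean(is.na(Gmiss$dosage)), 0.15)

  expect_error(generate_genotypes(50, ann, maf_range = c(0, 0.4)),
               class = "transppi_invalid_parameter")
  expect_error(generate_genotypes(50, ann, maf_range = c(0.1, 0.6)),
               class = "transppi_invalid_parameter")
})

test_that("SNPs on exon boundaries are exonic (closed 1-based intervals)", {
  ann <- toy_annotation()
  snps <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4", "s5"),
    chrom = "chr1",
    pos = c(1000L, 1999L, 2000L, 4500L, 2099999L))
  out <- transppi:::annotate_snps(snps, ann)
  expect_equal(out$exonic, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$source_gene[1:4], rep("gA", 4))
  expect_true(is.na(out$source_gene[5])) # just upstream of gB's span
})

test_that("effect planting honours counts, proximity and hub bias", {
  st <- standard_study()
  pp <- planned_pairs(st$plan)
  tf <- pp[pp$type == "tf", ]
  expect_true(all(table(tf$source_gene) == st$config$targets_per_tf))
  # proximal_radius = 1: exon targets are direct interactors
  D <- all_pairs_distances(st$network)
  ex <- pp[pp$type == "exon", ]
  expect_true(all(D[cbind(ex$source_gene, ex$target_gene)] <=
                    st$config$proximal_radius))
  # hub bias: planted exon target mean degree exceeds network mean
  deg <- igraph::degree(st$network)
  expect_gt(mean(deg[ex$target_gene]), mean(deg))
  # TF units stay in the source's planted block
  block <- stats::setNames(igraph::V(st$network)$block,
                           igraph::V(st$network)$name)
  expect_true(all(block[tf$source_gene] == block[tf$target_gene]))
  # every pair is trans and no target equals its source
  expect_true(all(pp$source_gene != pp$target_gene))
  ann <- st$annotation
  for (i in seq_len(nrow(pp))) {
    a <- ann[ann$gene_id == pp$source_gene[i], ]
    b <- ann[ann$gene_id == pp$target_gene[i], ]
    expect_true(a$chrom != b$chrom ||
                  min(abs(a$start - b$end), abs(b$start - a$end)) >= 1e6)
  }
  # infeasible request errors
  expect_error(
    plant_effects(st$annotation, st$network, st$genotypes,
                  n_exon_sources = 500, n_tf_sources = 0),
    class = "transppi_feasibility_error")
})

test_that("expression generator produces the planted regression structure", {
  st <- standard_study()
  # unknown gene in plan triggers a consistency error
  bad <- st$plan
  bad$source_gene[1] <- "NOT_A_GENE"
  expect_error(generate_expression(st$genotypes, bad, st$annotation),
               class = "transppi_consistency_error")

  # null model: with no effects, gene-gene correlations stay near zero
  ann <- generate_annotation(30, seed = 11)
  G0 <- generate_genotypes(50, ann, missing_rate = 0, seed = 11)
  plan0 <- st$plan[0, ]
  E0 <- generate_expression(G0, plan0, ann, noise_sd = 1, seed = 11)
  R <- abs(cor(E0, method = "spearman"))
  offdiag <- R[upper.tri(R)]
  # 95th percentile of |r| under the null stays below the two-sided
  # critical value at alpha = 0.005, n = 50 (~0.39)
  expect_lt(quantile(offdiag, 0.95), 0.39)
})

test_that("cis beta is recovered within 3 SE in >= 95% of replicate seeds", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    maf <- 0.3; n <- 50
    d <- rbinom(n, 2, maf)
    if (var(d) == 0) return(NA)
    y <- 1.5 * d + rnorm(n, 0, 1)
    fit <- test_association(d, y)
    abs(fit$beta - 1.5) < 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("planted source-target co-expression exceeds background", {
  st <- standard_study()
  pp <- planned_pairs(st$plan)
  strong <- pp[pp$type %in% c("exon", "tf"), ]
  cmp <- coexpression_comparison(
    dplyr::rename(strong, esnp_id = snp_id), st$expression,
    max_background = 5000)
  expect_lt(cmp$wilcoxon_p, 0.01)
  expect_gt(cmp$median_abs_r_real, cmp$median_abs_r_background)
})

test_that("gene-set generator aligns categories with clusters", {
  st <- standard_study()
  gs <- st$gene_sets
  part <- st$partition
  cl1 <- part$node[part$cluster == 1]
  expect_setequal(gs$categories[["cluster_1"]], cl1)
  rand <- gs$categories[[grep("^random_", names(gs$categories))[1]]]
  expect_equal(length(rand), 15)
  expect_true(all(rand %in% gs$background))
  # a cluster-aligned category is extremely enriched in its own cluster
  res <- hypergeometric_enrichment(cl1, gs)
  expect_lt(res$p[res$category == "cluster_1"], 1e-6)
  expect_error(generate_gene_sets(st$annotation, part[0, ]),
               class = "transppi_invalid_parameter")
})

test_that("binding-pair generator mixes planted pairs with decoys", {
  st <- standard_study()
  pure <- generate_binding_pairs(st$plan, st$annotation,
                                 decoy_fraction = 0, seed = 2)
  pp <- planned_pairs(st$plan)
  tf <- pp[pp$type == "tf", ]
  expect_setequal(paste(pure$tf_gene, pure$target_gene),
                  paste(tf$source_gene, tf$target_gene))

  mixed <- generate_binding_pairs(st$plan, st$annotation,
                                  include_fraction = 1,
                                  decoy_fraction = 0.5, seed = 2)
  expect_equal(sum(mixed$planted), nrow(tf))
  expect_equal(sum(!mixed$planted), nrow(tf))
  # all planted pairs are found by membership lookup
  key <- paste(mixed$tf_gene, mixed$target_gene)
  expect_true(all(paste(tf$source_gene, tf$target_gene) %in% key))
})

test_that("generators are pure functions of their seeds", {
  a1 <- generate_annotation(15, seed = 42)
  g1 <- generate_ppi_network(40, 2, 0.4, 0.05, seed = 42)
  g2 <- generate_ppi_network(40, 2, 0.4, 0.05, seed = 42)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  G1 <- generate_genotypes(20, a1, seed = 42)
  G2 <- generate_genotypes(20, a1, seed = 42)
  expect_identical(G1$dosage, G2$dosage)
  # and the RNG state of the caller is untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_annotation(10, seed = 1))
  expect_identical(before, .Random.seed)
})
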