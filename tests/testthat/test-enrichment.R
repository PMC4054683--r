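test_that("Fisher 2x2 matches enumeration oracles on small tables", {
  expect_equal(fisher_2x2(1, 1, 1, 1, sided = "two")$p, 1)
  expect_equal(fisher_2x2(3, 1, 1, 3, sided = "greater")$p, 17 / 70,
               tolerance = 1e-12)
  # random small tables against the choose() enumeration
  set.seed(4)
  for (i in 1:20) {
    tab <- rmultinom(1, sample(8:30, 1), rep(0.25, 4))
    expect_equal(
      fisher_2x2(tab[1], tab[2], tab[3], tab[4], sided = "greater")$p,
      fisher_greater_enum(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-10)
  }
  expect_error(fisher_2x2(-1, 1, 1, 1), class = "transppi_invalid_parameter")
})

test_that("binomial cis-enrichment uses the strict upper tail", {
  expect_equal(binomial_cis_enrichment(2, 10, 0.5), 968 / 1024)
  expect_equal(binomial_cis_enrichment(10, 10, 0.5), 0)
  set.seed(9)
  for (i in 1:15) {
    n <- sample(5:30, 1); k <- sample(0:n, 1); p <- runif(1, 0.05, 0.5)
    expect_equal(binomial_cis_enrichment(k, n, p), binom_tail_enum(k, n, p),
                 tolerance = 1e-12)
  }
  expect_error(binomial_cis_enrichment(11, 10),
               class = "transppi_invalid_parameter")
})

test_that("hypergeometric enrichment matches enumeration and applies BH", {
  bg <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(setA = bg[1:5], setB = bg[6:15]), bg)
  res <- hypergeometric_enrichment(c(bg[1:4], bg[6]), coll)
  # overlap 4 of category 5, query 5, background 20 -> 76/15504
  expect_equal(res$p[res$category == "setA"], 76 / 15504,
               tolerance = 1e-12)
  expect_equal(res$p[res$category == "setA"],
               hyper_tail_enum(4, 5, 20, 5), tolerance = 1e-12)

  # zero overlap is excluded below min_overlap = 1 but p = 1 if tested
  res0 <- hypergeometric_enrichment(bg[16:20], coll, min_overlap = 0)
  expect_equal(res0$p[res0$category == "setA"], 1)

  expect_error(hypergeometric_enrichment("x", gene_set_collection(
    list(a = character(0)), character(0))),
    class = "transppi_invalid_parameter")
})

test_that("BH q-values match the hand-worked step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # order invariance
  p <- c(0.04, 0.001, 0.9, 0.2)
  q <- benjamini_hochberg(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
  expect_true(all(q <= 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "transppi_invalid_parameter")
})

test_that("planted TF units are enriched for their cluster category", {
  st <- standard_study()
  ue <- unit_enrichment(st$plan, st$gene_sets)
  expect_equal(ue$n_units, st$config$n_tf_sources)
  expect_gte(ue$n_enriched, 1)
  # a fully cluster-aligned unit (TF + 3 targets, category ~50 of 200)
  # reaches the exact hypergeometric floor P(X >= 4) ~ 3.7e-3, q < 0.05
  first <- ue$per_unit[[1]]
  floor_p <- hyper_tail_enum(4, first$set_size[which.min(first$p)], 200, 4)
  expect_lt(min(first$p), 0.005)
  expect_gte(min(first$p), floor_p - 1e-12)
  expect_lt(min(first$q), 0.05)
  expect_true(grepl("^cluster_", first$category[which.min(first$p)]))
  # units below two genes are skipped
  tiny <- tibble::tibble(tf_source = "solo", targets = list(character(0)))
  expect_equal(unit_enrichment(tiny, st$gene_sets)$n_units, 0)
})

test_that("rank-sum comparisons match enumeration on toy data", {
  x <- c(5.2, 6.1, 7.3); y <- c(4.0, 4.8, 5.5)
  expect_equal(effect_size_comparison(x, y), wilcox_greater_enum(x, y),
               tolerance = 1e-10)
  set.seed(2)
  z <- rnorm(30)
  expect_gt(effect_size_comparison(z, z), 0.4)
  expect_error(effect_size_comparison(numeric(0), 1),
               class = "transppi_invalid_parameter")
})

test_that("coexpression comparison ranks real pairs against background", {
  set.seed(6)
  E <- matrix(rnorm(50 * 12), 50, dimnames = list(NULL, letters[1:12]))
  E[, "b"] <- E[, "a"] + rnorm(50, 0, 0.4) # one strongly coupled pair
  pairs <- tibble::tibble(source_gene = "a", target_gene = "b")
  cmp <- coexpression_comparison(pairs, E)
  expect_gt(cmp$median_abs_r_real, cmp$median_abs_r_background)
  # rank-sum statistic agrees with a brute-force rank computation (5 v 5)
  xr <- abs(cmp$real_r)
  expect_equal(length(xr), 1)
  expect_error(coexpression_comparison(
    tibble::tibble(source_gene = "zz", target_gene = "qq"), E),
    class = "transppi_invalid_parameter")
})

test_that("cluster co-occurrence reproduces printed-table Fisher results", {
  # partition with a single cluster: co-occurrence is saturated, p = 1
  part <- tibble::tibble(node = letters[1:6], cluster = 1L)
  pairs <- tibble::tibble(source = c("a", "b"), target = c("c", "d"))
  nullp <- tibble::tibble(source = c("e", "a"), target = c("f", "d"))
  res <- cluster_cooccurrence(pairs, part, nullp)
  expect_equal(res$real_k, 2)
  expect_equal(res$fisher_p, 1)

  run <- standard_run()
  expect_lt(run$tf_cooccurrence$fisher_p, 0.05)
  expect_gt(run$tf_cooccurrence$real_k / run$tf_cooccurrence$real_n,
            run$tf_cooccurrence$null_k / run$tf_cooccurrence$null_n)
})

test_that("binding-database membership enrichment detects planted pairs", {
  st <- standard_study()
  run <- standard_run()
  expect_error(binding_membership_enrichment(
    run$tf_best, run$tf_best, tibble::tibble(tf_gene = character(0),
                                             target_gene = character(0))),
    class = "transppi_feasibility_error")
  # planted fixture: enrichment against an edge-switched null
  null_pairs <- sample_random_pairs(run$tf_best$source_gene,
                                    run$tf_best$target_gene, 2000,
                                    seed = 8)
  res <- binding_membership_enrichment(run$tf_best, null_pairs,
                                       st$binding_pairs)
  expect_lt(res$fisher_p, 0.01)
})

test_that("path-category counting includes repeats across paths", {
  mkpath <- function(...) {
    nodes <- c(...)
    structure(list(nodes = nodes, length = length(nodes) - 1L,
                   intermediates = nodes[-c(1, length(nodes))]),
              class = "path_record")
  }
  real <- list(mkpath("s1", "x", "t1"), mkpath("s2", "x", "t2"))
  perm <- list(list(mkpath("a", "b", "c"), mkpath("d", "e", "f")),
               list(mkpath("a", "x", "c"), mkpath("d", "e", "f")))
  bg <- c("s1", "s2", "t1", "t2", "x", letters[1:6])
  coll <- gene_set_collection(list(Y = "x", all = bg), bg)
  res <- path_category_enrichment(real, perm, coll)
  # gene x appears on two paths -> counted twice
  expect_equal(res$gene_count[res$category == "Y"], 2)
  expect_equal(res$path_count[res$category == "Y"], 2)
  # permuted sets reach (1, 1) and (0, 0): neither >= 2 -> p = 0
  expect_equal(res$gene_count_emp_p[res$category == "Y"], 0)
  # a category covering every gene ties in all permutations -> p = 1
  expect_equal(res$gene_count_emp_p[res$category == "all"], 1)
  expect_equal(res$path_count_emp_p[res$category == "all"], 1)
  # endpoints-excluded variant drops the endpoint-only contribution
  res2 <- path_category_enrichment(real, perm, coll,
                                   include_endpoints = FALSE)
  expect_equal(res2$gene_count[res2$category == "Y"], 2) # x is internal
})

test_that("positional bias handles strand-aware exon binning", {
  ann <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(100L, 5000L), end = c(1000L, 6000L),
    strand = c("+", "-"), is_tf = FALSE,
    exons = list(cbind(start = c(100L, 400L, 800L),
                       end = c(199L, 499L, 1000L)),
                 cbind(start = c(5000L, 5400L, 5800L),
                       end = c(5099L, 5499L, 6000L))))
  # exhaustive bin assignment on the + gene
  snp <- function(pos, gene = "gp") tibble::tibble(
    snp_id = "s", chrom = "chr1", pos = pos, source_gene = gene)
  # middle exon on + strand
  res_mid <- positional_bias_test(snp(450), snp(150), ann)
  expect_equal(res_mid$exon_bin_table, c(1, 0, 0, 1))
  # on the - strand the genomic last exon is transcript-first
  res_minus <- positional_bias_test(snp(5850, "gm"), snp(5050, "gm"), ann)
  # 5850 lies in genomic exon 3 = transcript exon 1 -> "first" (not middle)
  expect_equal(res_minus$exon_bin_table, c(0, 1, 0, 1))
  # fractional position is strand-aware: (6000 - 5850 + 1) / 401
  expect_equal(res_minus$esnp_positions, 151 / 401, tolerance = 1e-12)

  # planted middle-exon eSNPs versus uniform background SNPs
  st <- standard_study()
  snps <- st$genotypes$snps
  ex <- snps[snps$exonic & !is.na(snps$source_gene), ]
  classify <- positional_bias_test(ex, ex, st$annotation)
  expect_gt(classify$exon_bin_fisher_p, 0.05) # identical sets: no bias
  expect_gt(classify$transcript_position_wilcoxon_p, 0.05)
})

test_that("enrichment p-values are calibrated under their nulls", {
  # cluster co-occurrence: real pairs drawn from the same uniform scheme
  # as the null must give approximately uniform one-sided Fisher p
  g <- generate_ppi_network(120, 4, 0.3, 0.02, seed = 41)
  part <- louvain_clusters(g, seed = 1)
  ps <- vapply(1:200, function(b) {
    real <- sample_network_pairs(g, 150, seed = b)
    nullp <- sample_network_pairs(g, 3000, seed = 50000 + b)
    cluster_cooccurrence(real, part, nullp)$fisher_p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
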