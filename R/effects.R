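#' Plant cis-to-trans effect cascades on a genotype/network fixture
#'
#' Builds an effect plan with three kinds of entries, mirroring the two
#' trans-regulation modes the pipeline is designed to detect plus the
#' false-positive dilution that drives threshold trends:
#'
#' * **exon** sources: non-TF genes with exonic SNPs; each gets one trans
#'   target chosen within `proximal_radius` network hops, biased towards
#'   high-degree nodes and, when possible, towards a *different* planted
#'   block (so exon pairs cross functional clusters).
#' * **tf** sources: TF genes; each gets `targets_per_tf` distinct trans
#'   targets drawn from the source's own planted block (modular
#'   regulatory units).
#' * **background** pairs: weak trans effects (`trans_beta *
#'   background_scale`) from exonic sources to uniformly random on-network
#'   targets; these emulate the weaker/spurious associations that enter as
#'   the significance threshold is loosened.
#'
#' The causal SNP for every source is the most common (highest-MAF) SNP
#' of the required region class within the gene span, the standard choice
#' when planting detectable effects on common variants.
#'
#' @param annotation Gene annotation tibble.
#' @param network `igraph` graph keyed by gene ids, with a `block` vertex
#'   attribute when planted-block targeting is requested.
#' @param genotypes A [genotype_matrix()] over the same annotation.
#' @param n_exon_sources,n_tf_sources,targets_per_tf Planted counts.
#' @param cis_beta Expression units per dosage unit at the source.
#' @param trans_beta Source-to-target propagation coefficient.
#' @param proximal_radius Maximum hop distance for exon targets.
#' @param n_background Number of weak background pairs.
#' @param background_scale Multiplier on `trans_beta` for background pairs.
#' @param min_causal_maf Minimum minor-allele frequency of causal SNPs;
#'   effects are planted on common variants so they carry power at
#'   genome-wide thresholds with cohort-scale sample sizes.
#' @param seed Integer seed.
#' @return An `effect_plan`: tibble `(snp_id, source_gene, cis_beta, type,
#'   targets)` where `targets` is a list-column of tibbles
#'   `(target_gene, trans_beta)`; the seed is kept as an attribute.
#' @export
plant_effects <- function(annotation, network, genotypes,
                          n_exon_sources, n_tf_sources, targets_per_tf = 3,
                          cis_beta = 1.5, trans_beta = 1.5,
                          proximal_radius = 1, n_background = 0,
                          background_scale = 0.55, min_causal_maf = 0.3,
                          seed = 1L) {
  nodes <- igraph::V(network)$name
  block <- igraph::V(network)$block
  if (is.null(block)) block <- rep(1L, length(nodes))
  names(block) <- nodes
  deg <- igraph::degree(network)
  D <- all_pairs_distances(network)
  snps <- genotypes$snps

  g_chrom <- stats::setNames(annotation$chrom, annotation$gene_id)
  g_start <- stats::setNames(annotation$start, annotation$gene_id)
  g_end <- stats::setNames(annotation$end, annotation$gene_id)
  ann <- annotation[match(nodes, annotation$gene_id), , drop = FALSE]

  is_trans <- function(s, t) {
    ifelse(g_chrom[s] != g_chrom[t], TRUE,
           pmin(abs(g_start[s] - g_end[t]),
                abs(g_start[t] - g_end[s])) >= 1e6)
  }

  # Causal SNP for a source: the most common SNP of the required region
  # class with MAF >= min_causal_maf (effects are planted on common
  # variants so they are detectable at genome-wide thresholds at n ~ 50).
  # TF sources prefer intronic SNPs, as TF-span eSNPs mostly are.
  best_snp <- function(gene, need_exonic) {
    cand <- snps[!is.na(snps$source_gene) & snps$source_gene == gene &
                   snps$maf >= min_causal_maf, ]
    if (need_exonic) {
      cand <- cand[cand$exonic, ]
    } else if (any(!cand$exonic)) {
      cand <- cand[!cand$exonic, ]
    }
    if (nrow(cand) == 0) return(NA_character_)
    cand$snp_id[which.max(cand$maf)]
  }

  with_seed(seed, {
    used <- character(0) # genes already claimed as source or target
    entries <- list()

    # hub-biased choice: sample degree-weighted among the three
    # highest-degree candidates, so planted targets are neighbourhood hubs
    pick_target <- function(cands) {
      cands <- setdiff(cands, used)
      cands <- cands[deg[cands] > 0]
      if (!length(cands)) return(NA_character_)
      hubs <- cands[order(-deg[cands])][seq_len(min(3, length(cands)))]
      sample(hubs, 1, prob = deg[hubs])
    }

    # exon sources: proximal, hub-biased, cross-block targets
    exon_pool <- ann$gene_id[!ann$is_tf &
      vapply(ann$gene_id, function(g) !is.na(best_snp(g, TRUE)), logical(1))]
    exon_pool <- sample(exon_pool)
    for (g in exon_pool) {
      if (length(entries) >= n_exon_sources) break
      if (g %in% used) next
      within <- nodes[D[g, ] >= 1 & D[g, ] <= proximal_radius]
      within <- within[is_trans(g, within)]
      cross <- within[block[within] != block[[g]]]
      tgt <- pick_target(if (length(setdiff(cross, used))) cross else within)
      if (is.na(tgt)) next
      entries[[length(entries) + 1]] <- tibble::tibble(
        snp_id = best_snp(g, TRUE), source_gene = g, cis_beta = cis_beta,
        type = "exon",
        targets = list(tibble::tibble(target_gene = tgt,
                                      trans_beta = trans_beta)))
      used <- c(used, g, tgt)
    }
    if (sum(vapply(entries, function(e) e$type, character(1)) == "exon") <
        n_exon_sources) {
      abort(sprintf(
        "could only plant %d of %d requested exon sources",
        length(entries), n_exon_sources), class = "transppi_feasibility_error")
    }

    # TF sources: same-block modular units
    tf_pool <- ann$gene_id[ann$is_tf &
      vapply(ann$gene_id, function(g) !is.na(best_snp(g, FALSE)), logical(1))]
    tf_pool <- sample(tf_pool)
    n_tf_done <- 0
    for (g in tf_pool) {
      if (n_tf_done >= n_tf_sources) break
      if (g %in% used) next
      same <- setdiff(nodes[block == block[[g]]], c(g, used))
      same <- same[is_trans(g, same)]
      if (length(same) < targets_per_tf) next
      tgts <- sample(same, targets_per_tf,
                     prob = deg[same] + 1)
      entries[[length(entries) + 1]] <- tibble::tibble(
        snp_id = best_snp(g, FALSE), source_gene = g, cis_beta = cis_beta,
        type = "tf",
        targets = list(tibble::tibble(target_gene = tgts,
                                      trans_beta = trans_beta)))
      used <- c(used, g, tgts)
      n_tf_done <- n_tf_done + 1
    }
    if (n_tf_done < n_tf_sources) {
      abort(sprintf("could only plant %d of %d requested TF sources",
                    n_tf_done, n_tf_sources),
            class = "transppi_feasibility_error")
    }

    # weak background pairs: uniform random on-network trans targets,
    # up to two targets per source so the weak tier fits the gene budget
    bg_pool <- setdiff(exon_pool, used)
    n_bg_done <- 0
    for (g in sample(bg_pool)) {
      if (n_bg_done >= n_background) break
      cands <- setdiff(nodes, c(g, used))
      cands <- cands[is_trans(g, cands)]
      if (!length(cands)) next
      k <- min(2, length(cands), n_background - n_bg_done)
      tgt <- sample(cands, k)
      entries[[length(entries) + 1]] <- tibble::tibble(
        snp_id = best_snp(g, TRUE), source_gene = g, cis_beta = cis_beta,
        type = "background",
        targets = list(tibble::tibble(
          target_gene = tgt, trans_beta = trans_beta * background_scale)))
      used <- c(used, g, tgt)
      n_bg_done <- n_bg_done + k
    }
    if (n_bg_done < n_background) {
      abort(sprintf("could only plant %d of %d background pairs",
                    n_bg_done, n_background),
            class = "transppi_feasibility_error")
    }

    plan <- dplyr::bind_rows(entries)
    attr(plan, "seed") <- seed
    class(plan) <- c("effect_plan", class(plan))
    plan
  })
}

#' Flatten an effect plan to one row per source-target pair
#'
#' @param plan An `effect_plan`.
#' @return Tibble `(snp_id, source_gene, target_gene, cis_beta,
#'   trans_beta, type)`.
#' @export
planned_pairs <- function(plan) {
  if (nrow(plan) == 0) {
    return(tibble::tibble(snp_id = character(0), source_gene = character(0),
                          cis_beta = numeric(0), type = character(0),
                          target_gene = character(0),
                          trans_beta = numeric(0)))
  }
  tidyr::unnest(tibble::as_tibble(unclass(plan)[
    c("snp_id", "source_gene", "cis_beta", "type", "targets")]),
    "targets")
}

#' Generate expression driven by a planted effect plan
#'
#' Every gene starts as pure Gaussian noise `N(0, noise_sd)`. For each
#' plan entry the source gene's expression is `cis_beta * dosage +`
#' noise, and each target's expression is `trans_beta * (source
#' expression) +` noise, so trans effects propagate through the source
#' transcript exactly as the cis-to-trans mechanism assumes. Missing
#' dosages contribute the SNP's mean dosage (the generative model is
#' fully observed; missingness only affects downstream testing).
#'
#' @param genotypes A [genotype_matrix()].
#' @param plan An `effect_plan` from [plant_effects()].
#' @param annotation Gene annotation providing the gene universe.
#' @param noise_sd Residual standard deviation (> 0), expression units.
#' @param seed Integer seed.
#' @return Numeric matrix, samples x genes, on a normalised expression
#'   scale.
#' @export
generate_expression <- function(genotypes, plan, annotation,
                                noise_sd = 1, seed = 1L) {
  if (noise_sd <= 0) {
    abort("`noise_sd` must be positive", class = "transppi_invalid_parameter")
  }
  genes <- annotation$gene_id
  pp <- planned_pairs(plan)
  unknown <- setdiff(c(pp$source_gene, pp$target_gene), genes)
  if (length(unknown)) {
    abort(sprintf("effect plan names genes absent from annotation: %s",
                  paste(unknown, collapse = ", ")),
          class = "transppi_consistency_error")
  }
  if (!all(pp$snp_id %in% genotypes$snps$snp_id)) {
    abort("effect plan names SNPs absent from the genotype matrix",
          class = "transppi_consistency_error")
  }

  with_seed(seed, {
    n <- nrow(genotypes$dosage)
    E <- matrix(rnorm(n * length(genes), 0, noise_sd), nrow = n,
                dimnames = list(genotypes$samples, genes))
    for (i in seq_len(nrow(plan))) {
      d <- genotypes$dosage[, plan$snp_id[i]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      src <- plan$source_gene[i]
      E[, src] <- plan$cis_beta[i] * d + rnorm(n, 0, noise_sd)
      tg <- plan$targets[[i]]
      for (j in seq_len(nrow(tg))) {
        E[, tg$target_gene[j]] <-
          tg$trans_beta[j] * E[, src] + rnorm(n, 0, noise_sd)
      }
    }
    E
  })
}

#' Generate a synthetic TF-DNA binding-pair table
#'
#' Emulates a ChIP-derived TF binding database: a configurable fraction
#' of the planted TF-to-target pairs, plus random decoy pairs of a TF and
#' a gene.
#'
#' @param plan An `effect_plan` containing TF entries.
#' @param annotation Gene annotation (provides the TF and gene universe).
#' @param include_fraction Fraction of planted TF pairs included.
#' @param decoy_fraction Fraction of the output made up of random decoys.
#' @param seed Integer seed.
#' @return Tibble `(tf_gene, target_gene, planted)`.
#' @export
generate_binding_pairs <- function(plan, annotation, include_fraction = 1,
                                   decoy_fraction = 0, seed = 1L) {
  check_prob(include_fraction, "include_fraction")
  check_prob(decoy_fraction, "decoy_fraction")
  pp <- planned_pairs(plan)
  pp <- pp[pp$type == "tf", ]
  if (nrow(pp) == 0) {
    abort("effect plan contains no TF sources",
          class = "transppi_invalid_parameter")
  }
  with_seed(seed, {
    keep <- sample.int(nrow(pp), round(include_fraction * nrow(pp)))
    real <- tibble::tibble(tf_gene = pp$source_gene[keep],
                           target_gene = pp$target_gene[keep],
                           planted = TRUE)
    n_decoy <- if (decoy_fraction >= 1) 0L else
      round(decoy_fraction * nrow(real) / (1 - decoy_fraction))
    tfs <- annotation$gene_id[annotation$is_tf]
    decoys <- tibble::tibble(tf_gene = character(0),
                             target_gene = character(0), planted = logical(0))
    while (nrow(decoys) < n_decoy) {
      cand <- tibble::tibble(
        tf_gene = sample(tfs, n_decoy - nrow(decoys), replace = TRUE),
        target_gene = sample(annotation$gene_id, n_decoy - nrow(decoys),
                             replace = TRUE),
        planted = FALSE)
      cand <- cand[cand$tf_gene != cand$target_gene, ]
      decoys <- dplyr::distinct(
        dplyr::anti_join(dplyr::bind_rows(decoys, cand), real,
                         by = c("tf_gene", "target_gene")))
    }
    dplyr::bind_rows(real, decoys)
  })
}
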