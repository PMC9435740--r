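test_that("TMM gives unit factors for identical and depth-scaled columns", {
  x <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(tmm_normalize(x)$factors), c(1, 1))
  # pure depth: column b = 2x column a, composition unchanged
  y <- cbind(a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
  expect_equal(unname(tmm_normalize(y)$factors), c(1, 1))
  # all-zero sample is an error
  z <- cbind(a = c(1, 2), b = c(0, 0))
  expect_error(tmm_normalize(z), "all-zero")
})

test_that("TMM matches the straight-line oracle and edgeR on random matrices", {
  set.seed(88)
  for (i in 1:100) {
    ng <- sample(8:20, 1); ns <- sample(2:6, 1)
    x <- matrix(rnbinom(ng * ns, mu = 50 * runif(ng * ns, 0.2, 5),
                        size = 10), ng, ns)
    x[x == 0] <- 1      # strictly positive: reference choice is unambiguous
    colnames(x) <- paste0("s", 1:ns)
    f <- tmm_normalize(x)$factors
    expect_lt(max(abs(f - oracle_tmm(x))), 1e-9)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    if (requireNamespace("edgeR", quietly = TRUE)) {
      fe <- edgeR::calcNormFactors(x, method = "TMM")
      expect_equal(unname(f), unname(fe), tolerance = 1e-8)
    }
  }
})

test_that("isoform usage fractions are within-gene proportions", {
  expr <- rbind(t1 = c(6, 0), t2 = c(2, 0), t3 = c(5, 3))
  colnames(expr) <- c("s1", "s2")
  gene_of <- c(t1 = "g1", t2 = "g1", t3 = "g2")
  iu <- compute_iu(expr, gene_of)
  expect_equal(iu["t1", "s1"], 0.75)
  expect_equal(iu["t2", "s1"], 0.25)
  expect_true(is.na(iu["t1", "s2"]))      # gene total 0 -> missing
  expect_equal(iu["t3", "s2"], 1)         # single-transcript gene
  expect_error(compute_iu(expr, gene_of[-1]), "without gene")
  # conservation: IU sums to 1 per (gene, sample) wherever defined
  iu_all <- compute_iu(small_em$tpm, small_ref$gene_of)
  sums <- rowsum(iu_all, small_ref$gene_of[rownames(iu_all)])
  sums <- sums[!is.na(sums)]
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("quantification-ambiguous genes are flagged", {
  # 9-nt internal acceptor shift only -> flagged
  g <- mk_parts_gene(list(list(c(0, 200), c(100, 300)),
                          list(c(0, 191), c(100, 300))))
  expect_true(flag_ambiguous_genes(g)$flagged)
  # skipped exon -> different intron count -> not flagged
  g <- mk_parts_gene(list(list(c(0, 200, 400), c(100, 300, 500)),
                          list(c(0, 400), c(100, 500))))
  expect_false(flag_ambiguous_genes(g)$flagged)
  # identical duplicate -> flagged
  g <- mk_parts_gene(list(list(c(0, 200), c(100, 300)),
                          list(c(0, 200), c(100, 300))))
  expect_true(flag_ambiguous_genes(g)$flagged)
  # a 45-nt shift exceeds the default 30-nt window -> not flagged
  g <- mk_parts_gene(list(list(c(0, 200), c(100, 300)),
                          list(c(0, 155), c(100, 300))))
  expect_false(flag_ambiguous_genes(g)$flagged)
})

test_that("dominance records recover planted rank-1 switches", {
  cfg <- small_cfg
  em6 <- simulate_expression(small_ref, cfg, replicates = 6L,
                             seed_offset = 2000L)
  iu <- compute_iu(em6$tpm, small_ref$gene_of)
  rd <- rank_dominance(iu, em6$tpm, small_ref$gene_of, em6$samples,
                       orf_of = small_ref$proteins,
                       domains_of = small_ref$domains)
  truth <- small_ref$truth
  rs <- truth[truth$class == "rank_switch", ]
  rec <- rd$records
  expect_true(all(!rec$shared_rank1[rec$gene_id %in% rs$gene_id]))
  # background genes (no planted usage event) keep a shared dominant isoform
  moved <- truth$gene_id[truth$class %in% c("rank_switch", "diu", "deu")]
  bg <- rec[!rec$gene_id %in% moved, ]
  expect_true(mean(bg$shared_rank1) > 0.95)
  # sharing fraction is non-decreasing in the fold-change threshold
  curve <- rd$sharing_curve$frac_shared
  curve <- curve[!is.na(curve)]
  expect_true(all(diff(curve) >= -1e-12))
})

test_that("species-specific usage calls need all-4 significant pairs and none among the rest", {
  set.seed(123)
  species <- c("H", "C", "G", "O", "M")
  samples <- data.frame(
    sample_id = sprintf("%s_%d", rep(species, each = 6), 1:6),
    species = rep(species, each = 6), replicate = rep(1:6, 5))
  n_feat <- 40
  usage <- matrix(plogis(rnorm(n_feat * 30, 0, 0.3)), n_feat, 30,
                  dimnames = list(sprintf("f%02d", 1:n_feat),
                                  samples$sample_id))
  # feature f01: +0.4 usage in G only
  usage["f01", samples$species == "G"] <-
    usage["f01", samples$species == "G"] * 0.2 + 0.75
  res <- test_species_specific_usage(usage, samples)
  expect_equal(res$call[res$feature_id == "f01"], "up")
  expect_equal(res$species[res$feature_id == "f01"], "G")
  # feature f02: the same shift in two species is not species-specific
  usage2 <- usage
  usage2["f02", samples$species %in% c("H", "C")] <- 0.9
  res2 <- test_species_specific_usage(usage2, samples)
  expect_equal(res2$call[res2$feature_id == "f02"], "none")
})

test_that("the usage test controls type-I error on null data", {
  set.seed(321)
  species <- c("H", "C", "G", "O", "M")
  samples <- data.frame(
    sample_id = sprintf("%s_%d", rep(species, each = 6), 1:6),
    species = rep(species, each = 6), replicate = rep(1:6, 5))
  n_feat <- 200
  usage <- matrix(plogis(rnorm(n_feat * 30, 0, 0.4)), n_feat, 30,
                  dimnames = list(sprintf("f%03d", 1:n_feat),
                                  samples$sample_id))
  res <- test_species_specific_usage(usage, samples)
  expect_lte(mean(res$call != "none"), 0.08)
})

test_that("exonic-part usage coefficients and inclusion fractions", {
  pc <- rbind(p1 = c(10, 10), p2 = c(10, 10), p3 = c(0, 0))
  colnames(pc) <- c("s1", "s2")
  gene_of <- c(p1 = "g", p2 = "g", p3 = "g")
  samples <- data.frame(sample_id = c("s1", "s2"), species = c("H", "H"),
                        replicate = 1:2)
  u <- exonic_part_usage(pc, gene_of, samples)
  expect_equal(unname(u["p1", ]), c(0.5, 0.5))
  expect_equal(unname(u["p3", ]), c(0, 0))
  incl <- attr(u, "inclusion")
  expect_equal(unname(incl["p1", "H"]), 0.5)
  # gene with zero totals -> missing
  pc0 <- rbind(p1 = c(0, 0))
  expect_true(all(is.na(exonic_part_usage(pc0, c(p1 = "g")))))
})

test_that("batch correction centers batch medians without inventing signal", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:6), species = "H",
                        replicate = 1:6, batch = rep(c("b1", "b2"), each = 3))
  tpm <- matrix(rep(c(10, 10, 10, 40, 40, 40), 2), 2, 6, byrow = TRUE,
                dimnames = list(c("t1", "t2"), samples$sample_id))
  em <- expression_matrix(tpm, samples)
  cor <- correct_batch(em)
  # batch medians coincide after correction
  lg <- log2(cor$tpm + 1)
  expect_equal(stats::median(lg[1, 1:3]), stats::median(lg[1, 4:6]))
  # single batch: identity
  samples$batch <- "b1"
  em1 <- expression_matrix(tpm, samples)
  expect_equal(correct_batch(em1)$tpm, em1$tpm)
})
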