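test_that("configuration validates its planted-event budget", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, n_genes = 10L), "exceed")
  expect_error(sim_config(seed = 1, n_gain = 2L, n_gain_canonical = 5L),
               "n_gain_canonical")
  expect_error(sim_config(seed = 1, diu_delta = 1.2), "diu_delta")
  expect_error(sim_config(seed = 1, nb_dispersion = 0), "dispersion")
})

test_that("the same seed reproduces the fixture byte for byte", {
  cfg <- sim_config(seed = 5, n_genes = 12L, n_gain = 2L,
                    n_gain_canonical = 1L, n_exon_gain = 1L, n_diu = 2L,
                    n_deu = 2L, n_rank_switch = 1L, n_novel_gene = 1L,
                    n_nnc = 1L)
  d1 <- tempfile(); d2 <- tempfile()
  emit_fixture(cfg, d1)
  emit_fixture(cfg, d2)
  for (f in dir(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # refusing to overwrite without force
  expect_error(emit_fixture(cfg, d1), "not empty")
  expect_silent(suppressWarnings(emit_fixture(cfg, d1, force = TRUE)))
})

test_that("an emitted fixture loads back through the package readers", {
  cfg <- sim_config(seed = 6, n_genes = 12L, n_gain = 2L,
                    n_gain_canonical = 1L, n_exon_gain = 1L, n_diu = 2L,
                    n_deu = 2L, n_rank_switch = 1L, n_novel_gene = 1L,
                    n_nnc = 1L)
  d <- tempfile()
  out <- emit_fixture(cfg, d)
  ts <- read_annotation(file.path(d, "models_H.gtf"), "H")
  expect_equal(sort(ts$transcripts$transcript_id),
               sort(out$reference$annotations$H$transcripts$transcript_id))
  g <- read_genome(file.path(d, "genome_H.fa"), "H")
  expect_equal(sort(names(g$sequences)),
               sort(names(out$reference$genomes$H$sequences)))
  meta <- read_tables(file.path(d, "metadata.tsv"))
  paths <- stats::setNames(
    file.path(d, sprintf("abundance_%s.tsv", meta$sample_id)),
    meta$sample_id)
  em <- read_expression(paths, meta)
  expect_equal(dim(em$tpm), dim(out$expression$tpm))
  expect_equal(em$tpm[rownames(out$expression$tpm), colnames(out$expression$tpm)],
               out$expression$tpm, tolerance = 1e-4)
  om <- read_orthology(file.path(d, "orthology.tsv"))
  expect_true(all(c("junction", "exon") %in% om$feature_type))
  prot <- read_proteome(file.path(d, "proteome.fa"))
  expect_gt(length(prot), 0)
  truth <- read_tables(file.path(d, "truth.tsv"))
  expect_equal(nrow(truth), nrow(out$reference$truth))
})

test_that("truth ledger counts equal the configured plantings", {
  truth <- small_ref$truth
  cfg <- small_cfg
  cnt <- table(truth$class)
  expect_equal(unname(cnt["gain"]), cfg$n_gain)
  expect_equal(sum(truth$class == "gain" & truth$mechanism == "canonicity"),
               cfg$n_gain_canonical)
  expect_equal(unname(cnt["exon_gain"]), cfg$n_exon_gain)
  expect_equal(unname(cnt["diu"]), cfg$n_diu)
  expect_equal(unname(cnt["deu"]), cfg$n_deu)
  expect_equal(unname(cnt["rank_switch"]), cfg$n_rank_switch)
  expect_equal(unname(cnt["novel_gene"]), cfg$n_novel_gene)
  expect_equal(unname(cnt["nnc"]), cfg$n_nnc)
})

test_that("planted junction dinucleotides read back with the intended canonicity", {
  # every junction of every expressed transcript in its own species' genome
  # is canonical, except the planted canonicity-broken junctions
  truth <- small_ref$truth
  broken <- truth[truth$class == "gain" & truth$mechanism == "canonicity", ]
  for (sp in c("H", "M")) {
    ann <- small_ref$annotations[[sp]]
    for (tid in ann$transcripts$transcript_id[1:40]) {
      j <- extract_junctions(ann, tid, small_ref$genomes[[sp]])
      if (nrow(j) == 0) next
      lab <- classify_canonicity(j$donor, j$acceptor)
      keys <- sprintf("jx|%s|%s|%d|%d", j$chrom, j$strand, j$start, j$end)
      expected_broken <- keys %in% broken$feature & sp != broken$species[
        match(keys, broken$feature)]
      expected_broken[is.na(expected_broken)] <- FALSE
      expect_equal(lab == "noncanonical", expected_broken)
    }
  }
})

test_that("null configurations produce no species-specific structure", {
  cfg0 <- sim_config(seed = 8, n_genes = 15L, n_gain = 0L,
                     n_gain_canonical = 0L, n_exon_gain = 0L, n_diu = 0L,
                     n_deu = 0L, n_rank_switch = 0L, n_novel_gene = 0L,
                     n_nnc = 0L)
  ref0 <- simulate_reference(cfg0)
  expect_equal(nrow(ref0$truth), 0L)
  # all exons conserved
  ex_ids <- unique(ref0$orthology$feature_id[
    ref0$orthology$feature_type == "exon"])
  cons <- call_exon_conservation(ref0$orthology,
                                 stats::setNames(rep("H", length(ex_ids)),
                                                 ex_ids))
  expect_true(all(cons$status == "conserved"))
  # no canonicity changes
  cc <- detect_canonicity_changes(ref0$orthology, ref0$genomes)
  expect_false(any(cc$change))
  # no species-specific expression
  em0 <- simulate_expression(ref0, cfg0)
  ss <- call_species_specific(build_presence_matrix(em0, "strict"))
  expect_equal(nrow(ss), 0L)
})

test_that("planted gains give strict single-species presence profiles", {
  prof <- build_presence_matrix(small_em, "strict")
  truth <- small_ref$truth
  gains <- truth[truth$class == "gain", ]
  for (i in seq_len(nrow(gains))) {
    row <- prof[prof$transcript_id == gains$transcript_id[i], ]
    st <- unlist(row[c("H", "C", "G", "O", "M")])
    expect_equal(unname(st[gains$species[i]]), 1L)
    expect_true(all(st[setdiff(names(st), gains$species[i])] == 0L))
  }
})

test_that("the bundled smoke fixture loads and matches its generator", {
  d <- system.file("extdata", "smoke", package = "primatesplice")
  expect_true(dir.exists(d))
  ts <- read_annotation(file.path(d, "models_H.gtf"), "H")
  expect_gt(nrow(ts$transcripts), 0)
  meta <- read_tables(file.path(d, "metadata.tsv"))
  paths <- stats::setNames(
    file.path(d, sprintf("abundance_%s.tsv", meta$sample_id)),
    meta$sample_id)
  em <- read_expression(paths, meta)
  expect_equal(ncol(em$tpm), 15L)
  om <- read_orthology(file.path(d, "orthology.tsv"))
  expect_s3_class(om, "orthology_map")
  # regeneration with the baked-in configuration is byte-identical
  cfg <- sim_config(seed = 101, n_genes = 6L, n_gain = 1L,
                    n_gain_canonical = 1L, n_exon_gain = 1L, n_diu = 1L,
                    n_deu = 1L, n_rank_switch = 0L, n_novel_gene = 1L,
                    n_nnc = 1L)
  d2 <- tempfile()
  emit_fixture(cfg, d2)
  for (f in c("truth.tsv", "models_H.gtf", "genome_H.fa", "abundance_H_1.tsv"))
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d, f)), label = f)
})
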