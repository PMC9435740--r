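mk_omap <- function(statuses, coverages, focal = "H") {
  other <- setdiff(c("H", "C", "G", "O", "M"), focal)
  rbind(
    data.frame(feature_id = "e1", feature_type = "exon", species = focal,
               status = "MAPPED", chrom = "chr1", start = 0L, end = 100L,
               coverage = 1, stringsAsFactors = FALSE),
    data.frame(feature_id = "e1", feature_type = "exon", species = other,
               status = statuses, chrom = "chr1", start = 0L, end = 100L,
               coverage = coverages, stringsAsFactors = FALSE))
}

test_that("exon conservation follows the mapping + coverage rule", {
  focal_of <- c(e1 = "H")
  # mapped everywhere -> conserved
  r <- call_exon_conservation(mk_omap(rep("MAPPED", 4), rep(1, 4)), focal_of)
  expect_equal(r$status, "conserved")
  # all mappings failed, coverage {0, .2, .4, .1} -> species-specific
  r <- call_exon_conservation(mk_omap(rep("UNMAPPED", 4),
                                      c(0, 0.2, 0.4, 0.1)), focal_of)
  expect_equal(r$status, "species_specific")
  expect_equal(r$focal_species, "H")
  # one coverage at 0.6 -> unresolved under the strict < 0.5 rule
  r <- call_exon_conservation(mk_omap(rep("UNMAPPED", 4),
                                      c(0, 0.2, 0.6, 0.1)), focal_of)
  expect_equal(r$status, "unresolved")
  # boundary: coverage exactly 0.5 is not < 0.5
  r <- call_exon_conservation(mk_omap(rep("UNMAPPED", 4),
                                      c(0.5, 0.2, 0.4, 0.1)), focal_of)
  expect_equal(r$status, "unresolved")
  # mixed mapped/unmapped -> unresolved
  r <- call_exon_conservation(mk_omap(c("MAPPED", rep("UNMAPPED", 3)),
                                      c(1, 0.1, 0.1, 0.1)), focal_of)
  expect_equal(r$status, "unresolved")
  # failed mapping with missing coverage -> unresolved with warning
  expect_warning(
    r <- call_exon_conservation(mk_omap(rep("UNMAPPED", 4),
                                        c(NA, 0.1, 0.1, 0.1)), focal_of),
    "missing coverage")
  expect_equal(r$status, "unresolved")
})

test_that("conservation calls are monotone in coverage", {
  # lowering any coverage never converts species_specific -> conserved
  set.seed(5)
  focal_of <- c(e1 = "H")
  for (i in 1:30) {
    cov <- runif(4, 0, 1)
    r1 <- call_exon_conservation(mk_omap(rep("UNMAPPED", 4), cov), focal_of)
    cov2 <- cov * runif(4, 0, 1)    # lower each coverage
    r2 <- call_exon_conservation(mk_omap(rep("UNMAPPED", 4), cov2), focal_of)
    if (r1$status == "species_specific")
      expect_equal(r2$status, "species_specific")
    expect_false(r2$status == "conserved")
  }
})

test_that("exon placement relative to the CDS", {
  # exon fully in UTR of every containing transcript
  expect_equal(classify_exon_placement(c(0, 100),
                                       list(data.frame(start = 200, end = 500))),
               "full_UTR")
  # exon inside the CDS of every transcript
  expect_equal(classify_exon_placement(c(250, 300),
                                       list(data.frame(start = 200, end = 500))),
               "CDS_only")
  # exon straddling the stop codon
  expect_equal(classify_exon_placement(c(450, 550),
                                       list(data.frame(start = 200, end = 500))),
               "partial_UTR")
  # disagreement between containing transcripts -> partial
  expect_equal(classify_exon_placement(
    c(250, 300), list(data.frame(start = 200, end = 500),
                      data.frame(start = 400, end = 600))), "partial_UTR")
  expect_equal(classify_exon_placement(c(0, 100), list()), "missing")
})

test_that("flattening yields disjoint parts that tile the exon union", {
  # T1 exon [0,100); T2 exon [50,100)
  g <- mk_parts_gene(list(list(0, 100), list(50, 100)))
  p <- flatten_exonic_parts(g, "g")
  expect_equal(p$start, c(0, 50))
  expect_equal(p$end, c(50, 100))
  expect_equal(p$transcripts, c("t1", "t1,t2"))

  # T1 [0,100),[200,300); T2 [0,100),[200,250)
  g <- mk_parts_gene(list(list(c(0, 200), c(100, 300)),
                          list(c(0, 200), c(100, 250))))
  p <- flatten_exonic_parts(g, "g")
  expect_equal(p$start, c(0, 200, 250))
  expect_equal(p$end, c(100, 250, 300))

  # single transcript: parts are its exons
  g <- mk_parts_gene(list(list(c(0, 200), c(100, 300))))
  p <- flatten_exonic_parts(g, "g")
  expect_equal(p$start, c(0, 200))
  expect_equal(p$end, c(100, 300))

  # transcripts on both strands are an error
  ex <- data.frame(transcript_id = c("t1", "t2"), start = c(0, 0),
                   end = c(100, 100))
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g",
                   species_id = "H", chrom = "chr1", strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  expect_error(flatten_exonic_parts(transcript_set(ex, tx), "g"),
               "both strands")
})

test_that("flattening matches the per-base oracle and is idempotent", {
  set.seed(21)
  for (i in 1:120) {
    g <- random_toy_gene()
    p <- flatten_exonic_parts(g, "g1")
    o <- oracle_parts(g, "g1")
    expect_equal(p$start, o$start)
    expect_equal(p$end, o$end)
    expect_equal(p$transcripts, o$transcripts)
    # disjoint and conservative
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
    ex <- g$exons
    union_len <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(ex$start + 1, ex$end))))
    expect_equal(sum(p$end - p$start), union_len)
    # idempotence: flattening the parts again returns the same parts
    pts <- transcript_set(
      data.frame(transcript_id = sprintf("p%d", seq_len(nrow(p))),
                 start = p$start, end = p$end),
      data.frame(transcript_id = sprintf("p%d", seq_len(nrow(p))),
                 gene_id = "g1", species_id = "H", chrom = "chr1",
                 strand = "+", stringsAsFactors = FALSE),
      min_intron_length = 0L)
    p2 <- flatten_exonic_parts(pts, "g1")
    expect_equal(p2$start, p$start)
    expect_equal(p2$end, p$end)
  }
})

test_that("repeat overlap annotation and Alu enrichment on planted exonizations", {
  exons <- data.frame(exon_id = c("e1", "e2"), chrom = "chr1",
                      start = c(0, 300), end = c(100, 400))
  reps <- data.frame(chrom = "chr1", start = 50, end = 150,
                     family = "Alu", score = 0, strand = "+")
  r <- annotate_repeats(exons, reps)
  expect_equal(r$overlaps$families, c("Alu", ""))
  expect_equal(r$overlaps$any_overlap, c(TRUE, FALSE))
  # no repeats file: flags absent
  r0 <- annotate_repeats(exons, NULL)
  expect_true(all(is.na(r0$overlaps$any_overlap)))

  # planted Alu-tagged exonizations enrich over background exons
  truth <- small_ref$truth
  exg <- truth[truth$class == "exon_gain" & truth$mechanism == "Alu", ]
  expect_gt(nrow(exg), 0)          # alu_fraction makes this deterministic
  sp <- exg$species[1]
  om <- small_ref$orthology
  om <- om[om$feature_type == "exon" & om$species == sp, ]
  exons <- data.frame(exon_id = om$feature_id, chrom = om$chrom,
                      start = om$start, end = om$end)
  r <- annotate_repeats(exons, small_ref$repeats[[sp]],
                        focal_ids = exg$feature[exg$species == sp],
                        family = "Alu")
  expect_gt(r$enrichment$odds_ratio, 1)
})
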