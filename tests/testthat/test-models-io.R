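test_that("transcript_set enforces its invariants", {
  # overlapping exons rejected
  expect_error(make_query("t1", c(0, 50), c(100, 150)), "overlapping")
  # short intron rejected at default min_intron_length = 4
  expect_error(make_query("t1", c(0, 103), c(100, 200)), "intron shorter")
  expect_silent(make_query("t1", c(0, 104), c(100, 200)))
  # zero-length exon rejected
  expect_error(make_query("t1", c(0, 200), c(0, 300)), "length >= 1")
  # unknown strand rejected
  expect_error(make_query("t1", 0, 100, strand = "*"), "strand")
})

test_that("GTF I/O converts coordinates and round-trips exactly", {
  f <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), f)
  ts <- read_annotation(f, "H")
  e <- transcript_exons(ts, "t1")
  expect_equal(c(e$start, e$end), c(100, 200))  # 1-based incl -> 0-based half-open

  # two exons form one transcript with the expected intron
  writeLines(c(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
                      'gene_id "g1"; transcript_id "t1";'),
               paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
                      'gene_id "g1"; transcript_id "t1";')), f)
  ts <- read_annotation(f, "H")
  ic <- transcript_introns(ts, "t1")
  expect_equal(c(ic$start, ic$end), c(200, 300))

  # round trip through write_annotation preserves everything
  f2 <- tempfile(fileext = ".gtf"); f3 <- tempfile(fileext = ".gtf")
  write_annotation(ts, f2)
  ts2 <- read_annotation(f2, "H")
  write_annotation(ts2, f3)
  expect_identical(readLines(f2), readLines(f3))
  expect_equal(ts2$exons, ts$exons)
  expect_equal(ts2$transcripts, ts$transcripts)
})

test_that("GTF round trip is stable on a full synthetic annotation", {
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_annotation(small_ref$annotations$H, f1)
  back <- read_annotation(f1, "H")
  write_annotation(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("read_expression aligns abundance files on the shared model set", {
  dir <- tempfile(); dir.create(dir)
  write_ab <- function(name, ids, tpm, cnt) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(data.frame(target_id = ids, length = 500,
                                  eff_length = 500, est_counts = cnt,
                                  tpm = tpm),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  meta1 <- data.frame(sample_id = "s1", species = "H", replicate = 1)
  p1 <- write_ab("s1", c("t1", "t2"), c(5, 0), c(10, 0))
  em <- read_expression(c(s1 = p1), meta1)
  expect_equal(dim(em$tpm), c(2L, 1L))
  expect_equal(unname(em$tpm[, 1]), c(5, 0))

  # the full 15-sample design yields 5 species groups
  meta <- expand.grid(replicate = 1:3, species = c("H", "C", "G", "O", "M"))
  meta$sample_id <- sprintf("%s_%d", meta$species, meta$replicate)
  paths <- vapply(meta$sample_id, function(s)
    write_ab(s, c("t1", "t2"), c(1, 2), c(3, 4)), character(1))
  em <- read_expression(paths, meta)
  expect_equal(ncol(em$tpm), 15L)
  expect_equal(length(unique(em$samples$species)), 5L)

  # duplicated transcript id in one file is an error
  pd <- write_ab("dup", c("t1", "t1"), c(1, 2), c(1, 2))
  expect_error(read_expression(c(s1 = pd), meta1), "duplicated")
  # missing file for a metadata sample is an error
  expect_error(read_expression(c(sX = p1), meta1), "without abundance file")
  # negative TPM is an error
  pn <- write_ab("neg", c("t1", "t2"), c(-1, 2), c(1, 2))
  expect_error(read_expression(c(s1 = pn), meta1), "negative TPM")
})

test_that("extract_junctions reads dinucleotides in transcription orientation", {
  # chromosome: exon [0,10), intron [10,20) = GTxxxxxxAG, exon [20,30)
  intron <- paste0("GT", "AAAAAA", "AG")
  chrom <- paste0(strrep("C", 10), intron, strrep("C", 10))
  g <- genome_set("H", c(chr1 = chrom))
  ts <- make_query("t1", c(0, 20), c(10, 30))
  j <- extract_junctions(ts, "t1", g)
  expect_equal(j$donor, "GT")
  expect_equal(j$acceptor, "AG")

  # minus strand: genomic forward intron CT....AC reads GT-AG after
  # orientation (reverse complement, donor/acceptor swapped)
  intron2 <- paste0("CT", "AAAAAA", "AC")
  chrom2 <- paste0(strrep("C", 10), intron2, strrep("C", 10))
  g2 <- genome_set("H", c(chr1 = chrom2))
  ts2 <- make_query("t1", c(0, 20), c(10, 30), strand = "-")
  j2 <- extract_junctions(ts2, "t1", g2)
  expect_equal(j2$donor, "GT")
  expect_equal(j2$acceptor, "AG")

  # mono-exonic transcript has no junctions
  ts3 <- make_query("t1", 0, 30)
  expect_equal(nrow(extract_junctions(ts3, "t1", g)), 0L)

  # intron past chromosome end is an error
  ts4 <- make_query("t1", c(0, 40), c(10, 45))
  expect_error(extract_junctions(ts4, "t1", g), "past end")
})

test_that("junction dinucleotides are invariant under genome mirroring", {
  # reverse-complementing the chromosome and flipping the strand describes
  # the same molecule, so donor/acceptor must not change
  set.seed(401)
  for (rep in 1:20) {
    n <- 60L
    chrom <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    g <- genome_set("H", c(chr1 = chrom))
    ts <- make_query("t1", c(0, 40), c(20, 60), strand = "+")
    j <- extract_junctions(ts, "t1", g)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
    g_rc <- genome_set("H", c(chr1 = rc))
    ts_rc <- make_query("t1", c(n - 60, n - 20), c(n - 40, n), strand = "-")
    j_rc <- extract_junctions(ts_rc, "t1", g_rc)
    expect_equal(j_rc$donor, j$donor)
    expect_equal(j_rc$acceptor, j$acceptor)
  }
})

test_that("expression matrix column sums ignore row order", {
  tpm <- small_em$tpm
  perm <- sample(nrow(tpm))
  expect_equal(colSums(tpm[perm, ]), colSums(tpm))
})

test_that("write_tables is deterministic and round-trips", {
  d <- data.frame(id = c("b", "a", "c"), x = c(2, 1, 3),
                  stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_tables(d, f, key = "id")
  back <- read_tables(f)
  expect_equal(back$id, c("a", "b", "c"))
  f2 <- tempfile(fileext = ".tsv")
  write_tables(back, f2, key = "id")
  expect_identical(readLines(f), readLines(f2))
  # empty tables need the explicit flag
  expect_error(write_tables(d[0, ], f), "allow_empty")
  write_tables(d[0, ], f, allow_empty = TRUE)
  expect_equal(nrow(read_tables(f)), 0L)
})
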