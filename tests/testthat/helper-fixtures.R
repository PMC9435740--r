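# Shared small fixtures built once per test run.

# small synthetic reference + expression used across module tests
small_cfg <- sim_config(seed = 11, n_genes = 40L,
                        n_gain = 4L, n_gain_canonical = 2L,
                        n_exon_gain = 3L, n_diu = 4L, n_deu = 4L,
                        n_rank_switch = 2L, n_novel_gene = 2L, n_nnc = 3L)
small_ref <- simulate_reference(small_cfg)
small_em <- simulate_expression(small_ref, small_cfg)

# a hand-built two-gene reference annotation on one chromosome, + strand
# geneA: tA1 exons [100,200),[300,400),[500,600); tA2 skips the middle exon;
#        tA3 exons [100,200),[450,600) (alternative acceptor at 450)
# geneB: tB1 exons [1000,1100),[1200,1300)
tiny_ref <- local({
  exons <- data.frame(
    transcript_id = c(rep("tA1", 3), rep("tA2", 2), rep("tA3", 2),
                      rep("tB1", 2)),
    start = c(100, 300, 500, 100, 500, 100, 450, 1000, 1200),
    end = c(200, 400, 600, 200, 600, 200, 600, 1100, 1300))
  txs <- data.frame(
    transcript_id = c("tA1", "tA2", "tA3", "tB1"),
    gene_id = c("geneA", "geneA", "geneA", "geneB"),
    species_id = "H", chrom = "chr1",
    strand = "+", stringsAsFactors = FALSE)
  transcript_set(exons, txs)
})

# gene with several transcripts given as list(list(starts, ends), ...)
mk_parts_gene <- function(txl, strand = "+") {
  ex <- do.call(rbind, lapply(seq_along(txl), function(i)
    data.frame(transcript_id = sprintf("t%d", i),
               start = txl[[i]][[1]], end = txl[[i]][[2]])))
  txs <- data.frame(transcript_id = sprintf("t%d", seq_along(txl)),
                    gene_id = "g", species_id = "H", chrom = "chr1",
                    strand = strand, stringsAsFactors = FALSE)
  transcript_set(ex, txs)
}

make_query <- function(id, starts, ends, strand = "+", gene = "q",
                       chrom = "chr1") {
  transcript_set(
    data.frame(transcript_id = id, start = starts, end = ends),
    data.frame(transcript_id = id, gene_id = gene, species_id = "H",
               chrom = chrom, strand = strand, stringsAsFactors = FALSE))
}
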