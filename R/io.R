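# Readers and writers for the external formats the pipeline consumes:
# GTF annotations, genome/proteome FASTA, kallisto-style abundance TSVs,
# sample metadata, orthology maps, BED6 repeats, and generic result tables.

#' Read transcript models from a GTF file
#'
#' Parses exon features of an Ensembl-dialect GTF (1-based inclusive
#' coordinates, quoted `gene_id`/`transcript_id` attributes) into a
#' [transcript_set()]. Coordinates are converted to the package's internal
#' 0-based half-open convention.
#'
#' @param path GTF file path
#' @param species_id species label to assign to all transcripts
#' @param min_intron_length passed to [transcript_set()]
#' @return a `transcript_set`
#' @export
read_annotation <- function(path, species_id, min_intron_length = 4L) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  if (any(is.na(gr$gene_id)) || any(is.na(gr$transcript_id)))
    stop("exon feature without gene_id/transcript_id attribute in ", path)
  exons <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    start = BiocGenerics::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
  idx <- !duplicated(gr$transcript_id)
  transcripts <- data.frame(
    transcript_id = as.character(gr$transcript_id)[idx],
    gene_id = as.character(gr$gene_id)[idx],
    species_id = species_id,
    chrom = as.character(GenomicRanges::seqnames(gr))[idx],
    strand = as.character(BiocGenerics::strand(gr))[idx],
    stringsAsFactors = FALSE)
  if (any(!transcripts$strand %in% c("+", "-")))
    stop("exon feature with unstranded location in ", path)
  transcript_set(exons, transcripts, min_intron_length = min_intron_length)
}

#' Write transcript models as GTF
#'
#' Deterministic Ensembl-dialect writer: transcripts sorted by id, exons in
#' genomic order, coordinates converted back to 1-based inclusive. A round
#' trip through [read_annotation()] reproduces coordinates, strands and ids
#' exactly.
#'
#' @param ts a `transcript_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_annotation <- function(ts, path) {
  tr <- ts$transcripts[order(ts$transcripts$transcript_id), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(tr))) {
    e <- transcript_exons(ts, tr$transcript_id[i])
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        tr$gene_id[i], tr$transcript_id[i])
    lines <- c(lines, sprintf("%s\tprimatesplice\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom[i], e$start + 1L, e$end,
                              tr$strand[i], attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome (or any nucleotide) FASTA into a genome_set
#'
#' @param path FASTA file
#' @param species_id species label
#' @return a `genome_set`
#' @export
read_genome <- function(path, species_id) {
  seqs <- Biostrings::readDNAStringSet(path)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*$", "", names(seqs))
  genome_set(species_id, v)
}

#' Write a genome_set as FASTA
#' @param g a `genome_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome <- function(g, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$sequences), path)
  invisible(path)
}

#' Read per-sample abundance files into an expression matrix
#'
#' Consumes kallisto-style abundance tables (columns `target_id`,
#' `est_counts`, `tpm`) plus a sample metadata table (`sample_id`,
#' `species`, `replicate`, optional `batch`). Every sample must quantify
#' the full shared transcript set: a transcript missing from any file is an
#' error, because downstream presence/absence calls require complete
#' coverage of the projected models.
#'
#' @param paths named character vector of abundance TSV paths; names are
#'   sample ids and must cover the metadata
#' @param metadata data.frame or path to metadata TSV
#' @return an `expression_matrix`
#' @export
read_expression <- function(paths, metadata) {
  if (is.character(metadata))
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "replicate")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  missing_files <- setdiff(metadata$sample_id, names(paths))
  if (length(missing_files))
    stop("metadata sample(s) without abundance file: ",
         paste(missing_files, collapse = ", "))
  tabs <- lapply(metadata$sample_id, function(s) {
    d <- utils::read.delim(paths[[s]], stringsAsFactors = FALSE)
    if (!all(c("target_id", "est_counts", "tpm") %in% names(d)))
      stop("abundance file for ", s,
           " lacks target_id/est_counts/tpm columns")
    if (anyDuplicated(d$target_id))
      stop("duplicated transcript id in abundance file for sample ", s)
    if (any(d$tpm < 0)) stop("negative TPM in sample ", s)
    d
  })
  ids <- sort(unique(unlist(lapply(tabs, `[[`, "target_id"))))
  for (i in seq_along(tabs)) {
    absent <- setdiff(ids, tabs[[i]]$target_id)
    if (length(absent))
      stop("transcript(s) missing from sample ", metadata$sample_id[i],
           ": ", paste(utils::head(absent, 3), collapse = ", "))
  }
  tpm <- vapply(tabs, function(d) d$tpm[match(ids, d$target_id)],
                numeric(length(ids)))
  counts <- vapply(tabs, function(d) d$est_counts[match(ids, d$target_id)],
                   numeric(length(ids)))
  dimnames(tpm) <- dimnames(counts) <- list(ids, metadata$sample_id)
  expression_matrix(tpm, metadata, counts = counts)
}

#' Read an orthology mapping table
#'
#' Tab-separated table with columns `feature_id`, `feature_type`, `species`,
#' `status` (MAPPED/UNMAPPED), `chrom`, `start`, `end`, `coverage`
#' (alignment coverage in \[0,1\], NA when no mapping was attempted).
#'
#' @param path TSV path
#' @return data.frame of class `orthology_map`
#' @export
read_orthology <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "feature_type", "species", "status",
            "chrom", "start", "end", "coverage")
  if (!all(need %in% names(d)))
    stop("orthology map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d[c("feature_id", "species")]))
    stop("duplicated (feature_id, species) in orthology map")
  ok <- is.na(d$coverage) | (d$coverage >= 0 & d$coverage <= 1)
  if (!all(ok)) stop("coverage outside [0,1]")
  class(d) <- c("orthology_map", "data.frame")
  d
}

#' Read repeat-element intervals from a BED6 file
#'
#' 0-based half-open intervals; the name column is interpreted as the
#' repeat family label (e.g. "Alu", "L1").
#'
#' @param path BED6 path
#' @return data.frame with columns chrom, start, end, family, score, strand
#' @export
read_repeats <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 6) stop("expected BED6 with 6 columns")
  names(d)[1:6] <- c("chrom", "start", "end", "family", "score", "strand")
  d[1:6]
}

#' Write a result table deterministically
#'
#' Sorts rows by the given key columns and writes a TSV with a fixed column
#' order so that reruns are byte-identical and reloads reproduce content.
#'
#' @param x data.frame
#' @param path output file
#' @param key character vector of key column names used for row ordering
#'   (defaults to the first column)
#' @param allow_empty permit writing a header-only file
#' @return `path`, invisibly
#' @export
write_tables <- function(x, path, key = names(x)[1], allow_empty = FALSE) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0 && !allow_empty)
    stop("refusing to write empty result set without allow_empty = TRUE")
  if (nrow(x) > 0)
    x <- x[do.call(order, unname(x[key])), , drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_tables()]
#' @param path TSV path
#' @return data.frame
#' @export
read_tables <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
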