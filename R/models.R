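#' @keywords internal
"_PACKAGE"

# Canonical five-species labels, in phylogenetic order used throughout.
SPECIES5 <- c("H", "C", "G", "O", "M")

#' Construct a transcript set
#'
#' The central container for transcript models: an exon table (one row per
#' exon, 0-based half-open genomic intervals) plus a transcript index
#' carrying gene, species, chromosome and strand. All downstream analyses
#' (structural classification, event detection, flattening, ORF calling)
#' consume this class.
#'
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `species_id`, `chrom`, `strand` (`+` or `-`).
#' @param min_intron_length minimum allowed intron length; the two terminal
#'   dinucleotides of an intron must not overlap, hence the default 4.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(exons, transcripts, min_intron_length = 4L) {
  stopifnot(is.data.frame(exons), is.data.frame(transcripts))
  need_e <- c("transcript_id", "start", "end")
  need_t <- c("transcript_id", "gene_id", "species_id", "chrom", "strand")
  if (!all(need_e %in% names(exons)))
    stop("exons must have columns: ", paste(need_e, collapse = ", "))
  if (!all(need_t %in% names(transcripts)))
    stop("transcripts must have columns: ", paste(need_t, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id in transcript index")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end - exons$start < 1))
    stop("every exon must have length >= 1")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon rows reference unknown transcript ids")
  if (!all(transcripts$transcript_id %in% exons$transcript_id))
    stop("transcript without exons: ",
         paste(setdiff(transcripts$transcript_id, exons$transcript_id),
               collapse = ", "))
  # per-transcript checks: sorted, disjoint, intron length
  sp <- split(exons, exons$transcript_id)
  for (tx in names(sp)) {
    e <- sp[[tx]]
    if (nrow(e) > 1) {
      gaps <- e$start[-1] - e$end[-nrow(e)]
      if (any(gaps < 0)) stop("overlapping exons within transcript ", tx)
      if (any(gaps < min_intron_length))
        stop("intron shorter than min_intron_length (", min_intron_length,
             ") in transcript ", tx)
    }
  }
  structure(list(exons = exons, transcripts = transcripts,
                 min_intron_length = min_intron_length),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,",
      length(unique(x$transcripts$gene_id)), "genes,",
      "species:", paste(unique(x$transcripts$species_id), collapse = ","),
      "\n")
  invisible(x)
}

#' Exon intervals of one transcript
#'
#' @param ts a `transcript_set`
#' @param transcript_id transcript identifier
#' @return data.frame of exons sorted by start (genomic order).
#' @export
transcript_exons <- function(ts, transcript_id) {
  e <- ts$exons[ts$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0) stop("unknown transcript: ", transcript_id)
  e[order(e$start), , drop = FALSE]
}

#' Intron intervals of one transcript (genomic order)
#'
#' @inheritParams transcript_exons
#' @return data.frame with columns `start`, `end` (0-based half-open);
#'   zero rows for mono-exonic transcripts.
#' @export
transcript_introns <- function(ts, transcript_id) {
  e <- transcript_exons(ts, transcript_id)
  if (nrow(e) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = e$end[-nrow(e)], end = e$start[-1])
}

#' Construct a genome set
#'
#' Holds the chromosome sequences of one species' assembly. Sequences are
#' uppercased and validated against the A/C/G/T/N alphabet.
#'
#' @param species_id species label
#' @param sequences named character vector, chromosome name -> sequence
#' @return object of class `genome_set`
#' @export
genome_set <- function(species_id, sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by chromosome")
  sequences <- toupper(unlist(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN characters in chromosome(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(species_id = species_id, sequences = sequences),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", x$species_id, "-", length(x$sequences),
      "chromosome(s),", sum(nchar(x$sequences)), "bp\n")
  invisible(x)
}

#' Construct an expression matrix
#'
#' TPM (and optionally estimated-count) tables over transcripts x samples,
#' with sample metadata (species, replicate, batch).
#'
#' @param tpm numeric matrix, transcripts in rows, samples in columns
#' @param samples data.frame with columns `sample_id`, `species`,
#'   `replicate`, and optionally `batch`
#' @param counts optional matrix parallel to `tpm`
#' @return object of class `expression_matrix`
#' @export
expression_matrix <- function(tpm, samples, counts = NULL) {
  stopifnot(is.matrix(tpm))
  need <- c("sample_id", "species", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (is.null(samples$batch)) samples$batch <- "b1"
  if (ncol(tpm) != nrow(samples))
    stop("tpm columns must match sample metadata rows")
  if (is.null(colnames(tpm))) colnames(tpm) <- samples$sample_id
  if (!identical(colnames(tpm), as.character(samples$sample_id)))
    stop("tpm column names must equal samples$sample_id in order")
  if (any(tpm < 0)) stop("negative TPM values")
  if (!is.null(counts)) {
    stopifnot(is.matrix(counts))
    if (!identical(dim(counts), dim(tpm)))
      stop("counts must be parallel to tpm")
    if (is.null(rownames(counts))) rownames(counts) <- rownames(tpm)
    if (any(counts < 0)) stop("negative counts")
  }
  structure(list(tpm = tpm, counts = counts, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$tpm), "transcripts x", ncol(x$tpm),
      "samples;", length(unique(x$samples$species)), "species\n")
  invisible(x)
}

# samples of one species, in metadata order
species_samples <- function(em, species) {
  em$samples$sample_id[em$samples$species == species]
}
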