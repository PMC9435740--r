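# Splice junctions: extraction from transcript models + genome sequence,
# canonicity labels, and interspecies canonicity-change detection.

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

subseq0 <- function(chrom_seq, start, end) {
  # 0-based half-open extraction from a character chromosome (vectorized)
  substring(chrom_seq, start + 1L, end)
}

#' Extract splice junctions of a transcript
#'
#' One junction per intron, with donor and acceptor dinucleotides read from
#' the genome in transcription orientation: on the plus strand the donor is
#' the first two intron bases and the acceptor the last two; on the minus
#' strand the roles are swapped and both are reverse-complemented. Junctions
#' are returned in transcription order.
#'
#' @param ts a `transcript_set`
#' @param transcript_id transcript to process
#' @param genome a `genome_set` for the transcript's assembly
#' @return data.frame with columns `chrom`, `strand`, `start`, `end`
#'   (intron, 0-based half-open), `donor`, `acceptor`; zero rows for
#'   mono-exonic transcripts.
#' @export
extract_junctions <- function(ts, transcript_id, genome) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  if (nrow(tr) != 1) stop("unknown transcript: ", transcript_id)
  if (!tr$chrom %in% names(genome$sequences))
    stop("chromosome ", tr$chrom, " absent from genome ", genome$species_id)
  chrom_seq <- genome$sequences[[tr$chrom]]
  introns <- transcript_introns(ts, transcript_id)
  if (nrow(introns) == 0)
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      donor = character(0), acceptor = character(0)))
  if (any(introns$end > nchar(chrom_seq)))
    stop("intron extends past end of chromosome ", tr$chrom)
  first2 <- subseq0(chrom_seq, introns$start, introns$start + 2L)
  last2 <- subseq0(chrom_seq, introns$end - 2L, introns$end)
  if (tr$strand == "+") {
    donor <- first2; acceptor <- last2
  } else {
    donor <- revcomp(last2); acceptor <- revcomp(first2)
  }
  out <- data.frame(chrom = tr$chrom, strand = tr$strand,
                    start = introns$start, end = introns$end,
                    donor = donor, acceptor = acceptor,
                    stringsAsFactors = FALSE)
  if (tr$strand == "-") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify splice-site canonicity
#'
#' A junction is canonical iff its (donor, acceptor) dinucleotide pair is
#' GT-AG, GC-AG or AT-AC (transcription orientation). Any N in either
#' dinucleotide yields `noncanonical` with a warning.
#'
#' @param donor,acceptor 2-mer character vectors
#' @return character vector, `"canonical"` or `"noncanonical"`
#' @export
classify_canonicity <- function(donor, acceptor) {
  stopifnot(length(donor) == length(acceptor))
  if (any(grepl("N", c(donor, acceptor))))
    warning("N in splice-site dinucleotide; labelled noncanonical")
  pair <- paste(donor, acceptor, sep = "-")
  ifelse(pair %in% c("GT-AG", "GC-AG", "AT-AC"),
         "canonical", "noncanonical")
}

#' Detect interspecies canonicity changes at orthologous junctions
#'
#' For each junction, reads the per-species dinucleotide pairs at the
#' orthologous coordinates supplied by the mapping table, labels each
#' species canonical/noncanonical/missing, and flags junctions where at
#' least two non-missing species disagree. Also reports, per species, the
#' "canonical only in this species" indicator used for the canonicity-driven
#' gain mechanism downstream.
#'
#' @param omap `orthology_map` rows with `feature_type == "junction"`;
#'   `feature_id` is the junction key; `strand` column required
#' @param genomes named list of `genome_set`, one per species
#' @return data.frame, one row per (junction, species), with columns
#'   `junction_id`, `species`, `donor`, `acceptor`, `label`, `change`
#'   (per-junction flag), `canonical_only_here`
#' @export
detect_canonicity_changes <- function(omap, genomes) {
  j <- omap[omap$feature_type == "junction", , drop = FALSE]
  if (nrow(j) == 0) stop("no junction features in orthology map")
  if (is.null(j$strand)) stop("orthology map lacks strand for junctions")
  res <- lapply(seq_len(nrow(j)), function(i) {
    r <- j[i, ]
    if (r$status != "MAPPED" || is.na(r$start))
      return(data.frame(junction_id = r$feature_id, species = r$species,
                        donor = NA_character_, acceptor = NA_character_,
                        label = "missing", stringsAsFactors = FALSE))
    g <- genomes[[r$species]]
    if (is.null(g)) stop("no genome for species ", r$species)
    if (!r$chrom %in% names(g$sequences))
      stop("chromosome ", r$chrom, " absent from genome ", r$species)
    chrom_seq <- g$sequences[[r$chrom]]
    if (r$end > nchar(chrom_seq) || r$start < 0)
      stop("junction ", r$feature_id, " outside genome of ", r$species)
    first2 <- subseq0(chrom_seq, r$start, r$start + 2L)
    last2 <- subseq0(chrom_seq, r$end - 2L, r$end)
    if (r$strand == "+") {
      donor <- first2; acceptor <- last2
    } else {
      donor <- revcomp(last2); acceptor <- revcomp(first2)
    }
    data.frame(junction_id = r$feature_id, species = r$species,
               donor = donor, acceptor = acceptor,
               label = suppressWarnings(classify_canonicity(donor, acceptor)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  per <- split(out, out$junction_id)
  flags <- lapply(per, function(d) {
    present <- d$label[d$label != "missing"]
    change <- length(unique(present)) > 1 && sum(d$label != "missing") >= 2
    canon_here <- d$label == "canonical" &
      vapply(seq_len(nrow(d)), function(k) {
        others <- d$label[-k]
        all(others[others != "missing"] == "noncanonical") &&
          any(others != "missing")
      }, logical(1))
    data.frame(junction_id = d$junction_id, species = d$species,
               change = change, canonical_only_here = canon_here,
               stringsAsFactors = FALSE)
  })
  fl <- do.call(rbind, flags)
  out <- merge(out, fl, by = c("junction_id", "species"), sort = FALSE)
  out <- out[order(out$junction_id, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

junction_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = ":")
}
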