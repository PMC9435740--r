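# ORF prediction from transcript cDNA, in-silico tryptic digestion, and
# peptide novelty against a reference proteome (with I/L equivalence, the
# two residues being mass-indistinguishable in standard MS searches).

#' Spliced cDNA sequence of a transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements on
#' the minus strand, yielding the mature (unspliced-intron-free) sense
#' sequence.
#'
#' @param ts `transcript_set`
#' @param transcript_id transcript
#' @param genome `genome_set`
#' @return character cDNA sequence
#' @export
transcript_sequence <- function(ts, transcript_id, genome) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  if (nrow(tr) != 1) stop("unknown transcript: ", transcript_id)
  chrom_seq <- genome$sequences[[tr$chrom]]
  if (is.null(chrom_seq)) stop("chromosome absent: ", tr$chrom)
  e <- transcript_exons(ts, transcript_id)
  s <- paste(substring(chrom_seq, e$start + 1L, e$end), collapse = "")
  if (tr$strand == "-") s <- revcomp(s)
  s
}

translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  sub("\\*$", "", paste(aa, collapse = ""))
}

#' Predict the ORF of a transcript sequence
#'
#' Longest sense-strand open reading frame starting at ATG and ending at
#' the first in-frame stop codon; when no in-frame stop exists before the
#' transcript end the ORF is reported 3'-incomplete. Ties on protein
#' length are broken by the 5'-most start. Returns NULL when no ORF of at
#' least `min_aa` residues exists.
#'
#' @param seq cDNA sequence (A/C/G/T/N)
#' @param min_aa minimum protein length in residues (default 50)
#' @return NULL or a list: `cds_start`, `cds_end` (0-based half-open,
#'   transcript coordinates; stop codon included when complete),
#'   `protein`, `complete` (has in-frame stop)
#' @export
predict_orf <- function(seq, min_aa = 50L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(NULL)
  best <- NULL
  for (s in as.integer(starts)) {
    # codons from s (1-based) to first stop
    len_nt <- n - s + 1L
    n_codon <- len_nt %/% 3L
    if (n_codon < 1) next
    codons <- substring(seq, s + 3 * (0:(n_codon - 1)), s + 3 * (0:(n_codon - 1)) + 2)
    stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(stop_idx)) {
      aa_len <- stop_idx[1] - 1L
      complete <- TRUE
      cds_end <- s - 1L + 3L * stop_idx[1]          # includes stop codon
    } else {
      aa_len <- n_codon
      complete <- FALSE
      cds_end <- s - 1L + 3L * n_codon
    }
    if (aa_len < min_aa) next
    if (is.null(best) || aa_len > best$aa_len) {
      cds <- substr(seq, s, cds_end)
      best <- list(cds_start = s - 1L, cds_end = cds_end,
                   protein = translate_cds(cds),
                   complete = complete, aa_len = aa_len)
    }
  }
  if (is.null(best)) return(NULL)
  best$aa_len <- NULL
  best
}

#' Genomic CDS intervals of a predicted ORF
#'
#' Maps the ORF's transcript-coordinate CDS back onto the genome through
#' the exon chain.
#'
#' @param ts `transcript_set`
#' @param transcript_id transcript
#' @param orf result of [predict_orf()] for that transcript's sequence
#' @return data.frame of genomic intervals (`start`, `end`)
#' @export
orf_genomic_cds <- function(ts, transcript_id, orf) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  e <- transcript_exons(ts, transcript_id)
  lens <- e$end - e$start
  if (tr$strand == "-") { e <- e[rev(seq_len(nrow(e))), ]; lens <- rev(lens) }
  offs <- cumsum(c(0, lens))[seq_len(nrow(e))]
  out <- list()
  for (i in seq_len(nrow(e))) {
    a <- max(orf$cds_start, offs[i]); b <- min(orf$cds_end, offs[i] + lens[i])
    if (a >= b) next
    if (tr$strand == "+") {
      out[[length(out) + 1L]] <- c(e$start[i] + (a - offs[i]),
                                   e$start[i] + (b - offs[i]))
    } else {
      out[[length(out) + 1L]] <- c(e$end[i] - (b - offs[i]),
                                   e$end[i] - (a - offs[i]))
    }
  }
  m <- do.call(rbind, out)
  d <- data.frame(start = m[, 1], end = m[, 2])
  d[order(d$start), , drop = FALSE]
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, emits all
#' fragments with at most `missed_max` internal (missed) cleavage sites
#' and length within \[`len_min`, `len_max`\], deduplicated per protein.
#'
#' @param protein amino-acid string
#' @param missed_max maximum missed cleavages (default 2)
#' @param len_min,len_max peptide length bounds (defaults 7 and 40)
#' @return data.frame `peptide`, `missed` (minimum missed-cleavage count
#'   over occurrences); zero rows for an empty protein
#' @export
digest_tryptic <- function(protein, missed_max = 2L, len_min = 7L,
                           len_max = 40L) {
  empty <- data.frame(peptide = character(0), missed = integer(0))
  if (is.na(protein) || nchar(protein) == 0) return(empty)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  # cleavage after position i
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)
  bounds <- sort(unique(bounds))
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  res <- list()
  for (i in seq_len(nrow(segs))) {
    for (m in 0:missed_max) {
      j <- i + m
      if (j > nrow(segs)) break
      s <- segs$start[i] + 1L; e <- segs$end[j]
      len <- e - s + 1L
      if (len < len_min || len > len_max) next
      res[[length(res) + 1L]] <- data.frame(
        peptide = substr(protein, s, e), missed = m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  d <- do.call(rbind, res)
  d <- d[order(d$peptide, d$missed), ]
  d <- d[!duplicated(d$peptide), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Classify peptide novelty against a reference proteome
#'
#' A peptide is `annotated` iff it occurs as a substring of any reference
#' protein, with isoleucine and leucine treated as equivalent (both are
#' canonicalized to L before matching); otherwise `novel`.
#'
#' @param peptides character vector
#' @param proteome character vector of reference protein sequences (e.g.
#'   from [read_proteome()])
#' @param il_equivalence collapse I and L before matching (default TRUE)
#' @return character vector `"annotated"`/`"novel"`
#' @export
classify_peptide_novelty <- function(peptides, proteome,
                                     il_equivalence = TRUE) {
  canon <- function(x) if (il_equivalence) gsub("I", "L", x, fixed = TRUE) else x
  hay <- paste(canon(toupper(proteome)), collapse = "|")
  needles <- canon(toupper(peptides))
  unname(ifelse(vapply(needles, function(p) grepl(p, hay, fixed = TRUE),
                       logical(1)),
                "annotated", "novel"))
}

#' Read a proteome FASTA
#' @param path FASTA file
#' @return named character vector of protein sequences
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  v <- as.character(aa)
  names(v) <- sub("\\s.*$", "", names(aa))
  v
}

#' Write a protein database FASTA
#' @param proteins named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_proteome <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Per-gene novel-peptide flags
#'
#' For each gene, digests the ORFs of its transcripts and reports whether
#' at least one resulting peptide is novel against the reference proteome.
#'
#' @param proteins named character vector transcript -> protein
#' @param gene_of named transcript -> gene map
#' @param proteome reference proteome sequences
#' @param ... passed to [digest_tryptic()]
#' @return data.frame `gene_id`, `n_peptides`, `n_novel`, `has_novel`
#' @export
gene_peptide_novelty <- function(proteins, gene_of, proteome, ...) {
  genes <- sort(unique(unname(gene_of[names(proteins)])))
  out <- lapply(genes, function(g) {
    txs <- names(proteins)[gene_of[names(proteins)] == g]
    peps <- unique(unlist(lapply(proteins[txs], function(p)
      digest_tryptic(p, ...)$peptide)))
    if (length(peps) == 0)
      return(data.frame(gene_id = g, n_peptides = 0L, n_novel = 0L,
                        has_novel = FALSE))
    nov <- classify_peptide_novelty(peps, proteome)
    data.frame(gene_id = g, n_peptides = length(peps),
               n_novel = sum(nov == "novel"), has_novel = any(nov == "novel"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare ordered protein-domain combinations
#'
#' `novel_combination` iff the query ORF's ordered domain-label sequence
#' appears in no reference ORF; an empty combination matches reference
#' ORFs that also carry no domains.
#'
#' @param query_domains character vector of ordered domain strings (labels
#'   joined by "+"; "" = no domains)
#' @param reference_domains character vector of reference combinations
#' @return character vector `"known_combination"`/`"novel_combination"`
#' @export
compare_domain_combinations <- function(query_domains, reference_domains) {
  ifelse(query_domains %in% reference_domains,
         "known_combination", "novel_combination")
}
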