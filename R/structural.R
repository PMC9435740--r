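# Structural classification of transcript models against a reference
# annotation, following the SQANTI-style category scheme: FSM, ISM, NIC,
# NNC, FUSION, ANTISENSE, GENIC_INTRONIC, INTERGENIC. FSM/ISM count as
# "known", everything else as "novel".

STRUCTURAL_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC", "FUSION",
                           "ANTISENSE", "GENIC_INTRONIC", "INTERGENIC")

chain_string <- function(introns) {
  paste(sprintf("%d-%d", introns$start, introns$end), collapse = ";")
}

# index of a reference transcript_set used repeatedly during classification
ref_index <- function(ref) {
  tr <- ref$transcripts
  chains <- lapply(tr$transcript_id, function(id) transcript_introns(ref, id))
  names(chains) <- tr$transcript_id
  ex <- merge(ref$exons, tr[c("transcript_id", "gene_id", "chrom", "strand")],
              by = "transcript_id")
  gene_span <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  junc <- do.call(rbind, lapply(tr$transcript_id, function(id) {
    ic <- chains[[id]]
    if (nrow(ic) == 0) return(NULL)
    data.frame(chrom = tr$chrom[tr$transcript_id == id],
               strand = tr$strand[tr$transcript_id == id],
               start = ic$start, end = ic$end,
               gene_id = tr$gene_id[tr$transcript_id == id],
               stringsAsFactors = FALSE)
  }))
  list(transcripts = tr, chains = chains, exons = ex,
       gene_span = gene_span, junctions = junc)
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Classify a transcript against a reference annotation
#'
#' Assigns exactly one structural category by intron-chain comparison,
#' evaluated in priority order FSM, ISM, NIC, FUSION, NNC, ANTISENSE,
#' GENIC_INTRONIC, INTERGENIC. 5'/3' end positions are ignored: FSM is
#' intron-chain equality, ISM a consecutive sub-chain of one reference
#' transcript. NIC requires every splice site to be annotated on the same
#' chromosome and strand but the chain/combination to be new; NNC at least
#' one unannotated site. FUSION requires the chain to span two or more
#' non-overlapping reference genes with at least one junction in each.
#' Mono-exonic transcripts use the restricted rules: FSM when contained in
#' a same-strand reference exon, else ANTISENSE / GENIC_INTRONIC /
#' INTERGENIC (a genic mono-exon not contained in an exon falls to
#' GENIC_INTRONIC).
#'
#' @param ts `transcript_set` holding the query transcript
#' @param transcript_id query id
#' @param ref reference `transcript_set` on the same assembly, or a
#'   prebuilt index from the internal indexer
#' @return single category string
#' @export
classify_transcript <- function(ts, transcript_id, ref) {
  ri <- if (inherits(ref, "transcript_set")) ref_index(ref) else ref
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  if (nrow(tr) != 1) stop("unknown transcript: ", transcript_id)
  ex <- transcript_exons(ts, transcript_id)
  ic <- transcript_introns(ts, transcript_id)
  span <- c(min(ex$start), max(ex$end))

  same <- ri$transcripts$chrom == tr$chrom & ri$transcripts$strand == tr$strand
  same_ids <- ri$transcripts$transcript_id[same]
  rex_same <- ri$exons[ri$exons$chrom == tr$chrom & ri$exons$strand == tr$strand, ]
  rex_anti <- ri$exons[ri$exons$chrom == tr$chrom & ri$exons$strand != tr$strand, ]
  gspan <- ri$gene_span[ri$gene_span$chrom == tr$chrom, ]

  if (nrow(ic) == 0) {
    contained <- any(rex_same$start <= ex$start & rex_same$end >= ex$end)
    if (contained) return("FSM")
    anti_hit <- nrow(rex_anti) > 0 &&
      any(overlaps(ex$start, ex$end, rex_anti$start, rex_anti$end))
    same_ex_hit <- nrow(rex_same) > 0 &&
      any(overlaps(ex$start, ex$end, rex_same$start, rex_same$end))
    same_gene <- any(gspan$strand == tr$strand &
                       overlaps(span[1], span[2], gspan$start, gspan$end))
    if (anti_hit && !same_ex_hit && !same_gene) return("ANTISENSE")
    if (same_ex_hit || same_gene) return("GENIC_INTRONIC")
    return("INTERGENIC")
  }

  key <- chain_string(ic)
  ref_keys <- vapply(same_ids, function(id) chain_string(ri$chains[[id]]),
                     character(1))
  if (any(ref_keys == key)) return("FSM")
  # consecutive sub-chain of one reference transcript
  is_sub <- any(vapply(same_ids, function(id) {
    rc <- ri$chains[[id]]
    n <- nrow(rc); m <- nrow(ic)
    if (m >= n || m == 0) return(FALSE)
    for (off in 0:(n - m)) {
      if (all(rc$start[(off + 1):(off + m)] == ic$start) &&
          all(rc$end[(off + 1):(off + m)] == ic$end)) return(TRUE)
    }
    FALSE
  }, logical(1)))
  if (is_sub) return("ISM")

  rj <- ri$junctions
  if (is.null(rj)) {
    rj <- data.frame(chrom = character(0), strand = character(0),
                     start = integer(0), end = integer(0))
  }
  rj <- rj[rj$chrom == tr$chrom & rj$strand == tr$strand, , drop = FALSE]
  known_start <- ic$start %in% rj$start
  known_end <- ic$end %in% rj$end
  if (all(known_start) && all(known_end)) return("NIC")

  # fusion: junctions hitting >=2 non-overlapping same-strand genes
  g_same <- gspan[gspan$strand == tr$strand, ]
  if (nrow(g_same) >= 2) {
    hit <- vapply(seq_len(nrow(g_same)), function(k) {
      any(overlaps(ic$start, ic$end, g_same$start[k], g_same$end[k]))
    }, logical(1))
    hits <- g_same[hit, , drop = FALSE]
    if (nrow(hits) >= 2) {
      disj <- !any(vapply(seq_len(nrow(hits) - 1), function(a) {
        any(overlaps(hits$start[a], hits$end[a],
                     hits$start[-seq_len(a)], hits$end[-seq_len(a)]))
      }, logical(1)))
      if (disj) return("FUSION")
    }
  }
  # NNC: novel site(s) in a transcript overlapping same-strand annotation
  same_ex_hit <- nrow(rex_same) > 0 &&
    any(vapply(seq_len(nrow(ex)), function(k) {
      any(overlaps(ex$start[k], ex$end[k], rex_same$start, rex_same$end))
    }, logical(1)))
  if (same_ex_hit) return("NNC")
  anti_hit <- nrow(rex_anti) > 0 &&
    any(vapply(seq_len(nrow(ex)), function(k) {
      any(overlaps(ex$start[k], ex$end[k], rex_anti$start, rex_anti$end))
    }, logical(1)))
  in_gene <- any(gspan$strand == tr$strand &
                   overlaps(span[1], span[2], gspan$start, gspan$end))
  if (anti_hit && !in_gene) return("ANTISENSE")
  if (in_gene) return("GENIC_INTRONIC")
  if (anti_hit) return("ANTISENSE")
  "INTERGENIC"
}

#' Classify all transcripts of a set
#'
#' @param ts query `transcript_set`
#' @param ref reference `transcript_set` (same assembly)
#' @return data.frame with `transcript_id`, `gene_id`, `species_id`,
#'   `category`, `novelty` ("known" for FSM/ISM, else "novel")
#' @export
classify_transcripts <- function(ts, ref) {
  ri <- ref_index(ref)
  ids <- ts$transcripts$transcript_id
  cat <- vapply(ids, function(id) classify_transcript(ts, id, ri),
                character(1))
  data.frame(transcript_id = ids,
             gene_id = ts$transcripts$gene_id,
             species_id = ts$transcripts$species_id,
             category = unname(cat),
             novelty = ifelse(cat %in% c("FSM", "ISM"), "known", "novel"),
             stringsAsFactors = FALSE)
}

#' Classify junction novelty against a reference annotation
#'
#' A junction is "known" iff its exact intron interval appears in some
#' reference transcript on the same chromosome and strand. Junctions are
#' deduplicated across transcripts.
#'
#' @param ts query `transcript_set`
#' @param ref reference `transcript_set`
#' @return data.frame with one row per distinct junction: `chrom`,
#'   `strand`, `start`, `end`, `status`, `n_transcripts`
#' @export
classify_junctions <- function(ts, ref) {
  ri <- ref_index(ref)
  qs <- lapply(ts$transcripts$transcript_id, function(id) {
    ic <- transcript_introns(ts, id)
    if (nrow(ic) == 0) return(NULL)
    tr <- ts$transcripts[ts$transcripts$transcript_id == id, ]
    data.frame(chrom = tr$chrom, strand = tr$strand,
               start = ic$start, end = ic$end, stringsAsFactors = FALSE)
  })
  q <- do.call(rbind, qs)
  if (is.null(q))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      status = character(0), n_transcripts = integer(0)))
  key <- junction_key(q$chrom, q$strand, q$start, q$end)
  tab <- table(key)
  q <- q[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  rj <- ri$junctions
  rkey <- if (is.null(rj)) character(0) else
    junction_key(rj$chrom, rj$strand, rj$start, rj$end)
  q$status <- ifelse(key %in% rkey, "known", "novel")
  q$n_transcripts <- as.integer(tab[key])
  q <- q[order(q$chrom, q$strand, q$start, q$end), , drop = FALSE]
  rownames(q) <- NULL
  q
}

#' Summarise novelty proportions per species
#'
#' @param categories output of [classify_transcripts()] (possibly several
#'   species row-bound)
#' @param junctions optional output of [classify_junctions()]; junction
#'   fractions are reported overall when supplied
#' @return data.frame per species with transcript counts and known/novel
#'   fractions (fractions sum to 1)
#' @export
novelty_summary <- function(categories, junctions = NULL) {
  stopifnot(nrow(categories) >= 1)
  per <- lapply(split(categories, categories$species_id), function(d) {
    data.frame(species_id = d$species_id[1],
               n_transcripts = nrow(d),
               frac_known = mean(d$novelty == "known"),
               frac_novel = mean(d$novelty == "novel"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  if (!is.null(junctions) && nrow(junctions) > 0) {
    out$frac_junctions_known <- mean(junctions$status == "known")
    out$frac_junctions_novel <- mean(junctions$status == "novel")
  }
  out
}
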