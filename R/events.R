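# Local alternative-splicing event detection between the isoforms of one
# gene: skipped exons (SE), retained introns (RI), alternative 5'/3' splice
# sites (A5SS/A3SS, named in transcription orientation), and mutually
# exclusive exons (MEX). Events are reported at gene level, deduplicated by
# (class, defining intervals).

AS_CLASSES <- c("SE", "RI", "A5SS", "A3SS", "MEX")

# side = "start" or "end": which genomic boundary differs between the two
# junctions; maps to donor (5') or acceptor (3') by strand.
alt_ss_class <- function(side, strand) {
  if ((side == "start" && strand == "+") || (side == "end" && strand == "-"))
    "A5SS" else "A3SS"
}

event_row <- function(gene_id, class, chrom, strand, iv1, iv2,
                      inclusion, exclusion) {
  data.frame(gene_id = gene_id, event_class = class, chrom = chrom,
             strand = strand,
             start1 = iv1[1], end1 = iv1[2],
             start2 = if (is.null(iv2)) NA_integer_ else iv2[1],
             end2 = if (is.null(iv2)) NA_integer_ else iv2[2],
             inclusion = inclusion, exclusion = exclusion,
             stringsAsFactors = FALSE)
}

#' Detect alternative-splicing events within a gene
#'
#' Pairwise comparison of the exon chains of all transcripts of one gene:
#' \itemize{
#' \item SE: transcript A carries exon e whose two flanking junctions'
#'   outer boundaries coincide with a single junction of B that splices
#'   directly across e. Defining interval: the skipped exon.
#' \item RI: A has one exon spanning exactly the region that B splits by an
#'   intron whose outer exon boundaries match A's exon ends. Defining
#'   interval: the retained intron.
#' \item A5SS/A3SS: two junctions share one genomic boundary and differ at
#'   the other, with the exons abutting the differing boundaries
#'   overlapping each other (so that the shift happens within exonic
#'   context rather than skipping a complete exon). The donor/acceptor
#'   naming follows transcription orientation.
#' \item MEX: two non-overlapping exons, each skippable against the same
#'   outer flanking junction boundaries, that never co-occur in any
#'   transcript of the gene.
#' }
#'
#' @param ts `transcript_set`
#' @param gene_id gene whose transcripts are compared
#' @return data.frame of deduplicated events with inclusion/exclusion
#'   transcript id sets (comma-separated); zero rows for single-isoform
#'   genes
#' @export
detect_as_events <- function(ts, gene_id) {
  tx <- ts$transcripts[ts$transcripts$gene_id == gene_id, , drop = FALSE]
  empty <- event_row("x", "x", "x", "+", c(0L, 0L), NULL, "", "")[0, ]
  if (nrow(tx) < 2) return(empty)
  if (length(unique(tx$strand)) > 1 || length(unique(tx$chrom)) > 1)
    stop("transcripts of gene ", gene_id, " disagree on chrom/strand")
  strand <- tx$strand[1]; chrom <- tx$chrom[1]
  ids <- tx$transcript_id
  exl <- lapply(ids, function(id) transcript_exons(ts, id))
  inl <- lapply(ids, function(id) transcript_introns(ts, id))
  names(exl) <- names(inl) <- ids

  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  for (a in ids) for (b in ids) {
    if (a == b) next
    ea <- exl[[a]]; ia <- inl[[a]]; ib <- inl[[b]]
    # SE: internal exon i of a, flanked by introns i-1 and i of a's chain
    if (nrow(ea) >= 3 && nrow(ib) >= 1) {
      for (i in 2:(nrow(ea) - 1)) {
        u <- c(ea$end[i - 1], ea$start[i])   # upstream intron of e
        d <- c(ea$end[i], ea$start[i + 1])   # downstream intron of e
        if (any(ib$start == u[1] & ib$end == d[2]))
          add(event_row(gene_id, "SE", chrom, strand,
                        c(ea$start[i], ea$end[i]), NULL, a, b))
      }
    }
    # RI: exon of a spans exactly two consecutive exons + intron of b
    eb <- exl[[b]]
    if (nrow(eb) >= 2) {
      for (j in seq_len(nrow(eb) - 1)) {
        x <- eb$start[j]; s <- eb$end[j]
        e2 <- eb$start[j + 1]; y <- eb$end[j + 1]
        if (any(ea$start == x & ea$end == y))
          add(event_row(gene_id, "RI", chrom, strand, c(s, e2), NULL, a, b))
      }
    }
    # alternative donor/acceptor: introns sharing one boundary
    if (nrow(ia) >= 1 && nrow(ib) >= 1) {
      for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
        sa <- ia$start[i]; ea_ <- ia$end[i]
        sb <- ib$start[j]; eb_ <- ib$end[j]
        if (sa == sb && ea_ != eb_) {
          # differing end boundary: exons downstream of the introns overlap?
          exa <- ea[ea$start == ea_, ]; exb <- eb[eb$start == eb_, ]
          if (nrow(exa) == 1 && nrow(exb) == 1 &&
              max(exa$start, exb$start) < min(exa$end, exb$end)) {
            cls <- alt_ss_class("end", strand)
            iv <- rbind(sort(c(sa, ea_)), sort(c(sb, eb_)))
            iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
            incl <- if (ea_ < eb_) a else b   # shorter intron = inclusion
            excl <- if (ea_ < eb_) b else a
            add(event_row(gene_id, cls, chrom, strand, iv[1, ], iv[2, ],
                          incl, excl))
          }
        }
        if (ea_ == eb_ && sa != sb) {
          exa <- ea[ea$end == sa, ]; exb <- eb[eb$end == sb, ]
          if (nrow(exa) == 1 && nrow(exb) == 1 &&
              max(exa$start, exb$start) < min(exa$end, exb$end)) {
            cls <- alt_ss_class("start", strand)
            iv <- rbind(sort(c(sa, ea_)), sort(c(sb, eb_)))
            iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
            incl <- if (sa > sb) a else b
            excl <- if (sa > sb) b else a
            add(event_row(gene_id, cls, chrom, strand, iv[1, ], iv[2, ],
                          incl, excl))
          }
        }
      }
    }
  }

  # MEX: cassette contexts (outer donor boundary s, exon, outer acceptor e)
  ctx <- list()
  for (a in ids) {
    ea <- exl[[a]]
    if (nrow(ea) < 3) next
    for (i in 2:(nrow(ea) - 1)) {
      ctx[[length(ctx) + 1L]] <- list(
        s = ea$end[i - 1], e = ea$start[i + 1],
        exon = c(ea$start[i], ea$end[i]), tx = a)
    }
  }
  if (length(ctx) >= 2) {
    # transcripts containing a given exact exon
    has_exon <- function(tx_id, exon) {
      e <- exl[[tx_id]]
      any(e$start == exon[1] & e$end == exon[2])
    }
    for (i in seq_along(ctx)) for (j in seq_along(ctx)) {
      if (i >= j) next
      c1 <- ctx[[i]]; c2 <- ctx[[j]]
      if (c1$s != c2$s || c1$e != c2$e) next
      ex1 <- c1$exon; ex2 <- c2$exon
      if (identical(ex1, ex2)) next
      if (max(ex1[1], ex2[1]) < min(ex1[2], ex2[2])) next  # overlapping
      co <- any(vapply(ids, function(t)
        has_exon(t, ex1) && has_exon(t, ex2), logical(1)))
      if (co) next
      ord <- if (ex1[1] < ex2[1]) list(ex1, ex2) else list(ex2, ex1)
      incl <- paste(sort(unique(ids[vapply(ids, has_exon, logical(1),
                                           exon = ord[[1]])])), collapse = ",")
      excl <- paste(sort(unique(ids[vapply(ids, has_exon, logical(1),
                                           exon = ord[[2]])])), collapse = ",")
      add(event_row(gene_id, "MEX", chrom, strand, ord[[1]], ord[[2]],
                    incl, excl))
    }
  }

  if (length(rows) == 0) return(empty)
  ev <- do.call(rbind, rows)
  key <- with(ev, paste(event_class, start1, end1, start2, end2))
  agg <- lapply(split(seq_len(nrow(ev)), key), function(ix) {
    d <- ev[ix, , drop = FALSE]
    d$inclusion[1] <- paste(sort(unique(unlist(strsplit(d$inclusion, ",")))),
                            collapse = ",")
    d$exclusion[1] <- paste(sort(unique(unlist(strsplit(d$exclusion, ",")))),
                            collapse = ",")
    d[1, , drop = FALSE]
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$event_class, out$start1, out$end1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect AS events for every multi-isoform gene of a set
#'
#' @param ts `transcript_set`
#' @return row-bound event table across genes
#' @export
detect_as_events_all <- function(ts) {
  genes <- unique(ts$transcripts$gene_id)
  do.call(rbind, lapply(sort(genes), function(g) detect_as_events(ts, g)))
}
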