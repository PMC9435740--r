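# Cross-species orthology: conserved vs species-specific exon calls from
# precomputed liftOver/Liftoff-style mapping tables, flattening of gene
# models into orthologous exonic parts, exon placement relative to the ORF,
# and repeat-element overlap annotation.

#' Call conserved and species-specific exons
#'
#' Applies the mapping-based decision rule: an exon is `conserved` when it
#' maps successfully (status MAPPED) in all four non-focal assemblies;
#' `species_specific` when the mapping failed in every other assembly AND
#' the alignment coverage is strictly below `coverage_max` (default 0.5) in
#' all four of them; anything else — including a failed mapping with
#' missing coverage — is `unresolved`.
#'
#' @param omap `orthology_map` (rows with `feature_type == "exon"`); each
#'   exon must carry one row per non-focal species
#' @param focal_of named character vector mapping `feature_id` to its focal
#'   (origin) species
#' @param coverage_max species-specific requires coverage < this value in
#'   every other assembly
#' @return data.frame: `exon_id`, `focal_species`, `status`
#' @export
call_exon_conservation <- function(omap, focal_of, coverage_max = 0.5) {
  ex <- omap[omap$feature_type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("no exon features in orthology map")
  out <- lapply(split(ex, ex$feature_id), function(d) {
    fid <- d$feature_id[1]
    focal <- focal_of[[fid]]
    if (is.null(focal)) stop("no focal species for exon ", fid)
    d <- d[d$species != focal, , drop = FALSE]
    status <- if (nrow(d) == 0) {
      "unresolved"
    } else if (all(d$status == "MAPPED")) {
      "conserved"
    } else if (all(d$status == "UNMAPPED")) {
      if (any(is.na(d$coverage))) {
        warning("missing coverage for failed mapping of exon ", fid)
        "unresolved"
      } else if (all(d$coverage < coverage_max)) {
        "species_specific"
      } else "unresolved"
    } else "unresolved"
    data.frame(exon_id = fid, focal_species = focal, status = status,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$exon_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify exon placement relative to coding sequence
#'
#' Given the genomic CDS intervals of every transcript containing the exon:
#' `full_UTR` when the exon never intersects the CDS, `CDS_only` when it is
#' contained in the CDS of every containing transcript, else `partial_UTR`.
#'
#' @param exon length-2 numeric (start, end), 0-based half-open
#' @param cds_list list of per-transcript CDS interval data.frames with
#'   columns `start`, `end` (genomic, possibly several rows when the CDS
#'   spans introns); an empty list yields `"missing"`
#' @return single label
#' @export
classify_exon_placement <- function(exon, cds_list) {
  if (length(cds_list) == 0) return("missing")
  inter <- vapply(cds_list, function(cds) {
    if (is.null(cds) || nrow(cds) == 0) return(0)
    sum(pmax(0, pmin(exon[2], cds$end) - pmax(exon[1], cds$start)))
  }, numeric(1))
  len <- exon[2] - exon[1]
  if (all(inter == 0)) return("full_UTR")
  if (all(inter == len)) return("CDS_only")
  "partial_UTR"
}

#' Flatten a gene into exonic parts
#'
#' Splits the union of a gene's exons at every distinct exon boundary,
#' producing disjoint parts that tile the exon union; each part is
#' annotated with the set of transcripts whose exons cover it. Parts are
#' indexed in genomic order.
#'
#' @param ts `transcript_set`
#' @param gene_id gene to flatten
#' @return data.frame: `gene_id`, `part_index`, `start`, `end`,
#'   `transcripts` (comma-separated ids)
#' @export
flatten_exonic_parts <- function(ts, gene_id) {
  tx <- ts$transcripts[ts$transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(tx) == 0) stop("unknown gene: ", gene_id)
  if (length(unique(tx$strand)) > 1)
    stop("transcripts on both strands in gene ", gene_id)
  ex <- ts$exons[ts$exons$transcript_id %in% tx$transcript_id, , drop = FALSE]
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)  # 1-based closed
  parts <- IRanges::disjoin(ir)
  ov <- IRanges::findOverlaps(parts, ir)
  memb <- split(ex$transcript_id[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  membership <- vapply(seq_along(parts), function(i) {
    m <- memb[[as.character(i)]]
    paste(sort(unique(m)), collapse = ",")
  }, character(1))
  data.frame(gene_id = gene_id,
             part_index = seq_along(parts),
             start = IRanges::start(parts) - 1L,
             end = IRanges::end(parts),
             transcripts = membership,
             stringsAsFactors = FALSE)
}

#' Flatten every gene of a transcript set
#' @param ts `transcript_set`
#' @return row-bound exonic part table
#' @export
flatten_exonic_parts_all <- function(ts) {
  genes <- sort(unique(ts$transcripts$gene_id))
  do.call(rbind, lapply(genes, function(g) flatten_exonic_parts(ts, g)))
}

#' Annotate exons with repeat-element overlap
#'
#' Flags each exon with the repeat families it overlaps, and (optionally)
#' tests enrichment of a family's overlap in a focal exon set against a
#' background set with a two-sided Fisher test.
#'
#' @param exons data.frame with `exon_id`, `chrom`, `start`, `end`
#' @param repeats repeat table from [read_repeats()], or NULL (flags absent)
#' @param focal_ids optional exon ids forming the focal set; when supplied
#'   together with `family`, an [fisher_or_hypergeometric()] enrichment of
#'   family overlap in focal vs the remaining exons is attached
#' @param family repeat family to test (e.g. "Alu")
#' @return list with `overlaps` (per exon: `exon_id`, `families`,
#'   `any_overlap`) and `enrichment` (NULL unless requested)
#' @export
annotate_repeats <- function(exons, repeats, focal_ids = NULL, family = NULL) {
  if (is.null(repeats)) {
    ov <- data.frame(exon_id = exons$exon_id, families = NA_character_,
                     any_overlap = NA, stringsAsFactors = FALSE)
    return(list(overlaps = ov, enrichment = NULL))
  }
  fam <- vapply(seq_len(nrow(exons)), function(i) {
    r <- repeats[repeats$chrom == exons$chrom[i] &
                   repeats$start < exons$end[i] &
                   exons$start[i] < repeats$end, , drop = FALSE]
    paste(sort(unique(r$family)), collapse = ",")
  }, character(1))
  ov <- data.frame(exon_id = exons$exon_id, families = fam,
                   any_overlap = fam != "", stringsAsFactors = FALSE)
  enr <- NULL
  if (!is.null(focal_ids) && !is.null(family)) {
    hit <- vapply(strsplit(ov$families, ","), function(f) family %in% f,
                  logical(1))
    focal <- ov$exon_id %in% focal_ids
    a <- sum(focal & hit); b <- sum(focal & !hit)
    c_ <- sum(!focal & hit); d <- sum(!focal & !hit)
    enr <- fisher_or_hypergeometric(a, b, c_, d, mode = "fisher")
  }
  list(overlaps = ov, enrichment = enr)
}
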