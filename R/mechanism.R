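# Mechanisms behind species-specific transcript expression gains: does the
# isoform rely on a junction used in no other species, which AS class
# distinguishes it, and is it driven by a splice site that is canonical
# only in the species expressing it?

#' Annotate the gain mechanism of species-specific transcripts
#'
#' For each species-specific transcript (shared-frame coordinates), a
#' junction is "distinguishing" when it occurs in no other species'
#' expressed transcript set. The transcript is `canonicity_driven` when at
#' least one distinguishing junction is canonical only in the expressing
#' species (per [detect_canonicity_changes()]), and `conserved_canonicity`
#' when every one of its junctions is canonical in all species where the
#' orthologous position exists. The dominant AS class is the most frequent
#' event class among the gene's events involving the transcript.
#'
#' @param ss data.frame `transcript_id`, `species` from
#'   [call_species_specific()]
#' @param ts shared-frame `transcript_set` (all projected models)
#' @param profiles presence matrix from [build_presence_matrix()] defining
#'   each species' expressed set
#' @param canonicity output of [detect_canonicity_changes()]; junction ids
#'   in the `jx|chrom|strand|start|end` convention
#' @param events optional AS event table from [detect_as_events_all()]
#' @return data.frame per species-specific transcript: `transcript_id`,
#'   `species`, `uses_species_specific_junction`, `dominant_as_class`,
#'   `canonicity_driven`, `conserved_canonicity`
#' @export
assign_gain_mechanism <- function(ss, ts, profiles, canonicity,
                                  events = NULL) {
  species <- setdiff(names(profiles), c("transcript_id", "ambiguous"))
  tx_junc <- function(id) {
    tr <- ts$transcripts[ts$transcripts$transcript_id == id, ]
    if (nrow(tr) != 1) stop("transcript absent from model set: ", id)
    ic <- transcript_introns(ts, id)
    if (nrow(ic) == 0) return(character(0))
    sprintf("jx|%s|%s|%d|%d", tr$chrom, tr$strand, ic$start, ic$end)
  }
  # expressed junction set per species
  expr_junc <- lapply(stats::setNames(species, species), function(sp) {
    txs <- profiles$transcript_id[!is.na(profiles[[sp]]) &
                                    profiles[[sp]] == 1]
    unique(unlist(lapply(txs, tx_junc)))
  })
  canon_only <- canonicity[canonicity$canonical_only_here, , drop = FALSE]
  all_canon <- vapply(split(canonicity$label, canonicity$junction_id),
                      function(l) all(l[l != "missing"] == "canonical"),
                      logical(1))
  res <- lapply(seq_len(nrow(ss)), function(i) {
    id <- ss$transcript_id[i]; sp <- ss$species[i]
    jx <- tx_junc(id)
    other <- unique(unlist(expr_junc[setdiff(species, sp)]))
    disting <- setdiff(jx, other)
    canon_driver <- any(disting %in%
                          canon_only$junction_id[canon_only$species == sp])
    conserved <- length(jx) > 0 &&
      all(jx %in% names(all_canon)[all_canon])
    dom <- NA_character_
    if (!is.null(events) && nrow(events) > 0) {
      inv <- vapply(seq_len(nrow(events)), function(k)
        id %in% strsplit(events$inclusion[k], ",")[[1]] ||
          id %in% strsplit(events$exclusion[k], ",")[[1]], logical(1))
      if (any(inv)) {
        tab <- sort(table(events$event_class[inv]), decreasing = TRUE)
        dom <- names(tab)[1]
      }
    }
    data.frame(transcript_id = id, species = sp,
               uses_species_specific_junction = length(disting) > 0,
               dominant_as_class = dom,
               canonicity_driven = canon_driver,
               conserved_canonicity = conserved,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), species = character(0),
                      uses_species_specific_junction = logical(0),
                      dominant_as_class = character(0),
                      canonicity_driven = logical(0),
                      conserved_canonicity = logical(0))
  out
}
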