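# End-to-end planted-event recovery: run the full pipeline on a synthetic
# fixture and score every planted event class against the truth ledger.
# Sensitivity is the fraction of planted events recovered; empirical FDR
# counts calls that hit no planted signal. For usage-based calls (DIU,
# dominance) the false-positive unit is the (gene, species) pair, because a
# planted shift on one transcript necessarily moves the usage of its
# sibling transcripts and parts within the same gene.

#' Run the full recovery analysis on a synthetic fixture
#'
#' Generates the fixture, draws the presence-analysis expression (default
#' replicate count) and a usage-analysis expression set (`usage_replicates`
#' per species), runs every pipeline stage, and scores recovery of each
#' planted class.
#'
#' @param config a [sim_config()]
#' @param usage_replicates replicates for DIU/DEU/dominance analyses
#' @param alpha FDR level for usage tests
#' @return list of metrics (sensitivities, FDRs, call counts) plus the
#'   intermediate objects in `$detail`
#' @export
run_recovery <- function(config, usage_replicates = 6L, alpha = 0.05) {
  ref <- simulate_reference(config)
  em3 <- simulate_expression(ref, config)
  em6 <- simulate_expression(ref, config, replicates = usage_replicates,
                             seed_offset = 2000L)
  truth <- ref$truth
  gene_of <- ref$gene_of
  metrics <- list()
  planted_genes <- unique(truth$gene_id)

  ## species-specific transcript gains (strict presence criterion)
  prof <- build_presence_matrix(em3, "strict")
  ss <- call_species_specific(prof)
  t_gain <- truth[truth$class == "gain", ]
  t_ssx <- truth[truth$class %in% c("gain", "exon_gain"), ]
  key <- function(d) paste(d$transcript_id, d$species)
  metrics$gain_sensitivity <- mean(key(t_gain) %in% key(ss))
  metrics$gain_fdr <- if (nrow(ss)) 1 - mean(key(ss) %in% key(t_ssx)) else 0
  metrics$n_species_specific <- nrow(ss)

  ## canonicity-driven mechanism
  cc <- detect_canonicity_changes(ref$orthology, ref$genomes)
  events <- detect_as_events_all(ref$models)
  mech <- assign_gain_mechanism(ss, ref$models, prof, cc, events)
  t_canon <- t_gain[t_gain$mechanism == "canonicity", ]
  t_cons <- t_gain[t_gain$mechanism == "conserved", ]
  hit <- mech$canonicity_driven
  metrics$canonicity_sensitivity <-
    mean(key(t_canon) %in% key(mech[hit, , drop = FALSE]))
  metrics$canonicity_fdr <- if (any(hit))
    1 - mean(key(mech[hit, , drop = FALSE]) %in% key(t_canon)) else 0
  metrics$conserved_canonicity_rate <-
    mean(mech$conserved_canonicity[key(mech) %in% key(t_cons)])

  ## species-specific exons from the orthology map
  ex_ids <- ref$orthology$feature_id[ref$orthology$feature_type == "exon"]
  focal_of <- stats::setNames(rep("H", length(unique(ex_ids))),
                              unique(ex_ids))
  t_ex <- truth[truth$class == "exon_gain", ]
  focal_of[t_ex$feature] <- t_ex$species
  cons <- call_exon_conservation(ref$orthology, focal_of)
  called_ex <- cons[cons$status == "species_specific", ]
  ex_key <- function(d, id, sp) paste(d[[id]], d[[sp]])
  metrics$exon_sensitivity <-
    mean(paste(t_ex$feature, t_ex$species) %in%
           paste(called_ex$exon_id, called_ex$focal_species))
  metrics$exon_fdr <- if (nrow(called_ex))
    1 - mean(paste(called_ex$exon_id, called_ex$focal_species) %in%
               paste(t_ex$feature, t_ex$species)) else 0

  ## DIU on the usage-replicate draw
  iu <- compute_iu(em6$tpm, gene_of)
  gene_tpm <- rowsum(em6$tpm, gene_of[rownames(em6$tpm)])
  gexp <- gene_tpm[gene_of[rownames(em6$tpm)], , drop = FALSE]
  keep <- usage_expression_filter(em6$tpm, gexp, em6$samples)
  diu <- test_species_specific_usage(iu[keep, , drop = FALSE], em6$samples,
                                     alpha = alpha)
  called_diu <- diu[diu$call != "none", ]
  t_diu <- truth[truth$class == "diu", ]
  metrics$diu_sensitivity <-
    mean(paste(t_diu$transcript_id, t_diu$species, "up") %in%
           paste(called_diu$feature_id, called_diu$species, called_diu$call))
  fp_diu <- !(gene_of[called_diu$feature_id] %in% planted_genes)
  metrics$diu_fdr <- if (nrow(called_diu)) mean(fp_diu) else 0
  metrics$n_diu_calls <- nrow(called_diu)

  ## DEU on exonic parts
  parts <- flatten_exonic_parts_all(ref$models)
  pc <- derive_part_counts(parts, em6$counts, ref$tx_length)
  part_gene <- stats::setNames(parts$gene_id,
                               sprintf("%s:%d-%d", parts$gene_id,
                                       parts$start, parts$end))
  pu <- exonic_part_usage(pc, part_gene, em6$samples)
  deu <- test_species_specific_usage(pu, em6$samples, alpha = alpha)
  called_deu <- deu[deu$call != "none", ]
  t_deu <- truth[truth$class == "deu", ]
  metrics$deu_sensitivity <-
    mean(paste(t_deu$feature, t_deu$species, "up") %in%
           paste(called_deu$feature_id, called_deu$species,
                 called_deu$call))
  fp_deu <- !(part_gene[called_deu$feature_id] %in% planted_genes)
  metrics$deu_fdr <- if (nrow(called_deu)) mean(fp_deu) else 0
  metrics$n_deu_calls <- nrow(called_deu)

  ## dominant-isoform switches
  rd <- rank_dominance(iu, em6$tpm, gene_of, em6$samples,
                       orf_of = ref$proteins, domains_of = ref$domains)
  ns <- rd$records[!rd$records$shared_rank1, ]
  t_rs <- truth[truth$class == "rank_switch", ]
  usage_genes <- unique(truth$gene_id[truth$class %in%
                                        c("rank_switch", "diu", "deu")])
  metrics$rank_switch_sensitivity <- mean(t_rs$gene_id %in% ns$gene_id)
  metrics$rank_switch_fdr <- if (nrow(ns))
    mean(!ns$gene_id %in% usage_genes) else 0

  ## peptide novelty of unannotated genes
  pep <- gene_peptide_novelty(ref$proteins, gene_of, ref$proteome)
  t_ng <- truth[truth$class == "novel_gene", ]
  flagged <- pep$gene_id[pep$has_novel]
  metrics$peptide_sensitivity <- mean(t_ng$gene_id %in% flagged)
  metrics$peptide_fdr <- if (length(flagged))
    mean(!flagged %in% t_ng$gene_id) else 0

  ## structural classification on the human frame
  cls <- classify_transcripts(ref$annotations$H, ref$reference$H)
  t_nnc <- truth[truth$class == "nnc", ]
  nnc_cls <- cls$category[cls$transcript_id %in% t_nnc$transcript_id]
  ref_tx <- ref$reference$H$transcripts$transcript_id
  fsm_cls <- cls$category[cls$transcript_id %in% ref_tx]
  metrics$nnc_accuracy <- mean(nnc_cls == "NNC")
  metrics$fsm_accuracy <- mean(fsm_cls == "FSM")

  metrics$detail <- list(ref = ref, em3 = em3, em6 = em6, profiles = prof,
                         species_specific = ss, mechanism = mech,
                         conservation = cons, diu = diu, deu = deu,
                         dominance = rd, peptides = pep, classes = cls,
                         canonicity = cc)
  metrics
}

#' Null-fixture calibration
#'
#' Runs the species-specific gain calls and the DIU test on a fixture with
#' zero planted events; any call is a false positive.
#'
#' @param config a [sim_config()] with all planted counts 0
#' @param usage_replicates replicates for the usage draw
#' @param alpha FDR level
#' @return list: `n_species_specific`, `n_diu_calls`, `n_features_tested`
#' @export
run_null_calibration <- function(config, usage_replicates = 6L,
                                 alpha = 0.05) {
  ref <- simulate_reference(config)
  em3 <- simulate_expression(ref, config)
  em6 <- simulate_expression(ref, config, replicates = usage_replicates,
                             seed_offset = 2000L)
  prof <- build_presence_matrix(em3, "strict")
  ss <- call_species_specific(prof)
  iu <- compute_iu(em6$tpm, ref$gene_of)
  diu <- test_species_specific_usage(iu, em6$samples, alpha = alpha)
  list(n_species_specific = nrow(ss),
       n_diu_calls = sum(diu$call != "none"),
       n_features_tested = nrow(iu))
}
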