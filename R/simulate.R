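# Synthetic five-species fixture generator. Emulates the study design —
# five primate assemblies sharing projected transcript models, three (or
# more) RNA-seq replicates per species — with every analyzed event class
# planted and recorded in a machine-readable truth ledger: species-specific
# transcript expression gains (with or without a canonicity driver),
# species-specific exonizations with sub-threshold simulated alignment
# coverage, isoform-usage (DIU) and exonic-part (DEU) shifts, dominant-
# isoform switches, structurally novel (NNC) transcripts, and unannotated
# genes for peptide-novelty analysis. Genomes are kb-scale, one chromosome
# per gene neighborhood, diverged from one ancestral sequence by neutral
# substitutions that avoid splice-site dinucleotides; planted changes are
# the only canonicity-relevant differences. Simulated alignment coverage is
# drawn, not computed: the mapping table's contract is to exercise the
# decision rules downstream, not to model liftOver.

#' Simulation configuration
#'
#' Defaults reproduce the package's reference study conditions: 300 genes,
#' 5 species x 3 replicates, negative-binomial counts (dispersion 0.05),
#' and the planted-event census used by the recovery analyses (30
#' expression gains of which 10 canonicity-driven, 15 species-specific
#' exonizations, 30 DIU shifts of +0.4 usage, 40 DEU parts, 10 dominant-
#' isoform switches, 5 unannotated genes, 15 NNC transcripts).
#'
#' @param seed RNG seed (mandatory)
#' @param n_genes number of gene neighborhoods (one chromosome each)
#' @param replicates RNA-seq replicates per species
#' @param n_gain,n_gain_canonical expression gains (canonical subset uses a
#'   junction canonical only in the focal species)
#' @param n_exon_gain species-specific exonizations
#' @param n_diu,diu_delta usage-shift events and their effect size
#' @param n_deu,deu_delta exonic-part usage events and effect size
#' @param n_rank_switch dominant-isoform switches
#' @param n_novel_gene genes absent from reference annotation/proteome
#' @param n_nnc transcripts with a novel (unannotated) splice site
#' @param substitution_rate per-base neutral substitution probability per
#'   species
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion)
#' @param gene_mean_log,gene_mean_sd log-normal parameters of per-gene mean
#'   counts
#' @param batch_effect multiplicative log2 batch shift (0 = no batch
#'   structure)
#' @param alu_fraction fraction of planted exonizations tagged with an Alu
#'   repeat
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       n_genes = 300L,
                       replicates = 3L,
                       n_gain = 30L, n_gain_canonical = 10L,
                       n_exon_gain = 15L,
                       n_diu = 30L, diu_delta = 0.4,
                       n_deu = 40L, deu_delta = 0.4,
                       n_rank_switch = 10L,
                       n_novel_gene = 5L,
                       n_nnc = 15L,
                       substitution_rate = 0.002,
                       nb_dispersion = 0.05,
                       gene_mean_log = log(300), gene_mean_sd = 0.6,
                       batch_effect = 0,
                       alu_fraction = 0.8) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  if (cfg$n_gain_canonical > cfg$n_gain)
    stop("n_gain_canonical cannot exceed n_gain")
  if (cfg$diu_delta <= 0 || cfg$diu_delta >= 1)
    stop("diu_delta must be in (0,1)")
  if (cfg$nb_dispersion <= 0) stop("dispersion must be > 0")
  used <- cfg$n_gain + cfg$n_exon_gain + cfg$n_diu + cfg$n_deu +
    cfg$n_rank_switch + cfg$n_novel_gene + cfg$n_nnc
  if (used > cfg$n_genes)
    stop("planted events (", used, ") exceed n_genes (", cfg$n_genes, ")")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

set_bases <- function(seq, pos0, value) {
  # pos0: 0-based position of first base to replace
  substr(seq, pos0 + 1L, pos0 + nchar(value)) <- value
  seq
}

# plant canonical dinucleotides for intron [start, end) on given strand
plant_junction <- function(seq, start, end, strand) {
  if (strand == "+") {
    seq <- set_bases(seq, start, "GT")
    seq <- set_bases(seq, end - 2L, "AG")
  } else {
    seq <- set_bases(seq, start, "CT")   # acceptor (revcomp -> AG)
    seq <- set_bases(seq, end - 2L, "AC")  # donor (revcomp -> GT)
  }
  seq
}

# make the donor of intron [start, end) noncanonical (GT -> GA)
break_donor <- function(seq, start, end, strand) {
  if (strand == "+") set_bases(seq, start, "GA")
  else set_bases(seq, end - 2L, "TC")     # revcomp -> GA
}

#' Generate the five-species reference fixture
#'
#' Builds the shared gene models, the five genomes (ancestral sequence
#' plus per-species neutral substitutions plus planted changes), the
#' orthology map, repeat intervals, the reference proteome, the domain
#' table, and the truth ledger.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_reference`: `models` (full transcript_set,
#'   human frame), `annotations` (per-species transcript_set as observed),
#'   `reference` (per-species annotation minus novel/NNC content),
#'   `genomes` (named list of genome_set), `orthology` (orthology_map),
#'   `repeats` (per-species BED-like tables), `proteome`, `domains`
#'   (per-transcript ordered domain strings), `truth` (event ledger),
#'   `tx_length`, `gene_of`, `config`
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  # assign planted classes to disjoint gene indices
  idx <- seq_len(n)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  plan <- list(gain = take(config$n_gain),
               exon_gain = take(config$n_exon_gain),
               diu = take(config$n_diu),
               deu = take(config$n_deu),
               rank_switch = take(config$n_rank_switch),
               novel_gene = take(config$n_novel_gene),
               nnc = take(config$n_nnc))
  gain_canon <- plan$gain[seq_len(config$n_gain_canonical)]
  focal_pick <- function(k) sample(SPECIES5, k, replace = TRUE)
  focal <- list(gain = focal_pick(config$n_gain),
                exon_gain = focal_pick(config$n_exon_gain),
                diu = focal_pick(config$n_diu),
                deu = focal_pick(config$n_deu),
                rank_switch = focal_pick(config$n_rank_switch))

  exons_rows <- list(); tx_rows <- list()
  anc_seq <- character(n)
  chrom_of <- sprintf("chr%d", seq_len(n))
  gene_ids <- sprintf("g%03d", seq_len(n))
  truth <- list()
  gene_meta <- vector("list", n)
  # genome edits to apply later: list of (species, chrom, fun)
  edits <- list()
  orth_junc <- list(); orth_exon <- list()
  repeats <- stats::setNames(vector("list", length(SPECIES5)), SPECIES5)

  needs_plus <- sort(c(plan$gain, plan$exon_gain, plan$nnc))
  for (g in seq_len(n)) {
    gid <- gene_ids[g]; chrom <- chrom_of[g]
    strand <- if (g %in% needs_plus) "+" else sample(c("+", "-"), 1)
    n_e <- sample(4:6, 1)
    elen <- sample(seq(90, 201, by = 3), n_e, replace = TRUE)
    ilen <- sample(150:300, n_e - 1, replace = TRUE)
    flank <- 200L
    pos <- flank
    es <- integer(n_e); ee <- integer(n_e)
    for (i in seq_len(n_e)) {
      es[i] <- pos; ee[i] <- pos + elen[i]
      pos <- ee[i] + if (i < n_e) ilen[i] else 0L
    }
    clen <- pos + flank
    seq <- rand_dna(clen)
    # transcripts: t1 full, t2 skip exon 2, t3 skip exon 3 (if n_e >= 5)
    structs <- list(t1 = seq_len(n_e), t2 = setdiff(seq_len(n_e), 2L))
    if (n_e >= 5) structs$t3 <- setdiff(seq_len(n_e), 3L)
    extra <- list()
    gain_j <- nnc_j <- NULL
    if (g %in% plan$gain) {
      # gain transcript: exon2 truncated at +60, junction to exon 3 start
      gain_j <- c(es[2] + 60L, es[3])
      extra$tg <- list(keep = c(1L, 2L, 3:n_e), trunc2 = 60L)
    }
    if (g %in% plan$nnc) {
      nnc_j <- c(es[2] + 45L, es[3])
      extra$tn <- list(keep = c(1L, 2L, 3:n_e), trunc2 = 45L)
    }
    # exon table builder
    mk_exons <- function(keep, trunc2 = NULL) {
      s <- es[keep]; e <- ee[keep]
      if (!is.null(trunc2)) e[keep == 2L] <- es[2] + trunc2
      data.frame(start = s, end = e)
    }
    tx_list <- list()
    for (nm in names(structs))
      tx_list[[nm]] <- mk_exons(structs[[nm]])
    if (!is.null(extra$tg)) tx_list$tg <- mk_exons(extra$tg$keep, extra$tg$trunc2)
    if (!is.null(extra$tn)) tx_list$tn <- mk_exons(extra$tn$keep, extra$tn$trunc2)
    # plant canonical sites at every junction used by any transcript
    juncs <- unique(do.call(rbind, lapply(tx_list, function(e) {
      if (nrow(e) < 2) return(NULL)
      data.frame(start = e$end[-nrow(e)], end = e$start[-1])
    })))
    for (k in seq_len(nrow(juncs)))
      seq <- plant_junction(seq, juncs$start[k], juncs$end[k], strand)
    anc_seq[g] <- seq
    for (nm in names(tx_list)) {
      tid <- paste0(gid, ".", nm)
      tx_rows[[tid]] <- data.frame(
        transcript_id = tid, gene_id = gid, species_id = "ALL",
        chrom = chrom, strand = strand, stringsAsFactors = FALSE)
      exons_rows[[tid]] <- data.frame(
        transcript_id = tid, start = tx_list[[nm]]$start,
        end = tx_list[[nm]]$end, stringsAsFactors = FALSE)
    }
    gene_meta[[g]] <- list(gid = gid, chrom = chrom, strand = strand,
                           es = es, ee = ee, n_e = n_e,
                           tx = names(tx_list), gain_j = gain_j,
                           nnc_j = nnc_j)
    # orthology junction rows (same coordinates in all species)
    for (k in seq_len(nrow(juncs))) {
      jid <- sprintf("jx|%s|%s|%d|%d", chrom, strand,
                     juncs$start[k], juncs$end[k])
      orth_junc[[jid]] <- data.frame(
        feature_id = jid, feature_type = "junction", species = SPECIES5,
        status = "MAPPED", chrom = chrom, start = juncs$start[k],
        end = juncs$end[k], coverage = 1, strand = strand,
        stringsAsFactors = FALSE)
    }
    # canonicity-driven gains: break the gain junction's donor in the
    # four non-focal species
    if (g %in% gain_canon) {
      sp_f <- focal$gain[match(g, plan$gain)]
      for (sp in setdiff(SPECIES5, sp_f))
        edits[[length(edits) + 1L]] <- list(
          species = sp, chrom = chrom,
          fun = local({
            s0 <- gain_j[1]; e0 <- gain_j[2]; st <- strand
            function(x) break_donor(x, s0, e0, st)
          }))
    }
    # background conserved-exon orthology rows (focal frame H)
    for (i in seq_len(n_e)) {
      eid <- sprintf("ex|%s|%d|%d", chrom, es[i], ee[i])
      orth_exon[[eid]] <- data.frame(
        feature_id = eid, feature_type = "exon", species = SPECIES5,
        status = "MAPPED", chrom = chrom, start = es[i], end = ee[i],
        coverage = round(stats::runif(length(SPECIES5), 0.9, 1), 3),
        strand = strand, stringsAsFactors = FALSE)
    }
  }

  # planted exonizations: a new exon carved inside intron 1 of the focal
  # species (splice sites exist only there); no coordinate shifts
  for (m in seq_along(plan$exon_gain)) {
    g <- plan$exon_gain[m]; gm <- gene_meta[[g]]
    sp_f <- focal$exon_gain[m]
    ex_len <- 90L
    i_start <- gm$ee[1]; i_end <- gm$es[2]
    mstart <- i_start + ((i_end - i_start - ex_len) %/% 2L)
    mend <- mstart + ex_len
    # splice sites of the two sub-introns, focal genome only
    edits[[length(edits) + 1L]] <- list(
      species = sp_f, chrom = gm$chrom,
      fun = local({
        s1 <- i_start; a1 <- mstart; d2 <- mend; e2 <- i_end; st <- gm$strand
        function(x) {
          x <- plant_junction(x, s1, a1, st)
          plant_junction(x, d2, e2, st)
        }
      }))
    tid <- paste0(gm$gid, ".tx")
    tx_rows[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gm$gid, species_id = "ALL",
      chrom = gm$chrom, strand = gm$strand, stringsAsFactors = FALSE)
    exons_rows[[tid]] <- data.frame(
      transcript_id = tid,
      start = c(gm$es[1], mstart, gm$es[-1]),
      end = c(gm$ee[1], mend, gm$ee[-1]), stringsAsFactors = FALSE)
    eid <- sprintf("ex|%s|%d|%d", gm$chrom, mstart, mend)
    orth_exon[[eid]] <- data.frame(
      feature_id = eid, feature_type = "exon", species = SPECIES5,
      status = ifelse(SPECIES5 == sp_f, "MAPPED", "UNMAPPED"),
      chrom = gm$chrom, start = mstart, end = mend,
      coverage = ifelse(SPECIES5 == sp_f, 1,
                        round(stats::runif(length(SPECIES5), 0, 0.45), 3)),
      strand = gm$strand, stringsAsFactors = FALSE)
    alu <- stats::runif(1) < config$alu_fraction
    if (alu)
      repeats[[sp_f]] <- rbind(repeats[[sp_f]], data.frame(
        chrom = gm$chrom, start = mstart - 10L, end = mend + 10L,
        family = "Alu", score = 0L, strand = gm$strand,
        stringsAsFactors = FALSE))
    gene_meta[[g]]$exon_gain <- c(mstart, mend)
    gene_meta[[g]]$exon_gain_tx <- tid
    truth[[length(truth) + 1L]] <- data.frame(
      class = "exon_gain", gene_id = gm$gid, transcript_id = tid,
      feature = eid, species = sp_f,
      effect = NA_real_, mechanism = if (alu) "Alu" else "none",
      stringsAsFactors = FALSE)
  }

  # background repeats on every assembly (non-Alu, away from genes' exons)
  for (sp in SPECIES5) {
    bg <- do.call(rbind, lapply(sample(seq_len(n), min(40L, n)), function(g) {
      gm <- gene_meta[[g]]
      data.frame(chrom = gm$chrom, start = 5L, end = 80L,
                 family = sample(c("L1", "MIR"), 1), score = 0L,
                 strand = "+", stringsAsFactors = FALSE)
    }))
    repeats[[sp]] <- rbind(repeats[[sp]], bg)
  }

  # truth rows for gains / diu / deu / rank switches / novel genes / nnc
  for (m in seq_along(plan$gain)) {
    g <- plan$gain[m]; gm <- gene_meta[[g]]
    jid <- sprintf("jx|%s|%s|%d|%d", gm$chrom, gm$strand,
                   gm$gain_j[1], gm$gain_j[2])
    orth_junc[[jid]] <- data.frame(
      feature_id = jid, feature_type = "junction", species = SPECIES5,
      status = "MAPPED", chrom = gm$chrom, start = gm$gain_j[1],
      end = gm$gain_j[2], coverage = 1, strand = gm$strand,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      class = "gain", gene_id = gm$gid,
      transcript_id = paste0(gm$gid, ".tg"), feature = jid,
      species = focal$gain[m], effect = NA_real_,
      mechanism = if (g %in% gain_canon) "canonicity" else "conserved",
      stringsAsFactors = FALSE)
  }
  add_truth <- function(class, g, tx, feature, sp, effect, mech = "none") {
    truth[[length(truth) + 1L]] <<- data.frame(
      class = class, gene_id = gene_ids[g], transcript_id = tx,
      feature = feature, species = sp, effect = effect, mechanism = mech,
      stringsAsFactors = FALSE)
  }
  for (m in seq_along(plan$diu))
    add_truth("diu", plan$diu[m], paste0(gene_ids[plan$diu[m]], ".t2"),
              NA_character_, focal$diu[m], config$diu_delta)
  for (m in seq_along(plan$deu)) {
    g <- plan$deu[m]; gm <- gene_meta[[g]]
    part <- sprintf("%s:%d-%d", gm$gid, gm$es[2], gm$ee[2])
    add_truth("deu", g, paste0(gm$gid, ".t1"), part, focal$deu[m],
              config$deu_delta)
  }
  for (m in seq_along(plan$rank_switch))
    add_truth("rank_switch", plan$rank_switch[m],
              paste0(gene_ids[plan$rank_switch[m]], ".t2"), NA_character_,
              focal$rank_switch[m], NA_real_)
  for (g in plan$novel_gene)
    add_truth("novel_gene", g, NA_character_, NA_character_,
              NA_character_, NA_real_)
  for (g in plan$nnc) {
    gm <- gene_meta[[g]]
    add_truth("nnc", g, paste0(gm$gid, ".tn"),
              sprintf("jx|%s|%s|%d|%d", gm$chrom, gm$strand,
                      gm$nnc_j[1], gm$nnc_j[2]),
              NA_character_, NA_real_)
  }

  # species genomes: ancestral + neutral substitutions avoiding splice
  # dinucleotides, then planted edits
  oj <- do.call(rbind, orth_junc)
  protect <- new.env()
  for (g in seq_len(n)) {
    gm <- gene_meta[[g]]
    pp <- integer(0)
    jj <- oj[oj$chrom == gm$chrom, , drop = FALSE]
    pp <- c(pp, unlist(lapply(seq_len(nrow(jj)), function(k)
      c(jj$start[k], jj$start[k] + 1L, jj$end[k] - 2L, jj$end[k] - 1L))))
    if (!is.null(gm$exon_gain))
      pp <- c(pp, gm$exon_gain[1] - 2L, gm$exon_gain[1] - 1L,
              gm$exon_gain[2], gm$exon_gain[2] + 1L,
              gm$ee[1], gm$ee[1] + 1L, gm$es[2] - 2L, gm$es[2] - 1L)
    assign(gm$chrom, unique(pp), envir = protect)
  }
  genomes <- list()
  for (sp in SPECIES5) {
    seqs <- anc_seq
    for (g in seq_len(n)) {
      s <- seqs[g]
      nmut <- stats::rbinom(1, nchar(s), config$substitution_rate)
      if (nmut > 0) {
        pos <- sample.int(nchar(s), nmut) - 1L
        pos <- setdiff(pos, get(chrom_of[g], envir = protect))
        for (p in pos) {
          old <- substr(s, p + 1, p + 1)
          s <- set_bases(s, p, sample(setdiff(c("A", "C", "G", "T"), old), 1))
        }
      }
      seqs[g] <- s
    }
    names(seqs) <- chrom_of
    genomes[[sp]] <- genome_set(sp, seqs)
  }
  for (ed in edits) {
    g <- genomes[[ed$species]]
    g$sequences[[ed$chrom]] <- ed$fun(g$sequences[[ed$chrom]])
    genomes[[ed$species]] <- g
  }

  exons <- do.call(rbind, exons_rows)
  txs <- do.call(rbind, tx_rows)
  rownames(exons) <- rownames(txs) <- NULL
  models <- transcript_set(exons, transform(txs, species_id = "H"))
  truth_df <- do.call(rbind, truth)
  if (is.null(truth_df))
    truth_df <- data.frame(class = character(0), gene_id = character(0),
                           transcript_id = character(0),
                           feature = character(0), species = character(0),
                           effect = numeric(0), mechanism = character(0),
                           stringsAsFactors = FALSE)

  # per-species observed annotations: all shared models, plus the
  # exonization transcript only in its focal species
  exg_truth <- truth_df[truth_df$class == "exon_gain", , drop = FALSE]
  annotations <- list(); reference <- list()
  novel_tx <- txs$transcript_id[txs$gene_id %in% gene_ids[plan$novel_gene]]
  nnc_tx <- paste0(gene_ids[plan$nnc], ".tn")
  for (sp in SPECIES5) {
    drop_exg <- exg_truth$transcript_id[exg_truth$species != sp]
    keep <- !txs$transcript_id %in% drop_exg
    annotations[[sp]] <- transcript_set(
      exons[exons$transcript_id %in% txs$transcript_id[keep], ],
      transform(txs[keep, ], species_id = sp))
    keep_ref <- keep & !txs$transcript_id %in% c(novel_tx, nnc_tx)
    reference[[sp]] <- transcript_set(
      exons[exons$transcript_id %in% txs$transcript_id[keep_ref], ],
      transform(txs[keep_ref, ], species_id = sp))
  }

  omap <- rbind(do.call(rbind, orth_junc), do.call(rbind, orth_exon))
  rownames(omap) <- NULL
  class(omap) <- c("orthology_map", "data.frame")

  tx_length <- vapply(split(exons$end - exons$start, exons$transcript_id),
                      sum, numeric(1))
  gene_of <- stats::setNames(txs$gene_id, txs$transcript_id)

  # ORFs on the human genome frame; proteome excludes novel genes
  proteins <- character(0)
  for (tid in txs$transcript_id) {
    s <- transcript_sequence(models, tid, genomes[["H"]])
    orf <- predict_orf(s, min_aa = 20L)
    if (!is.null(orf)) proteins[tid] <- orf$protein
  }
  proteome <- proteins[!names(proteins) %in% novel_tx]
  # ordered domain combinations: deterministic per transcript structure
  domains <- vapply(txs$transcript_id, function(tid) {
    e <- exons[exons$transcript_id == tid, ]
    paste(sprintf("D%d", sort(unique((e$start %/% 500) %% 7 + 1))),
          collapse = "+")
  }, character(1))

  structure(list(models = models, annotations = annotations,
                 reference = reference, genomes = genomes,
                 orthology = omap, repeats = repeats,
                 proteome = proteome, proteins = proteins,
                 domains = domains, truth = truth_df,
                 tx_length = tx_length, gene_of = gene_of,
                 plan = plan, focal = focal, gene_meta = gene_meta,
                 config = config),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", x$config$n_genes, "genes,",
      nrow(x$models$transcripts), "transcripts,",
      nrow(x$truth), "planted events\n")
  invisible(x)
}

#' Simulate replicate expression over the fixture
#'
#' Negative-binomial counts per transcript and sample under the planted
#' usage program: expression gains are nonzero in every focal-species
#' replicate and exactly zero elsewhere; DIU/DEU shifts move usage
#' fractions at constant gene totals; rank switches swap the two top
#' isoforms in the focal species. TPM is computed from counts with
#' effective length equal to transcript length.
#'
#' @param ref a `sim_reference`
#' @param config its `sim_config` (defaults to `ref$config`)
#' @param replicates optional override of replicates per species (e.g. 6
#'   for usage analyses)
#' @param seed_offset added to `config$seed` so reference generation and
#'   expression draws use distinct streams
#' @return an `expression_matrix` (counts + TPM)
#' @export
simulate_expression <- function(ref, config = ref$config,
                                replicates = config$replicates,
                                seed_offset = 1000L) {
  set.seed((config$seed + seed_offset) %% .Machine$integer.max)
  txs <- ref$models$transcripts
  genes <- unique(txs$gene_id)
  size <- 1 / config$nb_dispersion
  samples <- do.call(rbind, lapply(SPECIES5, function(sp)
    data.frame(sample_id = sprintf("%s_%d", sp, seq_len(replicates)),
               species = sp, replicate = seq_len(replicates),
               batch = if (config$batch_effect > 0)
                 sprintf("b%d", seq_len(replicates)) else "b1",
               stringsAsFactors = FALSE)))
  truth <- ref$truth
  gene_ids <- sort(genes)
  mu_g <- stats::setNames(
    exp(stats::rnorm(length(gene_ids), config$gene_mean_log,
                     config$gene_mean_sd)), gene_ids)
  boosted <- unique(truth$gene_id[truth$class %in%
                                    c("gain", "exon_gain", "diu", "deu",
                                      "rank_switch")])
  mu_g[boosted] <- pmax(mu_g[boosted], 300)

  counts <- matrix(0, nrow(txs), nrow(samples),
                   dimnames = list(txs$transcript_id, samples$sample_id))
  base_w <- c(t1 = 0.55, t2 = 0.30, t3 = 0.15, tx = 0.25, tg = 0.30,
              tn = 0.15)
  for (g in gene_ids) {
    ids <- txs$transcript_id[txs$gene_id == g]
    suffix <- sub("^.*\\.", "", ids)
    w0 <- base_w[suffix]
    tr_g <- truth[truth$gene_id == g, , drop = FALSE]
    for (sp in SPECIES5) {
      w <- w0
      names(w) <- ids
      # expression gain: focal species only
      gn <- tr_g[tr_g$class == "gain", , drop = FALSE]
      if (nrow(gn) == 1) {
        tgid <- gn$transcript_id
        if (sp != gn$species) w[tgid] <- 0
      }
      # exonization transcript expressed only in its species' annotation
      eg <- tr_g[tr_g$class == "exon_gain", , drop = FALSE]
      if (nrow(eg) == 1 && sp != eg$species) w[eg$transcript_id] <- 0
      w <- w / sum(w)
      # usage shifts at constant gene totals
      du <- tr_g[tr_g$class == "diu", , drop = FALSE]
      if (nrow(du) == 1 && sp == du$species)
        w <- shift_usage(w, du$transcript_id, du$effect)
      de <- tr_g[tr_g$class == "deu", , drop = FALSE]
      if (nrow(de) == 1 && sp == de$species)
        w <- shift_usage(w, de$transcript_id, de$effect)
      rs <- tr_g[tr_g$class == "rank_switch", , drop = FALSE]
      if (nrow(rs) == 1 && sp == rs$species) {
        o <- order(-w)
        w[c(o[1], o[2])] <- w[c(o[2], o[1])]
      }
      # usage fractions are molar (TPM-scale): expected counts are
      # proportional to usage x transcript length, normalized so the gene
      # total stays at its baseline mean
      lens_g <- ref$tx_length[ids]
      wl <- w * lens_g
      cols <- samples$sample_id[samples$species == sp]
      for (ci in cols) {
        bmult <- if (config$batch_effect > 0)
          2^(config$batch_effect *
               (match(samples$batch[samples$sample_id == ci],
                      unique(samples$batch)) - 1)) else 1
        mu <- mu_g[g] * (wl / sum(wl)) * bmult
        cnt <- ifelse(mu == 0, 0,
                      stats::rnbinom(length(mu), mu = mu, size = size))
        # planted gains must be present in all focal replicates
        if (nrow(gn) == 1 && sp == gn$species)
          cnt[names(w) == gn$transcript_id] <-
            max(1, cnt[names(w) == gn$transcript_id])
        counts[ids, ci] <- cnt
      }
    }
  }
  lens <- ref$tx_length[rownames(counts)]
  rate <- counts / lens
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expression_matrix(tpm, samples, counts = counts)
}

# move delta usage mass onto `target`, scaling the rest down
shift_usage <- function(w, target, delta) {
  stopifnot(target %in% names(w))
  w_t <- min(w[target] + delta, 0.95)
  others <- setdiff(names(w), target)
  s <- sum(w[others])
  w[others] <- if (s > 0) w[others] * (1 - w_t) / s else 0
  w[target] <- w_t
  w
}

#' Write a complete fixture directory
#'
#' Emits every interface format the pipeline consumes: per-species genome
#' FASTA, observed and reference GTFs, repeat BEDs, abundance TSVs per
#' sample, metadata, the orthology map, the reference proteome, the domain
#' table and the truth ledger.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param force overwrite an existing non-empty directory
#' @return invisible list with the `sim_reference` and `expression_matrix`
#' @export
emit_fixture <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  em <- simulate_expression(ref, config)
  for (sp in SPECIES5) {
    write_genome(ref$genomes[[sp]], file.path(out_dir,
                                              sprintf("genome_%s.fa", sp)))
    write_annotation(ref$annotations[[sp]],
                     file.path(out_dir, sprintf("models_%s.gtf", sp)))
    write_annotation(ref$reference[[sp]],
                     file.path(out_dir, sprintf("reference_%s.gtf", sp)))
    rep_sp <- ref$repeats[[sp]]
    utils::write.table(rep_sp[order(rep_sp$chrom, rep_sp$start), ],
                       file.path(out_dir, sprintf("repeats_%s.bed", sp)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  for (s in em$samples$sample_id) {
    d <- data.frame(target_id = rownames(em$tpm),
                    length = ref$tx_length[rownames(em$tpm)],
                    eff_length = ref$tx_length[rownames(em$tpm)],
                    est_counts = em$counts[, s], tpm = em$tpm[, s])
    utils::write.table(d, file.path(out_dir, sprintf("abundance_%s.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(em$samples, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$orthology, file.path(out_dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_proteome(ref$proteome, file.path(out_dir, "proteome.fa"))
  utils::write.table(
    data.frame(transcript_id = names(ref$domains), domains = ref$domains),
    file.path(out_dir, "domains.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reference = ref, expression = em))
}

#' Per-part read counts derived from transcript counts
#'
#' Distributes each transcript's counts uniformly along its length and
#' accumulates them over the exonic parts it covers: count(part, s) =
#' sum over covering transcripts of count(t, s) * part_length /
#' transcript_length.
#'
#' @param parts exonic-part table from [flatten_exonic_parts_all()]
#' @param counts transcript count matrix
#' @param tx_length named transcript lengths
#' @return matrix parts x samples; rownames `gene:start-end`
#' @export
derive_part_counts <- function(parts, counts, tx_length) {
  out <- matrix(0, nrow(parts), ncol(counts),
                dimnames = list(sprintf("%s:%d-%d", parts$gene_id,
                                        parts$start, parts$end),
                                colnames(counts)))
  for (i in seq_len(nrow(parts))) {
    txs <- strsplit(parts$transcripts[i], ",")[[1]]
    txs <- txs[txs %in% rownames(counts)]
    if (!length(txs)) next
    plen <- parts$end[i] - parts$start[i]
    out[i, ] <- colSums(counts[txs, , drop = FALSE] / tx_length[txs]) * plen
  }
  out
}
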