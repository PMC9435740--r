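# Isoform- and exon-usage dynamics: TMM between-sample normalization,
# batch correction, isoform-usage (IU) fractions, ambiguous-gene filtering,
# dominant-isoform conservation, and replicate-aware species-specific
# differential usage tests (DIU at transcript level, DEU at exonic-part
# level).

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample composition normalization for count tables. The
#' reference sample is the one whose upper quartile of library-size-scaled
#' positive values is closest to the mean upper quartile. For every other
#' sample, per-gene M (log2 ratio of scaled abundances) and A (mean log2
#' abundance) are computed on doubly-positive genes; the most extreme 30%
#' of M values and 5% of A values are trimmed on each side (rank-based),
#' and the factor is 2 to the precision-weighted mean of the retained M
#' values, with weights from the asymptotic binomial variance
#' (1/count - 1/library size, summed over the two samples). Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts count matrix (features x samples), no all-zero column
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A
#' @param weighted use precision weights (default TRUE)
#' @return list: `factors` (named per-sample), `normalized` (counts scaled
#'   by library size x factor, per million), `ref` (reference sample name)
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.3, abs_trim = 0.05,
                          weighted = TRUE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts")
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j] / lib[j]
    stats::quantile(v[v > 0], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    logratio_trim, abs_trim, weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  eff <- lib * f
  normalized <- sweep(counts, 2, eff, "/") * 1e6
  list(factors = f, normalized = normalized,
       ref = if (is.null(colnames(counts))) ref else colnames(counts)[ref])
}

# factor for one sample against the reference
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abs_trim, weighted) {
  keep0 <- obs > 0 & ref > 0
  o <- obs[keep0]; r <- ref[keep0]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  w <- if (weighted) {
    1 / ((n_obs - o[keep]) / (n_obs * o[keep]) +
           (n_ref - r[keep]) / (n_ref * r[keep]))
  } else rep(1, sum(keep))
  2^(sum(w * M[keep]) / sum(w))
}

#' Per-batch median-centering batch correction
#'
#' Simple location correction on the log2(TPM+1) scale: within each batch,
#' each transcript's values are shifted so that batch medians agree with
#' the transcript's global median; values are mapped back to the TPM scale
#' and clamped at 0. With a single batch this is the identity.
#'
#' @param em `expression_matrix`
#' @return corrected `expression_matrix`
#' @export
correct_batch <- function(em) {
  batches <- unique(em$samples$batch)
  if (length(batches) < 2) return(em)
  lg <- log2(em$tpm + 1)
  for (i in seq_len(nrow(lg))) {
    gm <- stats::median(lg[i, ])
    for (b in batches) {
      cols <- em$samples$sample_id[em$samples$batch == b]
      lg[i, cols] <- lg[i, cols] - stats::median(lg[i, cols]) + gm
    }
  }
  tpm <- pmax(2^lg - 1, 0)
  expression_matrix(tpm, em$samples, counts = em$counts)
}

#' Isoform-usage fractions
#'
#' IU(t, s) = expression of transcript t in sample s divided by the summed
#' expression of its gene in s; NA where the gene total is zero.
#'
#' @param expr expression matrix (transcripts x samples), e.g. normalized
#'   TPM
#' @param gene_of named character vector transcript_id -> gene_id
#' @return matrix of usage fractions, same dimnames as `expr`
#' @export
compute_iu <- function(expr, gene_of) {
  if (any(!rownames(expr) %in% names(gene_of)))
    stop("transcript without gene assignment")
  g <- gene_of[rownames(expr)]
  totals <- rowsum(expr, g)
  tot <- totals[g, , drop = FALSE]
  iu <- expr / tot
  iu[tot == 0] <- NA
  iu
}

#' Flag genes whose transcripts are too similar to quantify separately
#'
#' A gene is flagged when some transcript pair has the same number of
#' introns and identical intron chains except for internal exon-boundary
#' shifts of at most `shift_max` nt (no junction gained or lost) —
#' internal exon extensions that make short-read quantification ambiguous.
#' Identical (duplicate) chains are also flagged.
#'
#' @param ts `transcript_set`
#' @param shift_max maximum boundary shift in nt (default 30)
#' @return data.frame `gene_id`, `flagged`
#' @export
flag_ambiguous_genes <- function(ts, shift_max = 30L) {
  genes <- sort(unique(ts$transcripts$gene_id))
  flg <- vapply(genes, function(g) {
    ids <- ts$transcripts$transcript_id[ts$transcripts$gene_id == g]
    if (length(ids) < 2) return(FALSE)
    chains <- lapply(ids, function(id) transcript_introns(ts, id))
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      a <- chains[[i]]; b <- chains[[j]]
      if (nrow(a) != nrow(b)) next
      if (nrow(a) == 0) return(TRUE)  # identical mono-exonic structures
      ds <- abs(a$start - b$start); de <- abs(a$end - b$end)
      # internal boundaries: all of them belong to internal exons except
      # none here — every intron boundary is internal to the chain
      if (all(ds <= shift_max) && all(de <= shift_max)) return(TRUE)
    }
    FALSE
  }, logical(1))
  data.frame(gene_id = genes, flagged = unname(flg), stringsAsFactors = FALSE)
}

#' Dominant-isoform conservation across species
#'
#' Ranks each gene's transcripts within each species by mean IU across
#' replicates (ties broken by higher total expression, then transcript
#' id). Reports whether one orthologous transcript is rank 1 in every
#' species, optional ORF and domain-combination sharing of the rank-1
#' transcripts, and the sharing curve over rank1/rank2 expression
#' fold-change thresholds.
#'
#' @param iu usage matrix from [compute_iu()]
#' @param expr expression matrix used for tie-breaks and fold changes
#' @param gene_of named transcript -> gene map
#' @param samples sample metadata data.frame (`sample_id`, `species`)
#' @param orf_of optional named transcript -> protein sequence
#' @param domains_of optional named transcript -> ordered domain string
#' @param fc_thresholds fold-change grid for the sharing curve
#' @return list: `records` (per gene: rank1/rank2 per species, shared
#'   flags, min fold change), `sharing_curve` (threshold, fraction, n)
#' @export
rank_dominance <- function(iu, expr, gene_of, samples,
                           orf_of = NULL, domains_of = NULL,
                           fc_thresholds = c(1, 1.5, 2, 3, 5)) {
  species <- unique(samples$species)
  g <- gene_of[rownames(iu)]
  recs <- list()
  for (gene in sort(unique(g))) {
    txs <- rownames(iu)[g == gene]
    if (length(txs) < 2) next
    per_sp <- lapply(species, function(sp) {
      cols <- samples$sample_id[samples$species == sp]
      mu <- rowMeans(iu[txs, cols, drop = FALSE])
      me <- rowMeans(expr[txs, cols, drop = FALSE])
      mu[is.na(mu)] <- -Inf
      ord <- order(-mu, -me, txs)
      list(rank1 = txs[ord[1]], rank2 = txs[ord[2]],
           fc = {
             e1 <- me[ord[1]]; e2 <- me[ord[2]]
             if (e2 == 0) Inf else e1 / e2
           })
    })
    names(per_sp) <- species
    r1 <- vapply(per_sp, `[[`, character(1), "rank1")
    shared <- length(unique(r1)) == 1
    minfc <- min(vapply(per_sp, `[[`, numeric(1), "fc"))
    shared_orf <- if (!is.null(orf_of))
      length(unique(unname(orf_of[r1]))) == 1 else NA
    shared_dom <- if (!is.null(domains_of))
      length(unique(unname(domains_of[r1]))) == 1 else NA
    recs[[gene]] <- data.frame(
      gene_id = gene, shared_rank1 = shared, min_rank_fc = minfc,
      shared_orf = shared_orf, shared_domain_combination = shared_dom,
      t(vapply(species, function(sp) per_sp[[sp]]$rank1, character(1))),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  curve <- do.call(rbind, lapply(fc_thresholds, function(th) {
    keep <- records$min_rank_fc >= th
    data.frame(fc_threshold = th,
               frac_shared = if (any(keep)) mean(records$shared_rank1[keep])
               else NA_real_,
               n_genes = sum(keep))
  }))
  list(records = records, sharing_curve = curve)
}

logit_eps <- function(u, eps = 0.01) {
  v <- (u + eps) / (1 + 2 * eps)
  log(v / (1 - v))
}

#' Species-specific differential usage test
#'
#' For each feature (transcript IU or exonic-part usage coefficient), runs
#' a two-sided Welch t-test on logit(usage + eps) for each of the 10
#' species pairs, BH-adjusts p-values across features within each pair,
#' and calls a feature species-specific "up" (or "down") for focal species
#' S iff all 4 pairs involving S are significant with a consistent sign
#' while none of the 6 pairs among the other species is significant.
#'
#' @param usage matrix features x samples of usage values in \[0,1\] (NA
#'   allowed; features with fewer than 2 usable replicates in a group are
#'   skipped for that pair)
#' @param samples metadata (`sample_id`, `species`)
#' @param alpha BH-adjusted significance level (default 0.05)
#' @param eps pseudo-usage added before the logit (default 0.01)
#' @return data.frame per feature: `feature_id`, `call` ("none"/"up"/
#'   "down"), `species` (focal, NA when none), plus per-pair adjusted
#'   p-values in attribute `"pairs"`
#' @export
test_species_specific_usage <- function(usage, samples, alpha = 0.05,
                                        eps = 0.01) {
  species <- unique(samples$species)
  pairs <- utils::combn(species, 2, simplify = FALSE)
  pair_names <- vapply(pairs, paste, character(1), collapse = "-")
  lu <- logit_eps(usage, eps)
  pmat <- matrix(NA_real_, nrow(usage), length(pairs),
                 dimnames = list(rownames(usage), pair_names))
  dmat <- pmat  # mean difference (first minus second species)
  grp_stats <- function(cols) {
    x <- lu[, cols, drop = FALSE]
    n <- rowSums(is.finite(x))
    x[!is.finite(x)] <- NA
    m <- rowMeans(x, na.rm = TRUE)
    v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, m = m, v = v)
  }
  sp_stats <- lapply(stats::setNames(species, species), function(sp)
    grp_stats(samples$sample_id[samples$species == sp]))
  for (k in seq_along(pairs)) {
    s1 <- sp_stats[[pairs[[k]][1]]]; s2 <- sp_stats[[pairs[[k]][2]]]
    ok <- s1$n >= 2 & s2$n >= 2
    d <- s1$m - s2$m
    se2 <- s1$v / s1$n + s2$v / s2$n
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((s1$v / s1$n)^2 / (s1$n - 1) +
                     (s2$v / s2$n)^2 / (s2$n - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # degenerate zero-variance cases
    zz <- s1$v == 0 & s2$v == 0
    p[zz & abs(d) < 1e-12] <- 1
    p[zz & abs(d) >= 1e-12] <- 0
    p[!ok] <- NA
    d[!ok] <- NA
    pmat[, k] <- p
    dmat[, k] <- d
  }
  padj <- apply(pmat, 2, bh_adjust)
  if (is.null(dim(padj))) padj <- matrix(padj, nrow = nrow(usage),
                                         dimnames = dimnames(pmat))
  call <- rep("none", nrow(usage)); focal <- rep(NA_character_, nrow(usage))
  for (i in seq_len(nrow(usage))) {
    for (sp in species) {
      inv <- vapply(pairs, function(p) sp %in% p, logical(1))
      p_in <- padj[i, inv]; p_out <- padj[i, !inv]
      if (any(is.na(p_in))) next
      sgn <- vapply(which(inv), function(k) {
        d <- dmat[i, k]
        if (pairs[[k]][1] == sp) sign(d) else -sign(d)
      }, numeric(1))
      sig_in <- all(p_in < alpha) && length(unique(sgn)) == 1 && sgn[1] != 0
      none_out <- all(is.na(p_out) | p_out >= alpha)
      if (sig_in && none_out) {
        call[i] <- if (sgn[1] > 0) "up" else "down"
        focal[i] <- sp
        break
      }
    }
  }
  out <- data.frame(feature_id = rownames(usage), call = call,
                    species = focal, stringsAsFactors = FALSE)
  attr(out, "pairs") <- padj
  out
}

#' Expression filter for usage testing
#'
#' Default filters: gene expression >= `gene_min` TPM in at least `k`
#' samples of every species, and the feature expressed (> 0) in at least
#' `k` samples of at least one species.
#'
#' @param expr feature expression matrix (TPM scale)
#' @param gene_expr gene-level expression matrix aligned to `expr` rows
#'   (same gene value repeated per feature)
#' @param samples metadata
#' @param gene_min,k thresholds
#' @return logical vector over features
#' @export
usage_expression_filter <- function(expr, gene_expr, samples,
                                    gene_min = 1, k = 2) {
  species <- unique(samples$species)
  ok_gene <- rep(TRUE, nrow(expr))
  ok_feat <- rep(FALSE, nrow(expr))
  for (sp in species) {
    cols <- samples$sample_id[samples$species == sp]
    ok_gene <- ok_gene &
      rowSums(gene_expr[, cols, drop = FALSE] >= gene_min) >= k
    ok_feat <- ok_feat | rowSums(expr[, cols, drop = FALSE] > 0) >= k
  }
  ok_gene & ok_feat
}

#' Exonic-part usage coefficients
#'
#' u(part, s) = count(part, s) / sum over the gene's parts of count(., s);
#' NA when the gene total is zero. For parts marked as skipping exons the
#' per-species mean usage is the descriptive inclusion-fraction
#' (PSI-analog) column.
#'
#' @param part_counts matrix parts x samples
#' @param gene_of named part -> gene map
#' @param samples optional metadata; when given, per-species mean usage is
#'   attached as attribute `"inclusion"`
#' @return usage matrix (parts x samples)
#' @export
exonic_part_usage <- function(part_counts, gene_of, samples = NULL) {
  u <- compute_iu(part_counts, gene_of)
  if (!is.null(samples)) {
    species <- unique(samples$species)
    incl <- vapply(species, function(sp) {
      cols <- samples$sample_id[samples$species == sp]
      rowMeans(u[, cols, drop = FALSE])
    }, numeric(nrow(u)))
    colnames(incl) <- species
    attr(u, "inclusion") <- incl
  }
  u
}
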