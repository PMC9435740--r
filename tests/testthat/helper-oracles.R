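# Independent oracles: brute-force / straight-line implementations used to
# validate the package's optimized code paths. Each oracle is written as a
# literal transcription of the operation's definition, independent of the
# implementation it checks.

## ---- Wagner parsimony: exhaustive enumeration on ((((H,C),G),O),M) ----

# nodes: H C G O M tips; internals A1=(H,C), A2=(A1,G), A3=(A2,O), R=(A3,M)
oracle_parsimony <- function(profile, gain_cost = 1, loss_cost = 1) {
  stopifnot(all(c("H", "C", "G", "O", "M") %in% names(profile)))
  edges <- list(c("R", "A3"), c("R", "M"), c("A3", "A2"), c("A3", "O"),
                c("A2", "A1"), c("A2", "G"), c("A1", "H"), c("A1", "C"))
  branch_name <- c(A3 = "HCGO", A2 = "HCG", A1 = "HC",
                   H = "H", C = "C", G = "G", O = "O", M = "M")
  best <- Inf; optima <- list()
  for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) for (r in 0:1) {
    st <- c(profile[c("H", "C", "G", "O", "M")],
            A1 = a1, A2 = a2, A3 = a3, R = r)
    cost <- 0; ev <- character(0)
    for (e in edges) {
      p <- st[[e[1]]]; ch <- st[[e[2]]]
      if (p == 0 && ch == 1) {
        cost <- cost + gain_cost
        ev <- c(ev, paste0(branch_name[[e[2]]], ":gain"))
      }
      if (p == 1 && ch == 0) {
        cost <- cost + loss_cost
        ev <- c(ev, paste0(branch_name[[e[2]]], ":loss"))
      }
    }
    if (cost < best) { best <- cost; optima <- list() }
    if (cost == best)
      optima[[length(optima) + 1L]] <- list(events = sort(ev), root = r)
  }
  all_ev <- sort(unique(unlist(lapply(optima, `[[`, "events"))))
  in_all <- vapply(all_ev, function(e)
    all(vapply(optima, function(o) e %in% o$events, logical(1))),
    logical(1))
  list(score = best, events = all_ev, ambiguous = all_ev[!in_all],
       root_states = sort(unique(vapply(optima, `[[`, numeric(1), "root"))))
}

# Fitch parsimony (equal-cost change count) for cross-checking scores
oracle_fitch <- function(profile) {
  setof <- function(s) if (is.na(s)) c(0, 1) else s
  count <- 0
  join <- function(a, b) {
    i <- intersect(a, b)
    if (length(i)) i else { count <<- count + 1; union(a, b) }
  }
  a1 <- join(setof(profile[["H"]]), setof(profile[["C"]]))
  a2 <- join(a1, setof(profile[["G"]]))
  a3 <- join(a2, setof(profile[["O"]]))
  join(a3, setof(profile[["M"]]))
  count
}

## ---- AS events: per-definition brute force over transcript pairs ----

# returns a sorted character vector of "class|start1|end1|start2|end2" keys
oracle_as_events <- function(ts, gene_id) {
  tx <- ts$transcripts[ts$transcripts$gene_id == gene_id, ]
  if (nrow(tx) < 2) return(character(0))
  strand <- tx$strand[1]
  ids <- tx$transcript_id
  E <- lapply(ids, function(id) transcript_exons(ts, id))
  I <- lapply(ids, function(id) transcript_introns(ts, id))
  names(E) <- names(I) <- ids
  keys <- character(0)
  k_add <- function(cls, iv1, iv2 = c(NA, NA))
    keys <<- c(keys, paste(cls, iv1[1], iv1[2], iv2[1], iv2[2], sep = "|"))
  for (a in ids) for (b in ids) {
    if (a == b) next
    ea <- E[[a]]; ia <- I[[a]]; ib <- I[[b]]; eb <- E[[b]]
    # SE
    if (nrow(ea) >= 3) for (i in 2:(nrow(ea) - 1)) {
      up_start <- ea$end[i - 1]; down_end <- ea$start[i + 1]
      spanned <- FALSE
      if (nrow(ib) > 0) for (j in seq_len(nrow(ib)))
        if (ib$start[j] == up_start && ib$end[j] == down_end) spanned <- TRUE
      if (spanned) k_add("SE", c(ea$start[i], ea$end[i]))
    }
    # RI: exon of a == two consecutive exons of b glued over b's intron
    if (nrow(eb) >= 2) for (j in seq_len(nrow(eb) - 1)) {
      for (i in seq_len(nrow(ea))) {
        if (ea$start[i] == eb$start[j] && ea$end[i] == eb$end[j + 1])
          k_add("RI", c(eb$end[j], eb$start[j + 1]))
      }
    }
    # alt splice sites
    if (nrow(ia) > 0 && nrow(ib) > 0)
      for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
        same_start <- ia$start[i] == ib$start[j]
        same_end <- ia$end[i] == ib$end[j]
        if (same_start && !same_end) {
          # downstream exons must overlap
          xa <- ea[ea$start == ia$end[i], ]
          xb <- eb[eb$start == ib$end[j], ]
          if (nrow(xa) == 1 && nrow(xb) == 1 &&
              max(xa$start, xb$start) < min(xa$end, xb$end)) {
            cls <- if (strand == "+") "A3SS" else "A5SS"
            ivs <- rbind(c(ia$start[i], ia$end[i]), c(ib$start[j], ib$end[j]))
            ivs <- ivs[order(ivs[, 1], ivs[, 2]), ]
            k_add(cls, ivs[1, ], ivs[2, ])
          }
        }
        if (same_end && !same_start) {
          xa <- ea[ea$end == ia$start[i], ]
          xb <- eb[eb$end == ib$start[j], ]
          if (nrow(xa) == 1 && nrow(xb) == 1 &&
              max(xa$start, xb$start) < min(xa$end, xb$end)) {
            cls <- if (strand == "+") "A5SS" else "A3SS"
            ivs <- rbind(c(ia$start[i], ia$end[i]), c(ib$start[j], ib$end[j]))
            ivs <- ivs[order(ivs[, 1], ivs[, 2]), ]
            k_add(cls, ivs[1, ], ivs[2, ])
          }
        }
      }
  }
  # MEX: cassette contexts that share outer boundaries, never co-occur
  ctx <- list()
  for (a in ids) {
    ea <- E[[a]]
    if (nrow(ea) >= 3) for (i in 2:(nrow(ea) - 1))
      ctx[[length(ctx) + 1L]] <- c(ea$end[i - 1], ea$start[i + 1],
                                   ea$start[i], ea$end[i])
  }
  if (length(ctx) >= 2) {
    ctx <- unique(ctx)
    for (i in seq_along(ctx)) for (j in seq_along(ctx)) {
      if (i >= j) next
      c1 <- ctx[[i]]; c2 <- ctx[[j]]
      if (c1[1] != c2[1] || c1[2] != c2[2]) next
      e1 <- c1[3:4]; e2 <- c2[3:4]
      if (identical(e1, e2)) next
      if (max(e1[1], e2[1]) < min(e1[2], e2[2])) next
      cooc <- FALSE
      for (t in ids) {
        et <- E[[t]]
        h1 <- any(et$start == e1[1] & et$end == e1[2])
        h2 <- any(et$start == e2[1] & et$end == e2[2])
        if (h1 && h2) cooc <- TRUE
      }
      if (!cooc) {
        ivs <- if (e1[1] < e2[1]) rbind(e1, e2) else rbind(e2, e1)
        k_add("MEX", ivs[1, ], ivs[2, ])
      }
    }
  }
  sort(unique(keys))
}

event_keys <- function(ev) {
  if (nrow(ev) == 0) return(character(0))
  sort(unique(paste(ev$event_class, ev$start1, ev$end1, ev$start2, ev$end2,
                    sep = "|")))
}

## ---- exonic parts: per-base membership oracle ----

oracle_parts <- function(ts, gene_id) {
  tx <- ts$transcripts[ts$transcripts$gene_id == gene_id, ]
  ex <- ts$exons[ts$exons$transcript_id %in% tx$transcript_id, ]
  lo <- min(ex$start); hi <- max(ex$end)
  memb <- vector("list", hi - lo)
  for (i in seq_len(nrow(ex)))
    for (p in seq(ex$start[i], ex$end[i] - 1))
      memb[[p - lo + 1]] <- c(memb[[p - lo + 1]], ex$transcript_id[i])
  sig <- vapply(memb, function(m)
    if (is.null(m)) "" else paste(sort(unique(m)), collapse = ","),
    character(1))
  out <- list(); run_start <- NULL
  for (p in seq_along(sig)) {
    prev <- if (p == 1) "" else sig[p - 1]
    if (sig[p] != prev) {
      if (!is.null(run_start) && prev != "")
        out[[length(out) + 1L]] <- data.frame(
          start = run_start + lo - 1, end = p + lo - 2 + 1,
          transcripts = prev, stringsAsFactors = FALSE)
      run_start <- if (sig[p] != "") p else NULL
    }
  }
  if (!is.null(run_start) && sig[length(sig)] != "")
    out[[length(out) + 1L]] <- data.frame(
      start = run_start + lo - 1, end = length(sig) + lo,
      transcripts = sig[length(sig)], stringsAsFactors = FALSE)
  d <- do.call(rbind, out)
  d[order(d$start), , drop = FALSE]
}

## ---- TMM: straight-line transcription of the recipe ----

oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  ns <- ncol(counts)
  lib <- colSums(counts)
  uq <- numeric(ns)
  for (j in 1:ns) {
    sc <- counts[, j] / lib[j]
    uq[j] <- stats::quantile(sc[sc > 0], 0.75, names = FALSE)
  }
  ref <- which.min(abs(uq - mean(uq)))
  fac <- numeric(ns)
  for (j in 1:ns) {
    if (j == ref) { fac[j] <- 1; next }
    o <- counts[, j]; r <- counts[, ref]
    use <- o > 0 & r > 0
    o <- o[use]; r <- r[use]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    if (length(M) == 0 || max(abs(M)) < 1e-6) { fac[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) { fac[j] <- 1; next }
    w <- 1 / ((lib[j] - o[keep]) / (lib[j] * o[keep]) +
                (lib[ref] - r[keep]) / (lib[ref] * r[keep]))
    fac[j] <- 2^(sum(w * M[keep]) / sum(w))
  }
  fac / exp(mean(log(fac)))
}

## ---- Fisher two-sided exact p: summation loop ----

oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  p_obs <- stats::dhyper(a, m, n, k)
  total <- 0
  for (x in lo:hi) {
    px <- stats::dhyper(x, m, n, k)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## ---- tryptic digestion: substring enumeration ----

oracle_digest <- function(protein, missed_max = 2, len_min = 7,
                          len_max = 40) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n == 0) return(character(0))
  is_site <- function(k) k >= 1 && k < n && aa[k] %in% c("K", "R") &&
    aa[k + 1] != "P"
  peps <- character(0)
  for (i in 1:n) for (j in i:n) {
    len <- j - i + 1
    if (len < len_min || len > len_max) next
    left_ok <- (i == 1) || is_site(i - 1)
    right_ok <- (j == n) || is_site(j)
    if (!left_ok || !right_ok) next
    internal <- 0
    if (j > i) for (k in i:(j - 1)) if (is_site(k)) internal <- internal + 1
    if (internal > missed_max) next
    peps <- c(peps, substr(protein, i, j))
  }
  sort(unique(peps))
}

## ---- random toy gene generator for event/part tests ----

random_toy_gene <- function(gene_id = "g1", strand = sample(c("+", "-"), 1),
                            n_tx = sample(2:4, 1)) {
  n_e <- sample(4:6, 1)
  elen <- sample(30:80, n_e, replace = TRUE)
  ilen <- sample(20:60, n_e - 1, replace = TRUE)
  pos <- 10L; es <- integer(n_e); ee <- integer(n_e)
  for (i in seq_len(n_e)) {
    es[i] <- pos; ee[i] <- pos + elen[i]
    pos <- ee[i] + if (i < n_e) ilen[i] else 0L
  }
  mk_tx <- function() {
    keep <- c(1, which(stats::runif(n_e - 2) > 0.4) + 1, n_e)
    keep <- sort(unique(keep))
    s <- es[keep]; e <- ee[keep]
    # random internal boundary shift (alt splice site)
    if (length(keep) >= 2 && stats::runif(1) < 0.4) {
      i <- sample(seq_len(length(keep) - 1), 1)
      if (stats::runif(1) < 0.5) {
        shift <- sample(5:15, 1)          # extend exon i (donor shift)
        if (s[i + 1] - (e[i] + shift) >= 4) e[i] <- e[i] + shift
      } else {
        shift <- sample(5:15, 1)          # extend exon i+1 (acceptor shift)
        if ((s[i + 1] - shift) - e[i] >= 4) s[i + 1] <- s[i + 1] - shift
      }
    }
    # random intron retention: merge two adjacent exons
    if (length(s) >= 2 && stats::runif(1) < 0.25) {
      i <- sample(seq_len(length(s) - 1), 1)
      e[i] <- e[i + 1]
      s <- s[-(i + 1)]; e <- e[-(i + 1)]
    }
    data.frame(start = s, end = e)
  }
  exl <- lapply(seq_len(n_tx), function(i) mk_tx())
  exons <- do.call(rbind, lapply(seq_along(exl), function(i)
    data.frame(transcript_id = sprintf("%s.t%d", gene_id, i),
               start = exl[[i]]$start, end = exl[[i]]$end)))
  txs <- data.frame(transcript_id = sprintf("%s.t%d", gene_id, seq_len(n_tx)),
                    gene_id = gene_id, species_id = "H", chrom = "chr1",
                    strand = strand, stringsAsFactors = FALSE)
  transcript_set(exons, txs)
}

# mirror a transcript_set: x -> L - x, flip strand
mirror_ts <- function(ts, L) {
  ex <- ts$exons
  new_ex <- data.frame(transcript_id = ex$transcript_id,
                       start = L - ex$end, end = L - ex$start)
  tr <- ts$transcripts
  tr$strand <- ifelse(tr$strand == "+", "-", "+")
  transcript_set(new_ex, tr)
}

# flip strand labels only (no coordinate change)
flip_strand_ts <- function(ts) {
  tr <- ts$transcripts
  tr$strand <- ifelse(tr$strand == "+", "-", "+")
  transcript_set(ts$exons, tr)
}
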