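# Evolution of transcript expression: binary presence/absence profiles over
# the five-primate phylogeny, Wagner parsimony (Sankoff dynamic programming
# with full enumeration of optimal labelings) for gain/loss reconstruction,
# species-specific transcript calls, and the gene-level up-regulation
# confound check.

#' The default five-primate phylogeny
#'
#' Rooted topology ((((H,C),G),O),M): human, chimpanzee, gorilla,
#' orangutan, rhesus macaque. Parsed with \pkg{ape}; internal nodes are
#' named by the leaf set of their clade (e.g. "HC", "HCG").
#'
#' @param newick newick string; any rooted binary tree with unique leaf
#'   labels is accepted
#' @return object of class `phylo_tree`: the ape tree plus parent/child
#'   tables and branch names
#' @export
phylo_tree <- function(newick = "((((H,C),G),O),M);") {
  tr <- ape::read.tree(text = newick)
  if (is.null(tr) || !ape::is.rooted(tr)) stop("need a rooted newick tree")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  labels <- character(n_tip + n_node)
  labels[seq_len(n_tip)] <- tr$tip.label
  # name internal nodes by sorted concatenation of descendant tips,
  # in tree tip order
  for (v in (n_tip + 1):(n_tip + n_node)) {
    tips <- ape::extract.clade(tr, v)$tip.label
    labels[v] <- paste(tr$tip.label[sort(match(tips, tr$tip.label))],
                       collapse = "")
  }
  root <- n_tip + 1L
  structure(list(tree = tr, n_tip = n_tip, root = root,
                 edge = tr$edge, labels = labels),
            class = "phylo_tree")
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("phylo_tree:", x$n_tip, "tips:",
      paste(x$tree$tip.label, collapse = ","), "\n")
  invisible(x)
}

# children of each node as a list
tree_children <- function(pt) {
  ch <- vector("list", pt$n_tip + pt$tree$Nnode)
  for (i in seq_len(nrow(pt$edge)))
    ch[[pt$edge[i, 1]]] <- c(ch[[pt$edge[i, 1]]], pt$edge[i, 2])
  ch
}

#' Reconstruct expression gains and losses by Wagner parsimony
#'
#' Sankoff dynamic programming over the binary states \{absent, present\}
#' with configurable gain (0 to 1) and loss (1 to 0) branch costs. All
#' optimal internal labelings are enumerated; an event (branch, type) that
#' appears in every optimal labeling is unambiguous, while events that
#' differ between optimal labelings are each reported with
#' `ambiguous_direction = TRUE` — e.g. a macaque-only presence cannot be
#' told apart from a great-ape stem loss under equal costs.
#'
#' @param profile named integer vector of 0/1 over the tree's tips
#' @param tree a [phylo_tree()]
#' @param gain_cost,loss_cost positive branch costs
#' @return list of class `parsimony_result`: `score`, `events` (data.frame
#'   `branch`, `type`, `ambiguous_direction`), `root_states`, `n_optima`
#' @export
reconstruct_gain_loss <- function(profile, tree = phylo_tree(),
                                  gain_cost = 1, loss_cost = 1) {
  stopifnot(gain_cost > 0, loss_cost > 0)
  tips <- tree$tree$tip.label
  if (!all(tips %in% names(profile)))
    stop("profile must be named over all tips")
  pv <- profile[tips]
  if (any(is.na(pv)) || !all(pv %in% c(0, 1)))
    stop("ambiguous or non-binary leaf state; filter profiles upstream")
  n_all <- tree$n_tip + tree$tree$Nnode
  ch <- tree_children(tree)
  # branch cost matrix: rows parent state (0/1), cols child state
  bc <- matrix(c(0, loss_cost, gain_cost, 0), 2, 2,
               dimnames = list(c("0", "1"), c("0", "1")))
  # Sankoff bottom-up: L[v, s] = min cost of subtree at v given state s
  L <- matrix(Inf, n_all, 2)
  # process nodes children-first (decreasing depth from the root)
  depth <- integer(n_all); depth[tree$root] <- 0L
  for (i in seq_len(nrow(tree$edge)))
    depth[tree$edge[i, 2]] <- depth[tree$edge[i, 1]] + 1L
  ord <- order(depth, decreasing = TRUE)
  for (v in ord) {
    if (v <= tree$n_tip) {
      s <- pv[tree$labels[v]]
      L[v, ] <- c(if (s == 0) 0 else Inf, if (s == 1) 0 else Inf)
    } else {
      for (s in 1:2) {
        L[v, s] <- sum(vapply(ch[[v]], function(c_) {
          min(bc[s, 1] + L[c_, 1], bc[s, 2] + L[c_, 2])
        }, numeric(1)))
      }
    }
  }
  score <- min(L[tree$root, ])
  # top-down enumeration of all optimal labelings
  enumerate <- function(v, s) {
    # returns list of named state vectors for the subtree rooted at v
    if (v <= tree$n_tip) return(list(stats::setNames(s, tree$labels[v])))
    per_child <- lapply(ch[[v]], function(c_) {
      costs <- c(bc[s + 1, 1] + L[c_, 1], bc[s + 1, 2] + L[c_, 2])
      opts <- which(costs == min(costs)) - 1L
      unlist(lapply(opts, function(sc) enumerate(c_, sc)), recursive = FALSE)
    })
    combos <- list(stats::setNames(s, tree$labels[v]))
    for (pc in per_child) {
      combos <- unlist(lapply(combos, function(base) {
        lapply(pc, function(sub) c(base, sub))
      }), recursive = FALSE)
    }
    combos
  }
  root_opts <- which(L[tree$root, ] == score) - 1L
  labelings <- unlist(lapply(root_opts, function(s) enumerate(tree$root, s)),
                      recursive = FALSE)
  # events per labeling
  ev_sets <- lapply(labelings, function(lab) {
    ev <- character(0)
    for (i in seq_len(nrow(tree$edge))) {
      p <- lab[[tree$labels[tree$edge[i, 1]]]]
      c_ <- lab[[tree$labels[tree$edge[i, 2]]]]
      if (p == 0 && c_ == 1)
        ev <- c(ev, paste0(tree$labels[tree$edge[i, 2]], ":gain"))
      if (p == 1 && c_ == 0)
        ev <- c(ev, paste0(tree$labels[tree$edge[i, 2]], ":loss"))
    }
    sort(ev)
  })
  all_ev <- sort(unique(unlist(ev_sets)))
  in_all <- vapply(all_ev, function(e)
    all(vapply(ev_sets, function(s) e %in% s, logical(1))), logical(1))
  events <- if (length(all_ev)) {
    parts <- strsplit(all_ev, ":", fixed = TRUE)
    data.frame(branch = vapply(parts, `[`, character(1), 1),
               type = vapply(parts, `[`, character(1), 2),
               ambiguous_direction = !in_all,
               stringsAsFactors = FALSE)
  } else {
    data.frame(branch = character(0), type = character(0),
               ambiguous_direction = logical(0))
  }
  structure(list(score = score, events = events,
                 root_states = sort(unique(vapply(labelings, function(l)
                   l[[tree$labels[tree$root]]], numeric(1)))),
                 n_optima = length(unique(lapply(labelings, function(l)
                   l[order(names(l))])))),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("parsimony_result: score", x$score, "-", nrow(x$events), "event(s)\n")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Build presence/absence profiles from expression
#'
#' Under the `strict` criterion a transcript is present (state 1) in a
#' species iff TPM > `presence_threshold` in ALL replicates; under
#' `lenient`, in at least 2 replicates. State 0 requires TPM <=
#' `absence_threshold` in all replicates; everything else is ambiguous
#' (kept, flagged, excluded from parsimony input).
#'
#' @param em `expression_matrix`
#' @param criterion `"strict"` or `"lenient"`
#' @param presence_threshold TPM threshold for presence (default 0,
#'   i.e. TPM > 0)
#' @param absence_threshold TPM at or below which a replicate counts as
#'   unexpressed (default 0)
#' @return data.frame: `transcript_id`, one column per species with values
#'   0/1/NA (NA = ambiguous), `ambiguous` flag
#' @export
build_presence_matrix <- function(em, criterion = c("strict", "lenient"),
                                  presence_threshold = 0,
                                  absence_threshold = 0) {
  criterion <- match.arg(criterion)
  species <- unique(em$samples$species)
  reps <- table(em$samples$species)
  if (any(reps < 2))
    stop("every species needs >= 2 replicates (",
         paste(names(reps)[reps < 2], collapse = ","), ")")
  states <- sapply(species, function(sp) {
    cols <- species_samples(em, sp)
    sub <- em$tpm[, cols, drop = FALSE]
    n_pos <- rowSums(sub > presence_threshold)
    n_abs <- rowSums(sub <= absence_threshold)
    present <- if (criterion == "strict") n_pos == ncol(sub) else n_pos >= 2
    absent <- n_abs == ncol(sub)
    ifelse(present, 1L, ifelse(absent, 0L, NA_integer_))
  })
  out <- data.frame(transcript_id = rownames(em$tpm), states,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$ambiguous <- apply(states, 1, anyNA)
  rownames(out) <- NULL
  out
}

#' Call species-specific transcripts
#'
#' A transcript is species-specific iff its (strict-criterion) profile is 1
#' in exactly one species and 0 in the four others; profiles containing an
#' ambiguous state are excluded.
#'
#' @param profiles output of [build_presence_matrix()]
#' @param species species columns to evaluate (default: all non-id,
#'   non-flag columns)
#' @return data.frame `transcript_id`, `species` (the focal species)
#' @export
call_species_specific <- function(profiles,
                                  species = setdiff(names(profiles),
                                                    c("transcript_id",
                                                      "ambiguous"))) {
  st <- as.matrix(profiles[species])
  ok <- !apply(st, 1, anyNA)
  one <- ok & rowSums(st == 1) == 1 & rowSums(st == 0) == length(species) - 1
  idx <- which(one)
  data.frame(
    transcript_id = profiles$transcript_id[idx],
    species = species[apply(st[idx, , drop = FALSE], 1, function(r)
      which(r == 1))],
    stringsAsFactors = FALSE)
}

#' Flag genes whose species-specific transcripts coincide with gene-level
#' up-regulation
#'
#' For each gene, compares gene-level expression (summed transcript TPM,
#' log2(x+1) scale) in the focal species against all other samples with a
#' Welch t-test; p-values are BH-adjusted across genes. A gene is flagged
#' `confounded` iff adjusted p < `alpha` AND the focal-vs-rest log2 fold
#' change is positive.
#'
#' @param em `expression_matrix`
#' @param gene_of named character vector transcript_id -> gene_id
#' @param focal data.frame with columns `gene_id`, `species` (the focal
#'   species of each gene's species-specific transcript)
#' @param alpha BH-adjusted significance threshold (default 0.1)
#' @return data.frame `gene_id`, `species`, `log2fc`, `p`, `padj`,
#'   `confounded`
#' @export
check_upregulation_confound <- function(em, gene_of, focal, alpha = 0.1) {
  gene_ids <- gene_of[rownames(em$tpm)]
  gene_tpm <- rowsum(em$tpm, gene_ids)
  res <- lapply(seq_len(nrow(focal)), function(i) {
    g <- focal$gene_id[i]; sp <- focal$species[i]
    if (!g %in% rownames(gene_tpm)) stop("gene absent from expression: ", g)
    v <- log2(gene_tpm[g, ] + 1)
    grp <- em$samples$species == sp
    x <- v[grp]; y <- v[!grp]
    lfc <- mean(x) - mean(y)
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    data.frame(gene_id = g, species = sp, log2fc = lfc, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out$confounded <- out$padj < alpha & out$log2fc > 0
  out
}
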