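# Splicing-evolution gene classes and the shared statistical utilities:
# two-sided Fisher / hypergeometric over-representation tests, BH
# adjustment, and all-pairs grouped rank tests (Wilcoxon-Holm, DSCF).

GENE_CLASSES <- c("MULTI_SPECIES_UP", "HUMAN_SPECIFIC_UP", "NHP_SPECIFIC_UP",
                  "OTHER_CHANGES", "CONSERVED")

#' Assign genes to splicing-evolution classes
#'
#' A gene's species-specific up events are the union of its
#' species-specific transcript gains, DIU up calls and DEU up calls per
#' species. Classes, by precedence: `MULTI_SPECIES_UP` (up events in >= 2
#' distinct species), `HUMAN_SPECIFIC_UP` / `NHP_SPECIFIC_UP` (up events
#' in exactly one species, human resp. non-human), `OTHER_CHANGES` (any
#' other usage difference recorded, e.g. down calls or group-level
#' differences), `CONSERVED` (no calls).
#'
#' @param universe character vector of evaluated gene ids
#' @param gains data.frame `gene_id`, `species` of species-specific
#'   transcript gains (may be empty)
#' @param diu,deu data.frames `gene_id`, `species`, `call` ("up"/"down")
#' @param other optional data.frame `gene_id` with non-species-specific
#'   usage differences
#' @param human_label species label denoting human (default "H")
#' @return data.frame `gene_id`, `class`, `up_species`
#' @export
assign_splicing_classes <- function(universe, gains = NULL, diu = NULL,
                                    deu = NULL, other = NULL,
                                    human_label = "H") {
  empty <- data.frame(gene_id = character(0), species = character(0),
                      call = character(0), stringsAsFactors = FALSE)
  std <- function(d, with_call) {
    if (is.null(d) || nrow(d) == 0) return(empty)
    if (!with_call) d$call <- "up"
    d[d$gene_id %in% universe, c("gene_id", "species", "call")]
  }
  ev <- rbind(std(gains, FALSE), std(diu, TRUE), std(deu, TRUE))
  res <- lapply(sort(universe), function(g) {
    e <- ev[ev$gene_id == g, , drop = FALSE]
    ups <- sort(unique(e$species[e$call == "up"]))
    has_other <- any(e$call != "up") ||
      (!is.null(other) && g %in% other$gene_id)
    cls <- if (length(ups) >= 2) "MULTI_SPECIES_UP"
    else if (length(ups) == 1 && ups == human_label) "HUMAN_SPECIFIC_UP"
    else if (length(ups) == 1) "NHP_SPECIFIC_UP"
    else if (has_other) "OTHER_CHANGES"
    else "CONSERVED"
    data.frame(gene_id = g, class = cls,
               up_species = paste(ups, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fisher / hypergeometric enrichment of a 2x2 table
#'
#' Fisher mode: two-sided exact p-value by point-probability summation of
#' the hypergeometric distribution (all tables with the observed margins
#' whose probability does not exceed that of the observed table, within a
#' relative tolerance of 1e-7), odds ratio (a d)/(b c) with zero cells
#' reported as 0 or Inf with `or_boundary = TRUE` (no continuity
#' correction). Hypergeometric mode: upper-tail over-representation
#' p-value and fold change observed/expected.
#'
#' @param a,b,c_,d the 2x2 counts: a = focal & annotated, b = focal &
#'   not, c_ = background-only & annotated, d = background-only & not
#' @param mode `"fisher"` or `"hypergeometric"`
#' @return list: `a`,`b`,`c`,`d`, `odds_ratio`, `p`, `or_boundary`,
#'   `mode`, and `fold_change` in hypergeometric mode
#' @export
fisher_or_hypergeometric <- function(a, b, c_, d,
                                     mode = c("fisher", "hypergeometric")) {
  mode <- match.arg(mode)
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  m <- a + c_          # annotated total
  n <- b + d           # unannotated total
  k <- a + b           # focal set size
  or_boundary <- (a == 0 || d == 0 || b == 0 || c_ == 0)
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  if (a == 0 || d == 0) or <- 0
  if (mode == "fisher") {
    lo <- max(0L, k - n); hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
    p <- min(1, p)
    list(a = a, b = b, c = c_, d = d, odds_ratio = or, p = p,
         or_boundary = or_boundary, mode = mode)
  } else {
    p <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
    expected <- k * m / (m + n)
    fc <- if (expected == 0) NaN else a / expected
    list(a = a, b = b, c = c_, d = d, odds_ratio = or, p = p,
         or_boundary = or_boundary, fold_change = fc, mode = mode)
  }
}

#' Enrichment of a gene set against an annotation list
#'
#' Convenience wrapper building the 2x2 table from a focal set, an
#' annotation gene list and an explicit background universe (the
#' background is always an explicit argument; no implicit genome-wide
#' default).
#'
#' @param set focal gene ids (must be contained in `background`)
#' @param annotation annotation gene ids
#' @param background background universe
#' @param mode passed to [fisher_or_hypergeometric()]
#' @return as [fisher_or_hypergeometric()]
#' @export
enrich_set <- function(set, annotation, background,
                       mode = c("fisher", "hypergeometric")) {
  if (!all(set %in% background)) stop("set must be a subset of background")
  if (length(annotation) == 0) stop("empty annotation list")
  if (length(background) < length(set)) stop("background smaller than set")
  ann <- intersect(annotation, background)
  a <- length(intersect(set, ann))
  b <- length(set) - a
  c_ <- length(setdiff(ann, set))
  d <- length(background) - a - b - c_
  fisher_or_hypergeometric(a, b, c_, d, mode = match.arg(mode))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; stable under
#' input reordering. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0,1\] (NA passed through)
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' All-pairs grouped rank tests
#'
#' Default method: two-sided Wilcoxon rank-sum tests for every class pair
#' with Holm adjustment. DSCF mode: the Dwass-Steel-Critchlow-Fligner
#' all-pairs procedure — each pairwise standardized rank-sum statistic is
#' referred to the studentized range distribution with k groups.
#'
#' @param values numeric vector
#' @param class factor/character of group labels, parallel to `values`
#' @param method `"wilcoxon"` (Holm-adjusted) or `"dscf"`
#' @return data.frame per pair: `class1`, `class2`, `statistic`, `p`,
#'   `p_adj`, `direction` (sign of median difference class1 - class2)
#' @export
grouped_rank_tests <- function(values, class, method = c("wilcoxon", "dscf")) {
  method <- match.arg(method)
  class <- as.character(class)
  groups <- sort(unique(class))
  if (length(groups) < 2) stop("need >= 2 classes")
  sizes <- table(class)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(groups))
    warning("class(es) with < 2 values skipped: ",
            paste(setdiff(groups, usable), collapse = ","))
  groups <- usable
  k <- length(groups)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- values[class == pr[1]]; y <- values[class == pr[2]]
    dir <- sign(stats::median(x) - stats::median(y))
    if (method == "wilcoxon") {
      if (length(unique(c(x, y))) == 1) {
        # fully tied samples carry no rank information
        wt <- list(statistic = length(x) * length(y) / 2, p.value = 1)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))
      }
      data.frame(class1 = pr[1], class2 = pr[2],
                 statistic = unname(wt$statistic), p = wt$p.value,
                 direction = dir, stringsAsFactors = FALSE)
    } else {
      n1 <- length(x); n2 <- length(y); N <- n1 + n2
      r <- rank(c(x, y))
      W <- sum(r[seq_len(n1)])
      ties <- table(r)
      sigma2 <- (n1 * n2 / 24) *
        (N + 1 - sum((ties^3 - ties) / ((N) * (N - 1))))
      z <- (W - n1 * (N + 1) / 2) / sqrt(sigma2)
      p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      data.frame(class1 = pr[1], class2 = pr[2], statistic = z, p = p,
                 direction = dir, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (method == "wilcoxon")
    stats::p.adjust(out$p, method = "holm") else out$p
  out[c("class1", "class2", "statistic", "p", "p_adj", "direction")]
}
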