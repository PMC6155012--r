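# Clone-sharing analyses: clone x site-isotype abundance matrices, clone-
# distribution clustering, subset-pair sharing percentages, GC-membership
# rates, per-donor Fisher exact overlap tests combined by Fisher's method,
# and the cross-donor public-clone rate.

#' Clone x site-isotype abundance matrix
#'
#' Rows are clones, columns are combinations of the grouping labels
#' (default site and isotype); cells count unique sequences (rows of the
#' input).  Row sums equal clone sizes by construction.  For display use
#' `log10(n + 1)` so absent combinations map to 0.
#'
#' @param records Rearrangement data frame with `clone_id` and the grouping
#'   columns.
#' @param by Grouping columns, default `c("site", "c_call")`.
#' @return Integer matrix, rownames = clone ids, colnames =
#'   `site.isotype` labels.
#' @export
clone_abundance_matrix <- function(records, by = c("site", "c_call")) {
  miss <- setdiff(c("clone_id", by), colnames(records))
  if (length(miss)) stopf("records lack column '%s'", miss[1])
  if (anyNA(records[c("clone_id", by)])) stopf("unlabeled sequence in records")
  col_key <- do.call(paste, c(records[by], sep = "."))
  tab <- table(records$clone_id, col_key)
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat
}

#' Display transform for abundance matrices
#'
#' @param mat Count matrix.
#' @return `log10(mat + 1)`.
#' @export
log_display <- function(mat) log10(mat + 1)

#' Hierarchical clustering of site-isotype clone distributions
#'
#' Each column is normalized by its total (the clone-frequency distribution
#' at that site-isotype), columns are compared by Manhattan (L1) distance,
#' and agglomerated with the Ward.D method.
#'
#' @param mat Clone x column count matrix from [clone_abundance_matrix()].
#' @param method Agglomeration method, default `"ward.D"`.
#' @return An [stats::hclust] object over columns.
#' @export
hcluster_site_isotype <- function(mat, method = "ward.D") {
  if (ncol(mat) < 2) stopf("need at least 2 columns")
  totals <- colSums(mat)
  if (any(totals == 0)) stopf("zero-total column: %s", colnames(mat)[totals == 0][1])
  freq <- sweep(mat, 2, totals, "/")
  d <- stats::dist(t(freq), method = "manhattan")
  stats::hclust(d, method = method)
}

#' Sharing percentages between two subsets across sites
#'
#' For subset A at site s1 against subset B at site s2: the numerator is
#' the number of unique sequences of subset A at s1 whose clone contains at
#' least one member of subset B at s2; the denominator is all unique
#' sequences of subset A at s1.  The two directions generally differ and
#' both are meaningful; call the function twice to get both.  Setting
#' `weighted = TRUE` weights sequences by duplicate count instead.
#'
#' @param records Rearrangement data frame with `clone_id`, `subset`,
#'   `site`.
#' @param subset_a,subset_b Subset labels.
#' @param weighted Duplicate-weight the numerator and denominator.
#' @return Data frame: `site_a`, `site_b`, `n`, `shared`, `percent`
#'   (NA when the denominator is empty).
#' @export
sharing_percentages <- function(records, subset_a, subset_b, weighted = FALSE) {
  sites <- sort(unique(records$site))
  w <- if (weighted) records$duplicate_count else rep(1, nrow(records))
  out <- list()
  for (s1 in sites) {
    a_rows <- records$subset == subset_a & records$site == s1
    for (s2 in sites) {
      b_clones <- unique(records$clone_id[records$subset == subset_b &
                                          records$site == s2])
      denom <- sum(w[a_rows])
      num <- sum(w[a_rows & records$clone_id %in% b_clones])
      out[[length(out) + 1L]] <- data.frame(
        site_a = s1, site_b = s2, n = denom, shared = num,
        percent = if (denom > 0) 100 * num / denom else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Germinal-centre membership rates of clone classes
#'
#' A clone belongs to a class when it contains at least one sequence of the
#' defining subset (optionally restricted to given sites); the rate is the
#' percentage of class clones that also contain a GC-subset member.
#'
#' @param records Rearrangement data frame with `clone_id` and `subset`.
#' @param classes Named list of defining subset labels, e.g.
#'   `list(mz = "mz", igm_only = "igm_only")`.
#' @param gc_subset GC subset label, default `"gc"`.
#' @param sites Optional site restriction for class membership and GC
#'   membership.
#' @return Data frame: `class`, `n_clones`, `n_with_gc`, `percent` (raw)
#'   and `percent_1dp` (rounded to one decimal for reporting).
#' @export
gc_membership_rates <- function(records, classes, gc_subset = "gc",
                                sites = NULL) {
  keep <- if (is.null(sites)) rep(TRUE, nrow(records)) else records$site %in% sites
  gc_clones <- unique(records$clone_id[keep & records$subset == gc_subset])
  out <- lapply(names(classes), function(cl) {
    cls_clones <- unique(records$clone_id[keep & records$subset == classes[[cl]]])
    n <- length(cls_clones)
    nw <- sum(cls_clones %in% gc_clones)
    data.frame(class = cl, n_clones = n, n_with_gc = nw,
               percent = if (n > 0) 100 * nw / n else 0,
               percent_1dp = if (n > 0) round(100 * nw / n, 1) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` compared against a chi-squared distribution with
#' `2k` degrees of freedom.
#'
#' @param p Vector of p-values in (0, 1].
#' @return List: `X2`, `df`, `p`.
#' @export
fisher_method <- function(p) {
  stopifnot(length(p) >= 1, all(p > 0), all(p <= 1))
  X2 <- -2 * sum(log(p))
  list(X2 = X2, df = 2L * length(p),
       p = stats::pchisq(X2, df = 2L * length(p), lower.tail = FALSE))
}

#' IgA-overlap test between two clone classes
#'
#' Per donor, builds the 2x2 table of clone class (contains subset A vs
#' contains subset B) against whether the clone contains an IgA member, and
#' applies the two-sided Fisher exact test (probability-mass rule).  The
#' per-donor p-values are combined by Fisher's method (df = 2 x number of
#' included donors); donors with a degenerate table (a zero margin) are
#' excluded and reported.  A pooled-table Fisher exact test over all donors
#' is reported alongside as a surrogate.
#'
#' @param records Rearrangement data frame with `clone_id`, `subset`,
#'   `c_call`, `donor`.
#' @param class_a,class_b Defining subset labels of the two clone classes.
#' @param iga_isotype Isotype label marking IgA members, default `"IgA"`.
#' @param sites Optional site restriction.
#' @return List: `per_donor` (data frame with counts and p), `combined`
#'   (Fisher's-method result), `pooled_table`, `pooled_p`, `excluded`.
#' @export
iga_overlap_test <- function(records, class_a = "mz", class_b = "igm_only",
                             iga_isotype = "IgA", sites = NULL) {
  keep <- if (is.null(sites)) rep(TRUE, nrow(records)) else records$site %in% sites
  rec <- records[keep, , drop = FALSE]
  iga_clones <- unique(rec$clone_id[rec$c_call == iga_isotype])
  donors <- sort(unique(rec$donor))
  rows <- list(); excluded <- character(0)
  for (d in donors) {
    rd <- rec[rec$donor == d, , drop = FALSE]
    a_cl <- unique(rd$clone_id[rd$subset == class_a])
    b_cl <- unique(rd$clone_id[rd$subset == class_b])
    a_with <- sum(a_cl %in% iga_clones); b_with <- sum(b_cl %in% iga_clones)
    tab <- matrix(c(a_with, length(a_cl) - a_with,
                    b_with, length(b_cl) - b_with), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || all(colSums(tab) == c(0, 0))) {
      excluded <- c(excluded, d)
      next
    }
    p <- stats::fisher.test(tab)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      donor = d, a_with_iga = a_with, a_total = length(a_cl),
      b_with_iga = b_with, b_total = length(b_cl), p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no donor with a non-degenerate table")
  per_donor <- do.call(rbind, rows)
  combined <- fisher_method(per_donor$p)
  pooled <- matrix(c(sum(per_donor$a_with_iga),
                     sum(per_donor$a_total) - sum(per_donor$a_with_iga),
                     sum(per_donor$b_with_iga),
                     sum(per_donor$b_total) - sum(per_donor$b_with_iga)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("class_a", "class_b"),
                                   c("with_iga", "without_iga")))
  list(per_donor = per_donor, combined = combined,
       pooled_table = pooled,
       pooled_p = stats::fisher.test(pooled)$p.value,
       excluded = excluded)
}

#' Cross-donor public-clone rate
#'
#' Percentage of unique sequences whose exact nucleotide sequence occurs in
#' more than one donor.
#'
#' @param records Rearrangement data frame with `sequence` and `donor`
#'   (rows = unique sequences).
#' @return List: `n_total`, `n_shared`, `percent`.
#' @export
public_clone_rate <- function(records) {
  if (length(unique(records$donor)) < 2) stopf("need at least 2 donors")
  donors_per_seq <- tapply(records$donor, records$sequence,
                           function(d) length(unique(d)))
  shared_seqs <- names(donors_per_seq)[donors_per_seq > 1]
  n_shared <- sum(records$sequence %in% shared_seqs)
  list(n_total = nrow(records), n_shared = n_shared,
       percent = 100 * n_shared / nrow(records))
}
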