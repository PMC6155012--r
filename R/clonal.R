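# Clonal grouping: V/J/junction-length partition, 5-mer-context-weighted
# normalized junction distance, single-linkage clone definition at a fixed
# threshold, distance-to-nearest diagnostics, germline-rooted lineage trees.

#' Read a 5-mer substitution weight model
#'
#' TSV with columns `fivemer`, `A`, `C`, `G`, `T`: the weight of observing a
#' substitution to each target base given the 5-mer context centred on the
#' mutated position.  A toy non-uniform model (synthetic weights, not the
#' published hypermutation tables) ships in `inst/extdata`.
#'
#' @param path TSV path; default the bundled toy model.
#' @return Numeric matrix, rownames = 5-mers, columns A/C/G/T.
#' @export
read_substitution_model <- function(path = system.file("extdata", "s5f_toy_synthetic.tsv",
                                                       package = "mzatlas")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, c("A", "C", "G", "T")])
  rownames(m) <- tab$fivemer
  if (any(m <= 0)) stopf("substitution weights must be positive")
  m
}

model_weight <- function(model, context, target) {
  if (is.null(model)) return(rep(1, length(context)))
  w <- model[cbind(match(context, rownames(model)), match(target, colnames(model)))]
  w[is.na(w)] <- 1  # incomplete/edge contexts fall back to uniform
  w
}

#' Weighted normalized junction distance
#'
#' Counts nucleotide differences between two equal-length junctions, each
#' difference weighted by a 5-mer context model of hypermutation targeting
#' and substitution, then normalizes by the junction length.  The weight of
#' a mismatch is symmetrized as the mean of the two directional weights
#' (a->b in a's context, b->a in b's context).  Positions where either
#' string has N are skipped and excluded from the evaluated length.  With a
#' uniform model (`model = NULL`) the distance is exactly the normalized
#' Hamming distance.
#'
#' @param a,b Equal-length junction strings.
#' @param model 5-mer weight matrix from [read_substitution_model()], or
#'   `NULL` for uniform weights.
#' @return Normalized distance (>= 0).
#' @export
weighted_junction_distance <- function(a, b, model = NULL) {
  if (nchar(a) != nchar(b)) stopf("junctions have unequal lengths")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- av != "N" & bv != "N"
  L <- sum(ok)
  if (L == 0) return(0)
  mm <- which(ok & av != bv)
  if (!length(mm)) return(0)
  ctx <- function(v, i) {
    vapply(i, function(k) {
      if (k - 2L < 1L || k + 2L > length(v)) NA_character_
      else paste(v[(k - 2L):(k + 2L)], collapse = "")
    }, character(1))
  }
  ca <- ctx(av, mm)
  cb <- ctx(bv, mm)
  wa <- model_weight(model, ca, bv[mm])
  wb <- model_weight(model, cb, av[mm])
  sum((wa + wb) / 2) / L
}

collapse_gene <- function(call) sub("\\*.*$", "", call)

#' Partition rearrangements by V gene, J gene and junction length
#'
#' Allele suffixes (`*01`, `*02`, ...) are collapsed to the gene level so
#' allele miscalls do not split true clones.
#'
#' @param records Data frame with `v_call`, `j_call`, `junction`.
#' @return List of integer row-index vectors, named by the
#'   `V|J|length` group key.
#' @export
vj_partition <- function(records) {
  if (any(is.na(records$v_call)) || any(is.na(records$j_call))) {
    stopf("missing V or J calls")
  }
  key <- paste(collapse_gene(records$v_call), collapse_gene(records$j_call),
               nchar(records$junction), sep = "|")
  split(seq_len(nrow(records)), key)
}

# single-linkage connected components under d < threshold (strict), via
# union-find; returns component id per element in input order
single_linkage_components <- function(D, threshold) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

group_distance_matrix <- function(junctions, model) {
  n <- length(junctions)
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- weighted_junction_distance(junctions[i],
                                                         junctions[j], model)
      }
    }
  }
  D
}

#' Define clones within V/J/length groups
#'
#' Within each group, sequences are linked when their weighted normalized
#' junction distance is strictly below the threshold; clones are the
#' single-linkage connected components.  Clone ids are globally unique and
#' assigned deterministically by first-seen member order.
#'
#' @param records Rearrangement data frame.
#' @param threshold Distance threshold in (0, 1), default 0.2.
#' @param model Substitution model (or `NULL` for uniform).
#' @return `records` with a `clone_id` column (`clone_0001`, ...).
#' @export
define_clones <- function(records, threshold = 0.2, model = NULL) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  groups <- vj_partition(records)
  clone_id <- rep(NA_character_, nrow(records))
  assign_order <- integer(0)
  comp_of <- integer(nrow(records))
  group_of <- character(nrow(records))
  for (g in names(groups)) {
    idx <- groups[[g]]
    D <- group_distance_matrix(records$junction[idx], model)
    comp <- single_linkage_components(D, threshold)
    comp_of[idx] <- comp
    group_of[idx] <- g
  }
  key <- paste(group_of, comp_of, sep = "#")
  first_seen <- unique(key)  # input order
  clone_id <- sprintf("clone_%04d", match(key, first_seen))
  records$clone_id <- clone_id
  records
}

#' Distance-to-nearest diagnostics
#'
#' Per-sequence minimum weighted normalized distance to any other sequence
#' in its V/J/length group.  Singletons are undefined (NA), not zero, and
#' are excluded from the histogram.  A diagnostic threshold suggestion is
#' the deepest density valley between the two largest modes of the nearest-
#' distance distribution; the operational default threshold remains 0.2.
#'
#' @param records Rearrangement data frame.
#' @param model Substitution model (or `NULL`).
#' @return List: `distances` (per record, NA for singletons), `suggested`
#'   (numeric or NA).
#' @export
distance_to_nearest <- function(records, model = NULL) {
  groups <- vj_partition(records)
  d <- rep(NA_real_, nrow(records))
  for (idx in groups) {
    if (length(idx) < 2) next
    D <- group_distance_matrix(records$junction[idx], model)
    diag(D) <- Inf
    d[idx] <- apply(D, 1, min)
  }
  finite <- d[!is.na(d)]
  if (!length(finite)) {
    warning("all sequences are singletons in their V/J/length groups")
    return(list(distances = d, suggested = NA_real_))
  }
  suggested <- NA_real_
  if (length(unique(finite)) > 3) {
    dens <- stats::density(finite, from = 0, to = max(finite) + 0.05)
    y <- dens$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(peaks) >= 2) {
      top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
      valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
      suggested <- dens$x[valley]
    }
  }
  list(distances = d, suggested = suggested)
}

hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (length(av) != length(bv)) stopf("sequences have unequal lengths")
  ok <- av != "N" & bv != "N"
  sum(av[ok] != bv[ok])
}

#' Build a germline-rooted lineage tree for one clone
#'
#' Minimum-spanning tree over the clone members plus the germline context,
#' on substitution-count distance, rooted at the germline (Prim's
#' algorithm).  Ties among minimum-weight attachments are broken by higher
#' duplicate count, then lexicographic sequence id.  A parsimony-style score
#' (total edge weight) is reported.  This is a parsimony-style approximation
#' to full maximum-parsimony tree search; no internal nodes are inferred.
#'
#' @param members Data frame with `sequence_id`, `sequence`, and optionally
#'   `duplicate_count` (default 1); at least 2 rows.
#' @param germline Germline sequence string (same length as members; N
#'   positions are skipped in distances).
#' @return A `lineage_tree`: list with `edges` (parent, child, weight),
#'   `root = "germline"`, `nodes`, `parsimony_score`.
#' @export
build_lineage <- function(members, germline) {
  if (nrow(members) < 2) stopf("lineage requires a clone with >= 2 members")
  ids <- c("germline", members$sequence_id)
  seqs <- c(germline, members$sequence)
  dup <- c(Inf, members$duplicate_count %||% rep(1, nrow(members)))
  if (is.null(members$duplicate_count)) dup <- c(Inf, rep(1, nrow(members)))
  n <- length(ids)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) D[i, j] <- D[j, i] <- hamming(seqs[i], seqs[j])
  }
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- data.frame(parent = character(0), child = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  while (!all(in_tree)) {
    cand <- expand.grid(from = which(in_tree), to = which(!in_tree))
    w <- D[cbind(cand$from, cand$to)]
    best_w <- min(w)
    sel <- cand[w == best_w, , drop = FALSE]
    # tie-break on the joining node: higher duplicate count, then lex id
    ord <- order(-dup[sel$to], ids[sel$to], ids[sel$from])
    pick <- sel[ord[1], ]
    edges <- rbind(edges, data.frame(parent = ids[pick$from],
                                     child = ids[pick$to],
                                     weight = best_w,
                                     stringsAsFactors = FALSE))
    in_tree[pick$to] <- TRUE
  }
  structure(
    list(edges = edges, root = "germline", nodes = ids,
         parsimony_score = sum(edges$weight)),
    class = "lineage_tree"
  )
}

#' Serialise a lineage tree as Newick
#'
#' @param tree A `lineage_tree`.
#' @param path Optional output file; when `NULL` the string is returned.
#' @return Newick string (invisibly if written to file).
#' @export
lineage_newick <- function(tree, path = NULL) {
  kids <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
  render <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(node)
    inner <- vapply(ch, function(e) {
      paste0(render(tree$edges$child[e]), ":", tree$edges$weight[e])
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", node)
  }
  nwk <- paste0(render(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
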