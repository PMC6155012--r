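# Suspension-cytometry subset analysis: arcsinh transform, gating, 2-D
# embedding, node clustering on the embedding, rule-based subset bubbles,
# median profiles, sample-level MDS, subset-level hierarchical clustering.

#' Arcsinh-transform marker intensities
#'
#' Applies `asinh(x / cofactor)` to every marker column (mass-cytometry
#' convention, cofactor 5).  Monotone, so event rank orders are preserved.
#'
#' @param table Event table.
#' @param cofactor Positive real, default 5.
#' @return Event table with transformed marker columns.
#' @export
transform_intensities <- function(table, cofactor = 5) {
  if (!is.numeric(cofactor) || cofactor <= 0) stopf("cofactor must be > 0")
  mk <- marker_names(table)
  table[mk] <- lapply(table[mk], function(x) asinh(x / cofactor))
  table
}

#' Construct a threshold gate
#'
#' @param marker Marker name.
#' @param threshold Numeric cut.
#' @param side `"above"` keeps events with intensity >= threshold,
#'   `"below"` keeps events with intensity < threshold.
#' @return A `gate` object.
#' @export
gate <- function(marker, threshold, side = c("above", "below")) {
  side <- match.arg(side)
  structure(list(type = "threshold", marker = marker, threshold = threshold,
                 side = side), class = "gate")
}

#' Construct a two-marker polygon gate
#'
#' @param marker_x,marker_y Marker names for the two axes.
#' @param px,py Polygon vertex coordinates (closed implicitly).
#' @return A `gate` object.
#' @export
polygon_gate <- function(marker_x, marker_y, px, py) {
  stopifnot(length(px) == length(py), length(px) >= 3)
  structure(list(type = "polygon", marker_x = marker_x, marker_y = marker_y,
                 px = px, py = py), class = "gate")
}

point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Apply an ordered list of gates to an event table
#'
#' Gates are applied sequentially; an event is retained iff it satisfies
#' every gate.  Applying the same gates twice is idempotent.
#'
#' @param table Event table.
#' @param gates List of [gate()] / [polygon_gate()] objects.
#' @param verbose Log retained counts per gate.
#' @return The gated event table (rows preserved in order).
#' @export
gate_events <- function(table, gates, verbose = FALSE) {
  mk <- marker_names(table)
  for (g in gates) {
    needed <- if (g$type == "threshold") g$marker else c(g$marker_x, g$marker_y)
    missing <- setdiff(needed, mk)
    if (length(missing)) stopf("gate references unknown marker: %s", missing[1])
    keep <- if (g$type == "threshold") {
      if (g$side == "above") table[[g$marker]] >= g$threshold
      else table[[g$marker]] < g$threshold
    } else {
      point_in_polygon(table[[g$marker_x]], table[[g$marker_y]], g$px, g$py)
    }
    table <- table[keep, , drop = FALSE]
    if (verbose) {
      message(sprintf("gate %s: %d events retained",
                      if (g$type == "threshold") g$marker else "polygon",
                      nrow(table)))
    }
  }
  table
}

# Exact (O(n^2)) t-SNE with perplexity calibration; adequate for the node- or
# subsample-level inputs used here.  Guarded against large n.
tsne_exact <- function(X, perplexity = 30, n_iter = 400, seed = NULL) {
  n <- nrow(X)
  if (n > 4000) stopf("exact t-SNE limited to 4000 rows; subsample or use PCA")
  if (n < 4) stopf("too few rows for t-SNE")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  with_seed(seed, {
    D <- as.matrix(stats::dist(X))^2
    P <- matrix(0, n, n)
    logU <- log(perplexity)
    for (i in seq_len(n)) {
      beta <- 1; betamin <- -Inf; betamax <- Inf
      Di <- D[i, -i]
      for (it in 1:50) {
        Pi <- exp(-Di * beta)
        sumP <- sum(Pi)
        H <- log(sumP) + beta * sum(Di * Pi) / sumP
        if (!is.finite(H) || abs(H - logU) < 1e-5) break
        if (H > logU) {
          betamin <- beta
          beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
        } else {
          betamax <- beta
          beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
        }
      }
      P[i, -i] <- Pi / sumP
    }
    P <- (P + t(P)) / (2 * n)
    P <- pmax(P, 1e-12)
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    for (it in seq_len(n_iter)) {
      mom <- if (it < 100) 0.5 else 0.8
      Pit <- if (it <= 100) P * 4 else P
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (rowSums(L) * Y - L %*% Y)
      inc <- mom * inc - 200 * grad
      Y <- inc + Y
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

pca_2d <- function(X) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  out <- matrix(0, nrow(X), 2)
  out[, seq_len(k)] <- pc$x[, seq_len(k)]
  # fix component signs for cross-platform determinism
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) out[, j] <- -out[, j]
  }
  out
}

# For each row of X, index of its nearest row in R (Euclidean), chunked.
nearest_row <- function(X, R) {
  rsq <- rowSums(R^2)
  out <- integer(nrow(X))
  step <- 2000L
  for (s in seq(1L, nrow(X), by = step)) {
    e <- min(s + step - 1L, nrow(X))
    D2 <- outer(rowSums(X[s:e, , drop = FALSE]^2), rsq, "+") -
      2 * tcrossprod(X[s:e, , drop = FALSE], R)
    out[s:e] <- max.col(-D2, ties.method = "first")
  }
  out
}

#' Embed events into two dimensions
#'
#' Neighborhood-preserving 2-D embedding with a pluggable backend:
#' `"tsne"` (default; exact t-SNE for up to `max_exact` events, above which
#' a seeded subsample is embedded and the remaining events are placed at the
#' coordinates of their nearest subsampled neighbour in marker space, the
#' usual down-sampling scheme for event-level embeddings) or `"pca"`
#' (deterministic linear projection; fast screening).  Output is row-aligned
#' with the input.
#'
#' @param table Event table (arcsinh scale).
#' @param markers Markers to embed on; default the nine subset-definition
#'   markers intersected with the panel.
#' @param seed Integer seed (subsample and t-SNE initialisation).
#' @param method `"tsne"` or `"pca"`.
#' @param perplexity t-SNE perplexity.
#' @param max_exact Event count above which the subsample-and-project
#'   scheme is used.
#' @return Numeric n x 2 matrix, columns `tsne1`, `tsne2`.
#' @export
embed_2d <- function(table, markers = NULL, seed = NULL,
                     method = c("tsne", "pca"), perplexity = 30,
                     max_exact = 1500) {
  method <- match.arg(method)
  mk <- marker_names(table)
  if (is.null(markers)) {
    markers <- intersect(clustering_markers(), mk)
  }
  stopifnot(length(markers) >= 1, all(markers %in% mk))
  if (nrow(table) < 2) stopf("need at least 2 events to embed")
  X <- as.matrix(table[markers])
  Y <- if (method == "pca") {
    pca_2d(X)
  } else if (nrow(X) <= max_exact) {
    tsne_exact(X, perplexity = perplexity, seed = seed)
  } else {
    with_seed(seed, {
      sub <- sort(sample.int(nrow(X), max_exact))
      Ys <- tsne_exact(X[sub, , drop = FALSE], perplexity = perplexity,
                       seed = NULL)
      nn <- nearest_row(X, X[sub, , drop = FALSE])
      Ys[nn, , drop = FALSE]
    })
  }
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Default subset-clustering marker list
#'
#' The nine markers used to define the known B cell subsets in the
#' suspension embedding: CD10, CD24, CD27, CD38, IgA, IgD, IgM, IgG, HLA-DR.
#'
#' @return Character vector.
#' @export
clustering_markers <- function() {
  c("CD10", "CD24", "CD27", "CD38", "IgA", "IgD", "IgM", "IgG", "HLA-DR")
}

#' Cluster embedded events into nodes
#'
#' Partitions events into `k` nodes by k-means on the two embedding
#' coordinates only (the SPADE-on-viSNE scheme), then computes per-node
#' medians on *all* panel markers, including markers that were not part of
#' the embedding.
#'
#' @param coords n x 2 embedding from [embed_2d()].
#' @param table Event table aligned with `coords`.
#' @param k Node count (2 <= k <= n), default 100.
#' @param seed Integer seed for k-means initialisation.
#' @return A `node_graph`: list with `membership` (node id per event),
#'   `medians` (k x markers matrix), `sizes`, `coords`.
#' @export
cluster_nodes <- function(coords, table, k = 100, seed = NULL) {
  n <- nrow(table)
  stopifnot(nrow(coords) == n)
  if (k < 2 || k > n) stopf("k must be in [2, number of events]")
  mk <- marker_names(table)
  membership <- with_seed(seed, {
    if (k == n) {
      seq_len(n)
    } else {
      km <- suppressWarnings(
        stats::kmeans(coords, centers = k, nstart = 5, iter.max = 200,
                      algorithm = "Lloyd"))
      km$cluster
    }
  })
  med <- matrix(NA_real_, k, length(mk), dimnames = list(NULL, mk))
  for (j in seq_along(mk)) {
    med[, j] <- tapply(table[[mk[j]]], factor(membership, levels = seq_len(k)),
                       stats::median)
  }
  structure(
    list(membership = membership, medians = med,
         sizes = as.integer(table(factor(membership, levels = seq_len(k)))),
         coords = coords),
    class = "node_graph"
  )
}

#' Default subset bubble rules
#'
#' Ordered rule list over node medians.  Each rule names positive and
#' negative markers; a node matches when all positive markers exceed their
#' thresholds and all negative markers fall below.  The first matching rule
#' in priority order wins (GC, plasmablast, transitional, precursor, MZ,
#' IgM-only, switched subsets, naive); unmatched nodes go to `"other"`.
#' Default thresholds are midpoints between the synthetic negative and
#' positive archetype locations; supply per-marker thresholds for real data.
#'
#' @param threshold Default per-marker cut (scalar) or named vector of
#'   marker-specific cuts.
#' @return List of rules, in priority order.
#' @export
default_bubble_rules <- function(threshold = 1.9) {
  rule <- function(name, pos, neg = character(0)) {
    list(name = name, pos = pos, neg = neg)
  }
  list(
    rule("gc",          pos = c("CD19", "CD20", "CD10", "CD38"), neg = "IgD"),
    rule("plasmablast", pos = c("CD27", "CD38"), neg = c("CD20", "CD10")),
    rule("transitional", pos = c("CD19", "CD20", "CD10")),
    rule("precursor",   pos = c("CD19", "CD20", "IgM", "IgD", "CD45RB"),
                        neg = c("CD27", "CD10")),
    rule("mz",          pos = c("CD19", "CD20", "CD27", "IgM", "IgD"),
                        neg = "CD10"),
    rule("igm_only",    pos = c("CD27", "IgM"), neg = c("IgD", "CD10")),
    rule("csm_igg",     pos = c("CD27", "IgG"), neg = c("IgM", "IgD")),
    rule("csm_iga",     pos = c("CD27", "IgA"), neg = c("IgM", "IgD")),
    rule("cd27neg_igg", pos = "IgG", neg = c("CD27", "IgM", "IgD", "CD10")),
    rule("cd27neg_iga", pos = "IgA", neg = c("CD27", "IgM", "IgD", "CD10")),
    rule("cd27neg_igm", pos = c("CD19", "IgM"),
                        neg = c("CD27", "IgD", "CD10", "IgG", "IgA")),
    rule("naive",       pos = c("CD19", "CD20", "IgM", "IgD"),
                        neg = c("CD27", "CD10", "CD45RB"))
  ) -> rules
  attr(rules, "threshold") <- threshold
  rules
}

#' Assign nodes to subset bubbles
#'
#' @param graph A `node_graph` from [cluster_nodes()].
#' @param rules Rule list from [default_bubble_rules()] (or the same shape).
#' @return Data frame `node`, `subset` with one row per node; unmatched
#'   nodes labelled `"other"`.
#' @export
assign_bubbles <- function(graph, rules = default_bubble_rules()) {
  med <- graph$medians
  thr <- attr(rules, "threshold") %||% 1.9
  thr_of <- function(m) if (length(thr) == 1L) thr else thr[[m]]
  subset <- rep("other", nrow(med))
  for (r in rules) {
    bad <- setdiff(c(r$pos, r$neg), colnames(med))
    if (length(bad)) stopf("rule '%s' references unknown marker %s", r$name, bad[1])
    ok <- rep(TRUE, nrow(med))
    for (m in r$pos) ok <- ok & med[, m] >= thr_of(m)
    for (m in r$neg) ok <- ok & med[, m] < thr_of(m)
    subset[subset == "other" & ok] <- r$name
  }
  data.frame(node = seq_len(nrow(med)), subset = subset,
             stringsAsFactors = FALSE)
}

#' Propagate bubble assignments to events
#'
#' @param graph A `node_graph`.
#' @param bubbles Node assignment from [assign_bubbles()].
#' @return Character vector of per-event subset labels.
#' @export
event_subsets <- function(graph, bubbles) {
  bubbles$subset[graph$membership]
}

#' Median expression profiles and subset fractions
#'
#' @param table Event table (with `tissue` column).
#' @param subset Per-event subset labels ([event_subsets()]).
#' @return List: `medians` (long data frame tissue/subset/marker/median) and
#'   `fractions` (tissue/subset/fraction; fractions within a tissue sum
#'   to 1).  Empty subsets are simply absent (missing, not zero).
#' @export
subset_medians <- function(table, subset) {
  stopifnot(length(subset) == nrow(table))
  mk <- marker_names(table)
  key <- interaction(table$tissue, subset, drop = TRUE, sep = "\r")
  med_list <- lapply(mk, function(m) tapply(table[[m]], key, stats::median))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  medians <- do.call(rbind, lapply(seq_along(mk), function(j) {
    data.frame(tissue = parts[, 1], subset = parts[, 2], marker = mk[j],
               median = as.numeric(med_list[[j]]), stringsAsFactors = FALSE)
  }))
  cnt <- table(table$tissue, subset)
  fr <- as.data.frame(prop.table(cnt, margin = 1), stringsAsFactors = FALSE)
  names(fr) <- c("tissue", "subset", "fraction")
  fr <- fr[fr$fraction > 0 | TRUE, ]
  list(medians = medians, fractions = fr)
}

#' Metric MDS of sample profiles with Kruskal stress
#'
#' Classical (Torgerson) scaling to two dimensions of the Euclidean
#' distances between per-sample profile vectors; reports Kruskal stress-1,
#' `sqrt(sum((d - delta)^2) / sum(delta^2))`, as the information lost.
#'
#' @param profiles Numeric matrix, samples x features (rownames = sample
#'   ids).
#' @return List: `coords` (samples x 2), `stress`.
#' @export
mds_samples <- function(profiles) {
  stopifnot(is.matrix(profiles) || is.data.frame(profiles))
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stopf("need at least 3 samples for MDS")
  delta <- stats::dist(profiles)
  if (max(delta) == 0) stopf("degenerate (all-identical) profiles")
  coords <- stats::cmdscale(delta, k = 2)
  d <- stats::dist(coords)
  stress <- sqrt(sum((d - delta)^2) / sum(delta^2))
  list(coords = coords, stress = stress)
}

#' Hierarchical clustering of subset profiles
#'
#' Agglomerates subsets on the Euclidean distance between their median
#' expression vectors over all measured markers.
#'
#' @param profiles Numeric matrix, subsets x markers (rownames = subsets).
#' @param method Linkage, default `"ward.D2"`.
#' @return An [stats::hclust] object.
#' @export
hcluster_subsets <- function(profiles, method = "ward.D2") {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stopf("need at least 2 subsets")
  if (anyNA(profiles)) stopf("missing marker values in profiles")
  stats::hclust(stats::dist(profiles), method = method)
}

#' Write a dendrogram as Newick
#'
#' @param hc An [stats::hclust] object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
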