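# Shared fixtures, built in code.  Heavy fixtures are memoised so multiple
# test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Minimal event table with explicit marker values, one row per event.
event_table <- function(..., tissue = "GALT") {
  df <- data.frame(..., check.names = FALSE)
  df$event_id <- sprintf("e%03d", seq_len(nrow(df)))
  df$sample_id <- "s1"
  df$tissue <- tissue
  df$donor <- "d1"
  df
}

# Two well-separated archetype clouds on a small panel.
two_cloud_archetypes <- function(sep = 4) {
  mk <- c("CD19", "CD20", "CD27", "IgM", "IgD")
  a <- stats::setNames(rep(1, length(mk)), mk)
  b <- a; b[c("CD27", "IgM")] <- 1 + sep
  list(subset_archetype("low", a, scale = 0.3, prevalence = 0.5),
       subset_archetype("high", b, scale = 0.3, prevalence = 0.5))
}

# Full GALT sample with the embedding/clustering pipeline applied once.
galt_pipeline_fixture <- function() {
  memo("galt_pipeline", {
    tab <- sim_cytometry_sample(default_cyto_archetypes("GALT"), 6000, seed = 101)
    coords <- embed_2d(tab, seed = 102, max_exact = 1200)
    graph <- cluster_nodes(coords, tab, k = 100, seed = 103)
    bubbles <- assign_bubbles(graph)
    list(tab = tab, coords = coords, graph = graph, bubbles = bubbles,
         subsets = event_subsets(graph, bubbles))
  })
}

# Small hand-laid two-zone geometry for array-level tests.
toy_geometry <- function(shape = c(24L, 16L), noise = 0.1) {
  shape <- as.integer(shape)
  m1 <- matrix(FALSE, shape[1], shape[2]); m1[1:(shape[1] %/% 2), ] <- TRUE
  m2 <- matrix(FALSE, shape[1], shape[2]); m2[(shape[1] %/% 2 + 1):shape[1], ] <- TRUE
  ch <- imc_channels()
  loc1 <- stats::setNames(rep(0.3, length(ch)), ch); loc1["CD3"] <- 3.5
  loc2 <- loc1; loc2["CD3"] <- 0.3; loc2[c("CD19", "CD20")] <- 3.5
  tissue_geometry(shape,
                  list(tissue_zone("t", m1, loc1), tissue_zone("b", m2, loc2)),
                  background_noise = noise)
}

# Exhaustive bootstrap-null oracle: all ordered resamples of size n_focal
# from a single-marker parent; returns the exact null mean/SD of the median.
enumerate_null <- function(values, n_focal) {
  grids <- do.call(expand.grid, rep(list(values), n_focal))
  meds <- apply(as.matrix(grids), 1, stats::median)
  list(mean = mean(meds), sd = sqrt(mean((meds - mean(meds))^2)), medians = meds)
}

# Independent brute-force weighted distance: explicit per-position context
# extraction and directional-weight averaging.
brute_force_distance <- function(a, b, model) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  total <- 0; L <- 0
  for (i in seq_along(av)) {
    if (av[i] == "N" || bv[i] == "N") next
    L <- L + 1
    if (av[i] == bv[i]) next
    wof <- function(v, from_i, target) {
      if (i < 3 || i > length(v) - 2) return(1)
      ctx <- paste(v[(i - 2):(i + 2)], collapse = "")
      w <- model[ctx, target]
      if (is.na(w)) 1 else w
    }
    total <- total + (wof(av, i, bv[i]) + wof(bv, i, av[i])) / 2
  }
  total / L
}

# Independent connected-components oracle (BFS over the d < threshold graph).
brute_force_components <- function(D, threshold) {
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- which(D[v, ] < threshold & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

# Independent MST total weight (Kruskal with union-find).
brute_force_mst_weight <- function(D) {
  n <- nrow(D)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  edges <- edges[order(D[edges]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  total <- 0; used <- 0L
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + D[edges[e, 1], edges[e, 2]]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  total
}

# Best-matching label agreement between a clustering and truth labels.
best_label_agreement <- function(cluster, truth) {
  tab <- table(cluster, truth)
  # greedy matching is enough for 2-3 clusters
  agree <- 0
  used <- character(0)
  for (cl in rownames(tab)) {
    row <- tab[cl, ]
    row <- row[setdiff(names(row), used)]
    if (!length(row)) next
    best <- names(which.max(row))
    agree <- agree + row[[best]]
    used <- c(used, best)
  }
  agree / length(cluster)
}
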