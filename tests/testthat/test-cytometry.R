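# Suspension analysis: transform, gating, embedding, node clustering,
# bubble assignment, profiles, MDS, subset dendrograms.

test_that("arcsinh transform is exact and order-preserving", {
  tab <- event_table(CD19 = c(0, 5, 10, 2), CD27 = c(1, 3, 2, 7))
  tr <- transform_intensities(tab, cofactor = 5)
  expect_equal(tr$CD19[1], 0)
  expect_equal(tr$CD19[2], asinh(1))
  expect_equal(round(tr$CD19[2], 4), 0.8814)
  expect_equal(order(tr$CD27), order(tab$CD27))
  expect_error(transform_intensities(tab, cofactor = 0), "cofactor")
})

test_that("gating retains exactly the events satisfying every gate", {
  tab <- event_table(CD19 = c(5, 1, 6, 0, 7, 2), CD3 = c(1, 1, 8, 0, 0, 9))
  expect_identical(gate_events(tab, list()), tab)
  expect_identical(gate_events(tab, list(gate("CD19", min(tab$CD19)))), tab)

  gates <- list(gate("CD19", 4, "above"), gate("CD3", 2, "below"))
  got <- gate_events(tab, gates)
  # exhaustive check over the 6 events
  manual <- tab[tab$CD19 >= 4 & tab$CD3 < 2, ]
  expect_identical(got, manual)
  expect_equal(nrow(got), 2)

  # idempotence
  expect_identical(gate_events(got, gates), got)
  expect_error(gate_events(tab, list(gate("CD99", 1))), "unknown marker")
})

test_that("polygon gates select points inside the polygon", {
  tab <- event_table(CD19 = c(0.5, 1.5, 0.5, 2.5), CD3 = c(0.5, 0.5, 1.5, 2.5))
  pg <- polygon_gate("CD19", "CD3", px = c(0, 2, 2, 0), py = c(0, 0, 2, 2))
  got <- gate_events(tab, list(pg))
  expect_equal(got$event_id, c("e001", "e002", "e003"))
})

test_that("embedding separates archetype clouds and is deterministic", {
  tab <- sim_cytometry_sample(two_cloud_archetypes(), 600, seed = 21)
  co <- embed_2d(tab, markers = marker_names(tab), seed = 22)
  expect_identical(co, embed_2d(tab, markers = marker_names(tab), seed = 22))
  set.seed(1)
  km <- stats::kmeans(co, 2, nstart = 10)
  expect_gte(best_label_agreement(km$cluster, tab$truth_subset), 0.95)
})

test_that("duplicated events stay mutual nearest neighbours in the embedding", {
  tab <- sim_cytometry_sample(two_cloud_archetypes(), 150, seed = 23)
  dup <- rbind(tab, tab)
  co <- embed_2d(dup, markers = marker_names(dup), seed = 24)
  n <- nrow(tab)
  D <- as.matrix(stats::dist(co))
  diag(D) <- Inf
  ok <- vapply(seq_len(n), function(i) {
    which.min(D[i, ]) == i + n && which.min(D[i + n, ]) == i
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("node clustering partitions events and recomputes medians exactly", {
  tab <- sim_cytometry_sample(two_cloud_archetypes(), 40, seed = 25)
  co <- embed_2d(tab, markers = marker_names(tab), seed = 26)
  g <- cluster_nodes(co, tab, k = nrow(tab), seed = 27)
  expect_equal(sort(unique(g$membership)), 1:40)
  for (m in marker_names(tab)) {
    expect_equal(g$medians[g$membership, m], tab[[m]])
  }
  tab2 <- sim_cytometry_sample(two_cloud_archetypes(), 200, seed = 28)
  co2 <- embed_2d(tab2, markers = marker_names(tab2), seed = 29)
  g2 <- cluster_nodes(co2, tab2, k = 2, seed = 27)
  expect_gte(best_label_agreement(g2$membership, tab2$truth_subset), 0.95)
  expect_error(cluster_nodes(co, tab, k = 1), "k must be")
  expect_error(cluster_nodes(co, tab, k = 41), "k must be")
})

test_that("CD45RB separates precursor-bearing nodes from naive-only nodes", {
  fx <- galt_pipeline_fixture()
  g <- fx$graph
  node_truth <- tapply(fx$tab$truth_subset, g$membership, function(s) {
    names(sort(table(s), decreasing = TRUE))[1]
  })
  pre_nodes <- as.integer(names(node_truth)[node_truth == "precursor"])
  naive_nodes <- as.integer(names(node_truth)[node_truth == "naive"])
  expect_gt(length(pre_nodes), 0)
  expect_gt(min(g$medians[pre_nodes, "CD45RB"]),
            max(g$medians[naive_nodes, "CD45RB"]))
})

test_that("bubble assignment recovers the twelve-subset mixture", {
  fx <- galt_pipeline_fixture()
  subs <- fx$subsets
  truth <- fx$tab$truth_subset
  # per-subset event counts within 5% (absolute, of total) of truth weights
  cnt_t <- table(truth)
  cnt_a <- table(factor(subs, levels = names(cnt_t)))
  expect_lt(max(abs(cnt_t - cnt_a)) / length(subs), 0.05)
  # precursor rule captures >= 90% of truth-precursor events
  expect_gte(mean(subs[truth == "precursor"] == "precursor"), 0.9)
  # overall recovery
  expect_gte(adjusted_rand(subs, truth), 0.8)
})

test_that("unmatched nodes fall into the other bucket", {
  med <- matrix(0.1, nrow = 3, ncol = length(default_panel()),
                dimnames = list(NULL, default_panel()))
  g <- structure(list(membership = c(1L, 2L, 3L), medians = med,
                      sizes = c(1L, 1L, 1L)), class = "node_graph")
  bub <- assign_bubbles(g)
  expect_true(all(bub$subset == "other"))
})

test_that("subset medians are exact and fractions sum to one", {
  tab <- event_table(CD19 = c(1, 2, 9, 4), CD27 = c(5, 5, 5, 1))
  prof <- subset_medians(tab, c("a", "a", "a", "b"))
  m <- prof$medians
  expect_equal(m$median[m$subset == "a" & m$marker == "CD19"], 2)
  expect_equal(m$median[m$subset == "b" & m$marker == "CD19"], 4)
  fr <- prof$fractions
  expect_equal(sum(fr$fraction[fr$tissue == "GALT"]), 1)
})

test_that("MDS embeds planar profiles exactly and reports Kruskal stress", {
  # profiles lying in a 2-D affine subspace
  base <- matrix(rnorm(10 * 2), 10, 2)
  prof <- cbind(base %*% matrix(c(1, 0, 1, 2, -1, 0), 2, 3) + 5, 0)
  rownames(prof) <- sprintf("s%02d", 1:10)
  res <- mds_samples(prof)
  expect_lte(res$stress, 1e-6)

  # 3 equidistant samples map to an equilateral configuration
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  res2 <- mds_samples(cbind(tri, 0, 0))
  d <- as.numeric(stats::dist(res2$coords))
  expect_lt(max(d) - min(d), 1e-6)

  expect_error(mds_samples(matrix(1, 3, 4)), "degenerate")
})

test_that("tissue replicates cluster together in sample MDS", {
  samples <- list(); lab <- character(0)
  i <- 0
  for (ti in c("GALT", "spleen", "tonsil")) {
    for (r in 1:3) {
      i <- i + 1
      tab <- sim_cytometry_sample(default_cyto_archetypes(ti), 1200,
                                  seed = 300 + i, tissue = ti)
      frac <- prop.table(table(factor(tab$truth_subset,
                                      levels = sort(unique(tab$truth_subset)))))
      med <- vapply(marker_names(tab), function(m) stats::median(tab[[m]]),
                    numeric(1))
      samples[[i]] <- c(as.numeric(frac), med)
      lab <- c(lab, ti)
    }
  }
  prof <- do.call(rbind, samples)
  rownames(prof) <- sprintf("%s_%d", lab, seq_along(lab))
  res <- mds_samples(prof)
  D <- as.matrix(stats::dist(res$coords))
  same <- outer(lab, lab, "==") & upper.tri(D)
  diff <- outer(lab, lab, "!=") & upper.tri(D)
  expect_lt(max(D[same]), min(D[diff]))
})

test_that("subset dendrogram pairs the precursor with the MZ subset", {
  fx <- galt_pipeline_fixture()
  tab <- fx$tab
  mk <- marker_names(tab)
  subsets <- sort(unique(tab$truth_subset))
  prof <- t(vapply(subsets, function(s) {
    vapply(mk, function(m) stats::median(tab[[m]][tab$truth_subset == s]),
           numeric(1))
  }, numeric(length(mk))))
  rownames(prof) <- subsets
  hc <- hcluster_subsets(prof)
  # mutual nearest subsets
  D <- as.matrix(stats::dist(prof)); diag(D) <- Inf
  expect_equal(colnames(D)[which.min(D["precursor", ])], "mz")
  expect_equal(colnames(D)[which.min(D["mz", ])], "precursor")
  # precursor+mz merge before either merges with a switched-memory subset
  merge_height <- function(hc, a, b) {
    ia <- match(a, hc$labels); ib <- match(b, hc$labels)
    sets <- list()
    for (k in seq_len(nrow(hc$merge))) {
      sets[[k]] <- unlist(lapply(hc$merge[k, ], function(x) {
        if (x < 0) -x else sets[[x]]
      }))
      if (all(c(ia, ib) %in% sets[[k]])) return(hc$height[k])
    }
    Inf
  }
  h_pair <- merge_height(hc, "precursor", "mz")
  for (sw in c("csm_igg", "csm_iga")) {
    expect_lt(h_pair, merge_height(hc, "precursor", sw))
    expect_lt(h_pair, merge_height(hc, "mz", sw))
  }
  # permutation invariance of merge heights
  perm <- sample(nrow(prof))
  hc2 <- hcluster_subsets(prof[perm, ])
  expect_equal(sort(hc2$height), sort(hc$height))
  # identical profiles merge first at height 0
  prof2 <- rbind(prof, dup = prof["mz", ])
  hc3 <- hcluster_subsets(prof2)
  expect_equal(min(hc3$height), 0)
})
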