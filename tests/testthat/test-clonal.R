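# Clonal grouping: weighted distances vs a brute-force oracle, V/J/length
# partitioning, single-linkage clone definition, diagnostics, lineages.

test_that("weighted junction distance satisfies the distance axioms", {
  model <- read_substitution_model()
  expect_equal(weighted_junction_distance("ACGTACGT", "ACGTACGT", model), 0)
  # uniform model reduces exactly to normalized Hamming
  a <- strrep("A", 20)
  b <- paste0("C", strrep("A", 19))
  expect_equal(weighted_junction_distance(a, b), 0.05)
  set.seed(51)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
    d_uniform <- weighted_junction_distance(x, y)
    mm <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    expect_equal(d_uniform, mm / 15)
    # symmetry under the non-uniform model
    expect_equal(weighted_junction_distance(x, y, model),
                 weighted_junction_distance(y, x, model))
  }
  expect_error(weighted_junction_distance("AAA", "AAAA"), "unequal")
})

test_that("non-uniform weights match a brute-force positional oracle", {
  model <- read_substitution_model()
  set.seed(52)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    yv <- strsplit(x, "")[[1]]
    pos <- sample(10, 2)
    for (p in pos) yv[p] <- sample(setdiff(c("A", "C", "G", "T"), yv[p]), 1)
    y <- paste(yv, collapse = "")
    expect_equal(weighted_junction_distance(x, y, model),
                 brute_force_distance(x, y, model))
  }
  # N positions are skipped and excluded from the evaluated length
  expect_equal(weighted_junction_distance("NCAAAAAAAA", "NAAAAAAAAA"), 1 / 9)
})

test_that("V/J/length partition collapses alleles to gene level", {
  rec <- data.frame(
    v_call = c("IGHV5-1*01", "IGHV5-1*02", "IGHV1-1*01", "IGHV5-1*01"),
    j_call = c("IGHJ4*02", "IGHJ4*01", "IGHJ4*02", "IGHJ4*02"),
    junction = c("TGTAAATGG", "TGTCCCTGG", "TGTAAATGG", "TGTAAATGGTGG"),
    stringsAsFactors = FALSE)
  groups <- vj_partition(rec)
  expect_length(groups, 3)
  expect_true(any(vapply(groups, function(g) setequal(g, c(1, 2)), logical(1))))
  expect_error(vj_partition(data.frame(v_call = NA, j_call = "J", junction = "T")),
               "missing")

  cfg <- repertoire_config(n_clones = 40, seed = 53)
  rep <- sim_repertoire(cfg)
  truth_keys <- unique(paste(sub("\\*.*", "", rep$v_call),
                             sub("\\*.*", "", rep$j_call),
                             rep$junction_length))
  expect_length(vj_partition(rep), length(truth_keys))
})

test_that("single-linkage chains merge into one clone", {
  # A-B 0.15, B-C 0.15, A-C 0.30 on length-20 junctions (3/6 mismatches)
  a <- strrep("A", 20)
  b <- paste0(strrep("C", 3), strrep("A", 17))
  c_ <- paste0(strrep("C", 3), strrep("G", 3), strrep("A", 14))
  rec <- data.frame(v_call = "IGHV1-1*01", j_call = "IGHJ4*02",
                    junction = c(a, b, c_), stringsAsFactors = FALSE)
  out <- define_clones(rec, threshold = 0.2)
  expect_length(unique(out$clone_id), 1)
  # identical junctions always share a clone
  rec2 <- rec; rec2$junction <- a
  expect_length(unique(define_clones(rec2)$clone_id), 1)
})

test_that("clone components agree with a brute-force graph oracle", {
  cfg <- repertoire_config(n_clones = 25, seed = 54, shm_rate = 0.02)
  rep <- sim_repertoire(cfg)
  out <- define_clones(rep)
  groups <- vj_partition(rep)
  for (idx in groups) {
    if (length(idx) < 2 || length(idx) > 8) next
    D <- matrix(0, length(idx), length(idx))
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (i < j) {
          D[i, j] <- D[j, i] <- weighted_junction_distance(
            rep$junction[idx[i]], rep$junction[idx[j]])
        }
      }
    }
    oracle <- brute_force_components(D, 0.2)
    got <- out$clone_id[idx]
    expect_equal(adjusted_rand(oracle, got), 1)
  }
})

test_that("clone recovery against generator truth is near-perfect", {
  cfg <- repertoire_config(n_clones = 80, chimera_rate = 0, seed = 55)
  rep <- sim_repertoire(cfg)
  out <- define_clones(rep, model = read_substitution_model())
  expect_gte(adjusted_rand(out$clone_id, rep$clone_id_truth), 0.95)
  # clones never span V/J/length groups
  key <- paste(sub("\\*.*", "", out$v_call), sub("\\*.*", "", out$j_call),
               nchar(out$junction))
  expect_true(all(tapply(key, out$clone_id, function(k) length(unique(k))) == 1))
})

test_that("clone count is non-increasing in the threshold", {
  cfg <- repertoire_config(n_clones = 40, seed = 56, shm_rate = 0.03)
  rep <- sim_repertoire(cfg)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th) {
    length(unique(define_clones(rep, threshold = th)$clone_id))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("distance-to-nearest marks singletons undefined and finds the gap", {
  rec <- data.frame(v_call = c("IGHV1-1*01", "IGHV1-1*01", "IGHV2-1*01"),
                    j_call = "IGHJ4*02",
                    junction = c("TGTAAATGG", "TGTAAATGG", "TGTCCCTGG"),
                    stringsAsFactors = FALSE)
  dtn <- distance_to_nearest(rec)
  expect_equal(dtn$distances[1:2], c(0, 0))
  expect_true(is.na(dtn$distances[3]))

  cfg <- repertoire_config(n_clones = 120, chimera_rate = 0, seed = 57)
  rep <- sim_repertoire(cfg)
  dtn2 <- distance_to_nearest(rep)
  # truth separation: suggested threshold falls inside the bimodal gap
  groups <- vj_partition(rep)
  within_max <- 0; between_min <- Inf
  for (idx in groups) {
    if (length(idx) < 2) next
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (i >= j) next
        d <- weighted_junction_distance(rep$junction[idx[i]], rep$junction[idx[j]])
        same <- rep$clone_id_truth[idx[i]] == rep$clone_id_truth[idx[j]]
        if (same) within_max <- max(within_max, d) else between_min <- min(between_min, d)
      }
    }
  }
  expect_false(is.na(dtn2$suggested))
  expect_gt(dtn2$suggested, within_max)
  expect_lt(dtn2$suggested, between_min)
})

test_that("lineage trees are germline-rooted MSTs with exact tie-breaks", {
  germ <- strrep("A", 30)
  m1 <- paste0("C", strrep("A", 29))              # 1 sub from germline
  m2 <- paste0("CG", strrep("A", 28))             # 2 subs, includes the first
  members <- data.frame(sequence_id = c("m1", "m2"), sequence = c(m1, m2),
                        duplicate_count = c(1L, 1L), stringsAsFactors = FALSE)
  tree <- build_lineage(members, germ)
  expect_equal(tree$edges$parent, c("germline", "m1"))
  expect_equal(tree$edges$child, c("m1", "m2"))
  expect_equal(tree$parsimony_score, 2)
  expect_match(lineage_newick(tree), "^\\(\\(m2:1\\)m1:1\\)germline;$")

  # all-identical members form a zero-weight star
  same <- data.frame(sequence_id = c("a", "b", "c"), sequence = germ,
                     duplicate_count = 1L, stringsAsFactors = FALSE)
  star <- build_lineage(same, germ)
  expect_true(all(star$edges$weight == 0))
  expect_equal(star$parsimony_score, 0)
  expect_error(build_lineage(same[1, ], germ), ">= 2")
})

test_that("lineage edge-weight totals match a brute-force MST oracle", {
  cfg <- repertoire_config(n_clones = 30, chimera_rate = 0, seed = 58)
  rep <- sim_repertoire(cfg)
  for (cl in unique(rep$clone_id_truth)) {
    mem <- rep[rep$clone_id_truth == cl, ]
    if (nrow(mem) < 2 || nrow(mem) > 6) next
    germ <- mem$germline_alignment[1]
    tree <- build_lineage(mem, germ)
    expect_setequal(tree$edges$child, mem$sequence_id)   # every member once
    seqs <- c(germ, mem$sequence)
    n <- length(seqs)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ai <- strsplit(seqs[i], "")[[1]]; bj <- strsplit(seqs[j], "")[[1]]
        ok <- ai != "N" & bj != "N"
        D[i, j] <- D[j, i] <- sum(ai[ok] != bj[ok])
      }
    }
    expect_equal(tree$parsimony_score, brute_force_mst_weight(D))
  }
})
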