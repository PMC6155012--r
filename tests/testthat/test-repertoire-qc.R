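# Read QC boundary semantics and conservation; sequence-level filters.

q40 <- function(n) strrep(intToUtf8(40 + 33), n)
qstr <- function(scores) intToUtf8(scores + 33, multiple = FALSE)

test_that("quality filter removes strictly below the length and Q bounds", {
  reads <- data.frame(
    read_id = c("short", "boundary", "lowq"),
    sequence = c(strrep("A", 249), strrep("A", 250), strrep("A", 250)),
    quality = c(q40(249), strrep(intToUtf8(20 + 33), 250),
                strrep(intToUtf8(19 + 33), 250)),
    stringsAsFactors = FALSE)
  out <- quality_filter(reads)
  expect_equal(out$reads$read_id, "boundary")
  expect_equal(out$log$n[out$log$reason == "short"], 1L)
  expect_equal(out$log$n[out$log$reason == "low_quality"], 1L)
  # conservation
  expect_equal(sum(out$log$n[out$log$reason != "retained"]) + nrow(out$reads),
               nrow(reads))

  empty <- quality_filter(reads[0, ])
  expect_equal(nrow(empty$reads), 0)
  expect_true(all(empty$log$n == 0))
})

test_that("MID demultiplexing is exact-match only", {
  mids <- c(M1 = strrep("A", 10), M2 = strrep("C", 10))
  body <- strrep("G", 30)
  perfect <- paste0(mids[["M1"]], body, revcomp(mids[["M1"]]))
  one_mm <- paste0("T", strrep("A", 9), body, revcomp(mids[["M1"]]))
  reads <- data.frame(read_id = c("ok", "mm"),
                      sequence = c(perfect, one_mm),
                      quality = c(q40(nchar(perfect)), q40(nchar(one_mm))),
                      stringsAsFactors = FALSE)
  out <- demux_mid(reads, mids)
  expect_equal(out$reads$read_id, "ok")
  expect_equal(out$reads$mid, "M1")
  expect_equal(out$reads$sequence, body)
  expect_equal(nchar(out$reads$quality), nchar(body))
  expect_error(demux_mid(reads, c(M1 = strrep("A", 10), M2 = strrep("A", 10))),
               "duplicate")
})

test_that("five-read MID fixture assigns three and removes two", {
  mids <- c(M1 = strrep("A", 10), M2 = strrep("C", 10))
  body <- strrep("G", 20)
  mk <- function(m5, m3) paste0(m5, body, revcomp(m3))
  seqs <- c(mk(mids[1], mids[1]), mk(mids[2], mids[2]), mk(mids[1], mids[2]),
            mk(strrep("T", 10), mids[1]), mk("GATTACAGAT", mids[2]))
  reads <- data.frame(read_id = sprintf("r%d", 1:5), sequence = seqs,
                      quality = vapply(seqs, function(s) q40(nchar(s)), ""),
                      stringsAsFactors = FALSE)
  out <- demux_mid(reads, mids)
  expect_equal(nrow(out$reads), 3)
  expect_equal(out$log$n[out$log$reason == "no_mid_match"], 2L)
  expect_equal(out$reads$mid_consistent, c(TRUE, TRUE, FALSE))
})

test_that("primer matching uses an inclusive 0.2 error budget", {
  primer <- strrep("A", 20)
  revp <- strrep("G", 20)
  flip <- function(p, k) paste0(strrep("T", k), substr(p, k + 1, nchar(p)))
  mkread <- function(fwd) paste0(fwd, strrep("C", 40), revp)
  reads <- data.frame(
    read_id = c("perfect", "four_mm", "five_mm"),
    sequence = c(mkread(primer), mkread(flip(primer, 4)), mkread(flip(primer, 5))),
    stringsAsFactors = FALSE)
  reads$quality <- vapply(reads$sequence, function(s) q40(nchar(s)), "")
  reads$mid <- "M1"
  out <- match_primers(reads, c(VH1 = primer), c(IgM = revp), max_error = 0.2)
  expect_setequal(out$reads$read_id, c("perfect", "four_mm"))
  expect_equal(out$log$n[out$log$reason == "no_fwd"], 1L)
  # forward region masked with Ns, length preserved minus trimmed reverse
  expect_true(all(substr(out$reads$sequence, 1, 20) == strrep("N", 20)))
  expect_true(all(nchar(out$reads$sequence) == 60))
  expect_equal(out$reads$c_call, c("IgM", "IgM"))
})

test_that("duplicate collapse keys on sequence, MID and both primers", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:5),
    sequence = c("AAA", "AAA", "AAA", "AAA", "CCC"),
    quality = rep("III", 5),
    mid = c("M1", "M1", "M2", "M1", "M1"),
    fwd_primer = "V1", rev_primer = "IgM",
    stringsAsFactors = FALSE)
  out <- collapse_duplicates(reads)
  expect_equal(nrow(out), 3)
  expect_equal(out$duplicate_count, c(3L, 1L, 1L))
  expect_equal(sum(out$duplicate_count), nrow(reads))
})

test_that("functionality filter removes non-functional and MID-mismatched", {
  rec <- data.frame(sequence_id = sprintf("s%d", 1:4),
                    functional = c(TRUE, FALSE, TRUE, FALSE),
                    mid_consistent = c(TRUE, TRUE, FALSE, FALSE))
  out <- functionality_filter(rec)
  expect_equal(out$records$sequence_id, "s1")
  expect_equal(out$log$n[out$log$reason == "non_functional"], 2L)
  expect_equal(out$log$n[out$log$reason == "mid_mismatch"], 1L)
  expect_error(functionality_filter(rec[, 1, drop = FALSE]), "flags")
})

test_that("chimera window rule is strictly more-than-five in ten", {
  germ <- strrep("A", 40)
  expect_true(chimera_window_filter(germ, germ))
  # 6 mismatches inside one 10-base window
  six <- paste0(strrep("A", 10), "CCCCCC", strrep("A", 24))
  expect_false(chimera_window_filter(six, germ))
  # exactly 5 mismatches in every window: alternate 1 mismatch per 2 bases
  five <- paste(rep(c("C", "A"), 20), collapse = "")
  expect_true(chimera_window_filter(five, germ))
  expect_error(chimera_window_filter("AAA", germ), "length mismatch")

  # brute-force window scan agreement on random cases
  set.seed(41)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C"), 30, replace = TRUE, prob = c(0.5, 0.5)),
               collapse = "")
    g <- strrep("A", 30)
    mm <- as.integer(strsplit(s, "")[[1]] != "A")
    worst <- max(vapply(1:21, function(k) sum(mm[k:(k + 9)]), numeric(1)))
    expect_equal(chimera_window_filter(s, g), worst <= 5)
  }
})

test_that("chimera filter is sensitive to spliced artefacts and spares SHM", {
  cfg <- repertoire_config(n_clones = 200, chimera_rate = 0.05, seed = 42)
  rep <- sim_repertoire(cfg)
  out <- chimera_filter_records(rep)
  kept <- rep$sequence_id %in% out$records$sequence_id
  truth <- rep$is_chimera_truth
  expect_gte(mean(!kept[truth]), 0.9)   # sensitivity
  expect_lte(mean(!kept[!truth]), 0.05) # false removal of genuine SHM
})

test_that("mutation frequency counts only germline-templated positions", {
  expect_equal(mutation_frequency("ACGT", "ACGT")$mutation_count, 0)
  s <- paste0("TTT", strrep("A", 297))
  g <- strrep("A", 300)
  mf <- mutation_frequency(s, g)
  expect_equal(mf$mutation_count, 3)
  expect_equal(mf$mutation_freq, 0.01)
  # N positions excluded from the evaluated length
  mf2 <- mutation_frequency("NNAC", "AAAC")
  expect_equal(mf2$evaluated_length, 2)
  expect_equal(mf2$mutation_count, 0)
  expect_error(mutation_frequency("NNNN", "NNNN"), "zero evaluated")
})

test_that("naive records are unmutated while memory records are mutated", {
  cfg <- repertoire_config(n_clones = 60, chimera_rate = 0, seed = 43)
  rep <- add_mutation_stats(sim_repertoire(cfg))
  expect_true(all(rep$mutation_freq[rep$subset == "naive"] == 0))
  mem <- rep$mutation_freq[rep$subset %in% c("csm", "igm_only")]
  expect_gt(stats::median(mem), 0)
})

test_that("the full read chain conserves counts at every stage", {
  cfg <- repertoire_config(n_clones = 40, seed = 44)
  rep <- sim_repertoire(cfg)
  reads <- sim_reads(rep, seed = 45,
                     quality = list(mean_q = 30, sd_q = 5, low_frac = 0.1,
                                    low_mean_q = 12))
  qf <- quality_filter(reads)
  expect_equal(sum(qf$log$n[qf$log$reason != "retained"]) + nrow(qf$reads),
               nrow(reads))
  dm <- demux_mid(qf$reads, default_mids())
  expect_equal(sum(dm$log$n[dm$log$reason != "retained"]) + nrow(dm$reads),
               nrow(qf$reads))
  pm <- match_primers(dm$reads, default_primers()$fwd, default_primers()$rev)
  expect_equal(sum(pm$log$n[pm$log$reason != "retained"]) + nrow(pm$reads),
               nrow(dm$reads))
  cd <- collapse_duplicates(pm$reads)
  expect_equal(sum(cd$duplicate_count), nrow(pm$reads))
  # order stability: re-running the chain gives identical output
  cd2 <- collapse_duplicates(match_primers(demux_mid(quality_filter(reads)$reads,
                                                     default_mids())$reads,
                                           default_primers()$fwd,
                                           default_primers()$rev)$reads)
  expect_identical(cd, cd2)
})
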