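# Synthetic IgH repertoire generator: clones with V/J/junction structure,
# somatic hypermutation, isotype/subset/site labels, chimeric artefacts, and
# raw amplicon reads with MID tags and primers.

.DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

#' Load the bundled synthetic germline pool
#'
#' A toy pool of 10 IGHV and 4 IGHJ segments (synthetic sequences, not IMGT
#' germlines) shipped under `inst/extdata`.  Sufficient to exercise V/J
#' partitioning, allele collapse and chimera detection.
#'
#' @return List with character vectors `v` (named by gene, 280 nt) and `j`
#'   (named by gene, 45 nt).
#' @export
germline_pool <- function() {
  read1 <- function(f) {
    x <- Biostrings::readDNAStringSet(
      system.file("extdata", f, package = "mzatlas", mustWork = TRUE))
    stats::setNames(as.character(x), names(x))
  }
  list(v = read1("germline_v_synthetic.fasta"),
       j = read1("germline_j_synthetic.fasta"))
}

#' Repertoire simulation configuration
#'
#' @param n_clones Number of clones to generate (>= 1).
#' @param clone_size Power-law clone-size law: `list(exponent, max)`; clone
#'   size k has weight k^-exponent, truncated at `max`.
#' @param shm_rate Per-base substitution probability per lineage step.
#' @param clone_type_probs Weights over clone lineage types
#'   (`mz`, `memory`, `naive`).
#' @param site_probs Dissemination weights over sampling sites.
#' @param chimera_rate Fraction of records converted to spliced-germline
#'   artefacts.
#' @param nonfunctional_rate Fraction of records flagged non-functional.
#' @param donors Donor labels; clones are split between donors and donors
#'   never share founders (so exact cross-donor sequence sharing is zero by
#'   construction).
#' @param germlines Germline pool as from [germline_pool()].
#' @param seed Integer seed.
#' @return A `repertoire_config` list.
#' @export
repertoire_config <- function(n_clones = 150,
                              clone_size = list(exponent = 2.0, max = 20),
                              shm_rate = 0.01,
                              clone_type_probs = c(mz = 0.3, memory = 0.5, naive = 0.2),
                              site_probs = c(PP = 0.3, A = 0.25, CF = 0.25, blood = 0.2),
                              chimera_rate = 0.02,
                              nonfunctional_rate = 0.02,
                              donors = c("D1", "D2"),
                              germlines = NULL,
                              seed = NULL) {
  stopifnot(n_clones >= 1, shm_rate >= 0, shm_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            nonfunctional_rate >= 0, nonfunctional_rate <= 1,
            all(site_probs >= 0), all(clone_type_probs >= 0))
  if (is.null(germlines)) germlines <- germline_pool()
  if (!length(germlines$v)) stopf("empty germline pool")
  stopifnot(all(grepl("^[ACGT]+$", germlines$v)), all(grepl("^[ACGT]+$", germlines$j)))
  structure(
    list(n_clones = n_clones, clone_size = clone_size, shm_rate = shm_rate,
         clone_type_probs = clone_type_probs / sum(clone_type_probs),
         site_probs = site_probs / sum(site_probs),
         chimera_rate = chimera_rate, nonfunctional_rate = nonfunctional_rate,
         donors = donors, germlines = germlines, seed = seed),
    class = "repertoire_config"
  )
}

mutate_seq <- function(seq, rate, hotspot = NULL) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(.DNA, bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate a clonal IgH repertoire with ground truth
#'
#' Clones share a V gene, J gene and junction length; the founder junction
#' starts with the conserved cysteine codon (TGT).  Members are generated by
#' independent per-base substitutions from the founder (star/branching
#' topology, 1-3 lineage steps), so within-clone junction distances are small
#' relative to between-clone distances at default rates.  Chimeric artefacts
#' splice a second V germline onto the record's V region at a random
#' breakpoint and are flagged in truth (half of them also carry inconsistent
#' MIDs).  The `germline_alignment` column holds the founder's germline
#' context, junction masked with Ns, for mutation counting and the
#' sliding-window chimera filter.
#'
#' @param config A [repertoire_config()].
#' @return Data frame with one row per rearrangement: `sequence_id`,
#'   `sequence`, `v_call`, `j_call`, `junction`, `junction_length`, `c_call`,
#'   `subset`, `site`, `donor`, `duplicate_count`, `clone_id_truth`,
#'   `is_chimera_truth`, `functional`, `mid_consistent`,
#'   `germline_alignment`.
#' @export
sim_repertoire <- function(config) {
  stopifnot(inherits(config, "repertoire_config"))
  with_seed(config$seed, {
    gl <- config$germlines
    v_genes <- names(gl$v)
    j_genes <- names(gl$j)
    sizes_k <- seq_len(config$clone_size$max)
    size_w <- sizes_k^(-config$clone_size$exponent)

    rows <- list()
    for (ci in seq_len(config$n_clones)) {
      donor <- config$donors[1L + (ci - 1L) %% length(config$donors)]
      type <- sample(names(config$clone_type_probs), 1L,
                     prob = config$clone_type_probs)
      vg <- sample(v_genes, 1L)
      jg <- sample(j_genes, 1L)
      v_allele <- sample(c("*01", "*02"), 1L)
      jl <- sample(seq(27L, 57L, by = 3L), 1L)
      junction <- paste0("TGT", random_dna(jl - 6L), "TGG")
      vseq <- gl$v[[vg]]
      jseq <- gl$j[[jg]]
      germ_aln <- paste0(vseq, strrep("N", jl), jseq)

      n_mem <- if (type == "naive") 1L else sample(sizes_k, 1L, prob = size_w)
      iso <- switch(type,
        naive = "IgM",
        mz = "IgM",
        memory = sample(c("IgM", "IgG", "IgA"), 1L, prob = c(0.3, 0.3, 0.4)))
      for (mi in seq_len(n_mem)) {
        depth <- if (type == "naive") 0L else sample(1:3, 1L)
        rate <- config$shm_rate * depth
        mut_j <- mutate_seq(junction, rate)
        mut_v <- mutate_seq(vseq, rate)
        mut_jseg <- mutate_seq(jseq, rate)
        subset <- switch(type,
          naive = "naive",
          mz = sample(c("mz", "gc"), 1L, prob = c(0.95, 0.05)),
          memory = sample(c("igm_only", "csm", "gc"), 1L,
                          prob = c(0.30, 0.65, 0.05)))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = sprintf("%s_c%04d_m%03d", donor, ci, mi),
          sequence = paste0(mut_v, mut_j, mut_jseg),
          v_call = paste0(vg, v_allele),
          j_call = paste0(jg, "*02"),
          junction = mut_j,
          junction_length = jl,
          c_call = iso,
          subset = subset,
          site = sample(names(config$site_probs), 1L, prob = config$site_probs),
          donor = donor,
          duplicate_count = stats::rgeom(1L, 0.6) + 1L,
          clone_id_truth = sprintf("%s_clone%04d", donor, ci),
          is_chimera_truth = FALSE,
          functional = TRUE,
          mid_consistent = TRUE,
          stringsAsFactors = FALSE
        )
        rows[[length(rows)]]$germline_alignment <- germ_aln
      }
    }
    rec <- do.call(rbind, rows)

    n <- nrow(rec)
    # spliced-germline chimeras: V-region prefix from the record's own V,
    # suffix from a different germline V
    n_chim <- round(config$chimera_rate * n)
    if (n_chim > 0) {
      idx <- sample.int(n, n_chim)
      vlen <- nchar(gl$v[[1]])
      for (i in idx) {
        own_gene <- sub("\\*.*$", "", rec$v_call[i])
        other <- sample(setdiff(v_genes, own_gene), 1L)
        bp <- sample(seq(30L, vlen - 30L), 1L)
        spliced_v <- paste0(substr(rec$sequence[i], 1L, bp),
                            substr(gl$v[[other]], bp + 1L, vlen))
        rec$sequence[i] <- paste0(spliced_v,
                                  substr(rec$sequence[i], vlen + 1L,
                                         nchar(rec$sequence[i])))
        rec$is_chimera_truth[i] <- TRUE
      }
      # half the chimeras also carry mismatched 5'/3' MIDs
      half <- idx[seq_len(floor(n_chim / 2))]
      rec$mid_consistent[half] <- FALSE
    }
    n_nf <- round(config$nonfunctional_rate * n)
    if (n_nf > 0) rec$functional[sample.int(n, n_nf)] <- FALSE
    rownames(rec) <- NULL
    rec
  })
}

#' Default MID tag set
#'
#' @param n Number of 10-nucleotide multiplex identifiers.
#' @param seed Seed for the tag draw (fixed default so the set is stable).
#' @return Named character vector `MID01`, `MID02`, ...
#' @export
default_mids <- function(n = 4, seed = 42) {
  with_seed(seed, {
    repeat {
      mids <- vapply(seq_len(n), function(i) random_dna(10L), character(1))
      if (!anyDuplicated(mids)) break
    }
    stats::setNames(mids, sprintf("MID%02d", seq_len(n)))
  })
}

#' Default primer sets for the synthetic amplicons
#'
#' Forward (V-region) primers are the first 20 nt of each synthetic V
#' germline; reverse (constant-region) primers are fixed 20-mers named by
#' isotype, so the isotype is recoverable from the reverse primer id.
#'
#' @param germlines Germline pool as from [germline_pool()].
#' @return List with named character vectors `fwd` and `rev`.
#' @export
default_primers <- function(germlines = germline_pool()) {
  fwd <- vapply(germlines$v, substr, character(1), 1L, 20L)
  rev_tab <- with_seed(7, {
    stats::setNames(vapply(1:4, function(i) random_dna(20L), character(1)),
                    c("IgM", "IgD", "IgG", "IgA"))
  })
  list(fwd = fwd, rev = rev_tab)
}

#' Emit raw FASTQ-style reads for a repertoire
#'
#' Read layout: `MID + amplicon + reverse primer + revcomp(MID)`, where the
#' amplicon begins with the forward-primer region (the first 20 nt of the V
#' segment).  Each record is emitted `duplicate_count` times with identical
#' sequence.  Per-base Phred scores are drawn from a normal quality model; a
#' configurable fraction of reads is given a degraded mean quality.  Records
#' flagged `mid_consistent = FALSE` get a 3' MID different from the 5' MID.
#'
#' @param records Repertoire data frame from [sim_repertoire()].
#' @param mids Named MID set ([default_mids()]); records map to MIDs by site.
#' @param primers Primer sets ([default_primers()]).
#' @param quality List: `mean_q`, `sd_q`, `low_frac`, `low_mean_q`.
#' @param seed Integer seed.
#' @return Data frame: `read_id`, `sequence`, `quality` (Phred+33 string),
#'   `truth_sequence_id`.
#' @export
sim_reads <- function(records, mids = default_mids(), primers = default_primers(),
                      quality = list(mean_q = 35, sd_q = 2, low_frac = 0,
                                     low_mean_q = 15),
                      seed = NULL) {
  stopifnot(all(nchar(mids) == 10L), length(primers$fwd) > 0, length(primers$rev) > 0)
  with_seed(seed, {
    sites <- sort(unique(records$site))
    site_mid <- stats::setNames(names(mids)[1L + (seq_along(sites) - 1L) %% length(mids)],
                                sites)
    out <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      mid5 <- site_mid[[r$site]]
      mid3 <- if (isTRUE(r$mid_consistent)) mid5 else {
        sample(setdiff(names(mids), mid5), 1L)
      }
      body <- paste0(r$sequence, primers$rev[[r$c_call]])
      seqread <- paste0(mids[[mid5]], body, revcomp(mids[[mid3]]))
      len <- nchar(seqread)
      ndup <- max(1L, r$duplicate_count)
      mean_q <- if (stats::runif(1) < quality$low_frac) quality$low_mean_q else quality$mean_q
      quals <- vapply(seq_len(ndup), function(d) {
        q <- round(stats::rnorm(len, mean_q, quality$sd_q))
        q <- pmin(pmax(q, 2L), 40L)
        intToUtf8(q + 33L)
      }, character(1))
      out[[i]] <- data.frame(
        read_id = sprintf("%s_r%d", r$sequence_id, seq_len(ndup)),
        sequence = seqread,
        quality = quals,
        truth_sequence_id = r$sequence_id,
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
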