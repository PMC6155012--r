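# End-to-end orchestration: configuration, per-stage seeding, logging and a
# reproducibility manifest.  Stage seeds are derived from the single global
# seed by a fixed counter scheme (see stage_seed()), so any stage re-run in
# isolation reproduces its in-pipeline stream.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global seed; expanded deterministically to per-stage seeds.
#' @param stages Stages to run, subset of `"cyto"`, `"distinct"`, `"imc"`,
#'   `"repertoire"`; simulation always runs for the selected stages.
#' @param n_cells Events per simulated cytometry sample.
#' @param n_samples_per_tissue Replicate samples per tissue.
#' @param imc_shape Simulated image shape.
#' @param n_clones Simulated clone count.
#' @param k Node count for suspension clustering.
#' @param B Bootstrap replicates for the distinctness test.
#' @param clone_threshold Clonal distance threshold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("cyto", "distinct", "imc", "repertoire"),
                            n_cells = 5000, n_samples_per_tissue = 3,
                            imc_shape = c(192L, 192L), n_clones = 120,
                            k = 60, B = 2000, clone_threshold = 0.2) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

manifest_entry <- function(path, n_records) {
  data.frame(file = basename(path),
             md5 = unname(tools::md5sum(path)),
             n_records = n_records,
             stringsAsFactors = FALSE)
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order on synthetic inputs,
#' writes stage outputs under `config$out_dir`, and emits a reproducibility
#' manifest (`manifest.json`) holding the configuration, per-file MD5
#' checksums, record counts and wall-clock seconds.  Identical
#' configurations reproduce identical checksums for all outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (list with `config`, `files`, `elapsed`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- function(...) file.path(config$out_dir, ...)

  if ("cyto" %in% config$stages || "distinct" %in% config$stages) {
    say("simulating cytometry samples")
    tissues <- c("GALT", "spleen", "tonsil")
    samples <- list()
    sidx <- 0L
    for (ti in tissues) {
      for (r in seq_len(config$n_samples_per_tissue)) {
        sidx <- sidx + 1L
        samples[[sidx]] <- sim_cytometry_sample(
          default_cyto_archetypes(ti), config$n_cells,
          seed = stage_seed(config$seed + sidx, "sim_cyto"),
          sample_id = sprintf("%s_rep%d", ti, r), tissue = ti,
          donor = sprintf("d%d", r))
      }
    }
    tab <- do.call(rbind, samples)
    p <- out("events.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(tab))
  }

  if ("cyto" %in% config$stages) {
    say("suspension subset analysis")
    galt <- tab[tab$tissue == "GALT", , drop = FALSE]
    co <- embed_2d(galt)
    g <- cluster_nodes(co, galt, k = config$k,
                       seed = stage_seed(config$seed, "cyto"))
    bub <- assign_bubbles(g)
    subs <- event_subsets(g, bub)
    assign_df <- data.frame(event_id = galt$event_id,
                            node_id = g$membership, subset = subs)
    p <- out("subset_assignments.csv")
    utils::write.csv(assign_df, p, row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(assign_df))

    prof <- subset_medians(galt, subs)
    p <- out("subset_profiles.tsv")
    utils::write.table(prof$medians, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(prof$medians))

    # sample-level MDS on per-sample subset-fraction profiles
    frac <- table(tab$sample_id, tab$truth_subset)
    profiles <- as.matrix(prop.table(frac, 1))
    mds <- mds_samples(profiles)
    p <- out("mds_samples.tsv")
    utils::write.table(
      data.frame(sample_id = rownames(mds$coords), mds$coords,
                 stress = mds$stress),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(mds$coords))
  }

  if ("distinct" %in% config$stages) {
    say("bootstrap distinctness test (precursor vs naive)")
    galt <- tab[tab$tissue == "GALT", , drop = FALSE]
    parent <- galt[galt$truth_subset %in% c("naive", "precursor"), ]
    focal <- galt[galt$truth_subset == "precursor", ]
    res <- distinctness_test(parent, focal, B = config$B,
                             seed = stage_seed(config$seed, "distinct"))
    p <- out("distinctness.tsv")
    utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(res))
  }

  if ("imc" %in% config$stages) {
    say("imaging mass cytometry pixel mapping")
    geom <- default_tissue_geometry(config$imc_shape)
    sim <- sim_imc_image(geom, seed = stage_seed(config$seed, "sim_imc"))
    ev <- pixels_to_events(sim$image)
    labels <- classify_pixels(ev, seed = config$seed)
    mk <- masks_from_labels(ev, labels, dim(sim$image)[1:2])
    ss <- spatial_summary(mk$masks,
                          list(gc = sim$truth_masks$gc,
                               epithelium = sim$truth_masks$epithelium))
    p <- out("spatial_summary.tsv")
    utils::write.table(ss, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(ss))
  }

  if ("repertoire" %in% config$stages) {
    say("repertoire simulation, QC, clonal grouping, overlap statistics")
    cfg <- repertoire_config(n_clones = config$n_clones,
                             seed = stage_seed(config$seed, "sim_rep"))
    rep <- sim_repertoire(cfg)
    ff <- functionality_filter(rep)
    cf <- chimera_filter_records(ff$records)
    rec <- add_mutation_stats(cf$records)
    rec <- define_clones(rec, threshold = config$clone_threshold,
                         model = read_substitution_model())
    p <- out("rearrangements.tsv")
    write_airr(rec, p)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(rec))

    mat <- clone_abundance_matrix(rec)
    p <- out("clone_site_isotype.tsv")
    utils::write.table(mat, p, sep = "\t", quote = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(mat))

    rates <- gc_membership_rates(rec, classes = list(mz = "mz",
                                                     igm_only = "igm_only"))
    p <- out("gc_membership.tsv")
    utils::write.table(rates, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <- manifest_entry(p, nrow(rates))
  }

  manifest <- list(
    config = unclass(config),
    files = do.call(rbind, files),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(
    list(config = unclass(config)[setdiff(names(config), "out_dir")],
         files = manifest$files, elapsed = manifest$elapsed),
    out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
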