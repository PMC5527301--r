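## End-to-end orchestration: simulate (or read) -> filter -> rarefy ->
## alpha sweep -> distances -> PCoA -> closest match -> PERMANOVA sweep ->
## pairing nulls -> indicators -> core OTUs -> sex enrichment, with a
## manifest recording config, seeds and timings.

#' Pipeline configuration
#'
#' All defaults are the canonical full-scale analysis settings: rarefaction
#' depth 5,293 reads, PERMANOVA and pairing nulls with 1,000 permutations /
#' pairings, IndVal and alpha tests with 999 permutations, classifier with
#' 1,000 trees and 10-fold CV, thresholds IndVal 0.7 / mean abundance 10 /
#' alpha 0.05 / 1% relative abundance. `scaled_down = TRUE` substitutes a
#' declared cheap configuration (recorded in the manifest) for test and demo
#' runs.
#'
#' @param otu_table_path,metadata_path optional input files; when NULL the
#'   couples-design simulator provides the data.
#' @param rarefaction_depth reads per sample after rarefaction (also the
#'   low-depth removal cutoff).
#' @param alpha_min,alpha_max,alpha_step,alpha_reps multiple-rarefaction grid
#'   (full scale: 100..5,290 by 100, 10 reps = 530 tables).
#' @param n_perms_permanova,n_pairings,n_perms_indval,n_perms_alpha
#'   permutation / pairing counts.
#' @param n_trees,n_folds classifier settings.
#' @param indval_min,mean_min,alpha_level,abundance_min thresholds.
#' @param categories metadata categories for the PERMANOVA and alpha sweeps.
#' @param sim_overrides named list forwarded to [sim_config()] when
#'   simulating.
#' @param seed master seed; every stage draws from one seeded stream.
#' @param scaled_down use the reduced-cost configuration.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table_path = NULL, metadata_path = NULL,
                            rarefaction_depth = 5293,
                            alpha_min = 100, alpha_max = 5290,
                            alpha_step = 100, alpha_reps = 10,
                            n_perms_permanova = 1000, n_pairings = 1000,
                            n_perms_indval = 999, n_perms_alpha = 999,
                            n_trees = 1000, n_folds = 10,
                            indval_min = 0.7, mean_min = 10,
                            alpha_level = 0.05, abundance_min = 0.01,
                            categories = c("participant", "couple", "sex",
                                           "moisture"),
                            sim_overrides = list(), seed = 1,
                            scaled_down = FALSE) {
  cfg <- as.list(environment())
  if (scaled_down) {
    cfg$n_perms_permanova <- 99
    cfg$n_pairings <- 49
    cfg$n_perms_indval <- 99
    cfg$n_perms_alpha <- 99
    cfg$n_trees <- 50
    cfg$n_folds <- 3
    cfg$alpha_reps <- 2
    cfg$alpha_min <- max(100, rarefaction_depth %/% 5)
    cfg$alpha_step <- max(1, (rarefaction_depth - cfg$alpha_min) %/% 2)
    cfg$alpha_max <- cfg$alpha_min + 2 * cfg$alpha_step
    if (is.null(cfg$sim_overrides$n_otus)) cfg$sim_overrides$n_otus <- 150
  }
  counts <- c(cfg$n_perms_permanova, cfg$n_pairings, cfg$n_perms_indval,
              cfg$n_perms_alpha, cfg$n_trees, cfg$n_folds, cfg$alpha_reps)
  if (any(counts < 1)) stop("all permutation/tree/fold counts must be >= 1")
  if (cfg$rarefaction_depth < 1) stop("rarefaction_depth must be >= 1")
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes filter -> rarefy -> alpha sweep -> Bray-Curtis -> PCoA ->
#' closest-match -> PERMANOVA sweep -> pairing nulls (both statistics) ->
#' IndVal -> core OTUs -> sex enrichment on user data or on a simulated
#' couples-design dataset, writing every result as TSV/JSON plus a run
#' manifest. Deterministic for a fixed config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisible list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage_times <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stage_times[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    res
  }
  files <- character(0)
  emit <- function(name) files <<- c(files, name)

  ## ---- input or simulation -------------------------------------------
  dat <- tick("input", {
    if (!is.null(config$otu_table_path)) {
      list(table = read_otu_table(config$otu_table_path),
           meta = read_metadata(config$metadata_path))
    } else {
      sim <- do.call(sim_config,
                     c(list(seed = config$seed), config$sim_overrides))
      out <- simulate_community(sim)
      out$table <- seed_low_depth_samples(out$table, n = 10L,
                                          below = config$rarefaction_depth,
                                          seed = config$seed + 1L)
      write_otu_table(out$table, file.path(out_dir, "otu_table.tsv"))
      write_metadata(out$meta, file.path(out_dir, "mapping.tsv"))
      write_sim_config(sim, file.path(out_dir, "sim_config.txt"))
      truth_files <- write_sim_truth(out$truth,
                                     file.path(out_dir, "sim_truth"))
      emit("otu_table.tsv"); emit("mapping.tsv"); emit("sim_config.txt")
      for (tf in truth_files) emit(basename(tf))
      out
    }
  })
  meta <- dat$meta

  ## ---- filter + rarefy ------------------------------------------------
  filt <- tick("filter", filter_low_depth(dat$table, config$rarefaction_depth))
  rare <- tick("rarefy", rarefy(filt$table, config$rarefaction_depth,
                                seed = config$seed + 2L))
  meta <- meta[meta$sample_id %in% sample_ids(rare), ]
  writeLines(filt$removed, file.path(out_dir, "removed_samples.txt"))
  emit("removed_samples.txt")

  ## ---- alpha diversity ------------------------------------------------
  alpha <- tick("alpha", multiple_rarefactions_alpha(
    rare, min_depth = config$alpha_min, max_depth = config$alpha_max,
    step = config$alpha_step, reps = config$alpha_reps,
    metric = "shannon", seed = config$seed + 3L))
  write_tsv(alpha$values, file.path(out_dir, "alpha_sweep.tsv"))
  emit("alpha_sweep.tsv")
  alpha_tests <- tick("alpha_tests", suppressWarnings(alpha_category_sweep(
    alpha, meta, categories = intersect(config$categories, names(meta)),
    n_perms = config$n_perms_alpha, seed = config$seed + 4L)))
  write_tsv(alpha_tests, file.path(out_dir, "alpha_category_tests.tsv"))
  emit("alpha_category_tests.tsv")

  ## ---- distances + ordination ----------------------------------------
  dm <- tick("bray_curtis", bray_curtis(rare))
  write_distance_matrix(dm, file.path(out_dir, "bray_curtis.tsv"))
  emit("bray_curtis.tsv")
  ord <- tick("pcoa", pcoa(dm, n_axes = min(3L, nrow(dm) - 1L)))
  ord_df <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, row.names = NULL)
  write_tsv(ord_df, file.path(out_dir, "pcoa_coordinates.tsv"))
  emit("pcoa_coordinates.tsv")

  ## ---- closest match --------------------------------------------------
  matches <- tick("match", {
    recs <- do.call(rbind, lapply(
      c("all", "nonself", "nonself_opposite_sex"),
      function(sc) suppressWarnings(
        nearest_neighbors(dm, meta, scope = sc, within_location = TRUE))))
    recs
  })
  write_tsv(matches, file.path(out_dir, "match_records.tsv"))
  emit("match_records.tsv")
  summ <- match_proportions(matches, meta)
  write_tsv(summ, file.path(out_dir, "match_summary.tsv"))
  emit("match_summary.tsv")
  ss <- tick("same_sex", same_sex_nonpartner_rate(matches, meta))

  ## ---- PERMANOVA sweep -------------------------------------------------
  sweep_res <- tick("permanova", suppressWarnings(category_sweep(
    dm, meta, categories = intersect(config$categories, names(meta)),
    per_location = FALSE, n_perms = config$n_perms_permanova,
    seed = config$seed + 5L, alpha = config$alpha_level)))
  write_tsv(sweep_res, file.path(out_dir, "permanova_sweep.tsv"))
  emit("permanova_sweep.tsv")

  ## ---- pairing nulls ---------------------------------------------------
  n_couples <- length(unique(meta$couple))
  pairings <- tick("pairings", sample_unique_pairings(
    n_couples, min(config$n_pairings, derangement_count(n_couples)),
    seed = config$seed + 6L))
  null_f <- tick("pairing_null_permanova",
                 pairing_null_permanova(dm, meta, pairings))
  null_err <- tick("pairing_null_classifier", pairing_null_classifier(
    rare, meta, pairings, n_trees = config$n_trees,
    n_folds = config$n_folds, seed = config$seed + 7L))
  write_tsv(data.frame(pairing = seq_len(nrow(pairings)),
                       permanova_F = null_f$null_values,
                       classifier_error = null_err$null_values),
            file.path(out_dir, "pairing_null_values.tsv"))
  emit("pairing_null_values.tsv")
  write_tsv(rbind(cbind(statistic = "permanova_F",
                        binned_null_histogram(null_f)),
                  cbind(statistic = "classifier_error",
                        binned_null_histogram(null_err))),
            file.path(out_dir, "pairing_null_hist.tsv"))
  emit("pairing_null_hist.tsv")
  jsonlite::write_json(
    list(permanova_F = list(observed = null_f$observed, p = null_f$p,
                            n_null = null_f$n_null),
         classifier_error = list(observed = null_err$observed,
                                 p = null_err$p, n_null = null_err$n_null),
         same_sex_nonpartner = ss),
    file.path(out_dir, "pairing_null_summary.json"),
    auto_unbox = TRUE, digits = NA)
  emit("pairing_null_summary.json")

  ## ---- indicators / core / enrichment ---------------------------------
  ind <- tick("indval", indval(rare, meta$sex,
                               n_perms = config$n_perms_indval,
                               seed = config$seed + 8L))
  write_tsv(filter_indicators(ind, config$indval_min, config$mean_min,
                              config$alpha_level),
            file.path(out_dir, "indicators_sex.tsv"))
  emit("indicators_sex.tsv")
  core <- tick("core", {
    data.frame(sex = c("female", "male"),
               n_core = c(length(core_otus(rare, meta, "sex", "female")),
                          length(core_otus(rare, meta, "sex", "male"))))
  })
  write_tsv(core, file.path(out_dir, "core_otus.tsv"))
  emit("core_otus.tsv")
  enr <- tick("enrichment", sex_enrichment_table(rare, meta))
  write_tsv(enr, file.path(out_dir, "sex_enrichment.tsv"))
  emit("sex_enrichment.tsv")

  ## ---- manifest --------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("skinmatch")),
    config = config[setdiff(names(config), "body_locations")],
    n_samples_input = nrow(dat$table$counts),
    n_samples_retained = nrow(rare$counts),
    removed_samples = filt$removed,
    files = files,
    stage_seconds = stage_times,
    wall_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(table = rare, meta = meta, alpha = alpha,
                 alpha_tests = alpha_tests, dm = dm, ordination = ord,
                 matches = matches, match_summary = summ,
                 same_sex = ss, permanova = sweep_res,
                 pairing_null_F = null_f, pairing_null_error = null_err,
                 indicators = ind, core = core, enrichment = enr,
                 manifest = manifest))
}
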