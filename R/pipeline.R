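#' Pipeline configuration
#'
#' One flat configuration for the whole chain, mirroring every stage's
#' keyword defaults: UMI/barcode filters (8 / 4), pseudo-replicate
#' subsampling (5 x 700), hyperparameter grids, and the simulator settings.
#' Round-trips through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()]; unknown keys are rejected.
#'
#' @param out_dir run directory.
#' @param seed master seed for every random stage.
#' @param sim named list of [sim_config()] overrides.
#' @param germline_vcf optional path to a germline VCF for exclusion.
#' @param min_umis,min_barcodes the consecutive false-positive filters.
#' @param n_reps,cells_per_rep pseudo-replicate subsampling.
#' @param lambda_grid,alpha_grid hyperparameter grids.
#' @param standardize standardize predictors within folds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "treeclock_run", seed = 1L,
                            sim = list(), germline_vcf = NULL,
                            min_umis = 8, min_barcodes = 4,
                            n_reps = 5, cells_per_rep = 700,
                            lambda_grid = c(0.1, 0.3, 1, 3, 10),
                            alpha_grid = c(0.6, 0.7, 0.8, 0.9, 1),
                            standardize = TRUE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              germline_vcf = germline_vcf, min_umis = min_umis,
              min_barcodes = min_barcodes, n_reps = n_reps,
              cells_per_rep = cells_per_rep, lambda_grid = lambda_grid,
              alpha_grid = alpha_grid, standardize = standardize)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    tc_abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
             "config")
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

# stage guard: skip when the parameter+input hash matches the stored marker
# and declared outputs exist
stage_hash <- function(params, input_files = character(0)) {
  key <- paste(utils::capture.output(utils::str(params)), collapse = "\n")
  if (length(input_files)) {
    sums <- tools::md5sum(sort(input_files[file.exists(input_files)]))
    key <- paste(key, paste(names(sums), sums, collapse = ";"), sep = "|")
  }
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(key, tf)
  unname(tools::md5sum(tf))
}

stage_fresh <- function(dir, hash, outputs) {
  marker <- file.path(dir, ".stage.json")
  if (!file.exists(marker)) return(FALSE)
  prev <- tryCatch(jsonlite::read_json(marker), error = function(e) NULL)
  identical(prev$hash, hash) && all(file.exists(outputs))
}

stage_done <- function(dir, hash, t0) {
  jsonlite::write_json(list(hash = hash,
                            runtime_s = as.numeric(Sys.time()) - t0),
                       file.path(dir, ".stage.json"), auto_unbox = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate -> filter -> alignments -> trees -> metrics -> fit in
#' order under `cfg$out_dir`, skipping stages whose parameter-and-input hash
#' is unchanged and whose outputs already exist. Writes a `manifest.json`
#' with the package version, full configuration and per-stage runtimes; the
#' manifest and seed suffice to reproduce a run. Stage failures abort with
#' the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @return The run directory, invisibly; outputs include
#'   `05_features/features.csv`, `06_model/predictions.csv`,
#'   `06_model/performance.json` and `06_model/coefficients.csv`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  runtimes <- list()

  run_stage <- function(name, dir, params, inputs, outputs, body) {
    dir.create(dir, showWarnings = FALSE)
    h <- stage_hash(params, inputs)
    if (stage_fresh(dir, h, outputs)) {
      runtimes[[name]] <<- 0
      return(invisible(NULL))
    }
    t0 <- as.numeric(Sys.time())
    tryCatch(body(), error = function(e)
      tc_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "pipeline"))
    stage_done(dir, h, t0)
    runtimes[[name]] <<- round(as.numeric(Sys.time()) - t0, 3)
    invisible(NULL)
  }

  scfg <- do.call(sim_config, modifyList(cfg$sim, list(seed = cfg$seed)))
  d_sim <- file.path(out, "01_cohort")
  run_stage("simulate", d_sim, scfg, character(0),
            file.path(d_sim, "metadata.csv"),
            function() simulate_cohort(scfg, out_dir = d_sim))
  metadata <- tibble::as_tibble(utils::read.csv(
    file.path(d_sim, "metadata.csv"), stringsAsFactors = FALSE))
  ids <- metadata$sample_id

  germ <- if (!is.null(cfg$germline_vcf))
    load_germline_vcf(cfg$germline_vcf) else NULL
  d_filt <- file.path(out, "02_filtered")
  filt_inputs <- file.path(d_sim, ids, "alt.mtx")
  run_stage("filter", d_filt,
            list(min_umis = cfg$min_umis, min_barcodes = cfg$min_barcodes,
                 germline = cfg$germline_vcf), filt_inputs,
            file.path(d_filt, ids, "alt.mtx"), function() {
    for (id in ids) {
      m <- load_call_matrix(file.path(d_sim, id, "alt.mtx"),
                            file.path(d_sim, id, "ref.mtx"),
                            file.path(d_sim, id, "barcodes.tsv"),
                            file.path(d_sim, id, "variants.csv"))
      f <- filter_variants(m, germ, cfg$min_umis, cfg$min_barcodes)
      write_call_matrix(f, file.path(d_filt, id))
    }
  })

  d_aln <- file.path(out, "03_alignments")
  rep_fa <- function(id) file.path(d_aln, id,
                                   sprintf("rep%d.fasta", seq_len(cfg$n_reps)))
  run_stage("alignments", d_aln,
            list(n_reps = cfg$n_reps, cells_per_rep = cfg$cells_per_rep,
                 min_umis = cfg$min_umis, seed = cfg$seed),
            file.path(d_filt, ids, "alt.mtx"),
            unlist(lapply(ids, rep_fa)), function() {
    for (i in seq_along(ids)) {
      id <- ids[i]
      m <- load_call_matrix(file.path(d_filt, id, "alt.mtx"),
                            file.path(d_filt, id, "ref.mtx"),
                            file.path(d_filt, id, "barcodes.tsv"),
                            file.path(d_filt, id, "variants.csv"))
      a <- encode_alignment(m, cfg$min_umis)
      reps <- subsample_pseudoreplicates(a, cfg$n_reps, cfg$cells_per_rep,
                                         seed = sample_seed(cfg$seed, i),
                                         sample_id = id)
      dir.create(file.path(d_aln, id), showWarnings = FALSE, recursive = TRUE)
      for (r in seq_along(reps))
        write_fasta(reps[[r]], file.path(d_aln, id, sprintf("rep%d.fasta", r)))
    }
  })

  d_tree <- file.path(out, "04_trees")
  rep_nwk <- function(id) file.path(d_tree, id,
                                    sprintf("rep%d.nwk", seq_len(cfg$n_reps)))
  run_stage("trees", d_tree, list(), unlist(lapply(ids, rep_fa)),
            unlist(lapply(ids, rep_nwk)), function() {
    for (id in ids) {
      alns <- lapply(rep_fa(id), read_fasta)
      trees <- infer_sample_trees(alns)
      dir.create(file.path(d_tree, id), showWarnings = FALSE, recursive = TRUE)
      for (r in seq_along(trees))
        write_newick(trees[[r]], file.path(d_tree, id, sprintf("rep%d.nwk", r)))
    }
  })

  d_feat <- file.path(out, "05_features")
  feat_csv <- file.path(d_feat, "features.csv")
  run_stage("metrics", d_feat, list(), unlist(lapply(ids, rep_nwk)),
            feat_csv, function() {
    tabs <- lapply(ids, function(id) {
      trees <- lapply(rep_nwk(id), read_newick)
      compute_feature_table(trees, sample_id = id,
                            replicate_id = seq_along(trees))
    })
    utils::write.csv(dplyr::bind_rows(tabs), feat_csv, row.names = FALSE)
  })

  d_mod <- file.path(out, "06_model")
  run_stage("fit", d_mod,
            list(lambda = cfg$lambda_grid, alpha = cfg$alpha_grid,
                 standardize = cfg$standardize), feat_csv,
            file.path(d_mod, c("predictions.csv", "performance.json",
                               "coefficients.csv")), function() {
    features <- tibble::as_tibble(utils::read.csv(feat_csv,
                                                  stringsAsFactors = FALSE))
    design <- build_design(features, metadata)
    cv <- nested_cv(design, cfg$lambda_grid, cfg$alpha_grid,
                    standardize = cfg$standardize)
    dummy <- dummy_baseline(design)
    utils::write.csv(age_acceleration(cv),
                     file.path(d_mod, "predictions.csv"), row.names = FALSE)
    jsonlite::write_json(list(model = as.list(cohort_performance(cv)),
                              dummy = as.list(cohort_performance(dummy)),
                              folds = cv$folds),
                         file.path(d_mod, "performance.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(tidy(cv), file.path(d_mod, "coefficients.csv"),
                     row.names = FALSE)
  })

  jsonlite::write_json(
    list(package = "treeclock",
         version = as.character(utils::packageVersion("treeclock")),
         seed = cfg$seed,
         config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
         config_hash = stage_hash(unclass(cfg)),
         stage_runtimes_s = runtimes),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
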