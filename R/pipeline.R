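# Pipeline orchestration: simulate -> fit -> stats with reproducible
# outputs, a manifest, and a thin command-line front-end.

.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Pipeline run configuration
#'
#' @param protocol path to a protocol JSON (default: packaged three-
#'   frequency protocol)
#' @param cohort a [cohort_spec()]
#' @param seed integer seed recorded in every output
#' @param snr phantom signal-to-noise ratio at b = 0
#' @param n_vox voxels per lesion ROI
#' @param out_dir output directory
#' @param stages character subset of `c("simulate", "fit", "stats")`
#' @param n_map_lesions number of lesions for which NIfTI phantoms and
#'   parameter maps are written (kept small; the cohort tables carry the
#'   per-lesion summaries)
#' @return a `run_config` list
#' @export
run_config <- function(protocol = NULL, cohort = cohort_spec(), seed = 1,
                       snr = 50, n_vox = 5, out_dir = tempfile("impulsed_run_"),
                       stages = c("simulate", "fit", "stats"),
                       n_map_lesions = 1) {
  stopifnot(all(stages %in% c("simulate", "fit", "stats")))
  structure(list(protocol = protocol, cohort = cohort, seed = as.integer(seed),
                 snr = snr, n_vox = n_vox, out_dir = out_dir, stages = stages,
                 n_map_lesions = n_map_lesions),
            class = "run_config")
}

.write_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# impulsedr v", as.character(utils::packageVersion("impulsedr")),
                    " seed=", seed,
                    " units: d_mean um, D um^2/ms, b s/mm^2, cellularity 1/um"),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Read a pipeline CSV (skipping the metadata header line)
#' @param path CSV written by the pipeline
#' @return data.frame
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order: `simulate` (roster + cohort
#' ground truth + per-lesion phantom signals), `fit` (voxelwise model and
#' ADC fits, ROI summaries; example NIfTI phantom/maps for the first
#' lesion(s)), `stats` (composition summary, comparison and ROC report
#' tables, observer ICCs). Stage dependencies are enforced: `fit` needs
#' `simulate`, `stats` needs `fit`. A manifest with the seed and a config
#' hash is written; re-running with an identical config reproduces
#' identical CSV payloads.
#'
#' @param config a [run_config()]
#' @return the output directory, invisibly; outputs: `roster.csv`,
#'   `cohort.csv`, `exclusion_report.csv`, `composition.csv`,
#'   `table4_report.csv`, `table5_report.csv`, `icc_report.csv`,
#'   `roi_summary.csv`, `manifest.json`, `maps/`
#' @export
run_pipeline <- function(config = run_config()) {
  st <- config$stages
  if ("fit" %in% st && !"simulate" %in% st)
    stop("stage dependency error: 'fit' requires 'simulate'", call. = FALSE)
  if ("stats" %in% st && !"fit" %in% st)
    stop("stage dependency error: 'stats' requires 'fit'", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- if (is.null(config$protocol)) default_protocol()
          else load_protocol(config$protocol)
  seed <- config$seed
  t0 <- Sys.time()

  if ("simulate" %in% st && !"fit" %in% st) {
    roster <- generate_roster(config$cohort, seed)
    exc <- apply_exclusions(roster)
    .write_csv(roster, file.path(config$out_dir, "roster.csv"), seed)
    .write_csv(as.data.frame(t(exc$report)),
               file.path(config$out_dir, "exclusion_report.csv"), seed)
    message(sprintf("[simulate] collected=%d enrolled=%d",
                    exc$report[["n_collected"]], exc$report[["n_enrolled"]]))
  }

  if ("fit" %in% st) {
    res <- run_cohort_analysis(config$cohort, prot, seed = seed,
                               snr = config$snr, n_vox = config$n_vox)
    .write_csv(res$roster, file.path(config$out_dir, "roster.csv"), seed)
    .write_csv(as.data.frame(t(res$exclusion_report)),
               file.path(config$out_dir, "exclusion_report.csv"), seed)
    .write_csv(res$cohort, file.path(config$out_dir, "cohort.csv"), seed)
    message(sprintf("[simulate] collected=%d enrolled=%d",
                    res$exclusion_report[["n_collected"]],
                    res$exclusion_report[["n_enrolled"]]))
    # example phantom + maps for the first lesion(s)
    map_dir <- file.path(config$out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    kernel <- .cached_kernel(prot)
    roi_all <- NULL
    n_map <- min(config$n_map_lesions, nrow(res$cohort))
    for (li in seq_len(n_map)) {
      truth <- res$cohort[li, c("d_mean_truth", "f_in_truth", "D_ex_truth")]
      names(truth) <- c("d_mean", "f_in", "D_ex")
      ph <- generate_lesion_image(truth, prot, snr = config$snr,
                                  seed = seed + li, kernel = kernel)
      id <- res$cohort$patient_id[li]
      write_nifti(ph$vol, file.path(map_dir, paste0(id, "_dwi.nii.gz")))
      write_nifti(ph$mask, file.path(map_dir, paste0(id, "_mask.nii.gz")))
      pm <- fit_maps(ph$vol, ph$mask, prot, kernel = kernel, lesion_id = id)
      for (mp in names(pm$maps))
        write_nifti(pm$maps[[mp]],
                    file.path(map_dir, paste0(id, "_", mp, ".nii.gz")))
      roi_all <- rbind(roi_all, pm$roi_summary)
    }
    .write_csv(roi_all, file.path(config$out_dir, "roi_summary.csv"), seed)
    message(sprintf("[fit] lesions=%d voxels_per_lesion=%d maps_written=%d",
                    nrow(res$cohort), config$n_vox, n_map))

    if ("stats" %in% st) {
      comp <- summarize_cohort(res$cohort)
      reports <- build_reports(res$cohort)
      iccs <- icc_report(res$cohort)
      .write_csv(comp, file.path(config$out_dir, "composition.csv"), seed)
      .write_csv(reports$table4,
                 file.path(config$out_dir, "table4_report.csv"), seed)
      .write_csv(reports$table5,
                 file.path(config$out_dir, "table5_report.csv"), seed)
      .write_csv(iccs, file.path(config$out_dir, "icc_report.csv"), seed)
      message(sprintf("[stats] comparisons=%d roc_rows=%d",
                      nrow(reports$table4), nrow(reports$table5)))
    }
  }

  manifest <- list(
    package = "impulsedr",
    version = as.character(utils::packageVersion("impulsedr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, snr = config$snr, stages = st,
    config_hash = .config_hash(config[c("cohort", "seed", "snr", "n_vox",
                                        "stages")]),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
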