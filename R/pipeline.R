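#' Validating cohort loader
#'
#' Reads a cohort CSV and validates every categorical field against the
#' canonical vocabularies, reporting the offending row (1-based data row)
#' and field on failure.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (length(readLines(path, n = 1)) == 0) abort("no header: file is empty.")
  data <- read_cohort(path)
  vocab <- cohort_vocabularies()
  for (cl in intersect(names(vocab), names(data))) {
    v <- as.character(data[[cl]])
    bad <- which(!is.na(v) & !(v %in% vocab[[cl]]))
    if (length(bad)) {
      abort(paste0(
        "row ", bad[1], ", field `", cl, "`: unknown category '",
        v[bad[1]], "' (expected one of ", paste(vocab[[cl]], collapse = ", "), ")"
      ))
    }
  }
  for (cl in intersect(c("serum_25ohd", "fdsk_score"), names(data))) {
    if (!is.numeric(data[[cl]])) {
      abort(paste0("field `", cl, "` is not numeric."))
    }
  }
  if (all(c("serum_25ohd", "severity") %in% names(data))) {
    both <- !is.na(data$serum_25ohd) & !is.na(data$severity)
    mismatch <- which(both &
      as.character(assign_severity(data$serum_25ohd[both])) !=
        as.character(data$severity[both]))
    if (length(mismatch)) {
      warn(paste0(
        length(mismatch), " row(s) have a severity label inconsistent ",
        "with the serum value (first: row ", which(both)[mismatch[1]], ")."
      ))
    }
  }
  data
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with one master seed from which
#' every stage's sub-seed is derived (see [derive_seed()]), so altering one
#' stage never shifts another stage's random stream.
#'
#' @param generator A [cohort_config()] (its `seed` is overridden by the
#'   derived generator sub-seed).
#' @param preprocess A [preprocess_config()].
#' @param iwoa An [iwoa_config()].
#' @param base_specs Stacking base models.
#' @param k_folds_inner Inner OOF folds for stacking.
#' @param cv_folds Outer evaluation folds.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            preprocess = preprocess_config(),
                            iwoa = iwoa_config(),
                            base_specs = c("RF", "SVM", "GB"),
                            k_folds_inner = 5,
                            cv_folds = 10,
                            seed = 1L) {
  generator$seed <- derive_seed(seed, "generator-master")
  preprocess$seed <- derive_seed(seed, "preprocess-master")
  iwoa$seed <- derive_seed(seed, "iwoa-master")
  structure(
    list(
      generator = generator, preprocess = preprocess, iwoa = iwoa,
      base_specs = base_specs, k_folds_inner = as.integer(k_folds_inner),
      cv_folds = as.integer(cv_folds), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' Accepts a nested JSON document with any of the keys `generator`,
#' `preprocess`, `iwoa`, `base_specs`, `k_folds_inner`, `cv_folds`, `seed`;
#' unknown keys (at top level or within a stage) are rejected.
#'
#' @param path JSON file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("generator", "preprocess", "iwoa", "base_specs", "k_folds_inner", "cv_folds", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")))
  }
  call_checked <- function(fun, args, stage) {
    ok <- names(formals(fun))
    extra <- setdiff(names(args), ok)
    if (length(extra)) {
      abort(paste0("unknown ", stage, " key(s): ", paste(extra, collapse = ", ")))
    }
    do.call(fun, args)
  }
  gen_args <- as.list(raw$generator %||% list())
  for (nm in c("seasonal_mean", "seasonal_sd", "effect_weights")) {
    if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  }
  pipeline_config(
    generator = call_checked(cohort_config, gen_args, "generator"),
    preprocess = call_checked(preprocess_config, as.list(raw$preprocess %||% list()), "preprocess"),
    iwoa = call_checked(iwoa_config, as.list(raw$iwoa %||% list()), "iwoa"),
    base_specs = raw$base_specs %||% c("RF", "SVM", "GB"),
    k_folds_inner = raw$k_folds_inner %||% 5,
    cv_folds = raw$cv_folds %||% 10,
    seed = raw$seed %||% 1L
  )
}

run_manifest <- function(config, stage, artifacts, timings) {
  list(
    stage = stage,
    package_version = as.character(utils::packageVersion("vdseverity")),
    master_seed = config$seed,
    config_digest = config_digest(config),
    artifacts = artifacts,
    elapsed_seconds = timings
  )
}

# Stable digest of a configuration: deparse to canonical text and hash.
config_digest <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 4294967291)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, paste0("manifest-", manifest$stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage commands
#'
#' `cmd_simulate()` generates a cohort CSV; `cmd_select()` runs IWOA feature
#' selection on a cohort and writes the selection JSON; `cmd_train_eval()`
#' cross-validates the stacking pipeline (optionally restricted to a
#' selected mask) and writes metric and confusion-matrix artifacts. Each
#' command writes a run manifest and reruns byte-identically under the same
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param data_path Cohort CSV (for select/train-eval stages).
#' @param selection_path Optional selection JSON from `cmd_select()`.
#' @return The manifest list, invisibly; artifacts are written to `out_dir`.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  cohort <- generate_cohort(config$generator)
  path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, path)
  manifest <- run_manifest(
    config, "simulate", list(cohort = path),
    proc.time()[["elapsed"]] - t0
  )
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' @rdname cmd_simulate
#' @export
cmd_select <- function(config, data_path, out_dir) {
  if (!file.exists(data_path)) {
    abort(paste0("expected cohort artifact not found: ", data_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  cohort <- load_cohort(data_path)
  enc <- encode_features(cohort)
  dat <- enc$X
  dat$severity <- cohort$severity
  res <- run_iwoa(dat, outcome = "severity", config = config$iwoa)
  path <- file.path(out_dir, "selection.json")
  jsonlite::write_json(
    list(
      mask = as.integer(res$best_mask), features = res$features,
      best_fitness = res$best_fitness, trajectory = res$trajectory,
      n_evaluations = res$n_evaluations, seed = res$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  manifest <- run_manifest(
    config, "select", list(selection = path),
    proc.time()[["elapsed"]] - t0
  )
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' @rdname cmd_simulate
#' @export
cmd_train_eval <- function(config, data_path, out_dir, selection_path = NULL) {
  if (!file.exists(data_path)) {
    abort(paste0("expected cohort artifact not found: ", data_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  cohort <- load_cohort(data_path)
  mask <- NULL
  if (!is.null(selection_path)) {
    if (!file.exists(selection_path)) {
      abort(paste0("expected selection artifact not found: ", selection_path))
    }
    sel <- jsonlite::read_json(selection_path, simplifyVector = TRUE)
    mask <- stats::setNames(as.integer(sel$mask), sel$features)
  }
  report <- crossval_evaluate(
    cohort,
    outcome = "severity", k = config$cv_folds,
    seed = derive_seed(config$seed, "train-eval"),
    base_specs = config$base_specs, mask = mask,
    k_folds_inner = config$k_folds_inner
  )
  metrics_path <- file.path(out_dir, "metrics.tsv")
  readr::write_tsv(report$folds, metrics_path)
  cm_path <- file.path(out_dir, "confusion.tsv")
  cm <- as.data.frame(report$confusion$counts)
  readr::write_tsv(cbind(truth = rownames(cm), cm), cm_path)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(
      mean_accuracy = report$mean_accuracy, sd_accuracy = report$sd_accuracy,
      k = report$k, per_class = report$summary
    ),
    summary_path,
    auto_unbox = TRUE, digits = NA
  )
  manifest <- run_manifest(
    config, "train-eval",
    list(metrics = metrics_path, confusion = cm_path, summary = summary_path),
    proc.time()[["elapsed"]] - t0
  )
  write_manifest(manifest, out_dir)
  invisible(manifest)
}
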