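# End-to-end orchestration: prepare -> build inputs -> sweep k -> train ->
# select -> enrich -> marker shifts, driven by a single config list (or
# YAML file), with per-stage timings and an output manifest.

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file with the fields of [run_pipeline()]'s
#'   `config`.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

.validate_config <- function(config) {
  mode <- config$mode %||% abort("config$mode is required")
  if (!mode %in% c("global", "local", "functional")) {
    abort("mode must be one of global, local, functional")
  }
  if (mode %in% c("local", "functional") && is.null(config$anchor_type)) {
    abort(paste0("mode '", mode, "' requires config$anchor_type"))
  }
  if (mode == "functional" && is.null(config$functional_marker)) {
    abort("functional mode requires config$functional_marker")
  }
  if (length(config$k_grid %||% integer(0)) == 0) {
    abort("config$k_grid must be a nonempty vector of neighbourhood sizes")
  }
  invisible(config)
}

# build inputs for one k under the configured mode
.build_inputs <- function(table, config, k) {
  anchor_seed <- config$seeds$anchor_seed %||% 1L
  switch(config$mode,
    global = build_global_inputs(
      table, k = k,
      n_anchors_per_image = config$n_anchors_per_image %||% 100,
      seed = anchor_seed),
    local = build_local_inputs(
      table, anchor_type = config$anchor_type, k = k, seed = anchor_seed),
    functional = build_functional_inputs(
      table, anchor_type = config$anchor_type,
      functional_marker = config$functional_marker, k = k))
}

# condition labels (not BG) ordered by input count, most frequent first
.condition_pair <- function(labels) {
  tab <- sort(base::table(labels[labels != "BG"]), decreasing = TRUE)
  if (length(tab) < 2) abort("need at least two condition classes")
  names(tab)[1:2]
}

#' Rank a model's filters by validation frequency significance
#'
#' Scores each filter of a trained model individually: cells are selected
#' by that filter's response, per-sample selected-cell frequencies are
#' computed on the validation inputs, and the two condition classes are
#' compared (plus, when a background class is present, the winning
#' condition against background). The filter with the most significant
#' condition comparison is the one the downstream characterisation
#' reports.
#'
#' @param model A `niche_model`.
#' @param table The `cell_table` behind the inputs.
#' @param inputs An `mc_inputs` tibble with a `set` column.
#' @return A tibble with one row per filter: `filter`, `p_condition`,
#'   `direction`, `p_background`.
#' @export
filter_comparisons <- function(model, table, inputs) {
  stopifnot("set" %in% names(inputs))
  .filter_comparisons(model, table, inputs)
}

# internal core of filter_comparisons
.filter_comparisons <- function(model, table, inputs) {
  va <- inputs[inputs$set == "validation", ]
  pair <- .condition_pair(as.character(va$label))
  purrr::map_dfr(seq_len(nrow(model$W)), function(f) {
    selection <- select_cells(model, table, inputs, filter_index = f)
    freqs <- frequency_per_sample(selection, va)
    cmp <- compare_frequencies(freqs, pair[1], pair[2])
    bg_p <- NA_real_
    if (any(va$label == "BG")) {
      winner <- cmp$direction
      if (is.na(winner)) winner <- pair[1]
      bg <- compare_frequencies(freqs, winner, "BG")
      bg_p <- bg$p_value
    }
    tibble::tibble(filter = f, p_condition = cmp$p_value,
                   direction = cmp$direction, p_background = bg_p)
  })
}

.write_stage <- function(df, dir, name) {
  path <- file.path(dir, name)
  partial <- paste0(path, ".partial")
  readr::write_csv(as.data.frame(df), partial, progress = FALSE)
  file.rename(partial, path)
  path
}

#' Run the full spatial enrichment pipeline
#'
#' Sequences the whole analysis from a single configuration: load (or
#' accept) a cell table, preprocess intensities, build multi-cell inputs
#' for every k in the grid, train a model per k with random hyperparameter
#' search, compare validation selected-cell frequencies, choose the best k,
#' and characterise the winning selection (per-sample frequencies,
#' enrichment scores, marker shifts). All outputs are tidy CSVs under
#' `config$out_dir`, and a manifest (config snapshot, timings, file
#' digests) is written alongside and returned. Deterministic stages
#' reproduce their digests when rerun with identical seeds.
#'
#' @param config A list (or [read_run_config()] result) with fields:
#'   `input` (path or `cell_table`), optional `schema`, `mode`
#'   (`"global"`, `"local"` or `"functional"`), `anchor_type`,
#'   `functional_marker`, `k_grid`, `n_anchors_per_image`, `split`
#'   (`n_test_samples_per_condition`, `val_fraction`), `train`
#'   (`n_trials`, `pooling`, `epochs`, `batch_size`, `patience`), `alpha`,
#'   `seeds` (`split_seed`, `anchor_seed`, `train_seed`), `out_dir`.
#' @return A `run_manifest` list; its `results` element carries the in-
#'   memory stage outputs (`k_sweep`, `best_k`, `selection`, `frequencies`,
#'   `comparison`, `enrichment`, `marker_shift`, `fit`).
#' @export
run_pipeline <- function(config) {
  .validate_config(config)
  out_dir <- config$out_dir %||% tempfile("cytoniche_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    inform(paste0("[", name, "] done in ", timings[[name]], "s"))
    res
  }

  table <- stage("prepare", {
    tab <- if (is.character(config$input)) {
      load_cell_table(config$input, config$schema %||% list())
    } else config$input
    if (!is_preprocessed(tab)) tab <- preprocess_intensities(tab)
    inform(paste0("[prepare] ", nrow(tab), " cells, ",
                  length(unique(tab$image_id)), " images, ",
                  length(unique(tab$sample_id)), " samples"))
    tab
  })

  split <- make_split(
    table,
    n_test_samples_per_condition =
      config$split$n_test_samples_per_condition %||% 0,
    val_fraction = config$split$val_fraction %||% 0.2,
    seed = config$seeds$split_seed %||% 1L)

  tr_cfg <- config$train %||% list()
  train_one <- function(inputs) {
    task <- if (config$mode == "functional") "regression"
            else "classification"
    niche_train(inputs, task = task,
               n_trials = tr_cfg$n_trials %||% 200,
               seed = config$seeds$train_seed %||% 1L,
               pooling = tr_cfg$pooling %||% "mean",
               epochs = tr_cfg$epochs %||% 50,
               batch_size = tr_cfg$batch_size %||% 64,
               patience = tr_cfg$patience %||% 5)
  }

  sweep <- stage("sweep_k", {
    purrr::map(config$k_grid, function(k) {
      inputs <- .build_inputs(table, config, k)
      inputs <- assign_sets(inputs, split)
      class_inputs <- if (config$mode == "functional") {
        dichotomize_functional(inputs)
      } else inputs
      fit <- train_one(inputs)
      cmps <- .filter_comparisons(fit$model, table, class_inputs)
      best_f <- which.min(cmps$p_condition)
      list(k = k, inputs = inputs, class_inputs = class_inputs, fit = fit,
           filter = best_f,
           summary = tibble::tibble(
             k = k, val_score = fit$val_score, test_score = fit$test_score,
             filter = best_f,
             p_condition = cmps$p_condition[best_f],
             direction = cmps$direction[best_f],
             p_background = cmps$p_background[best_f]))
    })
  })
  k_sweep <- dplyr::bind_rows(purrr::map(sweep, "summary"))

  pick <- choose_k(k_sweep,
                   mode = if (config$mode == "local") "local" else "global",
                   alpha = config$alpha %||% 0.05)
  if (!pick$admissible) {
    warn("no admissible k under the local selection rule; reporting the smallest condition p-value instead")
    pick$best_k <- k_sweep$k[which.min(k_sweep$p_condition)]
  }
  best <- sweep[[which(k_sweep$k == pick$best_k)]]

  results <- stage("characterize", {
    selection <- select_cells(best$fit$model, table, best$inputs,
                              filter_index = best$filter, scope = "all")
    freqs <- frequency_per_sample(selection, best$class_inputs)
    pair <- .condition_pair(as.character(best$class_inputs$label))
    comparison <- compare_frequencies(freqs, pair[1], pair[2])
    counts <- tabulate_counts(table, selection, best$inputs)
    scored <- if (config$mode == "global") global_es(counts)
              else local_es(counts)
    enr <- aggregate_es(scored)
    shifts <- differential_markers(table, selection)
    list(selection = selection, frequencies = freqs,
         comparison = comparison, enrichment = enr, marker_shift = shifts)
  })

  files <- stage("write", {
    c(k_sweep = .write_stage(k_sweep, out_dir, "k_sweep.csv"),
      selected_cells = .write_stage(results$selection, out_dir,
                                    "selected_cells.csv"),
      frequencies = .write_stage(results$frequencies, out_dir,
                                 "frequencies.csv"),
      enrichment = .write_stage(results$enrichment, out_dir,
                                "enrichment.csv"),
      marker_shift = .write_stage(results$marker_shift, out_dir,
                                  "marker_shift.csv"))
  })

  manifest <- structure(list(
    config = config[setdiff(names(config), "input")],
    version = as.character(utils::packageVersion("cytoniche")),
    best_k = pick$best_k,
    admissible = pick$admissible,
    filter = best$filter,
    timings = timings,
    files = as.list(files),
    digests = as.list(tools::md5sum(unname(files))),
    results = c(list(k_sweep = k_sweep, best_k = pick$best_k,
                     fit = best$fit), results)),
    class = "run_manifest")
  yaml::write_yaml(
    manifest[c("config", "version", "best_k", "admissible", "filter",
               "timings", "files", "digests")],
    file.path(out_dir, "manifest.yaml"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> mode:", x$config$mode, "| best k:", x$best_k,
      "| filter:", x$filter, "\n  outputs:",
      paste(basename(unlist(x$files)), collapse = ", "), "\n")
  invisible(x)
}
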