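#' Construct and validate a cell table
#'
#' A cell table is the starting point of every analysis: one row per
#' segmented cell from a multiplexed imaging experiment, with planar
#' coordinates, marker intensities, an annotated cell type and a
#' sample-level condition. `cell_table()` validates a data frame against the
#' schema invariants and returns a tibble subclass that downstream verbs
#' recognise.
#'
#' Required columns: `cell_id` (unique integer), `sample_id`, `image_id`
#' (each image belongs to exactly one sample), `x`, `y` (planar coordinates,
#' consistent units within an image), `cell_type`, `condition` (constant
#' within a sample), plus one numeric column per marker.
#'
#' @param df A data frame with the columns above.
#' @param markers Character vector naming the marker columns, in the order
#'   they should be kept.
#' @param preprocessed Logical flag recording whether marker intensities have
#'   already been log-transformed and Z-scored (see
#'   [preprocess_intensities()]).
#' @return A `cell_table` tibble; marker names are stored in
#'   `attr(x, "markers")` and the preprocessing state in
#'   `attr(x, "preprocessed")`.
#' @seealso [load_cell_table()], [preprocess_intensities()]
#' @export
cell_table <- function(df, markers, preprocessed = FALSE) {
  required <- c("cell_id", "sample_id", "image_id", "x", "y",
                "cell_type", "condition")
  missing_cols <- setdiff(c(required, markers), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cytoniche_schema_error")
  }
  df <- tibble::as_tibble(df)[, c(required, markers)]

  if (anyDuplicated(df$cell_id)) {
    abort("cell_id values must be unique", class = "cytoniche_integrity_error")
  }
  if (anyNA(df$x) || anyNA(df$y)) {
    abort("coordinates must not contain missing values",
          class = "cytoniche_integrity_error")
  }
  img_map <- dplyr::distinct(df, .data$image_id, .data$sample_id)
  if (anyDuplicated(img_map$image_id)) {
    abort("each image_id must map to exactly one sample_id",
          class = "cytoniche_integrity_error")
  }
  cond_map <- dplyr::distinct(df, .data$sample_id, .data$condition)
  if (anyDuplicated(cond_map$sample_id)) {
    abort("each sample_id must map to exactly one condition",
          class = "cytoniche_integrity_error")
  }
  for (m in markers) {
    if (!is.numeric(df[[m]])) {
      abort(paste0("marker column '", m, "' is not numeric"),
            class = "cytoniche_parse_error")
    }
    if (anyNA(df[[m]])) {
      abort(paste0("marker column '", m, "' contains missing values"),
            class = "cytoniche_parse_error")
    }
  }

  structure(df,
            markers = markers,
            preprocessed = isTRUE(preprocessed),
            class = c("cell_table", class(tibble::tibble())))
}

#' Marker column names of a cell table
#' @param table A `cell_table`.
#' @return Character vector of marker column names.
#' @export
markers <- function(table) attr(table, "markers")

#' Has a cell table been preprocessed?
#' @param table A `cell_table`.
#' @return Logical scalar.
#' @export
is_preprocessed <- function(table) isTRUE(attr(table, "preprocessed"))

# marker matrix (cells x markers) for a subset of marker columns
marker_matrix <- function(table, which_markers = markers(table)) {
  m <- as.matrix(as.data.frame(table)[, which_markers, drop = FALSE])
  rownames(m) <- as.character(table$cell_id)
  m
}

#' Read a per-cell flat table from delimited text
#'
#' Reads the "flat table" export of a segmented multiplexed imaging
#' experiment (CSV or TSV, auto-detected from the file extension) and
#' validates it into a [cell_table()]. A `schema` maps the file's column
#' names onto the required roles, so tables from different platforms can be
#' loaded without renaming files by hand. Lines starting with `#` are
#' treated as comments; a provenance comment written by [write_cell_table()]
#' restores the preprocessing flag on round trip.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping roles to file column names. Roles:
#'   `cell_id`, `sample_id`, `image_id`, `x`, `y`, `cell_type`, `condition`,
#'   and `markers` (character vector of marker column names). Roles whose
#'   file column already carries the canonical name may be omitted;
#'   `markers` defaults to every numeric column not claimed by another role.
#' @return A validated `cell_table`.
#' @export
load_cell_table <- function(path, schema = list()) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  preprocessed <- grepl("preprocessed=true", first, fixed = TRUE)

  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)

  roles <- c("cell_id", "sample_id", "image_id", "x", "y",
             "cell_type", "condition")
  for (role in roles) {
    src <- schema[[role]] %||% role
    if (!src %in% names(raw)) {
      abort(paste0("schema role '", role, "' maps to column '", src,
                   "', which is absent from ", path),
            class = "cytoniche_schema_error")
    }
    if (src != role) names(raw)[names(raw) == src] <- role
  }
  mk <- schema$markers
  if (is.null(mk)) {
    candidates <- setdiff(names(raw), roles)
    mk <- candidates[vapply(raw[candidates], is.numeric, logical(1))]
    if (length(mk) == 0) {
      abort("no numeric marker columns found and schema$markers not given",
            class = "cytoniche_schema_error")
    }
  } else if (!all(mk %in% names(raw))) {
    abort(paste0("marker column(s) absent: ",
                 paste(setdiff(mk, names(raw)), collapse = ", ")),
          class = "cytoniche_schema_error")
  }
  cell_table(raw, markers = mk, preprocessed = preprocessed)
}

#' Write a cell table to CSV
#'
#' Serialises a [cell_table()] as plain CSV with a leading provenance
#' comment line recording the preprocessing state, so that
#' [load_cell_table()] round-trips losslessly.
#'
#' @param table A `cell_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  header <- paste0("# cytoniche cell table; preprocessed=",
                   tolower(as.character(is_preprocessed(table))),
                   "; markers=", paste(markers(table), collapse = "|"))
  writeLines(header, path)
  readr::write_csv(as.data.frame(table), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Log-transform and Z-score marker intensities
#'
#' Applies the standard two-step preprocessing for multiplexed imaging
#' intensities: each raw value x is replaced by `log(offset + x)` and each
#' marker column is then standardised to mean 0 and standard deviation 1.
#' By default the moments are computed across the whole dataset (all
#' samples, including any eventual test samples); set
#' `scaling_scope = "train_only"` to compute them on a subset of samples
#' and apply them to the rest.
#'
#' @param table A raw (not yet preprocessed) `cell_table` with nonnegative
#'   marker intensities.
#' @param offset Positive offset added before the natural log; default 1e-3.
#' @param scaling_scope `"dataset"` (default) or `"train_only"`.
#' @param scaling_samples When `scaling_scope = "train_only"`, the sample ids
#'   whose cells define the standardisation moments.
#' @return A preprocessed `cell_table`.
#' @export
preprocess_intensities <- function(table, offset = 1e-3,
                                   scaling_scope = c("dataset", "train_only"),
                                   scaling_samples = NULL) {
  scaling_scope <- match.arg(scaling_scope)
  if (is_preprocessed(table)) {
    abort("table is already preprocessed; refusing to preprocess twice",
          class = "cytoniche_state_error")
  }
  mk <- markers(table)
  x <- marker_matrix(table)
  if (any(x < 0)) {
    abort("raw marker intensities must be nonnegative",
          class = "cytoniche_domain_error")
  }
  x <- log(offset + x)

  ref_rows <- if (scaling_scope == "train_only") {
    if (is.null(scaling_samples)) {
      abort("scaling_samples required when scaling_scope = 'train_only'")
    }
    table$sample_id %in% scaling_samples
  } else rep(TRUE, nrow(x))

  mu <- colMeans(x[ref_rows, , drop = FALSE])
  sg <- apply(x[ref_rows, , drop = FALSE], 2, sd)
  if (any(sg == 0)) {
    abort(paste0("constant marker column(s) after log transform: ",
                 paste(mk[sg == 0], collapse = ", ")),
          class = "cytoniche_domain_error")
  }
  x <- sweep(sweep(x, 2, mu, "-"), 2, sg, "/")

  out <- table
  for (j in seq_along(mk)) out[[mk[j]]] <- unname(x[, j])
  attr(out, "preprocessed") <- TRUE
  out
}

#' Patient-level train/validation/test split
#'
#' Holds out whole samples (patients/donors) as a test set, drawn per
#' condition without replacement, so that no cell of a test patient ever
#' informs training. The remaining samples' multi-cell inputs are later
#' partitioned into training and validation fractions by [assign_sets()].
#'
#' @param table A `cell_table`.
#' @param n_test_samples_per_condition Number of samples per condition to
#'   hold out entirely (0 for no test set).
#' @param val_fraction Fraction of non-test inputs assigned to validation
#'   (default 0.2, i.e. an 80/20 train/validation partition).
#' @param seed Integer seed; the split is reproducible under it.
#' @return A `split_assignment` object with elements `test_samples`,
#'   `val_fraction` and `seed`.
#' @export
make_split <- function(table, n_test_samples_per_condition,
                       val_fraction = 0.2, seed = 1L) {
  stopifnot(val_fraction >= 0, val_fraction < 1)
  cond_map <- dplyr::distinct(as.data.frame(table),
                              .data$sample_id, .data$condition)
  test_samples <- character(0)
  if (n_test_samples_per_condition > 0) {
    test_samples <- withr::with_seed(derive_seed(seed, "split"), {
      unlist(lapply(split(cond_map$sample_id, cond_map$condition), function(s) {
        if (length(s) <= n_test_samples_per_condition) {
          abort(paste0("a condition has only ", length(s),
                       " samples; cannot hold out ",
                       n_test_samples_per_condition),
                class = "cytoniche_domain_error")
        }
        sample(as.character(s), n_test_samples_per_condition)
      }), use.names = FALSE)
    })
  }
  structure(list(test_samples = test_samples,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment> test samples:",
      if (length(x$test_samples)) paste(x$test_samples, collapse = ", ")
      else "(none)",
      "| val fraction:", x$val_fraction, "| seed:", x$seed, "\n")
  invisible(x)
}
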