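# Cell-type enrichment scores for selected cells in anchor neighbourhoods,
# computed per image and aggregated across the cohort by median and MAD.

#' Tabulate per-image enrichment counts
#'
#' For every image and cell type, counts the eight quantities the
#' enrichment scores are built from: N (cells in the image), N_T (cells of
#' the type), K (cells in the union of the image's anchor neighbourhoods),
#' K_T, and their selected-cell counterparts N_S, N_T_S, K_S, K_T_S.
#' Overlapping anchor neighbourhoods are merged as a set union, so a shared
#' cell is counted once. Background-labelled inputs do not contribute to
#' the neighbourhood union.
#'
#' @param table A `cell_table`.
#' @param selection A [select_cells()] result covering the counted cells
#'   (use `scope = "all"` so that image-wide counts N_S, N_T_S are defined).
#' @param inputs The `mc_inputs` tibble whose member sets define the anchor
#'   neighbourhoods.
#' @return A tibble with one row per (image, cell type) and count columns
#'   `N`, `N_T`, `K`, `K_T`, `N_S`, `N_T_S`, `K_S`, `K_T_S`, plus
#'   provenance (`image_id`, `sample_id`, `condition`).
#' @export
tabulate_counts <- function(table, selection, inputs) {
  anchor_inputs <- inputs[as.character(inputs$label) != "BG", ]
  imgs <- unique(table$image_id)
  no_input <- setdiff(imgs, unique(anchor_inputs$image_id))
  if (length(no_input) > 0) {
    warn(paste0("skipping ", length(no_input),
                " image(s) with no anchor inputs"))
    imgs <- setdiff(imgs, no_input)
  }
  sel <- selection$selected[match(table$cell_id, selection$cell_id)]
  if (anyNA(sel[table$image_id %in% imgs])) {
    abort(paste0("selection does not cover every cell of the counted ",
                 "images; run select_cells(scope = \"all\")"))
  }
  types <- sort(unique(as.character(table$cell_type)))

  nb_by_img <- lapply(split(anchor_inputs$members, anchor_inputs$image_id),
                      function(m) unique(unlist(m, use.names = FALSE)))

  out <- lapply(imgs, function(img) {
    rows <- table$image_id == img
    ct <- as.character(table$cell_type[rows])
    s <- sel[rows]
    in_nb <- table$cell_id[rows] %in% nb_by_img[[as.character(img)]]
    n_t <- base::table(factor(ct, levels = types))
    k_t <- base::table(factor(ct[in_nb], levels = types))
    n_t_s <- base::table(factor(ct[s], levels = types))
    k_t_s <- base::table(factor(ct[in_nb & s], levels = types))
    tibble::tibble(
      image_id = img,
      sample_id = table$sample_id[rows][1],
      condition = as.character(table$condition[rows][1]),
      cell_type = types,
      N = sum(rows), N_T = as.integer(n_t),
      K = sum(in_nb), K_T = as.integer(k_t),
      N_S = sum(s), N_T_S = as.integer(n_t_s),
      K_S = sum(in_nb & s), K_T_S = as.integer(k_t_s))
  })
  dplyr::bind_rows(out)
}

# exact rational-style evaluation of the local enrichment score for one row
.local_es_one <- function(N, N_T, K, K_T, N_S, N_T_S, K_S, K_T_S) {
  if (N == 0 || N_S == 0) return(NA_real_)
  E_T <- K * N_T / N
  E_T_S <- K_S * N_T_S / N_S
  if (E_T == 0 || E_T_S == 0) return(NA_real_)
  S_T <- K_T / E_T
  if (S_T == 0) return(NA_real_)
  (K_T_S / E_T_S) / S_T
}

.global_es_one <- function(N, N_T, N_S, N_T_S) {
  if (N == 0 || N_T == 0 || N_S == 0) return(NA_real_)
  N_T_S / (N_S * N_T / N)
}

#' Local enrichment score per (image, cell type)
#'
#' The local score compares how over-represented a cell type is among
#' selected cells inside the anchor neighbourhoods against how
#' over-represented the type is in the neighbourhoods at all:
#' `ES_T = (K_T_S / E_T_S) / (K_T / E_T)` with expectations
#' `E_T = K * N_T / N` and `E_T_S = K_S * N_T_S / N_S`. A value above one
#' indicates enrichment of the selected cells of that type in the anchor
#' niche. Rows whose expectations (or `K_T / E_T`) are zero get `NA` with
#' `es_defined = FALSE` rather than a propagating NaN.
#'
#' @param counts A [tabulate_counts()] result.
#' @return `counts` with columns `es` and `es_defined` added.
#' @export
local_es <- function(counts) {
  es <- mapply(.local_es_one, counts$N, counts$N_T, counts$K, counts$K_T,
               counts$N_S, counts$N_T_S, counts$K_S, counts$K_T_S)
  out <- counts
  out$es <- as.numeric(es)
  out$es_defined <- !is.na(out$es)
  out
}

#' Global enrichment score per (image, cell type)
#'
#' The global score is the image-wide selected-vs-expected ratio
#' `ES_T = N_T_S / (N_S * N_T / N)`, which equals the ratio of the type's
#' share among selected cells to its share among all cells. Undefined when
#' the type or the selection is absent from the image.
#'
#' @param counts A [tabulate_counts()] result.
#' @return `counts` with columns `es` and `es_defined` added.
#' @export
global_es <- function(counts) {
  es <- mapply(.global_es_one, counts$N, counts$N_T, counts$N_S,
               counts$N_T_S)
  out <- counts
  out$es <- as.numeric(es)
  out$es_defined <- !is.na(out$es)
  out
}

#' Aggregate enrichment scores across the cohort
#'
#' Reduces per-image scores to one value per sample (median over the
#' sample's images) and then summarises each (condition, cell type) by the
#' cohort median and the median absolute deviation (MAD, unscaled).
#' Undefined per-image scores are excluded and counted. The
#' `selected_ratio` column (selected / total cells of the type within the
#' group) is the bubble-size statistic of the standard enrichment plots.
#'
#' @param scored A [local_es()] or [global_es()] result.
#' @return An `enrichment_result` tibble with one row per
#'   (condition, cell type): `median_es`, `mad_es`, `n_samples`,
#'   `n_excluded`, `selected_ratio`.
#' @export
aggregate_es <- function(scored) {
  per_sample <- dplyr::summarise(
    dplyr::group_by(scored, .data$condition, .data$cell_type,
                    .data$sample_id),
    es_sample = if (any(.data$es_defined)) {
      median(.data$es[.data$es_defined])
    } else NA_real_,
    n_excluded = sum(!.data$es_defined),
    .groups = "drop")

  ratio <- dplyr::summarise(
    dplyr::group_by(scored, .data$condition, .data$cell_type),
    selected_ratio = ifelse(sum(.data$N_T) > 0,
                            sum(.data$N_T_S) / sum(.data$N_T), NA_real_),
    .groups = "drop")

  out <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$condition, .data$cell_type),
    median_es = if (any(!is.na(.data$es_sample))) {
      median(.data$es_sample, na.rm = TRUE)
    } else NA_real_,
    mad_es = if (any(!is.na(.data$es_sample))) {
      mad(.data$es_sample, constant = 1, na.rm = TRUE)
    } else NA_real_,
    n_samples = sum(!is.na(.data$es_sample)),
    n_excluded = sum(.data$n_excluded),
    .groups = "drop")
  out <- dplyr::left_join(out, ratio, by = c("condition", "cell_type"))
  structure(out,
            class = c("enrichment_result", class(tibble::tibble())))
}
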