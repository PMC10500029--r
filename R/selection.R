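# Selection of phenotype-relevant cells by positive filter response and
# their per-patient frequency statistics.

#' Score cells by filter response and flag the selected subset
#'
#' Computes the filter response (scalar product with one trained filter) for
#' every cell in scope and flags cells whose response exceeds the threshold
#' as "selected". The default scope is every cell that appears as a member
#' of at least one multi-cell input; `scope = "all"` scores every cell of
#' the table instead (needed for image-wide enrichment counts).
#'
#' @param model A `niche_model`.
#' @param table The `cell_table` the inputs were built from.
#' @param inputs The `mc_inputs` tibble defining the default scope.
#' @param filter_index Which filter to use (1-based).
#' @param threshold Selection threshold on the response (default 0).
#' @param scope `"inputs"` (default) or `"all"`.
#' @return A `selection_result` tibble with `cell_id`, `response`,
#'   `selected`; the filter index and threshold are kept as attributes.
#' @export
select_cells <- function(model, table, inputs, filter_index = 1L,
                         threshold = 0, scope = c("inputs", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(model, "niche_model"))
  if (scope == "inputs") {
    if (nrow(inputs) == 0) abort("empty input list")
    ids <- sort(unique(unlist(inputs$members, use.names = FALSE)))
  } else {
    ids <- table$cell_id
  }
  fm <- model$feature_markers
  if (!all(fm %in% markers(table))) {
    abort("model feature markers are absent from the table")
  }
  x <- marker_matrix(table[match(ids, table$cell_id), ], fm)
  response <- unname(filter_response(model, x, filter_index))
  structure(
    tibble::tibble(cell_id = ids, response = response,
                   selected = response > threshold),
    filter_index = as.integer(filter_index), threshold = threshold,
    scope = scope,
    class = c("selection_result", class(tibble::tibble())))
}

#' Per-sample selected-cell frequencies by label class
#'
#' For every sample and input label class, the relative frequency of
#' selected cells among that sample's input member-cell occurrences (a cell
#' occurring in several inputs counts each time). Background-labelled
#' inputs are reported as their own class.
#'
#' @param selection A [select_cells()] result covering the input members.
#' @param inputs The `mc_inputs` tibble.
#' @return A tibble with `sample_id`, `label`, `n_occurrences`,
#'   `n_selected`, `frequency`.
#' @export
frequency_per_sample <- function(selection, inputs) {
  lens <- lengths(inputs$members)
  occ <- tibble::tibble(
    sample_id = rep(inputs$sample_id, lens),
    label = rep(as.character(inputs$label), lens),
    cell_id = unlist(inputs$members, use.names = FALSE))
  sel <- selection$selected[match(occ$cell_id, selection$cell_id)]
  if (anyNA(sel)) {
    abort("selection does not cover all input member cells")
  }
  occ$selected <- sel
  out <- dplyr::summarise(
    dplyr::group_by(occ, .data$sample_id, .data$label),
    n_occurrences = dplyr::n(),
    n_selected = sum(.data$selected),
    frequency = mean(.data$selected),
    .groups = "drop")
  out
}

#' Compare selected-cell frequencies between two groups
#'
#' Two-sided Wilcoxon rank-sum test on per-sample frequencies: exact when
#' both groups have at most 12 samples and no ties, normal approximation
#' (with continuity correction) otherwise. The direction reports which
#' group has the larger median frequency.
#'
#' @param freqs A [frequency_per_sample()] result.
#' @param group_a,group_b Label classes to compare.
#' @return A one-row tibble with group sizes, medians, `direction`
#'   (the group with the larger median, `NA` if tied), `p_value`, `method`.
#' @export
compare_frequencies <- function(freqs, group_a, group_b) {
  fa <- freqs$frequency[freqs$label == group_a]
  fb <- freqs$frequency[freqs$label == group_b]
  if (length(fa) < 2 || length(fb) < 2) {
    abort("need at least two samples per group",
          class = "cytoniche_domain_error")
  }
  all_tied <- length(unique(c(fa, fb))) == 1L
  if (all_tied) {
    p <- 1
    method <- "degenerate (all values tied)"
  } else {
    has_ties <- anyDuplicated(c(fa, fb)) > 0
    use_exact <- length(fa) <= 12 && length(fb) <= 12 && !has_ties
    wt <- suppressWarnings(
      wilcox.test(fa, fb, alternative = "two.sided",
                  exact = use_exact, correct = TRUE))
    p <- wt$p.value
    method <- if (use_exact) "exact rank-sum" else "normal approximation"
  }
  med_a <- median(fa)
  med_b <- median(fb)
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    n_a = length(fa), n_b = length(fb),
    median_a = med_a, median_b = med_b,
    direction = if (med_a == med_b) NA_character_
                else if (med_a > med_b) group_a else group_b,
    p_value = p, method = method)
}

#' Choose the neighbourhood size k from a sweep
#'
#' Global mode: the k with the smallest validation condition-vs-condition
#' p-value wins. Local mode follows the two-step rule: (1) keep only the k
#' at which the two conditions' selected-cell frequencies differ
#' significantly (at `alpha`), then (2) among those, pick the k with the
#' most significant winning-condition-vs-background comparison. Ties go to
#' the smaller k.
#'
#' @param per_k A tibble with one row per evaluated k: column `k`,
#'   `p_condition` (condition-vs-condition p on validation) and, for local
#'   mode, `p_background` (winning condition vs background).
#' @param mode `"global"` or `"local"`.
#' @param alpha Significance level for local step (1); default 0.05.
#' @return A one-row tibble with `best_k` (`NA` if local mode finds no
#'   admissible k) and `admissible` (logical).
#' @export
choose_k <- function(per_k, mode = c("global", "local"), alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(nrow(per_k) >= 1, "k" %in% names(per_k),
            "p_condition" %in% names(per_k))
  per_k <- per_k[order(per_k$k), ]
  if (mode == "global") {
    best <- per_k$k[which.min(per_k$p_condition)]
    return(tibble::tibble(best_k = best, admissible = TRUE, mode = mode))
  }
  stopifnot("p_background" %in% names(per_k))
  keep <- per_k[!is.na(per_k$p_condition) & per_k$p_condition < alpha, ]
  if (nrow(keep) == 0) {
    return(tibble::tibble(best_k = NA_integer_, admissible = FALSE,
                          mode = mode))
  }
  best <- keep$k[which.min(keep$p_background)]
  tibble::tibble(best_k = best, admissible = TRUE, mode = mode)
}

#' Group functional-mode inputs into high/low label classes
#'
#' For regression analyses, inputs are grouped by whether their continuous
#' label is above or below the mean label across all inputs, mirroring the
#' high/low reporting of functional spatial enrichment.
#'
#' @param inputs A functional-mode `mc_inputs` tibble (numeric labels).
#' @return `inputs` with the `label` column replaced by `"high"`/`"low"`;
#'   the original labels are kept in `label_value`.
#' @export
dichotomize_functional <- function(inputs) {
  y <- as.numeric(inputs$label)
  out <- inputs
  out$label_value <- y
  out$label <- ifelse(y > mean(y), "high", "low")
  out
}
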