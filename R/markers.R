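# Differential marker expression between selected and non-selected cells,
# quantified by the two-sample Kolmogorov-Smirnov statistic used as an
# effect size (no p-values).

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum over x of the absolute difference between the two empirical
#' CDFs. Values are in \[0, 1\]: 0 means the distributions coincide, 1
#' means disjoint supports. Ties within and across samples are handled
#' exactly. The statistic is invariant under any common strictly monotone
#' transform of both samples.
#'
#' @param a,b Nonempty numeric samples.
#' @return The KS statistic, a number in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be nonempty", class = "cytoniche_domain_error")
  }
  x <- sort(unique(c(a, b)))
  fa <- findInterval(x, sort(a)) / length(a)
  fb <- findInterval(x, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Differential marker expression of the selected subset
#'
#' For the all-cells scope and for each cell type with enough cells in both
#' groups, computes the KS statistic per marker between selected and
#' non-selected cells, together with the direction of the shift (sign of
#' the median difference). Markers are rank-ordered by KS within each
#' scope. KS is computed on the table's (preprocessed) intensities; since
#' the statistic is invariant to monotone rescaling, min-max normalisation
#' is only a display choice and does not affect the values.
#'
#' @param table A `cell_table`.
#' @param selection A [select_cells()] result; cells in its scope are
#'   compared (selected vs non-selected).
#' @param min_cells Minimum cells required in each group of a scope for the
#'   KS statistics to be reported (default 10); smaller scopes are kept as
#'   flagged rows with `ks = NA`.
#' @return A `marker_shift` tibble: `scope` (`"all"` or a cell type),
#'   `marker`, `ks`, `rank` (within scope), `direction`
#'   (`"higher"`/`"lower"` in the selected subset), `n_selected`,
#'   `n_nonselected`, `flagged`.
#' @export
differential_markers <- function(table, selection, min_cells = 10L) {
  idx <- match(selection$cell_id, table$cell_id)
  if (anyNA(idx)) abort("selection cells missing from table")
  sub <- table[idx, ]
  sel <- selection$selected
  mk <- markers(table)
  scopes <- c("all", sort(unique(as.character(sub$cell_type))))

  one_scope <- function(scope) {
    rows <- if (scope == "all") rep(TRUE, nrow(sub))
            else as.character(sub$cell_type) == scope
    s <- sel[rows]
    n_sel <- sum(s)
    n_non <- sum(!s)
    flagged <- n_sel < min_cells || n_non < min_cells
    res <- lapply(mk, function(m) {
      v <- sub[[m]][rows]
      if (flagged) {
        tibble::tibble(marker = m, ks = NA_real_, direction = NA_character_)
      } else {
        a <- v[s]
        b <- v[!s]
        d <- median(a) - median(b)
        tibble::tibble(marker = m, ks = ks_statistic(a, b),
                       direction = if (d > 0) "higher"
                                   else if (d < 0) "lower" else "equal")
      }
    })
    res <- dplyr::bind_rows(res)
    res$scope <- scope
    res$n_selected <- n_sel
    res$n_nonselected <- n_non
    res$flagged <- flagged
    res$rank <- if (flagged) NA_integer_ else {
      as.integer(rank(-res$ks, ties.method = "first"))
    }
    res
  }

  out <- dplyr::bind_rows(lapply(scopes, one_scope))
  out <- out[, c("scope", "marker", "ks", "rank", "direction",
                 "n_selected", "n_nonselected", "flagged")]
  structure(tibble::as_tibble(out),
            min_cells = as.integer(min_cells),
            class = c("marker_shift", class(tibble::tibble())))
}
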