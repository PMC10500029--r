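#' k-nearest spatial neighbours of one anchor cell
#'
#' Finds the k cells of one image nearest to an anchor cell by Euclidean
#' distance on the (x, y) coordinates. The anchor itself is excluded unless
#' `include_anchor = TRUE`; distance ties are broken deterministically by
#' ascending `cell_id` so results are bit-reproducible.
#'
#' @param image_cells Data frame of the cells of a single image, with
#'   columns `cell_id`, `x`, `y`.
#' @param anchor `cell_id` of the anchor cell (must occur in `image_cells`).
#' @param k Neighbourhood size.
#' @param include_anchor Keep the anchor cell itself as a neighbour?
#' @return Integer vector of the k nearest `cell_id`s, ordered by distance.
#' @export
knn_query <- function(image_cells, anchor, k, include_anchor = FALSE) {
  i <- match(anchor, image_cells$cell_id)
  if (is.na(i)) abort("anchor cell not found in image_cells")
  n_avail <- nrow(image_cells) - if (include_anchor) 0L else 1L
  if (n_avail < k) {
    abort(paste0("image has only ", nrow(image_cells),
                 " cells; cannot form a ", k, "-neighbourhood"),
          class = "cytoniche_domain_error")
  }
  d2 <- (image_cells$x - image_cells$x[i])^2 +
        (image_cells$y - image_cells$y[i])^2
  ids <- image_cells$cell_id
  if (!include_anchor) {
    d2 <- d2[-i]
    ids <- ids[-i]
  }
  ord <- order(d2, ids)[seq_len(k)]
  ids[ord]
}

# k-NN member lists for several anchors of one image (row indices into the
# image's cell set); same ordering contract as knn_query.
.knn_members <- function(xy, ids, anchor_rows, k, include_anchor = FALSE) {
  lapply(anchor_rows, function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    keep_ids <- ids
    if (!include_anchor) {
      d2 <- d2[-i]
      keep_ids <- keep_ids[-i]
    }
    keep_ids[order(d2, keep_ids)[seq_len(k)]]
  })
}

# assemble an mc_inputs tibble from per-input pieces
.new_mc_inputs <- function(anchor_id, image_id, sample_id, label, members,
                           table, feature_markers, k, mode,
                           functional_marker = NULL) {
  xm <- marker_matrix(table, feature_markers)
  row_of <- match(unlist(members, use.names = FALSE), table$cell_id)
  lens <- lengths(members)
  idx <- split(row_of, rep(seq_along(members), lens))
  features <- lapply(idx, function(r) xm[r, , drop = FALSE])

  out <- tibble::tibble(
    input_id = seq_along(members),
    anchor_cell_id = anchor_id,
    image_id = image_id,
    sample_id = sample_id,
    label = label,
    members = members,
    features = unname(features)
  )
  structure(out,
            k = as.integer(k), mode = mode,
            feature_markers = feature_markers,
            functional_marker = functional_marker,
            class = c("mc_inputs", class(tibble::tibble())))
}

# images large enough to host a k-neighbourhood; warn about the rest
.usable_images <- function(table, k) {
  sizes <- base::table(table$image_id)
  too_small <- names(sizes)[sizes < k + 1]
  if (length(too_small) > 0) {
    warn(paste0("skipping ", length(too_small), " image(s) with fewer than ",
                k + 1, " cells: ", paste(too_small, collapse = ", ")))
  }
  setdiff(unique(table$image_id), too_small)
}

.check_preprocessed <- function(table) {
  if (!is_preprocessed(table)) {
    warn("cell table is not preprocessed; multi-cell inputs built on raw intensities")
  }
}

#' Build global-mode multi-cell inputs
#'
#' Global spatial enrichment analysis draws random anchor cells in every
#' image and represents each anchor by the marker matrix of its k nearest
#' neighbours. Every multi-cell input inherits the condition label of the
#' image's sample, so a classifier trained on these inputs is weakly
#' supervised: it sees only sample-level phenotype labels.
#'
#' @param table A preprocessed `cell_table`.
#' @param k Neighbourhood size (typically 10--100).
#' @param n_anchors_per_image Random anchors per image (default 100); images
#'   with fewer cells contribute one anchor per cell.
#' @param seed Integer seed for the anchor draws.
#' @param include_anchor Keep anchors inside their own neighbourhoods?
#' @return An `mc_inputs` tibble with one row per multi-cell input: anchor,
#'   provenance, label, member `cell_id`s and the K x M feature matrix.
#' @export
build_global_inputs <- function(table, k, n_anchors_per_image = 100,
                                seed = 1L, include_anchor = FALSE) {
  .check_preprocessed(table)
  imgs <- .usable_images(table, k)
  if (length(imgs) == 0) abort("no image is large enough for this k")

  withr::with_seed(derive_seed(seed, "anchors"), {
    pieces <- lapply(imgs, function(img) {
      cells <- table[table$image_id == img, ]
      n_anchor <- min(n_anchors_per_image, nrow(cells))
      rows <- sample.int(nrow(cells), n_anchor)
      members <- .knn_members(cbind(cells$x, cells$y), cells$cell_id,
                              rows, k, include_anchor)
      list(anchor = cells$cell_id[rows],
           image = rep(img, n_anchor),
           sample = rep(cells$sample_id[1], n_anchor),
           label = rep(as.character(cells$condition[1]), n_anchor),
           members = members)
    })
    .new_mc_inputs(
      anchor_id = unlist(lapply(pieces, `[[`, "anchor")),
      image_id = unlist(lapply(pieces, `[[`, "image")),
      sample_id = unlist(lapply(pieces, `[[`, "sample")),
      label = unlist(lapply(pieces, `[[`, "label")),
      members = do.call(c, lapply(pieces, `[[`, "members")),
      table = table, feature_markers = markers(table), k = k,
      mode = "global")
  })
}

#' Build local-mode multi-cell inputs (typed anchors plus background)
#'
#' Local spatial enrichment analysis asks which cell subsets are enriched in
#' the immediate neighbourhood of a chosen anchor cell type. Every cell of
#' the anchor type becomes an anchor whose k-NN neighbourhood is labelled
#' with the sample's condition; a matched set of neighbourhoods around
#' random anchors of any type is added under the background label `"BG"`,
#' so that the classifier must find signatures specific to the anchor
#' type's niche rather than generic image-level differences.
#'
#' @param table A preprocessed `cell_table`.
#' @param anchor_type Cell type whose niches are analysed.
#' @param k Neighbourhood size.
#' @param seed Integer seed for the background anchor draws.
#' @param n_background Number of background inputs; defaults to the mean
#'   per-condition input count, keeping the classes balanced.
#' @param exclude_anchor_type_bg Exclude anchor-type cells from serving as
#'   background anchors? Default `FALSE`.
#' @param include_anchor Keep anchors inside their own neighbourhoods?
#' @return An `mc_inputs` tibble with labels in
#'   `c(levels(condition), "BG")`.
#' @export
build_local_inputs <- function(table, anchor_type, k, seed = 1L,
                               n_background = NULL,
                               exclude_anchor_type_bg = FALSE,
                               include_anchor = FALSE) {
  .check_preprocessed(table)
  if (!anchor_type %in% table$cell_type) {
    abort(paste0("anchor type '", anchor_type, "' absent from table"),
          class = "cytoniche_domain_error")
  }
  imgs <- .usable_images(table, k)
  if (length(imgs) == 0) abort("no image is large enough for this k")
  tab <- table[table$image_id %in% imgs, ]

  typed <- lapply(imgs, function(img) {
    cells <- tab[tab$image_id == img, ]
    rows <- which(cells$cell_type == anchor_type)
    if (length(rows) == 0) return(NULL)
    members <- .knn_members(cbind(cells$x, cells$y), cells$cell_id,
                            rows, k, include_anchor)
    list(anchor = cells$cell_id[rows],
         image = rep(img, length(rows)),
         sample = rep(cells$sample_id[1], length(rows)),
         label = rep(as.character(cells$condition[1]), length(rows)),
         members = members)
  })
  typed <- typed[!vapply(typed, is.null, logical(1))]
  if (length(typed) == 0) {
    abort("anchor type occurs only in images too small for this k",
          class = "cytoniche_domain_error")
  }
  lab <- unlist(lapply(typed, `[[`, "label"))
  if (is.null(n_background)) {
    n_background <- round(mean(base::table(lab)))
  }

  bg <- withr::with_seed(derive_seed(seed, "background"), {
    pool <- tab
    if (exclude_anchor_type_bg) pool <- pool[pool$cell_type != anchor_type, ]
    rows <- sample.int(nrow(pool), min(n_background, nrow(pool)))
    picked <- pool[rows, c("cell_id", "image_id")]
    by_img <- split(picked$cell_id, picked$image_id)
    pieces <- lapply(names(by_img), function(img) {
      cells <- tab[tab$image_id == img, ]
      arows <- match(by_img[[img]], cells$cell_id)
      members <- .knn_members(cbind(cells$x, cells$y), cells$cell_id,
                              arows, k, include_anchor)
      list(anchor = cells$cell_id[arows],
           image = rep(img, length(arows)),
           sample = rep(cells$sample_id[1], length(arows)),
           members = members)
    })
    pieces
  })

  .new_mc_inputs(
    anchor_id = c(unlist(lapply(typed, `[[`, "anchor")),
                  unlist(lapply(bg, `[[`, "anchor"))),
    image_id = c(unlist(lapply(typed, `[[`, "image")),
                 unlist(lapply(bg, `[[`, "image"))),
    sample_id = c(unlist(lapply(typed, `[[`, "sample")),
                  unlist(lapply(bg, `[[`, "sample"))),
    label = c(lab, rep("BG", sum(vapply(bg, function(p) length(p$anchor),
                                        integer(1))))),
    members = c(do.call(c, lapply(typed, `[[`, "members")),
                do.call(c, lapply(bg, `[[`, "members"))),
    table = table, feature_markers = markers(table), k = k,
    mode = "local")
}

#' Build functional-mode multi-cell inputs (continuous labels)
#'
#' Functional spatial enrichment analysis relates the composition of an
#' anchor type's niche to a continuous readout of local signalling: each
#' anchor-type cell yields one input whose label is the mean expression of
#' a chosen functional marker over the k neighbourhood cells. That marker
#' is removed from the feature matrix, leaving M-1 feature columns, so the
#' regression cannot read its own target off the inputs.
#'
#' @param table A preprocessed `cell_table`.
#' @param anchor_type Anchor cell type.
#' @param functional_marker Marker whose local mean expression is the
#'   regression label.
#' @param k Neighbourhood size.
#' @param include_anchor Keep anchors inside their own neighbourhoods?
#' @return An `mc_inputs` tibble with numeric labels and K x (M-1) feature
#'   matrices.
#' @export
build_functional_inputs <- function(table, anchor_type, functional_marker,
                                    k, include_anchor = FALSE) {
  .check_preprocessed(table)
  mk <- markers(table)
  if (!functional_marker %in% mk) {
    abort(paste0("functional marker '", functional_marker, "' not found"),
          class = "cytoniche_domain_error")
  }
  if (length(mk) < 2) {
    abort("need at least two markers to exclude the functional marker",
          class = "cytoniche_domain_error")
  }
  if (!anchor_type %in% table$cell_type) {
    abort(paste0("anchor type '", anchor_type, "' absent from table"),
          class = "cytoniche_domain_error")
  }
  imgs <- .usable_images(table, k)
  if (length(imgs) == 0) abort("no image is large enough for this k")
  tab <- table[table$image_id %in% imgs, ]

  pieces <- lapply(imgs, function(img) {
    cells <- tab[tab$image_id == img, ]
    rows <- which(cells$cell_type == anchor_type)
    if (length(rows) == 0) return(NULL)
    members <- .knn_members(cbind(cells$x, cells$y), cells$cell_id,
                            rows, k, include_anchor)
    fm <- cells[[functional_marker]]
    labels <- vapply(members, function(ids)
      mean(fm[match(ids, cells$cell_id)]), numeric(1))
    list(anchor = cells$cell_id[rows],
         image = rep(img, length(rows)),
         sample = rep(cells$sample_id[1], length(rows)),
         label = labels,
         members = members)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    abort("anchor type occurs only in images too small for this k",
          class = "cytoniche_domain_error")
  }

  .new_mc_inputs(
    anchor_id = unlist(lapply(pieces, `[[`, "anchor")),
    image_id = unlist(lapply(pieces, `[[`, "image")),
    sample_id = unlist(lapply(pieces, `[[`, "sample")),
    label = unlist(lapply(pieces, `[[`, "label")),
    members = do.call(c, lapply(pieces, `[[`, "members")),
    table = table, feature_markers = setdiff(mk, functional_marker), k = k,
    mode = "functional", functional_marker = functional_marker)
}

#' Assign multi-cell inputs to train/validation/test sets
#'
#' Inputs from held-out test samples go to the test set; the rest are
#' partitioned at random into training and validation at the split's
#' `val_fraction`, reproducibly under the split's seed. The partition is at
#' input level, but test membership is at sample level, so no patient leaks
#' across the test boundary.
#'
#' @param inputs An `mc_inputs` tibble.
#' @param split A [make_split()] result.
#' @return `inputs` with an added `set` column
#'   (`"train"`, `"validation"`, `"test"`).
#' @export
assign_sets <- function(inputs, split) {
  stopifnot(inherits(split, "split_assignment"))
  set <- rep("train", nrow(inputs))
  is_test <- inputs$sample_id %in% split$test_samples
  set[is_test] <- "test"
  nontest <- which(!is_test)
  n_val <- round(split$val_fraction * length(nontest))
  val_idx <- withr::with_seed(derive_seed(split$seed, "valsplit"),
                              sample(nontest, n_val))
  set[val_idx] <- "validation"
  out <- inputs
  out$set <- set
  out
}
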