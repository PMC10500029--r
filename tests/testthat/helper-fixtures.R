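# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# minimal hand-written table: 3 cells, 2 markers, 1 image
tiny_table <- function() {
  cell_table(
    data.frame(cell_id = 1:3, sample_id = "s1", image_id = "i1",
               x = c(0, 1, 2), y = c(0, 0, 0),
               cell_type = c("a", "b", "a"), condition = "g1",
               mk1 = c(0.5, 1.5, 2.5), mk2 = c(3, 2, 1)),
    markers = c("mk1", "mk2"))
}

# random multi-image table with controllable geometry
random_table <- function(n_images = 2, cells_per_image = 50, n_markers = 3,
                         n_samples = n_images, seed = 1,
                         preprocessed = FALSE, integer_coords = FALSE) {
  withr::with_seed(seed, {
    mk <- paste0("mk", seq_len(n_markers))
    rows <- lapply(seq_len(n_images), function(i) {
      s <- paste0("s", ((i - 1) %% n_samples) + 1)
      df <- data.frame(
        cell_id = (i - 1) * cells_per_image + seq_len(cells_per_image),
        sample_id = s, image_id = paste0("i", i),
        x = if (integer_coords) sample(0:14, cells_per_image, TRUE)
            else runif(cells_per_image),
        y = if (integer_coords) sample(0:14, cells_per_image, TRUE)
            else runif(cells_per_image),
        cell_type = sample(c("a", "b", "c"), cells_per_image, TRUE),
        condition = if (as.integer(sub("s", "", s)) %% 2 == 1) "g1" else "g2")
      for (m in mk) df[[m]] <- if (preprocessed) rnorm(cells_per_image)
                               else rexp(cells_per_image)
      df
    })
    cell_table(do.call(rbind, rows), markers = mk,
               preprocessed = preprocessed)
  })
}

# hand-assembled mc_inputs from a list of feature matrices (model tests)
mc_inputs_from_features <- function(features, labels, sets = NULL,
                                    sample_ids = NULL,
                                    feature_markers = NULL) {
  n <- length(features)
  k <- nrow(features[[1]])
  if (is.null(feature_markers)) {
    feature_markers <- paste0("mk", seq_len(ncol(features[[1]])))
  }
  out <- tibble::tibble(
    input_id = seq_len(n), anchor_cell_id = NA_integer_,
    image_id = "i1",
    sample_id = sample_ids %||% rep("s1", n),
    label = labels,
    members = replicate(n, integer(0), simplify = FALSE),
    features = features)
  if (!is.null(sets)) out$set <- sets
  structure(out, k = k, mode = "synthetic",
            feature_markers = feature_markers,
            class = c("mc_inputs", class(tibble::tibble())))
}

# two-class separable multi-cell inputs: class "A" inputs contain a subset
# of cells shifted on one marker
separable_inputs <- function(n_per_class = 150, k = 20, n_markers = 12,
                             shift = 2, n_shifted = 5, shift_marker = 7,
                             seed = 1, val_fraction = 0.2) {
  withr::with_seed(seed, {
    make_one <- function(shifted) {
      x <- matrix(rnorm(k * n_markers), k, n_markers)
      if (shifted) {
        x[seq_len(n_shifted), shift_marker] <-
          x[seq_len(n_shifted), shift_marker] + shift
      }
      x
    }
    feats <- c(lapply(seq_len(n_per_class), function(i) make_one(TRUE)),
               lapply(seq_len(n_per_class), function(i) make_one(FALSE)))
    n_val <- round(val_fraction * n_per_class)
    sets <- rep(rep(c("train", "validation"),
                    c(n_per_class - n_val, n_val)), 2)
    mc_inputs_from_features(
      feats, labels = rep(c("A", "B"), each = n_per_class), sets = sets,
      sample_ids = rep(c("sA", "sB"), each = n_per_class))
  })
}

# construct a niche_model by hand from explicit weights
manual_model <- function(W, b = NULL, W_out = NULL, b_out = NULL,
                         pooling = "mean", task = "regression",
                         classes = NULL, feature_markers = NULL) {
  W <- as.matrix(W)
  structure(list(
    W = W, b = b %||% numeric(nrow(W)),
    W_out = W_out %||% matrix(1, nrow(W), if (task == "regression") 1
                              else length(classes)),
    b_out = b_out %||% numeric(if (task == "regression") 1
                               else length(classes)),
    pooling = pooling, task = task, classes = classes,
    feature_markers = feature_markers %||% paste0("mk", seq_len(ncol(W))),
    k = NA_integer_, hyperparams = list(), val_score = NA_real_,
    seed = NA_integer_), class = "niche_model")
}

# exhaustive-enumeration oracle for the two-sided rank-sum p-value
# (continuous data, no ties), mirroring the exact test's tail doubling
wilcox_enum_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  ws <- apply(idx, 2, function(ii) sum(r[ii])) - n * (n + 1) / 2
  if (w_obs > n * m / 2) {
    p <- 2 * mean(ws >= w_obs)
  } else {
    p <- 2 * mean(ws <= w_obs)
  }
  min(p, 1)
}

# exhaustive ECDF-sup oracle for the KS statistic
ks_oracle <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# brute-force k-NN oracle: full distance sort with cell_id tie-break
knn_oracle <- function(image_cells, anchor, k) {
  i <- match(anchor, image_cells$cell_id)
  d2 <- (image_cells$x - image_cells$x[i])^2 +
        (image_cells$y - image_cells$y[i])^2
  ord <- order(d2, image_cells$cell_id)
  ids <- image_cells$cell_id[ord]
  setdiff(ids, anchor)[seq_len(k)]
}
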