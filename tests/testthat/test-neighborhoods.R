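test_that("knn_query returns nearest cells with deterministic tie-breaks", {
  cells <- data.frame(cell_id = 1:4, x = c(0, 1, 2, 3), y = 0)
  expect_equal(knn_query(cells, anchor = 1, k = 1), 2)
  expect_equal(knn_query(cells, anchor = 1, k = 3), c(2, 3, 4))

  # two cells exactly equidistant: smaller cell_id wins
  tie <- data.frame(cell_id = c(10, 7, 3), x = c(0, 1, -1), y = 0)
  expect_equal(knn_query(tie, anchor = 10, k = 1), 3)

  expect_error(knn_query(cells, anchor = 1, k = 4),
               class = "cytoniche_domain_error")
})

test_that("knn_query agrees with the brute-force distance-sort oracle", {
  for (seed in 1:3) {
    tab <- random_table(n_images = 1, cells_per_image = 50, seed = seed)
    cells <- as.data.frame(tab)[, c("cell_id", "x", "y")]
    for (anchor in sample(cells$cell_id, 5)) {
      expect_equal(knn_query(cells, anchor, k = 10),
                   knn_oracle(cells, anchor, k = 10))
    }
  }
  # integer coordinates force many exact ties
  tab <- random_table(n_images = 1, cells_per_image = 60, seed = 8,
                      integer_coords = TRUE)
  cells <- as.data.frame(tab)[, c("cell_id", "x", "y")]
  for (anchor in cells$cell_id[1:8]) {
    expect_equal(knn_query(cells, anchor, k = 12),
                 knn_oracle(cells, anchor, k = 12))
  }
})

test_that("global inputs: counts, label propagation, seeding, provenance", {
  tab <- random_table(n_images = 2, cells_per_image = 60, seed = 3,
                      preprocessed = TRUE)
  inp <- build_global_inputs(tab, k = 30, n_anchors_per_image = 100,
                             seed = 5)
  # images smaller than the anchor request contribute one input per cell
  expect_equal(nrow(inp), 2 * 60)
  expect_true(all(lengths(inp$members) == 30))
  expect_true(all(vapply(inp$features, nrow, integer(1)) == 30))

  # labels equal the condition of each input's sample
  cond <- unique(as.data.frame(tab)[, c("sample_id", "condition")])
  expect_equal(inp$label,
               cond$condition[match(inp$sample_id, cond$sample_id)])

  # neighbourhoods never cross image boundaries
  img_of <- tab$image_id[match(unlist(inp$members), tab$cell_id)]
  expect_equal(img_of, rep(inp$image_id, lengths(inp$members)))

  inp2 <- build_global_inputs(tab, k = 30, n_anchors_per_image = 100,
                              seed = 5)
  expect_identical(inp$anchor_cell_id, inp2$anchor_cell_id)
  expect_identical(inp$members, inp2$members)
})

test_that("input counts follow sum over images of min(anchors, cells)", {
  tab <- random_table(n_images = 3, cells_per_image = 40, seed = 6,
                      preprocessed = TRUE)
  inp <- build_global_inputs(tab, k = 10, n_anchors_per_image = 25, seed = 1)
  expect_equal(nrow(inp), 3 * 25)
})

test_that("local inputs give one input per typed anchor plus matched background", {
  tab <- random_table(n_images = 4, cells_per_image = 50, seed = 7,
                      preprocessed = TRUE)
  inp <- build_local_inputs(tab, anchor_type = "a", k = 8, seed = 2)

  n_a <- sum(tab$cell_type == "a")
  expect_equal(sum(inp$label != "BG"), n_a)
  counts <- table(inp$label[inp$label != "BG"])
  expect_equal(sum(inp$label == "BG"), round(mean(counts)))

  # typed anchors really are of the anchor type
  typed <- inp[inp$label != "BG", ]
  expect_true(all(
    tab$cell_type[match(typed$anchor_cell_id, tab$cell_id)] == "a"))

  # background members are genuine k-NN sets of their anchors
  bg <- inp[inp$label == "BG", ]
  for (i in head(seq_len(nrow(bg)), 10)) {
    cells <- as.data.frame(tab[tab$image_id == bg$image_id[i],
                               c("cell_id", "x", "y")])
    expect_equal(sort(bg$members[[i]]),
                 sort(knn_oracle(cells, bg$anchor_cell_id[i], 8)))
  }

  expect_error(build_local_inputs(tab, anchor_type = "nope", k = 8),
               class = "cytoniche_domain_error")
})

test_that("functional inputs drop the label marker and average it over members", {
  tab <- random_table(n_images = 2, cells_per_image = 40, seed = 12,
                      preprocessed = TRUE)
  inp <- build_functional_inputs(tab, anchor_type = "b",
                                 functional_marker = "mk2", k = 6)
  expect_true(all(vapply(inp$features, ncol, integer(1)) ==
                    length(markers(tab)) - 1))
  expect_false("mk2" %in% attr(inp, "feature_markers"))

  # labels recomputed independently from the table
  relabel <- vapply(inp$members, function(ids) {
    mean(tab$mk2[match(ids, tab$cell_id)])
  }, numeric(1))
  expect_equal(inp$label, relabel, tolerance = 1e-12)

  one <- cell_table(as.data.frame(tab)[, c("cell_id", "sample_id",
                                           "image_id", "x", "y",
                                           "cell_type", "condition",
                                           "mk1")],
                    markers = "mk1", preprocessed = TRUE)
  expect_error(build_functional_inputs(one, "b", "mk1", k = 6),
               class = "cytoniche_domain_error")
})

test_that("all builders produce neighbourhoods equal to the oracle", {
  tab <- random_table(n_images = 2, cells_per_image = 45, seed = 20,
                      preprocessed = TRUE)
  inp <- build_global_inputs(tab, k = 7, n_anchors_per_image = 10, seed = 4)
  for (i in seq_len(nrow(inp))) {
    cells <- as.data.frame(tab[tab$image_id == inp$image_id[i],
                               c("cell_id", "x", "y")])
    expect_equal(sort(inp$members[[i]]),
                 sort(knn_oracle(cells, inp$anchor_cell_id[i], 7)))
  }
})
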