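test_that("select_cells flags exactly the positive-response cells", {
  tab <- random_table(n_images = 2, cells_per_image = 40, seed = 3,
                      preprocessed = TRUE)
  inp <- build_global_inputs(tab, k = 5, n_anchors_per_image = 10, seed = 1)

  # one-hot filter on mk2: selection must equal mk2 > 0
  m <- manual_model(W = matrix(c(0, 1, 0), 1, 3),
                    feature_markers = markers(tab))
  sel <- select_cells(m, tab, inp, filter_index = 1)
  expect_setequal(sel$cell_id, unique(unlist(inp$members)))
  mk2 <- tab$mk2[match(sel$cell_id, tab$cell_id)]
  expect_identical(sel$selected, mk2 > 0)
  expect_equal(sel$response, mk2)

  # threshold at +Inf selects nothing
  none <- select_cells(m, tab, inp, threshold = Inf)
  expect_false(any(none$selected))

  # scope = "all" scores every cell of the table
  all_sel <- select_cells(m, tab, inp, scope = "all")
  expect_equal(nrow(all_sel), nrow(tab))

  expect_error(select_cells(m, tab, inp[0, ]), regexp = "empty")
})

test_that("per-sample frequencies count member-cell occurrences", {
  tab <- random_table(n_images = 2, cells_per_image = 30, seed = 5,
                      preprocessed = TRUE)
  inp <- build_global_inputs(tab, k = 4, n_anchors_per_image = 6, seed = 2)
  m <- manual_model(W = matrix(c(1, 0, 0), 1, 3),
                    feature_markers = markers(tab))
  sel <- select_cells(m, tab, inp)

  fr <- frequency_per_sample(sel, inp)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1))
  expect_equal(fr$n_selected / fr$n_occurrences, fr$frequency)
  # occurrences are conserved: totals match the input member counts
  expect_equal(sum(fr$n_occurrences), sum(lengths(inp$members)))

  # saturation and emptiness
  sel_all <- sel
  sel_all$selected <- TRUE
  expect_true(all(frequency_per_sample(sel_all, inp)$frequency == 1))
  sel_none <- sel
  sel_none$selected <- FALSE
  expect_true(all(frequency_per_sample(sel_none, inp)$frequency == 0))
})

test_that("a hand-built two-sample toy gives the expected frequency", {
  tab <- cell_table(
    data.frame(cell_id = 1:20,
               sample_id = rep(c("sA", "sB"), each = 10),
               image_id = rep(c("iA", "iB"), each = 10),
               x = rep(seq(0, 0.9, 0.1), 2), y = 0,
               cell_type = "t", condition = rep(c("g1", "g2"), each = 10),
               mk1 = 0),
    markers = "mk1", preprocessed = TRUE)
  inp <- tibble::tibble(
    input_id = 1:2, anchor_cell_id = NA_integer_,
    image_id = c("iA", "iB"), sample_id = c("sA", "sB"),
    label = c("g1", "g2"),
    members = list(1:10, 11:20),
    features = list(matrix(0, 10, 1), matrix(0, 10, 1)))
  sel <- tibble::tibble(cell_id = 1:20,
                        response = c(rep(1, 3), rep(-1, 7),
                                     rep(1, 5), rep(-1, 5)),
                        selected = response > 0)
  fr <- frequency_per_sample(sel, inp)
  expect_equal(fr$frequency[fr$sample_id == "sA"], 0.3)
  expect_equal(fr$frequency[fr$sample_id == "sB"], 0.5)
})

test_that("rank-sum comparison is exact for small untied groups", {
  fr <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    label = rep(c("g1", "g2"), each = 5),
    n_occurrences = 10, n_selected = 5,
    frequency = c(0.6, 0.7, 0.8, 0.9, 1.0, 0.1, 0.2, 0.3, 0.4, 0.5))
  cmp <- compare_frequencies(fr, "g1", "g2")
  expect_equal(cmp$p_value, 2 / 252)  # complete separation, n = m = 5
  expect_equal(cmp$direction, "g1")

  tied <- fr
  tied$frequency <- 0.4
  cmp2 <- compare_frequencies(tied, "g1", "g2")
  expect_equal(cmp2$p_value, 1)
  expect_true(is.na(cmp2$direction))

  expect_error(compare_frequencies(fr[c(1, 6), ], "g1", "g2"),
               class = "cytoniche_domain_error")
})

test_that("rank-sum p-values match exhaustive enumeration for n, m <= 6", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      m <- sample(2:6, 1)
      vals <- runif(n + m)
      fr <- tibble::tibble(
        sample_id = paste0("s", seq_len(n + m)),
        label = rep(c("g1", "g2"), c(n, m)),
        n_occurrences = 1, n_selected = 0, frequency = vals)
      expect_equal(compare_frequencies(fr, "g1", "g2")$p_value,
                   wilcox_enum_oracle(vals[seq_len(n)],
                                      vals[n + seq_len(m)]),
                   tolerance = 1e-12)
    }
  })
})

test_that("choose_k follows the global argmin and the local two-step rule", {
  per_k <- tibble::tibble(k = c(10, 30, 50),
                          p_condition = c(0.2, 1e-6, 0.01))
  expect_equal(choose_k(per_k, "global")$best_k, 30)

  local <- tibble::tibble(
    k = c(20, 30, 40),
    p_condition = c(0.2, 0.01, 0.03),     # survivors: 30, 40
    p_background = c(1e-9, 1e-4, 1e-2))   # 30 wins step (2)
  expect_equal(choose_k(local, "local")$best_k, 30)

  none <- tibble::tibble(k = c(10, 20), p_condition = c(0.4, 0.9),
                         p_background = c(0.1, 0.1))
  out <- choose_k(none, "local")
  expect_false(out$admissible)
  expect_true(is.na(out$best_k))

  single <- tibble::tibble(k = 40, p_condition = 0.7)
  expect_equal(choose_k(single, "global")$best_k, 40)

  # ties go to the smaller k
  tie <- tibble::tibble(k = c(50, 10), p_condition = c(0.02, 0.02))
  expect_equal(choose_k(tie, "global")$best_k, 10)
})

test_that("functional inputs dichotomize around the mean label", {
  feats <- replicate(6, matrix(0, 2, 2), simplify = FALSE)
  inp <- mc_inputs_from_features(feats, labels = c(1, 2, 3, 4, 5, 6))
  d <- dichotomize_functional(inp)
  expect_equal(d$label, c("low", "low", "low", "high", "high", "high"))
  expect_equal(d$label_value, 1:6)
})
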