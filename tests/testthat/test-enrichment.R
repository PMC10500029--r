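# Brute-force oracle: recount all eight quantities by explicit iteration
# over a per-cell data frame (type, selected, in_neighbourhood) and
# evaluate the score formulas directly.
es_oracle <- function(cells, type, mode = "local") {
  N <- nrow(cells)
  N_T <- sum(cells$type == type)
  N_S <- sum(cells$selected)
  N_T_S <- sum(cells$type == type & cells$selected)
  K <- sum(cells$in_nb)
  K_T <- sum(cells$in_nb & cells$type == type)
  K_S <- sum(cells$in_nb & cells$selected)
  K_T_S <- sum(cells$in_nb & cells$selected & cells$type == type)
  if (mode == "global") {
    if (N == 0 || N_T == 0 || N_S == 0) return(NA_real_)
    return(N_T_S / (N_S * N_T / N))
  }
  if (N == 0 || N_S == 0) return(NA_real_)
  E_T <- K * N_T / N
  E_T_S <- K_S * N_T_S / N_S
  if (E_T == 0 || E_T_S == 0 || K_T / E_T == 0) return(NA_real_)
  (K_T_S / E_T_S) / (K_T / E_T)
}

counts_row <- function(N, N_T, K, K_T, N_S, N_T_S, K_S, K_T_S) {
  tibble::tibble(image_id = "i", sample_id = "s", condition = "g",
                 cell_type = "T", N = N, N_T = N_T, K = K, K_T = K_T,
                 N_S = N_S, N_T_S = N_T_S, K_S = K_S, K_T_S = K_T_S)
}

test_that("local and global scores reproduce the worked examples", {
  row <- counts_row(N = 20, N_T = 8, K = 10, K_T = 4,
                    N_S = 5, N_T_S = 3, K_S = 4, K_T_S = 3)
  expect_equal(local_es(row)$es, 1.25)   # E_T=4, S_T=1, E_T_S=2.4
  expect_equal(global_es(row)$es, 1.5)   # E_T_S = 5*8/20 = 2
})

test_that("neutral, zero and saturated selections hit the fixed points", {
  # type-neutral uniform selection with K_T = E_T forces ES = 1
  neutral <- counts_row(N = 40, N_T = 10, K = 16, K_T = 4,
                        N_S = 20, N_T_S = 5, K_S = 8, K_T_S = 2)
  expect_equal(local_es(neutral)$es, 1)

  zero <- counts_row(N = 20, N_T = 8, K = 10, K_T = 4,
                     N_S = 5, N_T_S = 3, K_S = 4, K_T_S = 0)
  expect_equal(local_es(zero)$es, 0)

  # selecting every cell makes the global score 1 for every type
  sat <- counts_row(N = 30, N_T = 12, K = 10, K_T = 4,
                    N_S = 30, N_T_S = 12, K_S = 10, K_T_S = 4)
  expect_equal(global_es(sat)$es, 1)

  undef <- counts_row(N = 20, N_T = 0, K = 10, K_T = 0,
                      N_S = 5, N_T_S = 0, K_S = 4, K_T_S = 0)
  expect_false(global_es(undef)$es_defined)
  expect_false(local_es(undef)$es_defined)
})

test_that("the global score equals the proportion-ratio identity and is scale invariant", {
  withr::with_seed(17, {
    for (i in 1:50) {
      N <- sample(20:200, 1)
      N_T <- sample.int(N, 1)
      N_S <- sample.int(N, 1)
      N_T_S <- sample.int(min(N_T, N_S), 1)
      row <- counts_row(N, N_T, 0, 0, N_S, N_T_S, 0, 0)
      es <- global_es(row)$es
      expect_equal(es, (N_T_S / N_S) / (N_T / N), tolerance = 1e-12)
      # duplicating every cell doubles all counts but not the score
      expect_equal(global_es(counts_row(2 * N, 2 * N_T, 0, 0, 2 * N_S,
                                        2 * N_T_S, 0, 0))$es,
                   es, tolerance = 1e-12)
    }
  })
})

test_that("tabulate_counts merges overlapping neighbourhoods as a union", {
  # 12-cell image; two anchors with neighbourhoods sharing cell 5
  tab <- cell_table(
    data.frame(cell_id = 1:12, sample_id = "s1", image_id = "i1",
               x = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11), y = 0,
               cell_type = rep(c("t1", "t2"), 6), condition = "g1",
               mk1 = 0),
    markers = "mk1", preprocessed = TRUE)
  inp <- tibble::tibble(
    input_id = 1:2, anchor_cell_id = c(3L, 6L), image_id = "i1",
    sample_id = "s1", label = "g1",
    members = list(c(2L, 4L, 5L), c(5L, 7L, 8L)),
    features = list(matrix(0, 3, 1), matrix(0, 3, 1)))
  sel <- tibble::tibble(cell_id = 1:12, response = 0, selected = FALSE)

  cnt <- tabulate_counts(tab, sel, inp)
  expect_equal(unique(cnt$K), 5)  # union {2,4,5,7,8}, shared cell once
  expect_equal(unique(cnt$N), 12)
  expect_true(all(cnt$N_S == 0 & cnt$K_S == 0 &
                    cnt$N_T_S == 0 & cnt$K_T_S == 0))
})

test_that("counts satisfy their invariants and scores match the oracle on random images", {
  withr::with_seed(23, {
    for (r in 1:20) {
      n <- sample(50:200, 1)
      cells <- data.frame(
        type = sample(c("t1", "t2", "t3"), n, TRUE),
        selected = runif(n) < runif(1, 0.1, 0.9),
        in_nb = runif(n) < runif(1, 0.2, 0.8))
      tab <- cell_table(
        data.frame(cell_id = seq_len(n), sample_id = "s1",
                   image_id = "i1", x = runif(n), y = runif(n),
                   cell_type = cells$type, condition = "g1", mk1 = 0),
        markers = "mk1", preprocessed = TRUE)
      inp <- tibble::tibble(
        input_id = 1L, anchor_cell_id = NA_integer_, image_id = "i1",
        sample_id = "s1", label = "g1",
        members = list(which(cells$in_nb)),
        features = list(matrix(0, sum(cells$in_nb), 1)))
      sel <- tibble::tibble(cell_id = seq_len(n), response = 0,
                            selected = cells$selected)
      cnt <- tabulate_counts(tab, sel, inp)

      expect_equal(sum(cnt$N_T), unique(cnt$N))
      expect_equal(sum(cnt$K_T), unique(cnt$K))
      expect_equal(sum(cnt$N_T_S), unique(cnt$N_S))
      expect_equal(sum(cnt$K_T_S), unique(cnt$K_S))
      expect_true(all(cnt$K_T_S <= pmin(cnt$K_T, cnt$N_T_S)))

      loc <- local_es(cnt)
      glo <- global_es(cnt)
      for (tt in unique(cells$type)) {
        expect_equal(loc$es[loc$cell_type == tt],
                     es_oracle(cells, tt, "local"), tolerance = 1e-12)
        expect_equal(glo$es[glo$cell_type == tt],
                     es_oracle(cells, tt, "global"), tolerance = 1e-12)
      }
    }
  })
})

test_that("cohort aggregation uses medians and unscaled MAD", {
  scored <- tibble::tibble(
    image_id = c("i1", "i2", "i3"), sample_id = c("s1", "s2", "s3"),
    condition = "g1", cell_type = "T",
    N = 10, N_T = 5, K = 4, K_T = 2, N_S = 5, N_T_S = 2, K_S = 2,
    K_T_S = 1, es = c(1, 2, 3), es_defined = TRUE)
  agg <- aggregate_es(scored)
  expect_equal(agg$median_es, 2)
  expect_equal(agg$mad_es, 1)
  expect_equal(agg$n_samples, 3)

  single <- aggregate_es(scored[1, ])
  expect_equal(single$median_es, 1)
  expect_equal(single$mad_es, 0)

  # undefined scores are excluded and counted, not imputed
  part <- scored
  part$es[2] <- NA
  part$es_defined[2] <- FALSE
  agg2 <- aggregate_es(part)
  expect_equal(agg2$median_es, 2)  # median of per-sample values {1, 3}
  expect_equal(agg2$n_excluded, 1)
})
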