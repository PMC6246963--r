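test_that("correlation matrix is symmetric with unit diagonal, entries in [-1, 1]", {
  cohort <- clean_cohort(60, seed = 41)
  mat <- error_correlation_matrix(compute_metrics(cohort$responses, table1))
  expect_equal(mat, t(mat))
  expect_equal(unname(diag(mat)), rep(1, 20))
  expect_true(all(abs(mat) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("pairs with too few common participants are masked", {
  # P1 and P2 answer potato+kiwi; only P1 answers avocado
  m <- tibble::tibble(
    participant_id = c("P1", "P1", "P1", "P2", "P2", "P3", "P3"),
    food_id = c("potato", "kiwi", "avocado", "potato", "kiwi",
                "potato", "kiwi"),
    eta = c(0.1, 0.2, 0.3, -0.1, 0.05, 0.4, 0.1)
  )
  mat <- error_correlation_matrix(m, min_overlap = 3)
  expect_true(is.na(mat["potato", "avocado"]))
  expect_false(is.na(mat["potato", "kiwi"]))
  expect_equal(mat["avocado", "avocado"], 1)
})

test_that("graph thresholding keeps strong positive pairs only", {
  mat <- diag(4)
  dimnames(mat) <- list(letters[1:4], letters[1:4])
  mat["a", "b"] <- mat["b", "a"] <- 0.8
  mat["c", "d"] <- mat["d", "c"] <- 0.4
  mat["a", "c"] <- mat["c", "a"] <- -0.9  # negative: never an edge
  mat["b", "d"] <- mat["d", "b"] <- 0.1

  g <- build_food_graph(mat, threshold = 0.3)
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el$from, el$to), c("a b", "c d"))
  expect_equal(sort(el$distance), sort(1 - c(0.8, 0.4)))

  expect_equal(igraph::ecount(build_food_graph(mat, threshold = 0.95)), 0)
  allpos <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(allpos) <- 1
  expect_equal(igraph::ecount(build_food_graph(allpos, threshold = 1e-6)), 3)
  expect_error(build_food_graph(mat, threshold = 1.2), "in \\(0, 1\\)")
})

test_that("clustering separates disjoint perfectly-correlated pairs", {
  mat <- diag(4)
  dimnames(mat) <- list(letters[1:4], letters[1:4])
  mat["a", "b"] <- mat["b", "a"] <- 1
  mat["c", "d"] <- mat["d", "c"] <- 1
  cl <- cluster_foods(mat)
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  expect_equal(cl$cluster[cl$food_id == "a"], cl$cluster[cl$food_id == "b"])
  expect_equal(cl$cluster[cl$food_id == "c"], cl$cluster[cl$food_id == "d"])
  expect_false(cl$cluster[cl$food_id == "a"] == cl$cluster[cl$food_id == "c"])
})

test_that("degenerate clustering inputs: singletons and all-missing", {
  one <- matrix(1, 1, 1, dimnames = list("a", "a"))
  expect_equal(cluster_foods(one),
               tibble::tibble(food_id = "a", cluster = 1L))

  allna <- matrix(NA_real_, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(allna) <- 1
  cl <- cluster_foods(allna)
  expect_equal(dplyr::n_distinct(cl$cluster), 3)
})

test_that("adjusted Rand index matches hand-computed values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(1, 1, 1)), 1)
  # hand-computed from the pair-counting formula:
  # a = {1,1,2,2}, b = {1,2,1,2}: sum_ij C(n_ij,2) = 0, sum_a = 2, sum_b = 2,
  # n2 = 6, expected = 2/3, max = 2 -> ARI = -0.5
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("network results are invariant to participant and row order", {
  cohort <- clean_cohort(50, seed = 42)
  metrics <- compute_metrics(cohort$responses, table1)
  mat1 <- error_correlation_matrix(metrics)
  set.seed(1)
  shuffled <- metrics[sample(nrow(metrics)), ]
  mat2 <- error_correlation_matrix(shuffled)
  expect_equal(mat1, mat2[rownames(mat1), colnames(mat1)])
  cl1 <- cluster_foods(mat1)
  cl2 <- cluster_foods(mat2[rownames(mat1), colnames(mat1)])
  expect_equal(adjusted_rand_index(cl1$cluster, cl2$cluster), 1)
})

test_that("graph export writes GraphML and an edge list", {
  cohort <- clean_cohort(40, seed = 43)
  mat <- error_correlation_matrix(compute_metrics(cohort$responses, table1))
  g <- build_food_graph(mat, threshold = 0.1)
  dir <- withr::local_tempdir()
  paths <- write_food_graph(g, file.path(dir, "g.graphml"),
                            file.path(dir, "edges.csv"))
  expect_true(file.exists(file.path(dir, "g.graphml")))
  el <- readr::read_csv(file.path(dir, "edges.csv"), show_col_types = FALSE)
  expect_equal(names(el), c("source", "target", "correlation", "distance"))
  expect_equal(nrow(el), igraph::ecount(g))
  expect_equal(el$distance, 1 - el$correlation)
})
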