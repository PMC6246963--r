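#' Food-by-food error correlation matrix
#'
#' Entry (j, j') is the Pearson correlation, across participants who
#' answered both foods, of the per-participant percent error — so a
#' participant who proportionally underestimates broccoli and also
#' underestimates cauliflower contributes positive correlation. Percent
#' error (the default) removes food-scale effects; raw error is available
#' via `measure = "e"`. Pairs with fewer than `min_overlap` common
#' participants are set to `NA` and never become graph edges. The diagonal
#' is 1.
#'
#' @param metrics Metric tibble from [compute_metrics()] (or any tibble with
#'   `participant_id`, `food_id` and the chosen measure column).
#' @param measure `"eta"` (percent error, default) or `"e"` (kcal).
#' @param min_overlap Minimum common participants per pair (default 3).
#' @return A symmetric correlation matrix with food_ids as dimnames.
#' @export
error_correlation_matrix <- function(metrics, measure = c("eta", "e"),
                                     min_overlap = 3) {
  measure <- match.arg(measure)
  assert_columns(metrics, c("participant_id", "food_id", measure), "metrics")
  wide <- metrics %>%
    dplyr::select("participant_id", "food_id", dplyr::all_of(measure)) %>%
    tidyr::pivot_wider(names_from = "food_id",
                       values_from = dplyr::all_of(measure))
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 2 || nrow(m) < 2) {
    abort("need at least 2 foods and 2 participants with overlapping answers")
  }
  cors <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(m))
  cors[overlap < min_overlap] <- NA_real_
  diag(cors) <- 1
  cors
}

#' Threshold an error-correlation matrix into a food graph
#'
#' Foods are nodes; pairs whose error correlation reaches the threshold are
#' connected, with the correlation and the correlation distance `1 - r`
#' attached to each edge (strongly correlated foods are "close"). Negative
#' correlations never produce edges.
#'
#' @param mat Correlation matrix from [error_correlation_matrix()].
#' @param threshold Minimum correlation for an edge, in (0, 1); default 0.3.
#' @return An undirected `igraph` graph with vertex attribute `name` and
#'   edge attributes `correlation` and `distance`.
#' @export
build_food_graph <- function(mat, threshold = 0.3) {
  if (!(threshold > 0 && threshold < 1)) {
    abort("threshold must be in (0, 1)")
  }
  foods <- colnames(mat)
  idx <- which(upper.tri(mat) & !is.na(mat) & mat >= threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = foods[idx[, 1]],
    to = foods[idx[, 2]],
    correlation = mat[idx],
    distance = 1 - mat[idx]
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble::tibble(name = foods))
  g
}

#' Cluster foods by error-correlation distance
#'
#' Average-linkage agglomerative clustering on the correlation distance
#' `1 - r`, with the tree cut at a fixed height (default 0.7, i.e. foods
#' merge while their average correlation exceeds 0.3). Missing correlations
#' are treated as 0 (distance 1), so never-observed pairs do not merge;
#' with an all-missing matrix every food is its own cluster. Singleton
#' clusters are allowed.
#'
#' @param mat Correlation matrix from [error_correlation_matrix()].
#' @param cut_height Tree cut height on the distance scale (default 0.7).
#' @return A tibble `food_id`, `cluster` (integer labels).
#' @export
cluster_foods <- function(mat, cut_height = 0.7) {
  foods <- colnames(mat)
  if (length(foods) < 2) {
    return(tibble::tibble(food_id = foods,
                          cluster = rep(1L, length(foods))))
  }
  d <- 1 - mat
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, h = cut_height)
  tibble::tibble(food_id = foods, cluster = unname(labels))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones. Used to score recovery of planted block structure.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Export a food graph
#'
#' Writes the graph as GraphML plus an edge-list CSV
#' (`source,target,correlation,distance`).
#'
#' @param graph Graph from [build_food_graph()].
#' @param graphml_path,edges_csv_path Output file paths (either may be
#'   `NULL` to skip that format).
#' @return Invisible named vector of written paths.
#' @export
write_food_graph <- function(graph, graphml_path = NULL,
                             edges_csv_path = NULL) {
  written <- character()
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
    written["graphml"] <- graphml_path
  }
  if (!is.null(edges_csv_path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("source", "target")
    readr::write_csv(tibble::as_tibble(el), edges_csv_path)
    written["edges_csv"] <- edges_csv_path
  }
  invisible(written)
}
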