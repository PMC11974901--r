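#' Assign ancestry from per-group proportions
#'
#' Takes nonnegative per-group scores (admixture proportions, classifier
#' probabilities, or normalized inverse distances) and assigns each sample
#' to the group with the highest value; exact ties go to the
#' lexicographically first group label.
#'
#' @param x A matrix or data frame of nonnegative proportions with one
#'   column per group (group labels as column names) and sample ids as row
#'   names / a `sample_id` column, or an [fit_supervised_admixture()] fit
#'   (query rows are used).
#' @return A tibble `sample_id`, one proportion column per group,
#'   `assigned_group`.
#' @export
assign_from_proportions <- function(x) {
  if (inherits(x, "admixture_fit")) {
    q <- x$Q[x$query_ids, , drop = FALSE]
    return(assign_from_proportions(q))
  }
  if (is.data.frame(x)) {
    ids <- if ("sample_id" %in% names(x)) x$sample_id else rownames(x)
    q <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
    rownames(q) <- ids
  } else {
    q <- as.matrix(x)
  }
  if (is.null(colnames(q))) abort("Proportions need group labels as column names.")
  if (any(q < 0, na.rm = TRUE) || anyNA(q)) abort("Proportions must be nonnegative and non-missing.")
  zero <- rowSums(q) == 0
  if (any(zero)) {
    abort(paste0("All-zero proportion row(s): ",
                 paste(head(rownames(q)[zero], 5), collapse = ", ")))
  }
  groups <- colnames(q)
  assigned <- apply(q, 1, argmax_lex, labels = groups)
  out <- as_tibble(as.data.frame(q[, sort(groups), drop = FALSE]))
  dplyr::bind_cols(tibble(sample_id = rownames(q) %||% as.character(seq_len(nrow(q)))),
                   out, tibble(assigned_group = unname(assigned)))
}

# extract the PC score matrix and ids from a scores tibble
score_matrix <- function(scores) {
  pc_cols <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  if (length(pc_cols) == 0) abort("Score table has no PC columns.")
  m <- as.matrix(scores[, pc_cols])
  rownames(m) <- scores$sample_id
  m
}

#' Nearest-centroid ancestry classification on PC scores
#'
#' Computes the centroid of each ancestry group in the reference PC space
#' and assigns each query to the group with the smallest Euclidean distance
#' to its centroid, over all components. For a uniform output shape the
#' distances are also reported as normalized inverse distances; these are
#' pseudo-scores for ranking, not probabilities.
#'
#' @param ref_scores Tibble of labelled reference scores (columns
#'   `sample_id`, `ancestry_group`, `PC1` ...), e.g. `model$scores` from
#'   [fit_reference_pca()].
#' @param query_scores Tibble of query scores from [project_pca()], with the
#'   same PC columns.
#' @return A tibble `sample_id`, per-group pseudo-score columns,
#'   `assigned_group`.
#' @export
centroid_classify <- function(ref_scores, query_scores) {
  rs <- score_matrix(ref_scores)
  qs <- score_matrix(query_scores)
  if (nrow(rs) == 0) abort("Empty reference scores.")
  if (ncol(rs) != ncol(qs)) abort("Reference and query scores differ in PC dimensionality.")
  groups <- sort(unique(ref_scores$ancestry_group))
  if (any(table(factor(ref_scores$ancestry_group, levels = groups)) == 0)) {
    abort("Empty ancestry group in reference scores.")
  }
  centroids <- t(vapply(groups, function(g) {
    colMeans(rs[ref_scores$ancestry_group == g, , drop = FALSE])
  }, numeric(ncol(rs))))
  d2 <- outer(rowSums(qs^2), rep(1, length(groups))) -
    2 * qs %*% t(centroids) +
    outer(rep(1, nrow(qs)), rowSums(centroids^2))
  dist <- sqrt(pmax(d2, 0))
  colnames(dist) <- groups
  props <- t(apply(dist, 1, function(dr) {
    if (any(dr == 0)) {
      p <- as.numeric(dr == 0)
    } else {
      p <- 1 / dr
    }
    p / sum(p)
  }))
  colnames(props) <- groups
  rownames(props) <- rownames(qs)
  assign_from_proportions(props)
}

#' Random-forest ancestry classification on PC scores
#'
#' Trains an ensemble of randomized decision trees (via
#' \pkg{randomForest}) on the labelled reference PC scores and predicts
#' per-group class probabilities (tree-vote fractions) for the queries.
#' The RNG seed is applied locally so results are reproducible and the
#' caller's random stream is untouched.
#'
#' @inheritParams centroid_classify
#' @param n_trees Number of trees; default 100.
#' @param seed Integer seed for the forest; default 1.
#' @return A tibble `sample_id`, per-group probability columns,
#'   `assigned_group`.
#' @export
rf_classify <- function(ref_scores, query_scores, n_trees = 100, seed = 1) {
  rs <- score_matrix(ref_scores)
  qs <- score_matrix(query_scores)
  if (ncol(rs) != ncol(qs)) abort("Reference and query scores differ in PC dimensionality.")
  groups <- sort(unique(ref_scores$ancestry_group))
  if (length(groups) < 2) abort("Random forest needs at least 2 ancestry groups.")
  y <- factor(ref_scores$ancestry_group, levels = groups)
  fit <- with_local_seed(seed, {
    randomForest::randomForest(x = rs, y = y, ntree = n_trees)
  })
  probs <- stats::predict(fit, newdata = qs, type = "prob")
  rownames(probs) <- rownames(qs)
  assign_from_proportions(probs)
}
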