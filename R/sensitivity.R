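#' Single-knockdown sensitivity matrix
#'
#' For each species, scales its `y_max` by `factor` (0.5 = half-knockdown)
#' in a fixed context (typically steady-state stretch), recomputes the
#' steady state, and records the change of every species relative to the
#' context steady state. Columns are perturbed nodes, rows responding
#' nodes.
#'
#' @param model A `network_model`.
#' @param context Optional [perturbation()] defining the reference
#'   condition (e.g. `perturbation(set_input = c(Stretch = 0.7))`).
#' @param factor `y_max` multiplier for the knocked-down node
#'   (default 0.5).
#' @param nodes Species to perturb (default all).
#' @param config A [solver_config()].
#' @return A `sensitivity_matrix`: list with `delta` (responding x
#'   perturbed matrix), `reference` steady state, `factor`, `context`, and
#'   `failed` (perturbed nodes whose steady state did not converge; their
#'   columns are NA and excluded from rankings).
#' @examples
#' m <- toy_motifs()$chain
#' sm <- knockdown_matrix(m, perturbation(set_input = c(S = 0.7)))
#' round(sm$delta, 3)
#' @export
knockdown_matrix <- function(model, context = NULL, factor = 0.5,
                             nodes = NULL, config = solver_config()) {
  stopifnot(factor >= 0)
  ctx <- if (is.null(context)) model else apply_perturbation(model, context)
  if (is.null(nodes)) nodes <- species_ids(model)
  ref <- steady_state(ctx, config)
  delta <- matrix(NA_real_, nrow = length(ref), ncol = length(nodes),
                  dimnames = list(names(ref), nodes))
  failed <- character(0)
  for (j in nodes) {
    m <- apply_perturbation(ctx, perturbation(
      scale_ymax = stats::setNames(factor, j)))
    ss <- tryCatch(steady_state(m, config), error = function(e) NULL)
    if (is.null(ss)) failed <- c(failed, j)
    else delta[, j] <- ss - ref
  }
  if (length(failed))
    warning("steady state did not converge for knockdown of: ",
            paste(failed, collapse = ", "), call. = FALSE)
  structure(list(delta = delta, reference = ref, factor = factor,
                 context = context, failed = failed),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity matrix: %d responding x %d perturbed, factor %g>\n",
              nrow(x$delta), ncol(x$delta), x$factor))
  invisible(x)
}

#' Rank perturbed nodes by influence over a row subset
#'
#' Influence of a perturbed node is the mean absolute activity change it
#' causes across the given responding rows (mean signed change available
#' as an option). Influence over transcription factors and over outputs is
#' obtained by passing those row sets.
#'
#' @param matrix A [knockdown_matrix()] result.
#' @param rows Responding species ids to aggregate over.
#' @param k Number of top nodes to return (default 9).
#' @param agg `"mean_abs"` (default) or `"mean_signed"`.
#' @param exclude Perturbed nodes to drop from the ranking (e.g. the rows
#'   themselves); default none.
#' @return Data frame `species`, `score`, ordered by decreasing score.
#' @export
influence_ranking <- function(matrix, rows, k = 9,
                              agg = c("mean_abs", "mean_signed"),
                              exclude = character(0)) {
  agg <- match.arg(agg)
  stopifnot(length(rows) > 0)
  d <- matrix$delta
  bad <- setdiff(rows, rownames(d))
  if (length(bad)) stop("unknown responding species: ",
                        paste(bad, collapse = ", "))
  cols <- setdiff(colnames(d), c(matrix$failed, exclude))
  sub <- d[rows, cols, drop = FALSE]
  score <- if (agg == "mean_abs") colMeans(abs(sub)) else colMeans(sub)
  if (k > length(score)) {
    warning("k exceeds available columns; returning all ", length(score),
            call. = FALSE)
    k <- length(score)
  }
  ord <- order(score, decreasing = TRUE)[seq_len(k)]
  data.frame(species = names(score)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Cluster influential hubs by their sensitivity profiles
#'
#' Agglomerative clustering of sensitivity-matrix columns (each column =
#' one hub's delta profile over the chosen rows) with Euclidean distance
#' and unweighted average linkage (UPGMA), cut at a fixed distance
#' criterion. Raw deltas are used by default; `standardize` scales rows to
#' unit variance first.
#'
#' @param matrix A [knockdown_matrix()] result.
#' @param columns Hub subset (>= 2 perturbed nodes).
#' @param rows Responding rows defining the profile (e.g. transcription
#'   factors plus outputs).
#' @param criterion Cut height (default 0.3).
#' @param standardize Scale rows before computing distances (default
#'   FALSE).
#' @return List with `labels` (named cluster assignment), `n_clusters`,
#'   `merge_heights` and the `hclust` object.
#' @export
cluster_hubs <- function(matrix, columns, rows, criterion = 0.3,
                         standardize = FALSE) {
  stopifnot(length(columns) >= 2L, criterion > 0)
  sub <- matrix$delta[rows, columns, drop = FALSE]
  if (standardize) sub <- t(scale(t(sub)))
  hc <- stats::hclust(stats::dist(t(sub), method = "euclidean"),
                      method = "average")
  labels <- stats::cutree(hc, h = criterion)
  list(labels = labels, n_clusters = max(labels),
       merge_heights = hc$height, hclust = hc)
}

#' Pairwise combination-perturbation screen
#'
#' For every unordered pair of distinct nodes and each direction
#' (both `y_max` decreased by `factor`, i.e. scaled by `1 - factor`, or
#' both increased, scaled by `1 + factor`), computes the steady-state
#' change of each output relative to the context steady state and scores
#' the pair's additional benefit: the combined delta minus the single
#' delta of larger magnitude among the two individual perturbations in the
#' same direction. Raw signed values are reported; for outputs one wants
#' to lower (hypertrophic gene expression under stretch), beneficial
#' combinations have negative combined deltas and negative additional
#' benefit.
#'
#' @param model A `network_model`.
#' @param context Optional [perturbation()] reference condition.
#' @param outputs Species ids to read out.
#' @param factor Fractional change of `y_max` (default 0.5).
#' @param nodes Candidate nodes (default all species).
#' @param directions Subset of `c("decrease", "increase")`.
#' @param config A [solver_config()].
#' @return Data frame with one row per pair x direction x output:
#'   `node_a`, `node_b`, `direction`, `output`, `combined`, `single_a`,
#'   `single_b`, `additional_benefit`. Non-convergent pairs are skipped
#'   and listed in the `"failed_pairs"` attribute.
#' @export
pairwise_screen <- function(model, context = NULL, outputs,
                            factor = 0.5, nodes = NULL,
                            directions = c("decrease", "increase"),
                            config = solver_config()) {
  stopifnot(factor > 0, factor <= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  if (is.null(nodes)) nodes <- species_ids(model)
  bad <- setdiff(outputs, model$species$id)
  if (length(bad)) stop("unknown outputs: ", paste(bad, collapse = ", "))
  ctx <- if (is.null(context)) model else apply_perturbation(model, context)
  ref <- steady_state(ctx, config)

  scale_of <- c(decrease = 1 - factor, increase = 1 + factor)
  singles <- lapply(directions, function(dir) {
    suppressWarnings(
      knockdown_matrix(model, context, factor = scale_of[[dir]],
                       nodes = nodes, config = config))
  })
  names(singles) <- directions

  pairs <- utils::combn(nodes, 2L)
  rows <- vector("list", ncol(pairs) * length(directions))
  failed <- character(0)
  k <- 0L
  for (dir in directions) {
    sm <- singles[[dir]]
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      if (a %in% sm$failed || b %in% sm$failed) {
        failed <- c(failed, paste(a, b, dir, sep = "|")); next
      }
      m <- apply_perturbation(ctx, perturbation(
        scale_ymax = stats::setNames(rep(scale_of[[dir]], 2L), c(a, b))))
      ss <- tryCatch(steady_state(m, config), error = function(e) NULL)
      if (is.null(ss)) {
        failed <- c(failed, paste(a, b, dir, sep = "|")); next
      }
      comb <- ss[outputs] - ref[outputs]
      sa <- sm$delta[outputs, a]
      sb <- sm$delta[outputs, b]
      extreme <- ifelse(abs(sb) > abs(sa), sb, sa)
      k <- k + 1L
      rows[[k]] <- data.frame(node_a = a, node_b = b, direction = dir,
                              output = outputs, combined = unname(comb),
                              single_a = unname(sa), single_b = unname(sb),
                              additional_benefit = unname(comb - extreme),
                              stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (length(failed))
    warning("skipped non-convergent combinations: ",
            paste(failed, collapse = ", "), call. = FALSE)
  attr(out, "failed_pairs") <- failed
  out
}

#' Overlap of the top synergistic combinations for two outputs
#'
#' Ranks each screen result by additional benefit (most negative first,
#' i.e. strongest extra suppression of the output) and returns the
#' fraction of combinations shared between the two top-k sets. A
#' combination is identified by its node pair and direction.
#'
#' @param results_a,results_b [pairwise_screen()] rows for one output
#'   each (filter the screen result by output first if needed).
#' @param k Number of top combinations to compare (default 50).
#' @return Overlap fraction in `[0, 1]`.
#' @export
top_overlap <- function(results_a, results_b, k = 50) {
  key <- function(df) paste(df$node_a, df$node_b, df$direction, sep = "|")
  top <- function(df, k) {
    ord <- order(df$additional_benefit)
    key(df)[ord][seq_len(k)]
  }
  n <- min(nrow(results_a), nrow(results_b))
  if (n < k) {
    warning("fewer than k = ", k, " combinations available; using ", n,
            call. = FALSE)
    k <- n
  }
  length(intersect(top(results_a, k), top(results_b, k))) / k
}
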