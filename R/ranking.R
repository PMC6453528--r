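#' Rank all genes for a directed relationship to a target
#'
#' Fits one factor model on the full interaction matrix and scores every
#' other gene for the requested directed relationship to the target: for
#' `direction = "downstream"` the score of gene g is the reconstructed value
#' at (target, g), i.e. how consistent a target -> g relationship would be
#' with the latent structure of the whole network; for `"upstream"` it is the
#' value at (g, target). Genes with a nonzero cell for that ordered pair are
#' flagged `known`. Cells of unobserved pairs are already zero, so a single
#' factorization scores every novel candidate; leave-one-out refits are only
#' needed to score pairs that exist (see [consistency_score()]).
#'
#' @param matrix an `interaction_matrix`.
#' @param target gene symbol present in the matrix.
#' @param direction `"downstream"` (target as agent) or `"upstream"`.
#' @param config an [als_config()]; its seed fixes the factor initialization.
#' @param model optionally a pre-fitted `factor_model` on the same matrix,
#'   to avoid refitting when ranking several targets.
#' @param include_known keep known partners in the list (default); if
#'   `FALSE` they are dropped before ranks are assigned, giving a novel-only
#'   ranking.
#' @return a `ranked_gene_list`: a data frame with columns `symbol`,
#'   `score`, `known`, `rank`, `percentile`, sorted by descending score
#'   (ties broken by gene symbol), with attributes `target`, `direction`,
#'   `n_ranked`.
#' @export
rank_relation <- function(matrix, target, direction = c("downstream", "upstream"),
                          config = als_config(), model = NULL,
                          include_known = TRUE) {
  direction <- match.arg(direction)
  k <- gene_ord(matrix, target)
  if (is.null(model)) model <- fit_implicit_als(matrix, config)
  scores <- if (direction == "downstream") score_row(model, target)
            else score_col(model, target)
  known_counts <- if (direction == "downstream") matrix$counts[k, ]
                  else matrix$counts[, k]
  keep <- matrix$genes != target
  df <- data.frame(symbol = matrix$genes[keep],
                   score = unname(scores[keep]),
                   known = unname(known_counts[keep] > 0),
                   stringsAsFactors = FALSE)
  if (!include_known) df <- df[!df$known, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty gene universe after exclusions")
  df <- df[order(-df$score, df$symbol), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$percentile <- 100 * df$rank / nrow(df)
  rownames(df) <- NULL
  structure(df, class = c("ranked_gene_list", "data.frame"),
            target = target, direction = direction, n_ranked = nrow(df))
}

#' Remove direct interactors from a ranked list
#'
#' Drops every gene with a direct literature edge to or from the target (in
#' either orientation) and re-ranks the remainder 1..m, recomputing
#' percentiles. Direct interactors reflect transient proximal effects rather
#' than the distal changes sought in pharmacodynamic biomarker discovery, so
#' the standard pipeline filters them after ranking.
#'
#' @param ranked a `ranked_gene_list` produced from `matrix`.
#' @param matrix the same `interaction_matrix` the ranking was built from.
#' @return a filtered, re-ranked `ranked_gene_list`.
#' @export
remove_direct <- function(ranked, matrix) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  target <- attr(ranked, "target")
  direct <- union(downstream_set(matrix, target), upstream_set(matrix, target))
  df <- ranked[!ranked$symbol %in% direct, , drop = FALSE]
  if (nrow(df)) {
    df$rank <- seq_len(nrow(df))
    df$percentile <- 100 * df$rank / nrow(df)
  }
  rownames(df) <- NULL
  structure(df, class = class(ranked), target = target,
            direction = attr(ranked, "direction"), n_ranked = nrow(df))
}

#' Leave-one-out consistency percentile of an existing relationship
#'
#' Evaluates how consistent one observed relationship is with the rest of
#' the network: the (agent, theme) cell is zeroed (a no-op if it is already
#' zero), the model refitted, and the reconstructed score recorded. The same
#' zero-refit-score procedure is applied to `background_size` uniformly
#' sampled existing (nonzero) relationships to form a background population;
#' the returned value is the percentage of background scores less than or
#' equal to the focal score.
#'
#' @param matrix an `interaction_matrix`.
#' @param agent,theme gene symbols of the focal relationship.
#' @param config an [als_config()].
#' @param background_size number of background relationships to sample.
#' @param seed seed governing background sampling and the per-refit
#'   initializations.
#' @return list with `percentile`, `score`, and the `background` score
#'   vector.
#' @export
consistency_score <- function(matrix, agent, theme, config = als_config(),
                              background_size = 200L, seed = 1L) {
  a <- gene_ord(matrix, agent); b <- gene_ord(matrix, theme)
  nz <- Matrix::which(matrix$counts != 0, arr.ind = TRUE)
  # exclude the focal cell from the background candidates
  nz <- nz[!(nz[, 1] == a & nz[, 2] == b), , drop = FALSE]
  if (background_size > nrow(nz))
    stop(sprintf("background_size %d exceeds the %d available nonzero cells",
                 background_size, nrow(nz)))
  loo_score <- function(i, j, fit_seed) {
    m2 <- matrix
    m2$counts[i, j] <- 0
    m2$counts <- Matrix::drop0(m2$counts)
    cfg <- config; cfg$seed <- fit_seed
    model <- fit_implicit_als(m2, cfg)
    drop(model$W[i, , drop = FALSE] %*% model$H[, j, drop = FALSE])
  }
  picks <- with_seed(seed, sample.int(nrow(nz), background_size))
  focal <- loo_score(a, b, seed)
  bg <- vapply(seq_along(picks), function(s) {
    loo_score(nz[picks[s], 1], nz[picks[s], 2], seed + s)
  }, numeric(1))
  list(percentile = 100 * sum(bg <= focal) / length(bg),
       score = focal, background = bg)
}
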