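# Similar-row explanations: a prediction for gene X is justified by genes
# whose overall connection pattern resembles X's and which already carry the
# predicted relationship. Connections are the undirected union of in- and
# out-neighbors in the binary view, matching the single "total connections"
# number such explanation tables print per gene.

# n x n symmetric logical adjacency (union of both orientations, no diagonal)
undirected_adjacency <- function(matrix) {
  b <- binary_view(matrix)
  adj <- (b + Matrix::t(b)) > 0
  Matrix::diag(adj) <- FALSE
  adj
}

chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(statistic = 0, p_value = 1))
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Find genes with connection patterns similar to a query gene
#'
#' For every other gene g, forms the 2x2 contingency table over the partner
#' universe (all genes except the query and g): is a partner connected to
#' the query? is it connected to g? The 1-degree-of-freedom chi-squared
#' statistic (without continuity correction by default) measures how far the
#' shared-neighbor count exceeds what the two genes' individual connection
#' frequencies predict under independence; its upper-tail p-value orders the
#' output.
#'
#' @param matrix an `interaction_matrix`.
#' @param query gene symbol with at least one connection.
#' @param top_n number of similar genes to return.
#' @param correct apply the Yates continuity correction.
#' @return data frame with columns `similar_gene`, `shared_connections`,
#'   `similar_total`, `query_total`, `chi2_statistic`, `p_value`, `enriched`
#'   (shared count at or above its independence expectation). Enriched genes
#'   sort first, then ascending p-value (ties: descending shared
#'   connections, then symbol).
#' @export
similar_rows <- function(matrix, query, top_n = 10L, correct = FALSE) {
  q <- gene_ord(matrix, query)
  adj <- undirected_adjacency(matrix)
  n_genes <- length(matrix$genes)
  nq <- as.numeric(adj[, q])
  if (!any(nq > 0)) stop("query gene '", query, "' has no connections")
  deg <- Matrix::colSums(adj)
  edge_qg <- as.numeric(adj[q, ])  # 1 if the pair itself is connected
  # Partner universe for pair (q, g) excludes q and g themselves; since the
  # adjacency has no diagonal, the shared count is the plain inner product
  # and the totals are degrees minus the pair's own edge.
  shared <- as.numeric(Matrix::crossprod(adj, nq))
  a <- shared
  qt <- deg[q] - edge_qg          # a + b
  st <- deg - edge_qg             # a + c
  n <- n_genes - 2
  b <- qt - a; cc <- st - a; d <- n - a - b - cc
  others <- setdiff(seq_len(n_genes), q)
  stats <- vapply(others, function(g) {
    chi <- chi2_2x2(a[g], b[g], cc[g], d[g], correct = correct)
    c(chi$statistic, chi$p_value)
  }, numeric(2))
  expected <- (a + b) * (a + cc) / n
  out <- data.frame(similar_gene = matrix$genes[others],
                    shared_connections = a[others],
                    similar_total = st[others],
                    query_total = unname(qt[others]),
                    chi2_statistic = stats[1, ],
                    p_value = stats[2, ],
                    enriched = a[others] >= expected[others],
                    stringsAsFactors = FALSE)
  # the chi-squared is two-sided: genes sharing fewer neighbors than chance
  # are anti-similar, so enriched pairs always sort first
  out <- out[order(!out$enriched, out$p_value, -out$shared_connections,
                   out$similar_gene), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Explain one prediction by analogy and direct evidence
#'
#' Bundles everything a scientist needs to assess a predicted
#' target-candidate relationship: the model's score for the pair, the
#' candidate's most similar genes restricted to those that already carry the
#' predicted relationship with the target (`carries_connection`), and any
#' direct literature edges between target and candidate.
#'
#' @param matrix an `interaction_matrix`.
#' @param model a `factor_model` fitted on it.
#' @param target,candidate gene symbols.
#' @param direction `"downstream"` (the explained relationship is
#'   target -> candidate) or `"upstream"`.
#' @param top_n number of supporting similar genes to retain.
#' @return a `prediction_explanation` list: `score`, `similar` (similar-row
#'   table with a `carries_connection` column, filtered to carriers),
#'   `direct_evidence` (counts of the pair's direct edges, both
#'   orientations).
#' @export
explain_prediction <- function(matrix, model, target, candidate,
                               direction = c("downstream", "upstream"),
                               top_n = 10L) {
  direction <- match.arg(direction)
  t_ord <- gene_ord(matrix, target); c_ord <- gene_ord(matrix, candidate)
  sc <- if (direction == "downstream") score_pair(model, target, candidate)
        else score_pair(model, candidate, target)
  sims <- similar_rows(matrix, candidate, top_n = length(matrix$genes))
  carrier_set <- if (direction == "downstream") downstream_set(matrix, target)
                 else upstream_set(matrix, target)
  sims$carries_connection <- sims$similar_gene %in% carrier_set
  supporting <- utils::head(sims[sims$carries_connection, , drop = FALSE], top_n)
  rownames(supporting) <- NULL
  structure(list(
    target = target, candidate = candidate, direction = direction,
    score = sc,
    similar = supporting,
    direct_evidence = list(
      target_to_candidate = matrix$counts[t_ord, c_ord],
      candidate_to_target = matrix$counts[c_ord, t_ord])),
    class = "prediction_explanation")
}

#' @export
print.prediction_explanation <- function(x, ...) {
  cat(sprintf("prediction_explanation: %s %s of %s, score %.4f\n",
              x$candidate, x$direction, x$target, x$score))
  de <- x$direct_evidence
  if (de$target_to_candidate > 0 || de$candidate_to_target > 0)
    cat(sprintf("  direct edges: %s->%s in %d article(s), %s->%s in %d\n",
                x$target, x$candidate, de$target_to_candidate,
                x$candidate, x$target, de$candidate_to_target))
  else cat("  no direct literature edge between the pair\n")
  if (nrow(x$similar)) {
    cat(sprintf("  %d similar gene(s) carrying the predicted connection:\n",
                nrow(x$similar)))
    print(utils::head(x$similar, 5))
  } else cat("  no similar gene carries the predicted connection\n")
  invisible(x)
}
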