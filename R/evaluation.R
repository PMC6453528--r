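#' ROC AUC from the ranks of the positive genes
#'
#' The AUC is the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative (rank 1 = best). With distinct integer ranks
#' among `n_total` ranked items this equals the normalized count of
#' positive-negative pairs in which the positive has the better rank — the
#' rank-sum (Mann-Whitney) statistic.
#'
#' @param ranks_of_positives distinct positive-gene ranks, each in
#'   `1..n_total`.
#' @param n_total total number of ranked genes.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 2), 4)  # both positives outrank both negatives -> 1
roc_auc <- function(ranks_of_positives, n_total) {
  r <- as.numeric(ranks_of_positives)
  if (length(r) == 0L) stop("no positive ranks supplied")
  if (anyDuplicated(r)) stop("positive ranks must be distinct")
  if (any(r < 1 | r > n_total)) stop("ranks must lie in 1..n_total")
  P <- length(r); N <- n_total - P
  if (N <= 0) stop("n_total leaves no negatives")
  # negatives outranked by each positive: (n_total - r) minus the positives
  # ranked below it; summing removes choose(P, 2) positive-positive pairs
  (sum(n_total - r) - choose(P, 2)) / (P * N)
}

#' ROC AUC from scores with ties counted half
#'
#' Mid-rank AUC over an explicitly scored universe: tied positive-negative
#' pairs contribute 1/2. Used for score-based rankings with ties, such as
#' the co-occurrence baseline where many genes share a count.
#'
#' @param scores numeric vector, higher = stronger prediction.
#' @param positive logical vector marking the gold-standard genes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_scores <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  P <- sum(positive); N <- sum(!positive)
  if (P == 0L || N == 0L) stop("need at least one positive and one negative")
  rk <- rank(scores)  # mid-ranks, ascending
  (sum(rk[positive]) - P * (P + 1) / 2) / (P * N)
}

#' Stepwise ROC curve points
#'
#' Walks the ranking from best to worst and records (FPR, TPR) at every
#' positive-set change, starting at (0, 0) and ending at (1, 1).
#'
#' @inheritParams roc_auc
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(ranks_of_positives, n_total) {
  r <- sort(as.numeric(ranks_of_positives))
  P <- length(r); N <- n_total - P
  tp <- cumsum(seq_len(n_total) %in% r)
  fp <- seq_len(n_total) - tp
  data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
}

#' Count gold genes retrieved within a top-percentile threshold
#'
#' In `"nearest"` mode (default) a positive is counted when its percentile
#' `100 * rank / n_total` rounds to an integer at or below the threshold, so
#' a gene at 20.4% counts as "top 20%". In `"strict"` mode the gene's rank
#' must be at most `floor(threshold * n_total / 100)`.
#'
#' @inheritParams roc_auc
#' @param threshold_percent percentile threshold in (0, 100].
#' @param rounding `"nearest"` or `"strict"`.
#' @return integer count of positives within the threshold.
#' @export
recall_at_percentile <- function(ranks_of_positives, n_total,
                                 threshold_percent,
                                 rounding = c("nearest", "strict")) {
  rounding <- match.arg(rounding)
  if (threshold_percent <= 0 || threshold_percent > 100)
    stop("threshold must lie in (0, 100]")
  r <- as.numeric(ranks_of_positives)
  pct <- 100 * r / n_total
  if (rounding == "nearest") sum(round(pct) <= threshold_percent)
  else sum(r <= floor(threshold_percent * n_total / 100))
}

#' Rank genes by literature co-occurrence count
#'
#' The baseline ranking: genes ordered by how many abstracts mention them
#' together with the target, under standard competition ranking — every gene
#' receives rank 1 + (number of genes with a strictly greater count), so
#' tied counts share a rank.
#'
#' @param counts named non-negative integer vector (gene -> co-occurrence
#'   count).
#' @return data frame with columns `gene`, `count`, `rank`, sorted by
#'   descending count then gene symbol.
#' @export
#' @examples
#' cooccurrence_rank(c(A = 5, B = 1, C = 1, D = 0))
cooccurrence_rank <- function(counts) {
  if (length(counts) == 0L) stop("empty co-occurrence table")
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  cnt <- as.numeric(counts)
  rk <- vapply(cnt, function(x) 1L + sum(cnt > x), integer(1))
  out <- data.frame(gene = names(counts), count = cnt, rank = rk,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile of a rank, and its display form
#'
#' `rank_percentile` returns the numeric percentile `100 * rank / n_total`.
#' `format_percentile` renders it the way ranking tables print it: whole
#' percent when it rounds to at least 1%, two decimal places below that
#' (e.g. rank 3 of 13595 -> "0.02%").
#'
#' @param rank rank of the gene, 1-based.
#' @param n_total total number of ranked genes.
#' @export
rank_percentile <- function(rank, n_total) {
  if (any(rank < 1) || any(rank > n_total)) stop("rank out of range")
  100 * rank / n_total
}

#' @rdname rank_percentile
#' @export
format_percentile <- function(rank, n_total) {
  p <- rank_percentile(rank, n_total)
  ifelse(round(p) >= 1, sprintf("%d%%", round(p)), sprintf("%.2f%%", p))
}

#' Read a gold-standard gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#' @param path text file path.
#' @return character vector of symbols.
#' @export
read_gold_set <- function(path) {
  if (!file.exists(path)) stop("gold-set file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("gold set is empty: ", path)
  unique(x)
}

#' Evaluate a ranking against a gold-standard gene list
#'
#' Resolves the gold symbols against the ranked universe (unresolvable
#' symbols are reported with a warning and excluded from both numerator and
#' denominator), then computes the rank-sum AUC, the stepwise ROC points,
#' and recall at the given percentile thresholds.
#'
#' @param ranked a `ranked_gene_list`.
#' @param gold character vector of gold-standard gene symbols.
#' @param thresholds percentile thresholds for recall (default 5 and 20).
#' @param rounding recall rounding mode, see [recall_at_percentile()].
#' @return an `eval_report` list: `auc`, `roc_points`, `recall_at`,
#'   `gold_ranks`, `n_ranked`, `unresolved`.
#' @export
evaluate_ranking <- function(ranked, gold, thresholds = c(5, 20),
                             rounding = c("nearest", "strict")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(ranked, "ranked_gene_list"))
  unresolved <- setdiff(gold, ranked$symbol)
  if (length(unresolved))
    warning("gold genes absent from the ranked universe (excluded): ",
            paste(unresolved, collapse = ", "))
  hits <- intersect(gold, ranked$symbol)
  if (length(hits) == 0L) stop("no gold genes resolvable against the ranking")
  gr <- ranked$rank[match(hits, ranked$symbol)]
  names(gr) <- hits
  n <- attr(ranked, "n_ranked")
  recall <- stats::setNames(
    vapply(thresholds, function(t) recall_at_percentile(gr, n, t, rounding),
           numeric(1)),
    paste0("top", thresholds, "pct"))
  structure(list(auc = roc_auc(gr, n),
                 roc_points = roc_points(gr, n),
                 recall_at = recall,
                 gold_ranks = gr[order(gr)],
                 n_ranked = n,
                 unresolved = unresolved),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC %.3f over %d ranked genes, %d gold genes\n",
              x$auc, x$n_ranked, length(x$gold_ranks)))
  for (nm in names(x$recall_at))
    cat(sprintf("  recall %s: %d of %d\n", nm, as.integer(x$recall_at[[nm]]),
                length(x$gold_ranks)))
  invisible(x)
}
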