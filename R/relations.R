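#' Relation catalogs
#'
#' A relation catalog maps canonical relation names (e.g. `"Regulation
#' Negative"`, `"Phosphorylation"`, `"Binding"`) to their directionality and
#' optional lowercase trigger phrases. Directionality decides how a triple is
#' entered into the interaction matrix: a directional relation contributes to
#' the (agent, theme) cell only, a non-directional one (such as binding) to
#' both orientations.
#'
#' @param entries a list of entries created by [relation_entry()].
#' @return an object of class `relation_catalog`.
#' @export
#' @examples
#' cat <- relation_catalog(list(
#'   relation_entry("Phosphorylation", directional = TRUE),
#'   relation_entry("Binding", directional = FALSE)
#' ))
#' is_directional(cat, "Binding")
relation_catalog <- function(entries) {
  stopifnot(is.list(entries))
  names <- vapply(entries, function(e) e$canonical_name, character(1))
  if (anyDuplicated(names))
    stop("duplicate canonical relation names in catalog: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  structure(list(entries = stats::setNames(entries, names)),
            class = "relation_catalog")
}

#' @param canonical_name nonempty relation name.
#' @param trigger_phrases character vector of lowercase trigger phrases.
#' @param directional logical; does the relation have a causal direction?
#' @rdname relation_catalog
#' @export
relation_entry <- function(canonical_name, trigger_phrases = character(),
                           directional = TRUE) {
  stopifnot(is.character(canonical_name), nzchar(canonical_name),
            length(canonical_name) == 1L, is.logical(directional))
  trigger_phrases <- unique(trigger_phrases)
  if (length(trigger_phrases) &&
      (any(!nzchar(trigger_phrases)) ||
       any(trigger_phrases != tolower(trigger_phrases))))
    stop("trigger phrases must be nonempty and lowercase")
  list(canonical_name = canonical_name,
       trigger_phrases = trigger_phrases,
       directional = isTRUE(directional))
}

#' Default catalog of canonical gene-gene relations. Directional relations
#' carry a causal agent and an affected theme; binding and association do not.
#' @rdname relation_catalog
#' @export
default_relation_catalog <- function() {
  relation_catalog(list(
    relation_entry("Regulation Positive", c("activates", "upregulates", "induces")),
    relation_entry("Regulation Negative", c("inhibits", "downregulates", "represses")),
    relation_entry("Regulation", c("regulates", "modulates")),
    relation_entry("Phosphorylation", c("phosphorylates")),
    relation_entry("Expression", c("expresses")),
    relation_entry("Binding", c("binds"), directional = FALSE),
    relation_entry("Association", c("associates with"), directional = FALSE)
  ))
}

#' @param catalog a `relation_catalog`.
#' @param relation canonical relation name(s).
#' @return logical vector; unknown relations are treated as directional.
#' @rdname relation_catalog
#' @export
is_directional <- function(catalog, relation) {
  stopifnot(inherits(catalog, "relation_catalog"))
  vapply(relation, function(r) {
    e <- catalog$entries[[r]]
    if (is.null(e)) TRUE else e$directional
  }, logical(1), USE.NAMES = FALSE)
}

#' Create a set of relation triples
#'
#' A triple is one directed literature assertion: an agent gene acting on a
#' theme gene through a canonical relation, supported by `article_count`
#' documents. Self-loops are permitted but flagged in the `self_loop` column.
#'
#' @param agent,theme character vectors of gene symbols.
#' @param relation canonical relation names (recycled if length 1).
#' @param article_count positive integer vector of supporting-article counts.
#' @return a `data.frame` of class `relation_triples`.
#' @export
relation_triples <- function(agent, relation, theme, article_count) {
  if (length(relation) == 1L) relation <- rep(relation, length(agent))
  stopifnot(length(agent) == length(theme),
            length(agent) == length(relation),
            length(agent) == length(article_count))
  agent <- as.character(agent); theme <- as.character(theme)
  article_count <- as.integer(article_count)
  if (any(!nzchar(agent)) || any(!nzchar(theme)))
    stop("agent and theme symbols must be nonempty")
  if (any(is.na(article_count)) || any(article_count < 1L))
    stop("article_count must be a positive integer for every triple")
  out <- data.frame(agent = agent, relation = as.character(relation),
                    theme = theme, article_count = article_count,
                    stringsAsFactors = FALSE)
  out$self_loop <- out$agent == out$theme
  class(out) <- c("relation_triples", "data.frame")
  out
}

#' Read relation triples from a CSV edge list
#'
#' Ingests an edge list in the deposited supplementary-table shape: one row
#' per (agent, relation, theme) with a supporting-article count. Column names
#' are configurable so the reader can be pointed at files with arbitrary
#' headers. Rows with missing symbols or non-positive counts are rejected
#' with a warning giving their line numbers; the count of rejected rows is
#' attached as attribute `n_rejected`.
#'
#' @param path path to a CSV file with a header row.
#' @param catalog relation catalog used downstream; relations absent from the
#'   catalog are mapped to `default_relation`.
#' @param columns named character vector mapping roles `agent`, `theme`,
#'   `count` and (optionally) `relation` to the file's column names.
#' @param default_relation canonical name assigned when the file has no
#'   relation column or the stated relation is unknown to the catalog.
#' @return a `relation_triples` data frame.
#' @export
read_triples <- function(path, catalog = default_relation_catalog(),
                         columns = c(agent = "agent", relation = "relation",
                                     theme = "theme", count = "count"),
                         default_relation = "Regulation") {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("agent", "theme", "count")) {
    col <- columns[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("mandatory column '%s' (role %s) missing from %s",
                   col %||% role, role, path))
  }
  if (nrow(raw) == 0L) {
    warning("edge list ", path, " contains a header but no rows")
    out <- relation_triples(character(), character(0), character(), integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  agent <- trimws(as.character(raw[[columns[["agent"]]]]))
  theme <- trimws(as.character(raw[[columns[["theme"]]]]))
  count <- suppressWarnings(as.numeric(raw[[columns[["count"]]]]))
  rel_col <- columns["relation"]
  if (!is.na(rel_col) && rel_col %in% names(raw)) {
    relation <- trimws(as.character(raw[[rel_col]]))
  } else {
    relation <- rep(default_relation, nrow(raw))
  }
  relation[!nzchar(relation) | is.na(relation)] <- default_relation
  unknown <- !(relation %in% names(catalog$entries))
  relation[unknown] <- default_relation

  bad <- is.na(agent) | !nzchar(agent) | is.na(theme) | !nzchar(theme) |
    is.na(count) | count < 1 | count != floor(count)
  if (any(bad)) {
    # +1 for the header line
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- relation_triples(agent[!bad], relation[!bad], theme[!bad],
                          as.integer(count[!bad]))
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write relation triples to CSV
#'
#' Aggregates article counts over identical (agent, relation, theme) rows and
#' writes them under a canonical sort, so that read/write round trips are
#' byte-stable.
#'
#' @param triples a `relation_triples` data frame.
#' @param path output CSV path.
#' @export
write_triples <- function(triples, path) {
  agg <- stats::aggregate(article_count ~ agent + relation + theme,
                          data = as.data.frame(triples), FUN = sum)
  agg <- agg[order(agg$agent, agg$relation, agg$theme),
             c("agent", "relation", "theme", "article_count")]
  names(agg)[4] <- "count"
  utils::write.csv(agg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the interaction matrix from relation triples
#'
#' Builds the sparse gene-by-gene count matrix underlying all inference: cell
#' (i, j) holds the total number of supporting articles for relationships
#' with agent i and theme j. The row and column universes are identical — the
#' full set of genes observed anywhere in the triples — so any gene can be
#' scored as a candidate theme of any other. Non-directional relations (per
#' the catalog) contribute their count to both orientations. All canonical
#' relations for an ordered pair collapse into one cell.
#'
#' @param triples a `relation_triples` data frame (nonempty).
#' @param catalog a `relation_catalog` deciding directionality.
#' @return an object of class `interaction_matrix`: a list with `counts`
#'   (a sparse `dgCMatrix` with gene-symbol dimnames) and `genes` (the
#'   ordered gene universe).
#' @export
#' @examples
#' tr <- relation_triples(c("BTK", "LYN"), "Phosphorylation",
#'                        c("PLCG2", "BTK"), c(4L, 2L))
#' m <- build_matrix(tr)
#' downstream_set(m, "BTK")
build_matrix <- function(triples, catalog = default_relation_catalog()) {
  stopifnot(inherits(triples, "relation_triples"))
  if (nrow(triples) == 0L) stop("cannot build a matrix from zero triples")
  genes <- sort(unique(c(triples$agent, triples$theme)))
  dir <- is_directional(catalog, triples$relation)
  i <- c(triples$agent, triples$theme[!dir])
  j <- c(triples$theme, triples$agent[!dir])
  x <- c(triples$article_count, triples$article_count[!dir])
  counts <- Matrix::sparseMatrix(
    i = match(i, genes), j = match(j, genes), x = as.double(x),
    dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes))
  structure(list(counts = counts, genes = genes),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d genes, %d nonzero cells, total article mass %g\n",
              length(x$genes), Matrix::nnzero(x$counts), sum(x$counts)))
  invisible(x)
}

#' Binary view of an interaction matrix
#'
#' The 0/1 matrix X with X[i, j] = 1 iff any article supports agent i acting
#' on theme j; the preference matrix consumed by the factorization.
#' @param matrix an `interaction_matrix`.
#' @return a sparse pattern-valued numeric matrix of the same shape.
#' @export
binary_view <- function(matrix) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  b <- matrix$counts
  b@x <- rep(1, length(b@x))
  b
}

gene_ord <- function(matrix, symbol) {
  k <- match(symbol, matrix$genes)
  if (is.na(k)) stop_unknown_gene(symbol, "interaction matrix gene universe")
  k
}

#' Direct neighbor sets of a gene
#'
#' `downstream_set` returns the themes the target acts on (nonzero cells in
#' the target's agent row); `upstream_set` the agents acting on the target
#' (nonzero cells in its theme column). The target itself is excluded.
#'
#' @param matrix an `interaction_matrix`.
#' @param target a gene symbol present in the matrix.
#' @return character vector of gene symbols.
#' @export
downstream_set <- function(matrix, target) {
  k <- gene_ord(matrix, target)
  out <- matrix$genes[Matrix::which(matrix$counts[k, ] > 0)]
  setdiff(out, target)
}

#' @rdname downstream_set
#' @export
upstream_set <- function(matrix, target) {
  k <- gene_ord(matrix, target)
  out <- matrix$genes[Matrix::which(matrix$counts[, k] > 0)]
  setdiff(out, target)
}

#' Export an interaction matrix as coordinate-format text
#'
#' Writes one line per nonzero cell: row gene symbol, column gene symbol,
#' count — a symbol-labelled MatrixMarket-style coordinate listing.
#' @param matrix an `interaction_matrix`.
#' @param path output path.
#' @export
export_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  m <- methods::as(matrix$counts, "TsparseMatrix")
  ord <- order(m@i, m@j)
  df <- data.frame(row_gene = matrix$genes[m@i[ord] + 1L],
                   col_gene = matrix$genes[m@j[ord] + 1L],
                   count = m@x[ord])
  utils::write.table(df, path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}
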