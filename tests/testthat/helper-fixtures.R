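# Shared fixtures, built in code.

# tiny directed triple set over an explicit universe
toy_triples <- function() {
  relation_triples(
    agent = c("A", "B", "A", "C"),
    relation = c("Regulation", "Regulation", "Phosphorylation", "Binding"),
    theme = c("B", "C", "B", "D"),
    article_count = c(2L, 1L, 4L, 3L))
}

# random sparse count matrix as an interaction_matrix, seeded
random_matrix <- function(n, density = 0.3, seed = 1, max_count = 5) {
  with_seed_local(seed, {
    genes <- sprintf("g%02d", seq_len(n))
    cells <- which(matrix(stats::runif(n * n) < density, n, n) &
                   !diag(TRUE, n))
    if (length(cells) == 0) cells <- 2L  # guarantee one off-diagonal cell
    i <- ((cells - 1L) %% n) + 1L
    j <- ((cells - 1L) %/% n) + 1L
    tr <- relation_triples(genes[i], "Regulation", genes[j],
                           sample(max_count, length(cells), replace = TRUE))
    build_matrix(tr)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# brute-force implicit-feedback objective: explicit double loop over cells
objective_bruteforce <- function(m, W, H, lambda, alpha, use_counts = TRUE) {
  X <- as.matrix(m$counts)
  total <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    p <- as.numeric(X[i, j] > 0)
    cij <- 1 + if (use_counts) alpha * X[i, j] else alpha * (X[i, j] > 0)
    s <- sum(W[i, ] * H[, j])
    total <- total + cij * (p - s)^2
  }
  total + lambda * (sum(W^2) + sum(H^2))
}

# ridge normal-equation oracle for one ALS half-step (agent rows given H),
# formed explicitly with dense algebra and a generic solver
half_step_oracle <- function(m, H, lambda, alpha, use_counts = TRUE) {
  X <- as.matrix(m$counts)
  k <- nrow(H)
  W <- matrix(0, nrow(X), k)
  for (i in seq_len(nrow(X))) {
    cvec <- 1 + if (use_counts) alpha * X[i, ] else alpha * (X[i, ] > 0)
    p <- as.numeric(X[i, ] > 0)
    A <- H %*% diag(cvec, ncol(X)) %*% t(H) + lambda * diag(k)
    b <- H %*% (cvec * p)
    W[i, ] <- solve(A, b)
  }
  W
}

# pairwise-comparison AUC oracle: count positive-negative pairs directly
auc_oracle <- function(pos_ranks, n_total) {
  neg_ranks <- setdiff(seq_len(n_total), pos_ranks)
  wins <- 0
  for (p in pos_ranks) for (q in neg_ranks) {
    if (p < q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos_ranks) * length(neg_ranks))
}

table3_ranks <- function() {
  path <- system.file("extdata", "btk_expert_gene_ranks.csv",
                      package = "litnetmf")
  utils::read.csv(path)
}
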