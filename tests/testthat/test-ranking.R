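test_that("a single known edge puts its theme first in a 3-gene ranking", {
  tr <- relation_triples("A", "Regulation", "B", 1L)
  tr <- rbind(tr, relation_triples("C", "Regulation", "C", 1L))  # C indexed
  class(tr) <- c("relation_triples", "data.frame")
  m <- build_matrix(tr)
  ranked <- rank_relation(m, "A", "downstream", als_config(rank = 2, seed = 4))
  expect_equal(ranked$symbol[1], "B")
  expect_true(ranked$known[ranked$symbol == "B"])
  expect_false(any(ranked$symbol == "A"))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_equal(ranked$percentile, 100 * ranked$rank / nrow(ranked))
})

test_that("ranking covers the full universe with finite scores", {
  m <- random_matrix(20, density = 0.15, seed = 6)
  # a gene with no incident edges at all still gets ranked candidates
  ranked <- rank_relation(m, m$genes[1], "downstream",
                          als_config(rank = 3, iterations = 5, seed = 1))
  expect_equal(nrow(ranked), 19L)
  expect_true(all(is.finite(ranked$score)))
  expect_error(rank_relation(m, "ABSENT"), "ABSENT")
})

test_that("remove_direct drops both orientations and re-ranks the rest", {
  tr <- relation_triples(c("A", "D", "C"), "Regulation",
                         c("B", "A", "D"), c(1L, 2L, 1L))
  m <- build_matrix(tr)
  ranked <- rank_relation(m, "A", "downstream",
                          als_config(rank = 2, iterations = 5, seed = 2))
  filtered <- remove_direct(ranked, m)
  # B (downstream of A) and D (upstream of A) must both disappear
  direct <- union(downstream_set(m, "A"), upstream_set(m, "A"))
  expect_length(intersect(filtered$symbol, direct), 0)
  expect_equal(filtered$rank, seq_len(nrow(filtered)))
  expect_equal(attr(filtered, "n_ranked"), nrow(filtered))
  # order among survivors is preserved
  expect_equal(filtered$symbol,
               ranked$symbol[!ranked$symbol %in% direct])
})

test_that("remove_direct is the identity when the target has no interactors", {
  # Z appears only as a self-loop, so it has no direct interactors
  tr <- relation_triples(c("A", "B", "Z"), "Regulation",
                         c("B", "C", "Z"), c(1L, 2L, 1L))
  m <- build_matrix(tr)
  ranked <- rank_relation(m, "Z", "downstream",
                          als_config(rank = 2, iterations = 4, seed = 3))
  expect_equal(as.data.frame(remove_direct(ranked, m)),
               as.data.frame(ranked))
})

test_that("filtered rankings never contain the target's direct neighborhood", {
  # set-difference oracle on synthetic matrices
  for (s in 1:3) {
    truth <- generate_network(synthetic_spec(n_genes = 60, edge_density = 0.08,
                                             n_known_downstream = 5,
                                             n_heldout_downstream = 3,
                                             seed = s))
    m <- build_matrix(truth$edges)
    tgt <- truth$spec$target_gene
    ranked <- rank_relation(m, tgt, "downstream",
                            als_config(rank = 5, iterations = 5, seed = s))
    filtered <- remove_direct(ranked, m)
    oracle_keep <- setdiff(setdiff(m$genes, tgt),
                           union(downstream_set(m, tgt), upstream_set(m, tgt)))
    expect_setequal(filtered$symbol, oracle_keep)
  }
})

test_that("upstream ranking scores the transposed orientation", {
  tr <- relation_triples(c("A", "B"), "Regulation", c("C", "C"), c(3L, 2L))
  m <- build_matrix(tr)
  cfg <- als_config(rank = 2, iterations = 6, seed = 8)
  model <- fit_implicit_als(m, cfg)
  up <- rank_relation(m, "C", "upstream", cfg, model = model)
  expect_true(all(up$known[up$symbol %in% c("A", "B")]))
  expect_equal(up$score[up$symbol == "A"], score_pair(model, "A", "C"))
})

test_that("shuffling input rows leaves the ranking unchanged", {
  truth <- generate_network(synthetic_spec(n_genes = 50, edge_density = 0.1,
                                           n_known_downstream = 5,
                                           n_heldout_downstream = 3, seed = 4))
  tr <- truth$edges
  shuffled <- tr[with_seed_local(1, sample(nrow(tr))), ]
  class(shuffled) <- class(tr)
  cfg <- als_config(rank = 4, iterations = 5, seed = 5)
  r1 <- rank_relation(build_matrix(tr), truth$spec$target_gene, "downstream", cfg)
  r2 <- rank_relation(build_matrix(shuffled), truth$spec$target_gene,
                      "downstream", cfg)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("consistency_score is a no-op on zero cells and matches a sort oracle", {
  m <- random_matrix(4, density = 0.6, seed = 12)
  cfg <- als_config(rank = 2, iterations = 4, seed = 1)
  zero_cells <- which(as.matrix(m$counts) == 0 & !diag(TRUE, 4), arr.ind = TRUE)
  zc <- zero_cells[1, ]
  before <- as.matrix(m$counts)
  cs <- consistency_score(m, m$genes[zc[1]], m$genes[zc[2]], cfg,
                          background_size = 3, seed = 2)
  expect_identical(as.matrix(m$counts), before)  # input untouched
  expect_true(is.finite(cs$score))

  # full-background percentile equals an explicit sort computation
  nnz <- Matrix::nnzero(m$counts)
  cs2 <- consistency_score(m, m$genes[zc[1]], m$genes[zc[2]], cfg,
                           background_size = nnz, seed = 3)
  sorted <- sort(cs2$background)
  expect_equal(cs2$percentile,
               100 * findInterval(cs2$score, sorted) / length(sorted))
  expect_error(
    consistency_score(m, m$genes[zc[1]], m$genes[zc[2]], cfg,
                      background_size = nnz + 50, seed = 1),
    "background_size")
})

test_that("held-out true relationships score above random zero cells", {
  percs_true <- c(); percs_zero <- c()
  for (s in 1:5) {
    truth <- generate_network(synthetic_spec(n_genes = 80, edge_density = 0.08,
                                             n_known_downstream = 6,
                                             n_heldout_downstream = 4,
                                             seed = s))
    m <- build_matrix(truth$edges)
    tgt <- truth$spec$target_gene
    cfg <- als_config(rank = 5, iterations = 8, seed = s)
    model <- fit_implicit_als(m, cfg)
    scores <- litnetmf:::score_row(model, tgt)
    held <- truth$heldout_positives
    zeros <- setdiff(m$genes[m$counts[litnetmf:::gene_ord(m, tgt), ] == 0],
                     c(tgt, held))
    rnd <- with_seed_local(s, sample(zeros, length(held)))
    percs_true <- c(percs_true, mean(scores[held]))
    percs_zero <- c(percs_zero, mean(scores[rnd]))
  }
  expect_gt(mean(percs_true), mean(percs_zero))
})
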