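# brute-force contingency oracle: build the 2x2 table cell by cell
contingency_oracle <- function(m, q_sym, g_sym) {
  adj <- as.matrix(m$counts) + t(as.matrix(m$counts))
  adj <- adj > 0; diag(adj) <- FALSE
  q <- match(q_sym, m$genes); g <- match(g_sym, m$genes)
  partners <- setdiff(seq_along(m$genes), c(q, g))
  a <- b <- cc <- d <- 0
  for (p in partners) {
    if (adj[p, q] && adj[p, g]) a <- a + 1
    else if (adj[p, q]) b <- b + 1
    else if (adj[p, g]) cc <- cc + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = cc, d = d)
}

test_that("genes with identical connection rows are each other's top match", {
  with_seed_local(21, {
    n <- 50
    genes <- sprintf("g%02d", seq_len(n))
    # two genes wired to the same 12 partners, plus background edges
    partners <- sample(genes[5:n], 12)
    bg_a <- sample(genes[5:n], 40, replace = TRUE)
    bg_t <- sample(genes[5:n], 40, replace = TRUE)
    keep <- bg_a != bg_t
    tr <- relation_triples(
      c(rep(c("g01", "g02"), each = 12), bg_a[keep]),
      "Regulation",
      c(partners, partners, bg_t[keep]),
      rep(1L, 24 + sum(keep)))
    m <- build_matrix(tr)
    sims <- similar_rows(m, "g01", top_n = 5)
    expect_equal(sims$similar_gene[1], "g02")
    expect_equal(sims$shared_connections[1], sims$query_total[1])
    sims2 <- similar_rows(m, "g02", top_n = 5)
    expect_equal(sims2$similar_gene[1], "g01")
  })
})

test_that("chi-squared matches brute-force contingency and chisq.test", {
  for (s in 1:6) {
    m <- random_matrix(sample(10:30, 1), density = 0.25, seed = 300 + s)
    conn <- m$genes[Matrix::colSums(litnetmf:::undirected_adjacency(m)) > 0]
    q <- conn[1]
    sims <- similar_rows(m, q, top_n = length(m$genes))
    for (r in sample(nrow(sims), min(5, nrow(sims)))) {
      g <- sims$similar_gene[r]
      tab <- contingency_oracle(m, q, g)
      expect_equal(sims$shared_connections[r], unname(tab["a"]))
      expect_equal(sims$query_total[r], unname(tab["a"] + tab["b"]))
      expect_equal(sims$similar_total[r], unname(tab["a"] + tab["c"]))
      mt <- matrix(tab, 2, 2, byrow = TRUE)
      if (all(rowSums(mt) > 0) && all(colSums(mt) > 0)) {
        ref <- suppressWarnings(stats::chisq.test(mt, correct = FALSE))
        expect_equal(sims$chi2_statistic[r], unname(ref$statistic),
                     tolerance = 1e-12)
        expect_equal(sims$p_value[r], unname(ref$p.value), tolerance = 1e-12)
      }
    }
  }
})

test_that("the statistic is symmetric in the gene pair", {
  m <- random_matrix(15, density = 0.3, seed = 31)
  sims_a <- similar_rows(m, m$genes[1], top_n = length(m$genes))
  sims_b <- similar_rows(m, m$genes[2], top_n = length(m$genes))
  row_ab <- sims_a[sims_a$similar_gene == m$genes[2], ]
  row_ba <- sims_b[sims_b$similar_gene == m$genes[1], ]
  expect_equal(row_ab$shared_connections, row_ba$shared_connections)
  expect_equal(row_ab$chi2_statistic, row_ba$chi2_statistic, tolerance = 1e-12)
})

test_that("an overlap at its independence expectation scores chi2 ~ 0", {
  # 8 partners: query connects to 4, candidate to 4, overlap exactly 2
  # => expected overlap 4*4/8 = 2, so chi2 = 0 and p = 1
  tr <- relation_triples(
    c("Q", "Q", "Q", "Q", "C", "C", "C", "C"),
    "Regulation",
    c("p1", "p2", "p3", "p4", "p3", "p4", "p5", "p6"),
    rep(1L, 8))
  # two filler partners with no edges to Q or C
  tr <- rbind(tr, relation_triples(c("p7", "p8"), "Regulation",
                                   c("p8", "p7"), c(1L, 1L)))
  class(tr) <- c("relation_triples", "data.frame")
  m <- build_matrix(tr)
  sims <- similar_rows(m, "Q", top_n = length(m$genes))
  row_c <- sims[sims$similar_gene == "C", ]
  expect_equal(row_c$shared_connections, 2)
  expect_equal(row_c$chi2_statistic, 0, tolerance = 1e-12)
  expect_equal(row_c$p_value, 1)
})

test_that("p-values are approximately uniform for independent rows", {
  # independent random wiring: no similarity signal, so upper-tail p-values
  # should be near-uniform; Kolmogorov-Smirnov distance as a sanity bound
  m <- random_matrix(520, density = 0.12, seed = 77, max_count = 1)
  conn <- m$genes[Matrix::colSums(litnetmf:::undirected_adjacency(m)) > 20]
  sims <- similar_rows(m, conn[1], top_n = length(m$genes))
  ks <- suppressWarnings(stats::ks.test(sims$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("queries without connections are rejected", {
  tr <- relation_triples(c("A", "Z"), "Regulation", c("B", "Z"), c(1L, 1L))
  m <- build_matrix(tr)
  expect_error(similar_rows(m, "Z"), "no connections")
})

test_that("explanations name analogous genes that carry the connection", {
  # gene C duplicates the connection row of known-downstream gene B
  with_seed_local(41, {
    n <- 40
    genes <- sprintf("g%02d", seq_len(n))
    tgt <- "g01"
    partners <- genes[10:21]
    tr <- relation_triples(
      c(tgt, rep("g02", 12), rep("g03", 12),
        sample(genes[10:n], 30, replace = TRUE)),
      "Regulation",
      c("g02", partners, partners,
        sample(genes[10:n], 30, replace = TRUE)),
      rep(1L, 55))
    tr <- tr[!tr$self_loop, ]
    class(tr) <- c("relation_triples", "data.frame")
    m <- build_matrix(tr)
    cfg <- als_config(rank = 4, iterations = 6, seed = 2)
    model <- fit_implicit_als(m, cfg)
    expl <- explain_prediction(m, model, tgt, "g03", "downstream", top_n = 5)
    # g02 is directly downstream of the target and shares g03's full row
    expect_true("g02" %in% expl$similar$similar_gene)
    expect_true(all(expl$similar$carries_connection))
    expect_equal(expl$score, score_pair(model, tgt, "g03"))
    expect_equal(expl$direct_evidence$target_to_candidate, 0)
  })
})

test_that("direct evidence is listed when the pair has a literature edge", {
  tr <- relation_triples(c("T", "T", "X"), "Regulation",
                         c("C", "X", "C"), c(2L, 1L, 1L))
  m <- build_matrix(tr)
  cfg <- als_config(rank = 2, iterations = 4, seed = 1)
  model <- fit_implicit_als(m, cfg)
  expl <- explain_prediction(m, model, "T", "C", "downstream")
  expect_equal(expl$direct_evidence$target_to_candidate, 2)
  expect_equal(expl$direct_evidence$candidate_to_target, 0)
  expect_s3_class(expl$similar, "data.frame")  # bundle complete even if empty
})
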