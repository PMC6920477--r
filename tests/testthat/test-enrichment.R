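test_that("ranked lists carry signed -log10 p in deterministic order", {
  res <- make_results_table(c(0.01, 1, 0.1), genes = c("UP", "FLAT", "DOWN"),
                            direction = c(1L, 1L, -1L))
  rl <- make_ranked_list(res)
  expect_equal(rl$gene, c("UP", "FLAT", "DOWN"))
  expect_equal(rl$score, c(2, 0, -1))

  # non-converged rows are dropped with a message; duplicates are errors
  res$converged[2] <- FALSE
  expect_message(rl2 <- make_ranked_list(res), "non-converged")
  expect_equal(rl2$gene, c("UP", "DOWN"))
  res2 <- make_results_table(c(0.5, 0.5), genes = c("A", "A"))
  expect_error(make_ranked_list(res2), "duplicate")

  # score ties break by gene symbol
  res3 <- make_results_table(c(0.2, 0.2, 0.2), genes = c("C", "A", "B"))
  expect_equal(make_ranked_list(res3)$gene, c("A", "B", "C"))
})

test_that("enrichment scores match the brute-force running-sum oracle exactly", {
  # hand-specified case: scores 10..1, set at ranks 1-3, weight 1
  ranked <- data.frame(gene = sprintf("G%02d", 1:10), score = 10:1)
  sets <- gene_set_collection(list(TOP3 = c("G01", "G02", "G03")))
  r <- gsea_preranked(ranked, sets, n_perm = 100, weight = 1, seed = 2)
  member <- ranked$gene %in% sets$sets$TOP3
  expect_equal(r$es, oracle_es(ranked$score, member, 1))
  expect_equal(r$es, 1) # all hits precede all misses

  # singleton set at rank 1, weight 0: running sum peaks at 1 immediately
  single <- gene_set_collection(list(S = "G01"))
  expect_equal(gsea_preranked(ranked, single, n_perm = 100, weight = 0,
                              seed = 2)$es, 1)

  # random instances on lists of N <= 20, both weights
  set.seed(33)
  for (k in 1:25) {
    N <- sample(5:20, 1)
    scores <- sort(round(rnorm(N, 0, 3), 2), decreasing = TRUE)
    rl <- data.frame(gene = sprintf("R%02d", 1:N), score = scores)
    m <- sample(N, sample(1:(N - 1), 1))
    gs <- gene_set_collection(list(K = rl$gene[m]))
    w <- sample(c(0, 1), 1)
    got <- gsea_preranked(rl, gs, n_perm = 100, weight = w, seed = k)
    expect_equal(got$es, oracle_es(scores, seq_len(N) %in% m, w))
  }
})

test_that("enrichment invariances hold: scale, reversal, reproducibility", {
  set.seed(12)
  N <- 60
  rl <- data.frame(gene = sprintf("R%02d", 1:N),
                   score = sort(rnorm(N), decreasing = TRUE))
  gs <- gene_set_collection(list(A = rl$gene[c(2, 9, 17, 30)],
                                 B = rl$gene[c(50, 55, 58)]))
  a <- gsea_preranked(rl, gs, n_perm = 200, weight = 0, seed = 7)
  # positive rescaling leaves weight-0 ES untouched
  rl2 <- transform(rl, score = score * 37.5)
  b <- gsea_preranked(rl2, gs, n_perm = 200, weight = 0, seed = 7)
  expect_equal(a$es, b$es)

  # reversing the ranking negates every weight-0 ES
  rl_rev <- data.frame(gene = rev(rl$gene), score = rev(-rl$score))
  c_ <- gsea_preranked(rl_rev, gs, n_perm = 200, weight = 0, seed = 7)
  expect_equal(c_$es[match(a$set, c_$set)], -a$es)

  # same seed, same permutation p-values
  a2 <- gsea_preranked(rl, gs, n_perm = 200, weight = 0, seed = 7)
  expect_identical(a$p_perm, a2$p_perm)

  # a set covering the whole list is skipped with a warning
  full <- gene_set_collection(list(ALL = rl$gene, A = rl$gene[1:4]))
  expect_warning(r <- gsea_preranked(rl, full, n_perm = 100, seed = 1),
                 "whole list")
  expect_equal(r$set, "A")
})

test_that("Monte-Carlo panel test matches the hypergeometric null", {
  # degenerate universes
  all_sig <- make_results_table(rep(0.001, 50))
  r <- montecarlo_set_test(all_sig, all_sig$gene[1:5], b_draws = 1000,
                           seed = 1)
  expect_equal(r$observed, 5)
  expect_equal(r$p_emp, 1)
  none_sig <- make_results_table(rep(0.9, 50))
  r0 <- montecarlo_set_test(none_sig, none_sig$gene[1:5], b_draws = 1000,
                            seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_emp, 1)
  expect_equal(r0$analytic_p, 1)

  # randomized (N, K, m) instances: empirical tail within 3 MC SEs of the
  # exact hypergeometric tail, which the sampling-without-replacement
  # null reduces to
  set.seed(44)
  for (k in 1:8) {
    N <- sample(80:300, 1)
    K <- sample(5:40, 1)
    m <- sample(3:15, 1)
    p <- rep(0.5, N)
    p[sample(N, K)] <- 0.01
    res <- make_results_table(p)
    panel <- res$gene[sample(N, m)]
    out <- montecarlo_set_test(res, panel, b_draws = 4000, seed = 100 + k)
    exact <- stats::phyper(out$observed - 1, K, N - K, m, lower.tail = FALSE)
    expect_equal(out$analytic_p, exact)
    se <- sqrt(exact * (1 - exact) / out$b_draws)
    expect_lt(abs(out$p_emp - exact), 3 * se + 2 / out$b_draws)
  }

  # reproducibility and validation
  res <- make_results_table(runif(100))
  a <- montecarlo_set_test(res, res$gene[1:10], b_draws = 2000, seed = 5)
  b <- montecarlo_set_test(res, res$gene[1:10], b_draws = 2000, seed = 5)
  expect_identical(a$p_emp, b$p_emp)
  expect_warning(
    m2 <- montecarlo_set_test(res, c(res$gene[1:3], "ABSENT"),
                              b_draws = 1000, seed = 1),
    "ABSENT"
  )
  expect_equal(m2$m, 3)
  expect_error(suppressWarnings(montecarlo_set_test(res, "ABSENT",
                                                    b_draws = 1000)),
               "no panel gene")
  expect_error(montecarlo_set_test(res, res$gene[1], b_draws = 10), "b_draws")
  expect_error(montecarlo_set_test(res, res$gene[1], alpha_unc = 1.5), "alpha_unc")
})

test_that("panel screening reports found, missing and flagged genes", {
  res <- make_results_table(c(0.001, 0.2, 0.04), genes = c("PER1", "CRY1", "CLOCK"),
                            direction = c(1L, -1L, -1L))
  res$q <- c(0.01, 0.6, 0.2)
  sc <- screen_panel(res, c("PER1", "CRY1", "CLOCK", "GONE"))
  expect_equal(nrow(sc$table), 3)
  expect_equal(sc$missing, "GONE")
  expect_equal(sc$table$regulation, c("up", "down", "down"))
  expect_equal(sc$table$sig_unc, c(TRUE, FALSE, TRUE))
  expect_equal(sc$table$sig_fdr, c(TRUE, FALSE, FALSE))

  # empty intersection
  sc0 <- screen_panel(res, c("NOPE1", "NOPE2"))
  expect_equal(nrow(sc0$table), 0)
  expect_equal(sort(sc0$missing), c("NOPE1", "NOPE2"))

  # the 23-gene circadian panel against a universe containing it
  universe <- make_results_table(runif(100, 0.2, 1),
                                 genes = c(circadian_panel(),
                                           sprintf("G%03d", 1:77)))
  sc23 <- screen_panel(universe, circadian_panel())
  expect_equal(nrow(sc23$table), 23)
  expect_length(sc23$missing, 0)
})
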