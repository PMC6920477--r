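test_that("bh_fdr equals the brute-force step-up and handles edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (k in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p-rank
    expect_true(all(q >= p - 1e-12 & q <= 1))
  }
})

test_that("single-gene LRT matches its contract on degenerate and signed inputs", {
  st <- make_paired_study(25, n_genes = 2, shift_t2 = c(1.2, 0), seed = 21)
  # constant gene: flagged, never thrown
  st$values[2, ] <- 3
  r <- fit_gene_lrt(st, st$genes[2], contrast_spec("M1"))
  expect_false(r$converged)
  expect_equal(r$p, 1)

  # clearly upregulated gene: positive estimate, direction +1, small p
  r1 <- fit_gene_lrt(st, st$genes[1], contrast_spec("M1"))
  expect_true(r1$converged)
  expect_gt(r1$estimate, 0)
  expect_equal(r1$direction, 1)
  expect_lt(r1$p, 1e-4)
  expect_gte(r1$lrt_stat, 0)
  expect_error(fit_gene_lrt(st, "NOPE", contrast_spec("M1")), "NOPE")
})

test_that("balanced two-timepoint LRT agrees with the closed-form paired-t oracle", {
  set.seed(140)
  for (k in 1:12) {
    st <- make_paired_study(sample(10:40, 1), n_genes = 1,
                            shift_t2 = runif(1, -0.5, 0.5), seed = 1000 + k)
    r <- fit_gene_lrt(st, st$genes[1], contrast_spec("M1"))
    expect_lt(abs(r$p - oracle_paired_lrt_p(st)), 1e-6)
  }
})

test_that("M2 interaction is recovered with the right sign and dies under label permutation", {
  # responders gain 1 log-unit at T2; non-responders flat
  eff <- effect_spec("group_by_time", genes = "G00001", magnitude = 1,
                     timepoint_profile = c(0, 1, 1),
                     group_restriction = "responder")
  cfg <- sim_config(n_genes = 40, effects = list(eff), seed = 55)
  st <- simulate_cohort(cfg)
  res <- run_transcriptome(st, "M2")
  row <- res[res$gene == "G00001", ]
  expect_lt(row$q, 0.05)
  expect_equal(row$direction, 1)
  expect_equal(row$estimate, 1, tolerance = 0.35)
  # with one gene the adjustment is the identity
  one <- fit_gene_lrt(st, "G00001", contrast_spec("M2"))
  expect_equal(one$q, one$p)

  # permuting response labels across subjects destroys the signal:
  # p-values become uniform (KS check over the null genes)
  set.seed(9)
  s <- st$samples
  subj <- unique(s$subject_id[s$group != "control"])
  newgrp <- setNames(sample(s$group[match(subj, s$subject_id)]), subj)
  s2 <- s
  pat <- s2$group != "control"
  s2$group[pat] <- newgrp[s2$subject_id[pat]]
  stp <- expression_study(st$values, s2)
  resp <- run_transcriptome(stp, "M2")
  ks <- suppressWarnings(stats::ks.test(resp$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("baseline linear models recover shifts, respect symmetry, and validate groups", {
  # identical groups by construction: copied data, relabeled subjects
  st <- make_paired_study(10, n_genes = 30, seed = 61)
  s <- st$samples
  s2 <- s
  s2$subject_id <- paste0("X", s2$subject_id)
  s2$sample_id <- paste(s2$subject_id, s2$timepoint, sep = "_")
  s2$group <- "non_responder"
  both <- rbind(s, s2)
  vals2 <- st$values
  colnames(vals2) <- s2$sample_id
  st2 <- expression_study(cbind(st$values, vals2), both)
  sym <- baseline_differences(st2, "response")
  expect_true(all(abs(sym$estimate) < 1e-8))

  # injected baseline shift of 1 log-unit is recovered at q < 0.05
  eff <- effect_spec("baseline_shift", genes = "G00010", magnitude = 1,
                     group_restriction = "responder")
  cfg <- sim_config(n_genes = 200, effects = list(eff), seed = 71)
  stsim <- simulate_cohort(cfg)
  bl <- baseline_differences(stsim, "response")
  expect_lt(bl$q[bl$gene == "G00010"], 0.05)
  # sampling SE of the group difference is ~0.2 here; allow 4 SEs
  expect_equal(bl$estimate[bl$gene == "G00010"], 1, tolerance = 0.8)

  # a null simulation stays quiet
  nul <- baseline_differences(simulate_cohort(sim_config(n_genes = 200,
                                                         seed = 72)),
                              "case")
  expect_lte(sum(nul$q < 0.05), 1)

  # absent comparison group is an error
  resp_only <- subset_samples(stsim, stsim$samples$group == "responder")
  expect_error(baseline_differences(resp_only, "response"), "non-responders")
  expect_error(baseline_differences(resp_only, "case"), "controls")
})

test_that("likelihood ratios are non-negative for nested fits across contrasts", {
  cfg <- sim_config(n_genes = 15, seed = 81,
                    effects = list(effect_spec("time_main", genes = "G00002",
                                               magnitude = 0.6,
                                               timepoint_profile = c(0, 1, 1))))
  st <- simulate_cohort(cfg)
  for (nm in c("M1", "M2", "M3")) {
    res <- run_transcriptome(st, nm)
    expect_true(all(res$lrt_stat[res$converged] >= 0))
    expect_true(all(res$q[res$converged] >= res$p[res$converged] - 1e-12))
    expect_equal(res$p, sort(res$p)) # sorted ascending
  }
})
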