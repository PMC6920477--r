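make_three_tp_study <- function(n_subjects, n_genes, bump = 0, seed = 1,
                                sigma_u = 0.5, sigma_e = 0.5) {
  # bump: shared standardized-scale shift at T2 and T3 for all genes
  set.seed(seed)
  part <- matrix(c(n_subjects, n_subjects, n_subjects, 0L, 0L, 0L,
                   0L, 0L, 0L), nrow = 3, byrow = TRUE)
  effs <- if (bump != 0) list(
    effect_spec("set_coherent_trajectory",
                genes = sprintf("G%05d", seq_len(n_genes)),
                magnitude = bump, timepoint_profile = c(0, 1, 1))
  ) else list()
  cfg <- sim_config(n_genes = n_genes, participation = part,
                    subject_intercept_sd = sigma_u, residual_sd = sigma_e,
                    effects = effs, n_protocol_violators = 0, seed = seed)
  simulate_cohort(cfg)
}

test_that("time-constant gene sets yield a null time-course test", {
  st <- make_three_tp_study(15, 8, seed = 301)
  # make genes literally independent of timepoint: copy T1 values
  subj <- unique(st$samples$subject_id)
  for (tp in c("T2", "T3"))
    st$values[, paste0(subj, "_", tp)] <- st$values[, paste0(subj, "_T1")]
  r <- tcgsa_lrt(st, st$genes, cohort = "patients", ref = "chisq")
  expect_true(r$converged)
  expect_lt(r$lrt_stat, 1e-4)
  expect_gt(r$p, 0.99)
})

test_that("a coherent injected trajectory is detected and a null one is not", {
  hit <- tcgsa_lrt(make_three_tp_study(30, 20, bump = 1, seed = 302),
                   st_genes <- sprintf("G%05d", 1:20), cohort = "patients")
  expect_true(hit$converged)
  expect_lt(hit$p, 1e-4)

  nul <- tcgsa_lrt(make_three_tp_study(30, 20, bump = 0, seed = 303),
                   sprintf("G%05d", 1:20), cohort = "patients")
  expect_gt(nul$p, 0.001)
})

test_that("ill-conditioned sets take the excluded-as-non-converged path", {
  st <- make_three_tp_study(12, 6, seed = 304)
  sets <- gene_set_collection(list(
    OK = sprintf("G%05d", 1:5),
    BAD = "G00006" # single gene: cannot separate gene and time variation
  ))
  out <- run_tcgsa_collection(st, sets, cohorts = "patients")
  expect_equal(out$patients$excluded, "BAD")
  tab <- out$patients$table
  expect_true(tab$converged[tab$set == "OK"])
  expect_false(tab$converged[tab$set == "BAD"])
  expect_true(is.na(tab$p[tab$set == "BAD"]))
  # converged sets still get q-values; q >= p
  expect_gte(tab$q[tab$set == "OK"], tab$p[tab$set == "OK"])

  expect_error(run_tcgsa_collection(st, sets, cohorts = "aliens"),
               "unknown cohort")
  expect_error(run_tcgsa_collection(st, sets, cohorts = "controls"),
               "no samples")
})

test_that("protocol-violating T3 samples are excluded from the stack", {
  st <- make_three_tp_study(10, 4, seed = 305)
  st$samples$protocol_violation[st$samples$timepoint == "T3"][1:2] <- TRUE
  stk <- sdexpr:::tcgsa_stack(st, st$genes, "patients")
  expect_equal(nrow(stk$samples), 30 - 2)
  expect_false(any(stk$samples$protocol_violation &
                     stk$samples$timepoint == "T3"))
})

test_that("trend extraction zeroes T1, partitions genes, matches hand computation", {
  # 2 genes, 1 subject: trends equal raw T-minus-T1 differences after
  # within-gene standardization
  vals <- rbind(G1 = c(1, 3, 5), G2 = c(2, 2, 8))
  st <- make_manual_study(vals, subjects = rep("S1", 3),
                          timepoints = c("T1", "T2", "T3"))
  tr <- extract_trends(st, c("G1", "G2"), cohort = "patients",
                       n_clusters = 2)
  expect_equal(unname(tr[, "T1"]), rep(0, nrow(tr)))
  z1 <- (c(1, 3, 5) - 3) / sd(c(1, 3, 5))
  z2 <- (c(2, 2, 8) - 4) / sd(c(2, 2, 8))
  expected <- rbind(z1 - z1[1], z2 - z2[1])
  got <- unclass(tr)[c(which(sapply(attr(tr, "membership"),
                                    function(m) "G1" %in% m)),
                       which(sapply(attr(tr, "membership"),
                                    function(m) "G2" %in% m))), ]
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)

  # membership is a partition of the used genes
  st2 <- make_three_tp_study(8, 10, seed = 306)
  tr2 <- extract_trends(st2, st2$genes, cohort = "patients", n_clusters = 4)
  members <- unlist(attr(tr2, "membership"))
  expect_setequal(members, st2$genes)
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(unname(tr2[, "T1"]), rep(0, nrow(tr2)))

  # constant genes give a single all-zero trend row
  flat <- make_manual_study(rbind(G1 = c(2, 2, 2), G2 = c(7, 7, 7)),
                            subjects = rep("S1", 3),
                            timepoints = c("T1", "T2", "T3"))
  trf <- extract_trends(flat, c("G1", "G2"), cohort = "patients")
  expect_true(all(trf == 0))
})

test_that("trend heatmaps render significant sets deterministically", {
  st <- make_three_tp_study(20, 24, bump = 1, seed = 307)
  sets <- gene_set_collection(list(SIG = sprintf("G%05d", 1:12),
                                   SIG2 = sprintf("G%05d", 13:24)))
  out <- run_tcgsa_collection(st, sets, cohorts = "patients")
  expect_gte(out$patients$n_significant, 1)
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "a.png")
  f2 <- file.path(tmp, "b.png")
  m1 <- render_trend_heatmap(out$patients, f1)
  m2 <- render_trend_heatmap(out$patients, f2)
  expect_true(file.exists(f1))
  expect_identical(m1, m2)
  expect_file_md5_equal(f1, f2)
  # rows carry 3 timepoint columns
  expect_equal(ncol(m1), 3)
  # excluding a set removes its rows
  m3 <- render_trend_heatmap(out$patients, file.path(tmp, "c.png"),
                             exclude = "SIG2")
  expect_false(any(grepl("^SIG2:", rownames(m3))))

  # nothing significant: placeholder plus warning
  null_res <- out$patients
  null_res$table$q[] <- 1
  expect_warning(render_trend_heatmap(null_res, file.path(tmp, "d.png")),
                 "placeholder")
  expect_true(file.exists(file.path(tmp, "d.png")))
})
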