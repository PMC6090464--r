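smallSweep <- function(masterSeed = 1, noiseSd = 0, nSubjects = 2) {
  cfg <- sweepConfig(
    input = ensembleSpec(nRegions = 30, nSubjects = nSubjects,
                         noiseSd = noiseSd, seed = 99),
    nGrid = seq(-1, 3, by = 1), pValues = 0.01, nTrials = 200,
    masterSeed = masterSeed)
  runSweep(cfg)
}

test_that("sweep tables have one row per (subject, n, p) cell", {
  res <- smallSweep()
  st <- subjectTable(res)
  et <- ensembleTable(res)
  expect_equal(nrow(st), 2 * 5 * 1)
  expect_equal(nrow(et), 5 * 1)
  expect_true(all(c("subject_id", "n", "p", "w_t", "m", "lcc_fraction",
                    "clustering", "delta_clustering", "ks_boundary_power",
                    "ks_truncated_power_law") %in% names(st)))
})

test_that("identical subjects give ensemble averages equal to each subject", {
  res <- smallSweep(noiseSd = 0)
  st <- subjectTable(res)
  et <- ensembleTable(res)
  s1 <- st[st$subject_id == "sim001", ]
  # deterministic metrics coincide subject-by-subject
  for (col in c("w_t", "lcc_fraction", "clustering", "delta_clustering",
                "ks_boundary_power", "ks_truncated_power_law"))
    expect_equal(et[[col]], s1[[col]], tolerance = 1e-12)
  # the Monte-Carlo metric averages the per-subject estimates
  s2 <- st[st$subject_id == "sim002", ]
  expect_equal(et$m, (s1$m + s2$m) / 2, tolerance = 1e-12)
})

test_that("ensemble rows recompute as the mean of the subject rows", {
  res <- smallSweep(noiseSd = 0.03, nSubjects = 3)
  st <- subjectTable(res)
  et <- ensembleTable(res)
  for (i in seq_len(nrow(et))) {
    sel <- st$n == et$n[i] & st$p == et$p[i]
    expect_equal(et$m[i], mean(st$m[sel]), tolerance = 1e-12)
    expect_equal(et$clustering[i], mean(st$clustering[sel]),
                 tolerance = 1e-12)
  }
})

test_that("component curves are non-increasing in n for every subject", {
  res <- smallSweep(noiseSd = 0.03)
  st <- subjectTable(res)
  for (sid in unique(st$subject_id)) {
    g <- st[st$subject_id == sid, ]
    g <- g[order(g$n), ]
    expect_true(all(diff(g$lcc_fraction) <= 1e-12))
  }
})

test_that("sweeps are byte-identical under the same master seed", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeSweepTable(smallSweep(masterSeed = 7), f1)
  writeSweepTable(smallSweep(masterSeed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed moves the stochastic column
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeSweepTable(smallSweep(masterSeed = 8), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("cells with too few surviving weights are logged, not fatal", {
  cfg <- sweepConfig(
    input = ensembleSpec(nRegions = 20, nSubjects = 1, seed = 3),
    nGrid = c(0, 2, 6), pValues = 0.01, nTrials = 100, masterSeed = 1)
  res <- runSweep(cfg)
  expect_gt(nrow(res@failures), 0)
  st <- subjectTable(res)
  expect_true(any(is.na(st$ks_boundary_power)))
  expect_true(all(is.finite(st$m)))
})

test_that("critical-point localization breaks ties toward smaller n", {
  toy <- data.frame(
    n = 1:5, p = 0.01,
    w_t = seq(0.1, 0.5, 0.1),
    m = c(0.1, 0.3, 0.2, 0.3, 0.1),
    delta_clustering = c(0, 0.05, 0.2, 0.1, NA),
    ks_boundary_power = c(0.5, 0.2, 0.1, 0.1, 0.4),
    lcc_fraction = c(1, 1, 0.9, 0.5, 0.1))
  cs <- locateCriticalPoint(toy, 0.01)
  expect_equal(cs$n_mi, 2) # tie with n = 4 resolved downward
  expect_equal(cs$n_delta_clustering, 3)
  expect_equal(cs$n_ks, 3) # tie with n = 4 resolved downward
  expect_equal(cs$steps_mi_deltaC, 1)
  expect_false(cs$mi_at_boundary)
  expect_equal(cs$transition_region, c(3, 5))

  # duplicated rows leave the summary unchanged
  cs2 <- locateCriticalPoint(rbind(toy, toy), 0.01)
  expect_equal(cs2[c("n_mi", "n_delta_clustering", "n_ks")],
               cs[c("n_mi", "n_delta_clustering", "n_ks")])

  # a monotone curve localizes at the boundary and is flagged
  mono <- toy
  mono$m <- seq(0.5, 0.1, length.out = 5)
  expect_true(locateCriticalPoint(mono, 0.01)$mi_at_boundary)

  expect_error(locateCriticalPoint(toy[1:2, ], 0.01), "at least 3")
  expect_output(print(cs), "Critical point summary")
})

test_that("all seven curve kinds render to image files", {
  res <- smallSweep()
  kinds <- c("mi_vs_n", "lcc_vs_n", "mi_vs_lcc", "clustering_vs_n",
             "delta_clustering_vs_lcc", "ks_vs_n", "ks_vs_lcc")
  dir <- withr::local_tempdir()
  for (k in kinds) {
    path <- file.path(dir, paste0(k, ".pdf"))
    plotCurves(res, k, path)
    expect_true(file.exists(path))
    expect_gt(file.info(path)$size, 0)
  }
  expect_error(plotCurves(res, "fig42", tempfile()), "unknown kind")

  empty <- new("SweepResult", subjectTable = data.frame(),
               ensembleTable = data.frame(), config = res@config,
               failures = data.frame())
  expect_error(plotCurves(empty, "mi_vs_n", tempfile()), "empty")
})

test_that("directory input feeds the sweep through the matrix reader", {
  dir <- withr::local_tempdir()
  mats <- generateEnsemble(ensembleSpec(nRegions = 15, nSubjects = 2,
                                        seed = 4))
  for (m in mats)
    writeConnectivityMatrix(m, file.path(dir, paste0(subjectId(m), ".txt")))
  cfg <- sweepConfig(input = dir, nGrid = c(0, 1, 2), pValues = 0.05,
                     nTrials = 100, masterSeed = 2,
                     models = "boundary_power")
  res <- runSweep(cfg)
  expect_equal(nrow(subjectTable(res)), 2 * 3)
  expect_true(all(is.na(subjectTable(res)$ks_truncated_power_law)))
})
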