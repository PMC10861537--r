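test_that("cohort generator validates inputs, naming the offending field", {
  expect_error(generate_cohort(1), "n_patients")
  expect_error(generate_cohort(10, mix_before = c("CAF-S1" = 0.7)), "mix_before")
  expect_error(generate_cohort(10, switch_prob = 1.4), "switch_prob")
  expect_error(generate_cohort(10, rho_true = -2), "rho_true")
  expect_error(generate_cohort(10, noise_sd = -1), "noise_sd")
})

test_that("cohorts are seed-reproducible and respect the marker schema", {
  a <- generate_cohort(30, seed = 14)
  b <- generate_cohort(30, seed = 14)
  c <- generate_cohort(30, seed = 15)
  expect_identical(a, b)
  expect_false(identical(a$markers$hscore, c$markers$hscore))
  mk <- a$markers
  expect_true(all(mk$hscore >= 0 & mk$hscore <= 400))
  expect_true(all(mk$intensity >= 0 & mk$intensity <= 4))
  expect_true(all(mk$pct_stained >= 0 & mk$pct_stained <= 100))
  expect_equal(mk$hscore, mk$intensity * mk$pct_stained)
  expect_setequal(unique(mk$marker),
                  c("FAP", "CD29", "SMA", "FSP1", "ANTXR1", "YAP1"))
  expect_true(all(a$tils$count >= 0))
  expect_true(all(a$tils$area_mm2 > 0))
})

test_that("zero-noise, zero-switch cohorts reproduce profile means exactly", {
  co <- generate_cohort(15, noise_sd = 0, switch_prob = 0, seed = 2)
  prof <- caf_marker_profiles()
  mk <- co$markers
  for (i in seq_len(nrow(mk))) {
    expect_equal(mk$hscore[i],
                 prof[co$truth$pop_before[mk$patient_id[i]], mk$marker[i]])
  }
  after <- mk[mk$timepoint == "after", ]
  before <- mk[mk$timepoint == "before", ]
  key <- function(d) order(d$patient_id, d$marker)
  expect_equal(after$hscore[key(after)], before$hscore[key(before)])
})

test_that("planted delta anti-correlation is recovered from the tables", {
  co <- generate_cohort(200, rho_true = -0.6, seed = 7)
  d_fap <- compute_delta(co$markers)
  d_fap <- d_fap[d_fap$marker == "FAP", ]
  cd8 <- co$tils[co$tils$cell_type == "CD8", ]
  cd8$density <- compute_til_density(cd8$count, cd8$area_mm2)
  d_cd8 <- compute_delta(cd8, value = "density", by = "cell_type")
  rho <- spearman_test(d_fap$delta[order(d_fap$patient_id)],
                       d_cd8$delta[order(d_cd8$patient_id)])$statistic
  expect_lt(abs(rho - (-0.6)), 0.15)
})

test_that("degenerate all-CAF-S2 mixtures classify entirely as CAF-S2", {
  co <- generate_cohort(40, mix_before = c("CAF-S2" = 1), switch_prob = 0,
                        noise_sd = 10, seed = 3)
  th <- learned_thresholds(seed = 55)
  calls <- classify_cohort(co$markers, th)
  expect_true(mean(calls$population == "CAF-S2") >= 0.95)
})

test_that("cell maps honor Poisson intensities and hard exclusion radii", {
  st <- spatial_truth(c(0, 200, 0, 200), c(A = 0.002))
  mp <- generate_cellmap(st, seed = 4)$map
  lambda_a <- 0.002 * 200 * 200  # expected 80 points
  expect_lt(abs(nrow(mp$cells) - lambda_a), 4 * sqrt(lambda_a))
  expect_true(all(mp$cells$x >= 0 & mp$cells$x <= 200))

  st2 <- spatial_truth(c(0, 500, 0, 500), c(A = 0.0004, B = 0.0004),
                       list(list(type = "exclusion", a = "A", b = "B",
                                 d_excl = 50)))
  mm <- generate_cellmap(st2, seed = 5)$map
  ca <- mm$cells[mm$cells$label == "A", ]
  cb <- mm$cells[mm$cells$label == "B", ]
  dmin <- min(sqrt(outer(ca$x, cb$x, "-")^2 + outer(ca$y, cb$y, "-")^2))
  expect_gte(dmin, 50)
  # reproducibility
  expect_identical(generate_cellmap(st2, seed = 5), generate_cellmap(st2, seed = 5))
  # an exclusion radius covering the window cannot be satisfied
  st3 <- spatial_truth(c(0, 100, 0, 100), c(A = 0.005, B = 0.005),
                       list(list(type = "exclusion", a = "A", b = "B",
                                 d_excl = 400)))
  expect_error(generate_cellmap(st3, seed = 6), "unsatisfiable")
  expect_error(spatial_truth(c(0, 10, 0, 10), c(A = -1)), "intensity")
  expect_error(spatial_truth(c(0, 10, 0, 10), c(A = 1),
                             list(list(type = "exclusion", a = "A", b = "A",
                                       d_excl = 0))), "d_excl")
})

test_that("planted attraction raises the co-occurrence ratio at cluster scale", {
  ratios <- vapply(1:20, function(s) {
    st <- spatial_truth(c(0, 500, 0, 500), c(A = 0.0008, B = 1),
                        list(list(type = "attraction", parent = "A",
                                  offspring = "B", cluster_sd = 10,
                                  mean_count = 3)))
    mp <- generate_cellmap(st, seed = 1000 + s)$map
    r <- co_occurrence(mp, radii = 30, ref_labels = "A", target_labels = "B")
    r$ratio
  }, numeric(1))
  expect_gt(mean(ratios, na.rm = TRUE), 1)
})

test_that("spot datasets follow the planted program model", {
  tr <- program_truth(3, 60, 80)
  ds <- generate_spot_dataset(tr, seed = 21)
  expect_identical(ds, generate_spot_dataset(tr, seed = 21))
  expect_equal(rowSums(ds$truth$usage), rep(1, 80))
  expect_true(all(ds$truth$programs >= 0))
  expect_true(all(ds$counts@x >= 0))
  expect_true(all(ds$abundance == floor(ds$abundance)))
  # genes with zero program mass everywhere stay zero columns
  mu <- ds$truth$lib_sizes * (ds$truth$usage %*% ds$truth$programs)
  zero_mean <- colSums(mu) == 0
  if (any(zero_mean)) {
    expect_true(all(as.matrix(ds$counts)[, zero_mean] == 0))
  }
  # K_true = 1 gives an expected rank-1 count matrix: one NMF factor
  # reaches a reconstruction error comparable to the true factorization
  tr1 <- program_truth(1, 50, 60)
  ds1 <- generate_spot_dataset(tr1, seed = 22)
  X <- as.matrix(ds1$counts)
  fit <- nmf(X, 1, seed = 1, max_iter = 300, tol = 1e-7)
  err_fit <- sum((X - fit$usage %*% fit$programs)^2)
  mu1 <- ds1$truth$lib_sizes * (ds1$truth$usage %*% ds1$truth$programs)
  err_true <- sum((X - mu1)^2)
  expect_lt(err_fit, 2 * err_true)
  # negative binomial converges to Poisson as dispersion grows
  tr_nb <- program_truth(2, 40, 2000, noise = "nb", dispersion = 1e8)
  tr_po <- program_truth(2, 40, 2000, noise = "poisson")
  m_nb <- colMeans(as.matrix(generate_spot_dataset(tr_nb, seed = 9)$counts))
  m_po <- colMeans(as.matrix(generate_spot_dataset(tr_po, seed = 9)$counts))
  expect_equal(m_nb, m_po, tolerance = 0.05)
  expect_error(program_truth(0, 10, 10), "k_true")
  expect_error(program_truth(5, 3, 10), "n_genes")
})

test_that("spot datasets round-trip through MTX/TSV/CSV files", {
  ds <- generate_spot_dataset(program_truth(2, 30, 40), seed = 31)
  dir <- tempfile()
  write_spot_dataset(ds, dir)
  back <- read_spot_counts(dir)
  expect_equal(as.matrix(back), as.matrix(ds$counts))
  ab <- read.csv(file.path(dir, "abundance.csv"))
  expect_equal(as.matrix(ab[, -1]),
               matrix(ds$abundance, nrow(ds$abundance),
                      dimnames = list(NULL, colnames(ds$abundance))))
})

test_that("regulon datasets drive targets by planted TF activity", {
  rt <- regulon_truth(n_tfs = 1, targets_per_tf = 10, noise_sd = 0,
                      prop_repressed = 0)
  rd <- generate_regulon_dataset(rt, 50, seed = 41)
  act <- tf_activity(rd$expr, rd$regulons, min_confidence = "C")
  # with zero noise and all-activating targets the estimated activity is a
  # strictly increasing function of the planted one
  common <- intersect(rownames(act), rownames(rd$truth$activity))
  o <- order(rd$truth$activity[common[1], ])
  expect_true(all(diff(act[common[1], o]) > 0))
  # constant planted activity gives near-constant estimates
  rt2 <- regulon_truth(n_tfs = 2, targets_per_tf = 10, noise_sd = 0.01)
  rd2 <- generate_regulon_dataset(rt2, 40, seed = 42)
  rd2$truth$activity[] <- 0  # not used; regenerate expression directly
  reg <- rd2$regulons
  expr <- sapply(seq_len(nrow(reg)), function(j) rnorm(40, 5, 0.01))
  colnames(expr) <- reg$target
  act2 <- tf_activity(expr, reg, "C")
  expect_lt(max(apply(act2, 1, sd)), 1.5)  # z-scores of pure noise stay tame
  # schema round-trip
  path <- tempfile(fileext = ".tsv")
  write_regulon_table(rd$regulons, path)
  expect_equal(read_regulon_table(path), rd$regulons)
  expect_error(regulon_truth(targets_per_tf = 0), "target")
})
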