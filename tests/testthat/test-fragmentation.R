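# b/y ladders, spectrum annotation, and spectrum-graph de novo sequencing.

test_that("ion ladder values match hand summation and complementarity", {
  lad <- ion_ladder("GG")
  expect_equal(lad$b[1], 58.02874, tolerance = 1e-5)
  expect_equal(lad$y[1], 76.03930, tolerance = 1e-5)
  set.seed(3)
  for (i in 1:50) {
    s <- random_sequence(sample(4:25, 1))
    lad <- ion_ladder(s)
    n <- nchar(s)
    # b_i + y_(n-i) = [M+H]+ + proton at every index
    expect_equal(lad$b[seq_len(n - 1)] + lad$y[rev(seq_len(n - 1))],
                 rep(lad$mh + 1.007276, n - 1))
  }
  # published fragment anchor: the CAM'd 12-mer ladder closes at 1383.60
  lad12 <- ion_ladder("KNGIPCGESCVY", list(mod_carbamidomethyl()))
  expect_equal(lad12$mh, 1383.60, tolerance = 0.5)
  expect_equal(lad12$b[11] + lad12$y[1], lad12$mh + 1.007276)
})

test_that("annotation coverage reflects which backbone bonds have ions", {
  s <- "KNGIPCGESCVF"
  lad <- ion_ladder(s)
  n <- nchar(s)
  full <- msms_spectrum(lad$mh, c(lad$b[1:(n - 1)], lad$y[1:(n - 1)]))
  expect_equal(annotate_spectrum(full, s)$coverage, 1.0)
  # deleting every second b ion leaves coverage 1 while y ions survive
  bkeep <- lad$b[seq(1, n - 1, by = 2)]
  sp2 <- msms_spectrum(lad$mh, c(bkeep, lad$y[1:(n - 1)]))
  expect_equal(annotate_spectrum(sp2, s)$coverage, 1.0)
  # y-only spectrum with half the ions covers exactly those bonds
  ykeep_idx <- seq(1, n - 1, by = 2)
  sp3 <- msms_spectrum(lad$mh, lad$y[ykeep_idx])
  expect_equal(annotate_spectrum(sp3, s)$coverage, length(ykeep_idx) / (n - 1))
  # annotating the wrong species is refused on precursor mismatch
  expect_error(annotate_spectrum(full, "KNGIPCGESCVY"), "precursor")
})

test_that("coverage equals direct set arithmetic on a partially retained spectrum", {
  cfg <- generator_config(seed = 7, msms_retention = 0.6, msms_jitter_sd = 0)
  s <- "SCVYIPCFTSVIGCSCSNKVCYKNGIPCGE"
  sp <- simulate_msms(s, cfg)
  lad <- attr(sp, "truth")
  n <- nchar(s)
  got <- annotate_spectrum(sp, s)$coverage
  b_obs <- which(lad$b[1:(n - 1)] %in% sp$mz)
  y_obs <- which(lad$y[1:(n - 1)] %in% sp$mz)
  expect_equal(got, length(union(b_obs, n - y_obs)) / (n - 1))
})

test_that("annotation coverage never grows as the tolerance shrinks", {
  cfg <- generator_config(seed = 19, msms_retention = 0.8,
                          msms_jitter_sd = 0.08)
  s <- "NGIPCGESCVYIPCFTSVIGCSCSNK"
  sp <- simulate_msms(s, cfg)
  tols <- c(0.5, 0.3, 0.15, 0.05, 0.01)
  covs <- vapply(tols, function(tl) {
    sp$tolerance <- tl
    annotate_spectrum(sp, s)$coverage
  }, numeric(1))
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("de novo recovers full-ladder peptides up to Leu/Ile, 100/100", {
  ok <- 0L
  set.seed(123)
  lens <- sample(8:30, 100, replace = TRUE)
  for (i in 1:100) {
    cfg <- generator_config(seed = 1000 + i, msms_retention = 1,
                            msms_jitter_sd = 0)
    s <- random_sequence(lens[i])
    sp <- simulate_msms(s, cfg, modifications = list(mod_carbamidomethyl()))
    top <- denovo_sequence(sp, modifications = list(mod_carbamidomethyl()))
    if (nrow(top) > 0 && top$complete[1] &&
        top$sequence[1] == gsub("[LI]", "J", s)) ok <- ok + 1L
  }
  expect_identical(ok, 100L)
})

test_that("a deleted b/y pair is bridged when the complement survives", {
  s <- "GASPVTKFE"
  lad <- ion_ladder(s)
  n <- nchar(s)
  # remove b4 but keep y5 (same bond): path must still be unique
  mz <- c(lad$b[setdiff(1:(n - 1), 4)], lad$y[1:(n - 1)])
  sp <- msms_spectrum(lad$mh, mz)
  top <- denovo_sequence(sp)
  expect_identical(top$sequence[1], gsub("[LI]", "J", s))
  expect_true(top$complete[1])
})

test_that("empty and sparse spectra degrade gracefully", {
  sp <- msms_spectrum(1000, numeric(0))
  res <- denovo_sequence(sp)
  expect_equal(nrow(res), 0L)
  # two uninformative peaks: best partial paths are flagged incomplete
  sp2 <- msms_spectrum(3000, c(250.1, 251.3))
  res2 <- denovo_sequence(sp2)
  expect_true(all(!res2$complete))
})

test_that("de novo is deterministic for fixed inputs", {
  cfg <- generator_config(seed = 77, msms_retention = 0.9,
                          msms_jitter_sd = 0.02)
  sp <- simulate_msms("KNGIPCGESCVYIPW", cfg)
  a <- denovo_sequence(sp)
  b <- denovo_sequence(sp)
  expect_identical(a, b)
})
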