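# Mass arithmetic for linear and cyclic peptides with disulfides and
# derivatization.

test_that("single-residue and toy masses are exact", {
  expect_equal(monoisotopic_mass(peptide_species("G")), 75.03202,
               tolerance = 1e-4)
  # [M+H]+ is always the neutral mass plus one proton
  sp <- peptide_species("VCYK", modifications = list(mod_carbamidomethyl()))
  expect_equal(mh_plus(sp) - monoisotopic_mass(sp), 1.007276)
  expect_equal(mh_plus(sp), 569.28, tolerance = 0.01)
})

test_that("published fragment and parent masses are reproduced", {
  cam <- function(n) list(list(spec = mod_carbamidomethyl(), count = n))
  chym <- peptide_species("KNGIPCGESCVY", modifications = cam(2))
  expect_equal(mh_plus(chym), 1383.60, tolerance = 0.01)
  native <- peptide_species(SPAT1, "cyclic", n_disulfides = 3)
  expect_equal(monoisotopic_mass(native), 3149.3247, tolerance = 1e-3)
  expect_equal(mh_plus(native), 3150.1, tolerance = 0.5)  # observed MALDI
  gluc <- peptide_species("SCVYIPCFTSVIGCSCSNKVCYKNGIPCGE",
                          modifications = cam(6))
  expect_equal(mh_plus(gluc), 3516.19, tolerance = 0.5)   # observed MALDI
  chym18 <- peptide_species("IPCFTSVIGCSCSNKVCY", modifications = cam(4))
  expect_equal(mh_plus(chym18), 2151.73, tolerance = 0.5) # observed MALDI
})

test_that("derivatization and ring-opening shifts follow the Cys scaffold", {
  expect_identical(derivatization_shift(6, 3, nominal = TRUE), 348)
  expect_identical(derivatization_shift(0, 0, nominal = TRUE), 0)
  expect_equal(derivatization_shift(6, 3), 348.176, tolerance = 1e-3)
  expect_identical(ring_opening_shift(nominal = TRUE), 18)
  expect_equal(ring_opening_shift(), 18.010565)
  expect_identical(derivatization_shift(6, 3, nominal = TRUE) +
                     ring_opening_shift(nominal = TRUE), 366)
  expect_error(derivatization_shift(-1, 0), "non-negative")
  expect_error(derivatization_shift(2, 2), "exceed")
})

test_that("the derivatized linear form equals native + 348 + 18 compositionally", {
  native <- peptide_species(SPAT1, "cyclic", n_disulfides = 3)
  ra <- peptide_species(SPAT1, "cyclic", n_disulfides = 0,
                        modifications = list(list(spec = mod_carbamidomethyl(),
                                                  count = 6)))
  lin <- peptide_species(SPAT1, "linear", n_disulfides = 0,
                         modifications = list(list(spec = mod_carbamidomethyl(),
                                                   count = 6)))
  expect_equal(monoisotopic_mass(ra) - monoisotopic_mass(native),
               derivatization_shift(6, 3))
  expect_equal(monoisotopic_mass(lin) - monoisotopic_mass(ra),
               ring_opening_shift())
})

test_that("linearization adds exactly one water for any sequence", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_sequence(sample(5:40, 1))
    expect_equal(monoisotopic_mass(peptide_species(s, "linear")) -
                   monoisotopic_mass(peptide_species(s, "cyclic")),
                 18.010565)
  }
})

test_that("cyclic mass is invariant under all rotations", {
  n <- nchar(SPAT1)
  masses <- vapply(seq_len(n), function(i) {
    monoisotopic_mass(peptide_species(rotate_ring(SPAT1, i), "cyclic", 3))
  }, numeric(1))
  expect_equal(max(masses) - min(masses), 0)
})

test_that("masses agree with the per-atom summation oracle", {
  set.seed(7)
  for (i in 1:200) {
    s <- random_sequence(sample(3:40, 1))
    cyclic <- runif(1) < 0.5
    n_cys <- sum(strsplit(s, "")[[1]] == "C")
    ss <- if (n_cys >= 2) sample(0:(n_cys %/% 2), 1) else 0L
    sp <- peptide_species(s, if (cyclic) "cyclic" else "linear", ss)
    expect_equal(monoisotopic_mass(sp),
                 oracle_atom_mass(s, cyclic, ss), tolerance = 1e-6)
  }
})

test_that("invalid species are rejected with informative errors", {
  expect_error(peptide_species("GAXK"), "position 3")
  expect_error(peptide_species(""), "non-empty")
  expect_error(peptide_species("ACA", n_disulfides = 1), "Cys")
  expect_identical(unname(RESIDUE_MONO["J"]), unname(RESIDUE_MONO["L"]))
  expect_identical(unname(RESIDUE_MONO["J"]), unname(RESIDUE_MONO["I"]))
  expect_true(all(RESIDUE_MONO > 0))
  expect_identical(length(RESIDUE_MONO), 21L)
})
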