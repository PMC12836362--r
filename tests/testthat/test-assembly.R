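# Cyclic assembly from multi-enzyme evidence and Leu/Ile resolution.

spat1_evidence <- function() {
  path <- system.file("extdata", "spat1_evidence.fasta", package = "cycloseq")
  recs <- read_fasta(path)
  lapply(seq_len(nrow(recs)), function(i) {
    fragment_evidence(recs$sequence[i], enzyme = recs$enzyme[i],
                      form = if (identical(recs$topology[i], "linear"))
                        "linearized" else "cyclic")
  })
}

test_that("the five published evidences assemble into the 30-residue ring", {
  asm <- assemble_cyclic(spat1_evidence())
  expect_equal(asm$length, 30L)
  expect_equal(length(asm$cys_positions), 6L)
  expect_true(asm$junction_covered)  # via the junction-spanning tryptic 26-mer
  expect_identical(asm$ring,
                   canonical_rotation(gsub("[LI]", "J", SPAT1)))
})

test_that("hsAA composition resolves all three J positions to Ile", {
  asm <- assemble_cyclic(spat1_evidence())
  observed <- hydrolysis_transform(SPAT1)  # all-Ile ground truth
  res <- resolve_isobaric(asm, observed)
  expect_equal(res$distance, 0)
  expect_equal(res$n_optima, 1L)
  expect_identical(res$ring, canonical_rotation(SPAT1))
  expect_identical(rotate_ring(res$ring, "GIPC"), SPAT1)
})

test_that("an I=2/L=1 composition leaves three tied optima unresolved", {
  asm <- assemble_cyclic(spat1_evidence())
  observed <- hydrolysis_transform(SPAT1)
  observed["I"] <- 2; observed <- c(observed, L = 1)
  res <- resolve_isobaric(asm, observed)
  expect_equal(res$n_optima, 3L)        # choose(3,1) symmetric optima
  expect_equal(length(res$unresolved), 3L)
  expect_true(grepl("J", res$ring))
})

test_that("single and inconsistent evidences behave per contract", {
  one <- fragment_evidence("ACDF", form = "linearized")
  asm <- assemble_cyclic(list(one))
  expect_identical(asm$ring, canonical_rotation("ACDF"))
  expect_false(asm$junction_covered)
  bad <- list(fragment_evidence("SCVYJPCFTSVJGCSCSNKVCYKNGJPCGE",
                                form = "linearized"),
              fragment_evidence("QQQQ", enzyme = "trypsin"))
  expect_error(assemble_cyclic(bad), "QQQQ")
  expect_error(assemble_cyclic(list(fragment_evidence("VCYK"))), "full-length")
})

test_that("assembly is invariant to the rotation of the linearized evidence", {
  ring_j <- gsub("[LI]", "J", SPAT1)
  frags <- list(fragment_evidence("NGJPCGESCVYJPCFTSVJGCSCSNK", "trypsin"))
  outs <- vapply(c(1, 7, 16, 30), function(r) {
    ev <- c(list(fragment_evidence(rotate_ring(ring_j, r),
                                   form = "linearized")), frags)
    assemble_cyclic(ev)$ring
  }, character(1))
  expect_equal(length(unique(outs)), 1L)
})

test_that("hydrolysis transform pools Asx/Glx and drops Cys/Trp", {
  expect_identical(hydrolysis_transform("ACW"), c(A = 1L))
  expect_identical(hydrolysis_transform("NQ"), c(Asx = 1L, Glx = 1L))
  comp <- hydrolysis_transform(SPAT1)
  expected <- c(Asx = 2L, Glx = 1L, F = 1L, G = 3L, I = 3L, K = 2L, P = 2L,
                S = 4L, T = 1L, V = 3L, Y = 2L)
  expect_identical(comp[order(names(comp))], expected[order(names(expected))])
  expect_false(any(c("C", "W") %in% names(comp)))
  expect_error(hydrolysis_transform("GJG"), "J")
})

test_that("observable counts plus Cys/Trp conserve sequence length", {
  set.seed(17)
  for (i in 1:30) {
    s <- random_sequence(sample(5:40, 1))
    chars <- strsplit(s, "")[[1]]
    expect_equal(sum(hydrolysis_transform(s)) +
                   sum(chars %in% c("C", "W")), nchar(s))
  }
})

test_that("ring digest evidence round-trips through assembly, 100 seeds", {
  ok <- 0L
  for (seed in 1:100) {
    sp <- random_cyclotide(generator_config(seed = seed))
    ev <- simulate_digest_evidence(sp)
    asm <- assemble_cyclic(ev)
    if (identical(asm$ring, canonical_rotation(gsub("[LI]", "J", sp$sequence))))
      ok <- ok + 1L
  }
  expect_identical(ok, 100L)
})

test_that("rings without J pass through resolution unchanged", {
  res <- resolve_isobaric("GACDEF", hydrolysis_transform("GACDEF"))
  expect_identical(res$ring, canonical_rotation("GACDEF"))
  expect_equal(res$distance, 0)
  expect_error(resolve_isobaric(strrep("JA", 10), c(I = 10), max_j = 8),
               "cap")
})
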