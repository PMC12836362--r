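# Seeded generators for every input the pipeline consumes: cyclotide-like
# rings, MALDI screen triples, b/y MS/MS spectra, multi-enzyme digest
# evidence, acid-hydrolysis compositions, PI-uptake kinetics, and
# serial-dilution kill curves. Each generator is a pure function of
# (config, seed): identical configs give identical outputs.

#' Generator configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults emulate the
#' measurement conditions of a MALDI-TOF cyclotide discovery workflow:
#' calibration scatter of ~0.2 Da, a handful of background peaks per
#' spectrum, partially covered MS/MS ladders (85% ion retention, 0.05 Da
#' fragment jitter), noise-free amino-acid counts, logistic PI-uptake
#' kinetics and a log-linear kill curve over the 1 x 10^6 CFU/mL inoculum
#' with 100 uL plated.
#'
#' @param seed Integer seed.
#' @param loop_range Per-loop length range (min, max) for random rings;
#'   total length is constrained to `length_range`.
#' @param length_range Total ring length range (cyclotides: 28-37).
#' @param calib_sd Per-peak m/z jitter sd (Da) in MALDI peak lists.
#' @param noise_peaks Expected (Poisson) number of background peaks per
#'   MALDI peak list.
#' @param msms_retention Probability each theoretical b/y ion is observed.
#' @param msms_jitter_sd Fragment m/z jitter sd (Da).
#' @param msms_noise_peaks Expected number of MS/MS background peaks.
#' @param hsaa_noise_sd SD of count noise added per observable residue key.
#' @param pi_plateau,pi_rate,pi_t50 Logistic PI-uptake parameters: plateau
#'   (% uptake), rate (1/min), midpoint (min).
#' @param kill_log_slope Log10 kill per concentration doubling above the
#'   planted LC99.9.
#' @param initial_density,plated_volume Kill-curve inoculum (CFU/mL) and
#'   plated volume (mL).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             loop_range = c(1L, 7L),
                             length_range = c(28L, 37L),
                             calib_sd = 0.2,
                             noise_peaks = 5,
                             msms_retention = 0.85,
                             msms_jitter_sd = 0.05,
                             msms_noise_peaks = 0,
                             hsaa_noise_sd = 0,
                             pi_plateau = 90,
                             pi_rate = 0.5,
                             pi_t50 = 5,
                             kill_log_slope = 2,
                             initial_density = 1e6,
                             plated_volume = 0.1) {
  probs_ok <- msms_retention >= 0 && msms_retention <= 1
  if (!probs_ok || calib_sd < 0 || msms_jitter_sd < 0 || hsaa_noise_sd < 0) {
    stop("probabilities must lie in [0,1] and noise sds must be >= 0",
         call. = FALSE)
  }
  structure(as.list(environment())[setdiff(names(formals()), "probs_ok")],
            class = "generator_config")
}

#' Generate a random cyclotide-like peptide species
#'
#' Draws a head-to-tail cyclic species on the canonical cyclotide
#' scaffold: exactly six cysteines in three disulfides, a conserved
#' glutamic acid in loop 1 (and, as a generator idealization, no Glu
#' elsewhere, so EndoGluC linearization is single-site), and total length
#' inside `length_range`. Loop lengths are drawn uniformly from
#' `loop_range` with rejection until the total fits.
#'
#' @param config A [generator_config()]; its `seed` drives the draw.
#' @return A [peptide_species()] with `topology = "cyclic"`,
#'   `n_disulfides = 3`.
#' @export
random_cyclotide <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  lo <- config$loop_range[1]; hi <- config$loop_range[2]
  need <- config$length_range - 6L  # non-Cys residues
  if (6L * lo > need[2] || 6L * hi < need[1]) {
    stop("infeasible loop ranges for the requested total length",
         call. = FALSE)
  }
  set.seed(config$seed)
  # residue pools: no C anywhere outside the scaffold Cys; no E outside loop 1
  pool <- setdiff(names(CHARGE_PH7), c("C"))
  pool_no_e <- setdiff(pool, "E")
  repeat {
    lens <- sample(lo:hi, 6L, replace = TRUE)
    if (sum(lens) >= need[1] && sum(lens) <= need[2]) break
  }
  loops <- lapply(seq_len(6L), function(i) {
    sample(pool_no_e, lens[i], replace = TRUE)
  })
  epos <- sample.int(lens[1], 1L)
  loops[[1]][epos] <- "E"
  ring <- paste(unlist(lapply(loops, function(l) c("C", l))), collapse = "")
  peptide_species(ring, "cyclic", n_disulfides = 3L)
}

# Internal: Poisson background peaks over a window, log-normal intensities.
noise_peaklist <- function(n_expected, window) {
  n <- stats::rpois(1, n_expected)
  if (n == 0L) return(list(mz = numeric(), intensity = numeric()))
  list(mz = stats::runif(n, window[1], window[2]),
       intensity = stats::rlnorm(n, meanlog = 3, sdlog = 1))
}

#' Simulate a native / reduced-alkylated / digested MALDI triple
#'
#' Plants the species' \[M+H\]+ in the native list, the fully
#' reduced-alkylated mass (+exact derivatization shift) in the RA list and
#' the ring-opened mass (further +water) in the digested list, each
#' perturbed by `N(0, calib_sd^2)`, plus Poisson background peaks across
#' the window.
#'
#' @param species A cyclic [peptide_species()].
#' @param config A [generator_config()].
#' @param window Mass window over which background peaks are drawn.
#' @return List with `native`, `ra`, `digested` ([peaklist()]s) and the
#'   planted `truth` masses.
#' @export
simulate_screen_triple <- function(species, config = generator_config(),
                                   window = c(2500, 4000)) {
  stopifnot(inherits(species, "peptide_species"),
            inherits(config, "generator_config"))
  set.seed(config$seed)
  n_cys <- sum(strsplit(species$sequence, "")[[1]] == "C")
  native_mh <- mh_plus(species)
  ra_mh <- native_mh + derivatization_shift(n_cys, species$n_disulfides)
  dig_mh <- ra_mh +
    if (species$topology == "cyclic") ring_opening_shift() else 0
  plant <- function(mh) {
    bg <- noise_peaklist(config$noise_peaks, window)
    peaklist(c(mh + stats::rnorm(1, 0, config$calib_sd), bg$mz),
             c(stats::rlnorm(1, 5, 0.5), bg$intensity))
  }
  list(native = plant(native_mh), ra = plant(ra_mh), digested = plant(dig_mh),
       truth = c(native = native_mh, ra = ra_mh, digested = dig_mh))
}

#' Simulate a b/y MS/MS spectrum of a linear peptide
#'
#' Generates the full theoretical b/y ladder, retains each ion with
#' probability `msms_retention`, jitters retained m/z by
#' `N(0, msms_jitter_sd^2)` and adds Poisson background peaks below the
#' precursor.
#'
#' @param sequence Linear residue string.
#' @param config A [generator_config()].
#' @param modifications Fixed modifications (e.g. `mod_carbamidomethyl()`).
#' @return An [msms_spectrum()]; the generating ladder is attached as
#'   attribute `truth`.
#' @export
simulate_msms <- function(sequence, config = generator_config(),
                          modifications = list()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  lad <- ion_ladder(sequence, modifications)
  n <- nchar(lad$sequence)
  theo <- c(lad$b[seq_len(n - 1L)], lad$y[seq_len(n - 1L)])
  keep <- stats::runif(length(theo)) <= config$msms_retention
  mz <- theo[keep] + stats::rnorm(sum(keep), 0, config$msms_jitter_sd)
  intensity <- stats::rlnorm(sum(keep), 4, 0.8)
  bg <- noise_peaklist(config$msms_noise_peaks, c(100, lad$mh))
  sp <- msms_spectrum(lad$mh, c(mz, bg$mz), c(intensity, bg$intensity))
  attr(sp, "truth") <- lad
  sp
}

#' Simulate multi-enzyme digest evidence for assembly
#'
#' Digests a cyclic species with EndoGluC, trypsin and chymotrypsin and
#' returns the fragment sequences as [fragment_evidence()] with Leu/Ile
#' collapsed to `J` (what de novo sequencing of each fragment would
#' deliver). The EndoGluC product of a single-Glu ring is tagged
#' `linearized`.
#'
#' @param species A cyclic [peptide_species()].
#' @param enzymes Character vector of [enzyme_rule()] names.
#' @param max_missed Missed cleavages included for the fragment enzymes.
#' @return List of [fragment_evidence()].
#' @export
simulate_digest_evidence <- function(species,
                                     enzymes = c("endoGluC", "trypsin",
                                                 "chymotrypsin"),
                                     max_missed = 0L) {
  stopifnot(inherits(species, "peptide_species"))
  out <- list()
  for (enz in enzymes) {
    res <- digest(species, enzyme_rule(enz), max_missed = max_missed)
    if (nrow(res) == 0L) next
    full_len <- res$length == nchar(species$sequence) & res$missed == 0L
    for (i in seq_len(nrow(res))) {
      seq_j <- gsub("[LI]", "J", res$sequence[i])
      out[[length(out) + 1L]] <- fragment_evidence(
        seq_j, enzyme = enz,
        form = if (full_len[i] && species$topology == "cyclic")
          "linearized" else "cyclic")
    }
  }
  out
}

#' Simulate an acid-hydrolysis amino-acid composition
#'
#' Applies [hydrolysis_transform()] (Asn->Asx, Gln->Glx pooling, Cys/Trp
#' unobservable) and, if `hsaa_noise_sd > 0`, adds rounded Gaussian count
#' noise truncated at zero.
#'
#' @param sequence Concrete residue string (no `J`).
#' @param config A [generator_config()].
#' @return Named count vector in the [hydrolysis_transform()] convention.
#' @export
simulate_hsaa <- function(sequence, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  comp <- hydrolysis_transform(sequence)
  if (config$hsaa_noise_sd > 0) {
    set.seed(config$seed)
    noisy <- comp + round(stats::rnorm(length(comp), 0, config$hsaa_noise_sd))
    comp <- stats::setNames(pmax(as.integer(noisy), 0L), names(comp))
  }
  comp
}

#' Simulate PI-uptake kinetics
#'
#' Logistic permeabilization kinetics between an intact-membrane baseline
#' `Po` and a full-lysis control `P100`:
#' `Px(t) = Po + (P100 - Po) * plateau/100 / (1 + exp(-rate (t - t50)))`.
#'
#' @param config A [generator_config()] (uses `pi_plateau`, `pi_rate`,
#'   `pi_t50`, `seed`).
#' @param times Time grid in minutes.
#' @param Po_level,P100_level Control fluorescence levels.
#' @param noise_sd Gaussian fluorescence noise sd.
#' @return A list of class `pi_kinetics`: `time`, `Px`, `Po`, `P100` and
#'   the generating `truth` percent-uptake curve.
#' @export
simulate_pi <- function(config = generator_config(),
                        times = seq(0, 120, by = 2),
                        Po_level = 100, P100_level = 1100, noise_sd = 0) {
  stopifnot(inherits(config, "generator_config"))
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing",
                                  call. = FALSE)
  set.seed(config$seed)
  truth_pct <- config$pi_plateau /
    (1 + exp(-config$pi_rate * (times - config$pi_t50)))
  Px <- Po_level + (P100_level - Po_level) * truth_pct / 100
  if (noise_sd > 0) Px <- Px + stats::rnorm(length(times), 0, noise_sd)
  structure(list(time = times, Px = Px,
                 Po = rep(Po_level, length(times)),
                 P100 = rep(P100_level, length(times)),
                 truth = truth_pct),
            class = "pi_kinetics")
}

#' Simulate a serial-dilution kill curve with a planted LC99.9
#'
#' Builds undiluted-plate colony counts over a concentration series so that
#' `true_lc` is the lowest concentration meeting both LC99.9 gates
#' (>= 99.9% kill of the inoculum and <= 10 colonies on the undiluted
#' plate); survivor density falls log-linearly with `kill_log_slope` per
#' concentration doubling above the planted endpoint and stays above both
#' gates below it.
#'
#' @param config A [generator_config()] (uses `initial_density`,
#'   `plated_volume`, `kill_log_slope`, `seed`).
#' @param true_lc Planted LC99.9 (same unit as `concentrations`).
#' @param concentrations Tested concentration series (must contain
#'   `true_lc`).
#' @param count_noise Poisson-resample counts when `TRUE`.
#' @return A [kill_curve()]; the planted endpoint is attribute `truth`.
#' @export
simulate_kill <- function(config = generator_config(), true_lc = 20,
                          concentrations = c(5, 10, 20, 40),
                          count_noise = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  if (!(true_lc %in% concentrations)) {
    stop("true_lc must be one of the tested concentrations", call. = FALSE)
  }
  set.seed(config$seed)
  per_plate <- config$initial_density * config$plated_volume  # CFU plated
  counts <- vapply(concentrations, function(conc) {
    if (conc < true_lc) {
      # sub-lethal: well above both gates (>=0.2% survival, >10 colonies)
      round(per_plate * 0.005 * (true_lc / conc))
    } else {
      # at and above the endpoint: <=10 colonies and >=99.9% kill
      doublings <- log2(conc / true_lc)
      max(round(8 / 10^(config$kill_log_slope * doublings)), 0)
    }
  }, numeric(1))
  if (count_noise) counts <- stats::rpois(length(counts), counts)
  curve <- kill_curve(
    data.frame(concentration = concentrations, dilution = 1, count = counts),
    initial_density = config$initial_density,
    plated_volume = config$plated_volume)
  attr(curve, "truth") <- true_lc
  curve
}
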