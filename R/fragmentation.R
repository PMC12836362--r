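# Theoretical b/y-ion ladders, MS/MS spectrum annotation, and
# spectrum-graph de novo sequencing of linear peptides.
#
# Only singly charged b and y ions are modeled (the series used in manual
# MALDI-TOF/TOF annotation). Prefix masses: b_i = sum(residues 1..i) + proton;
# suffix masses: y_j = sum(last j residues) + water + proton; complementarity
# b_i + y_(n-i) = [M+H]+ + proton.

#' Construct an MS/MS spectrum
#'
#' @param precursor_mh Precursor \[M+H\]+ (Da).
#' @param mz,intensity Fragment peak m/z and intensities.
#' @param tolerance Fragment matching tolerance (Da); default 0.3 Da
#'   (MALDI-TOF/TOF scale).
#' @return A list of class `msms_spectrum`; fragment peaks above the
#'   precursor are kept but counted in `n_above_precursor` (noise warning).
#' @export
msms_spectrum <- function(precursor_mh, mz, intensity = rep(1, length(mz)),
                          tolerance = 0.3) {
  stopifnot(is.numeric(precursor_mh), length(precursor_mh) == 1L,
            precursor_mh > 0, tolerance > 0,
            length(mz) == length(intensity))
  ord <- order(mz)
  structure(list(precursor_mh = precursor_mh,
                 mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord]),
                 tolerance = tolerance,
                 n_above_precursor = sum(mz > precursor_mh)),
            class = "msms_spectrum")
}

# Internal: per-position residue masses with fixed residue-targeted mods
# applied (e.g. Cys searched as Cys+CAM when sequencing the alkylated form).
residue_masses_with_mods <- function(chars, modifications = list()) {
  m <- unname(RESIDUE_MONO[chars])
  for (mod in modifications) {
    spec <- if (inherits(mod, "mod_spec")) mod else mod$spec
    if (length(spec$targets) > 0L) {
      m[chars %in% spec$targets] <- m[chars %in% spec$targets] + spec$delta
    }
  }
  m
}

#' Theoretical b/y ion ladder of a linear peptide
#'
#' @param sequence Linear residue string (may contain `J`).
#' @param modifications List of fixed [mod_spec()]s (or `(spec, count)`
#'   pairs) applied at full occupancy of their target residues.
#' @return A list of class `ion_ladder` with `b` and `y` m/z arrays
#'   (singly protonated; `b[i]` covers prefix i, `y[j]` suffix j) and the
#'   peptide `mh`.
#' @examples
#' ion_ladder("GG")$b[1]  # 58.029
#' @export
ion_ladder <- function(sequence, modifications = list()) {
  chars <- split_residues(sequence)
  m <- residue_masses_with_mods(chars, modifications)
  n <- length(m)
  proton <- MASS_CONSTANTS[["proton"]]; water <- MASS_CONSTANTS[["water"]]
  structure(list(
    sequence = paste(chars, collapse = ""),
    b = cumsum(m) + proton,
    y = cumsum(rev(m)) + water + proton,
    mh = sum(m) + water + proton),
    class = "ion_ladder")
}

#' Annotate an MS/MS spectrum with a candidate sequence
#'
#' Matches every theoretical b/y ion of the candidate to its nearest
#' observed peak within the fragment tolerance and reports backbone-bond
#' coverage: the fraction of the n-1 bonds evidenced by at least one b or
#' y ion (bond i is covered by b_i or y_(n-i)).
#'
#' @param spectrum An [msms_spectrum()].
#' @param sequence Candidate linear sequence.
#' @param modifications Fixed modifications as in [ion_ladder()].
#' @param precursor_tol Precursor agreement required before annotation
#'   (Da); a mismatch is an error, preventing annotation of the wrong
#'   species.
#' @return A list of class `annotation_result`: `matches` (data frame of
#'   ion type, index, theoretical and observed m/z, error) and `coverage`.
#' @export
annotate_spectrum <- function(spectrum, sequence, modifications = list(),
                              precursor_tol = 0.5) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  lad <- ion_ladder(sequence, modifications)
  if (abs(lad$mh - spectrum$precursor_mh) > precursor_tol) {
    stop(sprintf(
      "candidate [M+H]+ %.3f does not match precursor %.3f (tol %.3f)",
      lad$mh, spectrum$precursor_mh, precursor_tol), call. = FALSE)
  }
  n <- nchar(lad$sequence)
  theo <- data.frame(
    ion = rep(c("b", "y"), each = n - 1L),
    index = rep(seq_len(n - 1L), 2L),
    mz = c(lad$b[seq_len(n - 1L)], lad$y[seq_len(n - 1L)]))
  obs <- spectrum$mz
  hit <- lapply(seq_len(nrow(theo)), function(i) {
    if (length(obs) == 0L) return(NULL)
    d <- abs(obs - theo$mz[i])
    j <- which.min(d)
    if (d[j] > spectrum$tolerance) return(NULL)
    cbind(theo[i, , drop = FALSE],
          observed = obs[j], error = obs[j] - theo$mz[i])
  })
  hit <- do.call(rbind, hit[!vapply(hit, is.null, logical(1))])
  if (is.null(hit)) {
    hit <- data.frame(ion = character(), index = integer(), mz = numeric(),
                      observed = numeric(), error = numeric())
  }
  rownames(hit) <- NULL
  # bond i covered by b_i or y_(n-i)
  bonds <- unique(c(hit$index[hit$ion == "b"],
                    n - hit$index[hit$ion == "y"]))
  structure(list(matches = hit,
                 coverage = length(bonds) / (n - 1L),
                 sequence = lad$sequence),
            class = "annotation_result")
}

#' Spectrum-graph de novo sequencing
#'
#' Reconstructs linear peptide sequences from a b/y MS/MS spectrum, the
#' computational counterpart of manual b-/y-series alignment. Nodes of the
#' graph are putative prefix-residue masses: 0, the total residue mass
#' (precursor - water - proton), prefix masses read directly off b peaks,
#' and prefix masses obtained from y peaks through the complement
#' transform. Edges connect node pairs whose mass difference matches one
#' residue (with fixed modifications applied) within tolerance. A beam
#' search driven by supporting-ion votes (peaks voting for a path's
#' interior nodes) collects complete paths, which are then ranked by the
#' fraction of their theoretical b/y ions matched by observed peaks
#' (presence-based, length-normalized), ties broken by total absolute mass
#' error, then lexicographically. Leu/Ile are isobaric and emitted as `J`.
#'
#' @param spectrum An [msms_spectrum()].
#' @param modifications Fixed modifications (e.g. `mod_carbamidomethyl()`
#'   when sequencing the reduced/alkylated peptide).
#' @param tol Node/edge mass tolerance (Da); defaults to the spectrum's
#'   fragment tolerance.
#' @param beam Beam width per node (default 64).
#' @param top_n Number of ranked paths returned.
#' @return Data frame of class `denovo_result` with columns `sequence`
#'   (over the 21-letter alphabet, `J` for Leu/Ile), `score`,
#'   `total_error`, `complete`; best path first. When no complete path
#'   exists the best partial paths are returned with `complete = FALSE`.
#' @export
denovo_sequence <- function(spectrum, modifications = list(), tol = NULL,
                            beam = 64L, top_n = 5L) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (is.null(tol)) tol <- spectrum$tolerance
  proton <- MASS_CONSTANTS[["proton"]]; water <- MASS_CONSTANTS[["water"]]
  total <- spectrum$precursor_mh - water - proton

  # residue alphabet with fixed mods; collapse L/I (and J) to J
  letters21 <- setdiff(names(RESIDUE_MONO), c("L", "I"))
  res_mass <- vapply(letters21, function(a) {
    residue_masses_with_mods(a, modifications)
  }, numeric(1))

  empty <- function() {
    structure(data.frame(sequence = character(), score = numeric(),
                         total_error = numeric(), complete = logical()),
              class = c("denovo_result", "data.frame"))
  }
  if (length(spectrum$mz) < 2L || total <= 0) return(empty())

  # candidate prefix masses with ion-support counts
  pref_b <- spectrum$mz - proton
  pref_y <- total + water + proton - spectrum$mz  # complement transform
  cand <- c(0, total, pref_b, pref_y)
  support <- c(0, 0, rep(1, length(pref_b)), rep(1, length(pref_y)))
  keep <- cand > -tol & cand < total + tol
  cand <- cand[keep]; support <- support[keep]
  # merge nodes closer than tol/2 (b/y pairs voting for the same bond)
  ord <- order(cand)
  cand <- cand[ord]; support <- support[ord]
  node_mass <- c(); node_support <- c()
  for (i in seq_along(cand)) {
    k <- length(node_mass)
    if (k > 0L && cand[i] - node_mass[k] <= tol / 2) {
      # weighted merge keeps node near its voters
      w <- node_support[k] + support[i]
      node_mass[k] <- if (w > 0)
        (node_mass[k] * node_support[k] + cand[i] * support[i]) / max(w, 1)
      else (node_mass[k] + cand[i]) / 2
      node_support[k] <- node_support[k] + support[i]
    } else {
      node_mass <- c(node_mass, cand[i])
      node_support <- c(node_support, support[i])
    }
  }
  # pin the endpoints exactly
  node_mass[1] <- 0
  node_mass[length(node_mass)] <- total
  nn <- length(node_mass)

  # beam of partial paths per node: list of (seq, score, err)
  max_res <- max(res_mass); min_res <- min(res_mass)
  paths <- vector("list", nn)
  paths[[1]] <- list(list(seq = "", score = 0, err = 0))
  for (j in 2:nn) {
    acc <- list()
    for (i in (j - 1L):1L) {
      d <- node_mass[j] - node_mass[i]
      if (d > max_res + tol) break  # nodes sorted: no farther edge matches
      if (d < min_res - tol) next
      if (is.null(paths[[i]]) || length(paths[[i]]) == 0L) next
      hits <- which(abs(res_mass - d) <= tol)
      if (length(hits) == 0L) next
      for (h in hits) {
        aa <- letters21[h]
        err_h <- abs(res_mass[h] - d)
        for (p in paths[[i]]) {
          acc[[length(acc) + 1L]] <- list(
            seq = paste0(p$seq, aa),
            score = p$score + node_support[j],
            err = p$err + err_h)
        }
      }
    }
    if (length(acc) == 0L) next
    sc <- vapply(acc, `[[`, numeric(1), "score")
    er <- vapply(acc, `[[`, numeric(1), "err")
    sq <- vapply(acc, `[[`, character(1), "seq")
    # beam ordering penalizes length (2 votes expected per bond), so
    # fully supported paths tie regardless of residue count and the
    # exact-mass path wins on accumulated error
    ord <- order(-(sc - 2 * nchar(sq)), er, sq)
    paths[[j]] <- acc[ord[seq_len(min(beam, length(ord)))]]
  }

  done <- paths[[nn]]
  complete <- TRUE
  if (is.null(done) || length(done) == 0L) {
    # no complete path: report best partials, flagged
    complete <- FALSE
    done <- unlist(paths[-1], recursive = FALSE)
    if (is.null(done) || length(done) == 0L) return(empty())
  }
  sq <- vapply(done, `[[`, character(1), "seq")
  if (complete) {
    # Node-support scores overvalue mirror/chimeric paths built from the
    # complement transform's spurious nodes (each y peak also casts a
    # prefix-mass vote at total + water - prefix, whose own b/y ions
    # coincide with observed peaks). Rescore each complete path by the
    # fraction of its theoretical b/y ions matched to an observed peak
    # within tolerance -- length-normalized, so inserting near-isobaric
    # residue pairs buys no extra credit -- with ties broken by the summed
    # match error, which is zero only for the exact ladder.
    resc <- lapply(unique(sq), function(s) {
      lad <- ion_ladder(s, modifications)
      np <- nchar(s)
      theo <- c(lad$b[seq_len(np - 1L)], lad$y[seq_len(np - 1L)])
      errs <- vapply(theo, function(t) min(abs(spectrum$mz - t)), numeric(1))
      hit <- errs <= tol
      list(seq = s, score = sum(hit) / length(theo), err = sum(errs[hit]))
    })
    done <- resc
    sq <- vapply(done, `[[`, character(1), "seq")
  }
  sc <- vapply(done, `[[`, numeric(1), "score")
  er <- vapply(done, `[[`, numeric(1), "err")
  ord <- order(-sc, er, sq)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  structure(data.frame(sequence = sq[ord], score = sc[ord],
                       total_error = er[ord], complete = complete),
            class = c("denovo_result", "data.frame"))
}
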