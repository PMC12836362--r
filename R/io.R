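# Plain-text readers and writers: two-column peak lists, FASTA with
# key=value description tags (topology=cyclic, enzyme=...), and aligned
# FASTA. Newick I/O lives next to the tree code in phylogeny.R.

#' Read / write a two-column peak list
#'
#' Peak lists are whitespace- or comma-delimited text with two numeric
#' columns (m/z, intensity); `#` lines and an optional non-numeric header
#' row are ignored. Peaks are sorted on read; writing uses 17 significant
#' digits so that a write/read round trip is exact.
#'
#' @param path File path.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data rows in ", path, call. = FALSE)
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[,\t ]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[idx[1]])
  if (all(is.na(first))) idx <- idx[-1]  # header row
  rows <- lapply(idx, function(i) {
    v <- parse_row(lines[i])
    if (length(v) < 2L || anyNA(v[1:2])) {
      stop(sprintf("malformed peak-list row at line %d of %s: '%s'",
                   i, path, lines[i]), call. = FALSE)
    }
    v[1:2]
  })
  m <- do.call(rbind, rows)
  peaklist(m[, 1], m[, 2], label = basename(path))
}

#' @rdname read_peaklist
#' @param peaks A [peaklist()].
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(inherits(peaks, "peaklist"))
  lines <- c("# m/z\tintensity",
             sprintf("%.17g\t%.17g", peaks$mz, peaks$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA with key=value description tags
#'
#' Minimal FASTA dialect used across the pipeline: the header line is
#' `>id key=value ...`; recognized tags are `topology=` (`cyclic` or
#' `linear`) and `enzyme=`. Duplicate ids are an error.
#'
#' @param path File path.
#' @return A data frame with columns `id`, `sequence`, `topology`,
#'   `enzyme` (tag columns `NA` when absent).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(starts), function(k) {
    header <- sub("^>", "", lines[starts[k]])
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1]
    tags <- fields[-1][grepl("=", fields[-1])]
    tagval <- function(key) {
      hit <- grep(paste0("^", key, "="), tags, value = TRUE)
      if (length(hit) == 0L) NA_character_ else sub("^[^=]+=", "", hit[1])
    }
    body <- if (ends[k] > starts[k])
      paste(lines[(starts[k] + 1L):ends[k]], collapse = "") else ""
    data.frame(id = id, sequence = gsub("\\s", "", body),
               topology = tagval("topology"), enzyme = tagval("enzyme"))
  })
  out <- do.call(rbind, recs)
  if (anyDuplicated(out$id)) {
    stop("duplicate FASTA ids in ", path, call. = FALSE)
  }
  out
}

#' @rdname read_fasta
#' @param records Data frame with columns `id`, `sequence` and optional
#'   `topology`, `enzyme`.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    tags <- character()
    for (key in c("topology", "enzyme")) {
      if (key %in% names(records) && !is.na(records[[key]][i])) {
        tags <- c(tags, paste0(key, "=", records[[key]][i]))
      }
    }
    writeLines(paste(c(paste0(">", records$id[i]), tags), collapse = " "),
               con)
    s <- records$sequence[i]
    for (j in seq(1L, nchar(s), by = width)) {
      writeLines(substr(s, j, min(j + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA into an [aligned_set()]
#'
#' @param path File path.
#' @return An [aligned_set()]; ragged alignments are an error.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path)
  aligned_set(stats::setNames(recs$sequence, recs$id))
}
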