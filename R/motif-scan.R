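#' Specify a binding-site consensus motif
#'
#' Two kinds are supported: a fixed IUPAC consensus string (e.g. the
#' CA-rich octamer `CAUCAUCA`) and a triplet repeat given as a unit plus a
#' repeat count (e.g. `CNN` repeated 6 times). The alphabet is RNA with `N`
#' as a wildcard; `U` and `T` are interchangeable on input.
#'
#' @param motif_id Character identifier.
#' @param kind `"FIXED_IUPAC"` or `"TRIPLET_REPEAT"`.
#' @param pattern The consensus string, or the repeat unit for
#'   `TRIPLET_REPEAT`.
#' @param repeat_count Repeat count for `TRIPLET_REPEAT` (>= 1).
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(motif_id, kind = c("FIXED_IUPAC", "TRIPLET_REPEAT"),
                       pattern, repeat_count = 6L) {
  kind <- match.arg(kind)
  stopifnot(is.character(motif_id), length(motif_id) == 1L)
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop("`pattern` must be a non-empty string", call. = FALSE)
  }
  check_nucleotides(pattern, what = "motif pattern")
  if (kind == "TRIPLET_REPEAT") {
    if (!is_scalar_number(repeat_count) || repeat_count < 1) {
      stop("`repeat_count` must be at least 1", call. = FALSE)
    }
  }
  structure(
    list(motif_id = motif_id, kind = kind, pattern = toupper(pattern),
         repeat_count = as.integer(repeat_count)),
    class = "motif_spec"
  )
}

check_nucleotides <- function(x, what = "sequence") {
  if (grepl("[^ACGTUNacgtun]", x)) {
    stop("invalid characters in ", what,
         " (allowed: A, C, G, T, U, N)", call. = FALSE)
  }
  invisible(x)
}

# Expand a motif_spec to the DNA-alphabet search pattern.
motif_pattern <- function(motif) {
  stopifnot(inherits(motif, "motif_spec"))
  pat <- if (motif$kind == "TRIPLET_REPEAT") {
    strrep(motif$pattern, motif$repeat_count)
  } else {
    motif$pattern
  }
  chartr("U", "T", pat)
}

#' Scan a transcript sequence for a consensus motif
#'
#' Reports all positions where the motif matches, with `N` matching any base
#' and `U` equivalent to `T` (mRNA sense strand only; the reverse strand is
#' not scanned). Coordinates are 1-based inclusive. With
#' `overlap_allowed = FALSE`, overlapping matches are resolved greedily left
#' to right.
#'
#' @param sequence Nucleotide string over A/C/G/T/U/N (case-insensitive).
#' @param motif A [motif_spec()].
#' @param overlap_allowed Report overlapping hits (default `TRUE`).
#' @param transcript Transcript id recorded in the hits.
#' @return Data frame of hits: `transcript`, `start`, `end` (1-based,
#'   inclusive), `matched` (the subsequence as supplied), `motif_id`.
#' @export
scan_motif <- function(sequence, motif, overlap_allowed = TRUE,
                       transcript = "seq") {
  stopifnot(inherits(motif, "motif_spec"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("`sequence` must be a non-empty string", call. = FALSE)
  }
  check_nucleotides(sequence)
  seq_up <- toupper(sequence)
  dna <- chartr("U", "T", seq_up)
  pat <- motif_pattern(motif)
  empty <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      motif_id = character(0))
  if (nchar(pat) > nchar(dna)) return(empty)
  hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(dna),
                                   fixed = FALSE)
  starts <- BiocGenerics::start(hits)
  ends <- BiocGenerics::end(hits)
  if (length(starts) == 0L) return(empty)
  if (!overlap_allowed) {
    keep <- logical(length(starts))
    last_end <- 0L
    for (i in seq_along(starts)) {
      if (starts[i] > last_end) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    starts <- starts[keep]
    ends <- ends[keep]
  }
  data.frame(
    transcript = transcript, start = starts, end = ends,
    matched = substring(seq_up, starts, ends), motif_id = motif$motif_id
  )
}

#' Scan every sequence of a FASTA file for a set of motifs
#'
#' @param path Path to a (DNA or RNA) FASTA file.
#' @param motifs A [motif_spec()] or list of them.
#' @param overlap_allowed Passed to [scan_motif()].
#' @return Data frame of hits across all sequences and motifs.
#' @export
scan_fasta <- function(path, motifs, overlap_allowed = TRUE) {
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  seqs <- Biostrings::readBStringSet(path)
  hits <- list()
  for (i in seq_along(seqs)) {
    id <- sub("\\s.*", "", names(seqs)[i])
    s <- as.character(seqs[[i]])
    for (m in motifs) {
      hits[[length(hits) + 1L]] <-
        scan_motif(s, m, overlap_allowed = overlap_allowed, transcript = id)
    }
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Convert motif hits to BED-like 0-based half-open coordinates
#'
#' @param hits Output of [scan_motif()] / [scan_fasta()].
#' @return Data frame with BED columns (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`); starts are 0-based, ends exclusive.
#' @export
motif_hits_to_bed <- function(hits) {
  data.frame(
    chrom = hits$transcript, start = hits$start - 1L, end = hits$end,
    name = hits$motif_id, score = ".", strand = "+"
  )
}

#' Read motif specifications from a YAML file
#'
#' Each entry needs `motif_id`, `kind`, `pattern` and, for triplet repeats,
#' `repeat_count`.
#'
#' @param path Path to the YAML file.
#' @return List of [motif_spec()]s.
#' @export
read_motifs <- function(path) {
  lapply(yaml::read_yaml(path), function(m) {
    motif_spec(m$motif_id, m$kind, m$pattern,
               repeat_count = m$repeat_count %||% 6L)
  })
}
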