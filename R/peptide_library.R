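# Standard IUPAC amino-acid residue masses (Da); peptide mass = sum of
# residue masses + one water.
RESIDUE_MASS_MONO <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047678, V = 99.068414, W = 186.079313, Y = 163.063329)

RESIDUE_MASS_AVG <- c(
  A = 71.078020, C = 103.142807, D = 115.087565, E = 129.114183,
  F = 147.174198, G = 57.051402, H = 137.139515, I = 113.157872,
  K = 128.172516, L = 113.157872, M = 131.196042, N = 114.102804,
  P = 97.115373, Q = 128.129422, R = 156.185922, S = 87.077425,
  T = 101.104042, V = 99.131254, W = 186.210314, Y = 163.173603)

WATER_MONO <- 18.0105646837
WATER_AVG <- 18.0152864349

#' Peptide mass on the monoisotopic and average scales
#'
#' Sum of standard IUPAC residue masses plus one water; no modifications.
#'
#' @param sequence Peptide sequence(s), canonical 20-letter alphabet.
#' @return A data.frame with columns `sequence`, `monoisotopic`, `average`
#'   (Da).
#' @examples
#' peptide_mass("NPATY")
#' @export
peptide_mass <- function(sequence) {
  sequence <- toupper(sequence)
  mono <- vapply(sequence, function(s) {
    ch <- .check_sequence(s, s)
    sum(RESIDUE_MASS_MONO[ch]) + WATER_MONO
  }, numeric(1))
  avg <- vapply(sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(RESIDUE_MASS_AVG[ch]) + WATER_AVG
  }, numeric(1))
  data.frame(sequence = sequence, monoisotopic = unname(mono),
             average = unname(avg), stringsAsFactors = FALSE)
}

#' Build the deduplicated oligopeptide library from digestion fragments
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (inclusive),
#' deduplicates by sequence while preserving occurrence counts and parent
#' provenance, and annotates masses. The default 2-6-residue window selects
#' the oligopeptides with absorbable molecular weight.
#'
#' @param fragments A fragment data.frame from [digest()]/[digest_proteome()]
#'   (a `"digestion"` object is also accepted), or a character vector of
#'   peptide sequences.
#' @param min_len,max_len Inclusive residue-length bounds.
#' @return A data.frame of class `"oligopeptide_library"` with columns
#'   `sequence`, `length`, `monoisotopic`, `average`, `occurrence`,
#'   `parents`.
#' @export
build_library <- function(fragments, min_len = 2L, max_len = 6L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  if (inherits(fragments, "digestion")) fragments <- fragments$fragments
  if (is.character(fragments))
    fragments <- data.frame(sequence = fragments, parent_id = NA_character_,
                            stringsAsFactors = FALSE)
  keep <- nchar(fragments$sequence) >= min_len &
    nchar(fragments$sequence) <= max_len
  kept <- fragments[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    out <- data.frame(sequence = character(0), length = integer(0),
                      monoisotopic = numeric(0), average = numeric(0),
                      occurrence = integer(0), parents = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("oligopeptide_library", "data.frame")
    return(out)
  }
  uniq <- .unique_view(data.frame(sequence = kept$sequence,
                                  parent_id = as.character(kept$parent_id),
                                  stringsAsFactors = FALSE))
  m <- peptide_mass(uniq$sequence)
  out <- data.frame(sequence = uniq$sequence,
                    length = nchar(uniq$sequence),
                    monoisotopic = m$monoisotopic, average = m$average,
                    occurrence = uniq$occurrence, parents = uniq$parents,
                    stringsAsFactors = FALSE)
  class(out) <- c("oligopeptide_library", "data.frame")
  out
}

#' Length distribution of a fragment set or library
#'
#' Counts sequences per length class; lengths above `max_len` are pooled
#' into a single `">max"` class, mirroring how digestion products are
#' summarised before the oligopeptide window is applied.
#'
#' @param x Fragment data.frame, `"digestion"` object, library, or character
#'   vector of sequences.
#' @param min_len,max_len Window whose occupancy fraction is reported.
#' @return A list with `counts` (named integer vector over length classes),
#'   `n`, and `fraction_in_window`.
#' @export
length_distribution <- function(x, min_len = 2L, max_len = 6L) {
  if (inherits(x, "digestion")) x <- x$fragments
  seqs <- if (is.character(x)) x else x$sequence
  if (length(seqs) == 0L) stop("no sequences to tabulate")
  len <- nchar(seqs)
  cls <- ifelse(len > max_len, paste0(">", max_len), as.character(len))
  lv <- c(as.character(seq_len(max_len)), paste0(">", max_len))
  counts <- table(factor(cls, levels = lv))
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, n = length(seqs),
       fraction_in_window = sum(len >= min_len & len <= max_len) / length(seqs))
}

#' The packaged bioactive-peptide reference table
#'
#' Known bioactive oligopeptides (ACE inhibition, antioxidation, glucose
#' uptake stimulation) shipped as a versioned CSV; a sequence may carry more
#' than one bioactivity label.
#'
#' @param path Optional path to an alternative reference CSV with columns
#'   `sequence`, `bioactivity`, `source`.
#' @return A data.frame with columns `sequence`, `bioactivity`, `source`.
#' @export
bioactive_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bioactive_reference.csv",
                        package = "pepscreen")
  ref <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  ref$sequence <- toupper(ref$sequence)
  ref
}

#' Match an oligopeptide library against a bioactive-peptide reference
#'
#' Exact full-sequence matching, case-insensitive on input; every
#' bioactivity label carried by a matching reference sequence is reported.
#'
#' @param library An `"oligopeptide_library"` data.frame or character vector
#'   of sequences.
#' @param reference Reference table as from [bioactive_reference()] (the
#'   packaged table by default).
#' @return A data.frame with one row per (sequence, bioactivity) pair:
#'   columns `sequence`, `bioactivity`, `source`.
#' @export
match_bioactive <- function(library, reference = bioactive_reference()) {
  seqs <- toupper(if (is.character(library)) library else library$sequence)
  if (nrow(reference) == 0L) {
    warning("empty bioactive reference; no matches possible")
    return(reference)
  }
  hits <- reference[reference$sequence %in% seqs, , drop = FALSE]
  hits <- hits[order(hits$sequence, hits$bioactivity), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
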