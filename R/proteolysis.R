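# Canonical amino-acid alphabet used throughout the package.
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.rule_cache <- new.env(parent = emptyenv())

#' Cleavage-rule tables for the supported digestive enzymes
#'
#' Loads the versioned PeptideCutter-style rule tables shipped with the
#' package (`inst/extdata/cleavage_rules.json`). Rules are pure functions of
#' local sequence context: an enzyme either cleaves the bond between P1 and
#' P1' or it does not, depending only on the residues at P4..P2'.
#'
#' @param path Optional path to an alternative rule-table JSON, for swapping
#'   in a different cleavage dialect.
#' @return A named list of enzyme rule definitions. Supported names:
#'   `"pepsin_pH1.3"`, `"pepsin_pH>2"`, `"trypsin"`, `"chymotrypsin_high"`,
#'   `"chymotrypsin_low"`.
#' @export
enzyme_rules <- function(path = NULL) {
  if (is.null(path)) {
    key <- "default"
    if (!is.null(.rule_cache[[key]])) return(.rule_cache[[key]])
    path <- system.file("extdata", "cleavage_rules.json", package = "pepscreen")
    tab <- jsonlite::fromJSON(path, simplifyVector = TRUE)$enzymes
    .rule_cache[[key]] <- tab
    return(tab)
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)$enzymes
}

#' The default simulated gastrointestinal enzyme set
#'
#' Pepsin at pH 1.3, trypsin, and high-specificity chymotrypsin: the three
#' typical enzymes of a simulated gastric + intestinal digestion.
#'
#' @return Character vector of enzyme names.
#' @export
gastrointestinal_enzymes <- function() {
  c("pepsin_pH1.3", "trypsin", "chymotrypsin_high")
}

.check_sequence <- function(sequence, id = "<sequence>", permissive = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence for '", id, "' must be a single non-empty string")
  ch <- strsplit(sequence, "")[[1]]
  alphabet <- if (permissive) c(AA_CANONICAL, "B", "Z", "X", "U") else AA_CANONICAL
  bad <- which(!(ch %in% alphabet))
  if (length(bad))
    stop("non-canonical residue '", ch[bad[1]], "' at position ", bad[1],
         " in '", id, "'")
  invisible(ch)
}

# Evaluate one enzyme's rule at every internal bond of `ch` (character
# vector).  Bond k separates residues k and k+1 (1-based), i.e. the 0-based
# inter-residue position k of the spec.  Returns an integer vector of sites.
.apply_rule <- function(ch, rule) {
  n <- length(ch)
  if (n < 2L) return(integer(0))
  k <- seq_len(n - 1L)
  p1 <- ch[k]
  p1p <- ch[k + 1L]
  if (identical(rule$type, "p1")) {
    blocked <- rule$blocked
    in_p1 <- p1 %in% names(blocked)
    ok <- in_p1
    if (any(in_p1)) {
      blk <- vapply(which(in_p1), function(i) {
        grepl(p1p[i], blocked[[p1[i]]], fixed = TRUE)
      }, logical(1))
      ok[in_p1] <- !blk
    }
    trip <- paste0(ifelse(k >= 2L, ch[pmax(k - 1L, 1L)], ""), p1, p1p)
    if (length(rule$cleave_triplets))
      ok <- ok | (in_p1 & trip %in% rule$cleave_triplets & k >= 2L)
    if (length(rule$block_triplets))
      ok <- ok & !(trip %in% rule$block_triplets & k >= 2L)
    return(k[ok])
  }
  if (identical(rule$type, "pepsin")) {
    set <- strsplit(rule$set, "")[[1]]
    # clause context: P3 = ch[k-2], P2 = ch[k-1], P2' = ch[k+2]; each must
    # exist for the clause naming it to apply.
    has_ctx <- k >= 3L & k <= n - 2L
    p3 <- ifelse(k >= 3L, ch[pmax(k - 2L, 1L)], NA)
    p2 <- ifelse(k >= 2L, ch[pmax(k - 1L, 1L)], NA)
    p2p <- ifelse(k <= n - 2L, ch[pmin(k + 2L, n)], NA)
    ctx_ok <- has_ctx & !(p3 %in% c("H", "K", "R")) & p2 != "P" & p2p != "P"
    ctx_ok[is.na(ctx_ok)] <- FALSE
    clause_a <- ctx_ok & p1 != "R" & p1p %in% set
    clause_b <- ctx_ok & p1 %in% set
    return(k[clause_a | clause_b])
  }
  stop("unknown rule type: ", rule$type)
}

#' Predict cleavage sites of one enzyme on one protein
#'
#' Applies the enzyme's positional rule table at every internal peptide bond
#' and returns the cleavable inter-residue positions. Positions are 0-based:
#' site `k` is the bond between residues `k-1` and `k` (0-based), so valid
#' sites lie strictly between 0 and the sequence length.
#'
#' @param protein A list or one-row data.frame with fields `id` and
#'   `sequence`, or a plain sequence string.
#' @param enzyme Enzyme name; see [enzyme_rules()].
#' @param permissive If `TRUE`, ambiguity codes (B, Z, X, U) are accepted and
#'   treated as never-cleavable context; by default they are rejected.
#' @return A data.frame with columns `position` (sorted, strictly increasing)
#'   and `enzyme`, carrying the protein id as attribute `protein_id`.
#' @examples
#' cleavage_sites("AKRPGKA", "trypsin")$position  # 2 and 6
#' @export
cleavage_sites <- function(protein, enzyme, permissive = FALSE) {
  rec <- .as_protein(protein)
  rules <- enzyme_rules()
  if (!enzyme %in% names(rules))
    stop("unsupported enzyme '", enzyme, "'; supported: ",
         paste(names(rules), collapse = ", "))
  ch <- .check_sequence(rec$sequence, rec$id, permissive = permissive)
  # ambiguity codes never satisfy a cleavage condition but are legal context
  sites <- .apply_rule(ch, rules[[enzyme]])
  out <- data.frame(position = sites,
                    enzyme = rep(enzyme, length(sites)),
                    stringsAsFactors = FALSE)
  attr(out, "protein_id") <- rec$id
  out
}

.as_protein <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) {
    nm <- names(protein)
    return(list(id = if (is.null(nm)) "protein" else nm,
                sequence = toupper(protein)))
  }
  if (is.data.frame(protein)) protein <- as.list(protein[1, , drop = FALSE])
  if (is.null(protein$id) || is.null(protein$sequence))
    stop("protein must have 'id' and 'sequence' fields")
  list(id = as.character(protein$id),
       sequence = toupper(as.character(protein$sequence)))
}

#' Digest one protein with one or more enzymes acting concurrently
#'
#' One-pot semantics: the cleavage-site sets of all enzymes are unioned and
#' the protein is cut at every site, yielding maximal fragments between
#' consecutive sites. The fragments tile the parent exactly — no gaps, no
#' overlaps — so their concatenation reconstructs the sequence. A sequential
#' mode digests with each enzyme in turn, re-digesting every fragment of the
#' previous stage (site sets are identical for context-local rules except
#' where cutting removes flanking context).
#'
#' @param protein As in [cleavage_sites()].
#' @param enzymes Character vector of enzyme names (at least one).
#' @param mode `"concurrent"` (default) or `"sequential"`.
#' @param permissive Passed to [cleavage_sites()].
#' @return A data.frame of fragments with columns `parent_id`, `start`,
#'   `end` (0-based half-open), `sequence`, `enzymes`.
#' @examples
#' digest("AKRPGKA", "trypsin")$sequence  # "AK" "RPGK" "A"
#' @export
digest <- function(protein, enzymes = gastrointestinal_enzymes(),
                   mode = c("concurrent", "sequential"), permissive = FALSE) {
  mode <- match.arg(mode)
  if (length(enzymes) < 1L) stop("at least one enzyme is required")
  rec <- .as_protein(protein)
  if (mode == "concurrent") {
    sites <- sort(unique(unlist(lapply(enzymes, function(e)
      cleavage_sites(rec, e, permissive = permissive)$position))))
    return(.fragments_from_sites(rec, sites, enzymes))
  }
  frags <- .fragments_from_sites(rec, integer(0), enzymes)
  for (e in enzymes) {
    frags <- do.call(rbind, lapply(seq_len(nrow(frags)), function(i) {
      sub <- list(id = rec$id, sequence = frags$sequence[i])
      s <- cleavage_sites(sub, e, permissive = permissive)$position
      out <- .fragments_from_sites(sub, s, enzymes)
      out$start <- out$start + frags$start[i]
      out$end <- out$end + frags$start[i]
      out
    }))
  }
  rownames(frags) <- NULL
  frags
}

.fragments_from_sites <- function(rec, sites, enzymes) {
  n <- nchar(rec$sequence)
  bounds <- c(0L, as.integer(sites), n)
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  data.frame(parent_id = rec$id,
             start = start, end = end,
             sequence = substring(rec$sequence, start + 1L, end),
             enzymes = paste(enzymes, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Digest a set of proteins and collect per-parent provenance
#'
#' Runs [digest()] over each record and reports both the total number of
#' fragment occurrences and the distinct-sequence view (occurrence counts
#' with parent lists), since "peptides obtained" can be counted either way.
#'
#' @param proteins A data.frame with columns `id` and `sequence` (e.g. from
#'   [read_fasta()]), or a named character vector of sequences.
#' @param enzymes,mode,permissive Passed to [digest()].
#' @return A list of class `"digestion"` with elements `fragments` (all
#'   occurrences), `unique` (distinct sequences with `occurrence` and
#'   `parents`), `n_fragments`, `n_unique`.
#' @export
digest_proteome <- function(proteins, enzymes = gastrointestinal_enzymes(),
                            mode = "concurrent", permissive = FALSE) {
  proteins <- .as_protein_set(proteins)
  if (anyDuplicated(proteins$id))
    stop("duplicate protein ids: ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  frags <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins[i, ], enzymes, mode = mode, permissive = permissive)))
  rownames(frags) <- NULL
  uniq <- .unique_view(frags)
  structure(list(fragments = frags, unique = uniq,
                 n_fragments = nrow(frags), n_unique = nrow(uniq),
                 enzymes = enzymes, mode = mode),
            class = "digestion")
}

.unique_view <- function(frags) {
  sp <- split(frags$parent_id, frags$sequence)
  uniq <- data.frame(sequence = names(sp),
                     occurrence = vapply(sp, length, integer(1)),
                     parents = vapply(sp, function(p)
                       paste(sort(unique(p)), collapse = ";"), character(1)),
                     stringsAsFactors = FALSE)
  uniq <- uniq[order(-uniq$occurrence, uniq$sequence), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

.as_protein_set <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
    proteins <- data.frame(id = ids, sequence = unname(toupper(proteins)),
                           stringsAsFactors = FALSE)
  }
  if (!is.data.frame(proteins) || !all(c("id", "sequence") %in% names(proteins)))
    stop("proteins must be a data.frame with 'id' and 'sequence' columns")
  if (nrow(proteins) < 1L) stop("at least one protein is required")
  proteins$sequence <- toupper(proteins$sequence)
  proteins
}

#' @export
print.digestion <- function(x, ...) {
  cat("Digestion (", x$mode, "): ", paste(x$enzymes, collapse = " + "), "\n",
      "  fragment occurrences: ", x$n_fragments, "\n",
      "  distinct sequences:   ", x$n_unique, "\n", sep = "")
  invisible(x)
}
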