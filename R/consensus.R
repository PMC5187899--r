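#' Docking score threshold from the initial ligand's score
#'
#' The screening threshold for a receptor is a fixed fraction (default 50%)
#' of the docking score obtained by the receptor's own co-crystallised
#' initial ligand. Scores are dimensionless, higher = better.
#'
#' @param initial_ligand_score Score of the initial ligand (> 0).
#' @param fraction Fraction in (0, 1].
#' @return The threshold (numeric scalar).
#' @examples
#' score_threshold(106.292)  # 53.146
#' @export
score_threshold <- function(initial_ligand_score, fraction = 0.5) {
  if (!is.numeric(initial_ligand_score) || initial_ligand_score <= 0)
    stop("initial_ligand_score must be > 0")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  fraction * initial_ligand_score
}

#' Per-receptor score filtering and multi-receptor intersection
#'
#' A ligand passes a receptor iff at least one of its poses scores at or
#' above that receptor's threshold (best-pose rule); the final candidate set
#' is the intersection of the per-receptor passing sets. A ligand absent
#' from a receptor's pose table fails that receptor.
#'
#' @param poses data.frame with columns `ligand`, `receptor`, `pose`,
#'   `score`.
#' @param thresholds Named numeric vector: threshold per receptor id; must
#'   cover every receptor present in `poses`.
#' @return A list of class `"screening_decisions"`: `decisions` (data.frame
#'   `ligand`, one logical column per receptor, `final_pass`), `passing`
#'   (named list of per-receptor passing ligand sets), `final` (character
#'   vector), `thresholds`.
#' @export
filter_and_intersect <- function(poses, thresholds) {
  receptors <- sort(unique(poses$receptor))
  if (!all(receptors %in% names(thresholds)))
    stop("thresholds missing for receptor(s): ",
         paste(setdiff(receptors, names(thresholds)), collapse = ", "))
  ligands <- sort(unique(poses$ligand))
  passmat <- sapply(receptors, function(r) {
    sub <- poses[poses$receptor == r, ]
    best <- tapply(sub$score, sub$ligand, max)
    vapply(ligands, function(lg) {
      !is.na(best[lg]) && best[lg] >= thresholds[[r]]
    }, logical(1))
  })
  passmat <- matrix(passmat, nrow = length(ligands),
                    dimnames = list(ligands, receptors))
  final <- rowSums(passmat) == length(receptors)
  decisions <- data.frame(ligand = ligands, passmat,
                          final_pass = unname(final),
                          stringsAsFactors = FALSE, check.names = FALSE)
  rownames(decisions) <- NULL
  structure(list(decisions = decisions,
                 passing = lapply(receptors, function(r)
                   ligands[passmat[, r]]) |> setNames(receptors),
                 final = ligands[final], thresholds = thresholds),
            class = "screening_decisions")
}

#' @export
print.screening_decisions <- function(x, ...) {
  sizes <- vapply(x$passing, length, integer(1))
  cat("Per-receptor passing sets:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  cat("Final (intersection):", length(x$final), "ligands\n")
  invisible(x)
}

#' Residue contact frequency across pose fingerprints
#'
#' Counts, per residue and interaction type, the number of poses exhibiting
#' the contact (a residue counts once per pose per type) and ranks residues
#' by count. At the `k`-th rank ties are included, so the top list may
#' exceed `k`; the expansion is flagged.
#'
#' @param fingerprints data.frame with at least columns `pose`, `type`,
#'   `residue` — the concatenated fingerprints of one receptor's poses (a
#'   `ligand` column, if present, is combined with `pose` to identify
#'   poses).
#' @param k Number of top residues to report (>= 1).
#' @param by_type Count per (residue, type) when `TRUE`; per residue
#'   (any type) otherwise. Default counts per type, matching per-class
#'   frequency tables.
#' @return A list of class `"residue_frequency"`: `table` (data.frame
#'   `residue`, `type`, `count`, `rank` — dense ranks), `top` (character
#'   vector of residues in the top `k` ranks by total count), `tie_expanded`.
#' @export
residue_frequency <- function(fingerprints, k = 4L, by_type = TRUE) {
  if (k < 1L) stop("k must be >= 1")
  if (nrow(fingerprints) == 0L) stop("no fingerprint records")
  pose_id <- if ("ligand" %in% names(fingerprints))
    paste(fingerprints$ligand, fingerprints$pose) else fingerprints$pose
  df <- unique(data.frame(pose = pose_id, type = fingerprints$type,
                          residue = fingerprints$residue,
                          stringsAsFactors = FALSE))
  tab_t <- aggregate(pose ~ residue + type, df, length)
  names(tab_t)[3] <- "count"
  tab_t <- tab_t[order(-tab_t$count, tab_t$residue), ]
  tab_t$rank <- match(-tab_t$count, sort(unique(-tab_t$count)))
  rownames(tab_t) <- NULL
  # residue-level totals (any type) for the top-k list
  per_res <- unique(df[, c("pose", "residue")])
  tot <- sort(table(per_res$residue), decreasing = TRUE)
  counts <- as.integer(tot)
  ranks <- match(-counts, sort(unique(-counts)))
  keep <- ranks <= k
  top <- names(tot)[keep]
  tie_expanded <- length(top) > k
  if (tie_expanded)
    message("tie at rank ", k, ": reporting ", length(top), " residues")
  structure(list(table = tab_t, top = top, tie_expanded = tie_expanded,
                 k = k, n_poses = length(unique(df$pose))),
            class = "residue_frequency")
}

#' @export
print.residue_frequency <- function(x, ...) {
  cat("Residue contact frequency over", x$n_poses, "poses; top",
      x$k, if (x$tie_expanded) "(tie-expanded)" else "", ":",
      paste(x$top, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise overlap of interaction residues between receptors
#'
#' For every receptor pair and interaction class (hydrogen bond,
#' electrostatic, hydrophobic by default) the shared residues are the
#' intersection of the per-receptor residue sets of that class.
#'
#' @param tables Named list (one element per receptor) of fingerprint
#'   data.frames (columns `type`, `residue`) or `"residue_frequency"`
#'   tables.
#' @param classes Interaction types to compare.
#' @return data.frame with columns `receptor_a`, `receptor_b`, `class`,
#'   `shared` (semicolon-joined residues, `"none"` when empty).
#' @export
pairwise_overlap <- function(tables,
                             classes = c("HBOND", "ELECTROSTATIC",
                                         "HYDROPHOBIC")) {
  sets <- lapply(tables, function(t) {
    if (inherits(t, "residue_frequency")) t <- t$table
    lapply(setNames(classes, classes), function(cl)
      sort(unique(t$residue[t$type == cl])))
  })
  recs <- names(sets)
  rows <- list()
  if (length(recs) >= 2L)
    for (i in seq_len(length(recs) - 1L)) for (j in (i + 1L):length(recs))
      for (cl in classes) {
        shared <- intersect(sets[[i]][[cl]], sets[[j]][[cl]])
        rows[[length(rows) + 1L]] <- data.frame(
          receptor_a = recs[i], receptor_b = recs[j], class = cl,
          shared = if (length(shared)) paste(shared, collapse = ";") else "none",
          stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

#' Classify final-pass ligands by their key-residue interactions
#'
#' Labels each ligand by which of the two consensus key interactions any of
#' its retained poses shows — by default a hydrogen bond to ALA354 and a
#' hydrophobic contact with VAL518, the two high-frequency interactions of
#' ACE inhibitors. Classes: `both_key_residues`, `only_<res>_<type>` for
#' each single residue, `neither`.
#'
#' @param ligands Character vector of final-pass ligand ids.
#' @param fingerprints data.frame with columns `ligand`, `type`, `residue`
#'   (all retained poses of all ligands).
#' @param key_residues Named character vector: residue -> required
#'   interaction type.
#' @return data.frame `ligand`, one logical column per key residue,
#'   `class`; plus attribute `representatives`: one ligand per class (first
#'   by library order).
#' @export
select_candidates <- function(ligands, fingerprints,
                              key_residues = c(ALA354 = "HBOND",
                                               VAL518 = "HYDROPHOBIC")) {
  if (is.null(names(key_residues)) || any(names(key_residues) == ""))
    stop("key_residues must be a named vector: residue -> interaction type")
  if (!all(key_residues %in% c("HBOND", "HYDROPHOBIC", "ELECTROSTATIC",
                               "METAL")))
    stop("unknown interaction type in key_residues")
  flags <- sapply(names(key_residues), function(res)
    vapply(ligands, function(lg) any(
      fingerprints$ligand == lg & fingerprints$residue == res &
        fingerprints$type == key_residues[[res]]), logical(1)))
  flags <- matrix(flags, nrow = length(ligands),
                  dimnames = list(ligands, names(key_residues)))
  cls <- apply(flags, 1, function(f) {
    if (all(f)) "both_key_residues"
    else if (!any(f)) "neither"
    else paste0("only_", names(f)[f], "_", tolower(key_residues[[names(f)[f]]]))
  })
  out <- data.frame(ligand = ligands, flags, class = unname(cls),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  reps <- out[!duplicated(out$class), c("ligand", "class")]
  attr(out, "representatives") <- reps
  out
}
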