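#' Read protein sequences from a multi-record FASTA file
#'
#' Header token before the first whitespace becomes the record id; sequences
#' are uppercased and validated against the canonical 20-letter alphabet
#' (ambiguity codes allowed only in permissive mode).
#'
#' @param path FASTA file path.
#' @param permissive Accept B/Z/X/U ambiguity codes.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, permissive = FALSE) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  for (i in seq_along(seqs)) .check_sequence(seqs[i], ids[i], permissive)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- .as_protein_set(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a receptor-ligand complex from a PDB file
#'
#' Polymer `ATOM` records become the receptor; `HETATM` records excluding
#' waters (HOH/WAT/DOD) and metal ions become the ligand; metal ions are
#' kept in a separate table, classed by element. A multi-`MODEL` file yields
#' one complex per model (poses share the topology).
#'
#' @param path PDB file path.
#' @param ligand_resname Optional residue name to restrict the ligand to.
#' @return A list of `"complex_structure"` objects, one per model; each has
#'   data.frames `receptor`, `ligand`, `metals` with columns `chain`,
#'   `resname`, `resno`, `atom`, `element`, `x`, `y`, `z`.
#' @export
read_complex_pdb <- function(path, ligand_resname = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el))
    element[missing_el] <- toupper(bio3d::atom2ele(at$elety[missing_el]))
  resname <- toupper(trimws(at$resid))
  is_water <- resname %in% c("HOH", "WAT", "DOD")
  is_metal <- at$type == "HETATM" & element %in% METAL_ELEMENTS &
    !is_water
  is_rec <- at$type == "ATOM"
  is_lig <- at$type == "HETATM" & !is_water & !is_metal
  if (!is.null(ligand_resname))
    is_lig <- is_lig & resname %in% toupper(ligand_resname)
  if (!any(is_lig)) stop("no ligand HETATM records in ", path,
                         " (waters and metals excluded)")
  nmodel <- nrow(pdb$xyz)
  lapply(seq_len(nmodel), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    tab <- function(sel) data.frame(
      chain = at$chain[sel], resname = resname[sel], resno = at$resno[sel],
      atom = trimws(at$elety[sel]), element = element[sel],
      x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
      stringsAsFactors = FALSE)
    structure(list(receptor = tab(is_rec), ligand = tab(is_lig),
                   metals = tab(is_metal)),
              class = "complex_structure")
  })
}

#' Write a receptor-ligand complex to a PDB file
#'
#' Inverse of [read_complex_pdb()] for package-built (synthetic) complexes:
#' receptor atoms as `ATOM`, ligand and metals as `HETATM`.
#'
#' @param complex A `"complex_structure"`.
#' @param path Output path.
#' @export
write_complex_pdb <- function(complex, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  fmt <- function(record, a) {
    serial <<- serial + 1L
    chain <- if (is.null(a$chain) || is.na(a$chain)) "A" else a$chain
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial,
            ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
            a$resname, chain, as.integer(a$resno),
            a$x, a$y, a$z, 1, 0, a$element)
  }
  wr <- function(df, record) {
    for (i in seq_len(NROW(df))) writeLines(fmt(record, df[i, ]), con)
  }
  wr(complex$receptor, "ATOM")
  writeLines("TER", con)
  wr(complex$ligand, "HETATM")
  if (!is.null(complex$metals)) wr(complex$metals, "HETATM")
  writeLines("END", con)
  invisible(path)
}
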