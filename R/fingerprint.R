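# residue-topology lookups for receptor atoms (standard PDB v3 atom names)

# side-chain / backbone donors (heavy atoms bearing amide/hydroxyl/amine H)
REC_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", TRP = "NE1",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))

# acceptors (lone-pair bearing O/N)
REC_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"))

# carbons bonded only to C/H in the ideal residue topology
REC_APOLAR <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  MET = "CB", PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"), GLU = c("CB", "CG"), ASP = "CB",
  GLN = c("CB", "CG"), ASN = "CB", HIS = "CB", THR = "CG2")

METAL_ELEMENTS <- c("ZN", "MG", "MN", "FE", "CU", "NI", "CO", "CA", "NA", "K")

#' Default interaction-detection parameters
#'
#' Cutoffs follow common structural-biology practice and are recorded in
#' every fingerprint: hydrogen bond donor-acceptor heavy-atom distance
#' 3.5 Angstrom with donor-H-acceptor angle >= 120 degrees (when the donor
#' has no explicit hydrogens the heavy-atom angle antecedent-donor-acceptor
#' >= 90 degrees is used instead); apolar carbon pair <= 4.5; opposite
#' formal-charge group centroids <= 5.5; ligand O/N/S to metal <= 3.0.
#' `his_charged` controls whether histidine side chains count as positive
#' ionizable groups (on by default: the ACE active-site histidines
#' participate in the electrostatic network around the zinc).
#'
#' @return Named list of parameters.
#' @export
default_interaction_params <- function() {
  list(hbond_dist = 3.5, hbond_angle = 120, hbond_angle_noH = 90,
       hydrophobic_dist = 4.5, electrostatic_dist = 5.5, metal_dist = 3.0,
       his_charged = TRUE)
}

#' Typed receptor-ligand interaction fingerprint of one pose
#'
#' Detects HBOND, HYDROPHOBIC, ELECTROSTATIC (salt-bridge) and METAL
#' (coordination) contacts between a receptor and a ligand pose, using the
#' geometric criteria of [default_interaction_params()]. Receptor chemistry
#' is assigned from standard residue/atom-name rules; ligand chemistry from
#' elements and covalent bonds inferred from interatomic distances. Records
#' are deduplicated by (type, residue, atom pair).
#'
#' @param complex A `"complex_structure"` (see [read_complex_pdb()]): list
#'   with data.frames `receptor`, `ligand`, `metals` (columns `resname`,
#'   `resno`, `atom`, `element`, `x`, `y`, `z`).
#' @param params Parameter list; defaults from
#'   [default_interaction_params()], individual entries may be overridden.
#' @return A data.frame of class `"pose_fingerprint"`: columns `type`,
#'   `residue`, `rec_atom`, `lig_atom`, `distance`, `angle` (NA except
#'   HBOND), with the parameters attached as attribute `params`.
#' @export
fingerprint_complex <- function(complex, params = default_interaction_params()) {
  params <- modifyList(default_interaction_params(), params)
  rec <- complex$receptor; lig <- complex$ligand
  metals <- complex$metals
  if (is.null(lig) || nrow(lig) == 0L) stop("complex has no ligand atoms")
  if (is.null(rec) || nrow(rec) == 0L) stop("complex has no receptor atoms")
  rec$element <- toupper(rec$element); lig$element <- toupper(lig$element)
  rxyz <- as.matrix(rec[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  resid_of <- paste0(rec$resname, rec$resno)

  lig_bonds <- .infer_bonds(lig)
  lig_nb <- .neighbors(lig_bonds, nrow(lig))
  lig_heavy <- lig$element != "H"
  lig_has_h <- vapply(seq_len(nrow(lig)), function(i)
    any(lig$element[lig_nb[[i]]] == "H"), logical(1))
  lig_don <- which(lig$element %in% c("N", "O") & lig_has_h)
  lig_acc <- which(lig$element == "O" |
                     (lig$element == "N" & lengths(lig_nb) <= 2L))
  lig_apolar <- which(lig$element == "C" & vapply(seq_len(nrow(lig)),
    function(i) !any(lig$element[lig_nb[[i]]] %in% c("N", "O", "S", "P")),
    logical(1)))

  rec_h <- which(rec$element == "H")
  rec_heavy <- which(rec$element != "H")
  rec_don <- which((rec$atom %in% REC_DONORS$backbone & rec$resname != "PRO" &
                      rec$element == "N") |
                     mapply(function(rn, at) at %in% (REC_DONORS[[rn]] %||% character(0)),
                            rec$resname, rec$atom))
  rec_acc <- which(rec$atom %in% REC_ACCEPTORS$backbone |
                     mapply(function(rn, at) at %in% (REC_ACCEPTORS[[rn]] %||% character(0)),
                            rec$resname, rec$atom))
  rec_apolar <- which(mapply(function(rn, at)
    at %in% (REC_APOLAR[[rn]] %||% character(0)), rec$resname, rec$atom))

  out <- list()
  emit <- function(type, residue, rec_atom, lig_atom, distance, angle = NA_real_)
    out[[length(out) + 1L]] <<- data.frame(
      type = type, residue = residue, rec_atom = rec_atom,
      lig_atom = lig_atom, distance = distance, angle = angle,
      stringsAsFactors = FALSE)

  hb_angle_ok <- function(don_xyz, acc_xyz, h_xyz_list, x_xyz_list) {
    if (length(h_xyz_list)) {
      ang <- vapply(h_xyz_list, function(h) .angle_deg(don_xyz, h, acc_xyz),
                    numeric(1))
      best <- max(ang)
      if (best >= params$hbond_angle) return(best) else return(NA_real_)
    }
    if (length(x_xyz_list)) {
      ang <- vapply(x_xyz_list, function(x) .angle_deg(x, don_xyz, acc_xyz),
                    numeric(1))
      best <- max(ang)
      if (best >= params$hbond_angle_noH) return(best) else return(NA_real_)
    }
    0  # lone atom donor: accept on distance, angle unknown
  }

  # hydrogens / heavy antecedents attached to a given atom
  att <- function(xyz, pool_xyz, pool_idx, rmax) {
    if (!length(pool_idx)) return(list())
    d <- sqrt(rowSums((pool_xyz[pool_idx, , drop = FALSE] -
                         matrix(xyz, length(pool_idx), 3, byrow = TRUE))^2))
    keep <- pool_idx[d > 0 & d < rmax]
    lapply(keep, function(i) pool_xyz[i, ])
  }

  # --- HBOND: receptor donor -> ligand acceptor, and ligand donor ->
  # receptor acceptor ---
  for (i in rec_don) for (j in lig_acc) {
    d <- sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))
    if (d <= params$hbond_dist && d > 0.5) {
      hs <- att(rxyz[i, ], rxyz, rec_h, 1.3)
      xs <- att(rxyz[i, ], rxyz, rec_heavy, 1.8)
      ang <- hb_angle_ok(rxyz[i, ], lxyz[j, ], hs, xs)
      if (!is.na(ang))
        emit("HBOND", resid_of[i], rec$atom[i], lig$atom[j], d, ang)
    }
  }
  lig_h <- which(lig$element == "H")
  for (j in lig_don) for (i in rec_acc) {
    d <- sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))
    if (d <= params$hbond_dist && d > 0.5) {
      hs <- att(lxyz[j, ], lxyz, lig_h, 1.3)
      xs <- att(lxyz[j, ], lxyz, which(lig_heavy), 1.8)
      ang <- hb_angle_ok(lxyz[j, ], rxyz[i, ], hs, xs)
      if (!is.na(ang))
        emit("HBOND", resid_of[i], rec$atom[i], lig$atom[j], d, ang)
    }
  }

  # --- HYDROPHOBIC: apolar carbon pairs ---
  for (i in rec_apolar) for (j in lig_apolar) {
    d <- sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))
    if (d <= params$hydrophobic_dist)
      emit("HYDROPHOBIC", resid_of[i], rec$atom[i], lig$atom[j], d)
  }

  # --- ELECTROSTATIC: opposite formal-charge group centroids ---
  rec_groups <- .receptor_charge_groups(rec, params$his_charged)
  lig_groups <- .ligand_charge_groups(lig, lig_nb)
  if (nrow(rec_groups) && nrow(lig_groups))
    for (i in seq_len(nrow(rec_groups))) for (j in seq_len(nrow(lig_groups))) {
      if (rec_groups$charge[i] * lig_groups$charge[j] >= 0) next
      d <- sqrt(sum((as.numeric(rec_groups[i, c("x", "y", "z")]) -
                       as.numeric(lig_groups[j, c("x", "y", "z")]))^2))
      if (d <= params$electrostatic_dist)
        emit("ELECTROSTATIC", rec_groups$residue[i], rec_groups$atoms[i],
             lig_groups$atoms[j], d)
    }

  # --- METAL: ligand O/N/S near a metal ion ---
  if (!is.null(metals) && nrow(metals)) {
    mxyz <- as.matrix(metals[, c("x", "y", "z")])
    coord_at <- which(lig$element %in% c("O", "N", "S"))
    for (m in seq_len(nrow(metals))) for (j in coord_at) {
      d <- sqrt(sum((mxyz[m, ] - lxyz[j, ])^2))
      if (d <= params$metal_dist)
        emit("METAL", toupper(metals$element[m]), metals$element[m],
             lig$atom[j], d)
    }
  }

  fp <- if (length(out)) do.call(rbind, out) else
    data.frame(type = character(0), residue = character(0),
               rec_atom = character(0), lig_atom = character(0),
               distance = numeric(0), angle = numeric(0))
  fp <- fp[!duplicated(fp[, c("type", "residue", "rec_atom", "lig_atom")]), ,
           drop = FALSE]
  rownames(fp) <- NULL
  attr(fp, "params") <- params
  class(fp) <- c("pose_fingerprint", "data.frame")
  fp
}

.receptor_charge_groups <- function(rec, his_charged) {
  rows <- list()
  push <- function(residue, atoms, xyz, charge)
    rows[[length(rows) + 1L]] <<- data.frame(
      residue = residue, atoms = atoms, x = xyz[1], y = xyz[2], z = xyz[3],
      charge = charge, stringsAsFactors = FALSE)
  for (key in unique(paste(rec$resname, rec$resno))) {
    sub <- rec[paste(rec$resname, rec$resno) == key, , drop = FALSE]
    rn <- sub$resname[1]; residue <- paste0(rn, sub$resno[1])
    grab <- function(at) sub[sub$atom %in% at, c("x", "y", "z"), drop = FALSE]
    if (rn %in% c("ASP", "GLU")) {
      at <- if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
      g <- grab(at)
      if (nrow(g) == 2L) push(residue, paste(at, collapse = ";"), colMeans(g), -1)
    } else if (rn == "LYS") {
      g <- grab("NZ")
      if (nrow(g) == 1L) push(residue, "NZ", as.numeric(g), +1)
    } else if (rn == "ARG") {
      g <- grab(c("CZ", "NH1", "NH2"))
      if (nrow(g) >= 2L) push(residue, "CZ;NH1;NH2", colMeans(g), +1)
    } else if (rn == "HIS" && his_charged) {
      g <- grab(c("ND1", "NE2"))
      if (nrow(g) == 2L) push(residue, "ND1;NE2", colMeans(g), +1)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(0), atoms = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0), charge = numeric(0))
}

.ligand_charge_groups <- function(lig, nb) {
  el <- lig$element
  rows <- list()
  push <- function(atoms_idx, charge) {
    xyz <- colMeans(lig[atoms_idx, c("x", "y", "z"), drop = FALSE])
    rows[[length(rows) + 1L]] <<- data.frame(
      residue = "LIG", atoms = paste(lig$atom[atoms_idx], collapse = ";"),
      x = xyz[1], y = xyz[2], z = xyz[3], charge = charge,
      stringsAsFactors = FALSE)
  }
  for (i in which(el %in% c("C", "P"))) {
    oxy <- nb[[i]][el[nb[[i]]] == "O"]
    terminal <- oxy[vapply(oxy, function(o)
      sum(el[nb[[o]]] != "H") == 1L, logical(1))]
    if (length(terminal) >= 2L) push(terminal, -1)
  }
  # amine nitrogens: <= 1 heavy neighbour (primary amine / N-terminus)
  for (i in which(el == "N")) {
    heavy_nb <- nb[[i]][el[nb[[i]]] != "H"]
    if (length(heavy_nb) <= 1L) push(i, +1)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(0), atoms = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0), charge = numeric(0))
}
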