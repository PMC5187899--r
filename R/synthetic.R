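# run expr with a local RNG seeded at `seed`, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Naive per-position cleavage-rule interpreter
#'
#' Reference implementation of the cleavage rules: walks every internal
#' peptide bond one at a time and evaluates the enzyme's positional
#' conditions literally on the local P3..P2' context. Independent of the
#' vectorised engine in [cleavage_sites()]; used to compute ground-truth
#' manifests and as the oracle in equivalence tests.
#'
#' @param sequence Protein sequence string.
#' @param enzyme Enzyme name (see [enzyme_rules()]).
#' @return Integer vector of 0-based cleavage positions.
#' @export
naive_cleavage_sites <- function(sequence, enzyme) {
  rule <- enzyme_rules()[[enzyme]]
  if (is.null(rule)) stop("unsupported enzyme: ", enzyme)
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  at <- function(i) if (i >= 1L && i <= n) ch[i] else NA_character_
  sites <- integer(0)
  for (k in seq_len(max(0L, n - 1L))) {
    p3 <- at(k - 2L); p2 <- at(k - 1L); p1 <- at(k)
    p1p <- at(k + 1L); p2p <- at(k + 2L)
    cut <- FALSE
    if (identical(rule$type, "p1")) {
      if (p1 %in% names(rule$blocked)) {
        blocked_set <- strsplit(rule$blocked[[p1]], "")[[1]]
        cut <- !(p1p %in% blocked_set)
        trip <- paste0(p2, p1, p1p)
        if (!is.na(p2)) {
          if (trip %in% rule$cleave_triplets) cut <- TRUE
          if (trip %in% rule$block_triplets) cut <- FALSE
        }
      }
    } else if (identical(rule$type, "pepsin")) {
      set <- strsplit(rule$set, "")[[1]]
      ctx <- !is.na(p3) && !is.na(p2) && !is.na(p2p) &&
        !(p3 %in% c("H", "K", "R")) && p2 != "P" && p2p != "P"
      a <- ctx && p1 != "R" && p1p %in% set
      b <- ctx && p1 %in% set
      cut <- a || b
    } else stop("unknown rule type")
    if (cut) sites <- c(sites, k)
  }
  sites
}

#' Generate a prolamin-like synthetic proteome with known cleavage truth
#'
#' Draws protein sequences from a glutamine/leucine/alanine/proline-rich
#' residue composition typical of seed-storage prolamins, planting
#' cleavage-prone residues (K, R, F, Y, W, L) at a controlled density. The
#' ground-truth manifest (per-enzyme cleavage sites and the fragment set of
#' the concurrent digestion) is computed with the naive per-position
#' interpreter, independently of the digestion engine.
#'
#' @param n_proteins Number of sequences (default 10, one small proteome of
#'   seed-storage monomers).
#' @param length_range Sequence length range (residues).
#' @param motif_density Per-position probability of planting a
#'   cleavage-prone residue (0 disables all cleavage sites).
#' @param enzymes Enzyme set used for the manifest.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A list: `proteins` (data.frame `id`, `sequence`), `manifest`
#'   (list with `sites` — data.frame `id`, `enzyme`, `position` — and
#'   `fragments` — the expected concurrent-digestion fragment table), and
#'   `config`.
#' @export
gen_proteome <- function(n_proteins = 10L, length_range = c(120L, 260L),
                         motif_density = 0.1,
                         enzymes = gastrointestinal_enzymes(), seed = 1L) {
  if (motif_density < 0 || motif_density > 1)
    stop("motif_density must be in [0, 1]")
  # prolamin-like background: Q/L/A/P-rich, cleavage-prone residues excluded
  bg <- c(Q = 0.28, A = 0.14, P = 0.10, S = 0.09, G = 0.08, V = 0.07,
          I = 0.06, T = 0.05, N = 0.05, E = 0.04, D = 0.03, M = 0.03,
          H = 0.02, C = 0.02)
  if (sum(bg) <= 0) stop("impossible composition: weights sum to 0")
  motif <- c(K = 0.2, R = 0.2, F = 0.2, Y = 0.15, W = 0.05, L = 0.2)
  .with_seed(seed, {
    proteins <- data.frame(
      id = sprintf("syncoixin%02d", seq_len(n_proteins)),
      sequence = vapply(seq_len(n_proteins), function(i) {
        len <- sample(length_range[1]:length_range[2], 1)
        plant <- runif(len) < motif_density
        ch <- ifelse(plant,
                     sample(names(motif), len, TRUE, motif),
                     sample(names(bg), len, TRUE, bg))
        paste(ch, collapse = "")
      }, character(1)), stringsAsFactors = FALSE)
    sites <- do.call(rbind, lapply(seq_len(n_proteins), function(i)
      do.call(rbind, lapply(enzymes, function(e) {
        s <- naive_cleavage_sites(proteins$sequence[i], e)
        if (!length(s)) return(NULL)
        data.frame(id = proteins$id[i], enzyme = e, position = s,
                   stringsAsFactors = FALSE)
      }))))
    fragments <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
      s <- sort(unique(unlist(lapply(enzymes, function(e)
        naive_cleavage_sites(proteins$sequence[i], e)))))
      .fragments_from_sites(list(id = proteins$id[i],
                                 sequence = proteins$sequence[i]), s, enzymes)
    }))
    rownames(fragments) <- NULL
    list(proteins = proteins,
         manifest = list(sites = sites, fragments = fragments),
         config = list(n_proteins = n_proteins, length_range = length_range,
                       motif_density = motif_density, enzymes = enzymes,
                       seed = seed))
  })
}

#' Generate a minimal synthetic complex with planted interactions
#'
#' Builds a tiny receptor fragment and ligand with each requested contact
#' placed at its exact geometry, stations 25 Angstrom apart so contacts do
#' not interfere. Available plants: a hydrogen bond (ligand carbonyl
#' acceptor vs receptor backbone amide N-H, exact donor-acceptor distance
#' and donor-H-acceptor angle), a hydrophobic contact (ligand methyl carbon
#' vs VAL CB), a salt bridge (ligand carboxylate vs LYS NZ) and a metal
#' coordination (ligand hydroxyl O vs Zn).
#'
#' @param hbond `list(distance=, angle=)` or `NULL`.
#' @param hydrophobic Distance (Angstrom) or `NULL`.
#' @param electrostatic Centroid distance or `NULL`.
#' @param metal Distance or `NULL`.
#' @return List with `complex` (a `"complex_structure"`) and `manifest`
#'   (data.frame of expected interaction records: `type`, `residue`,
#'   `distance`, `angle`).
#' @export
gen_complex <- function(hbond = list(distance = 2.9, angle = 160),
                        hydrophobic = NULL, electrostatic = NULL,
                        metal = NULL) {
  rec <- list(); lig <- list(); met <- list(); man <- list()
  station <- 0
  radd <- function(resname, resno, atom, element, xyz)
    rec[[length(rec) + 1L]] <<- data.frame(
      chain = "A", resname = resname, resno = resno, atom = atom,
      element = element, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  ladd <- function(atom, element, xyz)
    lig[[length(lig) + 1L]] <<- data.frame(
      chain = "B", resname = "LIG", resno = 900L, atom = atom,
      element = element, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)

  if (!is.null(hbond)) {
    d <- hbond$distance; ang <- hbond$angle
    # receptor GLY amide: N at station, H along +y; acceptor O placed so
    # that |N-O| = d and angle(N-H-O) = ang
    N <- c(station, 0, 0); H <- N + c(0, 1.0, 0)
    theta <- (180 - ang) * pi / 180        # angle of H->O from +y axis
    dir <- c(sin(theta), cos(theta), 0)
    # solve |H + r dir - N| = d  =>  r^2 + 2 r (dir . (H-N)) + |H-N|^2 - d^2 = 0
    b <- 2 * sum(dir * (H - N)); c0 <- sum((H - N)^2) - d^2
    r <- (-b + sqrt(b^2 - 4 * c0)) / 2
    O <- H + r * dir
    radd("GLY", 101L, "N", "N", N)
    radd("GLY", 101L, "H", "H", H)
    radd("GLY", 101L, "CA", "C", N + c(0, -1.47, 0))
    Cc <- O + c(0, 1.23, 0)                 # carbonyl C, away from receptor
    ladd("C1", "C", Cc)
    ladd("O1", "O", O)
    man[[length(man) + 1L]] <- data.frame(type = "HBOND", residue = "GLY101",
                                          distance = d, angle = ang)
    station <- station + 25
  }
  if (!is.null(hydrophobic)) {
    cb <- c(station, 0, 0)
    radd("VAL", 202L, "CB", "C", cb)
    ladd("C9", "C", cb + c(0, hydrophobic, 0))
    man[[length(man) + 1L]] <- data.frame(type = "HYDROPHOBIC",
                                          residue = "VAL202",
                                          distance = hydrophobic,
                                          angle = NA_real_)
    station <- station + 25
  }
  if (!is.null(electrostatic)) {
    nz <- c(station, 0, 0)
    radd("LYS", 303L, "NZ", "N", nz)
    radd("LYS", 303L, "CE", "C", nz + c(0, -1.49, 0))
    # carboxylate centroid at `electrostatic` from NZ: C with two terminal O
    ctr <- nz + c(0, electrostatic, 0)
    ladd("C5", "C", ctr + c(0, 0.65, 0))
    ladd("O5", "O", ctr + c(1.09, 0.04, 0))
    ladd("O6", "O", ctr + c(-1.09, -0.04, 0))
    man[[length(man) + 1L]] <- data.frame(type = "ELECTROSTATIC",
                                          residue = "LYS303",
                                          distance = electrostatic,
                                          angle = NA_real_)
    station <- station + 25
  }
  if (!is.null(metal)) {
    zn <- c(station, 10, 0)
    met[[length(met) + 1L]] <- data.frame(
      chain = "M", resname = "ZN", resno = 501L, atom = "ZN", element = "ZN",
      x = zn[1], y = zn[2], z = zn[3], stringsAsFactors = FALSE)
    ladd("O8", "O", zn + c(0, metal, 0))
    man[[length(man) + 1L]] <- data.frame(type = "METAL", residue = "ZN",
                                          distance = metal, angle = NA_real_)
  }
  if (!length(rec))
    radd("GLY", 1L, "CA", "C", c(-40, 0, 0))  # receptor must be non-empty
  if (!length(lig)) ladd("C1", "C", c(-40, 15, 0))
  complex <- structure(list(receptor = do.call(rbind, rec),
                            ligand = do.call(rbind, lig),
                            metals = if (length(met)) do.call(rbind, met)
                                     else NULL),
                       class = "complex_structure")
  all_atoms <- rbind(complex$receptor, complex$ligand, complex$metals)
  dmat <- as.matrix(dist(all_atoms[, c("x", "y", "z")]))
  if (any(dmat[upper.tri(dmat)] < 1.0 - 1e-9))
    stop("clashing atoms (< 1 Angstrom) in generated complex")
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(type = character(0), residue = character(0),
               distance = numeric(0), angle = numeric(0))
  list(complex = complex, manifest = manifest)
}

#' Generate a synthetic docking pose table with planted consensus truth
#'
#' Emulates a consensus docking campaign: each ligand forms a fixed number
#' of poses in each receptor, per-receptor passing sets of prescribed sizes
#' are planted so that their intersection has exactly the prescribed size,
#' and per-pose fingerprints plant residue-contact frequencies with a known
#' top-k ranking. Scores are drawn around each receptor's threshold (half
#' the initial-ligand score): passing ligands get one pose above it,
#' failing ligands stay below.
#'
#' @param n_ligands Number of screened ligands.
#' @param receptors Named numeric vector: initial-ligand score per receptor.
#' @param pass_sizes Named integer vector: planted per-receptor passing-set
#'   sizes.
#' @param n_intersection Planted size of the final intersection.
#' @param poses_per_ligand Poses per (ligand, receptor).
#' @param fraction Score-threshold fraction.
#' @param contact_plan data.frame `residue`, `type`, `n_poses`: how many
#'   retained poses (over the positive-control set) carry each contact.
#' @param n_positive Number of positive-control ligands whose poses receive
#'   planted contacts (130 poses total with the defaults).
#' @param seed RNG seed.
#' @return List: `scores` (data.frame `ligand`, `receptor`, `pose`,
#'   `score`), `fingerprints` (data.frame `ligand`, `receptor`, `pose`,
#'   `type`, `residue`), `thresholds`, `manifest` (planted passing sets,
#'   final set, expected top residues), `config`.
#' @export
gen_pose_table <- function(n_ligands = 41L,
                           receptors = c("1O86" = 106.292,
                                         "4CA5" = 102.324,
                                         "4BZR" = 156.907),
                           pass_sizes = c("1O86" = 34L, "4CA5" = 38L,
                                          "4BZR" = 24L),
                           n_intersection = 19L,
                           poses_per_ligand = 10L, fraction = 0.5,
                           contact_plan = data.frame(
                             residue = c("ALA354", "VAL518", "HIS353",
                                         "TYR523", "ZN"),
                             type = c("HBOND", "HYDROPHOBIC", "HBOND",
                                      "HBOND", "METAL"),
                             n_poses = c(90L, 70L, 30L, 25L, 20L)),
                           n_positive = 13L, seed = 1L) {
  rec_ids <- names(receptors)
  if (!setequal(rec_ids, names(pass_sizes)))
    stop("pass_sizes must be named like receptors")
  if (any(pass_sizes < n_intersection) || n_intersection > n_ligands)
    stop("infeasible planted sizes: intersection exceeds a passing set")
  extras <- pass_sizes[rec_ids] - n_intersection
  n_extra_pool <- n_ligands - n_intersection
  if (any(extras > n_extra_pool))
    stop("infeasible planted sizes: not enough non-intersection ligands")
  if (sum(extras) > n_extra_pool * (length(rec_ids) - 1L))
    stop("infeasible planted sizes: extras would force a larger intersection")
  .with_seed(seed, {
    ligands <- sprintf("pep%03d", seq_len(n_ligands))
    final <- ligands[seq_len(n_intersection)]
    pool <- setdiff(ligands, final)
    # round-robin extras over the pool; a pool ligand may pass at most
    # n_receptors - 1 receptors, keeping the intersection exact
    slots <- rep(0L, length(pool))
    passing <- lapply(rec_ids, function(r) final)
    names(passing) <- rec_ids
    for (r in rec_ids[order(-extras)]) {
      need <- extras[[r]]
      if (need == 0L) next
      avail <- order(slots)[seq_len(need)]
      passing[[r]] <- c(final, pool[avail])
      slots[avail] <- slots[avail] + 1L
    }
    thresholds <- vapply(receptors, score_threshold, numeric(1),
                         fraction = fraction)
    scores <- do.call(rbind, lapply(rec_ids, function(r) {
      thr <- thresholds[[r]]
      do.call(rbind, lapply(ligands, function(lg) {
        s <- thr * runif(poses_per_ligand, 0.45, 0.95)
        if (lg %in% passing[[r]])
          s[sample.int(poses_per_ligand, 1)] <- thr * runif(1, 1.02, 1.6)
        data.frame(ligand = lg, receptor = r,
                   pose = seq_len(poses_per_ligand), score = s,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(scores) <- NULL
    # planted fingerprints over the positive-control pose block
    pos_ligands <- sprintf("pos%02d", seq_len(n_positive))
    pose_grid <- expand.grid(ligand = pos_ligands,
                             pose = seq_len(poses_per_ligand),
                             stringsAsFactors = FALSE)
    n_poses_total <- nrow(pose_grid)
    if (any(contact_plan$n_poses > n_poses_total))
      stop("contact plan exceeds available poses")
    fps <- do.call(rbind, lapply(rec_ids, function(r)
      do.call(rbind, lapply(seq_len(nrow(contact_plan)), function(i) {
        rows <- sample.int(n_poses_total, contact_plan$n_poses[i])
        data.frame(ligand = pose_grid$ligand[rows], receptor = r,
                   pose = pose_grid$pose[rows],
                   type = contact_plan$type[i],
                   residue = contact_plan$residue[i],
                   stringsAsFactors = FALSE)
      }))))
    rownames(fps) <- NULL
    ord <- order(-contact_plan$n_poses)
    list(scores = scores, fingerprints = fps, thresholds = thresholds,
         manifest = list(passing = passing, final = final,
                         top_residues = contact_plan$residue[ord],
                         contact_counts = contact_plan[ord, ]),
         config = list(n_ligands = n_ligands, receptors = receptors,
                       pass_sizes = pass_sizes,
                       n_intersection = n_intersection,
                       poses_per_ligand = poses_per_ligand,
                       fraction = fraction, n_positive = n_positive,
                       seed = seed))
  })
}

#' Generate a synthetic dose-response assay with a planted IC50
#'
#' Samples a logistic inhibition curve at log-spaced concentrations around
#' the planted IC50, adds Gaussian noise to the inhibition values, and also
#' expresses each point as HA peak areas relative to a fixed control area,
#' mirroring the chromatographic readout.
#'
#' @param ic50 Planted IC50 (concentration units of choice).
#' @param hill Hill slope.
#' @param noise_sd Gaussian noise SD on inhibition (percentage points).
#' @param concentrations Dose vector; default 8 log-spaced points spanning
#'   two decades either side of the planted IC50.
#' @param A_control Control peak area.
#' @param seed RNG seed.
#' @return List: `data` (data.frame `sample`, `concentration`, `unit`,
#'   `A_control`, `A_sample`, `inhibition`), `ic50`, `config`.
#' @export
gen_dose_response <- function(ic50 = 61.88, hill = 1, noise_sd = 0,
                              concentrations = ic50 * 10^seq(-2, 2,
                                                             length.out = 8),
                              A_control = 1000, seed = 1L) {
  if (ic50 <= 0) stop("ic50 must be > 0")
  .with_seed(seed, {
    y0 <- 100 / (1 + (ic50 / concentrations)^hill)
    y <- pmin(100, pmax(0, y0 + rnorm(length(y0), 0, noise_sd)))
    data <- data.frame(sample = sprintf("dose%02d", seq_along(y)),
                       concentration = concentrations, unit = "uM",
                       A_control = A_control,
                       A_sample = A_control * (1 - y / 100),
                       inhibition = y, stringsAsFactors = FALSE)
    list(data = data, ic50 = ic50,
         config = list(ic50 = ic50, hill = hill, noise_sd = noise_sd,
                       A_control = A_control, seed = seed))
  })
}
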