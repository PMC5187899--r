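PHARM_TYPES <- c("HBA", "HBD", "NEG_IONIZABLE", "HYDROPHOBE")

#' Construct a sphere-based pharmacophore model
#'
#' @param target Target name.
#' @param features data.frame with columns `type` (one of HBA, HBD,
#'   NEG_IONIZABLE, HYDROPHOBE), `x`, `y`, `z` (Angstrom), `radius`
#'   (tolerance sphere, > 0) and `weight` (>= 0).
#' @return Object of class `"pharmacophore_model"`.
#' @export
pharmacophore_model <- function(target, features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("type", "x", "y", "z", "radius", "weight")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  if (nrow(features) < 1L) stop("a pharmacophore model needs >= 1 feature")
  if (!all(features$type %in% PHARM_TYPES))
    stop("unknown feature type(s): ",
         paste(setdiff(features$type, PHARM_TYPES), collapse = ", "))
  if (any(features$radius <= 0)) stop("tolerance radii must be > 0")
  if (any(features$weight < 0)) stop("feature weights must be >= 0")
  structure(list(target = target, features = features),
            class = "pharmacophore_model")
}

#' Read / write pharmacophore models as JSON
#'
#' Format: `{"target": ..., "features": [{"type", "center": [x,y,z],
#' "radius", "weight"}, ...]}`.
#'
#' @param path File path.
#' @return `read_pharmacophore` returns a `"pharmacophore_model"`.
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ctr <- do.call(rbind, obj$features$center)
  pharmacophore_model(obj$target, data.frame(
    type = obj$features$type,
    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
    radius = obj$features$radius,
    weight = if (is.null(obj$features$weight)) 1 else obj$features$weight,
    stringsAsFactors = FALSE))
}

#' @rdname read_pharmacophore
#' @param model A `"pharmacophore_model"`.
#' @export
write_pharmacophore <- function(model, path) {
  feats <- lapply(seq_len(nrow(model$features)), function(i) {
    f <- model$features[i, ]
    list(type = f$type, center = c(f$x, f$y, f$z),
         radius = f$radius, weight = f$weight)
  })
  jsonlite::write_json(list(target = model$target, features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The packaged four-feature ACE pharmacophore model
#'
#' One hydrogen-bond acceptor, one donor, one negative ionizable group and
#' one hydrophobe, arranged as in the lisinopril binding mode at the ACE
#' C-domain active site (carboxylate toward the catalytic zinc, donor toward
#' the ALA354 backbone, hydrophobe in the VAL518 pocket). The geometry is a
#' synthetic reconstruction shipped with the package, not published model
#' coordinates.
#'
#' @return A `"pharmacophore_model"`.
#' @export
ace_pharmacophore <- function() {
  read_pharmacophore(system.file("extdata", "ace_pharmacophore_synthetic.json",
                                 package = "pepscreen"))
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("Pharmacophore model:", x$target, "-", nrow(x$features), "features\n")
  print(x$features, ...)
  invisible(x)
}

#' Perceive pharmacophore feature points on a 3D conformer
#'
#' Rule-based typing on an atom table (element + coordinates; covalent bonds
#' inferred from interatomic distances):
#' * `HBD` — N or O bearing at least one bonded hydrogen (point at the heavy
#'   atom);
#' * `HBA` — any oxygen; nitrogen with coordination <= 2 (lone-pair bearing
#'   imine/aromatic N; amide and ammonium N excluded);
#' * `NEG_IONIZABLE` — carboxylate or phosphonate: C/P bonded to >= 2
#'   terminal oxygens (point at the centroid of those oxygens);
#' * `HYDROPHOBE` — centroid of each connected cluster of >= 3 apolar
#'   carbons (carbons with no N/O/S/P neighbour), e.g. aromatic rings and
#'   aliphatic side chains.
#'
#' @param conformer A list with `id`, optional `conformer` index, and
#'   `atoms`: data.frame with `element`, `x`, `y`, `z` — or the atom
#'   data.frame itself.
#' @return A list of class `"annotated_conformer"` with `id`, `conformer`,
#'   `atoms` and `features` (data.frame `type`, `x`, `y`, `z`, `atoms` =
#'   semicolon-joined source atom indices).
#' @export
perceive_features <- function(conformer) {
  if (is.data.frame(conformer))
    conformer <- list(id = "ligand", conformer = 1L, atoms = conformer)
  atoms <- as.data.frame(conformer$atoms, stringsAsFactors = FALSE)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("atoms need columns element, x, y, z")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  atoms$element <- toupper(atoms$element)
  bonds <- .infer_bonds(atoms)
  nb <- .neighbors(bonds, nrow(atoms))
  el <- atoms$element
  feats <- list()
  add <- function(type, xyz, src)
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, x = xyz[1], y = xyz[2], z = xyz[3],
      atoms = paste(src, collapse = ";"), stringsAsFactors = FALSE)

  heavy <- which(el != "H")
  for (i in heavy) {
    nbrs <- nb[[i]]
    has_h <- any(el[nbrs] == "H")
    if (el[i] %in% c("N", "O") && has_h)
      add("HBD", as.numeric(atoms[i, c("x", "y", "z")]), i)
    if (el[i] == "O")
      add("HBA", as.numeric(atoms[i, c("x", "y", "z")]), i)
    if (el[i] == "N" && length(nbrs) <= 2L)
      add("HBA", as.numeric(atoms[i, c("x", "y", "z")]), i)
  }
  # carboxylate / phosphonate groups
  for (i in which(el %in% c("C", "P"))) {
    oxy <- nb[[i]][el[nb[[i]]] == "O"]
    terminal <- oxy[vapply(oxy, function(o)
      sum(el[nb[[o]]] != "H") == 1L, logical(1))]
    if (length(terminal) >= 2L)
      add("NEG_IONIZABLE",
          colMeans(atoms[terminal, c("x", "y", "z")]), terminal)
  }
  # apolar carbon clusters
  apolar <- which(el == "C" & vapply(seq_along(el), function(i)
    !any(el[nb[[i]]] %in% c("N", "O", "S", "P")), logical(1)))
  if (length(apolar)) {
    comp <- .components(apolar, nb)
    for (cl in comp)
      if (length(cl) >= 3L)
        add("HYDROPHOBE", colMeans(atoms[cl, c("x", "y", "z")]), cl)
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), atoms = character(0))
  structure(list(id = conformer$id %||% "ligand",
                 conformer = conformer$conformer %||% 1L,
                 atoms = atoms, features = features),
            class = "annotated_conformer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# connected components of `nodes` under the bond graph, restricted to nodes
.components <- function(nodes, nb) {
  remaining <- nodes
  comps <- list()
  while (length(remaining)) {
    stack <- remaining[1]; comp <- integer(0)
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (!(v %in% comp)) {
        comp <- c(comp, v)
        stack <- c(stack, intersect(nb[[v]], setdiff(remaining, comp)))
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

#' Best pharmacophore fit of a ligand over its conformers
#'
#' For every conformer, every injective type-respecting assignment of model
#' features to perceived feature points, and the least-squares rigid
#' superposition of the assigned points onto the model centers, the fit is
#' \deqn{fit = \sum_f w_f \max(0, 1 - d_f/r_f) / \sum_f w_f}
#' with `d_f` the residual displacement of feature `f`. Every model feature
#' must be assigned, otherwise the assignment scores 0. The maximum over
#' conformers and assignments is returned; ties between equal-fit
#' assignments are broken by lexicographic assignment order.
#'
#' @param model A `"pharmacophore_model"`.
#' @param conformers A list of `"annotated_conformer"` objects (or raw
#'   conformers, which are run through [perceive_features()]).
#' @return A list of class `"fit_result"`: `ligand`, `fit` in \[0,1\],
#'   `conformer` (best index), `assignment` (data.frame feature ->
#'   point index with per-feature displacement), or fit 0 with `NA`
#'   assignment when some feature type cannot be matched.
#' @export
best_fit <- function(model, conformers) {
  if (!inherits(model, "pharmacophore_model")) stop("model must be a pharmacophore_model")
  if (inherits(conformers, "annotated_conformer")) conformers <- list(conformers)
  if (length(conformers) < 1L) stop("at least one conformer is required")
  conformers <- lapply(conformers, function(cf)
    if (inherits(cf, "annotated_conformer")) cf else perceive_features(cf))
  best <- list(ligand = conformers[[1]]$id, fit = 0, conformer = NA_integer_,
               assignment = NULL)
  class(best) <- "fit_result"
  mf <- model$features
  centers <- as.matrix(mf[, c("x", "y", "z")])
  for (ci in seq_along(conformers)) {
    fp <- conformers[[ci]]$features
    cand <- lapply(mf$type, function(tp) which(fp$type == tp))
    if (any(vapply(cand, length, integer(1)) == 0L)) next
    for (asg in .injective_assignments(cand)) {
      pts <- as.matrix(fp[asg, c("x", "y", "z")])
      d <- .assigned_displacements(centers, pts)
      fit <- sum(mf$weight * pmax(0, 1 - d / mf$radius)) / sum(mf$weight)
      if (fit > best$fit + 1e-12) {
        best$fit <- fit
        best$conformer <- ci
        best$assignment <- data.frame(type = mf$type, point = asg,
                                      displacement = d,
                                      stringsAsFactors = FALSE)
      }
    }
  }
  best$ligand <- conformers[[1]]$id
  best
}

# all injective selections, one index from each candidate set, lexicographic
.injective_assignments <- function(cand) {
  out <- list()
  rec <- function(i, chosen) {
    if (i > length(cand)) { out[[length(out) + 1L]] <<- chosen; return() }
    for (p in cand[[i]])
      if (!(p %in% chosen)) rec(i + 1L, c(chosen, p))
  }
  rec(1L, integer(0))
  out
}

# residual per-pair distances after optimal rigid superposition of pts onto
# centers; closed forms for n = 1, 2
.assigned_displacements <- function(centers, pts) {
  n <- nrow(centers)
  if (n == 1L) return(0)
  if (n == 2L) {
    lc <- sqrt(sum((centers[1, ] - centers[2, ])^2))
    lp <- sqrt(sum((pts[1, ] - pts[2, ])^2))
    return(rep(abs(lc - lp) / 2, 2))
  }
  sp <- kabsch_superpose(centers, pts)
  sqrt(rowSums((centers - sp$transformed)^2))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit", format(x$fit, digits = 4), "for", x$ligand,
      if (!is.na(x$conformer)) paste0("(conformer ", x$conformer, ")"), "\n")
  invisible(x)
}

#' Screen a ligand library against one or more pharmacophore models
#'
#' Computes [best_fit()] for every (model, ligand) pair and tabulates, per
#' target, the number of ligands with any positive fit (`hits`) and with fit
#' above the screening threshold, the reverse-profiling summary used to rank
#' candidate targets.
#'
#' @param models A `"pharmacophore_model"` or list of them.
#' @param ligands Named list: each element a list of conformers for one
#'   ligand (each conformer an atom data.frame or annotated conformer).
#' @param threshold Screening cutoff on the normalized fit (default 0.7).
#' @return A list with `summary` (data.frame `target`, `hits`,
#'   `hits_over_threshold`, sorted by the threshold column) and `fits`
#'   (data.frame `target`, `ligand`, `fit`, `pass`).
#' @export
screen_library <- function(models, ligands, threshold = 0.7) {
  if (inherits(models, "pharmacophore_model")) models <- list(models)
  if (length(models) < 1L) stop("at least one model is required")
  if (is.null(names(ligands)))
    names(ligands) <- paste0("ligand", seq_along(ligands))
  rows <- list()
  for (m in models)
    for (lg in names(ligands)) {
      cfs <- ligands[[lg]]
      if (inherits(cfs, "annotated_conformer") || is.data.frame(cfs))
        cfs <- list(cfs)
      fr <- best_fit(m, cfs)
      rows[[length(rows) + 1L]] <- data.frame(
        target = m$target, ligand = lg, fit = fr$fit,
        pass = fr$fit > threshold, stringsAsFactors = FALSE)
    }
  fits <- do.call(rbind, rows)
  sp <- split(fits, fits$target)
  summary <- do.call(rbind, lapply(sp, function(d) data.frame(
    target = d$target[1], hits = sum(d$fit > 0),
    hits_over_threshold = sum(d$pass), stringsAsFactors = FALSE)))
  summary <- summary[order(-summary$hits_over_threshold, -summary$hits), ]
  rownames(summary) <- NULL
  list(summary = summary, fits = fits, threshold = threshold)
}
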