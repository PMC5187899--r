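#' Optimal rigid-body superposition of matched point sets (Kabsch)
#'
#' Least-squares rigid superposition of `coordsB` onto `coordsA` via the
#' SVD of the covariance matrix, constrained to a proper rotation
#' (determinant +1, no reflection).
#'
#' @param coordsA,coordsB Numeric matrices of matched 3D points (n x 3,
#'   n >= 3, same n).
#' @return A list of class `"superposition"`: `rotation` (3x3, applied to
#'   centred B), `translation`, `rmsd` (Angstrom over matched pairs), and
#'   `transformed` (B after superposition onto A).
#' @examples
#' sq <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))
#' kabsch_superpose(sq, sq)$rmsd  # 0
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)) || ncol(coordsA) != 3L)
    stop("coordsA and coordsB must be matched n x 3 matrices")
  if (nrow(coordsA) < 3L) stop("at least 3 matched points are required")
  if (any(!is.finite(coordsA)) || any(!is.finite(coordsB)))
    stop("coordinates must be finite")
  cA <- colMeans(coordsA); cB <- colMeans(coordsB)
  A <- sweep(coordsA, 2, cA); B <- sweep(coordsB, 2, cB)
  H <- crossprod(B, A)                       # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bt <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  transformed <- sweep(Bt, 2, cA, "+")
  translation <- cA - as.vector(R %*% cB)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, transformed = transformed),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition: RMSD =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' TM-score between matched structures
#'
#' Length-normalised structural similarity in (0, 1]:
#' \deqn{TM = \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0)^2}, \quad
#'       d_0 = 1.24 (L-15)^{1/3} - 1.8}
#' maximised over rigid superpositions. The search seeds Kabsch fits on
#' contiguous residue windows and iteratively re-fits on the residue subset
#' currently within `d0`, which recovers the TM-optimal superposition for
#' same-sequence structure pairs (full alignment of non-identical sequences
#' is out of scope).
#'
#' @param coordsA,coordsB Matched coordinate matrices (n x 3), typically CA
#'   atoms paired by residue number.
#' @param L_target Normalisation length (>= 16; below that `d0` is not
#'   defined). Defaults to the number of matched points.
#' @param optimize If `FALSE`, the TM formula is evaluated at the
#'   coordinates as given (no superposition search) — useful when the pose
#'   is already aligned or to evaluate the closed form directly.
#' @return A list of class `"tm_score"`: `tm`, `d0`, `rmsd` (of the final
#'   fit subset), `superposition`.
#' @export
tm_score <- function(coordsA, coordsB, L_target = nrow(coordsA),
                     optimize = TRUE) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)))
    stop("coordsA and coordsB must be matched")
  if (L_target < 16) stop("L_target must be >= 16 (d0 undefined below)")
  n <- nrow(coordsA)
  d0 <- 1.24 * (L_target - 15)^(1/3) - 1.8
  if (!optimize) {
    d2 <- rowSums((coordsA - coordsB)^2)
    tm <- sum(1 / (1 + d2 / d0^2)) / L_target
    return(structure(list(tm = tm, d0 = d0, rmsd = sqrt(mean(d2)),
                          superposition = NULL, L_target = L_target),
                     class = "tm_score"))
  }
  score_of <- function(sp) {
    d2 <- rowSums((coordsA - sp$transformed)^2)
    sum(1 / (1 + d2 / d0^2)) / L_target
  }
  best <- NULL; best_tm <- -Inf
  # seed windows: every contiguous fragment for small chains; a geometric
  # ladder of lengths slid along the chain for large ones
  wins <- list()
  if (n <= 60L) {
    for (w in 5:n) for (s in 1:(n - w + 1L))
      wins[[length(wins) + 1L]] <- s:(s + w - 1L)
  } else {
    lens <- unique(pmin(n, pmax(5L, round(n * c(1, 0.7, 0.5, 0.35, 0.25,
                                                0.17, 0.12, 0.08)))))
    for (w in lens) {
      starts <- unique(c(seq(1L, n - w + 1L, by = max(1L, w %/% 4L)),
                         n - w + 1L))
      for (s in starts) wins[[length(wins) + 1L]] <- s:(s + w - 1L)
    }
  }
  for (idx in wins) {
    if (length(idx) < 3L) next
    sp <- tryCatch(kabsch_superpose(coordsA[idx, , drop = FALSE],
                                    coordsB[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(sp)) next
    # apply window fit to all points, then iteratively re-fit on the
    # subset currently within d0, scoring every iterate
    for (iter in 1:30) {
      full <- .apply_transform(coordsB, sp)
      tm <- sum(1 / (1 + rowSums((coordsA - full)^2) / d0^2)) / L_target
      if (tm > best_tm) {
        best_tm <- tm
        best <- list(rotation = sp$rotation, translation = sp$translation,
                     rmsd = sqrt(mean(rowSums((coordsA - full)^2))),
                     transformed = full)
        class(best) <- "superposition"
      }
      close_idx <- which(rowSums((coordsA - full)^2) <= d0^2)
      if (length(close_idx) < 3L) break
      sp2 <- tryCatch(kabsch_superpose(coordsA[close_idx, , drop = FALSE],
                                       coordsB[close_idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sp2)) break
      converged <- isTRUE(all.equal(sp2$rotation, sp$rotation,
                                    tolerance = 1e-10))
      sp <- sp2
      if (converged && iter > 1L) break
    }
  }
  structure(list(tm = best_tm, d0 = d0, rmsd = best$rmsd,
                 superposition = best, L_target = L_target),
            class = "tm_score")
}

.apply_transform <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.tm_score <- function(x, ...) {
  cat("TM-score =", format(x$tm, digits = 4),
      "(d0 =", format(x$d0, digits = 4), "A, L =", x$L_target, ")\n")
  invisible(x)
}

# --- small geometry helpers shared by feature perception and fingerprints ---

# covalent bond inference by distance: element-pair threshold from single-bond
# covalent radii + 0.45 A slack
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, ZN = 1.22, SE = 1.2)

.infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- COVALENT_RADII[toupper(atoms$element)]
  r[is.na(r)] <- 1.5
  d <- as.matrix(dist(xyz))
  thr <- outer(r, r, "+") + 0.45
  hit <- which(d > 0.4 & d < thr & upper.tri(d), arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2])
}

.neighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

.angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
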