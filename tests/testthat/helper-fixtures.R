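# shared fixture builders and independent oracles for the test suite

random_sequences <- function(n, max_len = 60L, seed = 20260927L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed(vapply(seq_len(n), function(i)
    paste(sample(aa, sample(2:max_len, 1), replace = TRUE), collapse = ""),
    character(1)))
}

# a conformer whose perceived feature points sit exactly at the packaged ACE
# model's four centers, optionally rigidly moved
ace_matching_conformer <- function(shift = c(0, 0, 0), rot = diag(3)) {
  at <- function(el, xyz) data.frame(element = el, x = xyz[1], y = xyz[2],
                                     z = xyz[3], stringsAsFactors = FALSE)
  a <- rbind(
    # carboxylate with O-centroid at the origin
    at("C", c(0, -0.65, 0)), at("O", c(1.09, 0.04, 0)),
    at("O", c(-1.09, -0.04, 0)),
    # tertiary amine N-H donor at (3, 1.2, 0.8)
    at("N", c(3, 1.2, 0.8)), at("H", c(3, 2.2, 0.8)),
    at("C", c(3, 1.2, -0.67)), at("C", c(4.4, 1.2, 1.3)),
    # lone-pair oxygen acceptor
    at("O", c(2.2, -2.0, 1.0)),
    # three-carbon apolar cluster with centroid (-3.5, 1.8, -0.5)
    at("C", c(-4.2, 1.8, -0.5)), at("C", c(-3.15, 2.85, -0.5)),
    at("C", c(-3.15, 0.75, -0.5)))
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  a
}

# annotated conformer built directly from feature points (bypasses atoms)
conformer_from_features <- function(features, id = "synthetic") {
  structure(list(id = id, conformer = 1L, atoms = NULL,
                 features = cbind(features, atoms = "")),
            class = "annotated_conformer")
}

# independent brute-force fit oracle: exhaustive assignment enumeration with
# its own recursion and its own superposition residuals (via kabsch only at
# the final scoring step, as the fit definition requires)
brute_force_fit <- function(model, features) {
  mf <- model$features
  centers <- as.matrix(mf[, c("x", "y", "z")])
  cand <- lapply(mf$type, function(tp) which(features$type == tp))
  if (any(lengths(cand) == 0)) return(0)
  best <- 0
  grid <- expand.grid(cand, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    if (anyDuplicated(asg)) next
    pts <- as.matrix(features[asg, c("x", "y", "z")])
    if (nrow(pts) >= 3) {
      sp <- kabsch_superpose(centers, pts)
      d <- sqrt(rowSums((centers - sp$transformed)^2))
    } else if (nrow(pts) == 2) {
      d <- rep(abs(dist(centers) - dist(pts)) / 2, 2)
    } else d <- 0
    fit <- sum(mf$weight * pmax(0, 1 - d / mf$radius)) / sum(mf$weight)
    best <- max(best, fit)
  }
  best
}

rotation3 <- function(axis, theta) pepscreen:::.rotation_matrix(axis, theta)
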