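test_that("planted hydrogen bond is detected at 2.9 A/160 deg and rejected at 4.0 A", {
  g <- gen_complex(hbond = list(distance = 2.9, angle = 160))
  fp <- fingerprint_complex(g$complex)
  expect_identical(nrow(fp), 1L)
  expect_identical(fp$type, "HBOND")
  expect_identical(fp$residue, "GLY101")
  expect_equal(fp$distance, 2.9, tolerance = 1e-9)
  expect_equal(fp$angle, 160, tolerance = 1e-6)

  stretched <- gen_complex(hbond = list(distance = 4.0, angle = 160))
  expect_identical(nrow(fingerprint_complex(stretched$complex)), 0L)
  # good distance but near-linear donor geometry violated
  bent <- gen_complex(hbond = list(distance = 2.9, angle = 100))
  expect_identical(nrow(fingerprint_complex(bent$complex)), 0L)
})

test_that("metal, hydrophobic and salt-bridge contacts follow their cutoffs", {
  g <- gen_complex(hbond = NULL, metal = 2.2)
  fp <- fingerprint_complex(g$complex)
  expect_identical(fp$type, "METAL")
  expect_identical(fp$residue, "ZN")
  expect_equal(fp$distance, 2.2, tolerance = 1e-9)
  expect_identical(nrow(fingerprint_complex(
    gen_complex(hbond = NULL, metal = 3.4)$complex)), 0L)

  g2 <- gen_complex(hbond = NULL, hydrophobic = 4.0, electrostatic = 5.0)
  fp2 <- fingerprint_complex(g2$complex)
  expect_setequal(fp2$type, c("HYDROPHOBIC", "ELECTROSTATIC"))
  expect_equal(fp2$distance[fp2$type == "ELECTROSTATIC"], 5.0,
               tolerance = 1e-9)
  expect_identical(nrow(fingerprint_complex(
    gen_complex(hbond = NULL, hydrophobic = 4.8)$complex)), 0L)
  expect_error(fingerprint_complex(list(receptor = g$complex$receptor,
                                        ligand = g$complex$ligand[0, ])),
               "no ligand")
})

test_that("fingerprints are invariant under rigid motion and monotone in cutoffs", {
  g <- gen_complex(hbond = list(distance = 3.2, angle = 140),
                   hydrophobic = 4.2, metal = 2.6)
  fp0 <- fingerprint_complex(g$complex)
  R <- rotation3(c(2, -1, 1), 0.9)
  move <- function(df) {
    if (is.null(df)) return(NULL)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + 11.5; df$y <- xyz[, 2] - 3; df$z <- xyz[, 3] + 6
    df
  }
  moved <- structure(list(receptor = move(g$complex$receptor),
                          ligand = move(g$complex$ligand),
                          metals = move(g$complex$metals)),
                     class = "complex_structure")
  fp1 <- fingerprint_complex(moved)
  expect_identical(fp0[, c("type", "residue", "rec_atom", "lig_atom")],
                   fp1[, c("type", "residue", "rec_atom", "lig_atom")])
  expect_equal(fp0$distance, fp1$distance, tolerance = 1e-9)

  # enlarging any cutoff never removes an interaction
  wide <- fingerprint_complex(g$complex, params = list(
    hbond_dist = 4.5, hydrophobic_dist = 6, electrostatic_dist = 8,
    metal_dist = 4))
  key <- function(fp) paste(fp$type, fp$residue, fp$rec_atom, fp$lig_atom)
  expect_true(all(key(fp0) %in% key(wide)))
})

test_that("Kabsch superposition: identity, rigid invariance, frozen oracle value", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(kabsch_superpose(sq, sq)$rmsd, 0, tolerance = 1e-12)
  R <- rotation3(c(0, 0, 1), pi / 2)
  moved <- sq %*% t(R) + matrix(c(3, -2, 7), 4, 3, byrow = TRUE)
  sp <- kabsch_superpose(sq, moved)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # unit square vs one corner displaced 0.4 A out of plane; expectation
  # frozen from a 200-restart rigid-transform optimisation oracle
  disp <- sq; disp[3, ] <- c(1, 1, 0.4)
  expect_equal(kabsch_superpose(sq, disp)$rmsd, 0.1019056315,
               tolerance = 1e-8)
  expect_error(kabsch_superpose(sq, sq[1:3, ]), "matched")
})

test_that("superposed RMSD never exceeds the unaligned RMSD", {
  set.seed(88)
  for (i in 1:20) {
    A <- matrix(rnorm(45), ncol = 3)
    B <- A %*% t(rotation3(rnorm(3), runif(1, 0, pi))) +
      matrix(rnorm(3), 15, 3, byrow = TRUE) + matrix(rnorm(45, 0, 0.3), ncol = 3)
    raw <- sqrt(mean(rowSums((A - B)^2)))
    expect_lte(kabsch_superpose(A, B)$rmsd, raw + 1e-12)
  }
})

test_that("TM-score: identity gives 1, the d0 closed form gives 0.5, symmetric", {
  set.seed(2)
  A <- matrix(rnorm(150, sd = 8), ncol = 3)
  expect_equal(tm_score(A, A)$tm, 1, tolerance = 1e-9)
  d0 <- 1.24 * (50 - 15)^(1 / 3) - 1.8
  B <- A + matrix(c(d0, 0, 0), 50, 3, byrow = TRUE)
  expect_equal(tm_score(A, B, optimize = FALSE)$tm, 0.5, tolerance = 1e-12)
  expect_error(tm_score(A[1:15, ], A[1:15, ]), "L_target")
  # symmetry under exchange at fixed L_target
  C <- A + matrix(rnorm(150, sd = 1.5), ncol = 3)
  expect_equal(tm_score(A, C, L_target = 50)$tm,
               tm_score(C, A, L_target = 50)$tm, tolerance = 1e-3)
})

test_that("TM-score search matches a reduced exhaustive-subset oracle on a coil pair", {
  set.seed(31)
  # random coil: cumulative CA-like steps of ~3.8 A
  steps <- matrix(rnorm(150), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  A <- apply(steps, 2, cumsum)
  B <- A + matrix(rnorm(150, sd = 1.2), ncol = 3)
  got <- tm_score(A, B)$tm
  # oracle: exhaustive Kabsch seeds on every contiguous window of length >= 5,
  # each refined by the same d0-subset reweighting definition, done longhand
  d0 <- 1.24 * (50 - 15)^(1 / 3) - 1.8
  best <- 0
  for (w in 5:50) for (s in 1:(50 - w + 1)) {
    idx <- s:(s + w - 1)
    sp <- kabsch_superpose(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
    for (it in 1:30) {
      full <- sweep(B %*% t(sp$rotation), 2, sp$translation, "+")
      tm <- sum(1 / (1 + rowSums((A - full)^2) / d0^2)) / 50
      best <- max(best, tm)
      sub <- which(rowSums((A - full)^2) <= d0^2)
      if (length(sub) < 3) break
      sp <- kabsch_superpose(A[sub, , drop = FALSE], B[sub, , drop = FALSE])
    }
  }
  expect_equal(got, best, tolerance = 1e-3)
})
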