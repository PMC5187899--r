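test_that("feature perception types acidic, donor, acceptor and hydrophobic groups", {
  # glycine zwitterion: exactly one negative ionizable point at the
  # carboxylate oxygens' centroid
  gly <- rbind(
    data.frame(element = "N", x = -1.95, y = 0.7, z = 0),
    data.frame(element = "H", x = -2.55, y = 1.5, z = 0),
    data.frame(element = "H", x = -2.55, y = -0.1, z = 0),
    data.frame(element = "H", x = -1.35, y = 0.7, z = 0.8),
    data.frame(element = "C", x = -0.9, y = 0, z = -0.6),
    data.frame(element = "H", x = -0.9, y = 0.2, z = -1.66),
    data.frame(element = "C", x = 0.45, y = 0.35, z = 0),
    data.frame(element = "O", x = 1.4, y = -0.45, z = 0.1),
    data.frame(element = "O", x = 0.6, y = 1.55, z = 0.25))
  f <- perceive_features(gly)$features
  neg <- f[f$type == "NEG_IONIZABLE", ]
  expect_identical(nrow(neg), 1L)
  expect_equal(c(neg$x, neg$y, neg$z), c(1.0, 0.55, 0.175), tolerance = 1e-6)
  expect_true("HBD" %in% f$type)  # ammonium N-H

  # planted donor + acceptor only
  da <- rbind(
    data.frame(element = "C", x = -1.2, y = 0.6, z = 0),
    data.frame(element = "N", x = 0, y = 0, z = 0),
    data.frame(element = "H", x = 0, y = -1.0, z = 0),
    data.frame(element = "C", x = 1.2, y = 0.6, z = 0),
    data.frame(element = "O", x = 5, y = 5, z = 5))
  f2 <- perceive_features(da)$features
  expect_identical(sort(f2$type), c("HBA", "HBD"))

  # tyrosine-like phenol ring: hydrophobe at the apolar ring-carbon centroid
  ring <- do.call(rbind, lapply(0:5, function(i) {
    a <- i * pi / 3
    data.frame(element = "C", x = 1.39 * cos(a), y = 1.39 * sin(a), z = 0)
  }))
  tyr <- rbind(ring, data.frame(element = "O", x = 2.75, y = 0, z = 0))
  f3 <- perceive_features(tyr)$features
  expect_true("HYDROPHOBE" %in% f3$type)
  hyd <- f3[f3$type == "HYDROPHOBE", ]
  expect_equal(hyd$z, 0)
  expect_error(perceive_features(data.frame(element = "C", x = NA, y = 0,
                                            z = 0)),
               "finite")
})

test_that("fit is 1 at exact overlap, 0 when a required feature is missing", {
  model <- ace_pharmacophore()
  fr <- best_fit(model, list(ace_matching_conformer()))
  expect_equal(fr$fit, 1.0, tolerance = 1e-9)
  expect_equal(fr$assignment$displacement, rep(0, 4), tolerance = 1e-7)
  # drop the carboxylate -> no NEG_IONIZABLE feature -> fit 0
  conf <- ace_matching_conformer()[-(1:3), ]
  expect_equal(best_fit(model, list(conf))$fit, 0)
})

test_that("features displaced by r/2 in balanced directions give fit 0.5", {
  feats <- data.frame(type = c("HBA", "HBD", "NEG_IONIZABLE", "HYDROPHOBE"),
                      x = c(1, 1, -1, -1), y = c(1, -1, -1, 1), z = 0,
                      radius = 1, weight = 1)
  model <- pharmacophore_model("toy", feats)
  # saddle-mode z displacement of r/2: orthogonal to every rigid motion, so
  # superposition cannot reduce it
  pts <- feats[, c("type", "x", "y", "z")]
  pts$z <- c(0.5, -0.5, 0.5, -0.5)
  fr <- best_fit(model, list(conformer_from_features(pts)))
  expect_equal(fr$fit, 0.5, tolerance = 1e-9)
  expect_equal(brute_force_fit(model, pts), 0.5, tolerance = 1e-9)
})

test_that("fit is invariant under rigid motion of the conformer", {
  model <- ace_pharmacophore()
  base <- best_fit(model, list(ace_matching_conformer()))$fit
  rots <- list(rotation3(c(0, 0, 1), pi / 2),
               rotation3(c(1, 2, 3), 1.1),
               rotation3(c(1, -1, 0.5), -2.4))
  for (i in seq_along(rots)) {
    moved <- ace_matching_conformer(shift = c(7, -4, 2) * i, rot = rots[[i]])
    expect_equal(best_fit(model, list(moved))$fit, base, tolerance = 1e-6)
  }
})

test_that("fit never increases as a feature point moves outward", {
  feats <- data.frame(type = c("HBA", "HBD", "NEG_IONIZABLE", "HYDROPHOBE"),
                      x = c(1, 1, -1, -1), y = c(1, -1, -1, 1), z = 0,
                      radius = 1, weight = 1)
  model <- pharmacophore_model("toy", feats)
  prev <- Inf
  for (dz in seq(0, 2.5, by = 0.25)) {
    pts <- feats[, c("type", "x", "y", "z")]
    pts$z <- c(dz, -dz, dz, -dz)
    fit <- best_fit(model, list(conformer_from_features(pts)))$fit
    expect_lte(fit, prev + 1e-12)
    prev <- fit
  }
  expect_equal(prev, 0)  # far outside every tolerance sphere
})

test_that("assignment search equals exhaustive enumeration with ambiguous points", {
  set.seed(404)
  feats <- data.frame(type = c("HBA", "HBA", "HBD", "HYDROPHOBE"),
                      x = rnorm(4, sd = 2), y = rnorm(4, sd = 2),
                      z = rnorm(4, sd = 2),
                      radius = c(1.2, 1.5, 1, 2), weight = c(2, 1, 1, 3))
  model <- pharmacophore_model("ambiguous", feats)
  for (rep in 1:10) {
    pts <- data.frame(type = sample(c("HBA", "HBA", "HBA", "HBD", "HBD",
                                      "HYDROPHOBE")),
                      x = rnorm(6, sd = 2.5), y = rnorm(6, sd = 2.5),
                      z = rnorm(6, sd = 2.5))
    got <- best_fit(model, list(conformer_from_features(pts)))$fit
    expect_equal(got, brute_force_fit(model, pts), tolerance = 1e-9)
  }
})

test_that("best_fit takes the maximum over conformers", {
  model <- ace_pharmacophore()
  good <- ace_matching_conformer()
  bad <- ace_matching_conformer()
  bad[, c("x", "y", "z")] <- bad[, c("x", "y", "z")] * 1.6  # distorted
  fr <- best_fit(model, list(bad, good))
  expect_equal(fr$fit, 1.0, tolerance = 1e-9)
  expect_identical(fr$conformer, 2L)
})

test_that("library screening tabulates hits and the 0.7 threshold per target", {
  model <- ace_pharmacophore()
  # two-feature decoy whose inter-feature distance no small ligand can span
  decoy <- pharmacophore_model("decoy", data.frame(
    type = c("NEG_IONIZABLE", "HBD"), x = c(0, 99), y = 0, z = 0,
    radius = 1, weight = 1))
  miss <- ace_matching_conformer()[-(1:3), ]   # no NEG group at all
  near <- ace_matching_conformer()
  # nudge the acceptor out to half its tolerance: fit ~ 1 - (0.75/1.5)/4
  near[8, c("x", "y", "z")] <- near[8, c("x", "y", "z")] + c(0, 0, 0.9)
  ligs <- list(perfect = ace_matching_conformer(), near = near, miss = miss)
  sc <- screen_library(list(model, decoy), ligs, threshold = 0.7)
  ace_row <- sc$summary[sc$summary$target == "ACE", ]
  expect_identical(ace_row$hits, 2L)
  expect_identical(ace_row$hits_over_threshold, 2L)
  expect_identical(sc$summary$hits[sc$summary$target == "decoy"], 0L)
  strict <- screen_library(model, ligs, threshold = 0.95)
  expect_identical(
    strict$summary$hits_over_threshold[strict$summary$target == "ACE"], 1L)
})
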