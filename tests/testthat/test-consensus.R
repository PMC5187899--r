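test_that("score threshold is the stated fraction of the initial-ligand score", {
  expect_equal(score_threshold(106.292, 0.5), 53.146)
  expect_equal(score_threshold(102.324, 0.5), 51.162)
  expect_equal(score_threshold(88.8, 1.0), 88.8)
  expect_error(score_threshold(-5), "> 0")
  expect_error(score_threshold(100, 0), "fraction")
  expect_error(score_threshold(100, 1.2), "fraction")
})

test_that("per-receptor filtering and intersection reproduce the planted design", {
  gp <- gen_pose_table(seed = 7L)
  dec <- filter_and_intersect(gp$scores, gp$thresholds)
  sizes <- vapply(dec$passing, length, integer(1))
  expect_identical(sizes[["1O86"]], 34L)
  expect_identical(sizes[["4CA5"]], 38L)
  expect_identical(sizes[["4BZR"]], 24L)
  expect_identical(length(dec$final), 19L)
  expect_setequal(dec$final, gp$manifest$final)
  for (r in names(dec$passing))
    expect_setequal(dec$passing[[r]], gp$manifest$passing[[r]])
  # intersection size bounded by the smallest passing set; dropping a
  # receptor never shrinks the final set
  expect_lte(length(dec$final), min(sizes))
  two <- filter_and_intersect(gp$scores[gp$scores$receptor != "4BZR", ],
                              gp$thresholds)
  expect_true(all(dec$final %in% two$final))
})

test_that("single receptor final set equals its passing set; missing ligand fails", {
  poses <- data.frame(ligand = c("a", "a", "b"), receptor = "R1",
                      pose = c(1, 2, 1), score = c(40, 60, 20))
  dec <- filter_and_intersect(poses, c(R1 = 50))
  expect_identical(dec$final, "a")
  poses2 <- rbind(poses, data.frame(ligand = "a", receptor = "R2",
                                    pose = 1, score = 99))
  dec2 <- filter_and_intersect(poses2, c(R1 = 50, R2 = 50))
  expect_identical(dec2$final, "a")     # b absent from R2: fails R2
  expect_false(dec2$decisions$final_pass[dec2$decisions$ligand == "b"])
  expect_error(filter_and_intersect(poses2, c(R1 = 50)), "thresholds missing")
})

test_that("raising the threshold fraction monotonically shrinks passing sets", {
  gp <- gen_pose_table(seed = 9L)
  init <- gp$config$receptors
  prev <- NULL
  for (f in c(0.5, 0.7, 0.9)) {
    thr <- vapply(init, score_threshold, numeric(1), fraction = f)
    dec <- filter_and_intersect(gp$scores, thr)
    if (!is.null(prev))
      for (r in names(dec$passing))
        expect_true(all(dec$passing[[r]] %in% prev[[r]]))
    prev <- dec$passing
  }
})

test_that("residue frequency recovers the planted ranking and conserves counts", {
  gp <- gen_pose_table(seed = 7L)
  fp1 <- gp$fingerprints[gp$fingerprints$receptor == "1O86", ]
  rf <- residue_frequency(fp1, k = 4)
  expect_identical(rf$top[1:2], c("ALA354", "VAL518"))
  expect_setequal(rf$top, c("ALA354", "VAL518", "HIS353", "TYR523"))
  # counts conserved against the raw record multiset (records are unique
  # per pose/type/residue by construction)
  expect_identical(sum(rf$table$count), nrow(fp1))
  expect_true(all(rf$table$count <= 130))
  # planted per-contact counts recovered exactly
  plan <- gp$manifest$contact_counts
  for (i in seq_len(nrow(plan))) {
    got <- rf$table$count[rf$table$residue == plan$residue[i] &
                            rf$table$type == plan$type[i]]
    expect_identical(got, plan$n_poses[i])
  }
})

test_that("residue frequency on a single pose and tie expansion at rank k", {
  one <- data.frame(pose = 1L, type = c("HBOND", "HBOND"),
                    residue = c("ALA354", "HIS353"))
  rf <- residue_frequency(one, k = 1)
  expect_true(all(rf$table$count == 1L))
  expect_true(rf$tie_expanded)          # both tied at rank 1
  expect_setequal(rf$top, c("ALA354", "HIS353"))
  expect_error(residue_frequency(one, k = 0), "k must be")
})

test_that("pairwise overlap intersects residue sets per interaction class", {
  tabA <- data.frame(type = c("HBOND", "HBOND", "HYDROPHOBIC",
                              "ELECTROSTATIC"),
                     residue = c("ALA354", "HIS353", "VAL518", "HIS383"))
  tabB <- data.frame(type = c("HBOND", "HYDROPHOBIC"),
                     residue = c("ALA354", "VAL518"))
  ov <- pairwise_overlap(list(R1 = tabA, R2 = tabB))
  expect_identical(ov$shared[ov$class == "HBOND"], "ALA354")
  expect_identical(ov$shared[ov$class == "HYDROPHOBIC"], "VAL518")
  expect_identical(ov$shared[ov$class == "ELECTROSTATIC"], "none")
  same <- pairwise_overlap(list(R1 = tabA, R2 = tabA))
  expect_identical(same$shared[same$class == "HBOND"],
                   paste(sort(c("ALA354", "HIS353")), collapse = ";"))
  disjoint <- pairwise_overlap(list(R1 = tabA, R2 = data.frame(
    type = "HBOND", residue = "TYR520")))
  expect_true(all(disjoint$shared == "none"))
})

test_that("candidate triage classes ligands by their key-residue interactions", {
  fp <- rbind(
    data.frame(ligand = "NPATY", type = c("HBOND", "HYDROPHOBIC"),
               residue = c("ALA354", "VAL518")),
    data.frame(ligand = "VSAIGF", type = "HYDROPHOBIC", residue = "VAL518"),
    data.frame(ligand = "NCHEF", type = "HBOND", residue = "ALA354"),
    data.frame(ligand = "OTHER", type = "HBOND", residue = "HIS353"))
  cls <- select_candidates(c("NPATY", "VSAIGF", "NCHEF", "OTHER"), fp)
  expect_identical(cls$class[cls$ligand == "NPATY"], "both_key_residues")
  expect_identical(cls$class[cls$ligand == "VSAIGF"],
                   "only_VAL518_hydrophobic")
  expect_identical(cls$class[cls$ligand == "NCHEF"], "only_ALA354_hbond")
  expect_identical(cls$class[cls$ligand == "OTHER"], "neither")
  reps <- attr(cls, "representatives")
  expect_identical(nrow(reps), 4L)
  expect_error(select_candidates("NPATY", fp,
                                 key_residues = c(ALA354 = "WRONGTYPE")),
               "unknown interaction")
})
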