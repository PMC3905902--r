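test_that("chirality sign flips under reflection and survives proper transforms", {
  s <- make_phosphate(handedness = 1)
  m <- s$models[[1]]
  p <- as.numeric(m[m$name == "PA", c("x", "y", "z")])
  subs <- as.matrix(m[match(c("O5'", "O1A", "O2A", "O3A"), m$name),
                      c("x", "y", "z")])
  d <- chirality_descriptor(p, subs)
  expect_equal(d$sign, 1L)
  mir <- subs; mir[, 2] <- -mir[, 2]; pm <- p; pm[2] <- -pm[2]
  dm <- chirality_descriptor(pm, mir)
  expect_equal(dm$sign, -1L)
  expect_equal(abs(dm$signed_volume), abs(d$signed_volume), tolerance = 1e-9)
  set.seed(12)
  for (i in 1:100) {
    R <- random_rotation(); t <- rnorm(3, sd = 8)
    dr <- chirality_descriptor(apply_rigid(rbind(p), R, t)[1, ],
                               apply_rigid(subs, R, t))
    expect_equal(dr$sign, d$sign)
    expect_equal(dr$signed_volume, d$signed_volume, tolerance = 1e-9)
  }
})

test_that("a flat arrangement of the phosphate oxygens raises the planarity flag", {
  p <- c(0, 0, 0)
  flat <- rbind(c(1.5, 0, 0.02), c(-0.7, 1.3, -0.02), c(-0.7, -1.3, 0.01),
                c(1.6, 0.2, -0.01))
  d <- chirality_descriptor(p, flat)
  expect_true(d$planarity_flag)
  expect_equal(d$sign, 0L)
  expect_error(chirality_descriptor(p, flat[1:3, ]), "4 substituent")
})

test_that("inversion is detected between a tetrahedron and its Walden image", {
  pre <- make_phosphate(handedness = 1,
                        bond_lengths = c(1.61, 1.48, 1.52, 1.64))
  m <- pre$models[[1]]
  expect_equal(
    sapply(c("O5'", "O1A", "O2A", "O3A"), function(nm)
      dist_xyz(atom_xyz(pre, paste0("B/1/", nm)), atom_xyz(pre, "B/1/PA"))),
    c(1.61, 1.48, 1.52, 1.64), tolerance = 1e-9, ignore_attr = TRUE)
  post <- invert_phosphate(pre)
  mapping <- setNames(paste0("B/1/", c("O5'", "O1A", "O2A", "O3A")),
                      paste0("B/1/", c("O5'", "O1A", "O2A", "O3A")))
  call <- detect_inversion(pre, post, "B/1/PA", mapping)
  expect_true(call$inverted)
  expect_equal(abs(call$post$signed_volume), abs(call$pre$signed_volume),
               tolerance = 1e-9)
  # self-comparison retains configuration; the call is symmetric
  expect_false(detect_inversion(pre, pre, "B/1/PA", mapping)$inverted)
  rev_call <- detect_inversion(post, pre, "B/1/PA", mapping)
  expect_identical(rev_call$inverted, call$inverted)
})

test_that("substitution mapping carries the leaving-for-incoming replacement", {
  snaps <- make_snapshot_series()
  call <- detect_inversion(snaps$ES, snaps$EpiP, "B/201/PA",
                           ligand_mapping_es_to_pip)
  expect_true(call$inverted)
  expect_error(
    detect_inversion(snaps$ES, snaps$EpiP, "B/201/PA",
                     ligand_mapping_es_to_pip[1:3]),
    "4 substituents")
})

test_that("axis rotation recovers planted angles and is transform-invariant", {
  snaps <- make_snapshot_series(phosphate_rotation = 40)
  axis <- c("B/201/O5'", "B/201/PA")
  rotset <- c("B/201/O1A", "B/201/O2A", "B/201/OW")
  expect_equal(axis_rotation(snaps$EpiP, snaps$EP, axis, rotset), 40,
               tolerance = 1e-6)
  expect_equal(axis_rotation(snaps$EpiP, snaps$EpiP, axis, rotset), 0,
               tolerance = 1e-9)
  for (ang in c(15, 90, 179)) {
    sn <- make_snapshot_series(phosphate_rotation = ang)
    expect_equal(axis_rotation(sn$EpiP, sn$EP, axis, rotset), ang,
                 tolerance = 1e-6)
  }
  set.seed(3)
  moved <- transform_structure(snaps$EP, random_rotation(), rnorm(3, sd = 6))
  expect_equal(axis_rotation(snaps$EpiP, moved, axis, rotset), 40,
               tolerance = 1e-6)
})

test_that("atom displacement recovers planted shifts in the main-chain frame", {
  snaps <- make_snapshot_series(p_shift = 1.57)
  expect_equal(atom_displacement(snaps$EpiP, snaps$EP, "B/201/PA"), 1.57,
               tolerance = 1e-6)
  expect_equal(atom_displacement(snaps$EpiP, snaps$EpiP, "B/201/PA"), 0,
               tolerance = 1e-9)
  # invariant to pre/post order and to a common global transform
  expect_equal(atom_displacement(snaps$EP, snaps$EpiP, "B/201/PA"), 1.57,
               tolerance = 1e-6)
  set.seed(14)
  moved <- transform_structure(snaps$EP, random_rotation(), rnorm(3, sd = 9))
  expect_equal(atom_displacement(snaps$EpiP, moved, "B/201/PA"), 1.57,
               tolerance = 1e-6)
})

test_that("residue motion reports the terminal-dihedral change and side-chain displacement span", {
  snaps <- make_snapshot_series(asp95_rotation = 15.8, asp42_cg_shift = 1.2)
  mot <- residue_motion(snaps$apo, snaps$ES, "A/95")
  expect_equal(mot$rotation, 15.8, tolerance = 1e-6)
  expect_equal(max(mot$displacements), mot$max_displacement)
  same <- residue_motion(snaps$ES, snaps$ES, "A/95")
  expect_equal(same$rotation, 0, tolerance = 1e-9)
  expect_equal(same$max_displacement, 0, tolerance = 1e-9)
  # Asp42 Cg displacements across the snapshot series stay within the range
  states <- snaps[c("apo", "ES", "EpiP", "EP")]
  cg <- combn(length(states), 2, function(ij)
    atom_displacement(states[[ij[1]]], states[[ij[2]]], "A/42/CG"))
  expect_equal(max(cg), 1.2, tolerance = 1e-6)
})

test_that("motion reports tabulate displacements for many atoms at once", {
  snaps <- make_snapshot_series()
  tab <- motion_report(snaps$apo, snaps$ES,
                       c("A/95/OD2", "A/95/OD1", "A/42/CG", "A/93/O"))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$displacement >= 0))
  expect_equal(tab$displacement[tab$atom == "A/95/OD2"], 0.61,
               tolerance = 1e-6)
  expect_equal(tab$displacement[tab$atom == "A/93/O"], 0, tolerance = 1e-9)
})
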