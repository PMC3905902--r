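test_that("a single well-formed ATOM record parses to one atom with its printed fields", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  39      -4.000   3.000  -6.000  1.00 10.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(n_models(s), 1)
  m <- s$models[[1]]
  expect_equal(nrow(m), 1)
  expect_equal(m$name, "CA")
  expect_equal(m$resname, "ALA")
  expect_equal(m$chain, "A")
  expect_equal(m$resseq, 39L)
  expect_equal(c(m$x, m$y, m$z), c(-4, 3, -6))
  expect_equal(m$occ, 1)
  expect_equal(m$b, 10)
  expect_equal(m$element, "C")
})

test_that("write-then-read round-trips coordinates to PDB precision and metadata exactly", {
  s <- make_attack_site()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_lt(max(abs(coord_matrix(s) - coord_matrix(s2))), 1e-3)
  for (col in c("name", "resname", "chain", "resseq", "element", "serial"))
    expect_equal(s2$models[[1]][[col]], s$models[[1]][[col]])
})

test_that("multi-model structures round-trip as ordered MODEL blocks", {
  snaps <- make_snapshot_series()
  traj <- morph(list(snaps$EpiP, snaps$EP), frames_per_transition = 2)
  expect_equal(n_models(traj), 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, path)
  txt <- readLines(path)
  expect_equal(sum(startsWith(txt, "MODEL")), 3)
  expect_equal(sum(startsWith(txt, "ENDMDL")), 3)
  back <- read_structure(path)
  expect_equal(n_models(back), 3)
  for (k in 1:3)
    expect_lt(max(abs(coord_matrix(traj, k) - coord_matrix(back, k))), 1e-3)
})

test_that("altloc policies collapse alternate conformers as documented", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A  39      -4.000   3.000  -6.000  0.70 10.00           C",
    "ATOM      2  CA BALA A  39      -3.000   3.000  -6.000  0.30 10.00           C",
    "END"), path)
  hi <- read_structure(path, altloc_policy = "highest")
  expect_equal(nrow(hi$models[[1]]), 1)
  expect_equal(hi$models[[1]]$alt_loc, "A")
  expect_equal(hi$models[[1]]$occ, 0.7)
  all_ <- read_structure(path, altloc_policy = "all")
  expect_equal(nrow(all_$models[[1]]), 2)
  # occupancy tie resolves towards altloc A
  writeLines(c(
    "ATOM      1  CA BALA A  39      -3.000   3.000  -6.000  0.50 10.00           C",
    "ATOM      2  CA AALA A  39      -4.000   3.000  -6.000  0.50 10.00           C",
    "END"), path)
  tie <- read_structure(path, altloc_policy = "highest")
  expect_equal(tie$models[[1]]$alt_loc, "A")
})

test_that("malformed coordinate fields are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  39      -4.000   3.000  -6.000  1.00 10.00           C",
    "ATOM      2  CB  ALA A  39      -4.0x0   3.000  -6.000  1.00 10.00           C",
    "END"), path)
  expect_error(read_structure(path), "line 2")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("Bondi radii give the P+O sum and unknown elements are named in errors", {
  expect_equal(vdw_radius("P") + vdw_radius("O"), 3.32)
  expect_equal(vdw_radius("C"), 1.70)
  expect_error(vdw_radius("Xx"), "XX")
  expect_error(covalent_radius("Qq"), "QQ")
  tab <- default_radii()
  expect_true(all(tab$vdw > 0) && all(tab$covalent > 0))
  # override file replaces and extends the table
  cfg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# override", "P 1.90 1.10", "XX 2.00 1.00"), cfg)
  tab2 <- default_radii(cfg)
  expect_equal(vdw_radius("P", tab2), 1.90)
  expect_equal(covalent_radius("XX", tab2), 1.00)
})

test_that("bond perception splits bonded, non-bonded and clashing pairs", {
  mk <- function(d) {
    m <- rbind(
      data.frame(record = "HETATM", serial = 1, name = "P", alt_loc = "",
                 resname = "PO4", chain = "B", resseq = 1, icode = "",
                 x = 0, y = 0, z = 0, occ = 1, b = 0, element = "P"),
      data.frame(record = "HETATM", serial = 2, name = "O1", alt_loc = "",
                 resname = "PO4", chain = "B", resseq = 1, icode = "",
                 x = d, y = 0, z = 0, occ = 1, b = 0, element = "O"))
    pdb_structure(m)
  }
  expect_equal(nrow(perceive_bonds(mk(1.60))$bonds), 1)   # covalent P-O
  expect_equal(nrow(perceive_bonds(mk(2.52))$bonds), 0)   # short nonbonded contact
  g0 <- perceive_bonds(mk(0))
  expect_equal(nrow(g0$clashes), 1)
  expect_equal(nrow(g0$bonds), 0)
  # symmetry of the adjacency relation
  g <- perceive_bonds(make_attack_site())
  expect_true(all(g$bonds[, 1] < g$bonds[, 2]))
  expect_true(is_bonded(g, g$bonds[1, 2], g$bonds[1, 1]))
})

test_that("bonded and clash sets are disjoint for random coincident-free structures", {
  s <- make_attack_site(jitter = 0.05, seed = 7)
  g <- perceive_bonds(s)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_length(intersect(key(g$bonds), key(g$clashes)), 0)
})
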