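test_that("simulate-then-attack round-trips the planted site through files", {
  out <- withr::local_tempdir()
  run_analysis(list(command = "simulate", out = out, seed = 3,
                    d_attack = 2.52, inline_angle = 175))
  run_analysis(list(command = "attack", out = out,
                    input = file.path(out, "synthetic_site.pdb"),
                    require_dutpase_coordination = TRUE))
  rep <- jsonlite::read_json(file.path(out, "attack_report.json"))
  expect_equal(rep$n_sites, 1)
  expect_equal(rep$sites[[1]]$d_attack, 2.52, tolerance = 1e-3)
  expect_equal(rep$sites[[1]]$inline_angle, 175, tolerance = 1e-3)
  expect_equal(rep$sites[[1]]$nucleophile, "W/1/O")
  # parameters echoed for provenance
  expect_equal(rep$parameters$require_dutpase_coordination, TRUE)
})

test_that("nmr-fit on the simulated series recovers the generator rate; short series error out", {
  out <- withr::local_tempdir()
  run_analysis(list(command = "simulate", out = out, seed = 1, k = 0.02))
  run_analysis(list(command = "nmr_fit", out = out,
                    input = file.path(out, "synthetic_timeseries.tsv")))
  rep <- jsonlite::read_json(file.path(out, "nmr_fit_report.json"))
  expect_equal(rep$k, 0.02, tolerance = 1e-5)
  short <- peak_series(c(0, 10), matrix(c(1, 0.5, 0, 0.5), 2),
                       c("decay", "rise"))
  write_timeseries(short, file.path(out, "short.tsv"))
  expect_error(run_analysis(list(command = "nmr_fit", out = out,
                                 input = file.path(out, "short.tsv"))),
               "3 time points")
})

test_that("survey command flags an empty corpus and unknown commands are rejected", {
  out <- withr::local_tempdir()
  apo <- make_snapshot_series()$apo
  p <- file.path(out, "apo.pdb")
  write_structure(apo, p)
  run_analysis(list(command = "survey", out = out, inputs = p))
  rep <- jsonlite::read_json(file.path(out, "survey_report.json"))
  expect_true(rep$undefined)
  expect_equal(rep$n_pairs, 0)
  expect_null(rep$band_fraction)
  expect_error(run_analysis(list(command = "frobnicate", out = out)),
               "unknown command")
  expect_error(run_analysis(list(command = "attack", out = out,
                                 input = "/no/such.pdb")), "does not exist")
})

test_that("inversion, tbp and morph commands write coherent reports", {
  out <- withr::local_tempdir()
  snaps <- make_snapshot_series()
  es <- file.path(out, "es.pdb"); pip <- file.path(out, "pip.pdb")
  ep <- file.path(out, "ep.pdb")
  write_structure(snaps$ES, es)
  write_structure(snaps$EpiP, pip)
  write_structure(snaps$EP, ep)
  run_analysis(list(command = "inversion", out = out, pre = es, post = pip,
                    phosphorus = "B/201/PA",
                    mapping = as.list(ligand_mapping_es_to_pip)))
  inv <- jsonlite::read_json(file.path(out, "inversion_report.json"))
  expect_true(inv$inverted)
  tb <- file.path(out, "tbp.pdb")
  write_structure(make_tbp_site(axial_angle = 174), tb)
  run_analysis(list(command = "tbp", out = out, input = tb,
                    phosphorus = "B/1/PA"))
  tbp <- jsonlite::read_json(file.path(out, "tbp_report.json"))
  expect_equal(sort(unlist(tbp$axial)), c("N3A", "OW"))
  expect_equal(tbp$axial_angle, 174, tolerance = 1e-3)
  run_analysis(list(command = "morph", out = out, inputs = c(pip, ep),
                    frames_per_transition = 3))
  traj <- read_structure(file.path(out, "morph_trajectory.pdb"))
  expect_equal(n_models(traj), 4)
})

test_that("aggregation preserves order, deduplicates and rejects conflicts", {
  r1 <- data.frame(pair = "E->E-S", metric = "Asp95 Od2 shift", value = 0.61)
  r2 <- data.frame(pair = "E-S->E-piP", metric = "inversion", value = 1)
  r3 <- data.frame(pair = "E-piP->E-P", metric = "alphaP shift", value = 1.57)
  tab <- aggregate_snapshot_report(list(r1, r2, r3))
  expect_equal(tab$pair, c("E->E-S", "E-S->E-piP", "E-piP->E-P"))
  expect_identical(aggregate_snapshot_report(list(r1)), r1)
  expect_warning(dd <- aggregate_snapshot_report(list(r1, r2, r1)),
                 "duplicated")
  expect_equal(nrow(dd), 2)
  r1b <- r1; r1b$value <- 0.7
  expect_error(suppressWarnings(aggregate_snapshot_report(list(r1, r1b))),
               "conflicting")
})
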