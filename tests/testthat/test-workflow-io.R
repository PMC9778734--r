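test_that("cv tables round-trip and report malformed rows", {
  s <- cv_series(c(0.5, 1, 1.5), cbind(d_acid = c(4.3, 4.4, 4.5),
                                       d_nuc = c(5.1, 5.0, 4.9)), 310)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cv_table(s, tf)
  s2 <- read_cv_table(tf)
  expect_equal(colnames(s2$values), c("d_acid", "d_nuc"))
  expect_equal(s2$values, s$values, tolerance = 1e-9)
  expect_equal(s2$times, s$times, tolerance = 1e-9)

  # 2-column table: one labeled coordinate
  writeLines(c("# time_ps\td_acid", "1\t4.3", "2\t4.5"), tf)
  s3 <- read_cv_table(tf)
  expect_equal(colnames(s3$values), "d_acid")
  expect_equal(n_frames(s3), 2)

  writeLines(c("# time_ps\td_acid", "1\t4.3", "2"), tf)
  expect_error(read_cv_table(tf), "line 3")
  writeLines(c("# time_ps\td_acid", "1\tfour"), tf)
  expect_error(read_cv_table(tf), "line 2")
  writeLines(c("1 2", "3 4"), tf)
  expect_error(read_cv_table(tf), "header")
})

test_that("profile export marks empty bins", {
  x <- c(rep(0.1, 5), rep(0.9, 5))
  prof <- direct_projection(matrix(x, ncol = 1), n_bins = 5,
                            temperature = 310, range = list(c(0, 1)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "bin_center")
  expect_equal(length(lines), 6)
  expect_equal(sum(grepl("TRUE", lines)), 3)
})

test_that("multi-model PDB reading handles models and altlocs", {
  rings <- lapply(c("4C1", "2SO", "E3"), generate_ring_conformer)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(rings, tf)
  tr <- read_trajectory(tf)
  expect_equal(length(tr$coords), 3)
  expect_equal(nrow(tr$atoms), 6)
  expect_equal(tr$atoms$name, c("O5", "C1", "C2", "C3", "C4", "C5"))
  expect_equal(tr$coords[[2]], unname(rings[[2]]$positions),
               tolerance = 2e-3)

  # altloc duplicates: first kept, warning logged
  pdb <- c(
    "MODEL        1",
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END")
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, tf2)
  expect_warning(tr2 <- read_trajectory(tf2), "altloc")
  expect_equal(nrow(tr2$atoms), 2)
  expect_equal(tr2$coords[[1]][1, ], c(0, 0, 0))

  bad <- c("MODEL        1",
           "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
           "ENDMDL",
           "MODEL        2",
           "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
           "ATOM      2  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
           "ENDMDL")
  writeLines(bad, tf2)
  expect_error(read_trajectory(tf2), "inconsistent")
})

test_that("XYZ trajectories round-trip at the written precision", {
  rings <- lapply(c("4C1", "1C4"), generate_ring_conformer)
  tf <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(rings, tf)
  tr <- read_trajectory(tf)
  expect_equal(length(tr$coords), 2)
  # written with %12.6f: read-back is bitwise equal to the rounded values
  expect_identical(tr$coords[[1]],
                   unname(round(rings[[1]]$positions, 6)))
  # writer/reader inverse on its own output
  tf2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("run_config validates before any compute", {
  expect_error(run_config(list(temperature = -1)), class = "glycopmf_validation")
  expect_error(run_config(list(trajectory = "/nope/missing.pdb")),
               class = "glycopmf_validation")
  cfg <- list(cv_table = NULL,
              cvs = list(rc = list(formula = "reaction_coordinate",
                                   args = c("d_glyc", "d_acid"))))
  expect_error(run_config(cfg), "undefined")
  expect_error(run_config(list(windows = list(list(file = "/nope")))),
               class = "glycopmf_validation")
})

test_that("cmd_projection workflow is deterministic end to end", {
  b <- list(
    list(mean = c(d_acid = 4.6, d_nuc = 5.1, d_glyc = 1.5), cov = 0.02,
         weight = 0.75),
    list(mean = c(d_acid = 7.0, d_nuc = 8.0, d_glyc = 1.5), cov = 0.02,
         weight = 0.25))
  s <- generate_active_site_series(b, n_frames = 500, seed = 2)
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "cvs_in.tsv")
  write_cv_table(s, tab)
  cfg <- run_config(list(cv_table = tab, out_dir = file.path(dir, "o1"),
                         n_bins = 20, seed = 5))
  m1 <- run_pipeline(cfg, "cmd_projection")
  expect_true(file.exists(m1$cvs))
  expect_true(all(file.exists(m1$profiles)))
  expect_true(file.exists(m1$provenance))
  cfg$out_dir <- file.path(dir, "o2")
  m2 <- run_pipeline(cfg, "cmd_projection")
  for (k in seq_along(m1$profiles)) {
    expect_identical(readLines(m1$profiles[k]), readLines(m2$profiles[k]))
  }
})

test_that("umbrella_wham workflow emits every artifact", {
  dw <- potential_spec("double_well", list(barrier = 3, half_separation = 1))
  ws <- suppressWarnings(
    generate_umbrella_set(dw, centers = seq(-1.2, 1.2, by = 0.15),
                          force_constant = 120,
                          steps_per_window = 1200, seed = 5, dt = 5e-4))
  dir <- withr::local_tempdir()
  man <- lapply(seq_along(ws), function(j) {
    f <- file.path(dir, sprintf("w%02d.tsv", j))
    s <- ws[[j]]$series
    aug <- cv_series(s$times,
                     cbind(x = s$values[, 1], x_sq = s$values[, 1]^2),
                     s$temperature)
    write_cv_table(aug, f)
    list(file = f, center = ws[[j]]$center, force_constant = 120)
  })
  cfg <- run_config(list(windows = man, out_dir = file.path(dir, "out"),
                         t_eq = 0.1, n_bins = 80))
  m <- run_pipeline(cfg, "umbrella_wham")
  expect_true(file.exists(m$pmf))
  expect_true(file.exists(m$convergence))
  expect_true(file.exists(m$weights))
  expect_true(file.exists(m$projections[["x_sq"]]))
  expect_true(file.exists(m$provenance))
  expect_true(m$result$wham$solution$converged)
  # provenance carries config hash and seed
  prov <- jsonlite::read_json(m$provenance)
  expect_true(nzchar(prov$config_hash))
  expect_true(!is.null(prov$seed))
})

test_that("the CLI maps outcomes to exit codes", {
  dir <- withr::local_tempdir()
  expect_equal(suppressMessages(glycopmf_cli(character(0))), 2L)
  expect_equal(suppressMessages(glycopmf_cli("frobnicate")), 2L)
  s <- cv_series(1:50, rnorm(50), 310, "x")
  tab <- file.path(dir, "t.tsv")
  write_cv_table(s, tab)
  out <- file.path(dir, "p.tsv")
  expect_equal(suppressMessages(
    glycopmf_cli(c("project", "--table", tab, "--out", out))), 0L)
  expect_true(file.exists(out))
  expect_equal(suppressMessages(suppressWarnings(
    glycopmf_cli(c("project", "--table", "/nope.tsv")))), 3L)
  # simulate writes a manifest consumable by wham
  wdir <- file.path(dir, "wins")
  expect_equal(suppressMessages(suppressWarnings(
    glycopmf_cli(c("simulate", "--potential", "double_well", "--barrier",
                   "3", "--wells", "1", "--windows", "-1.2:1.2:0.1",
                   "--k", "150", "--steps", "400", "--seed", "42",
                   "--out", wdir)))), 0L)
  pmf <- file.path(dir, "pmf.tsv")
  expect_equal(suppressMessages(
    glycopmf_cli(c("wham", "--manifest", file.path(wdir, "manifest.json"),
                   "--bins", "60", "--teq", "0.01", "--out", pmf))), 0L)
  expect_true(file.exists(pmf))
})
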