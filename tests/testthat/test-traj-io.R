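# Trajectory containers and file round-trips.

test_that("configuration and trajectory validate their invariants", {
  expect_error(configuration(matrix(numeric(0), 0, 3), matrix(0, 1, 3)),
               "solute")
  expect_error(configuration(matrix(c(1, NA, 0), 1, 3), matrix(0, 1, 3)),
               "finite")
  conf <- configuration(matrix(0, 2, 3), matrix(numeric(0), 0, 3))
  expect_equal(nrow(conf$solvent), 0)

  f1 <- random_configuration(3, 5, frame_index = 1)
  f2 <- random_configuration(3, 7, frame_index = 2)
  expect_error(trajectory(list(f1, f2)), "same solute and solvent")
  expect_error(trajectory(list(f1), lag_time = -1), "lag_time")
  expect_error(trajectory(list(f1), box = c(1, 2)), "box")
})

test_that("a literal 3-frame XYZ file parses with the expected shape", {
  path <- withr::local_tempfile(fileext = ".xyz")
  lines <- character(0)
  set.seed(42)
  for (f in 1:3) {
    coords <- round(matrix(rnorm(21), 7, 3), 4)
    lines <- c(lines, "7", paste("frame", f),
               sprintf("%s %.4f %.4f %.4f",
                       c("C", "C", "O", "O", "O", "O", "O"),
                       coords[, 1], coords[, 2], coords[, 3]))
  }
  writeLines(lines, path)
  sel <- selection_spec(solute = list(elements = "C"),
                        solvent = list(elements = "O"))
  tr <- read_trajectory(path, "xyz", sel)
  expect_length(tr$frames, 3)
  expect_equal(nrow(tr$frames[[1]]$solute), 2)
  expect_equal(nrow(tr$frames[[1]]$solvent), 5)
  # index-based selection picks the same atoms
  tr2 <- read_trajectory(path, "xyz", selection_spec(solute = 1:2, solvent = 3:7))
  expect_identical(tr$frames[[2]]$solvent, tr2$frames[[2]]$solvent)
})

test_that("XYZ and PDB round-trips preserve coordinates to printed precision", {
  tr <- random_trajectory(n_frames = 4, m = 5, n = 9, seed = 11)
  sel <- selection_spec(solute = 1:5, solvent = 5 + 1:9)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, xyz, "xyz")
  back <- read_trajectory(xyz, "xyz", sel)
  for (t in seq_along(tr$frames)) {
    expect_equal(back$frames[[t]]$solute, tr$frames[[t]]$solute, tolerance = 1e-9)
    expect_equal(back$frames[[t]]$solvent, tr$frames[[t]]$solvent, tolerance = 1e-9)
  }

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, pdb, "pdb")
  # default water selection: HETATM O in HOH; solute via residue MOL
  backp <- read_trajectory(pdb, "pdb", selection_spec(solute = list(residues = "MOL")))
  expect_length(backp$frames, 4)
  for (t in seq_along(tr$frames)) {
    # PDB prints 3 decimals
    expect_lt(max(abs(backp$frames[[t]]$solute - tr$frames[[t]]$solute)), 5.1e-4)
    expect_lt(max(abs(backp$frames[[t]]$solvent - tr$frames[[t]]$solvent)), 5.1e-4)
  }
})

test_that("selection and format errors name the offending frame", {
  path <- withr::local_tempfile(fileext = ".xyz")
  # frame 2 has no oxygen
  writeLines(c("2", "f1", "C 0 0 0", "O 1 0 0",
               "2", "f2", "C 0 0 0", "N 1 0 0"), path)
  sel <- selection_spec(solute = list(elements = "C"),
                        solvent = list(elements = "O"))
  expect_error(read_trajectory(path, "xyz", sel), "frame 2")

  # inconsistent atom counts across frames
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "f1", "C 0 0 0", "O 1 0 0",
               "3", "f2", "C 0 0 0", "O 1 0 0", "O 2 0 0"), bad)
  expect_error(read_trajectory(bad, "xyz", sel), "format error")

  # overlapping selections
  ok <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "f1", "C 0 0 0", "O 1 0 0"), ok)
  expect_error(read_trajectory(ok, "xyz", selection_spec(1:2, 2)), "overlap")
  expect_error(read_trajectory("/nonexistent/file.xyz", "xyz", sel), "not found")
})

test_that("writing rejects empty input and unwritable paths", {
  tr <- random_trajectory(2, 3, 4, seed = 2)
  expect_error(write_trajectory(list(), tempfile()), "non-empty trajectory")
  expect_error(write_trajectory(tr, "/nonexistent_dir/x.xyz"), "cannot open")
  one <- trajectory(tr$frames[1], trajectory_id = "one")
  p <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(one, p, "xyz")
  expect_identical(substr(readLines(p)[1], 1, 1), "7")
})

test_that("tidy.trajectory returns one row per atom per frame", {
  tr <- random_trajectory(3, 2, 4, seed = 5)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3 * (2 + 4))
  expect_setequal(unique(td$role), c("solute", "solvent"))
})
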