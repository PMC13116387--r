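# PDB parsing, structure screening, box construction and RMSD.

test_that("PDB text parses with metadata; altlocs resolve to one atom", {
  parsed <- readPDB(toyPDBText())
  expect_equal(nrow(parsed$atoms), 10L)
  expect_equal(parsed$meta$resolution, 2.10)
  expect_match(parsed$meta$organism, "HOMO SAPIENS")
  expect_equal(parsed$meta$n_chains, 1L)
  expect_error(readPDB("REMARK nothing here\nEND"), "no ATOM")

  line <- GradeScreen:::.pdbLine
  alt <- c(
    sub("^(.{16}).", "\\1A",
        line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C")),
    sub("^(.{16}).", "\\1B",
        line("ATOM", 2, "CA", "GLY", "A", 1, 9, 9, 9, "C")),
    "END")
  # occupancies 0.70 / 0.30
  alt[1] <- sub("  1.00", "  0.70", alt[1])
  alt[2] <- sub("  1.00", "  0.30", alt[2])
  p2 <- readPDB(paste(alt, collapse = "\n"))
  expect_equal(nrow(p2$atoms), 1L)
  expect_equal(p2$atoms$x, 0)            # higher occupancy wins

  nores <- readPDB(paste(
    GradeScreen:::.pdbLine("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    "END", sep = "\n"))
  expect_true(is.na(nores$meta$resolution))
})

test_that("ligand extraction keeps first instance, excludes water", {
  parsed <- readPDB(toyPDBText())
  lig <- extractLigand(parsed, "LIG")
  expect_equal(nrow(lig$coords), 4L)
  expect_equal(lig$coords[1, ], c(x = 10, y = 0, z = 0))
  expect_error(extractLigand(parsed, "HOH"), "water")
  expect_error(extractLigand(parsed, "XYZ"), "not found")

  line <- GradeScreen:::.pdbLine
  twocopy <- paste(c(
    line("HETATM", 1, "C1", "LIG", "A", 500, 0, 0, 0, "C"),
    line("HETATM", 2, "C2", "LIG", "A", 500, 1.5, 0, 0, "C"),
    line("HETATM", 3, "C1", "LIG", "B", 500, 50, 0, 0, "C"),
    line("HETATM", 4, "C2", "LIG", "B", 500, 51.5, 0, 0, "C"),
    "END"), collapse = "\n")
  lig2 <- extractLigand(readPDB(twocopy), "LIG")
  expect_equal(nrow(lig2$coords), 2L)
  expect_equal(lig2$chain, "A")          # first chain only
})

test_that("structure screening enforces all four criteria, failing closed", {
  good <- list(method = "X-RAY DIFFRACTION", resolution = 2.1,
               n_chains = 1L, organism = "HOMO SAPIENS",
               ligand_mw = 434)
  expect_true(screenStructure(good)$accept)
  lowres <- good; lowres$resolution <- 3.2
  out <- screenStructure(lowres)
  expect_false(out$accept)
  expect_true("resolution-too-low" %in% out$reasons)
  # the resolution bound is strict: exactly 3.0 is rejected
  expect_false(screenStructure(modifyList(good, list(resolution = 3.0)))$accept)
  small <- good; small$ligand_mw <- 95
  expect_true("ligand-too-small" %in% screenStructure(small)$reasons)
  # the ligand-weight bound is inclusive: exactly 100 Da passes
  expect_true(screenStructure(modifyList(good, list(ligand_mw = 100)))$accept)
  unk <- good; unk$resolution <- NA
  expect_true("unknown-resolution" %in% screenStructure(unk)$reasons)
  multi <- good; multi$n_chains <- 2L
  expect_false(screenStructure(multi)$accept)
})

test_that("box construction matches the midpoint/extent+2delta rule", {
  b1 <- computeBox(matrix(c(0, 0, 0), 1), padding = 4)
  expect_equal(boxCenter(b1), c(0, 0, 0))
  expect_equal(boxSize(b1), c(8, 8, 8))
  b2 <- computeBox(rbind(c(0, 0, 0), c(2, 4, 6)), padding = 4)
  expect_equal(boxCenter(b2), c(1, 2, 3))
  expect_equal(boxSize(b2), c(10, 12, 14))
  b3 <- computeBox(rbind(c(-1, -1, -1), c(1, 1, 1)), padding = 0)
  expect_equal(boxCenter(b3), c(0, 0, 0))
  expect_equal(boxSize(b3), c(2, 2, 2))
  expect_error(computeBox(matrix(numeric(), 0, 3)), "no atoms")
  expect_error(computeBox(rbind(c(0, 0, 0)), padding = -1), "non-negative")
})

test_that("boxes contain their ligand with the padding margin and translate", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    coords <- matrix(stats::rnorm(3 * n, sd = 5), ncol = 3)
    delta <- stats::runif(1, 0, 6)
    box <- computeBox(coords, padding = delta)
    lo <- boxCenter(box) - boxSize(box) / 2
    hi <- boxCenter(box) + boxSize(box) / 2
    for (k in 1:3) {
      expect_true(all(coords[, k] - lo[k] >= delta - 1e-9))
      expect_true(all(hi[k] - coords[, k] >= delta - 1e-9))
    }
    t <- stats::rnorm(3)
    box2 <- computeBox(sweep(coords, 2, -t), padding = delta)
    expect_equal(boxCenter(box2), boxCenter(box) + t)
    expect_equal(boxSize(box2), boxSize(box))
  }
})

test_that("RMSD matches hand cases and behaves like a metric", {
  a <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(computeRMSD(a, a), 0)
  shift <- sweep(a, 2, -c(3, 4, 0))
  expect_equal(computeRMSD(a, shift), 5)
  two <- rbind(c(0, 0, 0), c(1, 1, 1))
  two2 <- rbind(c(2, 0, 0), c(1, 1, 1))
  expect_equal(computeRMSD(two, two2), sqrt(2))
  b <- a + matrix(stats::rnorm(30), ncol = 3)
  expect_equal(computeRMSD(a, b), computeRMSD(b, a))
  t <- c(-2, 5, 1)
  expect_equal(computeRMSD(sweep(a, 2, -t), sweep(b, 2, -t)),
               computeRMSD(a, b))
  expect_error(computeRMSD(a, a[1:5, ]), "mismatch")
})

test_that("redock verdict is inclusive at the threshold", {
  expect_true(redockCheck(0))
  expect_true(redockCheck(2.0))
  expect_false(redockCheck(2.01))
  expect_true(redockCheck(2.4, threshold = 2.5))
})

test_that("ligand weight estimate and Vina config block behave", {
  lig <- extractLigand(readPDB(toyPDBText()), "LIG")
  # C2 + O + N heavy atoms: 12.011*2 + 15.999 + 14.007
  expect_equal(ligandWeight(lig), 2 * 12.011 + 15.999 + 14.007,
               tolerance = 1e-6)
  txt <- vinaConfig(computeBox(rbind(c(0, 0, 0), c(2, 4, 6))))
  expect_match(txt, "center_x = 1")
  expect_match(txt, "size_z = 14")
})
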