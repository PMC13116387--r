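# Atom role typing and distance-cutoff contact detection.

ligAtoms <- function(...) {
  # rows: name, element, x, y, z
  rows <- list(...)
  data.frame(record = "HETATM",
             serial = seq_along(rows),
             name = vapply(rows, `[[`, "", 1),
             altloc = "",
             resid = "LIG", chain = "L", resno = 900L,
             x = vapply(rows, function(r) as.numeric(r[[3]]), 0),
             y = vapply(rows, function(r) as.numeric(r[[4]]), 0),
             z = vapply(rows, function(r) as.numeric(r[[5]]), 0),
             occupancy = 1,
             element = vapply(rows, `[[`, "", 2))
}

protAtoms <- function(...) {
  # rows: resid, name, element, resno, x, y, z
  rows <- list(...)
  data.frame(record = "ATOM",
             serial = seq_along(rows),
             name = vapply(rows, `[[`, "", 2),
             altloc = "",
             resid = vapply(rows, `[[`, "", 1),
             chain = "A",
             resno = vapply(rows, function(r) as.integer(r[[4]]), 0L),
             x = vapply(rows, function(r) as.numeric(r[[5]]), 0),
             y = vapply(rows, function(r) as.numeric(r[[6]]), 0),
             z = vapply(rows, function(r) as.numeric(r[[7]]), 0),
             occupancy = 1,
             element = vapply(rows, `[[`, "", 3))
}

test_that("ligand typing perceives donors, acceptors, ions and carbons", {
  hydroxyl <- typeAtoms(ligAtoms(list("C1", "C", 0, 0, 0),
                                 list("O1", "O", 1.4, 0, 0)),
                        "ligand")$atoms
  expect_true(hydroxyl$donor[2] && hydroxyl$acceptor[2])
  expect_false(hydroxyl$hydrophobic[1])  # carbon bonded to O
  lone <- typeAtoms(ligAtoms(list("C1", "C", 0, 0, 0)), "ligand")$atoms
  expect_true(lone$hydrophobic[1])
  carboxylate <- typeAtoms(ligAtoms(
    list("C1", "C", 0, 0, 0),
    list("O1", "O", 1.25, 0, 0),
    list("O2", "O", -0.625, 1.08, 0)), "ligand")$atoms
  expect_true(all(carboxylate$anion[2:3]))
  expect_false(any(carboxylate$donor[2:3]))
  amine <- typeAtoms(ligAtoms(list("N1", "N", 0, 0, 0)), "ligand")$atoms
  expect_true(amine$cation[1] && amine$donor[1] && amine$acceptor[1])
})

test_that("a benzene fixture yields one ring with the hand centroid", {
  th <- (0:5) * pi / 3
  args <- lapply(1:6, function(k)
    list(paste0("C", k), "C", 5 + 1.39 * cos(th[k]),
         2 + 1.39 * sin(th[k]), 1))
  typed <- typeAtoms(do.call(ligAtoms, args), "ligand")
  expect_equal(nrow(typed$rings), 1L)
  expect_equal(c(typed$rings$x, typed$rings$y, typed$rings$z),
               c(5, 2, 1), tolerance = 1e-9)
  expect_true(all(typed$atoms$hydrophobic))
})

test_that("protein typing follows the residue templates", {
  typed <- typeAtoms(protAtoms(
    list("SER", "OG", "O", 10, 0, 0, 0),
    list("ASP", "OD1", "O", 11, 5, 0, 0),
    list("LYS", "NZ", "N", 12, 10, 0, 0),
    list("LEU", "CD1", "C", 13, 15, 0, 0),
    list("GLY", "N", "N", 14, 20, 0, 0),
    list("GLY", "O", "O", 15, 25, 0, 0)), "protein")$atoms
  expect_true(typed$donor[1] && typed$acceptor[1])   # Ser OG
  expect_true(typed$anion[2])                        # Asp OD1
  expect_true(typed$cation[3])                       # Lys NZ
  expect_true(typed$hydrophobic[4])                  # Leu CD1
  expect_true(typed$donor[5])                        # backbone N
  expect_true(typed$acceptor[6])                     # backbone O
})

test_that("contacts respect the cutoffs for each kind", {
  lig <- typeAtoms(ligAtoms(list("C1", "C", 0, 0, 0),
                            list("O1", "O", 1.4, 0, 0)), "ligand")
  prot_near <- typeAtoms(protAtoms(
    list("SER", "OG", "O", 10, 1.4 + 3.4, 0, 0)), "protein")
  cs <- contacts(findContacts(lig, prot_near))
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$kind, "hydrogen-bond")
  expect_equal(cs$distance, 3.4, tolerance = 1e-9)
  prot_far <- typeAtoms(protAtoms(
    list("SER", "OG", "O", 10, 1.4 + 3.6, 0, 0)), "protein")
  expect_equal(nrow(contacts(findContacts(lig, prot_far))), 0L)

  loneC <- typeAtoms(ligAtoms(list("C1", "C", 0, 0, 0)), "ligand")
  leu42 <- typeAtoms(protAtoms(
    list("LEU", "CD1", "C", 20, 4.2, 0, 0)), "protein")
  expect_equal(nrow(contacts(findContacts(loneC, leu42))), 0L)
  leu39 <- typeAtoms(protAtoms(
    list("LEU", "CD1", "C", 20, 3.9, 0, 0)), "protein")
  expect_equal(contacts(findContacts(loneC, leu39))$kind, "hydrophobic")

  carbox <- typeAtoms(ligAtoms(
    list("C1", "C", 0, 0, 0),
    list("O1", "O", 1.25, 0, 0),
    list("O2", "O", -0.625, 1.08, 0)), "ligand")
  lys <- typeAtoms(protAtoms(
    list("LYS", "NZ", "N", 30, 1.25 + 5.0, 0, 0)), "protein")
  sb <- contacts(findContacts(carbox, lys))
  expect_true("salt-bridge" %in% sb$kind)
  expect_equal(min(sb$distance[sb$kind == "salt-bridge"]), 5.0,
               tolerance = 1e-9)
})

test_that("enlarging a cutoff never removes contacts of that kind", {
  cx <- generateToyComplex(n_hbond = 2, n_saltbridge = 1,
                           n_hydrophobic = 2, n_pi = 1, seed = 5)
  base <- contacts(profileComplex(cx$pdb, "LIG"))
  wide <- defaultCutoffs() + 0.3
  more <- contacts(profileComplex(cx$pdb, "LIG", cutoffs = wide))
  for (k in unique(base$kind))
    expect_gte(sum(more$kind == k), sum(base$kind == k))
})

test_that("contact summaries group per residue with minimum distance", {
  tab <- data.frame(
    kind = c("hydrogen-bond", "hydrogen-bond", "hydrophobic"),
    ligand_atom = c(1L, 2L, 3L),
    residue = c("SER10:A", "SER10:A", "LEU9:A"),
    distance = c(3.2, 3.4, 3.8))
  s <- summarizeContacts(tab)
  expect_equal(nrow(s), 2L)
  expect_equal(s$residue[1], "LEU9:A")   # ordered by residue number
  hb <- s[s$kind == "hydrogen-bond", ]
  expect_equal(hb$n, 2L)
  expect_equal(hb$min_distance, 3.2)
  expect_equal(nrow(summarizeContacts(
    data.frame(kind = character(), ligand_atom = integer(),
               residue = character(), distance = numeric()))), 0L)
})

test_that("recovered contacts equal planted truth and the all-pairs oracle", {
  for (s in c(3, 17)) {
    cx <- generateToyComplex(n_hbond = 2, n_saltbridge = 1,
                             n_hydrophobic = 1, n_pi = 1, seed = s)
    got <- sortedContacts(profileComplex(cx$pdb, "LIG"))
    expect_equal(got[, c("kind", "ligand_atom", "residue")],
                 cx$contacts[, c("kind", "ligand_atom", "residue")])
    expect_equal(got$distance, cx$contacts$distance, tolerance = 1e-3)
    # brute-force all-pairs oracle on the same typed atoms
    parsed <- readPDB(cx$pdb)
    lig_rows <- parsed$atoms[parsed$atoms$resid == "LIG", ]
    prot_rows <- parsed$atoms[parsed$atoms$record == "ATOM", ]
    oracle <- bfContacts(typeAtoms(lig_rows, "ligand"),
                         typeAtoms(prot_rows, "protein"))
    rownames(oracle) <- NULL
    expect_equal(got[, c("kind", "ligand_atom", "residue")],
                 oracle[, c("kind", "ligand_atom", "residue")])
    expect_equal(got$distance, oracle$distance, tolerance = 1e-9)
  }
  none <- generateToyComplex(n_hbond = 0, n_saltbridge = 0,
                             n_hydrophobic = 0, n_pi = 0, seed = 1)
  expect_equal(nrow(contacts(profileComplex(none$pdb, "LIG"))), 0L)
})
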