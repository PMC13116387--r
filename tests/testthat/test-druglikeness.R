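# Component scorers, aggregation, grading and library summaries.

fakeDesc <- function(mw = 300, logp = 2, hbd = 1, hba = 3, rotb = 2,
                     tpsa = 80, molar_refractivity = 80,
                     atom_count = 40, aromatic_rings = 2,
                     qed_raw = 0.67, sa_raw = 2, n_alerts = 0) {
  list(mw = mw, logp = logp, hbd = hbd, hba = hba, rotb = rotb,
       tpsa = tpsa, molar_refractivity = molar_refractivity,
       atom_count = atom_count, aromatic_rings = aromatic_rings,
       qed_raw = qed_raw, sa_raw = sa_raw, n_alerts = n_alerts)
}

test_that("rule-based scorers return the fraction of criteria passed", {
  expect_equal(scoreLipinski(fakeDesc()), 1.0)
  expect_equal(scoreLipinski(fakeDesc(mw = 600, logp = 6)), 0.5)
  expect_equal(scoreVeber(fakeDesc(rotb = 2, tpsa = 80)), 1.0)
  expect_equal(scoreVeber(fakeDesc(rotb = 12, tpsa = 150)), 0.0)
  expect_equal(scoreAdmet(fakeDesc()), 1.0)
  expect_equal(scoreAdmet(fakeDesc(mw = 100)), 5 / 6)
  expect_equal(scoreAdmet(fakeDesc(mw = 100, logp = 6, tpsa = 150,
                                   rotb = 12, hbd = 7,
                                   aromatic_rings = 5)), 0.0)
  # ethanol: only the logP band passes; MW (46 < 160), molar
  # refractivity (~12.9 < 40) and atom count (9 < 20) all fail
  eth <- computeDescriptors(c(e = "CCO"))
  expect_equal(scoreGhose(eth), 0.25)
  # olaparib passes all of Lipinski
  ola <- computeDescriptors(c(o = olaparibSMILES()))
  expect_equal(scoreLipinski(ola), 1.0)
})

test_that("QED passes through; SA maps affinely with clamping", {
  expect_equal(scoreQed(fakeDesc(qed_raw = 0.67)), 0.67)
  expect_equal(scoreSa(fakeDesc(sa_raw = 1)), 1.0)
  expect_equal(scoreSa(fakeDesc(sa_raw = 10)), 0.0)
  expect_equal(scoreSa(fakeDesc(sa_raw = 4.6)), 0.6)
  expect_warning(out <- scoreSa(fakeDesc(sa_raw = 12)), "clamp")
  expect_equal(out, 0.0)
})

test_that("alert penalty is 0.5 per alert with a floor at zero", {
  expect_equal(scoreAlerts(0), 1.0)
  expect_equal(scoreAlerts(1), 0.5)
  expect_equal(scoreAlerts(3), 0.0)
  tab <- detectAlerts(c(cat = "Oc1ccccc1O"), catalogs = "PAINS")
  expect_equal(scoreAlerts(tab), max(0, 1 - 0.5 * nrow(tab)))
})

test_that("aggregation reproduces hand-computed weighted sums", {
  w <- defaultWeights()
  expect_equal(sum(w), 1)
  all1 <- rep(1, 7); all0 <- rep(0, 7)
  expect_equal(aggregateTotal(all1), 1.0)
  expect_equal(aggregateTotal(all0), 0.0)
  v <- c(lipinski = 1, veber = 1, ghose = 1, qed = 0.5, sa = 1,
         admet = 0.5, pains = 1)
  expect_equal(aggregateTotal(v), 0.80)
  expect_error(aggregateTotal(all1, weights = w / 2), "sum to 1")
})

test_that("grade bands are left-closed at 0.85/0.70/0.55/0.40", {
  expect_equal(assignGrade(c(0.85, 0.8499)), c("A", "B"))
  expect_equal(assignGrade(c(0.70, 0.55, 0.40)), c("B", "C", "D"))
  expect_equal(assignGrade(0.39), "F")
  expect_equal(assignGrade(c(0, 1)), c("F", "A"))
  expect_error(assignGrade(1.2), "0,1")
  expect_error(assignGrade(-0.1), "0,1")
})

test_that("total score is bounded and monotone over random components", {
  set.seed(42)
  w <- defaultWeights()
  for (i in 1:500) {
    v <- stats::runif(7)
    names(v) <- names(w)
    s <- aggregateTotal(v)
    expect_gte(s, 0); expect_lte(s, 1)
    j <- sample(7, 1)
    v2 <- v
    v2[j] <- min(1, v[j] + stats::runif(1, 0, 1 - v[j]))
    s2 <- aggregateTotal(v2)
    expect_gte(s2, s - 1e-12)
    g <- assignGrade(min(max(s, 0), 1)); g2 <- assignGrade(min(max(s2, 0), 1))
    expect_lte(match(g2, c("A", "B", "C", "D", "F")),
               match(g, c("A", "B", "C", "D", "F")))
  }
})

test_that("score cards re-derive their totals from stored components", {
  sc <- scoreCompounds(c(a = "CCO", b = "c1ccccc1",
                         o = olaparibSMILES(),
                         cat = "Oc1ccccc1O"))
  tab <- cards(sc)
  w <- scoreWeights(sc)
  redo <- as.matrix(tab[, paste0("s_", names(w))]) %*% w
  expect_true(all(abs(as.numeric(redo) - tab$s_total) < 1e-12))
  # determinism on repeat
  sc2 <- scoreCompounds(c(a = "CCO", b = "c1ccccc1",
                          o = olaparibSMILES(),
                          cat = "Oc1ccccc1O"))
  expect_identical(cards(sc), cards(sc2))
})

test_that("an engineered ideal profile grades A", {
  # components forced to 1 by construction
  v <- c(lipinski = 1, veber = 1, ghose = 1, qed = 1, sa = 1,
         admet = 1, pains = 1)
  expect_equal(assignGrade(aggregateTotal(v)), "A")
})

test_that("library summaries conserve counts and round half-up", {
  pct <- gradePercentages(c(A = 25, B = 92, C = 37, D = 10, F = 7))
  expect_equal(unname(pct), c(14.6, 53.8, 21.6, 5.8, 4.1))
  one <- summarizeLibrary(data.frame(identifier = "x", s_total = 0.72,
                                     grade = "B"))
  expect_equal(unname(gradePercent(one)), c(0, 100, 0, 0, 0))
  two <- summarizeLibrary(data.frame(identifier = c("x", "y"),
                                     s_total = c(0.6, 0.8),
                                     grade = c("C", "B")))
  expect_equal(two@mean_total, 0.700)
  expect_equal(two@median_total, 0.700)
  expect_error(summarizeLibrary(data.frame()), "empty")
  # conservation on a random library
  set.seed(7)
  s <- stats::runif(57)
  tab <- data.frame(identifier = paste0("c", 1:57), s_total = s,
                    grade = assignGrade(s))
  gs <- summarizeLibrary(tab)
  expect_equal(sum(gradeCounts(gs)), 57L)
  expect_lt(abs(sum(gradePercent(gs)) - 100), 0.3)
})
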