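test_that("the contact relation follows the |i-j| > 1 and d <= 10 formula exactly", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(10.0, 0, 0), c(13.801, 0, 0))
  s <- caOnlyStructure(ca)
  cm <- buildContactMap(s, radius = 10)
  m <- cm@map
  expect_false(m["0", "1"])   # sequence neighbours at 3.8 A: excluded
  expect_true(m["0", "2"])    # |i-j| = 2, d = 10.0: inclusive boundary
  expect_false(m["1", "3"])   # |i-j| = 2, d = 10.001: outside
  expect_true(all(m == t(m)))
  expect_false(any(diag(m)))

  # strict reading drops the boundary pair
  cms <- buildContactMap(s, radius = 10, inclusive = FALSE)
  expect_false(cms@map["0", "2"])
})

test_that("annotation composes the grade and burial rules", {
  s <- fixtureBundle()
  sr <- fixtureSasa()
  si <- residueTable(s)$seqIndex
  grades <- stats::setNames(rep(1L, length(si)), si)
  grades[c("3", "4", "5")] <- c(7L, 6L, 9L)
  ann <- annotateResidues(s, grades, sr)
  expect_true(ann$conserved[ann$seqIndex == 3])
  expect_false(ann$conserved[ann$seqIndex == 4])   # grade 6 < 7
  expect_true(ann$conserved[ann$seqIndex == 5])
  expect_identical(ann$conserved, !is.na(ann$grade) & ann$grade >= 7L)

  # residues missing from the table are non-conserved, with a warning
  expect_warning(ann2 <- annotateResidues(s, grades[1:10], sr), "missing")
  expect_false(any(ann2$conserved[is.na(ann2$grade)]))
})

test_that("findPbs matches an exhaustive brute-force recount on random instances", {
  set.seed(909)
  for (rep_ in 1:100) {
    n <- sample(20:200, 1)
    ca <- matrix(runif(3 * n, 0, (4 * n)^(1/3) * 2.2), n, 3)
    conserved <- runif(n) < 0.35
    exposed <- runif(n) < 0.6
    s <- caOnlyStructure(ca)
    ann <- data.frame(seqIndex = seq_len(n) - 1L, aa = "A",
                      grade = ifelse(conserved, 8L, 3L),
                      conserved = conserved,
                      burialClass = ifelse(exposed, "exposed", "buried"),
                      relativeArea = ifelse(exposed, 0.5, 0.1))
    p <- findPbs(ann, buildContactMap(s, radius = 10))
    oracle <- bruteForcePbs(ca, conserved, exposed)
    expect_identical(sort(pbsCentres(p)), sort(as.integer(oracle$centres)))
    expect_identical(p@neighbourCounts[order(as.integer(names(p@neighbourCounts)))],
                     oracle$counts[order(as.integer(names(oracle$counts)))])
  }
})

test_that("no conserved residue means no centres; exactly 5 neighbours is not a centre", {
  s <- fixtureBundle()
  sr <- fixtureSasa()
  si <- residueTable(s)$seqIndex
  none <- stats::setNames(rep(3L, length(si)), si)
  ann <- annotateResidues(s, none, sr)
  p <- findPbs(ann, buildContactMap(s))
  expect_length(pbsCentres(p), 0L)

  # a hand-built cluster: centre at origin with exactly 5 qualifying
  # neighbours (all pairwise within 10 A, sequence-separated)
  ca <- rbind(c(0, 0, 0),
              c(50, 50, 50),       # spacer so |i-j| > 1 for all cluster pairs
              c(3, 0, 0), c(60, 60, 60),
              c(0, 3, 0), c(70, 70, 70),
              c(0, 0, 3), c(80, 80, 80),
              c(-3, 0, 0), c(90, 90, 90),
              c(0, -3, 0))
  n <- nrow(ca)
  cons <- rep(TRUE, n)
  ann2 <- data.frame(seqIndex = seq_len(n) - 1L, aa = "A", grade = 9L,
                     conserved = cons, burialClass = "exposed",
                     relativeArea = 0.5)
  p2 <- findPbs(ann2, buildContactMap(caOnlyStructure(ca)))
  expect_equal(unname(p2@neighbourCounts["0"]), 5L)
  expect_false(0L %in% pbsCentres(p2))    # needs MORE than 5
})

test_that("raising the grade threshold or shrinking the radius never adds centres", {
  s <- fixtureBundle()
  sr <- fixtureSasa()
  g <- plantConservation(s, sr, seed = 77)
  ann7 <- annotateResidues(s, g, sr, conservedMin = 7L)
  ann8 <- annotateResidues(s, g, sr, conservedMin = 8L)
  cm10 <- buildContactMap(s, radius = 10)
  cm8 <- buildContactMap(s, radius = 8)
  c7 <- pbsCentres(findPbs(ann7, cm10))
  c8 <- pbsCentres(findPbs(ann8, cm10))
  expect_true(all(c8 %in% c7))
  cR8 <- pbsCentres(findPbs(ann7, cm8))
  expect_true(all(cR8 %in% c7))
})

test_that("planted clusters are recovered and background-only tables give none", {
  s <- fixtureBundle()
  sr <- fixtureSasa()
  cm <- buildContactMap(s)
  g <- plantConservation(s, sr, seed = 5)
  planted <- attr(g, "planted")
  expect_gte(length(planted), 7L)
  p <- findPbs(annotateResidues(s, g, sr), cm)
  expect_gte(sum(pbsCentres(p) %in% planted), 1L)

  si <- residueTable(s)$seqIndex
  set.seed(11)
  bg <- stats::setNames(sample(1:6, length(si), replace = TRUE), si)
  p0 <- findPbs(annotateResidues(s, bg, sr), cm)
  expect_length(pbsCentres(p0), 0L)
})

test_that("residue input order does not change the detection", {
  s <- fixtureBundle()
  sr <- fixtureSasa()
  g <- plantConservation(s, sr, seed = 13)
  ann <- annotateResidues(s, g, sr)
  cm <- buildContactMap(s)
  p1 <- findPbs(ann, cm)
  perm <- sample(nrow(ann))
  p2 <- findPbs(ann[perm, ], cm)
  expect_identical(sort(pbsCentres(p1)), sort(pbsCentres(p2)))
})

test_that("per-repeat counting and the contiguous >5 run rule", {
  reps <- data.frame(repeat_id = paste0("SR", 1:4),
                     start = c(0L, 10L, 20L, 30L), end = c(9L, 19L, 29L, 39L))
  mkPbs <- function(centres) new("PbsResult", centres = as.integer(centres),
                                 neighbourCounts = stats::setNames(
                                   rep(6L, length(centres)), centres),
                                 params = list())
  # counts [6,7,2,6] -> flagged [SR1-SR2], [SR4]
  centres <- c(0:5, 10:16, 20:21, 30:35)
  p <- countPbsPerRepeat(mkPbs(centres), reps)
  expect_equal(unname(p@perRepeatCounts), c(6L, 7L, 2L, 6L))
  expect_equal(p@flaggedRegions, list(c("SR1", "SR2"), "SR4"))

  # all centres in one repeat
  p2 <- countPbsPerRepeat(mkPbs(10:13), reps)
  expect_equal(unname(p2@perRepeatCounts), c(0L, 4L, 0L, 0L))
  expect_length(p2@flaggedRegions, 0L)

  # counts all <= 5: nothing flagged
  p3 <- countPbsPerRepeat(mkPbs(c(0:4, 20:24)), reps)
  expect_length(p3@flaggedRegions, 0L)

  # a centre outside every repeat goes to 'unassigned' with a warning
  expect_warning(p4 <- countPbsPerRepeat(mkPbs(99L), reps), "outside")
  expect_equal(unname(p4@perRepeatCounts["unassigned"]), 1L)
})

test_that("the buried/exposed split among conserved residues is a proper fraction pair", {
  ann <- data.frame(seqIndex = 0:2, aa = "A", grade = c(9L, 8L, 7L),
                    conserved = TRUE,
                    burialClass = c("buried", "exposed", "exposed"),
                    relativeArea = c(0.1, 0.5, 0.6))
  expect_equal(conservedBurialSplit(ann), c(buried = 1/3, exposed = 2/3))

  ann$burialClass <- "exposed"
  expect_equal(conservedBurialSplit(ann), c(buried = 0, exposed = 1))

  ann10 <- data.frame(seqIndex = 0:9, aa = "A", grade = 9L, conserved = TRUE,
                      burialClass = c("buried", rep("exposed", 9)),
                      relativeArea = 0.5)
  expect_equal(conservedBurialSplit(ann10), c(buried = 0.1, exposed = 0.9))

  ann$conserved <- FALSE
  expect_warning(out <- conservedBurialSplit(ann), "no conserved")
  expect_true(all(is.na(out)))
})
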