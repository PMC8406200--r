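test_that("native contacts honour the distance cutoff inclusively", {
  two <- function(d) data.frame(chain = c("A", "B"), resno = c(1L, 1L),
                                resid = "ALA", x = c(0, d), y = 0, z = 0)
  expect_equal(length(nativeContacts(two(7.4), 7.5)), 1)
  expect_equal(length(nativeContacts(two(7.6), 7.5)), 0)
  expect_error(nativeContacts(two(5), cutoff = -1), "positive")
})

test_that("sequence-separation rule excludes near-diagonal pairs", {
  # straight chain at 3.8 A spacing: |i-j| = 2 distance is 7.6 > 7.5
  ca <- extractCA(straightChain(10))
  expect_equal(length(nativeContacts(ca, 7.5, minSeqSep = 2)), 0)
  # |i-j| = 1 pairs are within cutoff but excluded as bonds
  expect_equal(length(nativeContacts(ca, 7.5, minSeqSep = 1)), 9)
})

test_that("native contacts match a brute-force double loop", {
  ca <- extractCA(makeCompactChain(40, seed = 6))
  cl <- nativeContacts(ca, 7.5, 2L)
  xyz <- caCoords(ca)
  count <- 0
  for (i in 1:39) for (j in (i + 1):40) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= 7.5 && j - i >= 2) count <- count + 1
  }
  expect_equal(length(cl), count)
  expect_true(all(contactPairs(cl)$d0 <= 7.5))
  expect_true(all(contactPairs(cl)$j - contactPairs(cl)$i >= 2))
})

test_that("contact selection is invariant under rigid motion", {
  ca <- extractCA(makeCompactChain(30, seed = 3))
  set.seed(5)
  R <- randomRotation()
  ca2 <- ca
  xyz <- sweep(caCoords(ca) %*% t(R), 2, c(10, -4, 2), "+")
  ca2$x <- xyz[, 1]; ca2$y <- xyz[, 2]; ca2$z <- xyz[, 3]
  expect_equal(contactPairs(nativeContacts(ca2))[, c("i", "j")],
               contactPairs(nativeContacts(ca))[, c("i", "j")])
})

test_that("pocket expansion is an inclusive 6-Angstrom sphere", {
  mk <- function(d) structureFromAtoms(data.frame(
    chain = "A", resno = 1L, x = d, y = 0, z = 0))
  lig <- data.frame(x = 0, y = 0, z = 0)
  expect_equal(length(pocketResidues(mk(5.9), lig)), 1)
  expect_equal(length(pocketResidues(mk(6.1), lig)), 0)
  expect_equal(length(pocketResidues(mk(500), lig)), 0)
  expect_error(pocketResidues(mk(1), lig[0, ]), "empty")
})

test_that("planted pockets are recovered exactly", {
  tet <- makeTetramerAnalog(40, seed = 7)
  for (ch in tet$chains) {
    lig <- tet$ligands[tet$ligands$chain == ch, ]
    got <- pocketResidues(tet$structure, lig, 6.0)
    expect_equal(residueIds(got)[, c("chain", "resno")],
                 residueIds(tet$pockets[[ch]])[, c("chain", "resno")])
  }
})

test_that("interface residues respect the 0.75-nm cutoff and chain groups", {
  far <- structureFromAtoms(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), x = c(0, 100), y = 0, z = 0))
  expect_equal(length(interfaceResidues(far, "A", "B")), 0)
  near <- structureFromAtoms(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), x = c(0, 7.49), y = 0, z = 0))
  expect_equal(length(interfaceResidues(near, "A", "B")), 1)
  expect_error(interfaceResidues(near, "A", "A"), "overlap")
  expect_error(interfaceResidues(near, "A", "Z"), "absent")
})

test_that("planted junction patches are recovered exactly", {
  oct <- makeOctamerAnalog(40, seed = 5)
  got <- interfaceResidues(oct$structure, oct$tetramer1, oct$linkers, 7.5)
  expect_equal(residueIds(got)[, c("chain", "resno")],
               residueIds(oct$junctionPatches$tetramer1)[,
                 c("chain", "resno")])
  # the dynamics junction set is the union with the adjacent-tetramer side
  uni <- junctionResidues(oct$structure, oct$tetramer1, oct$linkers,
                          oct$tetramer2)
  expect_gte(length(uni), length(got))
})

test_that("residue sets map across structures by offset and chain pairing", {
  s <- straightChain(5)
  set <- residueSet("A", 1:3, label = "custom")
  expect_equal(residueIds(mapResidueSet(set, s, s))$resno, 1:3)
  shifted <- straightChain(5)
  a <- atomData(shifted)
  a$resno <- a$resno + 100L
  shifted <- structureFromAtoms(a)
  got <- mapResidueSet(set, s, shifted, resnoOffset = 100L)
  expect_equal(residueIds(got)$resno, 101:103)
  expect_error(mapResidueSet(set, s, shifted), "unmapped")
})

test_that("a pocket transfers onto a rotated copy via superposition pairing", {
  tet <- makeTetramerAnalog(20, seed = 9)
  moved <- applyTransform(
    rigidTransform(rotationMatrix(c(1, 2, 3), 50), c(5, 5, 5)),
    tet$structure)
  got <- mapResidueSet(tet$pockets$A, tet$structure, moved)
  expect_equal(residueIds(got), residueIds(tet$pockets$A))
  # and the mapped set selects the same beads after superposing back
  fit <- superpose(caCoords(extractCA(moved)),
                   caCoords(extractCA(tet$structure)))
  expect_lt(fit$rmsd, 1e-8)
})

test_that("residue sets serialize as TSV", {
  set <- residueSet(c("A", "A"), c(1L, 2L), "ALA", "pocket")
  f <- tempfile(fileext = ".tsv")
  writeResidueSet(set, f)
  back <- read.delim(f)
  expect_equal(back$resno, c(1, 2))
  expect_equal(unique(back$label), "pocket")
})
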