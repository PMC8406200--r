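test_that("screw decomposition of a z-axis screw is exact", {
  tr <- rigidTransform(rotationMatrix(c(0, 0, 1), 40), c(0, 0, 50))
  sc <- screwDecompose(tr)
  expect_equal(sc@twist, 40, tolerance = 1e-9)
  expect_equal(sc@rise, 50, tolerance = 1e-9)
  expect_equal(sc@repeatsPerTurn, 9, tolerance = 1e-9)
  expect_equal(abs(sc@axis), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(sc@handedness, 1)
})

test_that("a pure rotation has zero rise and a defined axis", {
  sc <- screwDecompose(rigidTransform(rotationMatrix(c(1, 0, 0), 90),
                                      c(0, 0, 0)))
  expect_equal(sc@twist, 90, tolerance = 1e-9)
  expect_equal(sc@rise, 0, tolerance = 1e-9)
  expect_error(
    screwDecompose(rigidTransform(diag(3), c(1, 0, 0))),
    "translation")
})

test_that("repeatsPerTurn times twist is exactly 360", {
  set.seed(17)
  for (i in 1:20) {
    tr <- rigidTransform(randomRotation(), rnorm(3, sd = 20))
    sc <- screwDecompose(tr)
    expect_equal(sc@repeatsPerTurn * sc@twist, 360, tolerance = 1e-9)
  }
})

test_that("random screws decompose and recompose to 1e-6", {
  set.seed(23)
  worst <- 0
  for (i in 1:200) {
    tr <- rigidTransform(randomRotation(), rnorm(3, sd = 30))
    back <- screwCompose(screwDecompose(tr))
    worst <- max(worst,
                 max(abs(rotation(back) - rotation(tr))),
                 max(abs(translation(back) - translation(tr))))
  }
  expect_lt(worst, 1e-6)
})

test_that("handedness flips under mirror reflection of the motion", {
  R <- rotationMatrix(c(0, 0, 1), 40)
  right <- screwDecompose(rigidTransform(R, c(0, 0, 50)))
  M <- diag(c(1, -1, 1))  # mirror across the xz plane
  left <- screwDecompose(rigidTransform(M %*% R %*% M,
                                        as.numeric(M %*% c(0, 0, 50))))
  expect_equal(right@handedness, 1)
  expect_equal(left@handedness, -1)
  expect_equal(left@twist, right@twist, tolerance = 1e-9)
})

test_that("handedness is invariant under a global rigid motion", {
  tr <- rigidTransform(rotationMatrix(c(0.3, 1, 0.2), 35), c(5, 1, 40))
  base <- screwDecompose(tr)
  set.seed(31)
  for (i in 1:5) {
    g <- rigidTransform(randomRotation(), rnorm(3, sd = 10))
    conj <- composeTransform(g, composeTransform(tr, invertTransform(g)))
    expect_equal(screwDecompose(conj)@handedness, base@handedness)
    expect_equal(screwDecompose(conj)@twist, base@twist, tolerance = 1e-8)
  }
})

test_that("unitTransform recovers a planted inter-oligomer transform", {
  unit <- makeCompactChain(25, seed = 10, chainId = "A")
  tr <- rigidTransform(rotationMatrix(c(0, 0, 1), 40), c(50, 3, -2))
  moved <- applyTransform(tr, unit)
  a2 <- atomData(moved); a2$chain <- "B"
  both <- structureFromAtoms(rbind(atomData(unit), a2))
  fit <- unitTransform(both, "A", "B")
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(rotation(fit$transform), rotation(tr), tolerance = 1e-6)
  ident <- unitTransform(both, "A", "A")
  expect_equal(rotation(ident$transform), diag(3), tolerance = 1e-8)
  expect_error(unitTransform(both, c("A", "B"), "B"), "pairing")
})

test_that("filament replication applies the transform iteratively", {
  unit <- makeRodUnit(20, seed = 2)
  tr <- rigidTransform(rotationMatrix(c(1, 0, 0), 40), c(50, 0, 0))
  fil <- replicateFilament(unit, tr, 5)
  copies <- filamentCopies(fil)
  expect_equal(length(copies), 5)
  # closed-form check: copy k equals transform applied k times
  xyz <- caCoords(extractCA(unit))
  cur <- xyz
  for (k in 2:5) {
    cur <- applyTransform(tr, cur)
    expect_equal(unname(caCoords(extractCA(copies[[k]]))), unname(cur),
                 tolerance = 1e-9)
  }
  expect_error(replicateFilament(unit, tr, 0), "at least 1")
  one <- filamentCopies(replicateFilament(unit, tr, 1))
  expect_identical(atomData(one[[1]]), atomData(unit))
})

test_that("nine 40-degree repeats close a full turn", {
  tr <- rigidTransform(rotationMatrix(c(1, 0, 0), 40), c(50, 0, 0))
  acc <- tr
  for (k in 2:9) acc <- composeTransform(tr, acc)
  expect_equal(rotation(acc), diag(3), tolerance = 1e-6)
})

test_that("kink angles are recovered from planted fixtures", {
  unit <- makeRodUnit(40, seed = 1)
  # coplanar duplicate -> 0 degrees
  flat <- makeHelicalFixture(unit, twist = 0.5, rise = 60, kink = 0, n = 2)
  s0 <- filamentStructure(flat$filament)
  expect_lt(kinkAngle(s0, "A1", "A2", "inertia"), 0.1)
  # planted 30-degree kink
  bent <- makeHelicalFixture(unit, twist = 0.5, rise = 60, kink = 30, n = 2)
  s30 <- filamentStructure(bent$filament)
  expect_equal(kinkAngle(s30, "A1", "A2", "inertia"), 30, tolerance = 0.1)
  # both axis rules return something sane
  expect_true(kinkAngle(s30, "A1", "A2", "plane") >= 0)
})

test_that("filament structures concatenate all copies", {
  unit <- makeRodUnit(15, seed = 3)
  fil <- makeHelicalFixture(unit, twist = 40, rise = 50, n = 4)$filament
  s <- filamentStructure(fil)
  expect_equal(nAtoms(s), 4 * nAtoms(unit))
  expect_equal(length(chainIds(s)), 4)
  expect_gt(filamentClashReport(fil), 2)
})
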