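test_that("Go model partitions every pair into bond, contact or repulsion", {
  ca <- extractCA(makeCompactChain(10, seed = 2))
  model <- buildGoModel(ca)
  pc <- pairClasses(model)
  expect_equal(nrow(pc), choose(10, 2))
  expect_equal(sum(pc$class == "bond"), 9)
  # each pair appears exactly once
  expect_false(anyDuplicated(pc[, c("i", "j")]) > 0)
})

test_that("a bonded dimer has one bond and no contacts or repulsions", {
  ca <- data.frame(chain = "A", resno = 1:2, resid = "ALA",
                   x = c(0, 3.8), y = 0, z = 0)
  model <- buildGoModel(ca)
  expect_equal(nrow(model@bonds), 1)
  expect_equal(length(model@contacts), 0)
})

test_that("inter-chain pairs are never classed as bonds", {
  tet <- makeTetramerAnalog(15, seed = 3)
  model <- buildGoModel(extractCA(tet$structure))
  info <- model@beadInfo
  expect_true(all(info$chain[model@bonds$i] == info$chain[model@bonds$j]))
})

test_that("two approaching hard beads exchange velocities head-on", {
  ca <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resid = "ALA",
                   x = c(0, 10), y = 0, z = 0)
  model <- buildGoModel(ca, nativeContacts(ca, 7.5))
  tr <- runDMD(model, nSteps = 1, temperature = 0.5, seed = 1,
               snapshotEvery = 1, thermostatRate = 0,
               initVelocities = rbind(c(1, 0, 0), c(-1, 0, 0)))
  v <- tr@meta$finalVelocities
  expect_equal(v[1, ], c(-1, 0, 0))
  expect_equal(v[2, ], c(1, 0, 0))
  # collision happened at the hardcore diameter
  f <- frames(tr)[[2]]
  expect_equal(f[2, 1] - f[1, 1], 3.6, tolerance = 1e-9)
})

test_that("microcanonical runs conserve energy and momentum", {
  model <- buildGoModel(extractCA(makeCompactChain(40, seed = 3)))
  tr <- runDMD(model, nSteps = 1e5, temperature = 0.5, seed = 7,
               snapshotEvery = 1000, thermostatRate = 0)
  drift <- diff(range(tr@energy))
  expect_lt(drift, 1e-9 * 1e5)  # well under 1e-9 per event
  v <- tr@meta$finalVelocities
  expect_equal(colSums(v), c(0, 0, 0), tolerance = 1e-9)
})

test_that("the thermostat holds the kinetic temperature within 5%", {
  model <- buildGoModel(extractCA(makeCompactChain(40, seed = 3)))
  tr <- runDMD(model, nSteps = 2e5, temperature = 0.5, seed = 11,
               snapshotEvery = 1000, thermostatRate = 1)
  expect_lt(abs(kineticTemperature(tr) - 0.5) / 0.5, 0.05)
})

test_that("identical seeds give bit-identical trajectories", {
  model <- buildGoModel(extractCA(makeCompactChain(25, seed = 8)))
  a <- runDMD(model, 2e4, seed = 5)
  b <- runDMD(model, 2e4, seed = 5)
  expect_identical(frames(a), frames(b))
  expect_identical(a@energy, b@energy)
  c <- runDMD(model, 2e4, seed = 6)
  expect_false(identical(frames(a), frames(c)))
})

test_that("a folded chain retains most native contacts at low temperature", {
  model <- buildGoModel(extractCA(makeCompactChain(40, seed = 3)))
  tr <- runDMD(model, 1e5, temperature = 0.5, seed = 2,
               snapshotEvery = 1000, thermostatRate = 1)
  f <- frames(tr)[[length(frames(tr))]]
  cp <- contactPairs(model@contacts)
  d <- sqrt(rowSums((f[cp$i, ] - f[cp$j, ])^2))
  expect_gt(mean(d <= 1.15 * cp$d0 + 1e-9), 0.9)
})

test_that("degenerate initial states are rejected", {
  # a pair sitting below the inner wall of its well must be rejected
  ca <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resid = "ALA",
                   x = c(0, 3.0), y = 0, z = 0)
  cl <- new("ContactList", pairs = data.frame(i = 1L, j = 2L, d0 = 6),
            cutoff = 7.5, minSeqSep = 2L, nBeads = 2L)
  model <- buildGoModel(ca, cl)
  expect_error(suppressWarnings(runDMD(model, 10, seed = 1)), "overlap")
  far <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resid = "ALA",
                    x = c(0, 100), y = 0, z = 0)
  m2 <- buildGoModel(far, nativeContacts(far, 7.5))
  expect_error(runDMD(m2, 10, seed = 1, thermostatRate = 0,
                      initVelocities = matrix(0, 2, 3)),
               "starvation")
})

test_that("d_rms reproduces closed-form cases", {
  # native frame
  xyz <- testCloud(6)
  expect_equal(computeDrms(xyz, xyz, 1:6), 0)
  # two residues: d0 = 5, d = 7 -> 2
  ref <- rbind(c(0, 0, 0), c(5, 0, 0))
  cur <- rbind(c(0, 0, 0), c(7, 0, 0))
  expect_equal(computeDrms(cur, ref, 1:2), 2.0)
  # three residues, all d0 = 5, all d = 6 -> sqrt(3 * 1 / 3) = 1
  tri0 <- 5 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  tri1 <- 6 / 5 * tri0
  expect_equal(computeDrms(tri1, tri0, 1:3), 1.0, tolerance = 1e-12)
  expect_error(computeDrms(tri1, tri0, 1), "at least 2")
})

test_that("d_rms is rigid-motion invariant and matches a brute-force oracle", {
  set.seed(13)
  ref <- testCloud(20)
  cur <- ref + matrix(rnorm(60, sd = 0.7), 20, 3)
  idx <- c(2, 5, 6, 9, 14, 17)
  d <- computeDrms(cur, ref, idx)
  # brute force over all pairs of the set
  acc <- 0; np <- 0
  for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
    i <- idx[a]; j <- idx[b]
    acc <- acc + (sqrt(sum((cur[i, ] - cur[j, ])^2)) -
                    sqrt(sum((ref[i, ] - ref[j, ])^2)))^2
    np <- np + 1
  }
  expect_equal(d, sqrt(acc / np), tolerance = 1e-12)
  moved <- sweep(cur %*% t(randomRotation()), 2, c(9, -3, 4), "+")
  expect_equal(computeDrms(moved, ref, idx), d, tolerance = 1e-9)
})

test_that("drms profiles pool replicas and apply burn-in", {
  model <- buildGoModel(extractCA(makeCompactChain(20, seed = 4)))
  trajs <- runReplicas(model, 1e4, replicas = 2, baseSeed = 3,
                       snapshotEvery = 500)
  prof <- drmsProfile(trajs, model, 1:8, burnInFraction = 1 / 3)
  expect_true(all(prof$perFrame$step >= 1e4 / 3))
  expect_equal(sort(unique(prof$perFrame$replica)), 1:2)
  expect_gt(prof$mean, 0)
  expect_error(drmsProfile(trajs, model, 1:8, burnInFraction = 1),
               "burn-in")
  # identical seeds give an identical pooled distribution
  again <- runReplicas(model, 1e4, replicas = 2, baseSeed = 3,
                       snapshotEvery = 500)
  expect_identical(drmsProfile(again, model, 1:8)$perFrame$drms,
                   drmsProfile(trajs, model, 1:8)$perFrame$drms)
})

test_that("trajectories export as multi-model PDB and XYZ", {
  model <- buildGoModel(extractCA(makeCompactChain(8, seed = 1)))
  tr <- runDMD(model, 2000, seed = 2, snapshotEvery = 1000)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, model, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), length(frames(tr)))
  x <- tempfile(fileext = ".xyz")
  writeTrajectory(tr, model, x, format = "xyz")
  expect_equal(readLines(x)[1], "8")
})
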