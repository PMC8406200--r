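test_that("an isolated sphere reproduces its analytic area", {
  a <- sasa(matrix(0, 1, 3), probe = 1.4, nPoints = 960, radii = 1.9)
  exact <- 4 * pi * (1.9 + 1.4)^2
  expect_lt(abs(a - exact) / exact, 0.01)
  # two atoms far apart are both fully exposed
  pair <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.9, 1.9))
  expect_equal(pair, rep(exact, 2), tolerance = 0.01 * exact)
})

test_that("overlapping equal spheres lose one spherical cap each", {
  R <- 3.0  # augmented radius: vdW 1.6 + probe 1.4
  d <- 4.0
  a <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), probe = 1.4, nPoints = 960,
            radii = c(1.6, 1.6))
  exact <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_lt(max(abs(a - exact)) / exact, 0.02)
})

test_that("unknown elements without radii are rejected by name", {
  atoms <- data.frame(chain = "A", resno = 1L, x = 0, y = 0, z = 0,
                      elesy = "XX")
  expect_error(sasa(atoms), "XX")
})

test_that("SASA quadrature converges when the point count doubles", {
  xyz <- caCoords(extractCA(makeCompactChain(30, seed = 2)))
  a1 <- sum(sasa(xyz, probe = 1.4, nPoints = 480, radii = rep(1.7, 30)))
  a2 <- sum(sasa(xyz, probe = 1.4, nPoints = 960, radii = rep(1.7, 30)))
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("SASA agrees with an independent implementation on a 50-atom set", {
  set.seed(11)
  coords <- matrix(rnorm(150, sd = 4), 50, 3)
  mine <- sum(sasa(coords, probe = 1.4, nPoints = 960, radii = rep(1.7, 50)))
  csv <- tempfile(fileext = ".csv")
  out <- tempfile()
  write.csv(as.data.frame(coords), csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, pandas as pd",
    "import biotite.structure as struc",
    "df = pd.read_csv(sys.argv[1])",
    "arr = struc.AtomArray(len(df))",
    "arr.coord = df.to_numpy()",
    "arr.element = np.array(['C'] * len(df))",
    "arr.atom_name = np.array(['CA'] * len(df))",
    "arr.res_name = np.array(['ALA'] * len(df))",
    "arr.res_id = np.arange(1, len(df) + 1)",
    "arr.chain_id = np.array(['A'] * len(df))",
    "s = struc.sasa(arr, probe_radius=1.4, point_number=960,",
    "               vdw_radii=np.full(len(df), 1.7))",
    "open(sys.argv[2], 'w').write(str(float(np.nansum(s))))"), script)
  status <- suppressWarnings(
    system2("python", c(script, csv, out), stdout = FALSE, stderr = FALSE))
  skip_if(status != 0, "python/biotite unavailable for cross-check")
  indep <- as.numeric(suppressWarnings(readLines(out)))
  expect_lt(abs(mine - indep) / indep, 0.02)
})

test_that("total SASA decreases monotonically as two groups approach", {
  blob <- caCoords(extractCA(makeCompactChain(15, seed = 6)))
  totals <- vapply(c(15, 11, 8, 6), function(d) {
    xyz <- rbind(blob, sweep(blob, 2, c(d, 0, 0), "+"))
    sum(sasa(xyz, radii = rep(1.7, nrow(xyz))))
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("buried interface area matches the two-sphere cap closed form", {
  s <- structureFromAtoms(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), x = c(0, 4), y = 0, z = 0,
    elesy = "C"))
  # augmented radius 1.6 + 1.4 = 3.0, centre distance 4
  rep <- buriedInterfaceArea(s, "A", "B", probe = 1.4, nPoints = 1920,
                             radii = c(C = 1.6))
  exact <- 2 * pi * 3.0 * (3.0 - 2.0)
  expect_lt(abs(interfaceArea(rep) - exact) / exact, 0.02)
  expect_equal(nrow(residueIds(rep@residuesA)), 1)
})

test_that("separated groups bury no area and list no residues", {
  s <- structureFromAtoms(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), x = c(0, 100), y = 0, z = 0))
  rep <- buriedInterfaceArea(s, "A", "B")
  expect_equal(interfaceArea(rep), 0, tolerance = 1e-9)
  expect_equal(length(rep@residuesA), 0)
  expect_equal(interfaceCensus(s, "A", "B")$count, 0)
})

test_that("interface area is symmetric in the two groups", {
  oct <- makeOctamerAnalog(20, seed = 4)
  ab <- buriedInterfaceArea(oct$structure, "A", oct$linkers, nPoints = 480)
  ba <- buriedInterfaceArea(oct$structure, oct$linkers, "A", nPoints = 480)
  expect_equal(interfaceArea(ab), interfaceArea(ba), tolerance = 1e-6)
})

test_that("per-residue buried areas sum to twice the interface area", {
  oct <- makeOctamerAnalog(20, seed = 4)
  rep <- buriedInterfaceArea(oct$structure, "A", oct$linkers,
                             nPoints = 480)
  expect_equal(sum(rep@perResidue$buried) / 2, interfaceArea(rep),
               tolerance = 1e-6)
})

test_that("the census counts a planted contact patch", {
  oct <- makeOctamerAnalog(40, seed = 5)
  cen <- interfaceCensus(oct$structure, oct$tetramer1, oct$linkers,
                         nPoints = 480)
  expect_gt(cen$count, 0)
  # every counted residue is geometrically near a linker
  near <- interfaceResidues(oct$structure, oct$tetramer1, oct$linkers, 7.5)
  got <- paste(cen$table$chain, cen$table$resno)
  expect_true(all(got %in%
    paste(residueIds(near)$chain, residueIds(near)$resno)))
})
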