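# Library enumeration, design arithmetic and the count simulator.

test_that("single-position enumeration yields 20 aa variants plus a stop", {
  lib <- buildLibrary(1100, 1100, stopSpacing = 11)
  expect_equal(nrow(lib), 21L)
  expect_equal(sum(lib$vclass == "nonsense"), 1L)   # first stop site
  expect_equal(sum(lib$vclass == "synonymous"), 1L)
  expect_setequal(lib$mutAa, c(aminoAcids(), "*"))
})

test_that("full-range enumeration matches a brute-force oracle", {
  # independent enumeration of the inclusive-stepping stop rule
  oracle <- 0L
  stops <- 0L
  for (p in 1059:1345) {
    oracle <- oracle + 20L
    if ((p - 1059) %% 11 == 0) {
      oracle <- oracle + 1L
      stops <- stops + 1L
    }
  }
  lib <- buildLibrary(1059, 1345, stopSpacing = 11)
  expect_equal(nrow(lib), oracle)
  expect_equal(sum(lib$vclass == "nonsense"), stops)     # 27
  expect_equal(sum(lib$vclass != "nonsense"), 287L * 20L)  # 5740
})

test_that("supplied wild-type sequence drives every variant's wtAa", {
  wt <- setNames(rep(c("M", "K", "T"), length.out = 7), 1059:1065)
  lib <- buildLibrary(1059, 1065, wtSequence = wt)
  expect_true(all(lib$wtAa == wt[as.character(lib$position)]))
  # synonymous variants are exactly the wt == mut rows
  expect_true(all((lib$mutAa == lib$wtAa) ==
                    (lib$vclass == "synonymous")))
})

test_that("enumeration is deterministic, ordered and validates input", {
  a <- buildLibrary(1100, 1110)
  b <- buildLibrary(1100, 1110)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(!is.unsorted(a$position))
  # within a position: alphabetical amino acids, stop last
  first <- a[a$position == 1100, ]
  expect_identical(first$mutAa,
                   c(sort(aminoAcids()), "*"))
  expect_error(buildLibrary(1200, 1100), "range")
  expect_error(buildLibrary(1100, 1100, stopSpacing = 0), "stopSpacing")
})

test_that("sample counting reproduces the 222-sample design", {
  expect_identical(countSamples(ExperimentDesign()), 222L)
  one <- ExperimentDesign(nLibraries = 1, nReplicates = 1,
                          conditions = "DMSO", nPostTimepoints = 1)
  expect_identical(countSamples(one), 2L)
  mid <- ExperimentDesign(nLibraries = 1, nReplicates = 2,
                          conditions = c("a", "b", "c"),
                          nPostTimepoints = 3)
  expect_identical(countSamples(mid), 20L)   # 2x1 + 2x3x3
})

test_that("sample count is linear in post time points and conditions, and
          per-condition T0 only increases it", {
  base <- ExperimentDesign(nLibraries = 1, nReplicates = 2,
                           conditions = letters[1:4], nPostTimepoints = 2)
  plus1 <- ExperimentDesign(nLibraries = 1, nReplicates = 2,
                            conditions = letters[1:4], nPostTimepoints = 3)
  # adding one harvest adds exactly n_rep x n_cond samples
  expect_equal(countSamples(plus1) - countSamples(base), 2L * 4L)
  unshared <- ExperimentDesign(nLibraries = 1, nReplicates = 2,
                               conditions = letters[1:4],
                               nPostTimepoints = 2, sharedT0 = FALSE)
  expect_gt(countSamples(unshared), countSamples(base))
  soloShared <- ExperimentDesign(nLibraries = 1, nReplicates = 2,
                                 conditions = "a", nPostTimepoints = 2)
  soloUnshared <- ExperimentDesign(nLibraries = 1, nReplicates = 2,
                                   conditions = "a", nPostTimepoints = 2,
                                   sharedT0 = FALSE)
  expect_equal(countSamples(soloShared), countSamples(soloUnshared))
})

test_that("ground truth honors the wild-type convention and planting", {
  lib <- buildLibrary(1225, 1230)
  des <- ExperimentDesign(conditions = c("crizotinib", "DMSO"))
  cfg <- SimConfig(seed = 9, resistanceSpec = data.frame(
    position = 1228, mutAa = "N", condition = "crizotinib", beta = 1.0))
  truth <- drawGroundTruth(lib, des, cfg)
  beta <- trueBeta(truth)
  syn <- lib$vclass == "synonymous"
  expect_true(all(beta[syn, ] == 0))
  planted <- lib$position == 1228 & lib$mutAa == "N"
  expect_equal(unname(beta[planted, "crizotinib"]), 1.0)
  # nonsense variants sit at the dead level -d in every condition
  expect_true(all(beta[lib$vclass == "nonsense", ] == -2))
  # reproducible under the same seed
  truth2 <- drawGroundTruth(lib, des, cfg)
  expect_identical(trueBeta(truth2), beta)
})

test_that("degenerate mixture sends every missense DMSO score to the LOF
          center", {
  lib <- buildLibrary(1100, 1102)
  des <- ExperimentDesign(conditions = "DMSO")
  cfg <- SimConfig(seed = 1, dmsoMixture = list(
    weightWt = 0, meanWt = 0, sdWt = 0, meanLof = -2, sdLof = 0))
  beta <- trueBeta(drawGroundTruth(lib, des, cfg))
  expect_true(all(beta[lib$vclass == "missense", "DMSO"] == -2))
})

test_that("planting a variant absent from the library is an error", {
  lib <- buildLibrary(1100, 1102)
  des <- ExperimentDesign(conditions = c("crizotinib", "DMSO"))
  cfg <- SimConfig(seed = 1, resistanceSpec = data.frame(
    position = 1300, mutAa = "A", condition = "crizotinib", beta = 1))
  expect_error(drawGroundTruth(lib, des, cfg), "absent")
})

test_that("noiseless neutral variants track the wild-type pool exactly", {
  fx <- noiselessSim(plant = data.frame(
    position = 1100, mutAa = "C", condition = "crizotinib", beta = 0))
  cm <- counts(fx$sim)
  cd <- colData(fx$sim)
  v <- variantInfo(fx$sim)
  idx <- which(v$position == 1100 & v$mutAa == "C")
  syn <- which(v$vclass == "synonymous")[1]
  cols <- which(cd$condition == "crizotinib" & cd$replicate == 1)
  # read share relative to a wild-type-encoding variant stays constant
  ratio <- cm[idx, cols] / cm[syn, cols]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("a non-growing variant keeps constant absolute abundance while
          wild type quadruples per interval", {
  fx <- noiselessSim(plant = data.frame(
    position = 1100, mutAa = "C", condition = "crizotinib", beta = -2))
  cm <- counts(fx$sim)
  cd <- colData(fx$sim)
  v <- variantInfo(fx$sim)
  idx <- which(v$position == 1100 & v$mutAa == "C")
  syn <- which(v$vclass == "synonymous")[1]
  cols <- which(cd$condition == "crizotinib" & cd$replicate == 1)
  cols <- cols[order(cd$timepoint[cols])]
  # counts are depth-scaled shares, so the variant/wild-type ratio tracks
  # absolute abundance: constant variant vs 4x-per-interval wild type
  ratio <- cm[idx, cols] / cm[syn, cols]
  expect_equal(unname(ratio / ratio[1]), 4^-(0:3), tolerance = 1e-9)
})

test_that("multinomial sampling hits the depth and is seed-reproducible", {
  lib <- buildLibrary(1100, 1109)
  des <- ExperimentDesign(conditions = c("crizotinib", "DMSO"))
  cfg <- SimConfig(depthPerSample = 1e6, seed = 77)
  truth <- drawGroundTruth(lib, des, cfg)
  sim1 <- simulateExperiment(truth, des, cfg)
  tot <- colSums(counts(sim1))
  expect_true(all(tot == 1e6))   # multinomial totals are exact
  sim2 <- simulateExperiment(truth, des, cfg)
  expect_identical(counts(sim1), counts(sim2))
  # distinct replicates use distinct streams
  cd <- colData(sim1)
  r1 <- counts(sim1)[, cd$condition == "DMSO" & cd$replicate == 1 &
                       cd$timepoint == 1]
  r2 <- counts(sim1)[, cd$condition == "DMSO" & cd$replicate == 2 &
                       cd$timepoint == 1]
  expect_false(identical(r1, r2))
})

test_that("shared T0 is identical across conditions within a replicate", {
  fx <- noiselessSim()
  cd <- colData(fx$sim)
  cm <- counts(fx$sim)
  t0a <- cm[, cd$condition == "crizotinib" & cd$replicate == 2 &
              cd$timepoint == 0]
  t0b <- cm[, cd$condition == "DMSO" & cd$replicate == 2 &
              cd$timepoint == 0]
  expect_identical(t0a, t0b)
})

test_that("negative depth is rejected", {
  lib <- buildLibrary(1100, 1101)
  des <- ExperimentDesign(conditions = "DMSO")
  cfg <- SimConfig(seed = 1)
  truth <- drawGroundTruth(lib, des, cfg)
  cfg@depthPerSample <- -1
  expect_error(simulateExperiment(truth, des, cfg), "depth")
})
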