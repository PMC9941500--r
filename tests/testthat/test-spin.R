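# Spherical spin permutations and the categorical/continuous map tests.

parcFix <- simulateParcellation(34, 5, coupling = 1, seed = 50)

test_that("spins are deterministic, surjective and hemisphere-preserving", {
  sp1 <- spinPermutations(parcFix$parcellation, 100, seed = 51)
  sp2 <- spinPermutations(parcFix$parcellation, 100, seed = 51)
  expect_identical(sp1, sp2)                      # byte-identical under seed
  expect_true(all(sp1 >= 1 & sp1 <= 34))
  # every rotated region maps somewhere within its hemisphere (here: all
  # left), repeated labels permitted
  hemi <- parcFix$parcellation@hemisphere
  expect_true(all(hemi[sp1] == rep(hemi, each = nrow(sp1))))

  # the identity rotation induces the identity relabeling
  idx <- gsemCortex:::.nearestRelabel(parcFix$parcellation, diag(3))
  expect_identical(idx, seq_len(34L))
})

test_that("two-hemisphere parcellations spin with mirrored rotations", {
  set.seed(52)
  xyz <- matrix(rnorm(60), 20, 3)
  xyz[1:10, 1] <- -abs(xyz[1:10, 1]); xyz[11:20, 1] <- abs(xyz[11:20, 1])
  parc <- sphericalParcellation(paste0("r", 1:20), xyz,
                                rep(c("left", "right"), each = 10))
  sp <- spinPermutations(parc, 50, seed = 53)
  hemi <- parc@hemisphere
  expect_true(all(hemi[sp] == rep(hemi, each = nrow(sp))))
  # a mirror-symmetric pair of centroids relabels symmetrically under the
  # mirrored rotation: check by constructing exact mirror pairs
  xyzM <- rbind(xyz[1:10, ], xyz[1:10, ] * matrix(c(-1, 1, 1), 10, 3, TRUE))
  parcM <- sphericalParcellation(paste0("m", 1:20), xyzM,
                                 rep(c("left", "right"), each = 10))
  spM <- spinPermutations(parcM, 25, seed = 54)
  expect_identical(unname(spM[, 11:20]), unname(spM[, 1:10] + 10L))
})

test_that("degenerate parcellations are rejected", {
  xyz <- matrix(c(1, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  parc <- sphericalParcellation(c("a", "b", "c"), xyz)
  expect_error(spinPermutations(parc, 5, seed = 1), "duplicate")
  parc2 <- sphericalParcellation(c("a", "b"), xyz[c(1, 3), ])
  expect_error(spinPermutations(parc2, 5, seed = 1), "at least 3")
})

test_that("identical categorical maps sit at the permutation floor", {
  sp <- spinPermutations(parcFix$parcellation, 200, seed = 55)
  res <- categoricalSpinTest(parcFix$mapA, parcFix$mapA, sp,
                             fisherDraws = 100000, nullDraws = 2000,
                             seed = 56)
  expect_equal(res@pSpin, 1 / 201)
  expect_equal(res@nSpins, 200L)
})

test_that("single-class maps degrade gracefully to pSpin = 1", {
  sp <- spinPermutations(parcFix$parcellation, 20, seed = 57)
  one <- setNames(rep("c1", 34), colnames(sp))
  expect_warning(res <- categoricalSpinTest(one, parcFix$mapB, sp, seed = 58),
                 "single class")
  expect_equal(res@pSpin, 1)
})

test_that("pSpin is invariant to joint relabeling of regions in both maps", {
  A <- parcFix$mapA; B <- parcFix$mapB
  parc <- parcFix$parcellation
  sp <- spinPermutations(parc, 100, seed = 59)
  r1 <- categoricalSpinTest(A, B, sp, fisherDraws = 2000, nullDraws = 500,
                            seed = 60)
  # reorder the regions everywhere at once (parcellation and both maps)
  set.seed(63); perm <- sample(34)
  parc2 <- sphericalParcellation(parc@regions[perm],
                                 parc@centroids[perm, ],
                                 parc@hemisphere[perm])
  sp2 <- spinPermutations(parc2, 100, seed = 59)
  r2 <- categoricalSpinTest(A[perm], B[perm], sp2, fisherDraws = 2000,
                            nullDraws = 500, seed = 60)
  expect_equal(r2@pSpin, r1@pSpin)
})

test_that("continuous spin test: perfect separation, degenerate maps, FDR null", {
  sp <- spinPermutations(parcFix$parcellation, 200, seed = 61)
  labels <- parcFix$mapA
  sepMap <- as.numeric(factor(labels))          # exact class means, no noise
  names(sepMap) <- names(labels)
  res <- continuousSpinTest(labels, list(sep = sepMap), sp)
  expect_equal(res$pSpin[1], 1 / 201)

  constMap <- setNames(rep(1, 34), names(labels))
  resC <- continuousSpinTest(labels, list(const = constMap), sp)
  expect_true(resC$degenerate[1])
  expect_equal(resC$pSpin[1], 1)

  oneGroup <- setNames(rep("c1", 34), names(labels))
  expect_warning(resG <- continuousSpinTest(oneGroup,
                                            list(sep = sepMap), sp),
                 "single-group")
  expect_equal(resG$pSpin[1], 1)

  # global null: independent maps yield ~no BH discoveries
  set.seed(62)
  maps <- lapply(1:60, function(i) setNames(rnorm(34), names(labels)))
  names(maps) <- paste0("m", 1:60)
  resN <- continuousSpinTest(labels, maps, sp)
  expect_lte(mean(resN$q < 0.05), 0.05)
})
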