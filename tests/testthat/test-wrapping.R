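test_that("traceOutline returns the external one-pixel ring", {
  # single pixel -> its 8 neighbors
  ring <- traceOutline(cbind(y = 5L, x = 5L), dims = c(10, 10))
  expect_equal(sum(ring), 8)
  expect_false(ring[5, 5])

  # filled 3x3 square -> 16-pixel ring
  sq <- as.matrix(expand.grid(y = 4:6, x = 4:6))
  ring <- traceOutline(sq, dims = c(10, 10))
  expect_equal(sum(ring), 16)

  # disk radius 10: ring equals box dilation minus the disk (set oracle)
  disk <- diskMask(40, 40, 20, 20, 10)
  ring <- traceOutline(disk)
  dil <- EBImage::dilate(EBImage::Image(disk * 1), matrix(1, 3, 3))
  oracle <- (as.matrix(EBImage::imageData(dil)) > 0.5) & !disk
  expect_identical(ring, oracle)

  expect_error(traceOutline(matrix(FALSE, 5, 5)), "empty")
})

test_that("wrapFraction measures circumference coverage", {
  H <- W <- 48
  disk <- diskMask(H, W, 24, 24, 10)
  ring <- traceOutline(disk)
  ann <- arcMask(H, W, 24, 24, 10, 12.5, 1.0)
  expect_equal(wrapFraction(ring, ann), 1.0)
  expect_equal(wrapFraction(ring, matrix(FALSE, H, W)), 0.0)
  # half annulus, several offsets: brute-force rasterized arc
  for (off in c(0, 1.1, 2.7, 4.4)) {
    half <- arcMask(H, W, 24, 24, 10, 12.5, 0.5, off)
    expect_lt(abs(wrapFraction(ring, half) - 0.5), 0.05)
  }
  expect_error(wrapFraction(matrix(FALSE, H, W), ann), "empty")
})

test_that("wrapFraction is translation-invariant and monotone in myelin", {
  H <- W <- 64
  disk <- diskMask(H, W, 24, 24, 8)
  ring <- traceOutline(disk)
  arc <- arcMask(H, W, 24, 24, 8, 10, 0.6, 0.3)
  f0 <- wrapFraction(ring, arc)
  # shift everything by whole pixels
  sh <- function(m, dy, dx) {
    out <- matrix(FALSE, H, W)
    out[(1 + dy):H, (1 + dx):W] <- m[1:(H - dy), 1:(W - dx)]
    out
  }
  expect_identical(wrapFraction(sh(ring, 7, 11), sh(arc, 7, 11)), f0)
  # adding myelin pixels never decreases the fraction
  set.seed(1)
  for (i in 1:20) {
    extra <- arc | (matrix(runif(H * W), H, W) < 0.02)
    expect_gte(wrapFraction(ring, extra), f0)
  }
})

test_that("wrapFraction is stable under 90-degree rotation of the field", {
  H <- W <- 48
  disk <- diskMask(H, W, 24, 24, 10)
  ring <- traceOutline(disk)
  rot90 <- function(m) t(m[nrow(m):1, ])
  for (cv in c(0.3, 0.6, 0.9)) {
    arc <- arcMask(H, W, 24, 24, 10, 12.5, cv, 0.8)
    f0 <- wrapFraction(ring, arc)
    f1 <- wrapFraction(rot90(ring), rot90(arc))
    expect_lt(abs(f1 - f0), 0.05)
    expect_lt(abs(f0 - cv), 0.07)
  }
})

test_that("sheath segments are the maximal qualifying runs", {
  prof <- function(cov) new("WrapProfile", pillarId = 1L,
                            coverage = cov, zStepUm = 2)
  s <- sheathSegments(prof(c(0.9, 0.9, 0.9, 0.9)))
  expect_equal(nrow(s), 1)
  expect_equal(s$length_um, 8)

  s <- sheathSegments(prof(c(0.9, 0.7, 0.9)))
  expect_equal(nrow(s), 2)
  expect_equal(s$length_um, c(2, 2))

  # the threshold is strict: exactly 0.8 does not qualify
  expect_equal(nrow(sheathSegments(prof(c(0.8, 0.8)))), 0)

  # span convention
  s <- sheathSegments(prof(c(0.9, 0.9, 0.9)), lengthConvention = "spans")
  expect_equal(s$length_um, 4)

  # 1000 random profiles against the brute-force run finder
  set.seed(4)
  for (i in 1:1000) {
    cov <- runif(sample(3:10, 1))
    got <- sheathSegments(prof(cov))
    want <- runsOracle(cov > 0.8)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$slice_start, unname(want[, "start"]))
      expect_equal(got$slice_end, unname(want[, "end"]))
      expect_equal(got$length_um,
                   unname(want[, "end"] - want[, "start"] + 1) * 2)
    }
  }
})

test_that("the fully-wrapped classifier applies both strict thresholds", {
  prof <- function(cov) new("WrapProfile", pillarId = 1L,
                            coverage = cov, zStepUm = 2)
  expect_true(classifyFullyWrapped(prof(c(0.9, 0.9, 0.9, 0.9))))   # 8 um
  expect_false(classifyFullyWrapped(prof(c(0.9, 0.9, 0.9))))       # 6 um
  expect_false(classifyFullyWrapped(prof(c(1, 1, 0.5, 1, 1))))     # 4 um max
  # consistency with sheathSegments on random profiles
  set.seed(8)
  for (i in 1:200) {
    p <- prof(runif(8))
    segs <- sheathSegments(p)
    expect_identical(classifyFullyWrapped(p),
                     nrow(segs) > 0 && max(segs$length_um) > 6)
  }
})

test_that("the wrapping index is fully-wrapped count per nucleus", {
  expect_equal(wrappingIndex(5, 20), 0.25)
  expect_equal(wrappingIndex(0, 20), 0)
  expect_error(wrappingIndex(3, 0), "nuclei")
})

test_that("noise-free field metrics equal the analytic ground truth", {
  sp <- noiseFree(syntheticFieldSpec(
    wrapEvents = rbind(wrapEvent(1, 1, 4, 1.0),
                       wrapEvent(5, 2, 5, 0.9, 1.2),
                       wrapEvent(9, 1, 2, 0.5)),
    nNuclei = 8, seed = 7))
  fl <- generateField(sp)
  fm <- computeFieldMetrics(fl$stack)
  truth <- fl$truth
  expect_identical(fm@nPillars, 9L)
  expect_identical(fm@nNuclei, truth@nNuclei)
  expect_identical(fm@nFullyWrapped,
                   sum(truth@perPillar$fully_wrapped))
  expect_equal(fm@wi, truth@expectedWI)
  expect_identical(perPillarTable(fm)$fully_wrapped,
                   unname(truth@perPillar$fully_wrapped))
  expect_equal(perPillarTable(fm)$max_segment_um,
               unname(truth@perPillar$max_contig_um))
})

test_that("a field with no myelin yields zero wrapped pillars", {
  fl <- generateField(noiseFree(syntheticFieldSpec(nNuclei = 5, seed = 3)))
  fm <- computeFieldMetrics(fl$stack)
  expect_identical(fm@nFullyWrapped, 0L)
  expect_length(sheathLengths(fm), 0)
  expect_equal(fm@wi, 0)
})

test_that("a field without nuclei is flagged as WI-undefined", {
  fl <- generateField(noiseFree(syntheticFieldSpec(
    wrapEvents = wrapEvent(1, 1, 4, 1.0), nNuclei = 0, seed = 2)))
  fm <- computeFieldMetrics(fl$stack)
  expect_false(fm@wiValid)
  expect_true(is.na(fm@wi))
  expect_identical(fm@nFullyWrapped, 1L)
})

test_that("adding myelin never lowers segment lengths or the WI", {
  sp <- noiseFree(syntheticFieldSpec(
    wrapEvents = wrapEvent(5, 2, 4, 0.9, 0.5), nNuclei = 5, seed = 13))
  fl <- generateField(sp)
  fm0 <- computeFieldMetrics(fl$stack)
  # extend the same event to more slices and higher coverage
  sp2 <- noiseFree(syntheticFieldSpec(
    wrapEvents = rbind(wrapEvent(5, 1, 6, 1.0, 0.5),
                       wrapEvent(1, 1, 4, 1.0)),
    nNuclei = 5, seed = 13))
  fm1 <- computeFieldMetrics(generateField(sp2)$stack)
  expect_gte(fm1@nFullyWrapped, fm0@nFullyWrapped)
  expect_gte(fm1@wi, fm0@wi)
  expect_gte(max(c(0, fm1@sheathLengthsUm)), max(c(0, fm0@sheathLengthsUm)))
})
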