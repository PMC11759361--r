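fakeMetrics <- function(manifest, wi, valid = TRUE) {
  data.frame(well_id = manifest$well_id, field_id = manifest$field_id,
             wi = wi, wi_valid = valid)
}

fakeManifest <- function(conds, wells = 3, fields = 9) {
  do.call(rbind, lapply(conds, function(cc)
    expand.grid(well_id = paste0(cc, "_w", seq_len(wells)),
                field_id = paste0("f", seq_len(fields)),
                condition = cc, stringsAsFactors = FALSE)))
}

test_that("aggregation pools per-field WIs across the wells of a condition", {
  man <- fakeManifest("DMSO")            # 3 wells x 9 fields
  met <- fakeMetrics(man, 0.2)
  s <- aggregateFields(man, met)
  expect_equal(s$n_fields, 27)
  expect_equal(s$mean_wi, 0.2)
  expect_equal(s$sem_wi, 0)

  # a WI-undefined field is excluded, with a message
  met$wi_valid[5] <- FALSE
  expect_message(s2 <- aggregateFields(man, met), "excluded")
  expect_equal(s2$n_fields, 26)

  # all fields invalid -> error
  met$wi_valid <- FALSE
  suppressMessages(expect_error(aggregateFields(man, met), "zero valid"))

  # unmatched metrics row -> error
  bad <- fakeMetrics(man, 0.2)
  bad$well_id[1] <- "nope"
  expect_error(aggregateFields(man, bad), "matching")
})

test_that("compound means scale by the control mean", {
  man <- fakeManifest(c("DMSO", "cmpA"))
  set.seed(1)
  met <- fakeMetrics(man, ifelse(man$condition == "DMSO", 0.2, 0.3))
  s <- aggregateFields(man, met)
  sc <- scaleByControl(s, "DMSO")
  expect_equal(sc$scaled_wi[sc$compound == "cmpA"], 1.5)
  expect_equal(sc$scaled_wi[sc$compound == "DMSO"], 1.0)
  expect_error(scaleByControl(s, "water"), "control")
})

test_that("hits require the mean to strictly exceed control mean + 2 sd", {
  man <- fakeManifest(c("DMSO", "hi", "lo", "edge"))
  # control fields: mean 1.0, sd 0.1 exactly
  ctrl <- rep(c(0.9, 1.1), length.out = 27)
  mc <- mean(ctrl); sdc <- sd(ctrl)
  wi <- numeric(nrow(man))
  wi[man$condition == "DMSO"] <- ctrl
  wi[man$condition == "hi"] <- mc + 2 * sdc + 0.1
  wi[man$condition == "lo"] <- mc + 2 * sdc - 0.05
  wi[man$condition == "edge"] <- mc + 2 * sdc   # exactly on the line
  s <- aggregateFields(man, fakeMetrics(man, wi))
  h <- callHits(s, "DMSO")
  expect_true(h$hit[h$compound == "hi"])
  expect_false(h$hit[h$compound == "lo"])
  expect_false(h$hit[h$compound == "edge"])
  expect_false(h$hit[h$compound == "DMSO"])
})

test_that("ranking is by descending scaled WI with alphabetical ties", {
  res <- data.frame(compound = c("A", "B", "C"),
                    scaled_wi = c(2.0, 1.5, 1.8))
  r <- rankCompounds(res)
  expect_equal(r$compound, c("A", "C", "B"))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(compound = c("B", "A"), scaled_wi = c(1.5, 1.5))
  expect_equal(rankCompounds(tie)$compound, c("A", "B"))

  # permutation invariance
  perm <- res[c(3, 1, 2), ]
  expect_equal(rankCompounds(perm)$compound, r$compound)
})

test_that("exact Mann-Whitney p matches the permutation oracle", {
  mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")

  set.seed(6)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    got <- mannWhitney(x, y)
    expect_equal(got$p, mwPermOracle(x, y), tolerance = 1e-12)
    # mirrored identity
    expect_equal(mannWhitney(y, x)$U, n1 * n2 - got$U)
  }

  # cross-check against wilcox.test for tie-free samples
  for (i in 1:10) {
    x <- sample(1:100, 4); y <- setdiff(sample(1:100, 8), x)[1:4]
    wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    got <- mannWhitney(x, y)
    expect_equal(got$U, unname(wt$statistic))
    expect_equal(got$p, wt$p.value, tolerance = 1e-12)
  }

  expect_equal(mannWhitney(c(1, 2), c(1, 2))$p, 1.0)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")

  # large samples switch to the tie-corrected normal approximation
  set.seed(2)
  big <- mannWhitney(rnorm(20), rnorm(20) + 1)
  expect_equal(big$method, "normal")
  expect_true(big$p > 0 && big$p < 0.05)
})

test_that("Kruskal-Wallis matches the hand rank-sum computation", {
  kw <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # ranks 1..6, group rank sums 3, 7, 11:
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 32/7
  expect_equal(kw$H, 32 / 7)
  expect_equal(kw$df, 2)

  same <- kruskalWallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # rank-based: invariant under monotone transforms
  g <- list(c(1, 5, 3), c(2, 8, 4), c(9, 7, 6))
  expect_equal(kruskalWallis(g)$H,
               kruskalWallis(lapply(g, function(v) exp(v)))$H)

  expect_error(kruskalWallis(list(1:3, 4:6)), "3 groups")
})

test_that("one-way ANOVA pairs carry a C(k,2) Bonferroni factor", {
  same <- anovaBonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3),
                               c = c(1, 2, 3)))
  expect_equal(same$F, 0, tolerance = 1e-10)
  expect_true(all(same$pairwise$p_adj == 1))

  # two groups: adjusted equals raw (single pair)
  two <- anovaBonferroni(list(a = c(1, 2, 3), b = c(2, 3, 5)))
  expect_equal(two$pairwise$p_adj, two$pairwise$p_raw)

  # four groups: factor is choose(4, 2) = 6, capped at 1
  set.seed(3)
  g4 <- lapply(1:4, function(i) rnorm(5, mean = i * 0.3))
  names(g4) <- letters[1:4]
  ab <- anovaBonferroni(g4)
  expect_equal(nrow(ab$pairwise), 6)
  expect_equal(ab$pairwise$p_adj, pmin(1, ab$pairwise$p_raw * 6))

  expect_error(anovaBonferroni(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("inner wells exclude the plate perimeter", {
  w <- innerWells(8, 12)
  expect_length(w, 60)
  expect_true(all(grepl("^[B-G](2|3|4|5|6|7|8|9|10|11)$", w)))
  expect_identical(innerWells(3, 3), "B2")
  expect_length(innerWells(4, 4), 4)
  expect_error(innerWells(2, 12), "too small")
})

test_that("the 2-SD rule has low FPR and high TPR at a 3-sigma shift", {
  # control ~ N(1, 0.1), n = 27 fields; compound shift 0 (null) or 0.3
  nRep <- 100
  man <- fakeManifest(c("DMSO", "cmp"))
  fp <- 0; tp <- 0
  set.seed(77)
  for (r in 1:nRep) {
    ctrl <- rnorm(27, 1, 0.1)
    null <- rnorm(27, 1, 0.1)
    eff <- rnorm(27, 1.3, 0.1)
    wiN <- ifelse(man$condition == "DMSO", ctrl, null)
    wiE <- ifelse(man$condition == "DMSO", ctrl, eff)
    sN <- aggregateFields(man, fakeMetrics(man, wiN))
    sE <- aggregateFields(man, fakeMetrics(man, wiE))
    fp <- fp + callHits(sN, "DMSO")$hit[2]
    tp <- tp + callHits(sE, "DMSO")$hit[2]
  }
  expect_lte(fp / nRep, 0.1)
  expect_gte(tp / nRep, 0.9)
})

test_that("manifest-driven quantification feeds aggregation end to end", {
  d <- tempfile()
  mp <- writePlateFixture(d)
  man <- loadManifest(mp)
  met <- quantifyManifest(man)
  expect_equal(nrow(met), 4)
  expect_true(all(met$n_pillars == 9))
  expect_true(all(met$n_fully_wrapped == 1))
  s <- aggregateFields(man, met)
  expect_setequal(s$condition, c("DMSO", "cmpA"))
  expect_equal(s$n_fields, c(2, 2))
  expect_equal(s$mean_wi, c(0.2, 0.2))
  res <- writeReport(s, file.path(d, "out"), "DMSO")
  expect_true(file.exists(file.path(d, "out", "condition_summary.csv")))
  expect_equal(res$scaled_wi, c(1, 1))
})
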