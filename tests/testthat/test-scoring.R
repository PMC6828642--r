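test_that("quantitative-map bins reproduce the scoring criteria", {
  cases <- list(list(v = 950, m = "t1_map", s = 4L),
                list(v = 1100, m = "t1_map", s = 3L),
                list(v = 1300, m = "t1_map", s = 2L),
                list(v = 1600, m = "t1_map", s = 1L),
                list(v = 1900, m = "t1_map", s = 0L),
                list(v = 2500, m = "t1_map", s = 0L),
                list(v = 95, m = "t2_map", s = 4L),
                list(v = 130, m = "t2_map", s = 2L),
                list(v = 210, m = "t2_map", s = 0L))
  for (cs in cases) {
    expect_identical(score_qmap_value(cs$v, cs$m), cs$s)
  }
  # half-open edges: the shared endpoint belongs to the upper bin
  expect_identical(score_qmap_value(1000, "t1_map"), 3L)
  expect_identical(score_qmap_value(2000, "t1_map"), 0L)
  expect_error(score_qmap_value(-5, "t1_map"), "positive")
})

test_that("bin lookup equals a brute-force scan and is monotone", {
  bins <- score_bins()
  brute <- function(v, edges) {
    # linear scan of the bin table, highest bin first
    if (v < edges[[1]]) return(4L)
    for (i in 1:4) if (v >= edges[[i]] && v < edges[[i + 1]]) return(4L - i)
    0L
  }
  set.seed(20)
  v <- runif(10000, 1, 3000)
  expect_identical(score_qmap_value(v, "t1_map", bins),
                   vapply(v, brute, integer(1), edges = bins$t1_edges_ms))
  sv <- sort(v)
  expect_true(all(diff(score_qmap_value(sv, "t1_map", bins)) <= 0))
})

test_that("region extraction takes the median and demands a present region", {
  tpl <- cached_template(small_geometry())
  ph <- build_phantom(40, template = tpl, jitter_cv = 0)
  idx <- tpl$region_idx$thalamus$right
  expect_equal(extract_region_value(ph$t1, ph, "thalamus", "right"),
               ph$t1[idx][[1]])
  # one extreme outlier voxel leaves the median unchanged
  t1 <- ph$t1
  t1[idx[[1]]] <- 1e6
  expect_equal(extract_region_value(t1, ph, "thalamus", "right"),
               extract_region_value(ph$t1, ph, "thalamus", "right"))
  # a devastated side has no extractable region
  lesioned <- insert_pathology(ph, "right")
  expect_error(extract_region_value(lesioned$t1, lesioned, "thalamus",
                                    "right"), "absent")
  expect_error(extract_region_value(ph$t1, ph, "amygdala", "right"),
               "not a scored region")
})

test_that("hemisphere rule: right by default, left on right-sided pathology", {
  expect_identical(select_hemisphere("none"), "right")
  expect_identical(select_hemisphere("left"), "right")
  expect_identical(select_hemisphere("right"), "left")
  expect_error(select_hemisphere("bilateral"), "cannot be scored")
})

test_that("scoring a right-devastated phantom never reads the right side", {
  tpl <- cached_template(small_geometry())
  ph <- insert_pathology(build_phantom(40, template = tpl, jitter_cv = 0),
                         "right")
  # poison every right-hemisphere voxel: scores must be unaffected
  poisoned <- ph
  right <- which(!tpl$left_mask)
  poisoned$t1[right] <- 1e9
  poisoned$t2[right] <- 1e9
  hemisphere <- select_hemisphere("right")
  a <- score_qmap_subject(ph, "t1_map", hemisphere)
  b <- score_qmap_subject(poisoned, "t1_map", hemisphere)
  expect_identical(a$scores$score, b$scores$score)
})

test_that("conventional ratio ladder respects its ordinal semantics", {
  ladder <- conventional_ladder()
  # isointense to surround scores 0 regardless of CSF contrast
  expect_identical(score_conventional_region(10, 10, 2, "t1_conventional",
                                             ladder), 0L)
  # above every threshold scores 4 (hyperintensity ladder)
  expect_identical(score_conventional_region(40, 10, 10, "t1_conventional",
                                             ladder), 4L)
  # T2: considerably hypointense to both references scores 4
  expect_identical(score_conventional_region(2, 20, 20, "t2_conventional",
                                             ladder), 4L)
  expect_error(score_conventional_region(0, 10, 10), "positive")
})

test_that("ladder equals brute-force enumeration of levels", {
  ladder <- conventional_ladder()
  brute <- function(roi, sur, csf, modality) {
    if (modality == "t1_conventional") {
      rs <- roi / sur; rc <- roi / csf
      rs_th <- ladder$rs_thresholds; rc_th <- ladder$rc_thresholds
    } else {
      rs <- sur / roi; rc <- csf / roi
      rs_th <- ladder$rs_thresholds_t2; rc_th <- ladder$rc_thresholds_t2
    }
    best <- 0L
    for (l in 1:4) if (rs >= rs_th[[l]] && rc >= rc_th[[l]]) best <- l
    best
  }
  set.seed(12)
  for (i in 1:500) {
    roi <- runif(1, 1, 60); sur <- runif(1, 1, 60); csf <- runif(1, 1, 60)
    m <- sample(c("t1_conventional", "t2_conventional"), 1)
    expect_identical(score_conventional_region(roi, sur, csf, m, ladder),
                     brute(roi, sur, csf, m))
  }
})

test_that("MTS totals the seven regions and rejects malformed input", {
  mk <- function(scores) data.frame(region = scored_regions(),
                                    score = scores)
  expect_equal(compute_mts(mk(rep(0L, 7)))$total, 0)
  expect_equal(compute_mts(mk(rep(4L, 7)))$total, 28)
  expect_equal(compute_mts(mk(c(4L, 4L, 3L, 2L, 1L, 0L, 0L)))$total, 14)
  set.seed(3)
  for (i in 1:25) {
    s <- sample(0:4, 7, replace = TRUE)
    expect_equal(compute_mts(mk(s))$total, sum(s))
  }
  expect_error(compute_mts(mk(rep(5L, 7))), "0..4")
  expect_error(compute_mts(mk(rep(1L, 7))[-1, ]), "exactly one")
  dup <- rbind(mk(rep(1L, 7)), mk(rep(1L, 7))[1, ])
  expect_error(compute_mts(dup), "exactly one")
})

test_that("simulated raters perturb within bounds, deterministically", {
  truth <- compute_mts(data.frame(region = scored_regions(),
                                  score = c(0L, 4L, 2L, 3L, 1L, 0L, 4L)))
  exact <- simulate_rater(truth, rater_model("r0", 0, seed = 1))
  expect_identical(exact$scores$score, truth$scores$score)
  r <- rater_model("r1", 0.9, seed = 4)
  a <- simulate_rater(truth, r)
  b <- simulate_rater(truth, r)
  expect_identical(a$scores$score, b$scores$score)
  for (i in 1:20) {
    out <- simulate_rater(truth, rater_model("rx", 0.9, seed = i))
    expect_true(all(out$scores$score >= 0 & out$scores$score <= 4))
    expect_equal(out$total, sum(out$scores$score))
  }
})

test_that("phantom MTS is monotone non-decreasing in maturational age", {
  tpl <- cached_template(small_geometry())
  ages <- seq(33, 46, by = 1)
  totals <- vapply(ages, function(a) {
    ph <- build_phantom(a, template = tpl, jitter_cv = 0)
    score_qmap_subject(ph, "t1_map", "right")$total
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_gt(totals[[length(totals)]], totals[[1]])
})
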