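test_that("contingency table matches hand enumeration and conserves totals", {
  pred <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  gt <- array(c(1L, 1L, 1L, 2L), c(4, 1, 1))
  tab <- contingency(pred, gt, foreground_restricted = FALSE)
  expect_equal(attr(tab, "n_total"), 4)
  expect_equal(tab$n[tab$i == 1 & tab$j == 1], 2)
  expect_equal(tab$n[tab$i == 2 & tab$j == 1], 1)
  expect_equal(tab$n[tab$i == 2 & tab$j == 2], 1)

  # identical segmentations -> diagonal table
  t2 <- contingency(gt, gt, foreground_restricted = FALSE)
  expect_true(all(t2$i == t2$j))

  expect_error(contingency(array(1L, c(2, 2, 2)), array(1L, c(2, 2, 1))), "grid")
})

test_that("foreground restriction drops exactly the ground-truth membrane voxels", {
  gt <- tiny_gt(c(24, 24, 24), count = 4, seed = 5)
  m <- extract_membrane(gt)
  tab <- contingency(gt, gt, foreground_restricted = TRUE)
  expect_equal(attr(tab, "n_total"), sum(!m$mask))
})

test_that("worked Rand example: 2 segments vs 1 segment", {
  pred <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  gt <- array(1L, c(4, 1, 1))
  r <- rand_scores(contingency(pred, gt, foreground_restricted = FALSE))
  expect_equal(unname(r["split"]), 1)
  expect_equal(unname(r["merge"]), 0.5)
  expect_equal(unname(r["f"]), 2 / 3)
})

test_that("worked VI example: 4 singletons vs 2 pairs", {
  pred <- array(1:4, c(4, 1, 1))
  gt <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  v <- vi_scores(contingency(pred, gt, foreground_restricted = FALSE))
  expect_equal(unname(v["split"]), 0.5)
  expect_equal(unname(v["merge"]), 1)
  expect_equal(unname(v["f"]), 2 / 3)
})

test_that("scores match the brute-force oracle on 100 random volumes", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(8:64, 1)
    kp <- sample(2:6, 1); kg <- sample(2:6, 1)
    pred <- sample.int(kp, n, replace = TRUE)
    gt <- sample.int(kg, n, replace = TRUE)
    tab <- contingency(array(pred, c(n, 1, 1)), array(gt, c(n, 1, 1)),
                       foreground_restricted = FALSE)
    r <- rand_scores(tab); v <- vi_scores(tab)
    br <- brute_rand(pred, gt)
    expect_equal(unname(r["split"]), br$split, tolerance = 1e-12)
    expect_equal(unname(r["merge"]), br$merge, tolerance = 1e-12)
    if (length(unique(pred)) > 1 && length(unique(gt)) > 1) {
      bv <- brute_vi(pred, gt)
      expect_equal(unname(v["split"]), bv$split, tolerance = 1e-12)
      expect_equal(unname(v["merge"]), bv$merge, tolerance = 1e-12)
    }
  }
})

test_that("pure refinement yields rand split = 1 and vi merge = 1 exactly", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 60
    gt <- sample.int(4, n, replace = TRUE)
    # refine: split each gt segment into random subsegments
    pred <- gt * 10 + sample.int(3, n, replace = TRUE)
    tab <- contingency(array(pred, c(n, 1, 1)), array(gt, c(n, 1, 1)),
                       foreground_restricted = FALSE)
    expect_equal(unname(rand_scores(tab)["split"]), 1)
    if (length(unique(gt)) > 1)
      expect_equal(unname(vi_scores(tab)["merge"]), 1, tolerance = 1e-12)
  }
})

test_that("scores are invariant under label permutation and in [0, 1]", {
  set.seed(3)
  n <- 50
  pred <- sample.int(5, n, replace = TRUE)
  gt <- sample.int(4, n, replace = TRUE)
  tab1 <- contingency(array(pred, c(n, 1, 1)), array(gt, c(n, 1, 1)), FALSE)
  perm <- sample(5)
  tab2 <- contingency(array(perm[pred], c(n, 1, 1)), array(gt, c(n, 1, 1)), FALSE)
  expect_equal(rand_scores(tab1), rand_scores(tab2))
  expect_equal(vi_scores(tab1), vi_scores(tab2))
  all6 <- c(rand_scores(tab1), vi_scores(tab1))
  expect_true(all(all6 >= 0 & all6 <= 1))
})

test_that("identical segmentations score (1,1,1) on both metrics", {
  gt <- tiny_gt(c(16, 16, 16), count = 3, seed = 1, radius_range = c(20, 80))
  sc <- score_report(gt, gt, foreground_restricted = TRUE)
  expect_equal(unlist(unclass(sc)), rep(1, 6), ignore_attr = TRUE)
})

test_that("degenerate single-segment cases follow the stated convention", {
  one <- array(1L, c(3, 1, 1))
  two <- array(c(1L, 1L, 2L), c(3, 1, 1))
  expect_equal(unname(vi_scores(contingency(one, one, FALSE))), c(1, 1, 1))
  expect_error(vi_scores(contingency(one, two, FALSE)), "degenerate")
  expect_error(rand_scores(data.frame(i = integer(0), j = integer(0),
                                      n = integer(0))), "empty")
})
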