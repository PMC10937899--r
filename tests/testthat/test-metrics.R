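gt_tab <- function(x, y, d = 10) {
  tibble::tibble(center_x = x, center_y = y, diameter = d)
}

test_that("matching handles identity, empty, and the mixed small case", {
  gt <- gt_tab(c(10, 30, 50, 70), c(10, 30, 50, 70))
  m <- match_picks(gt, gt)
  expect_equal(m$tp, 4)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)

  m0 <- match_picks(gt[0, ], gt)
  expect_equal(m0$tp, 0)
  expect_equal(m0$fn, 4)

  # 4 gt, 3 predictions, 2 within tolerance: P = 2/3, R = 1/2, F1 = 4/7
  pred <- tibble::tibble(center_x = c(10.5, 30.2, 99), center_y = c(10, 30, 99))
  m2 <- match_picks(pred, gt)
  expect_equal(m2$tp, 2)
  expect_equal(m2$fp, 1)
  expect_equal(m2$fn, 2)
  p <- m2$tp / (m2$tp + m2$fp); r <- m2$tp / (m2$tp + m2$fn)
  expect_equal(p, 2 / 3)
  expect_equal(r, 1 / 2)
  expect_equal(2 * p * r / (p + r), 4 / 7)
})

test_that("matching maximizes true positives like brute-force bipartite matching", {
  brute_max <- function(pred, gt, tol) {
    allowed <- sqrt(outer(gt$center_x, pred$center_x, `-`)^2 +
                      outer(gt$center_y, pred$center_y, `-`)^2) <=
      tol * gt$diameter
    best <- 0
    rec <- function(g, used) {
      if (g > nrow(gt)) return(0)
      r <- rec(g + 1, used)
      for (p in which(allowed[g, ])) {
        if (!(p %in% used)) r <- max(r, 1 + rec(g + 1, c(used, p)))
      }
      r
    }
    rec(1, integer(0))
  }
  withr::with_seed(14, {
    for (case in 1:8) {
      ng <- sample(2:8, 1); np <- sample(2:8, 1)
      gt <- gt_tab(runif(ng, 0, 40), runif(ng, 0, 40), d = 12)
      pred <- tibble::tibble(center_x = runif(np, 0, 40),
                             center_y = runif(np, 0, 40))
      expect_equal(match_picks(pred, gt)$tp, brute_max(pred, gt, 0.5))
    }
  })
})

test_that("spurious picks never raise precision; correct picks never lower recall", {
  gt <- gt_tab(c(20, 40, 60), c(20, 40, 60))
  pred <- tibble::tibble(center_x = c(20, 40), center_y = c(20, 40))
  m <- match_picks(pred, gt)
  prec <- function(m) m$tp / (m$tp + m$fp)
  rec <- function(m) m$tp / (m$tp + m$fn)
  worse <- match_picks(rbind(pred, tibble::tibble(center_x = 99, center_y = 99)), gt)
  expect_lte(prec(worse), prec(m))
  better <- match_picks(rbind(pred, tibble::tibble(center_x = 60, center_y = 60)), gt)
  expect_gte(rec(better), rec(m))
})

test_that("dice score matches the analytic two-disk overlap", {
  gt <- gt_tab(50, 50, d = 20)
  expect_equal(dice_score(tibble::tibble(center_x = 50, center_y = 50),
                          gt, 100, 100), 1, tolerance = 0.05)
  expect_equal(dice_score(tibble::tibble(center_x = numeric(0),
                                         center_y = numeric(0)),
                          gt, 100, 100), 0)
  # centers one radius apart: lens area 2 r^2 cos^-1(1/2) - (r/2) sqrt(3) r
  r <- 10
  inter <- 2 * r^2 * acos(0.5) - (r / 2) * sqrt(4 * r^2 - r^2)
  expected <- 2 * inter / (2 * pi * r^2)
  got <- dice_score(tibble::tibble(center_x = 60, center_y = 50), gt, 110, 110)
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("evaluate reports per-micrograph rows plus a macro average", {
  gt <- list(a = gt_tab(c(10, 30), c(10, 30)),
             b = gt_tab(c(20, 40, 60), c(20, 40, 60)))
  pred <- tibble::tibble(micrograph = c("a", "a", "b", "b", "b"),
                         center_x = c(10, 30, 20, 40, 60),
                         center_y = c(10, 30, 20, 40, 60))
  rep <- evaluate(pred, gt, dims = c(80, 80))
  expect_equal(nrow(rep), 3)
  expect_equal(rep$micrograph[3], "average")
  expect_equal(rep$precision, c(1, 1, 1))
  expect_equal(rep$recall, c(1, 1, 1))
  expect_equal(rep$f1, c(1, 1, 1))
  expect_equal(rep$dice[1:2], c(1, 1), tolerance = 0.05)
  # aggregate counts are sums
  expect_equal(rep$tp[3], sum(rep$tp[1:2]))
  # zero-prediction micrograph flagged with precision 0
  rep0 <- evaluate(pred[pred$micrograph == "a", ], gt, dims = c(80, 80))
  expect_equal(rep0$precision[rep0$micrograph == "b"], 0)
  expect_true(rep0$undefined_precision[rep0$micrograph == "b"])
  # CSV serialization
  csv <- withr::local_tempfile(fileext = ".csv")
  evaluate(pred, gt, dims = c(80, 80), csv = csv)
  expect_equal(nrow(utils::read.csv(csv)), 3)
})

test_that("a jittered-and-corrupted copy of the truth recovers the implanted rates", {
  # 10% dropped, 10% spurious, sigma = 0.1 * diameter jitter
  withr::with_seed(77, {
    n <- 500
    gt <- gt_tab(runif(n, 20, 480), runif(n, 20, 480), d = 10)
    keep <- sample(n, round(0.9 * n))
    pred <- tibble::tibble(
      center_x = c(gt$center_x[keep] + rnorm(length(keep), 0, 1),
                   runif(round(0.1 * n), 20, 480)),
      center_y = c(gt$center_y[keep] + rnorm(length(keep), 0, 1),
                   runif(round(0.1 * n), 20, 480)))
  })
  m <- match_picks(pred, gt)
  p <- m$tp / (m$tp + m$fp)
  r <- m$tp / (m$tp + m$fn)
  # binomial error at n = 500 is ~0.013; allow 3 sigma plus chance hits
  expect_gt(p, 0.87)
  expect_gt(r, 0.87)
  expect_lt(abs(p - 0.9), 0.05)
  expect_lt(abs(r - 0.9), 0.05)
})
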