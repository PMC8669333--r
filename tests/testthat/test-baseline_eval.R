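test_that("Otsu's threshold separates two-level images exactly", {
  set.seed(30)
  img <- matrix(sample(c(0.2, 0.8), 400, replace = TRUE, prob = c(0.6, 0.4)),
                20, 20)
  th <- otsu_threshold(img)
  expect_gt(th, 0.2); expect_lt(th, 0.8)
  expect_equal(otsu_segment(img), (img == 0.8) * 1)
})

test_that("Otsu's threshold equals the exhaustive between-class scan", {
  set.seed(31)
  for (i in 1:10) {
    img <- rand_image(64)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("Otsu lands between the modes of a bimodal mixture", {
  set.seed(32)
  x <- c(rnorm(3000, 0.3, 0.05), rnorm(3000, 0.7, 0.05))
  img <- matrix(pmin(pmax(x, 0), 1), 60, 100)
  th <- otsu_threshold(img)
  expect_gt(th, 0.4); expect_lt(th, 0.6)
})

test_that("Otsu degenerate and inversion conventions hold", {
  const <- matrix(0.4, 8, 8)
  expect_equal(otsu_threshold(const), 0.4)
  expect_equal(otsu_segment(const), matrix(0, 8, 8))  # strict >: empty fg
  set.seed(33)
  img <- rand_image(32)
  expect_equal(otsu_segment(img, invert = TRUE), otsu_segment(1 - img))
  # every pixel is assigned exactly one class
  seg <- otsu_segment(img)
  expect_true(all(seg %in% c(0, 1)))
})

test_that("confusion counts enumerate pixels correctly", {
  set.seed(34)
  g <- rand_mask(10)
  cc <- confusion_counts(g, g)
  expect_equal(cc$FP + cc$FN, 0)
  cc2 <- confusion_counts(1 - g, g)
  expect_equal(cc2$TP + cc2$TN, 0)
  pred <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0), 3, 3)
  gt   <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  cc3 <- confusion_counts(pred, gt)
  expect_equal(cc3, list(TP = 2, FP = 2, TN = 3, FN = 2))
  expect_equal(with(cc3, TP + FP + TN + FN), 9)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("metrics follow their confusion-count definitions", {
  m <- segmentation_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(unname(m), c(0.75, 0.75, 0.75, 5 / 6))
  perfect <- segmentation_metrics(list(TP = 7, FP = 0, TN = 3, FN = 0))
  expect_equal(unname(perfect), rep(1, 4))
  degen <- segmentation_metrics(list(TP = 0, FP = 0, TN = 9, FN = 0))
  expect_true(is.nan(degen[["DSC"]]))
  # F1 identity: DSC = 2PR/(P+R) wherever defined
  set.seed(35)
  for (i in 1:20) {
    m <- segmentation_metrics(confusion_counts(rand_mask(12), rand_mask(12)))
    if (!any(is.nan(m[1:3])))
      expect_equal(m[["DSC"]],
                   2 * m[["precision"]] * m[["sensitivity"]] /
                     (m[["precision"]] + m[["sensitivity"]]))
  }
})

test_that("majority vote needs a strict pixel majority", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 0, 1), 2, 2)
  cc <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(majority_vote(list(a, b, cc)), matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(majority_vote(list(a, a, b)), a)
  expect_equal(majority_vote(list(a, a, a)), a)
  # even count: exact ties resolve to background
  expect_equal(majority_vote(list(a, b)), matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(majority_vote(list(a)), "two")
  expect_error(majority_vote(list(a, matrix(0, 3, 3))), "shape")
})

test_that("report aggregation computes mean and SEM per strategy", {
  per <- data.frame(strategy = rep(c("s1", "s2"), c(3, 1)),
                    image_id = c(1, 2, 3, 1),
                    DSC = c(0.7, 0.8, 0.9, 0.5),
                    precision = c(0.6, 0.6, 0.6, 0.4),
                    sensitivity = c(0.5, 0.7, 0.6, 0.3),
                    specificity = c(1, 1, 1, 1))
  rep <- aggregate_report(per)
  a <- rep$aggregate
  s1d <- a[a$strategy == "s1" & a$metric == "DSC", ]
  expect_equal(s1d$mean, 0.8)
  expect_equal(s1d$sem, sd(c(0.7, 0.8, 0.9)) / sqrt(3))
  expect_equal(a[a$strategy == "s1" & a$metric == "precision", "sem"], 0)
  expect_true(is.nan(a[a$strategy == "s2" & a$metric == "DSC", "sem"]))
  p <- withr::local_tempfile(fileext = ".csv")
  paths <- write_metrics_csv(rep, p)
  expect_true(all(file.exists(paths)))
  back <- read.csv(p)
  expect_equal(nrow(back), 4)
  expect_equal(back$DSC, c(70, 80, 90, 50))
})
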