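# brute-force pixel-counting oracle for the per-class metrics
brute_metrics <- function(pred, gt, k) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == k && gt[i] == k) tp <- tp + 1
    else if (pred[i] == k) fp <- fp + 1
    else if (gt[i] == k) fn <- fn + 1
  }
  safe <- function(n, d) if (d == 0) 1 else n / d
  c(dice = safe(2 * tp, 2 * tp + fp + fn),
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn))
}

test_that("core_metrics computes Dice/precision/recall with the zero-denominator rule", {
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  m <- core_metrics(lab, lab)
  expect_true(all(m$dice == 1 & m$precision == 1 & m$recall == 1))

  # class absent from both maps -> all metrics 1 by convention
  empty <- matrix(0L, 8, 8)
  m2 <- core_metrics(empty, empty)
  expect_true(all(m2$dice == 1))
  expect_false(any(m2$present_in_gt | m2$present_in_pred))

  # constructed overlap: 100 px gt, 100 px pred, 50 shared
  gt <- matrix(0L, 20, 20); gt[1:10, 1:10] <- 1L
  pr <- matrix(0L, 20, 20); pr[6:15, 1:10] <- 1L
  m3 <- core_metrics(pr, gt)
  inv <- m3[m3$class == "invasive", ]
  expect_equal(inv$dice, 0.5)
  expect_equal(inv$precision, 0.5)
  expect_equal(inv$recall, 0.5)
  expect_error(core_metrics(gt, gt[1:10, ]), "mismatch")
})

test_that("core_metrics agrees with brute-force counting on random maps", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      pr <- matrix(sample(0:3, 32 * 32, TRUE, prob = c(0.6, 0.2, 0.15, 0.05)), 32)
      gt <- matrix(sample(0:3, 32 * 32, TRUE, prob = c(0.6, 0.2, 0.15, 0.05)), 32)
    })
    m <- core_metrics(pr, gt)
    for (cls in c(invasive = 1L, benign = 2L, in_situ = 3L)) {
      want <- brute_metrics(pr, gt, cls)
      row <- m[m$class == names(which(c(invasive = 1L, benign = 2L,
                                        in_situ = 3L) == cls)), ]
      expect_equal(row$dice, want[["dice"]])
      expect_equal(row$precision, want[["precision"]])
      expect_equal(row$recall, want[["recall"]])
    }
  }
})

test_that("Dice is symmetric and precision/recall swap under map exchange", {
  withr::with_seed(61, {
    pr <- matrix(sample(0:3, 256, TRUE), 16)
    gt <- matrix(sample(0:3, 256, TRUE), 16)
  })
  a <- core_metrics(pr, gt); b <- core_metrics(gt, pr)
  expect_equal(a$dice, b$dice)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
})

test_that("removing a class from both maps leaves other metrics unchanged", {
  withr::with_seed(62, {
    pr <- matrix(sample(0:3, 256, TRUE), 16)
    gt <- matrix(sample(0:3, 256, TRUE), 16)
  })
  pr2 <- pr; gt2 <- gt
  pr2[pr2 == 3L] <- 0L; gt2[gt2 == 3L] <- 0L
  a <- core_metrics(pr, gt); b <- core_metrics(pr2, gt2)
  expect_equal(b$dice[b$class == "in_situ"], 1)
  expect_equal(a$dice[a$class == "invasive"], b$dice[b$class == "invasive"])
  expect_equal(a$dice[a$class == "benign"], b$dice[b$class == "benign"])
})

make_core_set <- function() {
  # three cores covering the row conditions for the benign class:
  # in gt+pred, in pred only, absent from both
  gt1 <- matrix(0L, 8, 8); gt1[1:4, ] <- 2L
  pr1 <- matrix(0L, 8, 8); pr1[1:3, ] <- 2L
  gt2 <- matrix(0L, 8, 8)
  pr2 <- matrix(0L, 8, 8); pr2[1, 1] <- 2L
  gt3 <- matrix(0L, 8, 8); pr3 <- matrix(0L, 8, 8)
  dplyr::bind_rows(core_metrics(pr1, gt1, core_ref = "a"),
                   core_metrics(pr2, gt2, core_ref = "b"),
                   core_metrics(pr3, gt3, core_ref = "c"))
}

test_that("rows I/II/III select the documented core subsets", {
  rows <- aggregate_rows(make_core_set())
  ben <- rows[rows$class == "benign", ]
  expect_equal(ben$n, c(3L, 2L, 1L))          # I, II, III
  expect_true(ben$dice_mean[1] != ben$dice_mean[2])
  # row III == the core with benign in gt
  one <- make_core_set()
  expect_equal(ben$dice_mean[3],
               one$dice[one$class == "benign" & one$present_in_gt])

  # subset nesting III <= II <= I by construction
  expect_true(all(diff(ben$n) <= 0))
})

test_that("all-empty cores propagate the convention into row I only", {
  empty <- matrix(0L, 8, 8)
  met <- dplyr::bind_rows(core_metrics(empty, empty, core_ref = "a"),
                          core_metrics(empty, empty, core_ref = "b"))
  rows <- aggregate_rows(met)
  inv <- rows[rows$class == "invasive", ]
  expect_equal(inv$dice_mean[inv$row == "I"], 1)
  expect_equal(inv$n[inv$row == "II"], 0L)
  expect_true(is.na(inv$dice_mean[inv$row == "II"]))
  expect_true(is.na(inv$dice_mean[inv$row == "III"]))
})

test_that("row aggregation is permutation-invariant", {
  met <- make_core_set()
  shuffled <- met[sample(nrow(met)), ]
  a <- aggregate_rows(met) |> dplyr::arrange(class, row)
  b <- aggregate_rows(shuffled) |> dplyr::arrange(class, row)
  expect_equal(a, b)
})

test_that("subgroup summaries report exact means per group with N", {
  met <- dplyr::bind_rows(
    core_metrics(matrix(1L, 4, 4), matrix(1L, 4, 4), core_ref = "a",
                 subtype = "NST", grade = 2),
    core_metrics(matrix(0L, 4, 4), matrix(1L, 4, 4), core_ref = "b",
                 subtype = "NST", grade = 2),
    core_metrics(matrix(1L, 4, 4), matrix(1L, 4, 4), core_ref = "c",
                 subtype = "lobular", grade = 3))
  s <- subgroup_summary(met, by = "subtype")
  inv <- s[s$class == "invasive", ]
  expect_equal(inv$n[inv$group == "NST"], 2L)
  expect_equal(inv$dice_mean[inv$group == "NST"], 0.5)   # (1 + 0) / 2
  expect_equal(inv$dice_mean[inv$group == "lobular"], 1)
  # a single group collapses to one row per class
  s2 <- subgroup_summary(met[met$subtype == "lobular", ], by = "subtype")
  expect_equal(nrow(s2), 3L)
  # unknown metadata groups under "unknown"
  met$subtype[1] <- "unknown"
  expect_true("unknown" %in% subgroup_summary(met, by = "subtype")$group)
})

test_that("qualitative scores are validated and zero-excluded in means", {
  scores <- tibble::tibble(case_id = c("c1", "c2", "c3"),
                           class = "benign", score = c(4L, 5L, 0L),
                           rater = "r1")
  rep <- qualitative_report(scores)
  expect_equal(rep$n, 2L)
  expect_equal(rep$mean, 4.5)

  all_zero <- tibble::tibble(case_id = "c1", class = "invasive",
                             score = 0L, rater = "r1")
  rep0 <- qualitative_report(all_zero)
  expect_equal(rep0$n, 0L)
  expect_true(is.na(rep0$mean))

  bad <- tibble::tibble(case_id = "c", class = "benign", score = 7L,
                        rater = "r")
  expect_error(qualitative_report(bad), "invalid score")
  badc <- tibble::tibble(case_id = "c", class = "stroma", score = 3L,
                         rater = "r")
  expect_error(qualitative_report(badc), "invalid class")

  # "Present" variant restricted by ground-truth presence
  pres <- tibble::tibble(case_id = c("c1", "c2", "c3"), class = "benign",
                         present = c(TRUE, FALSE, TRUE))
  rep2 <- qualitative_report(scores, pres)
  expect_equal(rep2$n[rep2$variant == "Present"], 1L)
  expect_equal(rep2$mean[rep2$variant == "Present"], 4)
})

test_that("score records survive a CSV round trip", {
  scores <- tibble::tibble(case_id = sprintf("case_%d", 1:6),
                           class = rep(c("benign", "invasive"), 3),
                           score = c(5L, 4L, 3L, 0L, 2L, 5L),
                           rater = rep(c("r1", "r2"), each = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(scores, path, row.names = FALSE)
  back <- validate_scores(utils::read.csv(path))
  expect_equal(as.data.frame(back), as.data.frame(scores))
})

test_that("evaluate_cores wraps per-core metrics with tidier accessors", {
  gt <- matrix(0L, 8, 8); gt[1:4, ] <- 1L
  pr <- gt
  ev <- evaluate_cores(list(list(pred = pr, gt = gt, core_ref = "x")))
  expect_s3_class(ev, "ihc_evaluation")
  expect_equal(nrow(tidy(ev)), 3L)
  g <- glance(ev)
  expect_equal(g$dice_mean_invasive, 1)
  expect_s3_class(autoplot(ev), "ggplot")
})
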