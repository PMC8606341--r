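# independent SOV'99 evaluation used to freeze the hand instances
sov99_by_hand <- function(ref_segs, pred_segs, L) {
  # single-class helper over explicit (start, end) segment lists
  num <- 0; norm <- 0
  for (a in seq_len(nrow(ref_segs))) {
    len1 <- ref_segs[a, 2] - ref_segs[a, 1] + 1
    hit <- FALSE
    for (b in seq_len(nrow(pred_segs))) {
      minov <- min(ref_segs[a, 2], pred_segs[b, 2]) -
        max(ref_segs[a, 1], pred_segs[b, 1]) + 1
      if (minov <= 0) next
      hit <- TRUE
      maxov <- max(ref_segs[a, 2], pred_segs[b, 2]) -
        min(ref_segs[a, 1], pred_segs[b, 1]) + 1
      len2 <- pred_segs[b, 2] - pred_segs[b, 1] + 1
      delta <- min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
      num <- num + len1 * (minov + delta) / maxov
      norm <- norm + len1
    }
    if (!hit) norm <- norm + len1
  }
  c(num = num, norm = norm)
}

lab_with_tm <- function(L, tm_segs) {
  labs <- rep("i", L)
  for (r in seq_len(nrow(tm_segs)))
    labs[tm_segs[r, 1]:tm_segs[r, 2]] <- "M"
  labs
}

test_that("Q2 counts two-state agreement", {
  expect_equal(q2("MMMiii", "MMMiii"), 1)
  expect_equal(q2("MMMiii", "iiiMMM"), 0)
  expect_equal(q2("MMMiii", "MMiiii"), 5 / 6)
  # projection: i and o both count as non-TM
  expect_equal(q2("MMoo", "MMii"), 1)
  expect_error(q2("MM", "MMM"), "mismatch")
})

test_that("SOV'99 reproduces hand-computed instances", {
  # identical labelings
  expect_equal(sov("MMMiii", "MMMiii"), 1)
  # disjoint segmentations in both classes
  expect_equal(sov(c(rep("M", 5), rep("i", 5)),
                   c(rep("i", 5), rep("M", 5))), 0)
  # ref TM 11-20 in L = 30, pred TM 13-22: delta saturates every pair
  ref <- lab_with_tm(30, rbind(c(11, 20)))
  pred <- lab_with_tm(30, rbind(c(13, 22)))
  tm <- sov99_by_hand(rbind(c(11, 20)), rbind(c(13, 22)), 30)
  non <- sov99_by_hand(rbind(c(1, 10), c(21, 30)),
                       rbind(c(1, 12), c(23, 30)), 30)
  expect_equal(sov(ref, pred),
               unname((tm["num"] + non["num"]) / (tm["norm"] + non["norm"])))
  expect_equal(sov(ref, pred), 1.0)   # frozen from the hand evaluation
  # non-saturating case: pred TM 18-25
  pred2 <- lab_with_tm(30, rbind(c(18, 25)))
  tm2 <- sov99_by_hand(rbind(c(11, 20)), rbind(c(18, 25)), 30)
  non2 <- sov99_by_hand(rbind(c(1, 10), c(21, 30)),
                        rbind(c(1, 17), c(26, 30)), 30)
  expect_equal(sov(ref, pred2),
               unname((tm2["num"] + non2["num"]) /
                        (tm2["norm"] + non2["norm"])))
  expect_equal(sov(ref, pred2), 0.6607843, tolerance = 1e-7)
  expect_error(sov("MM", "MMM"), "mismatch")
})

test_that("SOV is bounded and 1 only for identical segmentations", {
  set.seed(77)
  for (rep in 1:20) {
    L <- sample(10:40, 1)
    r <- lab_with_tm(L, rbind(sort(sample(L, 2))))
    p <- lab_with_tm(L, rbind(sort(sample(L, 2))))
    v <- sov(r, p)
    expect_gte(v, 0)
    expect_lte(v, 1)
    if (identical(r, p)) expect_equal(v, 1)
  }
})

test_that("topology correctness checks counts, overlaps, and sidedness", {
  ref <- c(rep("i", 5), rep("M", 6), rep("o", 5), rep("M", 6), rep("i", 5))
  expect_true(topology_correct(ref, ref, "alpha"))
  # merged helices: count differs
  merged <- c(rep("i", 5), rep("M", 17), rep("i", 5))
  expect_false(topology_correct(ref, merged, "alpha"))
  expect_false(strand_count_correct(ref, merged))
  # equal counts, in-order overlaps, but loops swapped in/out
  swapped <- c(rep("o", 5), rep("M", 6), rep("i", 5), rep("M", 6),
               rep("o", 5))
  expect_true(topology_correct(ref, swapped, "beta"))
  expect_false(topology_correct(ref, swapped, "alpha"))
  # equal counts but a segment shifted off its partner
  shifted <- c(rep("M", 6), rep("i", 5), rep("M", 6), rep("i", 10))
  expect_false(topology_correct(ref, shifted, "alpha"))
  expect_true(strand_count_correct(ref, shifted))
  # topology_correct implies strand_count_correct
  set.seed(79)
  for (rep in 1:20) {
    L <- 30
    r <- lab_with_tm(L, rbind(sort(sample(L, 2))))
    p <- lab_with_tm(L, rbind(sort(sample(L, 2))))
    if (topology_correct(r, p, "alpha"))
      expect_true(strand_count_correct(r, p))
  }
})

test_that("binary_stats computes the standard formulas and conventions", {
  s <- binary_stats(8, 2, 7, 3)
  expect_equal(s$mcc, 50 / sqrt(9900), tolerance = 1e-10)
  expect_equal(s$sensitivity, 8 / 11, tolerance = 1e-10)
  expect_equal(s$specificity, 7 / 9, tolerance = 1e-10)
  expect_equal(binary_stats(5, 0, 9, 0)$mcc, 1)
  # always-positive predictor: MCC 0 by convention
  expect_equal(binary_stats(10, 5, 0, 0)$mcc, 0)
  expect_error(binary_stats(0, 0, 0, 0), "zero")
  # MCC invariant under class swap
  a <- binary_stats(8, 2, 7, 3)$mcc
  b <- binary_stats(7, 3, 8, 2)$mcc
  expect_equal(a, b)
})

test_that("evaluation reports aggregate per-protein metrics", {
  refs <- list(labeled_sequence("a", strrep("A", 6), "MMMiii"),
               labeled_sequence("b", strrep("A", 4), "MMii"))
  preds <- list(c("M", "M", "i", "i", "i", "i"),
                c("M", "M", "i", "i"))
  rep <- evaluate_predictions(refs, preds, mode = "alpha")
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$q2, c(5 / 6, 1))
  agg <- glance(rep)
  expect_equal(agg$n, 2)
  expect_equal(agg$q2, mean(c(5 / 6, 1)))
  expect_equal(agg$q2_residue, (5 + 4) / 10)
  expect_equal(agg$n_count_correct, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep, path)
  expect_true(any(grepl("aggregate", readLines(path))))
})
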