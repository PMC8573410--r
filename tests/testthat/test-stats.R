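# Slice-restricted Dice, group summaries, normality-gated testing,
# Bonferroni correction, and the comparison plan.

test_that("slice restriction crops candidate voxels on reference-free slices", {
  man <- array(0L, c(8, 8, 6))
  man[3:5, 3:5, 2:3] <- 1L
  cand <- man
  cand[1:5, 1:2, 6] <- 1L    # 10 voxels on a slice without reference
  expect_equal(slice_restricted_dsc(cand, man), 1.0)
  expect_equal(slice_restricted_dsc(man, man), 1.0)

  far <- array(0L, c(8, 8, 6))
  far[3:5, 3:5, 5:6] <- 1L   # entirely on reference-free slices
  expect_equal(slice_restricted_dsc(far, man), 0)
  expect_error(slice_restricted_dsc(man, array(0L, c(8, 8, 6))), "empty")
})

test_that("slice-restricted Dice never falls below the plain Dice", {
  set.seed(8)
  for (i in 1:30) {
    man <- random_mask(c(6, 6, 6), 0.3)
    cand <- random_mask(c(6, 6, 6), 0.3)
    if (sum(man) == 0 || sum(cand) == 0) next
    expect_gte(slice_restricted_dsc(cand, man), dsc(cand, man))
  }
})

test_that("group summary returns mean and sd/sqrt(n)", {
  gs <- group_summary(c(1, 2, 3))
  expect_equal(gs[["mean"]], 2)
  expect_equal(gs[["sem"]], 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(group_summary(rep(5, 8))[["sem"]], 0)
  g2 <- group_summary(3 * c(1, 2, 3))
  expect_equal(unname(g2), 3 * unname(gs))
  expect_error(group_summary(1), "at least 2")
})

test_that("the normality test reproduces reference omnibus K2 values", {
  # frozen independent oracle values (scipy.stats.normaltest)
  x1 <- c(-1.423825, 1.263728, -0.870662, -0.259173, -0.075343, -0.740885,
          -1.367793, 0.648893, 0.361058, -1.952863, 2.34741, 0.968497)
  x2 <- c(1.1345, 0.010063, 2.788338, 0.301044, 4.294688, 0.679707, 0.00592,
          0.00164, 0.048262, 0.986588, 0.551455, 0.138451, 0.65574, 0.253559,
          0.111989)
  x3 <- c(1.72474, 2.618159, 0.777361, 0.828633, -0.958988, -1.209388,
          -1.412292, 0.541547, 0.751939)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 0.4185814397, tolerance = 1e-8)
  expect_equal(r1$p.value, 0.8111593812, tolerance = 1e-8)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 18.503832897043633, tolerance = 1e-8)
  expect_equal(r2$p.value, 9.592763541340981e-05, tolerance = 1e-8)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$statistic, 0.2736946745, tolerance = 1e-8)
  expect_equal(r3$p.value, 0.8721033537, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("the gate picks the t-test for normal data, rank-sum otherwise", {
  set.seed(9)
  a <- rnorm(10)
  r_id <- compare_groups(a, a)
  expect_equal(r_id$statistic, 0)
  expect_equal(r_id$p_raw, 1)
  expect_identical(r_id$test, "t_test")

  b <- rnorm(10, mean = 5)
  r_sep <- compare_groups(a, b)
  expect_identical(r_sep$test, "t_test")
  expect_lt(r_sep$p_raw, 0.001)

  # heavy-tailed mixture constructed to fail normality
  set.seed(10)
  repeat {
    h <- c(rnorm(17, sd = 0.2), rexp(3)^3 + 3)
    if (dagostino_pearson(h)$p.value < 0.05) break
  }
  r_h <- compare_groups(h, rnorm(10))
  expect_identical(r_h$test, "rank_sum")

  expect_error(compare_groups(rnorm(5), rnorm(10)), "n < 8")
  r_forced <- compare_groups(rnorm(5), rnorm(10), force = "rank_sum")
  expect_identical(r_forced$test, "rank_sum")
})

test_that("Bonferroni correction multiplies, caps and preserves order", {
  expect_equal(bonferroni(0.0025, m = 10), 0.025)
  expect_equal(bonferroni(0.5, m = 10), 1)
  expect_equal(bonferroni(c(0.1, 0.4), m = 2), c(0.2, 0.8))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(1.5, m = 2), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2, 0.3), m = 2), "family size")
  set.seed(11)
  for (i in 1:30) {
    ps <- runif(sample(2:12, 1))
    corr <- bonferroni(ps, m = length(ps) + sample(0:5, 1))
    expect_true(all(corr >= ps))
    expect_true(all(diff(corr[order(ps)]) >= 0))  # monotone in the raw p
  }
})

test_that("the comparison plan has the reference family structure 4+3+3", {
  plan <- comparison_plan()
  expect_equal(nrow(plan), 10)
  expect_equal(as.integer(table(plan$family)[c("a", "b", "c")]), c(4L, 3L, 3L))
  expect_false(any(duplicated(plan$label)))
  # family a: within-group initial vs corrected for both control groups,
  # plus between-control-group comparisons of each atlas kind
  fa <- plan[plan$family == "a", ]
  expect_true(any(fa$group_a == "hcp_test_control" & fa$kind_a == "atlas_initial" &
                    fa$group_b == "hcp_test_control" & fa$kind_b == "atlas_corrected"))
  expect_true(any(fa$group_a == "chiasm_control" & fa$kind_b == "atlas_corrected" &
                    fa$group_b == "chiasm_control"))
  expect_true(any(fa$kind_a == "atlas_initial" & fa$kind_b == "atlas_initial"))
  expect_true(any(fa$kind_a == "atlas_corrected" & fa$kind_b == "atlas_corrected"))
  expect_false(any(fa$group_a == "chiasm_albinism" | fa$group_b == "chiasm_albinism"))
  # family b: corrected vs cnn within every group
  fb <- plan[plan$family == "b", ]
  expect_setequal(fb$group_a, study_groups())
  expect_true(all(fb$kind_a == "atlas_corrected" & fb$kind_b == "cnn"))
  # family c: cnn across all group pairs
  fc <- plan[plan$family == "c", ]
  expect_true(all(fc$kind_a == "cnn" & fc$kind_b == "cnn"))
  expect_equal(nrow(fc), choose(3, 2))

  expect_equal(nrow(comparison_plan("one_group", "cnn")), 0)
})

test_that("cohort evaluation populates the full results table", {
  set.seed(12)
  groups <- c(rep("hcp_test_control", 10), rep("chiasm_control", 8),
              rep("chiasm_albinism", 9))
  ids <- sprintf("s%02d", seq_along(groups))
  records <- do.call(rbind, lapply(c("atlas_initial", "atlas_corrected", "cnn"),
    function(k) data.frame(id = ids, group = groups, kind = k,
                           dsc = pmin(1, pmax(0, rnorm(length(ids), 0.6, 0.1))),
                           stringsAsFactors = FALSE)))
  ev <- evaluate_cohort(records)
  expect_equal(nrow(ev$summary), 9)      # 3 groups x 3 kinds
  expect_false(any(is.na(ev$summary$mean)))
  expect_equal(nrow(ev$tests), 10)
  expect_equal(unique(ev$tests$m), 10)
  expect_equal(ev$tests$p_fwe, pmin(1, ev$tests$p_raw * 10))

  # permutation invariance
  ev2 <- evaluate_cohort(records[sample(nrow(records)), ])
  expect_equal(ev2$summary[order(ev2$summary$group, ev2$summary$kind), ],
               ev$summary[order(ev$summary$group, ev$summary$kind), ],
               ignore_attr = TRUE)
  expect_equal(ev2$tests[order(ev2$tests$label), "p_raw"],
               ev$tests[order(ev$tests$label), "p_raw"])

  # identical values everywhere -> all corrected p-values are 1
  flat <- records
  flat$dsc <- 0.5
  ev3 <- evaluate_cohort(flat)
  expect_true(all(ev3$tests$p_fwe == 1))
})
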