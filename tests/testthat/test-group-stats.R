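test_that("students_t handles one- and two-sample cases and degeneracy", {
  x <- c(1.2, 2.1, 0.8, 1.7)
  same <- students_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  one <- students_t(x, mu = 0)
  ref <- t.test(x)
  expect_equal(one$t, unname(ref$statistic))
  expect_equal(one$p, ref$p.value)
  expect_error(students_t(c(-5, -5, -5), mu = 0), "zero variance")
  expect_error(students_t(1), "at least 2")
})

test_that("dunnett reduces to the pooled t-test for one group", {
  set.seed(1)
  g <- rnorm(6, 1); ctl <- rnorm(6)
  d <- dunnett_test(list(A = g), ctl)
  ref <- t.test(g, ctl, var.equal = TRUE)
  expect_equal(d$t, unname(ref$statistic))
  expect_equal(d$p_adj, ref$p.value, tolerance = 1e-10)
})

test_that("dunnett adjustment is monotone, reproducible, and matches multcomp", {
  set.seed(42)
  groups <- lapply(c(0, 0.5, 1, 2), function(m) rnorm(8, m))
  names(groups) <- paste0("G", 1:4)
  ctl <- rnorm(8)
  d1 <- dunnett_test(groups, ctl)
  expect_true(all(d1$p_adj >= d1$p_raw - 1e-12))
  d2 <- dunnett_test(groups, ctl)
  expect_equal(d1$p_adj, d2$p_adj, tolerance = 2e-3)
  skip_if_not_installed("multcomp")
  dat <- data.frame(
    y = c(ctl, unlist(groups)),
    g = factor(rep(c("ctl", names(groups)),
                   times = c(length(ctl), lengths(groups))),
               levels = c("ctl", names(groups))))
  mc <- multcomp::glht(stats::aov(y ~ g, dat),
                       linfct = multcomp::mcp(g = "Dunnett"))
  p_mc <- summary(mc)$test$pvalues
  expect_equal(d1$p_adj, as.numeric(p_mc), tolerance = 5e-3)
})

test_that("dunnett controls the family-wise error under the null", {
  set.seed(2026)
  n_rej <- 0L
  reps <- 400L
  for (r in seq_len(reps)) {
    groups <- replicate(4, rnorm(5), simplify = FALSE)
    d <- dunnett_test(groups, rnorm(5))
    n_rej <- n_rej + any(d$p_adj < 0.05)
  }
  fwe <- n_rej / reps
  expect_gte(fwe, 0.02)
  expect_lte(fwe, 0.09)
})

test_that("duncan critical ranges grow with span and match the protection level", {
  lsr_q <- vapply(2:6, function(p) duncan_q(0.05, p, 20), 0)
  expect_true(all(diff(lsr_q) > 0))
  expect_equal(duncan_q(0.05, 2, 20), qtukey(0.95, 2, 20))
  expect_equal(duncan_q(0.05, 3, 20),
               qtukey(1 - (1 - (1 - 0.05)^2), 3, 20))
})

test_that("duncan reduces to the LSD t-test for two groups", {
  set.seed(3)
  for (r in 1:10) {
    a <- rnorm(5, 0); b <- rnorm(5, r / 4)
    mr <- duncan_mrt(list(A = a, B = b), alpha = 0.05)
    lsd_p <- t.test(a, b, var.equal = TRUE)$p.value
    distinct <- !any(mr$means$letters[1] == mr$means$letters[2])
    expect_equal(distinct, lsd_p < 0.05)
  }
})

test_that("duncan letters: separated means distinct, valid contiguous cover", {
  groups <- list(A = c(10, 11, 12), B = c(30, 31, 32), C = c(50, 51, 52))
  mr <- duncan_mrt(groups)
  expect_equal(sort(mr$means$letters), c("A", "B", "C"))
  set.seed(8)
  for (r in 1:30) {
    k <- sample(3:6, 1)
    gr <- lapply(seq_len(k), function(j) rnorm(4, sample(0:3, 1)))
    names(gr) <- paste0("G", seq_len(k))
    mr <- duncan_mrt(gr)
    lets <- strsplit(mr$means$letters, "")
    expect_true(all(lengths(lets) >= 1))       # every group lettered
    for (L in unique(unlist(lets))) {          # letter blocks contiguous
      idx <- which(vapply(lets, function(s) L %in% s, TRUE))
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
  expect_error(duncan_mrt(list(A = c(1, 1), B = c(1, 1))), "zero within-group")
  expect_error(duncan_mrt(list(A = c(1, 2))), "at least 2 groups")
})

test_that("duncan letter partitions agree with the recursive range oracle", {
  set.seed(99)
  for (r in 1:100) {
    k <- sample(3:6, 1)
    gr <- lapply(seq_len(k), function(j) rnorm(sample(3:5, 1), sample(0:2, 1)))
    names(gr) <- paste0("G", seq_len(k))
    mr <- duncan_mrt(gr)
    ms <- stats::setNames(mr$means$mean, mr$means$group)
    oracle <- duncan_oracle_blocks(ms, mr$lsr)
    main <- qtlpyramid:::range_blocks(ms, mr$lsr)
    expect_equal(main, oracle)
  }
})
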