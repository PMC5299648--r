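test_that("R-peak alignment truncates to the common overlap", {
  x <- saecg(sin(1:256 / 10), r_offset = 80L, fs = 256)
  y <- saecg(cos(1:256 / 10), r_offset = 90L, fs = 256)
  al <- pair_saecgs(x, y)
  expect_length(al$x, 246)        # min(80,90) + min(176,166)
  expect_length(al$y, 246)
  expect_identical(al$r_offset, 80L)
  expect_identical(al$x[al$r_offset + 1L], x$samples[81])
  expect_identical(al$y[al$r_offset + 1L], y$samples[91])
  # identical inputs come back unchanged
  al2 <- pair_saecgs(x, x)
  expect_identical(al2$x, x$samples)
  expect_identical(al2$x, al2$y)
  # pathological offsets leave too little overlap
  a <- saecg(rnorm(12), r_offset = 11L, fs = 256)
  b <- saecg(rnorm(12), r_offset = 0L, fs = 256)
  expect_error(pair_saecgs(a, b), "overlap")
  expect_error(pair_saecgs(x, saecg(rnorm(50), 10L, fs = 512)),
               "sampling frequency")
})

test_that("fit_itf recovers the generating model on an exact subject", {
  sub <- make_exact_subject()
  fit <- fit_itf(sub, "bda", 2, 3)
  expect_gte(fit$gf, 99.9)
  expect_identical(fit$pair, "bda")
  expect_identical(fit$subject_id, 1)
  # a self-pair behaves like a (near-)identity at low order
  self <- estimate_tf(sub$before$samples, c(0, sub$before$samples[-205]),
                      0, 1)
  expect_gte(self$gf, 99)
})

test_that("coefficient averaging is exact, order-checked and monic", {
  g1 <- dtf(c(2, 0), c(1, -0.4, 0.1))
  g2 <- dtf(c(0, 2), c(1, -0.2, 0.3))
  avg <- average_itfs(list(g1, g2))
  expect_equal(avg$tf$num, c(1, 1))
  expect_equal(avg$tf$den, c(1, -0.3, 0.2))
  expect_identical(avg$tf$den[1], 1)
  expect_identical(avg$n_subjects, 2L)
  # averaging identical models is the identity
  same <- average_itfs(list(g1, g1, g1))
  expect_equal(same$tf$num, g1$num)
  # permutation invariance
  expect_equal(average_itfs(list(g2, g1))$tf, avg$tf)
  # an analytic mean of many leading coefficients is matched to 1e-12
  set.seed(4)
  b4 <- rnorm(14)
  tfs <- lapply(b4, function(b) dtf(c(b, 1, 0, 0, 1), c(1, rep(0, 5))))
  expect_equal(average_itfs(tfs)$tf$num[1], mean(b4), tolerance = 1e-12)
  expect_error(average_itfs(list(g1, dtf(1, c(1, 0)))), "orders")
  expect_error(average_itfs(list()), "at least one")
})

test_that("homogeneous subjects give identical ITF and GTF columns", {
  sub <- make_exact_subject()
  subs <- list(sub, sub, sub)
  itfs <- lapply(subs, fit_itf, pair = "bda", num_order = 2, den_order = 3)
  gtf <- average_itfs(itfs, pair = "bda")
  ev <- evaluate_models(subs, itfs, gtf, "bda")
  expect_equal(ev$table$gf_itf, ev$table$gf_gtf, tolerance = 1e-6)
  expect_equal(ev$mean_diff, 0, tolerance = 1e-6)
  # single subject: the GTF is that subject's ITF
  ev1 <- evaluate_models(subs[1], itfs[1], average_itfs(itfs[1]), "bda")
  expect_equal(ev1$table$gf_itf, ev1$table$gf_gtf, tolerance = 1e-10)
})

test_that("subject-table aggregation reproduces the published averages", {
  tab <- reference_subject_gf()
  summ <- summarize_subject_table(tab)
  expect_equal(round(summ$avg[["gf_itf_bda"]], 2), 93.84)
  expect_equal(round(summ$avg[["gf_gtf_bda"]], 2), 93.61)
  # mean ITF-GTF differences per pair, computed from the table layout
  diffs <- round(c(summ$avg[["gf_itf_bda"]] - summ$avg[["gf_gtf_bda"]],
                   summ$avg[["gf_itf_daa"]] - summ$avg[["gf_gtf_daa"]],
                   summ$avg[["gf_itf_baa"]] - summ$avg[["gf_gtf_baa"]]), 2)
  expect_equal(diffs, c(0.23, 0.98, 1.47))
  # sample SDs with n-1, as reported
  expect_equal(summ$sd[["gf_gtf_bda"]], sd(tab$gf_gtf_bda))
  expect_identical(tail(summ$table$subject_id, 2), c("Avg", "SD"))
  # either model may win for an individual subject
  expect_true(any(tab$gf_gtf_bda > tab$gf_itf_bda))
  expect_true(any(tab$gf_itf_bda > tab$gf_gtf_bda))
})
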