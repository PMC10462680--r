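test_that("Crawford-Howell matches its closed form", {
  # case at the control mean: no evidence
  r0 <- crawford_howell(2, c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # df = 2 worked example: t = 8 / sqrt(4/3), p from the closed-form
  # survival function 2 * 0.5 * (1 - t / sqrt(2 + t^2))
  r <- crawford_howell(10, c(1, 2, 3))
  expect_equal(r$t, 8 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$t, 6.9282, tolerance = 1e-4)
  p_closed <- 1 - r$t / sqrt(2 + r$t^2)
  expect_equal(r$p, p_closed, tolerance = 1e-12)
  expect_equal(r$p, 0.0202, tolerance = 1e-3)
})

test_that("Crawford-Howell equals an independent recomputation at 1e-12", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    controls <- rnorm(n, sd = runif(1, 0.5, 5))
    case <- rnorm(1, sd = 3)
    r <- crawford_howell(case, controls)
    # brute-force recomputation from sums
    m <- sum(controls) / n
    s2 <- sum((controls - m)^2) / (n - 1)
    t_ref <- (case - m) / (sqrt(s2) * sqrt((n + 1) / n))
    expect_equal(r$t, t_ref, tolerance = 1e-12)
    expect_equal(r$p, 2 * pt(-abs(t_ref), n - 1), tolerance = 1e-12)
    # reflection invariance of the two-sided p
    refl <- crawford_howell(2 * m - case, controls)
    expect_equal(refl$p, r$p, tolerance = 1e-12)
    # one-sided halves add to one
    g <- crawford_howell(case, controls, "greater")$p
    l <- crawford_howell(case, controls, "less")$p
    expect_equal(g + l, 1, tolerance = 1e-12)
  }
  # degenerate controls
  d <- crawford_howell(5, c(2, 2, 2))
  expect_true(d$degenerate)
  expect_lte(d$p, .Machine$double.xmin)
  expect_equal(crawford_howell(2, c(2, 2, 2))$p, 1)
  expect_error(crawford_howell(1, 2), "at least 2")
})

test_that("the null rejection rate is calibrated at alpha = 0.05", {
  set.seed(52)
  nrep <- 10000
  n <- 4
  ctrl <- matrix(rnorm(nrep * n), nrep, n)
  case <- rnorm(nrep)
  m <- rowMeans(ctrl)
  s <- sqrt(rowSums((ctrl - m)^2) / (n - 1))
  t <- (case - m) / (s * sqrt((n + 1) / n))
  p <- 2 * pt(-abs(t), n - 1)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("Bonferroni adjustment caps at 1 and validates input", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.4, 0.9)), c(0.03, 1, 1))
  expect_equal(bonferroni(c(0.2, 0.2)), c(0.4, 0.4))   # ties preserved
  expect_error(bonferroni(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bonferroni(1.2), "\\(0, 1\\]")
})

test_that("length-matched controls reproduce the reference bin profile", {
  set.seed(53)
  # each reference length sits alone in its (log-spaced) bin, so the drawn
  # length multiset must equal the reference multiset exactly
  ref_len <- c(100, 100, 1000, 10000)
  pool <- data.frame(
    id = paste0("p", seq_len(24)),
    length = rep(c(100, 100, 1000, 10000), 6), stringsAsFactors = FALSE)
  sets <- sample_length_matched_controls(pool, ref_len, n_sets = 4,
                                         n_bins = 3, seed = 7)
  expect_length(sets, 4)
  all_ids <- unlist(lapply(sets, `[[`, "ids"))
  expect_equal(anyDuplicated(all_ids), 0)           # mutually disjoint
  for (s in sets) {
    expect_false(s$borrowed)
    got <- sort(pool$length[match(s$ids, pool$id)])
    expect_equal(got, sort(ref_len))                # exact profile
  }
  # determinism
  sets2 <- sample_length_matched_controls(pool, ref_len, n_sets = 4,
                                          n_bins = 3, seed = 7)
  expect_identical(sets, sets2)

  # excluded (case) ids are never drawn
  sets3 <- sample_length_matched_controls(pool, ref_len, n_sets = 2,
                                          n_bins = 3, seed = 7,
                                          exclude_ids = paste0("p", 1:4))
  expect_false(any(paste0("p", 1:4) %in% unlist(lapply(sets3, `[[`, "ids"))))

  # under-filled bins borrow from the nearest bin and flag the set
  thin <- data.frame(id = paste0("q", 1:12),
                     length = c(rep(300, 11), 9000))
  sets4 <- sample_length_matched_controls(thin, c(300, 9000), n_sets = 2,
                                          n_bins = 4, seed = 1)
  expect_true(any(vapply(sets4, `[[`, logical(1), "borrowed")))

  expect_error(sample_length_matched_controls(pool[1:3, ], ref_len),
               "smaller than one full control set")
})

test_that("enrichment tests per category match the Crawford-Howell oracle", {
  ann <- rbind(
    data.frame(contig_id = paste0("x", 1:50), category = "phage"),
    data.frame(contig_id = paste0("c1_", 1:10), category = "phage"),
    data.frame(contig_id = paste0("c2_", 1:12), category = "phage"),
    data.frame(contig_id = paste0("c3_", 1:9), category = "phage"),
    data.frame(contig_id = paste0("c4_", 1:11), category = "phage"),
    data.frame(contig_id = c(paste0("x", 1:3), paste0("c1_", 1:3),
                             paste0("c2_", 1:3), paste0("c3_", 1:3),
                             paste0("c4_", 1:3)), category = "IS"))
  ctrl <- list(paste0("c1_", 1:20), paste0("c2_", 1:20),
               paste0("c3_", 1:20), paste0("c4_", 1:20))
  res <- enrichment_test(ann, paste0("x", 1:60), ctrl)
  phage <- res[res$category == "phage", ]
  oracle <- crawford_howell(50, c(10, 12, 9, 11))
  expect_equal(phage$case, 50)
  expect_equal(phage$t, oracle$t, tolerance = 1e-12)
  expect_equal(phage$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, bonferroni(res$p))
  expect_equal(phage$stars, "***")

  # identical counts in case and all controls: p = 1
  is_row <- res[res$category == "IS", ]
  expect_equal(is_row$p, 1)

  # doubling all counts changes t only through the sd (scale equivariance)
  ann2 <- rbind(ann, ann[ann$category == "phage", ])
  res2 <- enrichment_test(ann2, paste0("x", 1:60), ctrl)
  oracle2 <- crawford_howell(100, c(20, 24, 18, 22))
  expect_equal(res2$t[res2$category == "phage"], oracle2$t,
               tolerance = 1e-12)

  # a category absent everywhere is skipped with a warning
  ann3 <- rbind(ann, data.frame(contig_id = "zz", category = "integron"))
  expect_warning(res3 <- enrichment_test(ann3, paste0("x", 1:60), ctrl),
                 "integron")
  expect_false("integron" %in% res3$category)
})
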