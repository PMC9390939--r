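test_that("median/IQR descriptives match sort-based quantiles", {
  d <- describe_median_iqr(1:5)
  expect_equal(unname(d), c(3, 2, 4))
  dc <- describe_median_iqr(rep(7, 10))
  expect_equal(dc[["q3"]] - dc[["q1"]], 0)
  set.seed(6)
  for (rep in 1:10) {
    v <- runif(sample(5:40, 1))
    d <- describe_median_iqr(v)
    expect_equal(unname(d),
                 unname(quantile(v, c(0.5, 0.25, 0.75))))
  }
})

test_that("the normality gate flags skewed samples and rejects bad input", {
  set.seed(12)
  skewed <- rexp(50)
  expect_lt(normality_gate(skewed)$p, 0.05)
  set.seed(12)
  expect_gt(normality_gate(rnorm(50))$p, 0.05)
  expect_error(normality_gate(rep(1, 10)), "identical")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("Kruskal-Wallis matches a hand-ranked computation", {
  # [1,2] vs [3,4] vs [5,6]: ranks 1..6, no ties
  # H = 12/(N(N+1)) * sum(n_i (rbar_i - (N+1)/2)^2) = 12/42 * (2*4 + 0 + 2*4)
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 12 / 42 * 16, tolerance = 1e-10)
  expect_equal(kw$df, 2)
  # identical groups: H = 0, p = 1
  kw0 <- kruskal_wallis(list(rep(2, 5), rep(2, 5)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(99)
  rejections <- 0L
  n_rep <- 1000
  for (r in seq_len(n_rep)) {
    groups <- replicate(4, rnorm(12), simplify = FALSE)
    if (kruskal_wallis(groups)$p < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.02)
})

test_that("Dunn post hoc with BH adjustment behaves correctly", {
  set.seed(21)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, mean = 3))
  d <- dunn_posthoc_bh(g)
  expect_true(isSymmetric(d$p_adjusted))
  # BH never lowers a raw p-value, and stays within [raw, 1]
  off <- upper.tri(d$p_raw)
  expect_true(all(d$p_adjusted[off] >= d$p_raw[off]))
  expect_true(all(d$p_adjusted[off] <= 1))
  # identical groups give p ~ 1 for that pair
  g2 <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = c(10, 11, 12, 13, 14))
  d2 <- dunn_posthoc_bh(g2)
  expect_equal(d2$z["a", "b"], 0)
  expect_equal(d2$p_adjusted["a", "b"], 1)
  # adjusted p equals hand-applied BH on the sorted raw p-values
  praw <- d$p_raw[upper.tri(d$p_raw)]
  expect_equal(sort(d$p_adjusted[upper.tri(d$p_adjusted)]),
               sort(p.adjust(praw, "BH")))
})

test_that("accuracy-ratio signed-rank test detects one-sided shifts", {
  # all 15 ratios above one: exact signed-rank p = 2 * 2^-15 < 0.05
  res <- acc_ratio_test(seq(101, 115), rep(100, 15))
  expect_lt(res$p, 0.05)
  expect_gt(res$median_ratio, 1)
  # degenerate all-equal case flagged with p = 1
  deg <- acc_ratio_test(rep(80, 10), rep(80, 10))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(acc_ratio_test(1:5, c(1, 2, 3, 4, 0)))
})

test_that("homogeneous subgroups are the cliques of the non-significance graph", {
  nm <- c("A", "B", "C", "D")
  p <- matrix(1, 4, 4, dimnames = list(nm, nm))
  # all pairs significant -> four singletons
  p_all <- p; p_all[upper.tri(p_all)] <- 0.001
  p_all[lower.tri(p_all)] <- t(p_all)[lower.tri(p_all)]
  sg <- homogeneous_subgroups(p_all)
  expect_equal(lengths(sg), rep(1, 4))
  # no pair significant -> one subgroup of all four
  sg2 <- homogeneous_subgroups(p)
  expect_equal(sg2, list(nm))
  # constructed graph: A-B, B-C, C-D non-significant, A-C, A-D, B-D sig.
  p3 <- p
  p3["A", "C"] <- p3["C", "A"] <- 0.01
  p3["A", "D"] <- p3["D", "A"] <- 0.01
  p3["B", "D"] <- p3["D", "B"] <- 0.01
  sg3 <- homogeneous_subgroups(p3)
  # oracle: brute-force maximal cliques on 4 nodes
  adj <- p3 >= 0.05; diag(adj) <- FALSE
  subsets <- unlist(lapply(1:4, function(k)
    combn(nm, k, simplify = FALSE)), recursive = FALSE)
  is_clique <- function(s) all(adj[s, s][upper.tri(diag(length(s)))])
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s)
    !any(vapply(cliques, function(c2)
      length(c2) > length(s) && all(s %in% c2), logical(1))), cliques)
  expect_setequal(lapply(sg3, sort), lapply(maximal, sort))
})

test_that("stats_report reproduces the study-level analysis layout", {
  # synthetic benchmark table with a clearly weak algorithm
  set.seed(55)
  rows <- do.call(rbind, lapply(c("r01", "r02"), function(rec) {
    do.call(rbind, lapply(c("GOOD", "MID", "BAD"), function(alg) {
      base <- c(GOOD = 95, MID = 90, BAD = 50)[[alg]]
      drop <- if (rec == "r02") 10 else 0
      data.frame(scenario_id = sprintf("%s_%02d", rec, 1:15),
                 record_id = rec, target_snr_db = -1, algorithm = alg,
                 acc_s1 = pmin(100, base - drop + rnorm(15, 0, 2)),
                 acc_s2 = NA, snr_in_db = NA, snr_out_db = NA,
                 snr_improvement_db = NA, interval_error_ms = NA,
                 stringsAsFactors = FALSE)
    }))
  }))
  rep_s <- stats_report(rows, "acc_s1")
  expect_equal(nrow(rep_s$descriptives), 6)   # 3 algorithms x 2 levels
  expect_lt(rep_s$kruskal$low$p, 0.05)
  expect_true(length(rep_s$subgroups$low) >= 1)
  # the weak algorithm separates from the strong one
  expect_false(any(vapply(rep_s$subgroups$low, function(s)
    all(c("GOOD", "BAD") %in% s), logical(1))))
  # ratio tests: every algorithm has low-noise accuracy above high-noise
  for (a in c("GOOD", "MID", "BAD")) {
    expect_gt(rep_s$ratio_tests[[a]]$median_ratio, 1)
    expect_lt(rep_s$ratio_tests[[a]]$p, 0.05)
  }
})
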