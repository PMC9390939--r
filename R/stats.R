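# Nonparametric comparison of the algorithms over the benchmark table:
# Shapiro-Wilk normality gate, median/IQR descriptives, Kruskal-Wallis,
# Dunn post hoc with Benjamini-Hochberg adjustment, homogeneous subgroups,
# and the Wilcoxon signed-rank test on low/high-noise accuracy ratios.

#' Median and interquartile range
#'
#' @param values nonempty numeric vector (NAs dropped).
#' @return Named vector `median`, `q1`, `q3` (type-7 quantiles).
#' @export
describe_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) > 0)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Shapiro-Wilk normality test
#'
#' Gate used to decide between parametric and nonparametric description;
#' deviations at p < 0.05 motivate the median/IQR summaries and rank tests.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` (W) and `p`.
#' @export
normality_gate <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (diff(range(values)) == 0)
    stop("all values identical: normality test undefined")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Kruskal-Wallis rank test across algorithm groups
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return List with `H` (tie-corrected statistic), `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  values <- unlist(groups)
  if (diff(range(values)) == 0)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- kruskal.test(values, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value)
}

#' Dunn's post-hoc test with Benjamini-Hochberg adjustment
#'
#' All pairwise Dunn z tests on the joint ranks (with tie correction),
#' two-sided p-values adjusted across the family of pairs by the
#' Benjamini-Hochberg procedure.
#'
#' @param groups named list of numeric vectors.
#' @return List with symmetric matrices `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc_bh <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  values <- unlist(groups)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  z <- p_raw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pair_p <- c()
  pair_idx <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j]))
      zij <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
      pij <- 2 * pnorm(-abs(zij))
      z[i, j] <- z[j, i] <- zij
      p_raw[i, j] <- p_raw[j, i] <- pij
      pair_p <- c(pair_p, pij)
      pair_idx[[length(pair_idx) + 1L]] <- c(i, j)
    }
  }
  p_adj_v <- p.adjust(pair_p, method = "BH")
  p_adj <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (m in seq_along(pair_idx)) {
    ij <- pair_idx[[m]]
    p_adj[ij[1], ij[2]] <- p_adj[ij[2], ij[1]] <- p_adj_v[m]
  }
  diag(z) <- 0; diag(p_raw) <- 1; diag(p_adj) <- 1
  list(z = z, p_raw = p_raw, p_adjusted = p_adj)
}

#' Wilcoxon signed-rank test on low/high-noise accuracy ratios
#'
#' Forms the elementwise ratios of paired low-noise and high-noise accuracy
#' values and tests whether their median differs from one (two-sided
#' signed-rank test on ratio - 1). Ratios above one indicate better
#' accuracy at the low interference level.
#'
#' @param acc_low,acc_high paired numeric vectors of equal length;
#'   `acc_high` must be positive.
#' @return List with `ratios`, `median_ratio`, `q1`, `q3`, `p` and a
#'   `degenerate` flag (all ratios exactly 1, reported as p = 1).
#' @export
acc_ratio_test <- function(acc_low, acc_high) {
  stopifnot(length(acc_low) == length(acc_high), all(acc_high > 0))
  ratios <- acc_low / acc_high
  d <- describe_median_iqr(ratios)
  if (all(ratios == 1))
    return(list(ratios = ratios, median_ratio = 1, q1 = d[["q1"]],
                q3 = d[["q3"]], p = 1, degenerate = TRUE))
  wt <- suppressWarnings(wilcox.test(ratios - 1, alternative = "two.sided"))
  list(ratios = ratios, median_ratio = d[["median"]], q1 = d[["q1"]],
       q3 = d[["q3"]], p = wt$p.value, degenerate = FALSE)
}

#' Homogeneous subgroups from a post-hoc p matrix
#'
#' Maximal subsets of algorithms in which no pair differs significantly at
#' level `alpha`: the maximal cliques of the graph whose edges connect
#' non-significant pairs. An algorithm may belong to several subgroups.
#'
#' @param adjusted_p symmetric matrix of adjusted pairwise p-values.
#' @param alpha significance level (default 0.05).
#' @return List of character vectors (subgroup memberships), ordered by
#'   first member.
#' @export
homogeneous_subgroups <- function(adjusted_p, alpha = 0.05) {
  stopifnot(is.matrix(adjusted_p), nrow(adjusted_p) == ncol(adjusted_p))
  nm <- rownames(adjusted_p)
  if (is.null(nm)) nm <- paste0("g", seq_len(nrow(adjusted_p)))
  adj <- adjusted_p >= alpha
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(gr)
  out <- lapply(cl, function(v) sort(nm[as.integer(v)]))
  out[order(vapply(out, `[`, character(1), 1), -lengths(out))]
}

#' Full statistical comparison of a benchmark table
#'
#' Reproduces the study-level analysis for one metric: per-algorithm
#' median (IQR) at the low (r01) and high (r02) interference levels,
#' Shapiro-Wilk normality gates, Kruskal-Wallis between-group tests per
#' level, Dunn/Benjamini-Hochberg post hoc with homogeneous subgroups when
#' the global test is significant, and (for accuracy metrics) the
#' signed-rank test on low/high ratios per algorithm.
#'
#' @param bench a benchmark table from [run_benchmark()].
#' @param metric column to analyse (e.g. `"acc_s1"`, `"acc_s2"`,
#'   `"snr_improvement_db"`, `"interval_error_ms"`).
#' @param alpha significance level.
#' @return A list of class `fpcg_stats` with `descriptives` (data frame),
#'   `kruskal` (per level), `posthoc`/`subgroups` (per level, when
#'   computed) and `ratio_tests` (per algorithm).
#' @export
stats_report <- function(bench, metric = "acc_s1", alpha = 0.05) {
  stopifnot(metric %in% names(bench))
  cells <- bench[bench$scenario_id != "Average", ]
  algs <- unique(cells$algorithm)
  levels_map <- c(r01 = "low", r02 = "high")
  split_groups <- function(rec) {
    sub <- cells[cells$record_id == rec, ]
    lapply(stats::setNames(algs, algs),
           function(a) sub[sub$algorithm == a, metric])
  }
  desc <- do.call(rbind, lapply(algs, function(a) {
    do.call(rbind, lapply(names(levels_map), function(rec) {
      v <- cells[cells$algorithm == a & cells$record_id == rec, metric]
      d <- describe_median_iqr(v)
      sw <- try(normality_gate(v), silent = TRUE)
      data.frame(algorithm = a, noise_level = levels_map[[rec]],
                 median = d[["median"]], q1 = d[["q1"]], q3 = d[["q3"]],
                 shapiro_p = if (inherits(sw, "try-error")) NA_real_
                             else sw$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  kruskal <- list(); posthoc <- list(); subgroups <- list()
  for (rec in names(levels_map)) {
    lev <- levels_map[[rec]]
    groups <- split_groups(rec)
    kruskal[[lev]] <- kruskal_wallis(groups)
    if (kruskal[[lev]]$p < alpha) {
      posthoc[[lev]] <- dunn_posthoc_bh(groups)
      subgroups[[lev]] <- homogeneous_subgroups(posthoc[[lev]]$p_adjusted,
                                                alpha)
    }
  }
  ratio_tests <- lapply(stats::setNames(algs, algs), function(a) {
    lo <- cells[cells$algorithm == a & cells$record_id == "r01", metric]
    hi <- cells[cells$algorithm == a & cells$record_id == "r02", metric]
    ok <- !is.na(lo) & !is.na(hi) & hi > 0
    if (sum(ok) < 3) return(NULL)
    acc_ratio_test(lo[ok], hi[ok])
  })
  structure(list(metric = metric, descriptives = desc, kruskal = kruskal,
                 posthoc = posthoc, subgroups = subgroups,
                 ratio_tests = ratio_tests, alpha = alpha),
            class = "fpcg_stats")
}

#' @export
print.fpcg_stats <- function(x, ...) {
  cat(sprintf("<fpcg_stats> metric %s\n", x$metric))
  for (lev in names(x$kruskal))
    cat(sprintf("  Kruskal-Wallis (%s): H = %.2f, p = %.4g\n", lev,
                x$kruskal[[lev]]$H, x$kruskal[[lev]]$p))
  for (lev in names(x$subgroups)) {
    cat(sprintf("  homogeneous subgroups (%s): %s\n", lev,
                paste(vapply(x$subgroups[[lev]], paste, character(1),
                             collapse = "+"), collapse = " | ")))
  }
  invisible(x)
}
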