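make_track <- function(values, starts = NULL, probe_len = 50L,
                       chrom = "chrI") {
  values <- as.matrix(values)
  if (is.null(starts)) starts <- (seq_len(nrow(values)) - 1L) * 86L
  probe_track(data.frame(chrom = chrom, start = as.integer(starts),
                         stringsAsFactors = FALSE),
              values, probe_len)
}

test_that("quantile normalization maps replicates onto mean order statistics", {
  tr <- make_track(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- quantile_normalize(tr)
  expect_equal(unname(out$intensity), cbind(c(2.5, 3.5, 4.5),
                                            c(2.5, 3.5, 4.5)))

  # identical replicates are a fixed point
  same <- make_track(cbind(c(1, 5, 2), c(1, 5, 2)))
  expect_equal(quantile_normalize(same)$intensity, same$intensity)

  # column means agree after normalization
  set.seed(1)
  x <- make_track(matrix(rnorm(300), ncol = 3))
  cm <- colMeans(quantile_normalize(x)$intensity)
  expect_equal(max(cm) - min(cm), 0, tolerance = 1e-12)

  expect_warning(quantile_normalize(make_track(matrix(1:5))), "single")
})

test_that("replicate summarization matches the stated estimators", {
  tr <- make_track(rbind(c(2, 2, 2), c(0, 0, 30), c(1, 2, 3)))
  m <- summarize_replicates(tr, "mean")
  expect_equal(m$value, c(2, 10, 2))
  b <- summarize_replicates(tr, "biweight")
  expect_equal(b$value[1], 2)
  expect_lt(b$value[2], 10)   # outlier down-weighted

  # direct one-step biweight formula evaluated independently
  x <- c(0, 0, 30)
  med <- median(x); s <- median(abs(x - med))
  u <- (x - med) / (5 * s + 1e-4)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  expect_equal(b$value[2], sum(w * x) / sum(w))

  x2 <- c(1, 2, 3)
  med <- median(x2); s <- median(abs(x2 - med))
  u <- (x2 - med) / (5 * s + 1e-4)
  w <- (1 - u^2)^2
  expect_equal(b$value[3], sum(w * x2) / sum(w))
})

test_that("replicate correlation is symmetric with unit diagonal", {
  tr <- make_track(cbind(c(1, 2, 3, 5), c(1, 2, 3, 5), -c(1, 2, 3, 5)))
  r <- replicate_correlation(tr)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(r, t(r))
  expect_warning(
    replicate_correlation(make_track(cbind(c(1, 1, 1), c(1, 2, 3)))),
    "zero-variance")
})

test_that("a flat track yields no peaks", {
  s <- summarize_replicates(make_track(matrix(1, nrow = 50, ncol = 2)),
                            "mean")
  expect_equal(nrow(call_tiling_peaks(s)), 0L)
})

test_that("a strong 6-probe run forms exactly one peak", {
  v <- rep(0, 100)
  v[41:46] <- 10
  s <- summarize_replicates(make_track(matrix(v)), "mean")
  suppressWarnings(pk <- call_tiling_peaks(s))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$n_probes, 6L)
  expect_equal(pk$start, 40L * 86L)
  expect_equal(pk$end, 45L * 86L + 50L)
  expect_equal(pk$score, 10)
  expect_gte(pk$neg_log10_p, 13)
})

test_that("runs separated by 150 bp merge into one peak", {
  # two 6-probe runs with a 150 bp inter-interval gap (> max_probe_gap so
  # they are distinct runs, < min_peak_distance so they merge)
  starts <- c(0:5 * 86L,                       # run 1: [0, 480)
              480L + 150L + 0:5 * 86L,         # run 2: [630, 1110)
              5000L + 0:87 * 86L)              # background probes
  v <- c(rep(10, 12), rep(0, 88))
  s <- summarize_replicates(make_track(matrix(v), starts = starts), "mean")
  suppressWarnings(pk <- call_tiling_peaks(s))
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start, pk$end), c(0L, 1110L))
  expect_equal(pk$n_probes, 12L)
})

test_that("grouping and merging agree with the brute-force oracle", {
  params <- carpet_params(neg_log_p_cutoff = 0, min_probes = 3L)
  withr::with_seed(42, {
    for (case in 1:20) {
      n <- sample(30:100, 1)
      starts <- cumsum(sample(c(86L, 86L, 86L, 172L, 400L), n,
                              replace = TRUE))
      v <- rnorm(n) + 6 * rbinom(n, 1, 0.3)
      s <- summarize_replicates(make_track(matrix(v), starts = starts),
                                "mean")
      got <- suppressWarnings(call_tiling_peaks(s, params))
      want <- oracle_group_merge(starts, v, 50L, params$percentile,
                                 params$min_probes, params$max_probe_gap,
                                 params$min_peak_distance)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  })
})

test_that("raising stringency never increases the peak count", {
  st <- simulate_study(sim_params(n_chroms = 1L, chrom_len = 500000L,
                                  n_genes = 25L, n_sites = 10L, seed = 2L))
  s <- summarize_replicates(quantile_normalize(st$tiling), "biweight")
  counts_pct <- sapply(c(0.90, 0.95, 0.99),
                       function(q) nrow(call_tiling_peaks(
                         s, carpet_params(percentile = q))))
  expect_true(all(diff(counts_pct) <= 0))
  counts_cut <- sapply(c(5, 13, 25, 60),
                       function(c) nrow(call_tiling_peaks(
                         s, carpet_params(neg_log_p_cutoff = c))))
  expect_true(all(diff(counts_cut) <= 0))
})

test_that("retained peaks respect the min-distance and containment invariants", {
  st <- simulate_study(sim_params(seed = 7L))
  s <- summarize_replicates(quantile_normalize(st$tiling), "biweight")
  pk <- call_tiling_peaks(s)
  expect_gt(nrow(pk), 0L)
  expect_true(all(pk$n_probes >= 5L))
  for (cn in unique(pk$chrom)) {
    d <- pk[pk$chrom == cn, ]
    if (nrow(d) >= 2L)
      expect_true(all(d$start[-1] - d$end[-nrow(d)] >=
                        carpet_params()$min_peak_distance))
  }
  expect_equal(sort(pk$rank), seq_len(nrow(pk)))
})

test_that("pure-noise tracks produce essentially no peaks at defaults", {
  false_calls <- sapply(1:10, function(sd) {
    p <- sim_params(n_chroms = 1L, chrom_len = 200000L, n_genes = 0L,
                    seed = sd)
    g <- make_genome(p)
    tr <- simulate_tiling_track(g, empty_truth_df(), p)
    s <- summarize_replicates(quantile_normalize(tr), "biweight")
    nrow(call_tiling_peaks(s))
  })
  expect_lte(mean(false_calls), 1)
})

test_that("evaluate_calls scores exact, empty and partial peak sets", {
  truth <- data.frame(chrom = "chrI", start = c(100L, 1000L),
                      end = c(300L, 1400L))
  exact <- data.frame(chrom = "chrI", start = c(100L, 1000L),
                      end = c(300L, 1400L))
  ev <- evaluate_calls(exact, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdr, 0)
  ev0 <- evaluate_calls(exact[0, ], truth)
  expect_equal(ev0$sensitivity, 0)
  half <- data.frame(chrom = "chrI", start = c(299L, 5000L),
                     end = c(400L, 5100L))
  evh <- evaluate_calls(half, truth)
  expect_equal(evh$sensitivity, 0.5)   # 1 bp overlap counts
  expect_equal(evh$fdr, 0.5)
})
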