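# Exhaustive two-sided rank-sum p by enumerating all rank splits.
exact_ranksum_oracle <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(N, n1)
  ws <- colSums(matrix(seq_len(N)[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

test_that("rank_sum_test matches the exhaustive enumeration oracle", {
  set.seed(100)
  for (rep in 1:30) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- runif(n1)
    y <- runif(n2)
    expect_equal(rank_sum_test(x, y), exact_ranksum_oracle(x, y),
                 tolerance = 1e-12)
  }
  # the worked case: maximal separation of 4 vs 4
  expect_equal(rank_sum_test(1:4, 5:8), exact_ranksum_oracle(1:4, 5:8))
  expect_equal(rank_sum_test(1:4, 5:8), 2 / choose(8, 4))
})

test_that("rank_sum_test handles symmetry, ties and degenerate input", {
  set.seed(101)
  x <- runif(10)
  y <- runif(14)
  expect_equal(rank_sum_test(x, y), rank_sum_test(y, x))
  expect_identical(rank_sum_test(rep(0.5, 3), rep(0.5, 3)), 1)
  expect_error(rank_sum_test(numeric(), 1), "empty")
  # tied data goes through the corrected normal approximation and agrees
  # with the reference implementation
  xt <- c(0.1, 0.1, 0.2, 0.3, 0.3)
  yt <- c(0.2, 0.2, 0.4, 0.4, 0.5)
  ref <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(rank_sum_test(xt, yt), ref)
})

test_that("vectorized per-probe p-values equal the scalar test", {
  set.seed(102)
  X1 <- matrix(runif(50 * 15), 50)
  X2 <- matrix(runif(50 * 20), 50)
  # inject ties and a constant probe
  X1[3, ] <- round(X1[3, ], 1)
  X2[3, ] <- round(X2[3, ], 1)
  X1[7, ] <- 0.4
  X2[7, ] <- 0.4
  pv <- methpanel:::wilcox_p_rows(X1, X2)
  ps <- vapply(seq_len(50), function(i) rank_sum_test(X1[i, ], X2[i, ]),
               numeric(1))
  expect_equal(pv, ps, tolerance = 1e-12)

  # small groups exercise the exact path
  Y1 <- matrix(runif(30 * 6), 30)
  Y2 <- matrix(runif(30 * 9), 30)
  pv2 <- methpanel:::wilcox_p_rows(Y1, Y2)
  ps2 <- vapply(seq_len(30), function(i) rank_sum_test(Y1[i, ], Y2[i, ]),
                numeric(1))
  expect_equal(pv2, ps2, tolerance = 1e-12)
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed non-trivial case: p*(m/i) then running minimum from the top
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
  set.seed(103)
  q <- runif(50)
  expect_true(all(bh_adjust(q) >= q))
  # adjusted values are non-decreasing along the raw-p ordering
  expect_true(all(diff(bh_adjust(q)[order(q)]) >= -1e-15))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("dmr_compare applies the 0.2 / 0.05 conjunction", {
  set.seed(104)
  n <- 20
  beta <- tibble::tibble(probe_id = sprintf("p%03d", 1:60))
  g1 <- paste0("A", 1:n)
  g2 <- paste0("B", 1:n)
  mu <- c(rep(0.6, 20), rep(0.2, 40))  # 20 shifted probes in group A
  for (s in g1) beta[[s]] <- rbeta(60, mu * 60, (1 - mu) * 60)
  for (s in g2) beta[[s]] <- rbeta(60, 0.2 * 60, 0.8 * 60)
  tb <- dmr_compare(beta, g1, g2)
  expect_identical(tb$delta, tb$mean_g1 - tb$mean_g2)
  expect_true(all(tb$p_adjusted >= tb$p_value))
  expect_true(all(tb$significant ==
                    (abs(tb$delta) >= 0.2 & tb$p_adjusted <= 0.05)))
  expect_true(all(tb$significant[1:20]))
  expect_false(any(tb$significant[21:60]))

  # identically distributed noise-free groups: all deltas zero, none called
  flat <- tibble::tibble(probe_id = c("q1", "q2"))
  for (s in c(g1[1:3], g2[1:3])) flat[[s]] <- c(0.4, 0.7)
  tb0 <- dmr_compare(flat, g1[1:3], g2[1:3])
  expect_true(all(tb0$delta == 0))
  expect_false(any(tb0$significant))

  expect_error(dmr_compare(beta, g1, c(g2, g1[1])), "overlap")
  expect_error(dmr_compare(beta, character(), g2), "empty")
})

test_that("planted markers are detected at the stated study conditions", {
  # delta 0.65, 40 vs 40, phi = 30: at least 99% of markers significant
  co <- roster_cohort()
  sheet <- co$sheet
  fb <- filter_probes(co$beta, co$annotation)
  g1 <- sheet$sample_id[sheet$project == "LIHC" & sheet$tissue_class == "tumor"]
  g2 <- sheet$sample_id[sheet$project == "BRCA" & sheet$tissue_class == "tumor"]
  tb <- dmr_compare(fb, g1, g2)
  mk <- intersect(co$truth$marker_probes$LIHC, tb$probe_id)
  hit <- tb$significant[match(mk, tb$probe_id)] &
    tb$delta[match(mk, tb$probe_id)] > 0
  expect_gte(mean(hit), 0.99)
})

test_that("intersect_significant equals the brute-force set intersection", {
  mk_table <- function(ids, sig, delta) {
    tibble::tibble(probe_id = ids, delta = delta, significant = sig)
  }
  ids <- sprintf("p%02d", 1:10)
  t1 <- mk_table(ids, c(rep(TRUE, 6), rep(FALSE, 4)), rep(0.4, 10))
  t2 <- mk_table(ids, c(rep(TRUE, 4), rep(FALSE, 6)), c(rep(0.4, 3), -0.4, rep(0.4, 6)))
  t3 <- mk_table(ids, rep(TRUE, 10), rep(0.4, 10))
  got <- intersect_significant(list(t1, t2, t3))
  want <- Reduce(intersect, list(
    ids[t1$significant & t1$delta > 0],
    ids[t2$significant & t2$delta > 0],
    ids[t3$significant & t3$delta > 0]
  ))
  expect_identical(got, want)
  expect_identical(got, ids[1:3])  # probe 4 flips sign, probes 5:6 fail t2
  expect_error(intersect_significant(list()), "at least one")
})

test_that("selection tiers respect their boundary cutoffs", {
  # constant-valued probes give exact means
  beta <- tibble::tibble(probe_id = c("clear", "border1", "border2"))
  tg <- paste0("T", 1:4)
  cp <- paste0("C", 1:4)
  probe_vals <- list(
    clear = c(0.80, 0.05),    # strict: delta .75, comparator .05
    border1 = c(0.35, 0.12),  # fails strict (.12 >= .1), passes relaxed
    border2 = c(0.35, 0.05)   # delta .30 not > .3 -> relaxed only
  )
  for (i in seq_along(tg)) {
    beta[[tg[i]]] <- vapply(probe_vals, `[[`, numeric(1), 1)
    beta[[cp[i]]] <- vapply(probe_vals, `[[`, numeric(1), 2)
  }
  target <- list(name = "T", sample_ids = tg)
  comps <- list(list(name = "C", sample_ids = cp))
  strict <- select_candidates(beta, target, comps, beta$probe_id, "strict")
  relaxed <- select_candidates(beta, target, comps, beta$probe_id, "relaxed")
  expect_identical(strict$probe_id, "clear")
  expect_setequal(relaxed$probe_id, c("clear", "border1", "border2"))
  # strict tier implies relaxed tier
  expect_true(all(strict$probe_id %in% relaxed$probe_id))
  # ordering by target mean, descending
  expect_identical(relaxed$probe_id[1], "clear")
  expect_error(select_candidates(beta, target, comps, "absent", "strict"),
               "absent")

  # "or" mode admits a probe passing only one relaxed condition
  beta$or_only <- NULL
  beta2 <- dplyr::bind_rows(beta, tibble::tibble(probe_id = "or_only"))
  for (i in seq_along(tg)) {
    beta2[[tg[i]]][4] <- 0.40
    beta2[[cp[i]]][4] <- 0.17  # delta .23 > .2 but comparator .17 >= .15
  }
  and_mode <- select_candidates(beta2, target, comps, beta2$probe_id,
                                "relaxed", relaxed_mode = "and")
  or_mode <- select_candidates(beta2, target, comps, beta2$probe_id,
                               "relaxed", relaxed_mode = "or")
  expect_false("or_only" %in% and_mode$probe_id)
  expect_true("or_only" %in% or_mode$probe_id)
})

test_that("normal-tissue verification annotates without removing", {
  beta <- tibble::tibble(probe_id = c("disc", "shared"))
  tg <- paste0("T", 1:3)
  nm <- paste0("N", 1:3)
  for (s in tg) beta[[s]] <- c(0.8, 0.8)
  for (s in nm) beta[[s]] <- c(0.05, 0.45)
  cands <- tibble::tibble(probe_id = c("disc", "shared"), target_mean = 0.8)
  out <- verify_in_normals(cands, beta, list(N = nm), nm)
  expect_identical(nrow(out), 2L)
  expect_identical(out$normal_status,
                   c("normal_discriminating", "shared_with_normal"))
  expect_equal(out$paired_normal_mean, c(0.05, 0.45))
})

test_that("planted shared probes are flagged as shared with normal tissue", {
  co <- small_cohort()
  run <- small_run()
  shared <- co$truth$shared_probes$PAAD
  paad <- run$candidates[run$candidates$cancer == "PAAD", ]
  found <- paad[paad$probe_id %in% shared, ]
  expect_gt(nrow(found), 0)
  expect_true(all(found$normal_status == "shared_with_normal"))
})

test_that("comparison plans have the stated structure", {
  co <- small_cohort()
  ident <- co$sheet[co$sheet$dataset == "identification", ]
  plan <- comparison_plan(ident, "non-clustered")
  # tumor and normal group per project, all pairs
  expect_length(plan$groups, 6)
  expect_identical(nrow(plan$pairs), 15L)

  # clustered plan: no same-cancer MC pairs
  fb <- filter_probes(co$beta, co$annotation)
  asg <- purrr::map(stats::setNames(unique(ident$project), unique(ident$project)),
                    function(p) {
    tums <- ident$sample_id[ident$project == p & ident$tissue_class == "tumor"]
    suppressWarnings(rpmm_cluster(fb, tums, k = 120, seed = 2L, project = p))
  })
  plan2 <- comparison_plan(ident, "clustered", asg)
  for (i in seq_len(nrow(plan2$pairs))) {
    a <- plan2$meta[[plan2$pairs$g1[i]]]
    b <- plan2$meta[[plan2$pairs$g2[i]]]
    expect_false(a$kind == "tumor" && b$kind == "tumor" &&
                   a$project == b$project)
  }
  # the clustered plan is at least as large as the non-clustered one
  expect_gte(nrow(plan2$pairs), nrow(plan$pairs))
})
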