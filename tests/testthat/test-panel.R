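toy_beta <- function(values) {
  # values: named list sample -> numeric vector over probes p1..pk
  k <- length(values[[1]])
  beta <- tibble::tibble(probe_id = paste0("p", seq_len(k)))
  for (s in names(values)) beta[[s]] <- values[[s]]
  beta
}

test_that("max-beta calling uses a strict cutoff", {
  beta <- toy_beta(list(S1 = c(0.10, 0.29), S2 = c(0.10, 0.31),
                        S3 = c(0.30, 0.30)))
  pan <- panel("X", c("p1", "p2"))
  calls <- call_samples(beta, pan)
  expect_equal(calls$max_beta, c(0.29, 0.31, 0.30))
  # a value of exactly 0.3 is negative under the strict rule
  expect_identical(calls$call, c(FALSE, TRUE, FALSE))

  expect_error(call_samples(beta, panel("X", "p9")), "p9")
  beta$S1[1] <- NA
  expect_error(call_samples(beta, pan), "p1.*S1")
  expect_error(panel("X", character()), "length")
  expect_error(panel("X", c("a", "a")), "anyDuplicated")
})

test_that("metrics_from_counts reproduces the worked confusion examples", {
  # large-cohort identification row
  m <- metrics_from_counts(list(
    target_pos = 344, target_n = 377, paired_normal_neg = 50,
    paired_normal_n = 50, other_ts_neg = 2116, other_ts_n = 2232,
    other_all_neg = 2357, other_all_n = 2476, total_n = 2853
  ))
  expect_equal(
    unlist(m[, c("sensitivity", "cancer_specificity", "ts_specificity",
                 "all_samples_specificity", "accuracy")], use.names = FALSE),
    c(91.2, 100.0, 94.8, 95.2, 94.7)
  )
  # low-sensitivity row
  m2 <- metrics_from_counts(list(
    target_pos = 28, target_n = 36, paired_normal_neg = 9, paired_normal_n = 9,
    other_ts_neg = 2338, other_ts_n = 2573, other_all_neg = 2582,
    other_all_n = 2817, total_n = 2853
  ))
  expect_equal(
    unlist(m2[, c("sensitivity", "cancer_specificity", "ts_specificity",
                  "all_samples_specificity", "accuracy")], use.names = FALSE),
    c(77.8, 100.0, 90.9, 91.7, 91.5)
  )
  # perfect classifier
  m3 <- metrics_from_counts(list(
    target_pos = 10, target_n = 10, paired_normal_neg = 5, paired_normal_n = 5,
    other_ts_neg = 20, other_ts_n = 20, other_all_neg = 25, other_all_n = 25,
    total_n = 35
  ))
  expect_true(all(unlist(m3[, 10:14]) == 100))
  # zero denominator -> not applicable
  m4 <- metrics_from_counts(list(
    target_pos = 1, target_n = 2, paired_normal_neg = 0, paired_normal_n = 0,
    other_ts_neg = 1, other_ts_n = 1, other_all_neg = 1, other_all_n = 1,
    total_n = 3
  ))
  expect_true(is.na(m4$cancer_specificity))
  expect_error(metrics_from_counts(list(
    target_pos = 3, target_n = 2, paired_normal_neg = 0, paired_normal_n = 1,
    other_ts_neg = 0, other_ts_n = 1, other_all_neg = 0, other_all_n = 1,
    total_n = 3
  )), "exceeds")
})

test_that("percent rounding is half-up to one decimal", {
  expect_equal(methpanel:::round_half_up1(91.25), 91.3)
  expect_equal(methpanel:::round_half_up1(91.24999), 91.2)
  expect_equal(methpanel:::round_half_up1(100), 100)
  # round() would give 91.2 here (banker's rounding); half-up must not
  expect_equal(methpanel:::pct(9125, 10000), 91.3)
})

test_that("evaluate_panel equals a brute-force per-sample loop", {
  set.seed(200)
  for (rep in 1:3) {
    n_probe <- 8
    projects <- c("A", "B", "C")
    sheet <- tibble::tibble(
      sample_id = sprintf("S%02d", 1:30),
      project = rep(projects, each = 10),
      tissue_class = rep(c(rep("tumor", 7), rep("normal", 3)), 3),
      dataset = "identification", ffpe = FALSE
    )
    beta <- tibble::tibble(probe_id = paste0("p", 1:n_probe))
    for (s in sheet$sample_id) beta[[s]] <- runif(n_probe)
    pan <- panel("A", sample(beta$probe_id, 3))
    ev <- evaluate_panel(beta, sheet, pan)

    # independent loop
    pos <- vapply(sheet$sample_id, function(s) {
      max(beta[[s]][match(pan$probes, beta$probe_id)]) > pan$cutoff
    }, logical(1))
    is_t <- sheet$project == "A" & sheet$tissue_class == "tumor"
    is_n <- sheet$project == "A" & sheet$tissue_class == "normal"
    is_ot <- !is_t & sheet$tissue_class == "tumor"
    want <- metrics_from_counts(list(
      target_pos = sum(pos[is_t]), target_n = sum(is_t),
      paired_normal_neg = sum(!pos[is_n]), paired_normal_n = sum(is_n),
      other_ts_neg = sum(!pos[is_ot]), other_ts_n = sum(is_ot),
      other_all_neg = sum(!pos[!is_t]), other_all_n = sum(!is_t),
      total_n = nrow(sheet)
    ))
    expect_equal(ev$metrics, want)

    # invariance to sample and probe order
    perm_beta <- beta[sample(nrow(beta)), c(1, 1 + sample(nrow(sheet)))]
    perm_sheet <- sheet[sample(nrow(sheet)), ]
    ev2 <- evaluate_panel(perm_beta, perm_sheet, pan)
    expect_equal(ev2$metrics, ev$metrics)
  }
})

test_that("a separable toy panel scores 100 everywhere", {
  sheet <- tibble::tibble(
    sample_id = c("T1", "T2", "N1", "O1", "O2"),
    project = c("A", "A", "A", "B", "B"),
    tissue_class = c("tumor", "tumor", "normal", "tumor", "tumor"),
    dataset = "identification", ffpe = FALSE
  )
  beta <- toy_beta(list(T1 = 1, T2 = 1, N1 = 0, O1 = 0, O2 = 0))
  ev <- evaluate_panel(beta, sheet, panel("A", "p1"))
  expect_true(all(unlist(ev$metrics[, 10:14]) == 100))
  expect_error(evaluate_panel(beta, sheet, panel("Z", "p1")), "absent")
})

test_that("adding probes is monotone: sensitivity up, specificities down", {
  set.seed(201)
  for (rep in 1:5) {
    sheet <- tibble::tibble(
      sample_id = sprintf("S%02d", 1:24),
      project = rep(c("A", "B"), each = 12),
      tissue_class = rep(c(rep("tumor", 9), rep("normal", 3)), 2),
      dataset = "identification", ffpe = FALSE
    )
    beta <- tibble::tibble(probe_id = paste0("p", 1:6))
    for (s in sheet$sample_id) beta[[s]] <- runif(6)
    probes <- sample(beta$probe_id)
    prev <- NULL
    for (m in 1:4) {
      ev <- evaluate_panel(beta, sheet, panel("A", probes[1:m]))
      if (!is.null(prev)) {
        expect_gte(ev$metrics$sensitivity, prev$sensitivity)
        expect_lte(ev$metrics$ts_specificity, prev$ts_specificity)
        expect_lte(ev$metrics$all_samples_specificity,
                   prev$all_samples_specificity)
        expect_lte(ev$metrics$cancer_specificity, prev$cancer_specificity)
      }
      prev <- ev$metrics
    }
  }
})

test_that("metastasis evaluation reproduces its worked example", {
  # 13/13 target metastases positive, 15/18 other metastases negative
  m <- metastasis_metrics_from_counts(list(
    target_pos = 13, target_n = 13, other_mts_neg = 15, other_mts_n = 18,
    other_ts_neg = 350, other_ts_n = 438, other_all_neg = 695,
    other_all_n = 802, total_n = 813
  ))
  expect_equal(m$metastasis_sensitivity, 100.0)
  expect_equal(m$metastasis_specificity, 83.3)

  # structured end-to-end check with explicit classes
  sheet <- tibble::tibble(
    sample_id = c("M1", "M2", "M3", "OM1", "OM2", "T1", "T2", "N1"),
    project = c("A", "A", "A", "B", "B", "A", "B", "A"),
    tissue_class = c("metastasis", "metastasis", "metastasis", "metastasis",
                     "metastasis", "tumor", "tumor", "normal"),
    dataset = "verification", ffpe = FALSE
  )
  beta <- toy_beta(list(M1 = 0.9, M2 = 0.9, M3 = 0.1, OM1 = 0.1, OM2 = 0.9,
                        T1 = 0.9, T2 = 0.1, N1 = 0.1))
  ev <- evaluate_metastasis_panel(beta, sheet, panel("A", "p1"))
  m2 <- ev$metrics
  expect_equal(m2$target_pos, 2)          # M1, M2
  expect_equal(m2$metastasis_sensitivity, 66.7)
  expect_equal(m2$other_mts_neg, 1)       # OM1
  expect_equal(m2$metastasis_specificity, 50.0)
  expect_equal(m2$other_ts_n, 4)          # T1 T2 OM1 OM2
  expect_equal(m2$other_all_n, 5)         # + N1
  # no target metastasis called positive -> sensitivity 0
  beta0 <- beta
  beta0$M1 <- beta0$M2 <- 0.1
  ev0 <- evaluate_metastasis_panel(beta0, sheet, panel("A", "p1"))
  expect_equal(ev0$metrics$metastasis_sensitivity, 0.0)
})

test_that("greedy panel construction behaves on constructed fixtures", {
  # one candidate that detects everything alone -> panel of exactly 1
  sheet <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:20),
    project = rep(c("A", "B"), each = 10),
    tissue_class = rep(c(rep("tumor", 8), rep("normal", 2)), 2),
    dataset = "identification", ffpe = FALSE
  )
  a_tumors <- sheet$sample_id[sheet$project == "A" & sheet$tissue_class == "tumor"]
  beta <- tibble::tibble(probe_id = c("perfect", "half1", "half2"))
  for (s in sheet$sample_id) {
    in_a <- s %in% a_tumors
    first_half <- in_a && s %in% a_tumors[1:4]
    beta[[s]] <- c(ifelse(in_a, 0.9, 0.05),
                   ifelse(first_half, 0.9, 0.05),
                   ifelse(in_a && !first_half, 0.9, 0.05))
  }
  cands <- tibble::tibble(probe_id = c("perfect", "half1", "half2"),
                          target_mean = c(0.9, 0.5, 0.5))
  pan <- build_panel(cands, beta, sheet, "A")
  expect_identical(pan$probes, "perfect")

  # two candidates covering disjoint halves -> both selected, union coverage
  cands2 <- cands[cands$probe_id != "perfect", ]
  pan2 <- build_panel(cands2, beta, sheet, "A")
  expect_setequal(pan2$probes, c("half1", "half2"))
  ev <- evaluate_panel(beta, sheet, pan2)
  expect_equal(ev$metrics$sensitivity, 100)

  expect_error(build_panel(cands[0, ], beta, sheet, "A"), "no candidates")
})

test_that("greedy panels reach the exhaustive optimum on small pools", {
  set.seed(202)
  n_done <- 0L
  for (rep in 1:5) {
    n_cand <- sample(5:9, 1)
    fx <- candidate_pool_fixture(n_cand)
    best <- tryCatch(build_panel(fx$cands, fx$beta, fx$sheet, "A",
                                 exhaustive = TRUE),
                     error = function(e) NULL)
    if (is.null(best)) next
    greedy <- build_panel(fx$cands, fx$beta, fx$sheet, "A", spec_slack = 100)
    sg <- evaluate_panel(fx$beta, fx$sheet, greedy)$metrics$sensitivity
    sb <- evaluate_panel(fx$beta, fx$sheet, best)$metrics$sensitivity
    expect_gte(sg, sb - 5)
    n_done <- n_done + 1L
  }
  expect_gte(n_done, 3L)
})

test_that("cfDNA evaluation reports per-probe betas and calls", {
  sheet <- tibble::tibble(
    sample_id = c("CF1", "CF2", "T1"),
    project = c("A", "A", "A"),
    tissue_class = c("cfdna", "cfdna", "tumor"),
    dataset = "verification", ffpe = FALSE
  )
  beta <- toy_beta(list(CF1 = c(0.05, 0.1), CF2 = c(0.5, 0.1), T1 = c(0.9, 0.9)))
  out <- evaluate_cfdna(beta, sheet, panel("A", c("p1", "p2")))
  expect_identical(out$calls$call, c(FALSE, TRUE))
  expect_identical(nrow(out$probe_betas), 4L)
  expect_equal(out$probe_betas$beta[out$probe_betas$sample_id == "CF2" &
                                      out$probe_betas$probe_id == "p1"], 0.5)
})
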