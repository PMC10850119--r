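#' Construct a diagnostic probe panel
#'
#' A panel is an ordered set of probes used jointly under the max-beta call
#' rule: a sample is called hypermethylated iff its maximum beta over the
#' panel probes strictly exceeds the cutoff (default 0.3; a value of
#' exactly 0.3 is negative).
#'
#' @param target Cancer label the panel diagnoses.
#' @param probes Non-empty character vector of unique probe ids.
#' @param cutoff Call threshold in (0, 1).
#' @param approach `"non-clustered"` or `"clustered"` provenance label.
#' @return A `meth_panel` object.
#' @export
panel <- function(target, probes, cutoff = 0.3, approach = "non-clustered") {
  stopifnot(length(probes) >= 1, !anyDuplicated(probes),
            cutoff > 0, cutoff < 1)
  structure(list(target = target, probes = as.character(probes),
                 cutoff = cutoff, approach = approach),
            class = "meth_panel")
}

#' @export
print.meth_panel <- function(x, ...) {
  cat(sprintf("<meth_panel> %s (%s approach), cutoff %.2f\n  %d probes: %s\n",
              x$target, x$approach, x$cutoff, length(x$probes),
              paste(x$probes, collapse = " ")))
  invisible(x)
}

#' Call samples with a panel
#'
#' @param beta A beta tibble.
#' @param pan A `meth_panel`.
#' @param sample_ids Samples to call (default: all columns of `beta`).
#' @return Tibble: `sample_id`, `max_beta`, `call` (logical,
#'   `max_beta > cutoff`).
#' @export
call_samples <- function(beta, pan, sample_ids = NULL) {
  stopifnot(inherits(pan, "meth_panel"))
  if (is.null(sample_ids)) sample_ids <- names(beta)[-1]
  missing <- setdiff(pan$probes, beta$probe_id)
  if (length(missing)) {
    stop("panel probe(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- beta_values(beta[match(pan$probes, beta$probe_id), , drop = FALSE],
                      sample_ids)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing beta for panel probe %s in sample %s",
                 rownames(vals)[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  mx <- apply(vals, 2, max)
  tibble::tibble(sample_id = sample_ids, max_beta = unname(mx),
                 call = unname(mx > pan$cutoff))
}

# percentages rounded half-up to one decimal
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10
pct <- function(num, den) {
  ifelse(den > 0, round_half_up1(100 * num / den), NA_real_)
}

#' Panel statistics from confusion counts
#'
#' Computes the five evaluation statistics from their underlying counts:
#' sensitivity (target tumors called positive), cancer specificity (the
#' target cancer's paired normals called negative), tumor-samples
#' specificity (all non-target tumor samples negative), all-samples
#' specificity (every non-target sample negative) and diagnostic accuracy
#' (`(target_pos + other_all_neg) / total_n`). Percentages are rounded
#' half-up to one decimal; a zero denominator yields `NA` (not
#' applicable).
#'
#' @param counts A list, one-row data frame or named vector with
#'   `target_pos`, `target_n`, `paired_normal_neg`, `paired_normal_n`,
#'   `other_ts_neg`, `other_ts_n`, `other_all_neg`, `other_all_n`,
#'   `total_n`.
#' @return One-row tibble: the nine counts plus `sensitivity`,
#'   `cancer_specificity`, `ts_specificity`, `all_samples_specificity`,
#'   `accuracy`.
#' @export
metrics_from_counts <- function(counts) {
  counts <- as.list(counts)
  need <- c("target_pos", "target_n", "paired_normal_neg", "paired_normal_n",
            "other_ts_neg", "other_ts_n", "other_all_neg", "other_all_n",
            "total_n")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count(s): ", paste(miss, collapse = ", "), call. = FALSE)
  counts <- purrr::map(counts[need], as.numeric)
  if (any(unlist(counts) < 0)) stop("negative count", call. = FALSE)
  with(counts, {
    if (target_pos > target_n || paired_normal_neg > paired_normal_n ||
        other_ts_neg > other_ts_n || other_all_neg > other_all_n) {
      stop("count exceeds its denominator", call. = FALSE)
    }
    tibble::tibble(
      target_pos = target_pos, target_n = target_n,
      paired_normal_neg = paired_normal_neg, paired_normal_n = paired_normal_n,
      other_ts_neg = other_ts_neg, other_ts_n = other_ts_n,
      other_all_neg = other_all_neg, other_all_n = other_all_n,
      total_n = total_n,
      sensitivity = pct(target_pos, target_n),
      cancer_specificity = pct(paired_normal_neg, paired_normal_n),
      ts_specificity = pct(other_ts_neg, other_ts_n),
      all_samples_specificity = pct(other_all_neg, other_all_n),
      accuracy = pct(target_pos + other_all_neg, total_n)
    )
  })
}

#' Evaluate a panel on primary tumors and normals
#'
#' Calls every tumor and normal sample of the chosen dataset and
#' aggregates: target = the panel cancer's tumor samples, paired normals =
#' that cancer's normal samples, other tumors = all remaining tumor
#' samples, all others = every non-target sample including the target
#' cancer's normals.
#'
#' @param beta A beta tibble.
#' @param sheet Sample sheet.
#' @param pan A `meth_panel`.
#' @param scope Dataset to evaluate on: `"identification"` or
#'   `"verification"`.
#' @return A `panel_eval`: `calls` (per-sample tibble with sheet columns),
#'   `metrics` (one-row tibble from [metrics_from_counts()]), `panel`,
#'   `scope`.
#' @export
evaluate_panel <- function(beta, sheet, pan, scope = "identification") {
  scope <- match.arg(scope, dataset_labels)
  sub <- sheet[sheet$dataset == scope & !sheet$ffpe &
                 sheet$tissue_class %in% c("tumor", "normal"), , drop = FALSE]
  sub <- sub[sub$sample_id %in% names(beta)[-1], , drop = FALSE]
  if (!any(sub$project == pan$target & sub$tissue_class == "tumor")) {
    stop("target cancer ", pan$target, " absent from ", scope, " scope", call. = FALSE)
  }
  calls <- dplyr::inner_join(call_samples(beta, pan, sub$sample_id), sub,
                             by = "sample_id")
  is_target <- calls$project == pan$target & calls$tissue_class == "tumor"
  is_paired <- calls$project == pan$target & calls$tissue_class == "normal"
  is_other_ts <- !is_target & calls$tissue_class == "tumor"
  metrics <- metrics_from_counts(list(
    target_pos = sum(calls$call[is_target]),
    target_n = sum(is_target),
    paired_normal_neg = sum(!calls$call[is_paired]),
    paired_normal_n = sum(is_paired),
    other_ts_neg = sum(!calls$call[is_other_ts]),
    other_ts_n = sum(is_other_ts),
    other_all_neg = sum(!calls$call[!is_target]),
    other_all_n = sum(!is_target),
    total_n = nrow(calls)
  ))
  structure(list(calls = calls, metrics = metrics, panel = pan, scope = scope),
            class = "panel_eval")
}

#' @export
print.panel_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<panel_eval> %s panel on %s scope (%d samples)\n",
              x$panel$target, x$scope, m$total_n))
  cat(sprintf(
    "  sensitivity %.1f%% | cancer spec %.1f%% | TS spec %.1f%% | all-samples spec %.1f%% | accuracy %.1f%%\n",
    m$sensitivity, m$cancer_specificity, m$ts_specificity,
    m$all_samples_specificity, m$accuracy))
  invisible(x)
}

#' Evaluate a panel on metastasis samples
#'
#' Metastasis variant of the five statistics: sensitivity over the target
#' cancer's metastases; metastasis specificity = other cancers' metastases
#' called negative; tumor-samples specificity over all primary tumors plus
#' the other metastases; all-samples specificity over every sample except
#' the target metastases; accuracy analogous. With no other metastases the
#' metastasis specificity is `NA`.
#'
#' @param beta A beta tibble.
#' @param sheet Sample sheet.
#' @param pan A `meth_panel`.
#' @param scope Dataset holding the metastases (default `"verification"`).
#' @return A `panel_eval` with metastasis-variant metrics
#'   (`metastasis_sensitivity`, `metastasis_specificity`,
#'   `ts_specificity`, `all_samples_specificity`, `accuracy`).
#' @export
evaluate_metastasis_panel <- function(beta, sheet, pan, scope = "verification") {
  scope <- match.arg(scope, dataset_labels)
  sub <- sheet[sheet$dataset == scope & !sheet$ffpe &
                 sheet$tissue_class %in% c("tumor", "normal", "metastasis"), ,
               drop = FALSE]
  sub <- sub[sub$sample_id %in% names(beta)[-1], , drop = FALSE]
  if (!any(sub$tissue_class == "metastasis" & sub$project == pan$target)) {
    stop("no ", pan$target, " metastases in ", scope, " scope", call. = FALSE)
  }
  calls <- dplyr::inner_join(call_samples(beta, pan, sub$sample_id), sub,
                             by = "sample_id")
  is_target_mts <- calls$tissue_class == "metastasis" & calls$project == pan$target
  is_other_mts <- calls$tissue_class == "metastasis" & calls$project != pan$target
  is_ts <- calls$tissue_class == "tumor" | is_other_mts
  is_other <- !is_target_mts
  metrics <- metastasis_metrics_from_counts(list(
    target_pos = sum(calls$call[is_target_mts]),
    target_n = sum(is_target_mts),
    other_mts_neg = sum(!calls$call[is_other_mts]),
    other_mts_n = sum(is_other_mts),
    other_ts_neg = sum(!calls$call[is_ts]),
    other_ts_n = sum(is_ts),
    other_all_neg = sum(!calls$call[is_other]),
    other_all_n = sum(is_other),
    total_n = nrow(calls)
  ))
  structure(list(calls = calls, metrics = metrics, panel = pan, scope = scope),
            class = "panel_eval")
}

#' Metastasis-variant statistics from counts
#'
#' Count-level companion of [evaluate_metastasis_panel()], used for worked
#' examples quoted from published confusion tables.
#'
#' @param counts List with `target_pos`, `target_n`, `other_mts_neg`,
#'   `other_mts_n`, `other_ts_neg`, `other_ts_n`, `other_all_neg`,
#'   `other_all_n`, `total_n`.
#' @return One-row tibble of counts and the five statistics.
#' @export
metastasis_metrics_from_counts <- function(counts) {
  counts <- purrr::map(as.list(counts), as.numeric)
  need <- c("target_pos", "target_n", "other_mts_neg", "other_mts_n",
            "other_ts_neg", "other_ts_n", "other_all_neg", "other_all_n",
            "total_n")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count(s): ", paste(miss, collapse = ", "), call. = FALSE)
  with(counts[need], tibble::tibble(
    target_pos = target_pos, target_n = target_n,
    other_mts_neg = other_mts_neg, other_mts_n = other_mts_n,
    other_ts_neg = other_ts_neg, other_ts_n = other_ts_n,
    other_all_neg = other_all_neg, other_all_n = other_all_n,
    total_n = total_n,
    metastasis_sensitivity = pct(target_pos, target_n),
    metastasis_specificity = pct(other_mts_neg, other_mts_n),
    ts_specificity = pct(other_ts_neg, other_ts_n),
    all_samples_specificity = pct(other_all_neg, other_all_n),
    accuracy = pct(target_pos + other_all_neg, total_n)
  ))
}

# sensitivity/specificity of a probe subset under max-calling, given a
# logical call matrix (probes x samples) and index vectors
subset_stats <- function(call_mat, probes, is_target, is_paired, is_other) {
  hit <- if (length(probes) == 1) call_mat[probes, ] else
    apply(call_mat[probes, , drop = FALSE], 2, any)
  list(
    sens = 100 * sum(hit & is_target) / max(sum(is_target), 1),
    cancer_spec = if (sum(is_paired)) 100 * sum(!hit & is_paired) / sum(is_paired) else NA_real_,
    all_spec = 100 * sum(!hit & is_other) / max(sum(is_other), 1),
    n_detected = sum(hit & is_target)
  )
}

#' Greedy construction of a diagnostic panel
#'
#' Ranks candidates by the stated preferences (selected in more target
#' methylation clusters first, then higher target mean, then probe id) and
#' grows the panel greedily: at each step the feasible candidate that
#' maximizes sensitivity on the identification scope is added, where
#' feasible means cancer specificity stays at or above
#' `min_cancer_specificity` and the all-samples specificity does not drop
#' more than `spec_slack` points below its current value. Growth stops
#' when the best addition newly detects fewer than `min_gain` target
#' samples; the result is the smallest prefix achieving the final
#' sensitivity.
#'
#' The cancer-specificity constraint is waived when every candidate is
#' `shared_with_normal` (a panel for a cancer whose markers are also
#' methylated in its tissue of origin is allowed, and its cancer
#' specificity is reported, not enforced).
#'
#' With `exhaustive = TRUE` (at most 12 candidates) all non-empty subsets
#' are scored under the cancer-specificity constraint and the
#' highest-sensitivity, smallest subset is returned.
#'
#' @param cands Candidate tibble ([select_candidates()], optionally
#'   [verify_in_normals()]; a column `n_target_mcs` is honoured if
#'   present).
#' @param beta A beta tibble.
#' @param sheet Sample sheet.
#' @param target Cancer label.
#' @param cutoff Call cutoff.
#' @param scope Dataset used for construction.
#' @param min_cancer_specificity Constraint, percent (default 90).
#' @param spec_slack Allowed drop in all-samples specificity per step,
#'   points (default 2).
#' @param min_gain Minimal newly detected target samples per step.
#' @param exhaustive Score all subsets instead of greedy growth.
#' @param approach Provenance label for the panel.
#' @return A `meth_panel`.
#' @export
build_panel <- function(cands, beta, sheet, target, cutoff = 0.3,
                        scope = "identification",
                        min_cancer_specificity = 90, spec_slack = 2,
                        min_gain = 1, exhaustive = FALSE,
                        approach = "non-clustered") {
  if (!nrow(cands)) stop("no candidates for target ", target, call. = FALSE)
  sub <- sheet[sheet$dataset == scope & !sheet$ffpe &
                 sheet$tissue_class %in% c("tumor", "normal"), , drop = FALSE]
  sub <- sub[sub$sample_id %in% names(beta)[-1], , drop = FALSE]
  enforce_cs <- !("normal_status" %in% names(cands)) ||
    any(cands$normal_status == "normal_discriminating")

  n_mcs <- if ("n_target_mcs" %in% names(cands)) cands$n_target_mcs else
    rep(1L, nrow(cands))
  ord <- order(-n_mcs, -cands$target_mean, cands$probe_id)
  probes <- cands$probe_id[ord]

  vals <- beta_values(beta[match(probes, beta$probe_id), , drop = FALSE],
                      sub$sample_id)
  call_mat <- vals > cutoff
  is_target <- sub$project == target & sub$tissue_class == "tumor"
  is_paired <- sub$project == target & sub$tissue_class == "normal"
  is_other <- !is_target

  feasible <- function(st, cur_all_spec) {
    (!enforce_cs || is.na(st$cancer_spec) ||
       st$cancer_spec >= min_cancer_specificity) &&
      st$all_spec >= cur_all_spec - spec_slack
  }

  if (exhaustive) {
    if (length(probes) > 12) stop("exhaustive search limited to 12 candidates", call. = FALSE)
    best <- NULL
    for (size in seq_along(probes)) {
      subsets <- utils::combn(probes, size, simplify = FALSE)
      for (s in subsets) {
        st <- subset_stats(call_mat, s, is_target, is_paired, is_other)
        ok <- !enforce_cs || is.na(st$cancer_spec) ||
          st$cancer_spec >= min_cancer_specificity
        if (ok && (is.null(best) || st$sens > best$sens + 1e-9)) {
          best <- list(sens = st$sens, probes = s)
        }
      }
    }
    if (is.null(best)) stop("no feasible subset for target ", target, call. = FALSE)
    return(panel(target, best$probes, cutoff, approach))
  }

  chosen <- character()
  detected <- 0
  cur_all_spec <- -Inf  # the empty panel constrains nothing yet
  remaining <- probes
  while (length(remaining)) {
    stats_list <- purrr::map(remaining, function(pr) {
      subset_stats(call_mat, c(chosen, pr), is_target, is_paired, is_other)
    })
    ok <- purrr::map_lgl(stats_list, feasible, cur_all_spec = cur_all_spec)
    if (!any(ok)) break
    sens <- purrr::map_dbl(stats_list, "sens")
    sens[!ok] <- -Inf
    pick <- which.max(sens)  # ties resolve to the best-ranked candidate
    st <- stats_list[[pick]]
    if (st$n_detected - detected < min_gain) break
    chosen <- c(chosen, remaining[pick])
    detected <- st$n_detected
    cur_all_spec <- st$all_spec
    remaining <- remaining[-pick]
  }
  if (!length(chosen)) {
    # no addition achieved the minimal gain under the constraints; fall back
    # to the single best-ranked feasible candidate
    st1 <- purrr::map(probes, function(pr) {
      subset_stats(call_mat, pr, is_target, is_paired, is_other)
    })
    ok <- purrr::map_lgl(st1, feasible, cur_all_spec = -Inf)
    if (!any(ok)) stop("no feasible candidate for target ", target, call. = FALSE)
    chosen <- probes[which(ok)[which.max(purrr::map_dbl(st1[ok], "sens"))]]
  }
  # smallest prefix achieving the final sensitivity
  final_sens <- subset_stats(call_mat, chosen, is_target, is_paired, is_other)$sens
  for (m in seq_along(chosen)) {
    if (subset_stats(call_mat, chosen[seq_len(m)], is_target, is_paired,
                     is_other)$sens >= final_sens - 1e-9) {
      chosen <- chosen[seq_len(m)]
      break
    }
  }
  panel(target, chosen, cutoff, approach)
}

#' Call cell-free DNA samples with a panel
#'
#' Per-sample, per-probe betas and the overall max-beta call for every
#' cfDNA sample. Sample counts in cfDNA studies are small, so no aggregate
#' statistics are computed.
#'
#' @param beta A beta tibble.
#' @param sheet Sample sheet.
#' @param pan A `meth_panel`.
#' @return List: `calls` (tibble `sample_id`, `project`, `max_beta`,
#'   `call`) and `probe_betas` (long tibble `sample_id`, `probe_id`,
#'   `beta`).
#' @export
evaluate_cfdna <- function(beta, sheet, pan) {
  cf <- sheet[sheet$tissue_class == "cfdna" & !sheet$ffpe, , drop = FALSE]
  cf <- cf[cf$sample_id %in% names(beta)[-1], , drop = FALSE]
  if (!nrow(cf)) {
    return(list(calls = tibble::tibble(sample_id = character(),
                                       project = character(),
                                       max_beta = numeric(), call = logical()),
                probe_betas = tibble::tibble(sample_id = character(),
                                             probe_id = character(),
                                             beta = numeric())))
  }
  calls <- dplyr::inner_join(call_samples(beta, pan, cf$sample_id),
                             cf[, c("sample_id", "project")], by = "sample_id")
  vals <- beta_values(beta[match(pan$probes, beta$probe_id), , drop = FALSE],
                      cf$sample_id)
  probe_betas <- tibble::tibble(
    sample_id = rep(cf$sample_id, each = length(pan$probes)),
    probe_id = rep(pan$probes, times = nrow(cf)),
    beta = as.vector(vals)
  )
  list(calls = calls[, c("sample_id", "project", "max_beta", "call")],
       probe_betas = probe_betas)
}
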