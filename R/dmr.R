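#' Two-sided Wilcoxon rank-sum p-value
#'
#' Policy used throughout the differential-methylation tests: the exact
#' (enumeration) p-value when both groups have at most 12 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. The degenerate case in which every observation of
#' both groups is identical carries no evidence and is defined as p = 1.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return Two-sided p-value in \[0, 1\].
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group in rank-sum test", call. = FALSE)
  if (length(unique(c(x, y))) == 1) return(1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 12 && length(y) <= 12
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
  min(unname(p), 1)
}

# Vectorized per-probe rank-sum p-values: X1, X2 are probe-by-sample
# matrices for the two groups (same probes, aligned rows). Uses the exact
# distribution for small untied rows and otherwise the identical
# tie/continuity-corrected normal approximation as stats::wilcox.test, so
# the per-probe values agree with rank_sum_test().
wilcox_p_rows <- function(X1, X2) {
  n1 <- ncol(X1)
  n2 <- ncol(X2)
  N <- n1 + n2
  XX <- cbind(X1, X2)
  p <- numeric(nrow(XX))
  ranks <- t(apply(XX, 1, rank))
  R1 <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  W <- R1 - n1 * (n1 + 1) / 2
  # tie correction only matters for rows with duplicated values; those are
  # rare for continuous betas, so find them first instead of tabulating
  # every row
  tie_term <- numeric(nrow(XX))
  tied_rows <- which(apply(XX, 1, anyDuplicated) > 0)
  for (i in tied_rows) {
    t <- rle(sort(XX[i, ]))$lengths
    tie_term[i] <- sum(t^3 - t)
  }
  has_ties <- tie_term > 0
  const_row <- logical(nrow(XX))
  const_row[tied_rows] <- apply(XX[tied_rows, , drop = FALSE], 1,
                                function(r) length(unique(r)) == 1)

  exact_ok <- !has_ties & n1 <= 12 & n2 <= 12
  if (any(exact_ok)) {
    w <- W[exact_ok]
    p_ex <- ifelse(w > n1 * n2 / 2,
                   2 * stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE),
                   2 * stats::pwilcox(w, n1, n2))
    p[exact_ok] <- pmin(p_ex, 1)
  }
  approx_idx <- which(!exact_ok & !const_row)
  if (length(approx_idx)) {
    z <- W[approx_idx] - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                    ((N + 1) - tie_term[approx_idx] / (N * (N - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    p[approx_idx] <- pmin(2 * stats::pnorm(-abs(z)), 1)
  }
  p[const_row] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

as_group <- function(g, name = NULL) {
  if (is.list(g) && !is.null(g$sample_ids)) {
    list(name = g$name %||% name %||% "group", sample_ids = g$sample_ids)
  } else {
    list(name = name %||% "group", sample_ids = as.character(g))
  }
}

#' Pairwise differential-methylation comparison
#'
#' For every probe, computes group means, their difference, a two-sided
#' rank-sum p-value and its Benjamini-Hochberg adjustment across all probes
#' of this comparison. A probe is significant iff `|delta| >= min_delta`
#' (default 0.2) and `p_adjusted <= alpha` (default 0.05).
#'
#' @param beta A beta tibble (filtered; no missing values).
#' @param g1,g2 Sample groups: character vectors of sample ids or lists
#'   with `name` and `sample_ids`. `g1` is the target (delta =
#'   `mean_g1 - mean_g2`). Groups must be disjoint and non-empty.
#' @param min_delta,alpha Significance cutoffs.
#' @return Tibble: `probe_id`, `mean_g1`, `mean_g2`, `delta`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
dmr_compare <- function(beta, g1, g2, min_delta = 0.2, alpha = 0.05) {
  g1 <- as_group(g1, "g1")
  g2 <- as_group(g2, "g2")
  if (!length(g1$sample_ids) || !length(g2$sample_ids)) {
    stop("empty comparison group", call. = FALSE)
  }
  if (length(intersect(g1$sample_ids, g2$sample_ids))) {
    stop("comparison groups overlap", call. = FALSE)
  }
  X1 <- beta_values(beta, g1$sample_ids)
  X2 <- beta_values(beta, g2$sample_ids)
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  p <- wilcox_p_rows(X1, X2)
  padj <- bh_adjust(p)
  tibble::tibble(
    probe_id = beta$probe_id,
    mean_g1 = unname(m1),
    mean_g2 = unname(m2),
    delta = unname(m1 - m2),
    p_value = p,
    p_adjusted = padj,
    significant = abs(m1 - m2) >= min_delta & padj <= alpha
  )
}

#' Intersect significant hypermethylated probes across comparisons
#'
#' Keeps the probes that are significant with a positive delta
#' (hypermethylated in the target) in every one of the supplied
#' target-versus-comparator tables.
#'
#' @param tables List of [dmr_compare()] tables, all with the same target
#'   as `g1`.
#' @return Character vector of probe ids (possibly empty).
#' @export
intersect_significant <- function(tables) {
  if (!length(tables)) stop("need at least one comparison table", call. = FALSE)
  sets <- purrr::map(tables, function(tb) tb$probe_id[tb$significant & tb$delta > 0])
  purrr::reduce(sets, intersect)
}

#' Select cancer-specific hypermethylated candidate probes
#'
#' Applies the selection cutoffs to the intersected probes. Strict tier:
#' for every comparator group, `delta > 0.3` and comparator mean `< 0.1`.
#' Relaxed tier: `delta > 0.2` and comparator mean `< 0.15` (the
#' conjunction; set `relaxed_mode = "or"` for the disjunctive reading).
#' Candidates are returned sorted by target mean, descending, which is the
#' panel builder's stated preference order.
#'
#' @param beta A beta tibble.
#' @param target Target group (list with `name`, `sample_ids`, or a
#'   character vector).
#' @param comparators List of comparator groups.
#' @param intersected Probe ids surviving [intersect_significant()].
#' @param tier `"strict"` or `"relaxed"`.
#' @param relaxed_mode `"and"` (default) or `"or"` for the relaxed tier.
#' @return Candidate tibble: `probe_id`, `target_group`, `target_mean`,
#'   `min_delta`, `max_comparator_mean`, `comparator_means` (list column of
#'   named vectors), `tier`.
#' @export
select_candidates <- function(beta, target, comparators, intersected,
                              tier = c("strict", "relaxed"),
                              relaxed_mode = c("and", "or")) {
  tier <- match.arg(tier)
  relaxed_mode <- match.arg(relaxed_mode)
  target <- as_group(target, "target")
  comparators <- purrr::imap(comparators, function(g, i) {
    as_group(g, if (is.character(i)) i else paste0("comparator", i))
  })
  missing <- setdiff(intersected, beta$probe_id)
  if (length(missing)) {
    stop("intersected probe(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!length(intersected)) {
    return(tibble::tibble(
      probe_id = character(), target_group = character(),
      target_mean = numeric(), min_delta = numeric(),
      max_comparator_mean = numeric(), comparator_means = list(),
      tier = character()
    ))
  }
  sub <- beta[match(intersected, beta$probe_id), , drop = FALSE]
  tmean <- rowMeans(beta_values(sub, target$sample_ids))
  cmeans <- vapply(comparators, function(g) {
    rowMeans(beta_values(sub, g$sample_ids))
  }, numeric(length(intersected)))
  cmeans <- matrix(cmeans, nrow = length(intersected),
                   dimnames = list(intersected, purrr::map_chr(comparators, "name")))
  worst <- apply(cmeans, 1, max)
  min_delta <- tmean - worst
  keep <- switch(tier,
    strict = min_delta > 0.3 & worst < 0.1,
    relaxed = if (relaxed_mode == "and") {
      min_delta > 0.2 & worst < 0.15
    } else {
      min_delta > 0.2 | worst < 0.15
    }
  )
  out <- tibble::tibble(
    probe_id = intersected[keep],
    target_group = target$name,
    target_mean = unname(tmean[keep]),
    min_delta = unname(min_delta[keep]),
    max_comparator_mean = unname(worst[keep]),
    comparator_means = purrr::map(which(keep), function(i) cmeans[i, ]),
    tier = tier
  )
  dplyr::arrange(out, dplyr::desc(.data$target_mean), .data$probe_id)
}

#' Annotate candidates with their behaviour in normal tissue
#'
#' Verification step: each candidate is annotated `normal_discriminating`
#' if the paired-normal mean beta is below the 0.3 call cutoff, otherwise
#' `shared_with_normal` (the pancreatic-cancer-like case in which a probe
#' is hypermethylated in the tumor and its tissue of origin). No candidate
#' is removed; per-normal-group means are recorded.
#'
#' @param cands Candidate tibble from [select_candidates()].
#' @param beta A beta tibble.
#' @param normal_groups List of normal-tissue groups (all projects).
#' @param paired_normal The target cancer's own normal group.
#' @param cutoff Call cutoff (default 0.3).
#' @return The candidate tibble with `paired_normal_mean`,
#'   `normal_status`, and `normal_means` (list column) added.
#' @export
verify_in_normals <- function(cands, beta, normal_groups, paired_normal,
                              cutoff = 0.3) {
  if (!nrow(cands)) {
    cands$paired_normal_mean <- numeric()
    cands$normal_status <- character()
    cands$normal_means <- list()
    return(cands)
  }
  paired_normal <- as_group(paired_normal, "paired_normal")
  normal_groups <- purrr::imap(normal_groups, function(g, i) {
    as_group(g, if (is.character(i)) i else paste0("normal", i))
  })
  sub <- beta[match(cands$probe_id, beta$probe_id), , drop = FALSE]
  pmeans <- rowMeans(beta_values(sub, paired_normal$sample_ids))
  nmeans <- purrr::map(normal_groups, function(g) {
    rowMeans(beta_values(sub, g$sample_ids))
  })
  cands$paired_normal_mean <- unname(pmeans)
  cands$normal_status <- unname(ifelse(pmeans < cutoff, "normal_discriminating",
                                       "shared_with_normal"))
  cands$normal_means <- purrr::map(seq_len(nrow(cands)), function(i) {
    vapply(nmeans, `[[`, numeric(1), i)
  })
  cands
}

#' Build the pairwise comparison plan
#'
#' Non-clustered approach: every project's tumor samples and every
#' project's normal samples form independent groups, and all unordered
#' group pairs are compared. Clustered approach: each methylation cluster
#' is a group (normals stay whole per project) and all pairs are compared
#' except pairs of clusters from the same cancer type.
#'
#' @param sheet Sample sheet (identification scope, FFPE excluded).
#' @param approach `"non-clustered"` or `"clustered"`.
#' @param assignments For the clustered approach, a named list of
#'   `mc_assignment` objects keyed by project.
#' @return List with `groups` (named list of sample-id vectors, with
#'   attributes `project` and `kind`) and `pairs` (tibble `g1`, `g2`).
#' @export
comparison_plan <- function(sheet, approach = c("non-clustered", "clustered"),
                            assignments = NULL) {
  approach <- match.arg(approach)
  sheet <- sheet[sheet$tissue_class %in% c("tumor", "normal"), , drop = FALSE]
  projects <- sort(unique(sheet$project))
  groups <- list()
  meta <- list()
  add_group <- function(name, ids, project, kind) {
    groups[[name]] <<- ids
    meta[[name]] <<- list(project = project, kind = kind)
  }
  for (p in projects) {
    tums <- sheet$sample_id[sheet$project == p & sheet$tissue_class == "tumor"]
    norms <- sheet$sample_id[sheet$project == p & sheet$tissue_class == "normal"]
    if (approach == "non-clustered") {
      if (length(tums)) add_group(paste0(p, "_T"), tums, p, "tumor")
    } else {
      asg <- assignments[[p]]
      if (is.null(asg)) stop("no cluster assignment for project ", p, call. = FALSE)
      for (mc in seq_len(asg$n_clusters)) {
        ids <- names(asg$labels)[asg$labels == mc]
        add_group(sprintf("%s_MC%d", p, mc), ids, p, "tumor")
      }
    }
    if (length(norms)) add_group(paste0(p, "_N"), norms, p, "normal")
  }
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  keep <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- meta[[pairs[1, j]]]
    b <- meta[[pairs[2, j]]]
    !(a$kind == "tumor" && b$kind == "tumor" && a$project == b$project)
  }, logical(1))
  list(
    groups = groups,
    meta = meta,
    pairs = tibble::tibble(g1 = pairs[1, keep], g2 = pairs[2, keep])
  )
}
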