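#' Pipeline configuration
#'
#' Collects the numeric constants and switches of the discovery pipeline:
#' differential-methylation cutoffs (minimum mean difference 0.2, adjusted
#' p 0.05), selection cutoffs (strict: delta > 0.3 with comparator means
#' < 0.1; relaxed: delta > 0.2 with comparator means < 0.15), the call
#' cutoff 0.3, the clustering controls (5000 most variable probes, depth,
#' minimal cluster size) and the panel-builder constraints.
#'
#' @param k Most-variable probes used for clustering.
#' @param max_depth,min_cluster_size,fuzzifier Clustering controls.
#' @param dmr_min_delta,dmr_alpha Significance cutoffs for
#'   [dmr_compare()].
#' @param relaxed_mode `"and"` or `"or"` for the relaxed selection tier.
#' @param min_strict_candidates Fall back to the relaxed tier when a
#'   cancer yields fewer strict candidates than this.
#' @param call_cutoff Max-beta call threshold.
#' @param min_cancer_specificity,spec_slack,min_gain Panel-builder
#'   constraints ([build_panel()]).
#' @param project_merge Named character vector of project relabellings
#'   applied before analysis (applied only to projects present).
#' @param seed Integer seed for the clustering.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 5000L, max_depth = 3L, min_cluster_size = 5L,
                            fuzzifier = 2, dmr_min_delta = 0.2,
                            dmr_alpha = 0.05, relaxed_mode = "and",
                            min_strict_candidates = 3L, call_cutoff = 0.3,
                            min_cancer_specificity = 90, spec_slack = 2,
                            min_gain = 1L,
                            project_merge = c(COAD = "CRC", READ = "CRC"),
                            seed = 1L) {
  stopifnot(k >= 1, dmr_min_delta > 0, dmr_min_delta < 1,
            dmr_alpha > 0, dmr_alpha < 1, call_cutoff > 0, call_cutoff < 1)
  structure(list(
    k = as.integer(k), max_depth = as.integer(max_depth),
    min_cluster_size = as.integer(min_cluster_size), fuzzifier = fuzzifier,
    dmr_min_delta = dmr_min_delta, dmr_alpha = dmr_alpha,
    relaxed_mode = relaxed_mode,
    min_strict_candidates = as.integer(min_strict_candidates),
    call_cutoff = call_cutoff,
    min_cancer_specificity = min_cancer_specificity,
    spec_slack = spec_slack, min_gain = as.integer(min_gain),
    project_merge = project_merge, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# Compute every pairwise DMR table of a plan once (unordered pairs) and
# index both directions: result[[g1]][[g2]] has g1 as target.
compute_dmr_tables <- function(beta, plan, cfg) {
  tables <- list()
  for (i in seq_len(nrow(plan$pairs))) {
    a <- plan$pairs$g1[i]
    b <- plan$pairs$g2[i]
    tb <- dmr_compare(beta, plan$groups[[a]], plan$groups[[b]],
                      min_delta = cfg$dmr_min_delta, alpha = cfg$dmr_alpha)
    if (is.null(tables[[a]])) tables[[a]] <- list()
    if (is.null(tables[[b]])) tables[[b]] <- list()
    tables[[a]][[b]] <- tb
    rev <- tb
    rev$mean_g1 <- tb$mean_g2
    rev$mean_g2 <- tb$mean_g1
    rev$delta <- -tb$delta
    tables[[b]][[a]] <- rev
  }
  tables
}

# Candidate selection for one target group against its comparator groups:
# intersect significant hypermethylated probes, apply the strict tier, fall
# back to relaxed when too few survive.
select_for_target <- function(beta, plan, tables, target_name, comparator_names,
                              cfg) {
  comp_tables <- purrr::map(comparator_names, function(nm) {
    tables[[target_name]][[nm]]
  })
  inter <- intersect_significant(comp_tables)
  target <- list(name = target_name, sample_ids = plan$groups[[target_name]])
  comparators <- purrr::map(comparator_names, function(nm) {
    list(name = nm, sample_ids = plan$groups[[nm]])
  })
  cands <- select_candidates(beta, target, comparators, inter, tier = "strict",
                             relaxed_mode = cfg$relaxed_mode)
  if (nrow(cands) < cfg$min_strict_candidates) {
    relaxed <- select_candidates(beta, target, comparators, inter,
                                 tier = "relaxed",
                                 relaxed_mode = cfg$relaxed_mode)
    relaxed <- relaxed[!relaxed$probe_id %in% cands$probe_id, , drop = FALSE]
    cands <- dplyr::bind_rows(cands, relaxed)
  }
  cands
}

prepare_inputs <- function(beta, sheet, annotation, cfg) {
  kept <- exclude_ffpe(beta, sheet)
  sheet <- merge_projects(kept$sheet, cfg$project_merge)
  beta <- filter_probes(kept$beta, annotation)
  list(beta = beta, sheet = sheet)
}

run_result <- function(approach, candidates, panels, evaluations, plan, cfg,
                       beta, sheet, assignments = NULL) {
  metrics <- dplyr::bind_rows(purrr::imap(evaluations, function(ev, nm) {
    dplyr::bind_cols(tibble::tibble(target = nm,
                                    n_probes = length(ev$panel$probes)),
                     ev$metrics)
  }))
  structure(list(
    approach = approach,
    candidates = candidates,
    panels = panels,
    evaluations = evaluations,
    metrics = metrics,
    assignments = assignments,
    n_comparisons = nrow(plan$pairs),
    manifest = list(
      approach = approach,
      config = unclass(cfg),
      seed = cfg$seed,
      beta_hash = rlang::hash(beta),
      sheet_hash = rlang::hash(sheet),
      result_hash = NULL
    )
  ), class = "meth_run")
}

#' @export
print.meth_run <- function(x, ...) {
  cat(sprintf("<meth_run> %s approach: %d comparisons, %d cancers with panels\n",
              x$approach, x$n_comparisons, length(x$panels)))
  print(x$metrics[, c("target", "n_probes", "sensitivity", "cancer_specificity",
                      "ts_specificity", "all_samples_specificity", "accuracy")])
  invisible(x)
}

#' Run the non-clustered discovery pipeline
#'
#' End-to-end identification run without sample clustering: FFPE
#' exclusion, project merging, probe filtering, all-pairs
#' differential-methylation testing between every project's tumor and
#' normal groups, per-cancer intersection and tiered selection,
#' normal-tissue verification, greedy panel construction and evaluation on
#' the identification dataset.
#'
#' @param beta A beta tibble.
#' @param sheet Sample sheet.
#' @param annotation Probe annotation.
#' @param cfg A [pipeline_config()].
#' @return A `meth_run`: `candidates` (tibble with a `cancer` column),
#'   `panels` (named list of `meth_panel`), `evaluations` (named list of
#'   `panel_eval`), `metrics` (tibble), `n_comparisons`, `manifest`.
#' @export
run_nonclustered <- function(beta, sheet, annotation, cfg = pipeline_config()) {
  prep <- prepare_inputs(beta, sheet, annotation, cfg)
  beta <- prep$beta
  ident <- prep$sheet[prep$sheet$dataset == "identification", , drop = FALSE]
  plan <- comparison_plan(ident, "non-clustered")
  tables <- compute_dmr_tables(beta, plan, cfg)

  tumor_groups <- names(plan$groups)[purrr::map_chr(plan$meta, "kind") == "tumor"]
  candidates <- list()
  panels <- list()
  evaluations <- list()
  for (tg in tumor_groups) {
    cancer <- plan$meta[[tg]]$project
    comparators <- setdiff(tumor_groups, tg)
    cands <- select_for_target(beta, plan, tables, tg, comparators, cfg)
    if (!nrow(cands)) next
    normal_groups <- names(plan$groups)[purrr::map_chr(plan$meta, "kind") == "normal"]
    paired <- paste0(cancer, "_N")
    if (paired %in% normal_groups) {
      cands <- verify_in_normals(
        cands, beta,
        purrr::map(stats::setNames(normal_groups, normal_groups),
                   function(nm) plan$groups[[nm]]),
        plan$groups[[paired]], cutoff = cfg$call_cutoff)
    }
    cands$cancer <- cancer
    candidates[[cancer]] <- cands
    panels[[cancer]] <- build_panel(
      cands, beta, prep$sheet, cancer, cutoff = cfg$call_cutoff,
      min_cancer_specificity = cfg$min_cancer_specificity,
      spec_slack = cfg$spec_slack, min_gain = cfg$min_gain,
      approach = "non-clustered")
    evaluations[[cancer]] <- evaluate_panel(beta, prep$sheet, panels[[cancer]],
                                            scope = "identification")
  }
  res <- run_result("non-clustered", dplyr::bind_rows(candidates), panels,
                    evaluations, plan, cfg, beta, prep$sheet)
  res$manifest$result_hash <- rlang::hash(res$metrics)
  res
}

#' Run the clustered discovery pipeline
#'
#' As [run_nonclustered()], but each project's tumor samples are first
#' clustered with [rpmm_cluster()] on the most variable probes; every
#' methylation cluster is an independent group, clusters of the same
#' cancer are never compared with each other, selection runs per cluster,
#' and a cancer's candidates are merged across its clusters with
#' `n_target_mcs` recording in how many of them each probe was selected.
#'
#' @inheritParams run_nonclustered
#' @return A `meth_run`; additionally carries `assignments`, the per-
#'   project `mc_assignment` objects.
#' @export
run_clustered <- function(beta, sheet, annotation, cfg = pipeline_config()) {
  prep <- prepare_inputs(beta, sheet, annotation, cfg)
  beta <- prep$beta
  ident <- prep$sheet[prep$sheet$dataset == "identification", , drop = FALSE]
  projects <- sort(unique(ident$project[ident$tissue_class == "tumor"]))
  assignments <- list()
  for (p in projects) {
    tums <- ident$sample_id[ident$project == p & ident$tissue_class == "tumor"]
    assignments[[p]] <- suppressWarnings(rpmm_cluster(
      beta, tums, k = cfg$k, max_depth = cfg$max_depth,
      min_cluster_size = cfg$min_cluster_size, fuzzifier = cfg$fuzzifier,
      seed = cfg$seed, project = p))
  }
  plan <- comparison_plan(ident, "clustered", assignments)
  tables <- compute_dmr_tables(beta, plan, cfg)

  kinds <- purrr::map_chr(plan$meta, "kind")
  tumor_groups <- names(plan$groups)[kinds == "tumor"]
  normal_groups <- names(plan$groups)[kinds == "normal"]
  candidates <- list()
  panels <- list()
  evaluations <- list()
  for (cancer in projects) {
    own_mcs <- tumor_groups[purrr::map_chr(plan$meta[tumor_groups], "project") == cancer]
    other_mcs <- setdiff(tumor_groups, own_mcs)
    per_mc <- purrr::map(own_mcs, function(tg) {
      select_for_target(beta, plan, tables, tg, other_mcs, cfg)
    })
    merged <- dplyr::bind_rows(per_mc)
    if (!nrow(merged)) next
    # merge across the cancer's clusters; count clusters per probe and keep
    # the strongest tier and highest target mean
    merged <- merged |>
      dplyr::group_by(.data$probe_id) |>
      dplyr::summarise(
        n_target_mcs = dplyr::n(),
        target_group = .data$target_group[which.max(.data$target_mean)],
        target_mean = max(.data$target_mean),
        min_delta = max(.data$min_delta),
        max_comparator_mean = min(.data$max_comparator_mean),
        comparator_means = .data$comparator_means[which.max(.data$target_mean)],
        tier = if (any(.data$tier == "strict")) "strict" else "relaxed",
        .groups = "drop"
      ) |>
      dplyr::arrange(dplyr::desc(.data$n_target_mcs),
                     dplyr::desc(.data$target_mean), .data$probe_id)
    paired <- paste0(cancer, "_N")
    if (paired %in% normal_groups) {
      merged <- verify_in_normals(
        merged, beta,
        purrr::map(stats::setNames(normal_groups, normal_groups),
                   function(nm) plan$groups[[nm]]),
        plan$groups[[paired]], cutoff = cfg$call_cutoff)
    }
    merged$cancer <- cancer
    candidates[[cancer]] <- merged
    panels[[cancer]] <- build_panel(
      merged, beta, prep$sheet, cancer, cutoff = cfg$call_cutoff,
      min_cancer_specificity = cfg$min_cancer_specificity,
      spec_slack = cfg$spec_slack, min_gain = cfg$min_gain,
      approach = "clustered")
    evaluations[[cancer]] <- evaluate_panel(beta, prep$sheet, panels[[cancer]],
                                            scope = "identification")
  }
  res <- run_result("clustered", dplyr::bind_rows(candidates), panels,
                    evaluations, plan, cfg, beta, prep$sheet, assignments)
  res$manifest$result_hash <- rlang::hash(res$metrics)
  res
}

#' Evaluate frozen panels on a verification dataset
#'
#' Takes the panels exactly as built on the identification dataset (they
#' are hashed before and after to assert they were not touched) and
#' evaluates them on verification primaries, on metastases where present,
#' and on cfDNA samples where present.
#'
#' @param panels Named list of `meth_panel` objects (or a `meth_run`).
#' @param beta Verification beta tibble.
#' @param sheet Verification sample sheet.
#' @param annotation Optional probe annotation for filtering; if `NULL`
#'   the matrix is used as supplied (metastasis and cfDNA columns are
#'   complete by construction).
#' @return List of class `meth_verification`: `primary` (named list of
#'   `panel_eval`), `metastasis` (named list), `cfdna` (named list),
#'   `comparison` (tibble of per-panel verification metrics).
#' @export
run_verification <- function(panels, beta, sheet, annotation = NULL) {
  if (inherits(panels, "meth_run")) panels <- panels$panels
  stopifnot(length(panels) > 0)
  hashes_before <- purrr::map_chr(panels, rlang::hash)
  if (!is.null(annotation)) beta <- filter_probes(beta, annotation)
  ver <- sheet[sheet$dataset == "verification" & !sheet$ffpe, , drop = FALSE]
  primary <- list()
  metastasis <- list()
  cfdna <- list()
  for (nm in names(panels)) {
    pan <- panels[[nm]]
    missing <- setdiff(pan$probes, beta$probe_id)
    if (length(missing)) {
      stop("panel probe(s) missing from verification matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(ver$project == nm & ver$tissue_class == "tumor")) {
      primary[[nm]] <- evaluate_panel(beta, sheet, pan, scope = "verification")
    }
    if (any(ver$project == nm & ver$tissue_class == "metastasis")) {
      metastasis[[nm]] <- evaluate_metastasis_panel(beta, sheet, pan,
                                                    scope = "verification")
    }
    if (any(ver$tissue_class == "cfdna")) {
      cfdna[[nm]] <- evaluate_cfdna(beta, ver, pan)
    }
  }
  stopifnot(identical(hashes_before, purrr::map_chr(panels, rlang::hash)))
  comparison <- dplyr::bind_rows(purrr::imap(primary, function(ev, nm) {
    dplyr::bind_cols(tibble::tibble(target = nm), ev$metrics)
  }))
  structure(list(primary = primary, metastasis = metastasis, cfdna = cfdna,
                 comparison = comparison),
            class = "meth_verification")
}
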