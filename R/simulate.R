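#' Draw beta-distributed methylation values
#'
#' Mean/concentration parameterization of the beta distribution: a draw with
#' mean `mu` and concentration `phi` uses shape parameters `(mu * phi,
#' (1 - mu) * phi)`. Means at or beyond the boundary are clamped to
#' `[1e-3, 1 - 1e-3]` before drawing, so all draws lie strictly inside
#' (0, 1).
#'
#' @param mean Target mean(s) in (0, 1); recycled against `n`.
#' @param precision Concentration `phi > 0`; larger values concentrate draws
#'   around the mean (within-group sd is about
#'   `sqrt(mean * (1 - mean) / (phi + 1))`).
#' @param n Number of draws (default: `length(mean)`).
#' @return Numeric vector of draws in (0, 1).
#' @export
sample_beta <- function(mean, precision, n = length(mean)) {
  stopifnot(is.numeric(mean), is.numeric(precision), all(precision > 0))
  mu <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  # extreme shape pairs can round to exactly 0 or 1 in floating point
  pmin(pmax(stats::rbeta(n, mu * precision, (1 - mu) * precision), 1e-9),
       1 - 1e-9)
}

#' Default seven-cancer project roster
#'
#' Desk-scale roster used by [cohort_config()]: seven adenocarcinoma
#' projects with 40 tumors and 10 normals each, 4--7 methylation subtypes,
#' 50 planted marker probes per cancer, and a pancreatic-cancer-like
#' project whose shared probes are hypermethylated in tumor and paired
#' normal alike.
#'
#' @return A tibble of per-project generator settings.
#' @export
default_projects <- function() {
  tibble::tibble(
    project = c("BRCA", "CHOL", "CRC", "LIHC", "LUAD", "PAAD", "STAD"),
    n_tumor = 40L,
    n_normal = 10L,
    n_clusters = c(7L, 4L, 4L, 6L, 4L, 5L, 6L),
    n_marker_probes = 50L,
    n_shared_probes = c(0L, 0L, 0L, 0L, 0L, 10L, 0L)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-project methylation study with planted ground truth:
#' per-project methylation subtypes (clusters), cancer-specific
#' hypermethylated marker probes, probes hypermethylated in a tumor and its
#' paired normal tissue (the pancreatic-cancer-like case), sex-chromosome
#' probes, duplicated probe ids and sporadic missing values. The default
#' roster emulates a seven-cancer study at desk scale: 40 tumors and 10
#' normals per project, 4--7 clusters per project, 50 markers per cancer
#' with target mean 0.70 against 0.05 elsewhere.
#'
#' @param projects Tibble with columns `project`, `n_tumor`, `n_normal`,
#'   `n_clusters` (in 4--7 for the default roster), `n_marker_probes`,
#'   `n_shared_probes`. Optionally `marker_clusters`, a list column of
#'   integer cluster indices in which the markers are hypermethylated
#'   (default: all clusters of the project).
#' @param marker_mean Mean beta of marker probes in the target tumors.
#' @param offtarget_mean Mean beta of marker probes everywhere else.
#' @param n_background_probes Probes with bimodal means shared by all
#'   samples (low mode ~0.1, high mode ~0.8).
#' @param n_cluster_probes Per-project probes whose tumor means track the
#'   cluster level (evenly spaced 0.25--0.65), making subtypes separable and
#'   orderable by mean methylation.
#' @param n_sexchrom_probes Probes annotated on X/Y (removed by
#'   [filter_probes()]).
#' @param n_duplicate_probes Background probes whose id is emitted twice.
#' @param missing_fraction Fraction of background probes given one missing
#'   value.
#' @param precision Beta concentration `phi` for all draws; the default 30
#'   gives within-group sd of roughly 0.08.
#' @param metastasis_noise Mean perturbation scale for
#'   [simulate_metastases()].
#' @param cfdna_fractions Default tumor fractions for [simulate_cfdna()].
#' @param seed Integer seed; fixes both the probe model and the draws.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(projects = default_projects(),
                          marker_mean = 0.7,
                          offtarget_mean = 0.05,
                          n_background_probes = 2000L,
                          n_cluster_probes = 150L,
                          n_sexchrom_probes = 40L,
                          n_duplicate_probes = 10L,
                          missing_fraction = 0.02,
                          precision = 30,
                          metastasis_noise = 0.05,
                          cfdna_fractions = c(0, 0.6),
                          seed = 1L) {
  stopifnot(
    all(c("project", "n_tumor", "n_normal", "n_clusters",
          "n_marker_probes", "n_shared_probes") %in% names(projects)),
    !anyDuplicated(projects$project),
    all(projects$n_tumor >= 0), all(projects$n_normal >= 0),
    all(projects$n_clusters >= 1),
    n_background_probes >= 0, n_cluster_probes >= 0,
    n_sexchrom_probes >= 0, n_duplicate_probes >= 0,
    missing_fraction >= 0, missing_fraction <= 1,
    precision > 0, metastasis_noise >= 0,
    all(cfdna_fractions >= 0 & cfdna_fractions <= 1)
  )
  if (marker_mean - offtarget_mean <= 0) {
    stop("marker_mean must exceed offtarget_mean", call. = FALSE)
  }
  structure(list(
    projects = projects,
    marker_mean = marker_mean,
    offtarget_mean = offtarget_mean,
    n_background_probes = as.integer(n_background_probes),
    n_cluster_probes = as.integer(n_cluster_probes),
    n_sexchrom_probes = as.integer(n_sexchrom_probes),
    n_duplicate_probes = as.integer(n_duplicate_probes),
    missing_fraction = missing_fraction,
    precision = precision,
    metastasis_noise = metastasis_noise,
    cfdna_fractions = cfdna_fractions,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Synthetic probe ids look like array CpG ids but are tagged "sy" so no one
# mistakes them for real annotations.
synth_probe_ids <- function(prefix, n) {
  if (n == 0) return(character())
  sprintf("sy%s%05d", prefix, seq_len(n))
}

# Deterministic probe-level model: for every probe, mean beta per
# (project, tissue, cluster) context. Depends only on the config (seeded by
# cfg$seed), so identification and verification cohorts share one truth.
build_probe_model <- function(cfg) {
  pr <- cfg$projects
  set.seed(cfg$seed)

  marker <- purrr::map2(pr$project, pr$n_marker_probes, function(p, n) {
    synth_probe_ids(paste0("mk", tolower(p)), n)
  })
  names(marker) <- pr$project
  shared <- purrr::map2(pr$project, pr$n_shared_probes, function(p, n) {
    synth_probe_ids(paste0("sh", tolower(p)), n)
  })
  names(shared) <- pr$project
  clusterp <- purrr::map(pr$project, function(p) {
    synth_probe_ids(paste0("cl", tolower(p)), cfg$n_cluster_probes)
  })
  names(clusterp) <- pr$project
  background <- synth_probe_ids("bg", cfg$n_background_probes)
  sexchrom <- synth_probe_ids("xy", cfg$n_sexchrom_probes)

  # bimodal background means, shared across all samples
  hi <- stats::runif(cfg$n_background_probes) < 0.35
  bg_mean <- ifelse(hi,
                    pmin(pmax(stats::rnorm(cfg$n_background_probes, 0.8, 0.05), 0.55), 0.95),
                    pmin(pmax(stats::rnorm(cfg$n_background_probes, 0.1, 0.04), 0.02), 0.35))
  names(bg_mean) <- background
  sex_mean <- stats::runif(cfg$n_sexchrom_probes, 0.05, 0.9)
  names(sex_mean) <- sexchrom

  # cluster levels: evenly spaced 0.25..0.65, highest level = cluster 1 so
  # recovered labels can be compared to truth after methylation ordering
  cluster_levels <- purrr::map(seq_len(nrow(pr)), function(i) {
    k <- pr$n_clusters[i]
    if (k == 1) 0.45 else seq(0.65, 0.25, length.out = k)
  })
  names(cluster_levels) <- pr$project

  # per-probe jitter on cluster-informative probes
  cluster_jitter <- purrr::map(pr$project, function(p) {
    stats::runif(cfg$n_cluster_probes, -0.03, 0.03)
  })
  names(cluster_jitter) <- pr$project

  marker_clusters <- if ("marker_clusters" %in% names(pr)) pr$marker_clusters else
    purrr::map(pr$n_clusters, seq_len)
  marker_clusters <- purrr::map2(marker_clusters, pr$n_clusters, function(mc, k) {
    if (is.null(mc)) seq_len(k) else as.integer(mc)
  })
  names(marker_clusters) <- pr$project

  dup_ids <- if (cfg$n_duplicate_probes > 0) {
    background[seq_len(min(cfg$n_duplicate_probes, length(background)))]
  } else character()
  miss_n <- round(cfg$missing_fraction * cfg$n_background_probes)
  miss_ids <- if (miss_n > 0 && length(background) > length(dup_ids)) {
    setdiff(background, dup_ids)[seq_len(min(miss_n, length(background) - length(dup_ids)))]
  } else character()

  list(
    marker = marker, shared = shared, clusterp = clusterp,
    background = background, sexchrom = sexchrom,
    bg_mean = bg_mean, sex_mean = sex_mean,
    cluster_levels = cluster_levels, cluster_jitter = cluster_jitter,
    marker_clusters = marker_clusters,
    dup_ids = dup_ids, miss_ids = miss_ids
  )
}

model_probe_ids <- function(model) {
  c(unlist(model$marker, use.names = FALSE),
    unlist(model$shared, use.names = FALSE),
    unlist(model$clusterp, use.names = FALSE),
    model$background, model$sexchrom)
}

# Mean beta for every model probe in one sample context.
context_means <- function(model, cfg, project, tissue, cluster = NA_integer_) {
  ids <- model_probe_ids(model)
  mu <- numeric(length(ids))
  names(mu) <- ids
  mu[model$background] <- model$bg_mean
  mu[model$sexchrom] <- model$sex_mean
  for (p in names(model$marker)) {
    on_target <- identical(p, project) && tissue == "tumor" &&
      (is.na(cluster) || cluster %in% model$marker_clusters[[p]])
    mu[model$marker[[p]]] <- if (on_target) cfg$marker_mean else cfg$offtarget_mean
    shared_on <- identical(p, project) &&
      (tissue == "normal" || (tissue == "tumor" &&
        (is.na(cluster) || cluster %in% model$marker_clusters[[p]])))
    mu[model$shared[[p]]] <- if (shared_on) cfg$marker_mean else cfg$offtarget_mean
    base <- model$cluster_jitter[[p]] + if (identical(p, project) && tissue == "tumor" && !is.na(cluster)) {
      model$cluster_levels[[p]][cluster]
    } else 0.1
    mu[model$clusterp[[p]]] <- pmin(pmax(base, 0.02), 0.98)
  }
  mu
}

#' Simulate a multi-project methylation cohort with known truth
#'
#' Generates a beta matrix, sample sheet, probe annotation and ground truth
#' for the configured roster. Tumor samples are partitioned among the
#' configured clusters (round-robin, so cluster sizes differ by at most
#' one); marker probes are hypermethylated in the target tumors only; shared
#' probes also in the target normals; cluster-informative probes track each
#' subtype's methylation level; background probes are bimodal and common to
#' all samples. Sex-chromosome probes, duplicated probe ids and sporadic
#' missing values exercise the filtering rules.
#'
#' The probe model (which probe means what, where) is derived from
#' `cfg$seed` alone, so an identification and a verification cohort drawn
#' from the same config share planted truth while their samples are
#' independent.
#'
#' @param cfg A [cohort_config()].
#' @param dataset `"identification"` or `"verification"`.
#' @param seed Seed for the draws; defaults to `cfg$seed` for
#'   identification and `cfg$seed + 1000003` for verification.
#' @return A list of class `meth_cohort`: `beta` (tibble), `sheet`
#'   (tibble), `annotation` (tibble) and `truth` (list with
#'   `marker_probes`, `shared_probes`, `cluster_probes`, `cluster_of`,
#'   `metastasis_source`, `cfdna_fraction`).
#' @export
simulate_cohort <- function(cfg, dataset = "identification", seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  dataset <- match.arg(dataset, dataset_labels)
  if (is.null(seed)) {
    seed <- cfg$seed + if (dataset == "verification") 1000003L else 0L
  }
  model <- build_probe_model(cfg)
  ids <- model_probe_ids(model)

  set.seed(seed)
  pr <- cfg$projects
  cols <- list()
  sheet <- list()
  cluster_of <- integer()
  for (i in seq_len(nrow(pr))) {
    p <- pr$project[i]
    tag <- if (dataset == "verification") "V" else "I"
    if (pr$n_tumor[i] > 0) {
      clusters <- rep(seq_len(pr$n_clusters[i]), length.out = pr$n_tumor[i])
      for (j in seq_len(pr$n_tumor[i])) {
        sid <- sprintf("%s_%s_T%03d", p, tag, j)
        mu <- context_means(model, cfg, p, "tumor", clusters[j])
        cols[[sid]] <- sample_beta(mu, cfg$precision)
        cluster_of[sid] <- clusters[j]
        sheet[[sid]] <- list(p, "tumor")
      }
    }
    for (j in seq_len(pr$n_normal[i])) {
      sid <- sprintf("%s_%s_N%03d", p, tag, j)
      mu <- context_means(model, cfg, p, "normal")
      cols[[sid]] <- sample_beta(mu, cfg$precision)
      sheet[[sid]] <- list(p, "normal")
    }
  }

  beta <- tibble::tibble(probe_id = ids)
  for (sid in names(cols)) beta[[sid]] <- cols[[sid]]

  # duplicated probe ids: re-emit the row id with freshly drawn values
  if (length(model$dup_ids)) {
    dup_rows <- beta[match(model$dup_ids, beta$probe_id), , drop = FALSE]
    for (sid in names(cols)) {
      dup_rows[[sid]] <- sample_beta(model$bg_mean[model$dup_ids], cfg$precision)
    }
    beta <- dplyr::bind_rows(beta, dup_rows)
  }
  # sprinkle one missing value on each designated background probe
  for (pid in model$miss_ids) {
    r <- which(beta$probe_id == pid)[1]
    s <- sample(names(cols), 1)
    beta[[s]][r] <- NA_real_
  }

  annotation <- tibble::tibble(
    probe_id = unique(ids),
    chromosome = ifelse(unique(ids) %in% model$sexchrom,
                        rep_len(c("X", "Y"), length(unique(ids))),
                        as.character(rep_len(1:22, length(unique(ids)))))
  )

  sheet_tbl <- tibble::tibble(
    sample_id = names(sheet),
    project = unname(purrr::map_chr(sheet, 1)),
    tissue_class = unname(purrr::map_chr(sheet, 2)),
    dataset = dataset,
    ffpe = FALSE
  )

  structure(list(
    beta = beta,
    sheet = sheet_tbl,
    annotation = annotation,
    truth = list(
      marker_probes = model$marker,
      shared_probes = model$shared,
      cluster_probes = model$clusterp,
      marker_clusters = model$marker_clusters,
      background_probes = model$background,
      cluster_of = cluster_of,
      metastasis_source = character(),
      cfdna_fraction = numeric()
    ),
    config = cfg,
    dataset = dataset
  ), class = "meth_cohort")
}

#' Add liver-metastasis samples to a simulated cohort
#'
#' Each metastasis is derived from one primary tumor column of the cohort:
#' the source sample's beta values serve as per-probe means, perturbed by a
#' uniform offset in `[-noise, +noise]` (truncated to (0, 1)) and redrawn
#' with [sample_beta()]. This emulates the observed conservation of
#' cancer-associated hypermethylation between primary tumors and their
#' metastases. Missing source values fall back to the project's tumor mean
#' for that probe, so metastasis columns are complete.
#'
#' @param cohort A `meth_cohort`.
#' @param project Source project label.
#' @param n Number of metastases (at most the project's tumor count).
#' @param noise Perturbation scale; defaults to the config value.
#' @param seed Integer seed.
#' @return The cohort with metastasis columns appended to `beta`, rows
#'   appended to `sheet` (`tissue_class = "metastasis"`), and
#'   `truth$metastasis_source` extended.
#' @export
simulate_metastases <- function(cohort, project, n, noise = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "meth_cohort"))
  cfg <- cohort$config
  if (is.null(noise)) noise <- cfg$metastasis_noise
  tumors <- cohort$sheet$sample_id[cohort$sheet$project == project &
                                     cohort$sheet$tissue_class == "tumor"]
  if (n > length(tumors)) {
    stop("n exceeds the number of ", project, " tumor samples", call. = FALSE)
  }
  set.seed(seed)
  sources <- sample(tumors, n)
  vals <- beta_values(cohort$beta, tumors)
  fallback <- rowMeans(vals, na.rm = TRUE)
  n0 <- sum(cohort$sheet$project == project &
              cohort$sheet$tissue_class == "metastasis")
  for (j in seq_len(n)) {
    src <- cohort$beta[[sources[j]]]
    src[is.na(src)] <- fallback[match(cohort$beta$probe_id, rownames(vals))][is.na(src)]
    mu <- pmin(pmax(src + stats::runif(length(src), -noise, noise), 1e-3), 1 - 1e-3)
    sid <- sprintf("%s_M%03d", project, n0 + j)
    cohort$beta[[sid]] <- sample_beta(mu, cfg$precision)
    cohort$sheet <- dplyr::bind_rows(cohort$sheet, tibble::tibble(
      sample_id = sid, project = project, tissue_class = "metastasis",
      dataset = cohort$dataset, ffpe = FALSE
    ))
    cohort$truth$metastasis_source[sid] <- sources[j]
  }
  cohort
}

#' Add cell-free DNA samples to a simulated cohort
#'
#' A cfDNA sample is a tumor/background mixture: per-probe mean
#' `f * tumor + (1 - f) * background`, drawn with [sample_beta()]. The
#' tumor profile is the mean over the source project's tumor columns; the
#' background profile is leukocyte-like -- every planted marker, shared and
#' cluster probe sits at the off-target mean while background probes keep
#' their bimodal means, matching the observation that the selected markers
#' are unmethylated in the cfDNA of healthy donors.
#'
#' @param cohort A `meth_cohort`.
#' @param project Source project label.
#' @param fractions Tumor fractions `f` in \[0, 1\], one cfDNA sample each.
#' @param precision Beta concentration; defaults to the config value.
#' @param seed Integer seed.
#' @return The cohort with cfDNA columns appended and
#'   `truth$cfdna_fraction` extended.
#' @export
simulate_cfdna <- function(cohort, project, fractions, precision = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "meth_cohort"))
  if (any(fractions < 0 | fractions > 1)) {
    stop("tumor fraction f must lie in [0, 1]", call. = FALSE)
  }
  cfg <- cohort$config
  if (is.null(precision)) precision <- cfg$precision
  model <- build_probe_model(cfg)
  tumors <- cohort$sheet$sample_id[cohort$sheet$project == project &
                                     cohort$sheet$tissue_class == "tumor"]
  if (!length(tumors)) stop("no tumor samples for project ", project, call. = FALSE)
  tumor_profile <- rowMeans(beta_values(cohort$beta, tumors), na.rm = TRUE)

  ids <- cohort$beta$probe_id
  background_profile <- rep(cfg$offtarget_mean, length(ids))
  names(background_profile) <- ids
  in_bg <- ids %in% model$background
  background_profile[in_bg] <- model$bg_mean[ids[in_bg]]
  in_xy <- ids %in% model$sexchrom
  background_profile[in_xy] <- model$sex_mean[ids[in_xy]]

  set.seed(seed)
  n0 <- sum(cohort$sheet$project == project &
              cohort$sheet$tissue_class == "cfdna")
  for (j in seq_along(fractions)) {
    f <- fractions[j]
    mu <- f * tumor_profile + (1 - f) * background_profile
    sid <- sprintf("%s_CF%03d", project, n0 + j)
    cohort$beta[[sid]] <- sample_beta(unname(mu), precision)
    cohort$sheet <- dplyr::bind_rows(cohort$sheet, tibble::tibble(
      sample_id = sid, project = project, tissue_class = "cfdna",
      dataset = cohort$dataset, ffpe = FALSE
    ))
    cohort$truth$cfdna_fraction[sid] <- f
  }
  cohort
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort A `meth_cohort`.
#' @param dir Output directory (created if absent). Writes `beta.tsv`,
#'   `samples.csv`, `annotation.csv` and `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  readr::write_csv(cohort$sheet, file.path(dir, "samples.csv"), progress = FALSE)
  readr::write_csv(cohort$annotation, file.path(dir, "annotation.csv"), progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
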