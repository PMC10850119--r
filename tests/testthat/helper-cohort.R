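# Shared synthetic fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small three-cancer cohort for fast pipeline tests
small_config <- function(seed = 7L, precision = 30) {
  cohort_config(
    projects = default_projects()[c(1, 4, 6), ],  # BRCA, LIHC, PAAD
    n_background_probes = 400L, n_cluster_probes = 60L,
    n_sexchrom_probes = 20L, n_duplicate_probes = 6L,
    missing_fraction = 0.02, precision = precision, seed = seed
  )
}

small_cohort <- function() memo("small", function() simulate_cohort(small_config()))

# small cohort augmented with PAAD metastases and BRCA cfDNA samples
small_mts_cohort <- function() memo("small_mts", function() {
  co <- small_cohort()
  co <- simulate_metastases(co, "PAAD", 8, seed = 41L)
  simulate_cfdna(co, "BRCA", c(0, 0.5), seed = 42L)
})

small_run <- function() memo("small_run", function() {
  co <- small_cohort()
  run_nonclustered(co$beta, co$sheet, co$annotation, pipeline_config(seed = 7L))
})

# default seven-cancer roster at the stated study conditions
roster_cohort <- function() memo("roster", function() {
  simulate_cohort(cohort_config(seed = 5L))
})

roster_run <- function() memo("roster_run", function() {
  co <- roster_cohort()
  run_nonclustered(co$beta, co$sheet, co$annotation, pipeline_config(seed = 5L))
})

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# three-cancer cohort with a 4-subtype project whose markers sit in only two
# subtypes, plus its clustered pipeline run
clustered_fixture <- function() memo("clustered_run", function() {
  proj <- tibble::tibble(
    project = c("LIHC", "BRCA", "CRC"),
    n_tumor = c(120L, 60L, 60L), n_normal = 10L,
    n_clusters = c(4L, 2L, 2L), n_marker_probes = 30L,
    n_shared_probes = 0L,
    marker_clusters = list(c(1L, 2L), NULL, NULL)
  )
  cfg <- cohort_config(projects = proj, n_background_probes = 500L,
                       n_cluster_probes = 250L, seed = 9L)
  co <- simulate_cohort(cfg)
  list(co = co,
       run = run_clustered(co$beta, co$sheet, co$annotation,
                           pipeline_config(k = 300L, seed = 9L)))
})

# Candidate-like probe pool for panel-builder tests: each probe is
# hypermethylated in a random subset of the target tumors and sits near the
# unmethylated baseline everywhere else, the regime selection hands to
# build_panel. Uses the caller's RNG stream.
candidate_pool_fixture <- function(n_cand) {
  sheet <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:40),
    project = rep(c("A", "B"), each = 20),
    tissue_class = rep(c(rep("tumor", 15), rep("normal", 5)), 2),
    dataset = "identification", ffpe = FALSE
  )
  a_t <- sheet$sample_id[sheet$project == "A" & sheet$tissue_class == "tumor"]
  beta <- tibble::tibble(probe_id = paste0("c", seq_len(n_cand)))
  tmean <- stats::runif(n_cand, 0.35, 0.8)
  coverage <- stats::runif(n_cand, 0.3, 0.9)
  hit <- vapply(seq_len(n_cand), function(j) stats::runif(15) < coverage[j],
                logical(15))
  for (i in seq_along(sheet$sample_id)) {
    s <- sheet$sample_id[i]
    mu <- if (s %in% a_t) {
      ifelse(hit[match(s, a_t), ], tmean, 0.07)
    } else rep(0.07, n_cand)
    beta[[s]] <- stats::rbeta(n_cand, mu * 30, (1 - mu) * 30)
  }
  list(sheet = sheet, beta = beta,
       cands = tibble::tibble(probe_id = beta$probe_id, target_mean = tmean))
}

# verification-side cohort matching small_cohort()'s truth
verification_fixture <- function() memo("ver_cohort", function() {
  v <- simulate_cohort(small_config(), dataset = "verification")
  v <- simulate_metastases(v, "PAAD", 10, seed = 141L)
  v <- simulate_metastases(v, "BRCA", 12, seed = 142L)
  simulate_cfdna(v, "BRCA", c(0, 0, 0.6, 0.6), seed = 143L)
})
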