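#' Read a probe-by-sample beta-value matrix
#'
#' Reads a tab-separated beta matrix with probe identifiers in the first
#' column and one column per sample. Beta values are decimal fractions in
#' \[0, 1\]; missing values are encoded as `NA`.
#'
#' Duplicate probe ids are permitted at read time (arrays can report a CpG
#' more than once); [filter_probes()] removes them. Duplicate sample ids are
#' an error.
#'
#' @param path Path to a TSV file. First column: probe id; header row:
#'   sample ids.
#' @return A beta tibble: column `probe_id` plus one numeric column per
#'   sample.
#' @seealso [write_beta_matrix()], [filter_probes()]
#' @export
read_beta_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2) {
    stop("beta matrix must have a probe id column and at least one sample column", call. = FALSE)
  }
  names(raw)[1] <- "probe_id"
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in beta matrix header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "), call. = FALSE)
  }
  parsed <- raw
  for (s in sample_ids) {
    cell <- raw[[s]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !(cell %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric beta value '%s' for probe %s, sample %s",
                   cell[bad[1]], raw$probe_id[bad[1]], s), call. = FALSE)
    }
    parsed[[s]] <- num
  }
  validate_beta(parsed)
  parsed
}

#' Write a beta matrix to TSV
#'
#' @param beta A beta tibble as returned by [read_beta_matrix()] or
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta(beta)
  readr::write_tsv(beta, path, na = "NA", progress = FALSE)
  invisible(path)
}

# Checks beta-tibble invariants: probe_id column, numeric samples, values in
# [0,1]; errors name the offending probe and sample.
validate_beta <- function(beta) {
  stopifnot(is.data.frame(beta))
  if (names(beta)[1] != "probe_id") {
    stop("first column of a beta matrix must be 'probe_id'", call. = FALSE)
  }
  for (s in names(beta)[-1]) {
    v <- beta[[s]]
    if (!is.numeric(v)) stop("sample column '", s, "' is not numeric", call. = FALSE)
    out <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(out)) {
      stop(sprintf("beta value %g out of [0,1] for probe %s, sample %s",
                   v[out[1]], beta$probe_id[out[1]], s), call. = FALSE)
    }
  }
  invisible(beta)
}

# beta tibble -> numeric matrix (rows = probes, cols = samples)
beta_values <- function(beta, samples = NULL) {
  m <- as.matrix(beta[, -1, drop = FALSE])
  rownames(m) <- beta$probe_id
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) {
      stop("sample(s) absent from beta matrix: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- m[, samples, drop = FALSE]
  }
  m
}

tissue_classes <- c("tumor", "normal", "metastasis", "cfdna")
dataset_labels <- c("identification", "verification")

#' Read a sample sheet
#'
#' Reads per-sample metadata: project (cancer type), tissue class, dataset
#' membership and a formalin-fixed (FFPE) flag. FFPE samples carry the flag
#' only; exclusion happens in the pipeline before any analysis.
#'
#' @param path CSV file with header
#'   `sample_id,project,tissue_class,dataset,ffpe`.
#' @return A tibble with those five columns; `ffpe` is logical.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    project = readr::col_character(),
    tissue_class = readr::col_character(),
    dataset = readr::col_character(),
    ffpe = readr::col_logical()
  ), progress = FALSE)
  validate_sheet(sheet)
  sheet
}

validate_sheet <- function(sheet) {
  needed <- c("sample_id", "project", "tissue_class", "dataset", "ffpe")
  miss <- setdiff(needed, names(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(sheet$tissue_class), tissue_classes)
  if (length(bad)) {
    stop("unknown tissue_class '", bad[1], "'; allowed: ",
         paste(tissue_classes, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(sheet$dataset), dataset_labels)
  if (length(bad)) {
    stop("unknown dataset '", bad[1], "'; allowed: ",
         paste(dataset_labels, collapse = ", "), call. = FALSE)
  }
  invisible(sheet)
}

#' Read a probe annotation table
#'
#' @param path CSV file with header `probe_id,chromosome`. Chromosome labels
#'   are `1`--`22`, `X`, `Y` (a `chr` prefix is tolerated and stripped).
#' @return A tibble with columns `probe_id`, `chromosome`.
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chromosome = readr::col_character()
  ), progress = FALSE)
  ann$chromosome <- sub("^chr", "", ann$chromosome)
  ann
}

#' Apply probe-exclusion rules to a beta matrix
#'
#' Retains exactly the probes that (a) lie on an autosome, (b) have no
#' missing value in any sample of the matrix, and (c) carry a unique probe
#' id -- every copy of a duplicated id is dropped, since there is no basis
#' for preferring one measurement. Retained values are passed through
#' unaltered. Sample columns are unchanged.
#'
#' @param beta A beta tibble.
#' @param annotation Probe annotation tibble (`probe_id`, `chromosome`);
#'   every probe in `beta` must be annotated.
#' @return The filtered beta tibble.
#' @export
filter_probes <- function(beta, annotation) {
  validate_beta(beta)
  idx <- match(beta$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    stop("unannotated probe(s): ",
         paste(utils::head(beta$probe_id[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  chrom <- annotation$chromosome[idx]
  autosomal <- !(chrom %in% c("X", "Y"))
  complete <- !apply(is.na(as.matrix(beta[, -1, drop = FALSE])), 1, any)
  unique_id <- !(beta$probe_id %in% beta$probe_id[duplicated(beta$probe_id)])
  keep <- autosomal & complete & unique_id
  if (!any(keep)) stop("no probes survive filtering", call. = FALSE)
  beta[keep, , drop = FALSE]
}

#' Relabel projects in a sample sheet
#'
#' Used to pool projects that are analyzed as one cancer type (e.g. colon
#' and rectum adenocarcinoma pooled as colorectal cancer). Idempotent: labels
#' not named in `mapping` are untouched, and reapplying the mapping is a
#' no-op.
#'
#' @param sheet A sample sheet tibble.
#' @param mapping Named character vector, `c(old = "new", ...)`.
#' @return The sheet with `project` relabelled.
#' @examples
#' sheet <- tibble::tibble(
#'   sample_id = c("a", "b"), project = c("COAD", "READ"),
#'   tissue_class = "tumor", dataset = "identification", ffpe = FALSE
#' )
#' merge_projects(sheet, c(COAD = "CRC", READ = "CRC"))
#' @export
merge_projects <- function(sheet, mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  if (any(!nzchar(mapping))) stop("mapping to an empty project label", call. = FALSE)
  hit <- sheet$project %in% names(mapping)
  sheet$project[hit] <- unname(mapping[sheet$project[hit]])
  sheet
}

#' Drop formalin-fixed samples from a sheet and matrix
#'
#' @param beta A beta tibble.
#' @param sheet A sample sheet tibble.
#' @return List with the `beta` and `sheet` restricted to `ffpe == FALSE`
#'   samples.
#' @export
exclude_ffpe <- function(beta, sheet) {
  keep <- sheet$sample_id[!sheet$ffpe]
  list(
    beta = beta[, c("probe_id", intersect(names(beta)[-1], keep)), drop = FALSE],
    sheet = sheet[!sheet$ffpe, , drop = FALSE]
  )
}
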