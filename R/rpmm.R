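#' Most variable probes within a sample group
#'
#' Ranks probes by sample variance across the given samples and returns the
#' top `k`. Ties are broken by probe id (lexicographic), so the selection is
#' deterministic. `k` larger than the number of probes returns all probes.
#'
#' @param beta A beta tibble.
#' @param sample_ids Character vector of sample ids (non-empty).
#' @param k Number of probes to keep.
#' @return Character vector of probe ids, most variable first.
#' @export
top_variable_probes <- function(beta, sample_ids, k = 5000L) {
  stopifnot(k >= 1)
  if (!length(sample_ids)) stop("empty sample group", call. = FALSE)
  x <- beta_values(beta, sample_ids)
  n <- ncol(x)
  if (n < 2) stop("variance needs at least two samples", call. = FALSE)
  v <- rowSums((x - rowMeans(x))^2) / (n - 1)
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(min(k, nrow(x)))]
}

# clamp betas away from {0,1} before beta log-densities
clamp_beta <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

#' Fuzzy two-class initialization
#'
#' Soft memberships used to initialize the beta-mixture EM at each split.
#' Uses the fanny fuzzy clustering algorithm (Euclidean distance, fuzzifier
#' `m_exp`), which is deterministic for a given input. If fanny fails or
#' degenerates to uniform memberships, a deterministic fallback splits the
#' samples at the median of their mean beta and assigns 0.9/0.1
#' memberships.
#'
#' @param x Sample-by-probe numeric matrix.
#' @param n_classes Number of classes (2 at a split).
#' @param m_exp Fuzzifier (membership exponent), default 2.
#' @return Membership matrix (samples by classes); rows sum to 1.
#' @export
fuzzy_init <- function(x, n_classes = 2L, m_exp = 2) {
  if (nrow(x) < n_classes) stop("fewer samples than classes", call. = FALSE)
  memb <- tryCatch({
    f <- cluster::fanny(x, k = n_classes, memb.exp = m_exp, metric = "euclidean",
                        maxit = 200)
    m <- f$membership
    if (max(abs(m - 1 / n_classes)) < 0.05) NULL else m
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(memb)) {
    lev <- rowMeans(x)
    hi <- lev > stats::median(lev)
    if (all(hi) || !any(hi)) hi <- seq_len(nrow(x)) > nrow(x) / 2
    memb <- cbind(ifelse(hi, 0.9, 0.1), ifelse(hi, 0.1, 0.9))
    if (n_classes > 2) stop("fallback initialization supports 2 classes", call. = FALSE)
  }
  rownames(memb) <- rownames(x)
  memb / rowSums(memb)
}

# Weighted method-of-moments beta shapes per probe for one class.
# Returns list(a, b) of length-p vectors; variance floored at 1e-6 and
# capped below mu*(1-mu) so shapes stay positive.
mom_shapes <- function(x, w) {
  sw <- sum(w)
  mu <- colSums(x * w) / sw
  v <- colSums((x - rep(mu, each = nrow(x)))^2 * w) / sw
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  v <- pmax(v, 1e-6)
  v <- pmin(v, 0.99 * mu * (1 - mu))
  s <- mu * (1 - mu) / v - 1
  list(a = mu * s, b = (1 - mu) * s)
}

# Sum of beta log-densities per sample for one class's shapes.
class_loglik <- function(x, a, b) {
  colSums(stats::dbeta(t(x), a, b, log = TRUE))
}

#' Fit a beta-mixture node by EM
#'
#' Fits a mixture of `K` classes (K = 2 at a split, K = 1 for a parent fit)
#' in which, within a class, probes are independent beta variables. The
#' M-step estimates each probe's shape pair by weighted method of moments
#' (`a = mu * (mu (1 - mu) / v - 1)`, `b = (1 - mu) * (...)`, variance
#' floored at 1e-6); the E-step recomputes responsibilities from joint
#' log-densities. Iteration stops when the log-likelihood gain drops below
#' `tol` or after `max_iter` iterations. Values are clamped to
#' `[1e-4, 1 - 1e-4]` before density evaluation.
#'
#' If a class's total weight falls below `min_cluster_size` the fit returns
#' with `collapsed = TRUE` rather than erroring, and the split layer treats
#' it as a rejected split.
#'
#' @param x Sample-by-probe matrix of beta values.
#' @param init_weights Initial membership matrix (samples by classes).
#' @param max_iter,tol EM controls.
#' @param min_cluster_size Minimal effective class size.
#' @return A `beta_mixture_node`: responsibilities (`weights`), per-class
#'   shape matrices `a` and `b` (classes by probes), mixing proportions,
#'   `log_likelihood`, its trace, and `collapsed`.
#' @export
fit_beta_node <- function(x, init_weights, max_iter = 200L, tol = 1e-6,
                          min_cluster_size = 5L) {
  x <- clamp_beta(as.matrix(x))
  w <- as.matrix(init_weights)
  stopifnot(nrow(w) == nrow(x))
  K <- ncol(w)
  n <- nrow(x)
  ll_trace <- numeric()
  ll <- -Inf
  collapsed <- FALSE
  a <- b <- matrix(NA_real_, K, ncol(x))
  mix <- rep(1 / K, K)
  for (iter in seq_len(max_iter)) {
    if (any(colSums(w) < min_cluster_size) && K > 1) {
      collapsed <- TRUE
      break
    }
    for (j in seq_len(K)) {
      sh <- mom_shapes(x, w[, j])
      a[j, ] <- sh$a
      b[j, ] <- sh$b
    }
    mix <- colSums(w) / n
    lp <- vapply(seq_len(K), function(j) class_loglik(x, a[j, ], b[j, ]) + log(mix[j]),
                 numeric(n))
    lp <- matrix(lp, nrow = n)
    m <- apply(lp, 1, max)
    ll_new <- sum(m + log(rowSums(exp(lp - m))))
    w <- exp(lp - m)
    w <- w / rowSums(w)
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(ll) && ll_new - ll < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  structure(list(
    weights = w, a = a, b = b, mixing = mix,
    log_likelihood = ll, ll_trace = ll_trace,
    n = n, n_probes = ncol(x), collapsed = collapsed
  ), class = "beta_mixture_node")
}

#' Level-weighted BIC split decision
#'
#' Compares the one-class (parent) fit with the two-class (children) fit of
#' the same samples using `BIC = -2 logL + p log(n)`, where `p` counts the
#' free beta shape parameters (two per probe per class) plus one mixing
#' weight for the split. Each node's contribution carries the level weight
#' `2^(-depth)` of the node being split; since both alternatives are scored
#' at that node, the weight scales both sides equally and the decision
#' reduces to the plain BIC comparison at every level. The split is
#' accepted iff the weighted split BIC is below the weighted parent BIC and
#' both children have at least `min_cluster_size` hard-assigned samples.
#'
#' @param parent One-class `beta_mixture_node`.
#' @param children Two-class `beta_mixture_node` on the same samples.
#' @param n Sample count at the node.
#' @param depth Node depth (root = 0).
#' @param min_cluster_size Minimal child size.
#' @return List: `accept`, child sizes, raw and weighted BIC values.
#' @export
level_weighted_bic <- function(parent, children, n, depth = 0L,
                               min_cluster_size = 5L) {
  p_parent <- 2 * parent$n_probes
  p_split <- 2 * 2 * children$n_probes + 1
  bic_parent <- -2 * parent$log_likelihood + p_parent * log(n)
  bic_split <- -2 * children$log_likelihood + p_split * log(n)
  wgt <- 2^(-depth)
  hard <- max.col(children$weights)
  sizes <- tabulate(hard, nbins = 2)
  accept <- !children$collapsed &&
    (wgt * bic_split < wgt * bic_parent) &&
    all(sizes >= min_cluster_size)
  list(accept = accept, sizes = sizes,
       bic_parent = bic_parent, bic_split = bic_split,
       weighted_parent = wgt * bic_parent, weighted_split = wgt * bic_split)
}

#' Recursively partitioned beta-mixture clustering of tumor samples
#'
#' Clusters one project's tumor samples on the `k` most variable probes by
#' recursive binary splitting: each node is initialized with [fuzzy_init()],
#' fitted with [fit_beta_node()], and split iff [level_weighted_bic()]
#' accepts. Leaves become methylation clusters, relabelled by
#' [label_clusters()] so that MC1 is the most methylated. Normal-tissue
#' samples are never clustered.
#'
#' @param beta A beta tibble (filtered; no missing values among the used
#'   probes).
#' @param sample_ids Tumor sample ids to cluster.
#' @param k Number of most-variable probes to cluster on (default 5000).
#' @param max_depth Maximal split depth (default 3, i.e. at most 8 leaves).
#' @param min_cluster_size Minimal leaf size (default 5).
#' @param fuzzifier Membership exponent for the initialization.
#' @param tol,max_iter EM controls.
#' @param seed Integer seed (the procedure is deterministic; the seed is
#'   fixed for reproducibility of any tie-breaking randomness in the
#'   initializer's internals).
#' @param project Optional project label carried into the result.
#' @return An `mc_assignment`: `labels` (named integer vector, sample to MC
#'   index), `cluster_means` (MC index to mean beta over the clustering
#'   probes), `probe_set`, `n_clusters`, `project`.
#' @export
rpmm_cluster <- function(beta, sample_ids, k = 5000L, max_depth = 3L,
                         min_cluster_size = 5L, fuzzifier = 2, tol = 1e-6,
                         max_iter = 200L, seed = 1L, project = NULL) {
  set.seed(seed)
  if (length(sample_ids) < 2 * min_cluster_size) {
    warning("too few samples to split; returning a single cluster")
    probes <- if (length(sample_ids) >= 2) {
      top_variable_probes(beta, sample_ids, k)
    } else beta$probe_id
    raw <- stats::setNames(rep(1L, length(sample_ids)), sample_ids)
    return(label_clusters(raw, beta, probes, project = project))
  }
  probes <- top_variable_probes(beta, sample_ids, k)
  x <- t(beta_values(beta, sample_ids)[probes, , drop = FALSE])
  x <- clamp_beta(x)

  leaves <- list()
  recurse <- function(rows, depth) {
    make_leaf <- function() leaves[[length(leaves) + 1]] <<- rows
    if (depth >= max_depth || length(rows) < 2 * min_cluster_size) {
      make_leaf()
      return(invisible())
    }
    xs <- x[rows, , drop = FALSE]
    init <- tryCatch(fuzzy_init(xs, 2L, fuzzifier), error = function(e) NULL)
    if (is.null(init)) {
      make_leaf()
      return(invisible())
    }
    children <- fit_beta_node(xs, init, max_iter = max_iter, tol = tol,
                              min_cluster_size = min_cluster_size)
    parent <- fit_beta_node(xs, matrix(1, nrow(xs), 1), max_iter = max_iter,
                            tol = tol, min_cluster_size = min_cluster_size)
    dec <- level_weighted_bic(parent, children, n = length(rows), depth = depth,
                              min_cluster_size = min_cluster_size)
    if (!dec$accept) {
      make_leaf()
      return(invisible())
    }
    hard <- max.col(children$weights)
    recurse(rows[hard == 1], depth + 1)
    recurse(rows[hard == 2], depth + 1)
    invisible()
  }
  recurse(sample_ids, 0L)

  raw <- integer(length(sample_ids))
  names(raw) <- sample_ids
  for (i in seq_along(leaves)) raw[leaves[[i]]] <- i
  label_clusters(raw, beta, probes, project = project)
}

#' Order and label methylation clusters by mean methylation
#'
#' Relabels raw leaf assignments so that MC1 is the cluster with the
#' highest mean beta over the clustering probe set, MC2 the second highest,
#' and so on. Ties are broken by cluster size (larger first), then by the
#' smallest original leaf index.
#'
#' @param raw Named integer vector: sample id to leaf index.
#' @param beta A beta tibble.
#' @param probe_set Probes over which cluster means are computed.
#' @param project Optional project label.
#' @return An `mc_assignment` (see [rpmm_cluster()]).
#' @export
label_clusters <- function(raw, beta, probe_set, project = NULL) {
  stopifnot(length(raw) > 0, !is.null(names(raw)))
  vals <- beta_values(beta, names(raw))
  vals <- vals[intersect(probe_set, rownames(vals)), , drop = FALSE]
  leaf_ids <- sort(unique(raw))
  means <- vapply(leaf_ids, function(l) {
    mean(vals[, names(raw)[raw == l], drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  sizes <- vapply(leaf_ids, function(l) sum(raw == l), integer(1))
  ord <- order(-means, -sizes, leaf_ids)
  relabel <- integer(max(leaf_ids))
  relabel[leaf_ids[ord]] <- seq_along(leaf_ids)
  labels <- stats::setNames(relabel[raw], names(raw))
  structure(list(
    project = project,
    labels = labels,
    cluster_means = stats::setNames(means[ord], paste0("MC", seq_along(leaf_ids))),
    probe_set = probe_set,
    n_clusters = length(leaf_ids)
  ), class = "mc_assignment")
}

#' @export
print.mc_assignment <- function(x, ...) {
  cat("Methylation cluster assignment",
      if (!is.null(x$project)) paste0(" (", x$project, ")"), "\n", sep = "")
  cat(sprintf("  %d samples in %d clusters on %d probes\n",
              length(x$labels), x$n_clusters, length(x$probe_set)))
  cat("  cluster means: ",
      paste(sprintf("%s=%.3f", names(x$cluster_means), x$cluster_means),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
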