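# Distance-based population divergence: frequency profiles, dissimilarity
# matrices, classical (Torgerson) MDS, and PERMANOVA with permutation
# nulls.

#' Population x variant allele-frequency profile matrix
#'
#' Pivots a long allele-frequency table into the population-profile matrix
#' used for MDS. Cells with no observation get frequency 0 (noted via a
#' message); rows follow the requested population order.
#'
#' @param af_table long table as from [allele_frequency_table()].
#' @param populations row labels (default: those present, in order of
#'   appearance).
#' @param variants column ids (default: those present).
#' @return numeric matrix, populations x variants, values in \[0,1\].
#' @export
population_profile_matrix <- function(af_table, populations = NULL,
                                      variants = NULL) {
  need <- c("variant_id", "population", "af")
  if (!all(need %in% names(af_table))) {
    stop("af_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(populations)) populations <- unique(af_table$population)
  if (is.null(variants)) variants <- unique(af_table$variant_id)
  if (length(variants) == 0L) stop("empty variant list", call. = FALSE)
  m <- matrix(NA_real_, length(populations), length(variants),
              dimnames = list(populations, variants))
  sel <- af_table$population %in% populations &
    af_table$variant_id %in% variants
  sub <- af_table[sel, ]
  m[cbind(match(sub$population, populations),
          match(sub$variant_id, variants))] <- sub$af
  n_unobs <- sum(is.na(m))
  if (n_unobs > 0L) {
    message(n_unobs, " unobserved (population, variant) cell(s) set to ",
            "frequency 0")
    m[is.na(m)] <- 0
  }
  if (any(m < 0 | m > 1)) stop("frequencies must lie in [0,1]",
                               call. = FALSE)
  m
}

#' Pairwise dissimilarity matrix
#'
#' Euclidean and Manhattan distances come from [stats::dist()] (whose
#' handling of missing features — pairwise-complete with proportional
#' rescaling — is exactly what genotype dosages with missing calls need);
#' Bray-Curtis comes from [vegan::vegdist()] and requires complete data.
#'
#' @param profiles entity x feature numeric matrix.
#' @param metric `"euclidean"`, `"manhattan"` or `"bray-curtis"`.
#' @return list of class `"distance_matrix"`: `labels`, `d` (full
#'   symmetric matrix, zero diagonal), `metric`, `is_metric` (whether the
#'   triangle inequality is guaranteed).
#' @export
distance_matrix <- function(profiles,
                            metric = c("euclidean", "manhattan",
                                       "bray-curtis")) {
  metric <- match.arg(metric)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("e%03d", seq_len(nrow(profiles)))
  }
  d <- switch(metric,
              euclidean = stats::dist(profiles, method = "euclidean"),
              manhattan = stats::dist(profiles, method = "manhattan"),
              `bray-curtis` = {
                if (anyNA(profiles)) {
                  stop("bray-curtis requires complete data", call. = FALSE)
                }
                vegan::vegdist(profiles, method = "bray")
              })
  structure(list(labels = rownames(profiles), d = as.matrix(d),
                 metric = metric,
                 is_metric = metric %in% c("euclidean", "manhattan")),
            class = "distance_matrix")
}

as_distance_mat <- function(D) {
  m <- if (inherits(D, "distance_matrix")) D$d
  else if (inherits(D, "dist")) as.matrix(D)
  else as.matrix(D)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) ||
      any(abs(diag(m)) > 1e-8)) {
    stop("D must be a symmetric dissimilarity matrix with zero diagonal",
         call. = FALSE)
  }
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric embedding through the doubly centered squared-distance matrix:
#' B = -(1/2) J D^2 J, eigendecomposition of B, coordinates given by the
#' top-k eigenvectors scaled by the square roots of their (nonnegative)
#' eigenvalues — delegated to [stats::cmdscale()]. When fewer than `k`
#' positive eigenvalues exist the returned dimensions are truncated with a
#' warning.
#'
#' @param D a [distance_matrix()], `dist`, or symmetric matrix.
#' @param k target embedding dimension (default 2).
#' @return list of class `"mds_embedding"`: `points` (centered entity x k'
#'   coordinates), `eig` (all eigenvalues, descending), `goodness`
#'   (fraction of positive eigenvalue mass captured), `k` (dimensions
#'   returned).
#' @export
classical_mds <- function(D, k = 2) {
  m <- as_distance_mat(D)
  n <- nrow(m)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k_req <- min(k, n - 1L)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = k_req, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive dimension(s) available; ",
            "requested ", k, call. = FALSE)
  }
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(pmax(eig, 0))
  goodness <- if (pos > 0 && ncol(pts) > 0) {
    sum(pmax(eig, 0)[seq_len(ncol(pts))]) / pos
  } else 0
  colnames(pts) <- if (ncol(pts) > 0) paste0("dim", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eig, goodness = goodness,
                 k = ncol(pts)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$points), "entities in", x$k,
      sprintf("dimension(s); %.1f%% of positive eigenvalue mass\n",
              100 * x$goodness))
  invisible(x)
}

# Within-group sum of squared distances for a label assignment.
ss_within_groups <- function(d2, groups) {
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssw
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared inter-point dissimilarities,
#' SS_total = (1/N) sum over i<j of d_ij^2, into within-group
#' (SS_within = sum over groups of (1/n_g) sum over i<j in g of d_ij^2)
#' and between-group components. The pseudo-F statistic is
#' (SS_between/(a-1)) / (SS_within/(N-a)) for a groups; R^2 =
#' SS_between / SS_total. Significance comes from uniform random label
#' permutations with the add-one estimator p = (1 + #\{F_perm >= F_obs\})
#' / (1 + n_permutations), so p is never zero and is bounded below by
#' 1/(n_permutations + 1).
#'
#' @param D a [distance_matrix()], `dist`, or symmetric matrix over
#'   entities.
#' @param groups group label per entity (>= 2 groups, each nonempty, not
#'   all entities in one group).
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return list of class `"permanova_result"`: `r2`, `f_stat`, `p_raw`,
#'   sums of squares, degrees of freedom, `n_total`, `n_groups`,
#'   `group_sizes`, `n_permutations`, `seed`.
#' @export
permanova <- function(D, groups, n_permutations = 999, seed = NULL) {
  m <- as_distance_mat(D)
  n <- nrow(m)
  groups <- droplevels(factor(groups))
  if (length(groups) != n) stop("one group label per entity is required",
                                call. = FALSE)
  a <- nlevels(groups)
  if (a < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 1L)) stop("every group needs >= 1 entity",
                                    call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1",
                               call. = FALSE)
  d2 <- m^2
  ss_total <- sum(d2) / (2 * n)
  ss_within <- ss_within_groups(d2, groups)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (a - 1)) / (ss_within / (n - a))
  r2 <- ss_between / ss_total

  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- groups[sample.int(n)]
      ssw <- ss_within_groups(d2, perm)
      f_b <- ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
      if (f_b >= f_obs) cnt <- cnt + 1L
    }
    cnt
  })
  p <- (1 + exceed) / (1 + n_permutations)
  structure(list(r2 = r2, f_stat = f_obs, p_raw = p,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_total, df_between = a - 1L,
                 df_within = n - a, n_total = n, n_groups = a,
                 group_sizes = as.integer(table(groups)),
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: %d entities, %d groups | R2 = %.4f, F = %.3f, p = %.4g (%d permutations)\n",
    x$n_total, x$n_groups, x$r2, x$f_stat, x$p_raw, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over all unordered population pairs
#'
#' Runs a two-group [permanova()] on the distance sub-matrix of each pair
#' of populations and applies Hochberg adjustment across pairs. Each
#' pair's permutation stream is derived deterministically from `seed`.
#'
#' @param D distances over all entities ([distance_matrix()], `dist`, or
#'   symmetric matrix).
#' @param populations population label per entity.
#' @param n_permutations permutations per pair.
#' @param seed optional integer master seed.
#' @return data.frame of class `"pairwise_permanova"`, one row per pair:
#'   `group1`, `group2`, `n1`, `n2`, `r2`, `f_stat`, `p_raw`,
#'   `p_adjusted`, `n_permutations`, `seed`.
#' @export
pairwise_permanova <- function(D, populations, n_permutations = 999,
                               seed = NULL) {
  m <- as_distance_mat(D)
  populations <- factor(populations)
  if (length(populations) != nrow(m)) {
    stop("one population label per entity is required", call. = FALSE)
  }
  pops <- levels(populations)
  if (length(pops) < 2L) stop("need at least two populations",
                              call. = FALSE)
  pairs <- utils::combn(pops, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    idx <- which(populations %in% c(g1, g2))
    res <- permanova(m[idx, idx, drop = FALSE],
                     droplevels(populations[idx]),
                     n_permutations = n_permutations,
                     seed = derive_seed(seed, i))
    data.frame(group1 = g1, group2 = g2,
               n1 = sum(populations == g1), n2 = sum(populations == g2),
               r2 = res$r2, f_stat = res$f_stat, p_raw = res$p_raw,
               n_permutations = n_permutations,
               seed = if (is.null(seed)) NA_integer_ else seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- hochberg_adjust(out$p_raw)
  out <- out[, c("group1", "group2", "n1", "n2", "r2", "f_stat",
                 "p_raw", "p_adjusted", "n_permutations", "seed")]
  rownames(out) <- NULL
  class(out) <- c("pairwise_permanova", "data.frame")
  out
}
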