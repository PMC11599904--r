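test_that("population profile matrix pivots and defaults correctly", {
  af <- data.frame(variant_id = rep(c("v1", "v2", "v3"), 2),
                   population = rep(c("A", "B"), each = 3),
                   af = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  m <- population_profile_matrix(af)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["B", "v2"], 0.5)

  single <- population_profile_matrix(af[af$population == "A", ])
  expect_equal(nrow(single), 1L)

  # unobserved cells become zero, with a message
  expect_message(m2 <- population_profile_matrix(af[-1, ]), "unobserved")
  expect_equal(m2["A", "v1"], 0)
  expect_error(population_profile_matrix(af, variants = character(0)),
               "empty")
})

test_that("distance matrices match a double-loop computation", {
  expect_equal(distance_matrix(rbind(c(0, 0), c(3, 4)))$d[1, 2], 5)
  expect_equal(distance_matrix(rbind(a = c(1, 2), b = c(1, 2)))$d[1, 2], 0)

  set.seed(12)
  x <- matrix(runif(6 * 4), 6, 4)
  for (metric in c("euclidean", "manhattan", "bray-curtis")) {
    D <- distance_matrix(x, metric)$d
    for (i in 1:6) for (j in 1:6) {
      want <- switch(metric,
                     euclidean = sqrt(sum((x[i, ] - x[j, ])^2)),
                     manhattan = sum(abs(x[i, ] - x[j, ])),
                     `bray-curtis` = sum(abs(x[i, ] - x[j, ])) /
                       sum(x[i, ] + x[j, ]))
      expect_equal(D[i, j], want, tolerance = 1e-12)
    }
  }
  expect_error(distance_matrix(x, "mahalanobis"))
})

test_that("missing features use pairwise-complete rescaled distances", {
  x <- rbind(c(1, 2, NA, 4), c(0, 2, 5, 8))
  D <- distance_matrix(x, "euclidean")
  expect_equal(D$d[1, 2], sqrt((4 / 3) * (1 + 0 + 16)))
  expect_error(distance_matrix(x, "bray-curtis"), "complete")
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  # 3-4-5 right triangle
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3
  D[1, 3] <- D[3, 1] <- 4
  D[2, 3] <- D[3, 2] <- 5
  emb <- classical_mds(D, k = 2)
  got <- as.matrix(stats::dist(emb$points))
  expect_equal(got, D, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colMeans(emb$points), c(dim1 = 0, dim2 = 0),
               tolerance = 1e-12)
  expect_equal(emb$eig, sort(emb$eig, decreasing = TRUE))

  # all-zero distances embed at the origin (with no positive dimension)
  expect_warning(z <- classical_mds(matrix(0, 4, 4), k = 2),
                 "positive dimension")
  expect_true(all(abs(z$points) < 1e-12))

  # Gram positivity: Euclidean point sets give eigenvalues >= -1e-9
  set.seed(5)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  e <- classical_mds(as.matrix(stats::dist(pts)), k = 3)
  expect_true(all(e$eig >= -1e-9))
  expect_equal(as.matrix(stats::dist(e$points)),
               as.matrix(stats::dist(pts)), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_warning(classical_mds(D, k = 5), "positive dimension")
})

make_two_cluster_D <- function(n1, n2, sep, seed) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 2), n1),
             matrix(rnorm(n2 * 2, mean = sep), n2))
  list(x = x, D = distance_matrix(x, "euclidean"),
       g = rep(c("a", "b"), c(n1, n2)))
}

test_that("PERMANOVA decomposition satisfies its identities", {
  tc <- make_two_cluster_D(8, 7, 3, seed = 31)
  res <- permanova(tc$D, tc$g, n_permutations = 99, seed = 1)
  expect_equal(res$r2 + res$ss_within / res$ss_total, 1, tolerance = 1e-12)
  expect_true(res$r2 >= 0 && res$r2 <= 1)
  expect_gte(res$p_raw, 1 / 100)

  # invariant to relabeling entities and to rescaling all distances
  perm <- sample(length(tc$g))
  res2 <- permanova(tc$D$d[perm, perm], tc$g[perm],
                    n_permutations = 99, seed = 1)
  expect_equal(res2$f_stat, res$f_stat, tolerance = 1e-10)
  expect_equal(res2$r2, res$r2, tolerance = 1e-10)
  res3 <- permanova(3.7 * tc$D$d, tc$g, n_permutations = 99, seed = 1)
  expect_equal(res3$f_stat, res$f_stat, tolerance = 1e-10)
  expect_equal(res3$r2, res$r2, tolerance = 1e-10)
  expect_equal(res3$p_raw, res$p_raw)

  # fixed seed reproduces p; different seeds move it within MC error
  resA <- permanova(tc$D, tc$g, n_permutations = 199, seed = 42)
  resB <- permanova(tc$D, tc$g, n_permutations = 199, seed = 42)
  expect_identical(resA$p_raw, resB$p_raw)

  expect_error(permanova(tc$D, rep("a", 15)), "two groups")
  expect_error(permanova(tc$D, tc$g, n_permutations = 0),
               "n_permutations")
})

test_that("PERMANOVA F matches the coordinate-based one-way pseudo-F", {
  set.seed(77)
  x <- matrix(rnorm(18 * 4), 18, 4)
  g <- rep(c("p", "q", "r"), each = 6)
  res <- permanova(distance_matrix(x, "euclidean"), g,
                   n_permutations = 9, seed = 1)
  expect_equal(res$f_stat, permanova_f_from_coords(x, g),
               tolerance = 1e-10)
})

test_that("PERMANOVA agrees with vegan's adonis2 on F and R2", {
  tc <- make_two_cluster_D(9, 8, 2, seed = 13)
  res <- permanova(tc$D, tc$g, n_permutations = 49, seed = 5)
  grp <- factor(tc$g)
  fit <- vegan::adonis2(stats::as.dist(tc$D$d) ~ grp, permutations = 49)
  expect_equal(res$f_stat, fit$F[1], tolerance = 1e-8)
  expect_equal(res$r2, fit$R2[1], tolerance = 1e-8)
})

test_that("permutation p converges to the exhaustive enumeration", {
  set.seed(55)
  x <- matrix(rnorm(6 * 2), 6, 2)
  x[4:6, ] <- x[4:6, ] + 1.5
  d2 <- as.matrix(stats::dist(x))^2
  p_exact <- permanova_exhaustive_p(d2, 3)
  res <- permanova(as.matrix(stats::dist(x)), rep(c("a", "b"), each = 3),
                   n_permutations = 9999, seed = 8)
  expect_lt(abs(res$p_raw - p_exact), 0.03)
})

test_that("pairwise PERMANOVA covers all pairs with Hochberg adjustment", {
  set.seed(91)
  x <- rbind(matrix(rnorm(12 * 3), 12),
             matrix(rnorm(10 * 3, 2), 10),
             matrix(rnorm(11 * 3, 4), 11))
  pops <- rep(c("A", "B", "C"), c(12, 10, 11))
  pp <- pairwise_permanova(distance_matrix(x, "euclidean"), pops,
                           n_permutations = 99, seed = 3)
  expect_equal(nrow(pp), 3L)
  expect_true(all(pp$p_adjusted >= pp$p_raw - 1e-12))
  expect_identical(
    pp$p_raw,
    pairwise_permanova(distance_matrix(x, "euclidean"), pops,
                       n_permutations = 99, seed = 3)$p_raw)

  # identical populations: no significance under the fixed seed
  y <- matrix(rnorm(20 * 3), 20)
  same <- pairwise_permanova(distance_matrix(y, "euclidean"),
                             rep(c("g1", "g2"), each = 10),
                             n_permutations = 199, seed = 7)
  expect_gt(same$p_adjusted[1], 0.05)
})

test_that("printed pairwise results are self-consistent with F = R2(n-2)/(1-R2)", {
  t4 <- load_study_table("table4")
  sizes <- c("IND-NLLA" = 59, "IND-LLA" = 5, AFR = 661, AMR = 347,
             EAS = 504, EUR = 503, SAS = 489)
  n <- sizes[t4$group1] + sizes[t4$group2]
  f_lo <- (t4$r2 - 5e-4) * (n - 2) / (1 - (t4$r2 - 5e-4))
  f_hi <- (t4$r2 + 5e-4) * (n - 2) / (1 - (t4$r2 + 5e-4))
  expect_true(all(t4$f >= f_lo & t4$f <= f_hi))
})
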