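make_groups_dist <- function(n_per = 3L, sep = 0, k = 2L, seed = 1L) {
  set.seed(seed)
  pts <- matrix(rnorm(k * n_per * 2), ncol = 2)
  pts[, 1] <- pts[, 1] + rep(seq_len(k) * sep, each = n_per)
  rownames(pts) <- paste0("s", seq_len(nrow(pts)))
  list(d = dist(pts), g = rep(letters[seq_len(k)], each = n_per), pts = pts)
}

test_that("anosim hits the definition extremes and matches vegan", {
  gd <- make_groups_dist(n_per = 4L, sep = 50, seed = 2L)
  res <- anosim(gd$d, gd$g, n_perm = 99L, seed = 1L)
  expect_equal(res$statistic, 1)           # all between > all within
  expect_lte(res$p_value, 0.05)
  ## statistic agrees with vegan on an unstructured instance
  gd2 <- make_groups_dist(n_per = 5L, sep = 0.5, seed = 3L)
  res2 <- anosim(gd2$d, gd2$g, n_perm = 99L, seed = 1L)
  veg <- vegan::anosim(gd2$d, gd2$g, permutations = 9L)
  expect_equal(res2$statistic, unname(veg$statistic), tolerance = 1e-12)
  expect_error(anosim(gd$d, c("a", rep("b", 7L))), "singleton")
})

test_that("anosim exact p matches exhaustive label enumeration", {
  gd <- make_groups_dist(n_per = 3L, sep = 1, seed = 5L)   # n = 6
  res <- anosim(gd$d, gd$g, seed = 1L, exact = TRUE)
  dm <- as.matrix(gd$d)
  perms <- oracle_perms(6L)
  obs <- oracle_anosim_R(dm, gd$g)
  stats <- apply(perms, 1L, function(ix) oracle_anosim_R(dm, gd$g[ix]))
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(stats >= obs - 1e-12), tolerance = 1e-12)
})

test_that("permanova equals coordinate-wise ANOVA F in Euclidean space", {
  gd <- make_groups_dist(n_per = 6L, sep = 4, k = 3L, seed = 7L)
  res <- permanova(gd$d, gd$g, n_perm = 99L, seed = 1L)
  ## classical one-way ANOVA on each coordinate; pseudo-F from pooled SS
  ss <- function(x) sum(scale(x, scale = FALSE)^2)
  sst <- sum(apply(gd$pts, 2L, ss))
  ssw <- sum(sapply(split(seq_len(nrow(gd$pts)), gd$g), function(ix)
    sum(apply(gd$pts[ix, , drop = FALSE], 2L, ss))))
  f_classic <- ((sst - ssw) / 2) / (ssw / (nrow(gd$pts) - 3L))
  expect_equal(res$statistic, f_classic, tolerance = 1e-10)
  ## agrees with vegan::adonis2
  ad <- vegan::adonis2(gd$d ~ g, data = data.frame(g = gd$g),
                       permutations = 9L)
  expect_equal(res$statistic, ad$F[1L], tolerance = 1e-10)
  ## duplicating every sample increases pseudo-F
  dm <- as.matrix(gd$d)
  big <- rbind(cbind(dm, dm), cbind(dm, dm))
  ids <- c(rownames(dm), paste0(rownames(dm), "_dup"))
  dimnames(big) <- list(ids, ids)
  res2 <- permanova(as.dist(big), rep(gd$g, 2L), n_perm = 9L, seed = 1L)
  expect_gt(res2$statistic, res$statistic)
})

test_that("mantel is exact under affine maps and exhaustive enumeration", {
  gd <- make_groups_dist(n_per = 5L, seed = 11L)  # n = 10
  d1 <- gd$d
  expect_equal(mantel_test(d1, d1, n_perm = 9L, seed = 1L)$statistic, 1)
  d2 <- 3 * d1 + 0.7
  expect_equal(mantel_test(d1, d2, n_perm = 9L, seed = 1L)$statistic, 1)

  set.seed(13)
  p1 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  p2 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  res <- mantel_test(dist(p1), dist(p2), exact = TRUE)
  m1 <- as.matrix(dist(p1)); m2 <- as.matrix(dist(p2))
  lt <- lower.tri(m1)
  obs <- cor(m1[lt], m2[lt])
  stats <- apply(oracle_perms(5L), 1L, function(ix)
    cor(m1[lt], m2[ix, ix][lt]))
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(stats >= obs - 1e-12), tolerance = 1e-12)

  bad <- m2; rownames(bad)[1] <- colnames(bad)[1] <- "zz"
  expect_error(mantel_test(dist(p1), bad), "zz")
})

test_that("procrustes m2 is invariant to similarity transforms", {
  set.seed(17)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- 2.5 * X %*% R + matrix(rep(c(3, -1), each = 10), 10, 2)
  rownames(Y) <- rownames(X)
  res <- procrustes_test(X, Y, n_perm = 99L, seed = 1L)
  expect_lt(res$statistic, 1e-10)
  expect_lte(res$p_value, 0.05)
  ## statistic agrees with vegan::protest (symmetric procrustes)
  set.seed(18)
  Y2 <- matrix(rnorm(20), 10, 2, dimnames = dimnames(X))
  res2 <- procrustes_test(X, Y2, n_perm = 99L, seed = 1L)
  pro <- vegan::protest(X, Y2, permutations = 9L)
  expect_equal(res2$statistic, unname(pro$ss), tolerance = 1e-10)
  ## m2 stays in [0, 1]
  for (k in 1:20) {
    set.seed(100 + k)
    A <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
    B <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
    m2 <- procrustes_test(A, B, n_perm = 0L, seed = 1L)$statistic
    expect_gte(m2, 0); expect_lte(m2, 1)
  }
})

test_that("simper matches the brute-force pair enumeration", {
  ## equal-proportion features contribute 0; the differing features carry
  ## the whole between-sample dissimilarity
  tab <- matrix(c(5L, 5L, 9L, 0L,
                  5L, 5L, 0L, 9L), 2, 4, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("a", "b", "c", "d")))
  res <- simper_contrib(tab, c("g1", "g2"))
  cc <- setNames(res$g1_vs_g2$contribution, res$g1_vs_g2$feature)
  expect_equal(unname(cc[c("a", "b")]), c(0, 0))
  expect_equal(unname(sum(cc[c("c", "d")])), 1)

  set.seed(19)
  tab2 <- random_table(7L, 4L, lambda = 10)
  g <- c("A", "A", "B", "B", "C", "C", "C")
  res2 <- simper_contrib(tab2, g)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    want <- oracle_simper_pair(tab2, g, pair[1], pair[2])
    df <- res2[[paste0(pair[1], "_vs_", pair[2])]]
    expect_equal(setNames(df$contribution, df$feature)[names(want)], want,
                 tolerance = 1e-12)
    expect_equal(sum(df$contribution), 1, tolerance = 1e-12)
    expect_equal(df$cumulative[nrow(df)], 1, tolerance = 1e-12)
  }
})

test_that("duncan letters separate forced means and match the t-test for k=2", {
  v <- c(1, 1.01, 0.99, 5, 5.01, 4.99, 9, 9.01, 8.99)
  g <- rep(c("lo", "mid", "hi"), each = 3)
  res <- anova_duncan(v, g)
  expect_setequal(res$letters, c("a", "b", "c"))
  expect_identical(res$letters[res$group == "hi"], "a")  # letters follow rank

  ## two-group Duncan decision == two-sample pooled t-test at alpha
  for (s in 1:25) {
    set.seed(200 + s)
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 2))
    dres <- anova_duncan(c(x, y), rep(c("x", "y"), each = 6))
    sep_duncan <- !grepl(dres$letters[1], dres$letters[2], fixed = TRUE)
    sep_t <- t.test(x, y, var.equal = TRUE)$p.value < 0.05
    expect_identical(sep_duncan, sep_t)
  }
})

test_that("duncan null behaviour matches its protection level", {
  ## share-one-letter frequency under the null: 1 - alpha for k = 2 and
  ## 1 - (1 - (1-alpha)^2) for k = 3 (only the full range is tested first)
  set.seed(2025)
  k3 <- mean(replicate(400, {
    r <- anova_duncan(rnorm(12), rep(c("a", "b", "c"), each = 4))
    all(grepl(r$letters[1], r$letters, fixed = TRUE))
  }))
  expect_gt(k3, 0.9025 - 3 * sqrt(0.9025 * 0.0975 / 400))
  expect_lt(k3, 0.9025 + 3 * sqrt(0.9025 * 0.0975 / 400))
  k2 <- mean(replicate(400, {
    r <- anova_duncan(rnorm(10), rep(c("a", "b"), each = 5))
    r$letters[1] == r$letters[2]
  }))
  expect_gte(k2, 0.90)
})

test_that("wilcoxon exact enumeration handles ties and separation", {
  expect_equal(wilcoxon_ranksum(11:15, 1:5, alternative = "greater")$p_value,
               1 / 252)
  expect_equal(wilcoxon_ranksum(c(2, 2, 3), c(2, 2, 3))$p_value, 1)
  ## agreement with stats::wilcox.test on tie-free exact cases
  for (s in 1:10) {
    set.seed(300 + s)
    x <- rnorm(6); y <- rnorm(7)
    got <- wilcoxon_ranksum(x, y)$p_value
    want <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
  ## exact and normal-approx branches agree at moderate n
  set.seed(314)
  x <- rnorm(12); y <- rnorm(8, 0.5)
  pe <- wilcoxon_ranksum(x, y, exact = TRUE)$p_value
  pa <- wilcoxon_ranksum(x, y, exact = FALSE)$p_value
  expect_lt(abs(pe - pa), 0.01)
})

test_that("permutation p-values use the add-one convention and never hit 0", {
  gd <- make_groups_dist(n_per = 4L, sep = 100, seed = 23L)
  res <- anosim(gd$d, gd$g, n_perm = 99L, seed = 5L)
  expect_gte(res$p_value, 1 / 100)
  res2 <- permanova(gd$d, gd$g, n_perm = 99L, seed = 5L)
  expect_gte(res2$p_value, 1 / 100)
  ## seeded reproducibility
  expect_identical(anosim(gd$d, gd$g, n_perm = 49L, seed = 9L)$p_value,
                   anosim(gd$d, gd$g, n_perm = 49L, seed = 9L)$p_value)
})
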