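# Permutation-based community statistics and group tests.
#
# All permutation tests share one engine: a seeded set of random label
# permutations, or the complete enumeration of all n! permutations when
# `exact = TRUE` (feasible for small n).  With random permutations the
# p-value uses the add-one convention p = (1 + #{perm >= obs}) / (1 + B),
# so p is never zero; with exhaustive enumeration p is the exact fraction
# of permutations (identity included) reaching the observed statistic.

perm_result <- function(name, statistic, p_value, n_perm, seed, exact,
                        extra = NULL) {
  structure(c(list(statistic_name = name, statistic = statistic,
                   p_value = p_value, n_permutations = n_perm,
                   seed = seed, exact = exact), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  tail_txt <- if (is.na(x$n_permutations %||% NA)) "(normal approximation)"
    else paste0(if (isTRUE(x$exact)) "(exact, " else "(",
                x$n_permutations, " permutations)")
  cat(x$statistic_name, " = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_value, digits = 4), " ", tail_txt, "\n", sep = "")
  invisible(x)
}

## all permutations of 1..n as an n! x n matrix (n <= 8 guarded)
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8 (n! blow-up)")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    blk <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

## statistic over observed + permutations; returns perm_result
run_permutation <- function(name, stat_fun, n, n_perm, seed, exact,
                            extra = NULL) {
  obs <- stat_fun(seq_len(n))
  if (exact) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, stat_fun)
    p <- mean(stats >= obs - 1e-12)
    return(perm_result(name, obs, p, nrow(perms), seed, TRUE, extra))
  }
  ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(b) stat_fun(sample.int(n)) >= obs - 1e-12,
               logical(1L)))
  })
  perm_result(name, obs, (1 + ge) / (1 + n_perm), n_perm, seed, FALSE, extra)
}

align_groups <- function(d, groups) {
  d <- validate_distance_matrix(d)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length must match distance matrix size")
  g <- as.factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 members (singleton group)")
  list(d = d, g = g, n = n)
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4) on
#' the ranked pairwise distances; significance by permutation of the group
#' labels (one-sided, large R).
#'
#' @param d `dist` or symmetric matrix of sample distances.
#' @param groups group labels, one per sample.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param exact enumerate all label permutations (small n only).
#' @return a `perm_test` with statistic `R`.
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  al <- align_groups(d, groups)
  r <- rank(as.vector(al$d))
  n <- al$n
  dm <- matrix(0, n, n)
  dm[lower.tri(dm)] <- r
  dm <- dm + t(dm)
  lt <- lower.tri(dm)
  g <- al$g
  denom <- n * (n - 1) / 4
  stat_fun <- function(idx) {
    w <- g[idx]
    same <- outer(w, w, "==")[lt]
    rv <- dm[lt]
    (mean(rv[!same]) - mean(rv[same])) / denom
  }
  run_permutation("ANOSIM R", stat_fun, n, n_perm, seed, exact)
}

#' One-factor PERMANOVA (ADONIS)
#'
#' Pseudo-F = (SS_between / (k-1)) / (SS_within / (n-k)) with sums of
#' squares partitioned from squared inter-point distances (Anderson's
#' decomposition); significance by label permutation (one-sided, large F).
#'
#' @inheritParams anosim
#' @return a `perm_test` with statistic `pseudo-F`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  al <- align_groups(d, groups)
  n <- al$n
  d2 <- as.matrix(al$d)^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  g <- al$g
  k <- nlevels(g)
  stat_fun <- function(idx) {
    w <- g[idx]
    ss_within <- 0
    for (lev in levels(g)) {
      m <- w == lev
      ss_within <- ss_within + sum(d2[m, m][lower.tri(d2[m, m])]) / sum(m)
    }
    ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  }
  run_permutation("pseudo-F", stat_fun, n, n_perm, seed, exact,
                  extra = list(df = c(k - 1L, n - k)))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries; p by joint
#' row/column permutation of the second matrix (one-sided, large r).
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same ids
#'   (aligned by labels when present).
#' @inheritParams anosim
#' @return a `perm_test` with statistic `Mantel r`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL, exact = FALSE) {
  d1 <- validate_distance_matrix(d1); d2 <- validate_distance_matrix(d2)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2))
      stop("distance matrices cover different ids: ",
           paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
    m2 <- m2[l1, l1]
  } else if (nrow(m1) != nrow(m2)) stop("distance matrices differ in size")
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  stat_fun <- function(idx) cor(v1, m2[idx, idx][lt])
  run_permutation("Mantel r", stat_fun, n, n_perm, seed, exact)
}

## symmetric Procrustes m2 between two centred, unit-trace configurations
procrustes_m2 <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  1 - sum(svd(crossprod(X, Y))$d)^2
}

#' Procrustes comparison of two ordinations (PROTEST)
#'
#' Symmetric Procrustes: both configurations are centred and scaled to
#' unit trace, the optimal rotation is found by SVD, and the statistic is
#' m2 = 1 - (sum of singular values)^2.  Significance by permuting the
#' rows of the second configuration (one-sided, small m2).
#'
#' @param ord1,ord2 `pcoa_ord` objects (or coordinate matrices with
#'   rownames) over the same samples.
#' @param k number of leading shared axes compared (default 2, capped at
#'   what both ordinations provide).
#' @inheritParams anosim
#' @return a `perm_test` with statistic `m2`.
#' @export
procrustes_test <- function(ord1, ord2, k = 2L, n_perm = 999L, seed = NULL,
                            exact = FALSE) {
  X <- if (inherits(ord1, "pcoa_ord")) ord1$coordinates else as.matrix(ord1)
  Y <- if (inherits(ord2, "pcoa_ord")) ord2$coordinates else as.matrix(ord2)
  if (!setequal(rownames(X), rownames(Y)))
    stop("ordinations cover different ids")
  Y <- Y[rownames(X), , drop = FALSE]
  k <- min(k, ncol(X), ncol(Y))
  X <- X[, seq_len(k), drop = FALSE]
  Y <- Y[, seq_len(k), drop = FALSE]
  n <- nrow(X)
  ## orientation: small m2 = concordant, so permutation tail uses -m2
  stat_fun <- function(idx) -procrustes_m2(X, Y[idx, , drop = FALSE])
  res <- run_permutation("Procrustes m2", stat_fun, n, n_perm, seed, exact)
  res$statistic <- -res$statistic
  res
}

#' SIMPER: per-feature contributions to between-group dissimilarity
#'
#' For every ordered pair of groups, the contribution of feature i for a
#' between-group sample pair (a, b) is `|p_ia - p_ib| / sum_f |p_fa - p_fb|`
#' (the Bray-Curtis numerator share on per-sample relative abundances),
#' averaged over all between-group pairs and ranked descending.
#'
#' @param table feature table (samples x features).
#' @param groups group labels, one per sample.
#' @return a named list (one element per group pair `"A_vs_B"`) of
#'   data.frames with columns `feature`, `contribution`, `cumulative`.
#' @export
simper_contrib <- function(table, groups) {
  validate_feature_table(table)
  g <- as.factor(groups)
  if (any(table(g) < 1L)) stop("empty group")
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  p <- table / rowSums(table)
  out <- list()
  levs <- levels(g)
  for (i in seq_len(length(levs) - 1L)) for (j in (i + 1L):length(levs)) {
    A <- which(g == levs[i]); B <- which(g == levs[j])
    contrib <- numeric(ncol(p))
    for (a in A) for (b in B) {
      dif <- abs(p[a, ] - p[b, ])
      tot <- sum(dif)
      if (tot > 0) contrib <- contrib + dif / tot
    }
    contrib <- contrib / (length(A) * length(B))
    ord <- order(-contrib, colnames(p))
    df <- data.frame(feature = colnames(p)[ord],
                     contribution = contrib[ord],
                     cumulative = cumsum(contrib[ord]) / sum(contrib),
                     row.names = NULL, stringsAsFactors = FALSE)
    out[[paste0(levs[i], "_vs_", levs[j])]] <- df
  }
  structure(out, class = "simper_table")
}

# ---- group tests ----------------------------------------------------------

#' One-way ANOVA with Duncan's multiple-range letters
#'
#' Fits a one-way ANOVA and applies Duncan's multiple-range test: group
#' means are ordered, and the range of every span of p consecutive means
#' is compared to the critical range
#' `r_p = q(1 - alpha_p, p, df) * sqrt(MSE / n)` with the Duncan
#' protection level `alpha_p = 1 - (1 - alpha)^(p - 1)` (studentized-range
#' quantiles from `qtukey`).  Letters follow the usual convention: groups
#' sharing no letter differ at level `alpha`.  Unequal group sizes are
#' handled through the harmonic mean of the sizes (flagged).
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level.
#' @return object of class `duncan_letters`: data.frame with `group`,
#'   `mean`, `sd`, `n`, `letters`, plus attributes `anova_p`, `alpha`,
#'   `balanced`.
#' @export
anova_duncan <- function(values, groups, alpha = 0.05) {
  g <- as.factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 replicates")
  fit <- aov(values ~ g)
  an <- anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  means <- tapply(values, g, mean)
  sds <- tapply(values, g, sd)
  ns <- tapply(values, g, length)
  balanced <- length(unique(ns)) == 1L
  if (!balanced)
    warning("unequal group sizes; using the harmonic mean of group sizes")
  nh <- length(ns) / sum(1 / ns)
  ord <- order(-means)
  m <- means[ord]
  k <- length(m)
  ## step-down multiple range: once a covering span tests non-significant,
  ## everything inside it is declared non-significant (Duncan protection)
  ns_pair <- matrix(FALSE, k, k)
  for (span in k:2) {
    ## protection level alpha_p = 1 - (1-alpha)^(span-1); upper quantile
    r_p <- qtukey((1 - alpha)^(span - 1), span, df) * sqrt(mse / nh)
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (ns_pair[i, j]) next
      if (m[i] - m[j] < r_p) ns_pair[i:j, i:j] <- TRUE
    }
  }
  diag(ns_pair) <- TRUE
  ## letters from maximal non-significant intervals over the sorted means
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && ns_pair[i, j + 1L]) j <- j + 1L
    intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) for (b in seq_along(intervals))
    if (a != b && keep[b] &&
        intervals[[a]][1] <= intervals[[b]][1] &&
        intervals[[a]][2] >= intervals[[b]][2] &&
        !identical(intervals[[a]], intervals[[b]])) keep[b] <- FALSE
  intervals <- unique(intervals[keep])
  letters_sorted <- rep("", k)
  for (li in seq_along(intervals)) {
    rng <- intervals[[li]]
    letters_sorted[rng[1]:rng[2]] <-
      paste0(letters_sorted[rng[1]:rng[2]], letters[li])
  }
  lab <- setNames(letters_sorted, names(m))
  out <- data.frame(group = levels(g), mean = as.numeric(means),
                    sd = as.numeric(sds), n = as.integer(ns),
                    letters = lab[levels(g)],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "anova_p") <- an[1, "Pr(>F)"]
  attr(out, "alpha") <- alpha
  attr(out, "balanced") <- balanced
  class(out) <- c("duncan_letters", "data.frame")
  out
}

#' Wilcoxon rank-sum test with midrank ties
#'
#' Rank-sum statistic with midranks for ties.  When the combined sample
#' size is at most 20 (and complete enumeration is affordable) the null
#' distribution of the rank sum is enumerated exactly over all
#' `choose(n+m, n)` assignments, which remains valid under ties; larger
#' samples use the normal approximation with continuity and tie
#' correction.  Two-sided p is `2 * min(P(W <= w), P(W >= w))`, capped
#' at 1.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by sample size.
#' @return a `perm_test`-shaped object with statistic `W` (rank sum of
#'   `x`).
#' @export
wilcoxon_ranksum <- function(x, y,
                             alternative = c("two.sided", "greater", "less"),
                             exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  use_exact <- exact %||% (n + m <= 20L)
  if (use_exact && choose(n + m, n) > 2e5) use_exact <- FALSE
  if (use_exact) {
    sets <- combn(n + m, n)
    w_all <- colSums(matrix(r[sets], nrow = n))
    p_le <- mean(w_all <= w + 1e-9)
    p_ge <- mean(w_all >= w - 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    n_perm <- ncol(sets)
  } else {
    mu <- n * (m + n + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((n + m + 1) -
                            sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    zstat <- function(shift) (w - mu + shift) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(zstat(0.5)),
                                           pnorm(zstat(-0.5), lower.tail = FALSE))),
                greater = pnorm(zstat(-0.5), lower.tail = FALSE),
                less = pnorm(zstat(0.5)))
    n_perm <- NA_integer_
  }
  perm_result("Wilcoxon W", w, p, n_perm, NULL, use_exact,
              extra = list(alternative = alternative))
}

#' Spearman correlation with permutation p-value
#'
#' @param x,y numeric vectors of equal length.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return a `perm_test` with statistic `rho`.
#' @export
spearman_perm <- function(x, y, n_perm = 999L, seed = NULL,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  rx_c <- rx - mean(rx); ry_c <- ry - mean(ry)
  den <- sqrt(sum(rx_c^2) * sum(ry_c^2))
  if (den == 0)   # a constant input: correlation undefined, flagged NA
    return(perm_result("Spearman rho", NA_real_, NA_real_, n_perm, seed,
                       FALSE, extra = list(alternative = alternative)))
  obs <- sum(rx_c * ry_c) / den
  sims <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      sum(rx_c * sample(ry_c)) / den, numeric(1L))
  })
  p <- switch(alternative,
              two.sided = (1 + sum(abs(sims) >= abs(obs) - 1e-12)) / (1 + n_perm),
              greater = (1 + sum(sims >= obs - 1e-12)) / (1 + n_perm),
              less = (1 + sum(sims <= obs + 1e-12)) / (1 + n_perm))
  perm_result("Spearman rho", obs, p, n_perm, seed, FALSE,
              extra = list(alternative = alternative))
}
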