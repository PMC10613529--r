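# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals.

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracle_chao1 <- function(x) {
  s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_simpson_dominance <- function(x) sum((x / sum(x))^2)

oracle_cv <- function(x) sd(x) / mean(x)

oracle_zscore <- function(x) (x - mean(x)) / sd(x)

## edge indices on the path from a tip to the root of an ape tree
tip_root_edges <- function(tr, tip) {
  node <- match(tip, tr$tip.label)
  root <- length(tr$tip.label) + 1L
  edges <- integer(0)
  while (node != root) {
    e <- which(tr$edge[, 2L] == node)
    edges <- c(edges, e)
    node <- tr$edge[e, 1L]
  }
  edges
}

oracle_faith_pd <- function(tr, tips) {
  ed <- unique(unlist(lapply(tips, tip_root_edges, tr = tr)))
  sum(tr$edge.length[ed])
}

oracle_unifrac_pair <- function(tr, tips_a, tips_b) {
  ea <- unique(unlist(lapply(tips_a, tip_root_edges, tr = tr)))
  eb <- unique(unlist(lapply(tips_b, tip_root_edges, tr = tr)))
  uni <- union(ea, eb)
  shared <- intersect(ea, eb)
  sum(tr$edge.length[setdiff(uni, shared)]) / sum(tr$edge.length[uni])
}

## SIMPER contribution of every feature for one group pair, by direct
## enumeration of between-group sample pairs
oracle_simper_pair <- function(tab, groups, ga, gb) {
  p <- tab / rowSums(tab)
  A <- which(groups == ga); B <- which(groups == gb)
  contrib <- numeric(ncol(tab))
  for (a in A) for (b in B) {
    dif <- abs(p[a, ] - p[b, ])
    if (sum(dif) > 0) contrib <- contrib + dif / sum(dif)
  }
  setNames(contrib / (length(A) * length(B)), colnames(tab))
}

## all set partitions of n elements as membership vectors (Bell(n) rows)
set_partitions <- function(n) {
  parts <- list(1L)
  for (i in seq_len(n)[-1L]) {
    new <- vector("list", 0L)
    for (p in parts) {
      k <- max(p)
      for (b in seq_len(k + 1L)) new[[length(new) + 1L]] <- c(p, b)
    }
    parts <- new
  }
  do.call(rbind, parts)
}

## MCC of a membership vector against a logical "close" upper-triangle
oracle_partition_mcc <- function(memb, close_ut) {
  n <- length(memb)
  same <- outer(memb, memb, "==")[upper.tri(diag(n))]
  tp <- sum(same & close_ut); fp <- sum(same & !close_ut)
  fn <- sum(!same & close_ut); tn <- sum(!same & !close_ut)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

## best achievable MCC over all set partitions (vectorised over partitions)
oracle_best_mcc <- function(dmat, cutoff) {
  n <- nrow(dmat)
  P <- set_partitions(n)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  close <- dmat[upper.tri(dmat)] <= cutoff
  S <- sapply(seq_len(nrow(ut)), function(k) P[, ut[k, 1]] == P[, ut[k, 2]])
  tp <- S %*% close; fp <- S %*% (!close)
  fn <- (!S) %*% close; tn <- (!S) %*% (!close)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
  max(mcc)
}

## all permutations of 1..n (recursive; independent of the package's)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

oracle_anosim_R <- function(dmat, labels) {
  n <- nrow(dmat)
  rv <- rank(dmat[lower.tri(dmat)])
  same <- outer(labels, labels, "==")[lower.tri(dmat)]
  (mean(rv[!same]) - mean(rv[same])) / (n * (n - 1) / 4)
}

oracle_pseudo_F <- function(dmat, labels) {
  n <- nrow(dmat); d2 <- dmat^2
  ss_tot <- sum(d2[lower.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(labels)) {
    m <- labels == g
    ss_w <- ss_w + sum(d2[m, m][lower.tri(d2[m, m])]) / sum(m)
  }
  k <- length(unique(labels))
  ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
}

## random feature table fixture
random_table <- function(n_samples = 10L, n_features = 30L, lambda = 20,
                         prefix_s = "S", prefix_f = "F") {
  counts <- matrix(rpois(n_samples * n_features, lambda), n_samples,
                   n_features,
                   dimnames = list(paste0(prefix_s, seq_len(n_samples)),
                                   paste0(prefix_f, seq_len(n_features))))
  storage.mode(counts) <- "integer"
  counts
}

## random 8-sequence clustering instance with distances straddling the
## cutoff: 3 centroids of length 60, members mutated 0..6 positions
random_cluster_instance <- function(len = 60L) {
  bases <- c("A", "C", "G", "T")
  cents <- replicate(3, paste(sample(bases, len, TRUE), collapse = ""))
  seqs <- character(8L)
  for (i in 1:8) {
    cen <- strsplit(cents[sample.int(3L, 1L)], "")[[1L]]
    nm <- sample(0:6, 1L)
    if (nm > 0) {
      pos <- sample(len, nm)
      for (p in pos) cen[p] <- sample(setdiff(bases, cen[p]), 1L)
    }
    seqs[i] <- paste(cen, collapse = "")
  }
  names(seqs) <- paste0("q", 1:8)
  seqs
}
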