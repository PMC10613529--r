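# De-novo OTU clustering at 97% identity.  The optimiser below follows the
# OptiClust scheme: single-sequence reassignment that greedily maximises
# the Matthews correlation coefficient of the pair classification implied
# by the partition against the distance cutoff.

#' Pairwise sequence distances
#'
#' Distance = 1 - matches / aligned columns from a global alignment with
#' terminal gaps excluded; internal gap columns count as mismatches.  For
#' equal-length substitution-only inputs this reduces exactly to
#' Hamming distance / length, which is computed directly.
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @return a `dist` object over the sequence ids with values in \[0, 1\].
#' @export
pairwise_distance <- function(seqs) {
  validate_repseqs(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  n <- length(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    D <- hamming_matrix(seqs) / lens[1L]
  } else {
    D <- matrix(0, n, n)
    subst <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
    for (i in seq_len(n - 1L)) {
      pa <- Biostrings::pairwiseAlignment(
        rep(seqs[i], n - i), seqs[(i + 1L):n], type = "overlap",
        substitutionMatrix = subst, gapOpening = 0, gapExtension = 1)
      matches <- Biostrings::nmatch(pa)
      ## aligned columns of the overlap region (terminal gaps excluded)
      cols <- nchar(as.character(Biostrings::pattern(pa)))
      D[i, (i + 1L):n] <- 1 - matches / cols
      D[(i + 1L):n, i] <- D[i, (i + 1L):n]
    }
  }
  dimnames(D) <- list(names(seqs), names(seqs))
  stats::as.dist(D)
}

## MCC of the pair classification given confusion counts.
## tp: close pairs clustered together; w: pairs clustered together;
## p: close pairs overall; n: all pairs.
pair_mcc <- function(tp, w, p, n) {
  fp <- w - tp
  fn <- p - tp
  tn <- n - w - fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
}

#' MCC of an arbitrary partition against a distance cutoff
#'
#' @param d `dist` of pairwise distances.
#' @param membership integer/character vector of cluster labels, aligned
#'   with the `dist` labels.
#' @param cutoff distance threshold defining "close" pairs.
#' @return the Matthews correlation coefficient.
#' @export
partition_mcc <- function(d, membership, cutoff = 0.03) {
  dm <- as.matrix(d)
  n_seq <- nrow(dm)
  ut <- upper.tri(dm)
  close <- dm[ut] <= cutoff
  same <- outer(membership, membership, "==")[ut]
  pair_mcc(sum(close & same), sum(same), sum(close), sum(ut))
}

#' Cluster sequences into OTUs with OptiClust
#'
#' Starts from all-singleton clusters and sweeps sequences in
#' abundance-descending order (ties broken lexicographically by id),
#' moving each sequence to the cluster (or to a fresh singleton) that
#' maximises the MCC of the implied within/between-cutoff pair
#' classification; iterates until the MCC improves by less than `tol`
#' or `max_sweeps` sweeps.  Deterministic for a given input.
#'
#' OTU labels are `OTU-1`, `OTU-2`, ... ranked by total member abundance
#' (descending), so OTU-1 is the most abundant cluster.
#'
#' @param d `dist` of pairwise sequence distances with labels.
#' @param cutoff clustering threshold (0.03 = 97% identity).
#' @param abundance optional named vector of per-sequence total abundances
#'   used for the sweep order and the OTU ranking; equal abundances are
#'   assumed when absent.
#' @param max_sweeps,tol convergence controls.
#' @return an object of class `opticlust`: list with `map` (named
#'   character, asv id -> otu id), `mcc`, `n_otus`, `cutoff`, `sweeps`.
#' @export
opticlust <- function(d, cutoff = 0.03, abundance = NULL,
                      max_sweeps = 100L, tol = 1e-4) {
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0, 1)")
  dm <- as.matrix(validate_distance_matrix(d))
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(dm)))
  n_seq <- nrow(dm)
  if (is.null(abundance)) abundance <- setNames(rep(1, n_seq), ids)
  ab <- abundance[ids]
  ab[is.na(ab)] <- 0
  order_idx <- order(-ab, ids)

  close <- dm <= cutoff
  diag(close) <- FALSE
  n_pairs <- n_seq * (n_seq - 1) / 2
  p_close <- sum(close) / 2

  cl <- seq_len(n_seq)              # cluster label per sequence
  tp <- 0; w <- 0                   # running confusion counts
  mcc <- pair_mcc(tp, w, p_close, n_pairs)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    for (i in order_idx) {
      a <- cl[i]
      mx <- max(cl)
      sizes <- tabulate(cl, nbins = mx)
      ## close neighbours of i per cluster
      tp_by <- tabulate(cl[close[i, ]], nbins = mx)
      ## baseline with i removed from its cluster
      tp0 <- tp - tp_by[a]
      w0 <- w - (sizes[a] - 1)
      cand <- which(sizes > 0L)
      cand_tp <- tp0 + ifelse(cand == a, tp_by[a], tp_by[cand])
      cand_w <- w0 + ifelse(cand == a, sizes[a] - 1, sizes[cand])
      ## fresh singleton
      cand <- c(cand, 0L)
      cand_tp <- c(cand_tp, tp0)
      cand_w <- c(cand_w, w0)
      scores <- pair_mcc(cand_tp, cand_w, p_close, n_pairs)
      ## prefer staying put on ties, then the lowest cluster label
      stay <- which(cand == a)
      best <- if (scores[stay] >= max(scores) - 1e-15) stay else
        which.max(scores)
      target <- cand[best]
      if (target == 0L) target <- max(cl) + 1L
      if (target != a) {
        cl[i] <- target
        tp <- cand_tp[best]
        w <- cand_w[best]
      }
    }
    new_mcc <- pair_mcc(tp, w, p_close, n_pairs)
    if (new_mcc - mcc < tol || sweeps >= max_sweeps) { mcc <- new_mcc; break }
    mcc <- new_mcc
  }

  ## stable OTU labels ranked by total member abundance (desc), then by
  ## lexicographically smallest member id
  uc <- unique(cl)
  tot <- vapply(uc, function(c0) sum(ab[cl == c0]), numeric(1L))
  first <- vapply(uc, function(c0) min(ids[cl == c0]), character(1L))
  rank_order <- order(-tot, first)
  label <- setNames(paste0("OTU-", seq_along(uc)), uc[rank_order])
  map <- setNames(label[as.character(cl)], ids)
  structure(list(map = map, mcc = mcc, n_otus = length(uc),
                 cutoff = cutoff, sweeps = sweeps),
            class = "opticlust")
}

#' @export
print.opticlust <- function(x, ...) {
  cat("OptiClust partition: ", length(x$map), " sequences -> ", x$n_otus,
      " OTUs at cutoff ", x$cutoff, "\n", sep = "")
  cat("pair-classification MCC = ", format(x$mcc, digits = 6),
      " (", x$sweeps, " sweeps)\n", sep = "")
  invisible(x)
}

#' Collapse an ASV table to an OTU table
#'
#' OTU count in a sample is the sum of its member ASV counts, so per-sample
#' totals are conserved exactly.  Columns are ordered by total OTU
#' abundance (descending) to match the OTU-1-is-most-abundant convention.
#'
#' @param table ASV feature table (samples x ASVs).
#' @param map named character vector (or `opticlust` object) mapping every
#'   ASV id to its OTU id.
#' @return OTU feature table (samples x OTUs).
#' @export
collapse_table <- function(table, map) {
  if (inherits(map, "opticlust")) map <- map$map
  validate_feature_table(table)
  unmapped <- setdiff(colnames(table), names(map))
  if (length(unmapped))
    stop("feature id(s) absent from the OTU map: ",
         paste(unmapped, collapse = ", "))
  grp <- map[colnames(table)]
  out <- t(rowsum(t(table), group = grp))
  out <- out[, order(-colSums(out), colnames(out)), drop = FALSE]
  storage.mode(out) <- "integer"
  validate_feature_table(out)
  out
}
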