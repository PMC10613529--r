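# Rarefaction, alpha diversity, unweighted UniFrac and PCoA.

#' Rarefy a feature table to even depth
#'
#' Samples whose total is below `depth` are dropped (with a warning
#' naming them); every retained sample is subsampled without replacement
#' to exactly `depth` reads.
#'
#' @param table feature table (samples x features).
#' @param depth target depth (reads per sample).
#' @param seed RNG seed for the subsampling.
#' @return rarefied integer feature table.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  validate_feature_table(table)
  if (depth < 1) stop("rarefaction depth must be >= 1")
  totals <- rowSums(table)
  drop <- totals < depth
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[drop], collapse = ", "))
  keep <- table[!drop, , drop = FALSE]
  if (!nrow(keep)) stop("no sample reaches rarefaction depth ", depth)
  ## vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  ## non-count data); our input is validated integer counts, so muffle it
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(keep, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  out
}

#' Per-sample alpha diversity
#'
#' Computes observed richness, Shannon entropy (natural log, so that
#' `exp(shannon)` is the Hill number of order 1), Pielou evenness
#' (`shannon / ln(richness)`, `NA` for single-feature samples), Simpson
#' dominance (sum of squared proportions), bias-corrected Chao1
#' (`S + F1*(F1-1) / (2*(F2+1))`), and, when a rooted tree is supplied,
#' Faith phylogenetic diversity (total branch length connecting the root
#' to all observed tips).
#'
#' @param table feature table (samples x features), typically rarefied.
#' @param tree optional rooted `phylo` whose tips cover the table features.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  validate_feature_table(table)
  if (any(rowSums(table) == 0)) stop("empty sample(s) in table")
  p <- table / rowSums(table)
  shannon <- -rowSums(ifelse(p > 0, p * log(p), 0))
  richness <- rowSums(table > 0)
  pielou <- ifelse(richness > 1, shannon / log(richness), NA_real_)
  simpson_dominance <- rowSums(p^2)
  f1 <- rowSums(table == 1)
  f2 <- rowSums(table == 2)
  chao1 <- richness + f1 * (f1 - 1) / (2 * (f2 + 1))
  out <- data.frame(sample_id = rownames(table), richness = richness,
                    shannon = shannon, pielou = pielou,
                    simpson_dominance = simpson_dominance, chao1 = chao1,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    missing <- setdiff(colnames(table), tree$tip.label)
    if (length(missing))
      stop("feature(s) absent from tree: ", paste(missing, collapse = ", "))
    pd <- picante::pd(table[, tree$tip.label[tree$tip.label %in% colnames(table)],
                            drop = FALSE],
                      ape::keep.tip(tree, intersect(tree$tip.label, colnames(table))),
                      include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  out
}

#' Unweighted UniFrac distances
#'
#' Presence/absence phylogenetic beta diversity: the branch length unique
#' to one of the two samples divided by the total branch length covered by
#' either, where a tip is present when its count is >= 1.
#'
#' @param table feature table (samples x features).
#' @param tree rooted `phylo` containing every table feature as a tip.
#' @return a `dist` over samples.
#' @export
unweighted_unifrac <- function(table, tree) {
  validate_feature_table(table)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("feature(s) absent from tree: ", paste(missing, collapse = ", "))
  tr <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(table)))
  comm <- (table[, tr$tip.label, drop = FALSE] >= 1) * 1L
  d <- picante::unifrac(comm, tr)
  validate_distance_matrix(d)
}

#' Principal coordinate analysis
#'
#' Metric multidimensional scaling: eigen-decomposition of the
#' double-centred `-d^2/2` matrix.  Negative eigenvalues are reported but
#' excluded from the `proportion_explained` denominator (no correction is
#' applied unless `correction = "cailliez"`).
#'
#' @param d `dist` or symmetric matrix of sample distances.
#' @param correction `"none"` or `"cailliez"` (adds the constant that
#'   removes negative eigenvalues).
#' @return object of class `pcoa_ord`: list with `ids`, `coordinates`
#'   (samples x positive axes), `eigenvalues` (all, descending),
#'   `proportion_explained` (per retained axis).
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- validate_distance_matrix(d)
  n <- attr(d, "Size")
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  res <- suppressWarnings(
    cmdscale(d, k = n - 1L, eig = TRUE, add = correction == "cailliez"))
  eig <- res$eig
  pos <- which(eig > max(eig) * 1e-9 & eig > 0)
  coords <- res$points[, seq_along(pos), drop = FALSE]
  rownames(coords) <- ids
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(ids = ids, coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = eig[pos] / sum(eig[eig > 0])),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("PCoA of", length(x$ids), "samples;", ncol(x$coordinates),
      "positive axes\n")
  k <- min(3L, length(x$proportion_explained))
  cat("proportion explained:",
      paste(sprintf("%s %.1f%%", colnames(x$coordinates)[seq_len(k)],
                    100 * x$proportion_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
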