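# Per-OTU microdiversity, persistence and variability: the headline
# statistics.  Microdiversity is the effective number of ASVs in an OTU --
# exp(Shannon entropy) of the member-ASV abundances (Hill number of order
# one) -- so it runs from 1 (one dominant member) to the member count
# (all members equally abundant).

#' Per-OTU microdiversity (effective number of ASVs)
#'
#' Member-ASV counts are pooled across all samples, normalised within the
#' OTU, and the effective ASV number is `exp(-sum(q * log(q)))`.  With
#' `per_sample = TRUE` the alternative per-sample variant is returned
#' instead: the mean of per-sample exp-Shannon over the samples where the
#' OTU occurs.
#'
#' @param asv_table ASV feature table (samples x ASVs).
#' @param map named character vector (or `opticlust`) mapping ASV -> OTU.
#' @param per_sample use the per-sample variant.
#' @return named numeric vector, one microdiversity per OTU (`NA` for an
#'   OTU with zero total abundance).
#' @export
otu_microdiversity <- function(asv_table, map, per_sample = FALSE) {
  if (inherits(map, "opticlust")) map <- map$map
  validate_feature_table(asv_table)
  unmapped <- setdiff(colnames(asv_table), names(map))
  if (length(unmapped))
    stop("unmapped ASV id(s): ", paste(unmapped, collapse = ", "))
  grp <- map[colnames(asv_table)]
  otus <- unique(grp)
  expH <- function(x) {
    tot <- sum(x)
    if (tot == 0) return(NA_real_)
    q <- x[x > 0] / tot
    exp(-sum(q * log(q)))
  }
  out <- vapply(otus, function(o) {
    sub <- asv_table[, grp == o, drop = FALSE]
    if (!per_sample) return(expH(colSums(sub)))
    occ <- rowSums(sub) > 0
    if (!any(occ)) return(NA_real_)
    mean(apply(sub[occ, , drop = FALSE], 1L, expH))
  }, numeric(1L))
  setNames(out, otus)
}

#' Per-OTU persistence
#'
#' Fraction of samples in which the OTU has at least one count; computed
#' on the rarefied OTU table.
#'
#' @param otu_table OTU feature table (samples x OTUs).
#' @return named numeric vector in \[0, 1\].
#' @export
otu_persistence <- function(otu_table) {
  validate_feature_table(otu_table)
  if (!nrow(otu_table)) stop("table has zero samples")
  colMeans(otu_table >= 1)
}

#' Per-OTU variability (coefficient of variation)
#'
#' Standard deviation of the OTU's per-sample relative abundance divided
#' by its mean (zeros included; sample sd with n-1 denominator).  Using
#' relative abundance makes the CV independent of sequencing depth.
#'
#' @param otu_table OTU feature table (samples x OTUs), typically rarefied.
#' @return named numeric vector (`NA` when the mean abundance is zero).
#' @export
otu_variability <- function(otu_table) {
  validate_feature_table(otu_table)
  if (nrow(otu_table) < 2L) stop("need >= 2 samples for a CV")
  p <- otu_table / rowSums(otu_table)
  mu <- colMeans(p)
  s <- apply(p, 2L, sd)
  ifelse(mu == 0, NA_real_, s / mu)
}

#' Assemble per-OTU microdiversity records
#'
#' One row per OTU: member count, microdiversity, persistence,
#' variability, and the persistent flag (`persistence > 0.75` AND
#' `variability < 2`, both strict as printed).
#'
#' @param asv_table ASV feature table (rarefied).
#' @param map ASV -> OTU map (named character or `opticlust`).
#' @param otu_table optional pre-collapsed OTU table; computed with
#'   [collapse_table()] when absent.
#' @param persistence_min,variability_max thresholds for the persistent
#'   flag.
#' @return data.frame of class `microdiv_records` with columns `otu_id`,
#'   `n_asvs`, `microdiversity`, `persistence`, `variability`,
#'   `persistent`, `multi_asv` (n_asvs >= 2), `multi_effective`
#'   (microdiversity >= 2).
#' @export
microdiversity_records <- function(asv_table, map, otu_table = NULL,
                                   persistence_min = 0.75,
                                   variability_max = 2) {
  if (inherits(map, "opticlust")) map <- map$map
  if (is.null(otu_table)) otu_table <- collapse_table(asv_table, map)
  md <- otu_microdiversity(asv_table, map)
  pers <- otu_persistence(otu_table)
  vari <- otu_variability(otu_table)
  otus <- colnames(otu_table)
  n_asvs <- table(factor(map[colnames(asv_table)], levels = otus))
  rec <- data.frame(otu_id = otus,
                    n_asvs = as.integer(n_asvs[otus]),
                    microdiversity = as.numeric(md[otus]),
                    persistence = as.numeric(pers[otus]),
                    variability = as.numeric(vari[otus]),
                    row.names = NULL, stringsAsFactors = FALSE)
  rec <- classify_stability(rec, persistence_min, variability_max)
  rec
}

#' Flag persistent OTUs and the microdiversity groupings
#'
#' Applies the strict persistence/variability thresholds and emits both
#' candidate groupings of the microdiversity contrast: by constituent ASV
#' count (`multi_asv`: n_asvs >= 2) and by effective ASV number
#' (`multi_effective`: microdiversity >= 2).  Neither is silently
#' preferred; downstream tests state which they use.
#'
#' @param records data.frame with `n_asvs`, `microdiversity`,
#'   `persistence`, `variability`.
#' @param persistence_min,variability_max strict thresholds.
#' @return `records` with `persistent`, `multi_asv`, `multi_effective`
#'   columns, classed `microdiv_records`.
#' @export
classify_stability <- function(records, persistence_min = 0.75,
                               variability_max = 2) {
  records$persistent <- !is.na(records$variability) &
    records$persistence > persistence_min &
    records$variability < variability_max
  records$multi_asv <- records$n_asvs >= 2L
  records$multi_effective <- !is.na(records$microdiversity) &
    records$microdiversity >= 2
  class(records) <- unique(c("microdiv_records", class(records)))
  records
}

#' @export
print.microdiv_records <- function(x, ...) {
  cat("microdiversity records for", nrow(x), "OTUs:",
      sum(x$multi_asv), "multi-ASV,", sum(x$persistent), "persistent\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Microdiversity versus OTU stability
#'
#' Tests the headline pattern: OTUs with at least two (effective) ASVs are
#' more persistent and less variable than single-ASV OTUs (one-sided
#' Wilcoxon rank-sum tests), and persistence/variability trend with
#' microdiversity (Spearman correlations with permutation p-values).
#'
#' @param records a `microdiv_records` data.frame.
#' @param grouping `"n_asvs"` (constituent ASV count >= 2) or
#'   `"effective"` (microdiversity >= 2).
#' @param n_perm permutations for the Spearman p-values.
#' @param seed RNG seed.
#' @return list with `grouping`, `n_multi`, `n_single`,
#'   `persistence_test`, `variability_test` (Wilcoxon `perm_test`s) and
#'   `cor_persistence`, `cor_variability` (Spearman `perm_test`s).
#' @export
stability_vs_microdiversity <- function(records,
                                        grouping = c("n_asvs", "effective"),
                                        n_perm = 999L, seed = NULL) {
  grouping <- match.arg(grouping)
  ok <- !is.na(records$variability) & !is.na(records$microdiversity)
  rec <- records[ok, , drop = FALSE]
  multi <- if (grouping == "n_asvs") rec$multi_asv else rec$multi_effective
  if (sum(multi) < 2L || sum(!multi) < 2L)
    stop("need >= 2 OTUs in both the multi and single group")
  list(grouping = grouping,
       n_multi = sum(multi), n_single = sum(!multi),
       persistence_test = wilcoxon_ranksum(rec$persistence[multi],
                                           rec$persistence[!multi],
                                           alternative = "greater"),
       variability_test = wilcoxon_ranksum(rec$variability[multi],
                                           rec$variability[!multi],
                                           alternative = "less"),
       cor_persistence = spearman_perm(rec$microdiversity, rec$persistence,
                                       n_perm = n_perm,
                                       seed = if (is.null(seed)) NULL else
                                         derive_seed(seed, "cor_pers")),
       cor_variability = spearman_perm(rec$microdiversity, rec$variability,
                                       n_perm = n_perm,
                                       seed = if (is.null(seed)) NULL else
                                         derive_seed(seed, "cor_vari")))
}
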