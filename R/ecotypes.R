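# Habitat-preference profiles and ecotype-environment association.
# ASVs from the same OTU can behave as distinct ecotypes: one member
# enriched toward the root surface (TS), another toward bulk soil, with
# opposite responses to soil chemistry.

#' Per-ASV habitat-preference z-scores
#'
#' Each ASV's per-sample relative abundance is z-scored across all samples
#' (sample sd), so the profile of every ASV has mean 0 and sd 1 and rare
#' and abundant ASVs become comparable.  A compartment's preference is
#' positive when the mean z-score of its samples is above 0 (the ASV sits
#' above its own mean abundance there) and negative otherwise.  ASVs with
#' zero variance are flagged constant and receive no preference.
#'
#' @param asv_table ASV feature table (samples x ASVs).
#' @param metadata metadata with `sample_id` and `compartment` covering
#'   all table samples.
#' @param map optional ASV -> OTU map used to annotate profiles.
#' @return object of class `preference_profile`: list with `zscores`
#'   (samples x ASVs), `profile` (data.frame: `asv_id`, `otu_id`,
#'   `z_BS`, `z_LS`, `z_TS`, `pref_BS`, `pref_LS`, `pref_TS`,
#'   `constant`).
#' @export
habitat_zscores <- function(asv_table, metadata, map = NULL) {
  validate_feature_table(asv_table)
  validate_metadata(metadata)
  if (inherits(map, "opticlust")) map <- map$map
  miss <- setdiff(rownames(asv_table), metadata$sample_id)
  if (length(miss)) stop("sample(s) missing from metadata: ",
                         paste(miss, collapse = ", "))
  comp <- metadata$compartment[match(rownames(asv_table), metadata$sample_id)]
  p <- asv_table / rowSums(asv_table)
  mu <- colMeans(p)
  s <- apply(p, 2L, sd)
  constant <- s == 0
  z <- sweep(sweep(p, 2L, mu, "-"), 2L, ifelse(constant, NA, s), "/")
  zc <- sapply(compartment_levels, function(cc)
    colMeans(z[comp == cc, , drop = FALSE]))
  pref <- ifelse(is.na(zc), NA_character_,
                 ifelse(zc > 0, "positive", "negative"))
  profile <- data.frame(asv_id = colnames(asv_table),
                        otu_id = if (is.null(map)) NA_character_ else
                          unname(map[colnames(asv_table)]),
                        z_BS = zc[, "BS"], z_LS = zc[, "LS"], z_TS = zc[, "TS"],
                        pref_BS = pref[, "BS"], pref_LS = pref[, "LS"],
                        pref_TS = pref[, "TS"], constant = constant,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(zscores = z, profile = profile),
            class = "preference_profile")
}

#' @export
print.preference_profile <- function(x, ...) {
  cat("habitat-preference profiles for", nrow(x$profile), "ASVs (",
      sum(x$profile$constant), "constant )\n")
  print.data.frame(utils::head(x$profile, 8L), digits = 3)
  invisible(x)
}

#' Top SIMPER-contributing member ASVs of focal OTUs
#'
#' For each focal OTU, runs SIMPER at the ASV level restricted to that
#' OTU's member ASVs and returns the `k` members with the largest average
#' contribution (averaged over all group pairs); ties are broken by total
#' abundance (descending) then id.  OTUs with fewer than `k` members
#' return all members.
#'
#' @param asv_table ASV feature table.
#' @param groups group labels per sample (compartments).
#' @param map ASV -> OTU map.
#' @param focal_otus OTU ids to inspect.
#' @param k number of members to return per OTU.
#' @return named list: focal OTU id -> character vector of ASV ids.
#' @export
select_top_contributors <- function(asv_table, groups, map, focal_otus,
                                    k = 3L) {
  if (inherits(map, "opticlust")) map <- map$map
  validate_feature_table(asv_table)
  grp <- map[colnames(asv_table)]
  tot <- colSums(asv_table)
  out <- list()
  for (otu in focal_otus) {
    members <- colnames(asv_table)[!is.na(grp) & grp == otu]
    if (!length(members)) stop("OTU ", otu, " has no member ASV in the table")
    if (length(members) <= k) { out[[otu]] <- sort(members); next }
    sim <- simper_contrib(asv_table[, members, drop = FALSE], groups)
    avg <- rowMeans(sapply(sim, function(df)
      df$contribution[match(members, df$feature)]))
    ord <- order(-avg, -tot[members], members)
    out[[otu]] <- members[ord][seq_len(k)]
  }
  out
}

#' Ecotype-environment association
#'
#' Correlates each ASV's per-sample relative abundance with each soil
#' variable (Spearman by default; Pearson via `method`), with seeded
#' permutation p-values and Benjamini-Hochberg correction across the
#' whole ASV x variable grid.  An ASV-variable pair is classed a
#' `positive` ecotype when r > 0 and the (adjusted) p < `alpha`,
#' `negative` when r < 0 and p < `alpha`, else `none`.
#'
#' @param asv_table ASV feature table.
#' @param metadata metadata with the environment columns.
#' @param asv_subset ASVs to test; defaults to the constituent ASVs of
#'   persistent OTUs when `map` and `records` are supplied, otherwise to
#'   all ASVs.
#' @param map optional ASV -> OTU map (for the default subset).
#' @param records optional `microdiv_records` (for the default subset).
#' @param env_vars environment columns to use.
#' @param alpha significance level.
#' @param n_perm permutations per correlation.
#' @param seed RNG seed.
#' @param method `"spearman"` or `"pearson"`.
#' @param adjust `"BH"` or `"none"` (raw-p replication mode).
#' @return data.frame of class `ecotype_association`: `asv_id`,
#'   `env_variable`, `r`, `p_value`, `p_adjusted`, `ecotype_class`.
#' @export
env_association <- function(asv_table, metadata, asv_subset = NULL,
                            map = NULL, records = NULL,
                            env_vars = env_variables, alpha = 0.05,
                            n_perm = 999L, seed = NULL,
                            method = c("spearman", "pearson"),
                            adjust = c("BH", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  validate_feature_table(asv_table)
  validate_metadata(metadata)
  if (inherits(map, "opticlust")) map <- map$map
  if (is.null(asv_subset)) {
    if (!is.null(map) && !is.null(records)) {
      keep_otus <- records$otu_id[records$persistent]
      asv_subset <- names(map)[map %in% keep_otus]
      asv_subset <- intersect(colnames(asv_table), asv_subset)
    } else asv_subset <- colnames(asv_table)
  }
  missing_asv <- setdiff(asv_subset, colnames(asv_table))
  if (length(missing_asv)) stop("ASV(s) not in table: ",
                                paste(missing_asv, collapse = ", "))
  env_vars <- intersect(env_vars, names(metadata))
  if (!length(env_vars)) stop("no environment columns present in metadata")
  idx <- match(rownames(asv_table), metadata$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from metadata")
  p <- asv_table / rowSums(asv_table)
  rows <- list()
  for (asv in asv_subset) for (v in env_vars) {
    env <- metadata[[v]][idx]
    ok <- !is.na(env)
    if (sum(ok) < 3L) {
      message("skipping ", asv, " x ", v, ": <3 non-missing values")
      next
    }
    x <- p[ok, asv]
    if (sd(x) == 0 || sd(env[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        asv_id = asv, env_variable = v, r = NA_real_, p_value = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    pt <- if (method == "spearman")
      spearman_perm(x, env[ok], n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else
                      derive_seed(seed, paste0(asv, ":", v)))
    else pearson_perm(x, env[ok], n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else
                        derive_seed(seed, paste0(asv, ":", v)))
    rows[[length(rows) + 1L]] <- data.frame(
      asv_id = asv, env_variable = v, r = pt$statistic,
      p_value = pt$p_value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(asv_id = character(0), env_variable = character(0),
               r = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else
    out$p_value
  pv <- out$p_adjusted
  out$ecotype_class <- ifelse(is.na(out$r) | pv >= alpha, "none",
                              ifelse(out$r > 0, "positive", "negative"))
  class(out) <- c("ecotype_association", "data.frame")
  out
}

## Pearson analogue of spearman_perm
pearson_perm <- function(x, y, n_perm = 999L, seed = NULL) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  obs <- sum(xc * yc) / den
  sims <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    sum(xc * sample(yc)) / den, numeric(1L)))
  perm_result("Pearson r", obs,
              (1 + sum(abs(sims) >= abs(obs) - 1e-12)) / (1 + n_perm),
              n_perm, seed, FALSE,
              extra = list(alternative = "two.sided"))
}
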