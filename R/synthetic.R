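# Synthetic rhizosphere-community generator.  Every downstream stage of the
# pipeline is validated against communities produced here, where the
# ASV->OTU partition, the habitat preference of every ASV and the soil
# chemistry are all known by construction.

#' Build a simulation scenario configuration
#'
#' Describes a synthetic amplicon survey: `n_otus` OTU centroids, each with
#' 1..k member ASVs obtained by substitution-only mutation, sampled across
#' three soil compartments (BS bulk, LS loosely bound, TS tightly bound)
#' with `replicates_per_compartment` replicates each, at a fixed read
#' `depth` under Dirichlet-multinomial noise.
#'
#' Per-member substitution counts are capped at
#' `floor(within_otu_divergence * seq_length / 2)` so that *pairwise*
#' within-OTU divergence never exceeds `within_otu_divergence`, keeping the
#' true partition recoverable at the 97% clustering threshold.
#'
#' @param n_otus number of OTUs.
#' @param asvs_per_otu either a single integer (every OTU has that many
#'   member ASVs) or a probability vector over 1..k_max member counts.
#' @param seq_length representative-sequence length (bp).
#' @param within_otu_divergence maximum within-OTU pairwise divergence,
#'   in (0, 0.03].
#' @param between_otu_divergence minimum divergence between OTU centroids.
#' @param replicates_per_compartment replicates per soil compartment.
#' @param depth reads per sample.
#' @param niche_model list: `type` is `"complementary"` (singleton OTUs are
#'   compartment specialists; members of multi-ASV OTUs are complementary
#'   specialists so the OTU as a whole is a generalist), `"none"` (all
#'   weights equal; null model) or `"matrix"` with `weights` an ASV x 3
#'   matrix; `leak` is the relative weight a specialist retains in its
#'   non-preferred compartments.
#' @param overdispersion Dirichlet concentration parameter (larger = closer
#'   to multinomial).
#' @param env_model named list of `c(mean, sd)` per soil variable
#'   (`soc`, `ph`, `no3_n`, `nh4_n`, `tn`) giving the BS baseline.
#' @param env_shift named list of per-variable additive shifts applied to
#'   the TS compartment (LS receives half the shift), planting the
#'   environment signal that the ecotype analysis is meant to recover.
#' @param base_abundance_sdlog log-sd of the lognormal per-ASV baseline
#'   abundances.
#' @param env_coupling list with `strength`: the first two members of the
#'   first multi-ASV OTU become a planted ecotype pair whose niche weight
#'   is multiplied by `exp(+/- strength * z_SOC)` per sample (opposite
#'   signs), i.e. their abundance responds directly and oppositely to the
#'   soil-carbon draw; `strength = 0` disables the plant.  The pair is
#'   recorded in the ground truth as `soc_coupled`.
#' @param seed integer RNG seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_otus = 50L,
                            asvs_per_otu = c(0.5, 0.25, 0.15, 0.10),
                            seq_length = 250L,
                            within_otu_divergence = 0.02,
                            between_otu_divergence = 0.10,
                            replicates_per_compartment = 6L,
                            depth = 12000L,
                            niche_model = list(type = "complementary", leak = 0.02),
                            overdispersion = 50,
                            env_model = list(soc = c(7.97, 0.31),
                                             ph = c(8.36, 0.03),
                                             no3_n = c(15.2, 1.5),
                                             nh4_n = c(4.6, 0.8),
                                             tn = c(0.83, 0.05)),
                            env_shift = list(soc = 1.2, ph = -0.12,
                                             no3_n = 4.5, nh4_n = 1.8,
                                             tn = 0.10),
                            base_abundance_sdlog = 1,
                            env_coupling = list(strength = 1),
                            seed = 1L) {
  cfg <- list(n_otus = as.integer(n_otus), asvs_per_otu = asvs_per_otu,
              seq_length = as.integer(seq_length),
              within_otu_divergence = within_otu_divergence,
              between_otu_divergence = between_otu_divergence,
              compartments = compartment_levels,
              replicates_per_compartment = as.integer(replicates_per_compartment),
              depth = as.integer(depth), niche_model = niche_model,
              overdispersion = overdispersion, env_model = env_model,
              env_shift = env_shift,
              base_abundance_sdlog = base_abundance_sdlog,
              env_coupling = env_coupling,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
  cfg
}

#' @rdname scenario_config
#' @param config a `scenario_config`.
#' @export
validate_scenario <- function(config) {
  with(config, {
    if (n_otus < 1L) stop("n_otus must be >= 1")
    if (seq_length < 10L) stop("seq_length too short")
    if (!(within_otu_divergence > 0 && within_otu_divergence <= 0.03))
      stop("within_otu_divergence must lie in (0, 0.03]")
    if (between_otu_divergence < 0.10)
      stop("between_otu_divergence must be >= 0.10")
    ## at most 3/4 of positions can differ between two random DNA strings
    if (between_otu_divergence > 0.75)
      stop("between_otu_divergence unattainable for random DNA centroids")
    if (depth < 1L) stop("depth must be >= 1")
    if (replicates_per_compartment < 1L) stop("replicates_per_compartment must be >= 1")
    if (overdispersion <= 0) stop("overdispersion must be positive")
    if (is.numeric(asvs_per_otu) && length(asvs_per_otu) == 1L &&
        asvs_per_otu < 1) stop("asvs_per_otu must be >= 1")
  })
  invisible(config)
}

#' The default study-like scenario
#'
#' Three soil compartments with six replicates each, 50 OTUs mixing
#' singletons and multi-ASV OTUs, complementary habitat niches inside
#' multi-ASV OTUs (one member preferring tightly bound soil, another the
#' bulk/loosely-bound side), and soil chemistry drawn per compartment from
#' the field-site baselines (SOC 7.97 +/- 0.31 g/kg, pH 8.36 +/- 0.03,
#' TN 0.83 +/- 0.05 g/kg) with a planted enrichment of SOC and mineral N
#' in the tightly bound compartment.
#'
#' @param seed integer RNG seed.
#' @return a `scenario_config`.
#' @export
paper_like_scenario <- function(seed = 1L) {
  scenario_config(seed = seed)
}

draw_asv_counts <- function(config) {
  spec <- config$asvs_per_otu
  if (length(spec) == 1L) rep(as.integer(spec), config$n_otus)
  else sample(seq_along(spec), config$n_otus, replace = TRUE, prob = spec)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

mutate_seq <- function(seq, n_sub) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate representative sequences, ground truth and a tree
#'
#' OTU centroids are i.i.d. random DNA; member ASVs are substitution-only
#' mutants of their centroid (no indels), so sequence identity equals
#' 1 - Hamming/length and the true partition is unambiguous.  The
#' phylogeny is neighbour-joining on pairwise Hamming distances,
#' midpoint-rooted.
#'
#' @param config a `scenario_config`.
#' @return list with `seqs` (named character), `truth` (list with
#'   `true_otu_map`, `true_preference`, `base_abundance`), `tree` (`phylo`).
#' @export
generate_sequences <- function(config) {
  validate_scenario(config)
  with_seed(config$seed, {
    L <- config$seq_length
    max_sub <- floor(config$within_otu_divergence * L / 2)
    if (max_sub < 1L)
      stop("infeasible config: within_otu_divergence * seq_length / 2 < 1 substitution")
    k <- draw_asv_counts(config)
    ## centroids; reject rare too-close pairs
    for (attempt in 1:20) {
      cent <- random_dna(config$n_otus, L)
      if (config$n_otus == 1L) break
      dmin <- min(hamming_matrix(cent)[upper.tri(diag(config$n_otus))]) / L
      if (dmin >= config$between_otu_divergence) break
      if (attempt == 20)
        stop("infeasible config: cannot achieve between_otu_divergence ",
             config$between_otu_divergence, " at seq_length ", L)
    }
    seqs <- character(0); otu_of <- character(0)
    for (i in seq_len(config$n_otus)) {
      otu_id <- paste0("sOTU", i)
      members <- cent[i]
      if (k[i] > 1L) {
        for (j in 2:k[i]) {
          repeat {
            m <- mutate_seq(cent[i], sample.int(max_sub, 1L))
            if (!m %in% members) break
          }
          members <- c(members, m)
        }
      }
      seqs <- c(seqs, members)
      otu_of <- c(otu_of, rep(otu_id, k[i]))
    }
    names(seqs) <- sprintf("ASV%03d", seq_along(seqs))
    true_otu_map <- setNames(otu_of, names(seqs))
    true_pref <- niche_weights(config, true_otu_map)
    ## planted SOC-coupled ecotype pair: the first two members of the first
    ## multi-ASV OTU respond directly (and oppositely) to the per-sample
    ## SOC draw instead of to the compartment label
    soc_coupled <- NULL
    strength <- config$env_coupling$strength %||% 0
    if (strength > 0 && !identical(config$niche_model$type, "none")) {
      multi <- which(k >= 2L)
      if (length(multi)) {
        members <- names(true_otu_map)[true_otu_map ==
                                         paste0("sOTU", multi[1L])]
        soc_coupled <- c(pos = members[1L], neg = members[2L])
        true_pref[members[1:2], ] <- 1   # generalists; env drives them
      }
    }
    base <- setNames(rlnorm(length(seqs), 0, config$base_abundance_sdlog),
                     names(seqs))
    tree <- njtree_from_seqs(seqs)
    truth <- list(true_otu_map = true_otu_map, true_preference = true_pref,
                  base_abundance = base, soc_coupled = soc_coupled)
    list(seqs = seqs, truth = truth, tree = tree)
  })
}

## per-ASV compartment weights under the configured niche model
niche_weights <- function(config, true_otu_map) {
  asv_ids <- names(true_otu_map)
  nm <- config$niche_model
  if (identical(nm$type, "none")) {
    w <- matrix(1, length(asv_ids), 3L,
                dimnames = list(asv_ids, compartment_levels))
    return(w)
  }
  if (identical(nm$type, "matrix")) {
    w <- nm$weights[asv_ids, compartment_levels, drop = FALSE]
    return(w)
  }
  leak <- nm$leak %||% 0.1
  w <- matrix(leak, length(asv_ids), 3L,
              dimnames = list(asv_ids, compartment_levels))
  for (otu in unique(true_otu_map)) {
    members <- asv_ids[true_otu_map == otu]
    ## complementary specialists: cycle the preferred compartment through
    ## the members, starting from a random compartment
    start <- sample.int(3L, 1L)
    for (j in seq_along(members)) {
      pref <- (start + j - 2L) %% 3L + 1L
      w[members[j], pref] <- 1
    }
  }
  w
}

hamming_matrix <- function(seqs) {
  n <- length(seqs)
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    mism <- rowSums(M[rest, , drop = FALSE] !=
                      matrix(M[i, ], length(rest), ncol(M), byrow = TRUE))
    D[i, rest] <- mism
    D[rest, i] <- mism
  }
  D
}

njtree_from_seqs <- function(seqs) {
  n <- length(seqs)
  if (n < 3L) stop("need >= 3 sequences to build a tree")
  L <- nchar(seqs[[1L]])
  d <- hamming_matrix(seqs) / L
  dimnames(d) <- list(names(seqs), names(seqs))
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  phangorn::midpoint(tr)
}

#' Generate a count table and sample metadata
#'
#' Expected relative abundance of ASV i in a sample from compartment c is
#' proportional to `base_abundance[i] * niche_weight[i, c]`; counts are
#' Dirichlet-multinomial at the configured depth and concentration, so
#' every sample's counts sum exactly to `depth`.  Soil chemistry is drawn
#' per compartment from the configured normals, with the TS shift applied
#' in full and the LS shift at half strength.
#'
#' @param config a `scenario_config`.
#' @param truth ground truth from [generate_sequences()].
#' @return list with `table` (samples x ASVs integer matrix) and
#'   `metadata` (data.frame); `truth` is returned augmented with
#'   `true_env`.
#' @export
generate_counts <- function(config, truth) {
  validate_scenario(config)
  with_seed(derive_seed(config$seed, "counts"), {
    asv_ids <- names(truth$true_otu_map)
    reps <- config$replicates_per_compartment
    comp <- rep(compartment_levels, each = reps)
    sample_ids <- paste0(comp, rep(seq_len(reps), times = 3L))
    n <- length(sample_ids)
    counts <- matrix(0L, n, length(asv_ids),
                     dimnames = list(sample_ids, asv_ids))
    ## environment first: the SOC-coupled ecotype pair needs the draws
    shift_frac0 <- c(BS = 0, LS = 0.5, TS = 1)
    env <- list()
    for (v in names(config$env_model)) {
      mu <- config$env_model[[v]][1L] +
        shift_frac0[comp] * (config$env_shift[[v]] %||% 0)
      env[[v]] <- rnorm(n, mu, config$env_model[[v]][2L])
    }
    strength <- config$env_coupling$strength %||% 0
    z_soc <- if (!is.null(env$soc) && sd(env$soc) > 0)
      as.vector(scale(env$soc)) else rep(0, n)
    for (s in seq_len(n)) {
      w <- truth$true_preference[, comp[s]]
      if (!is.null(truth$soc_coupled) && strength > 0) {
        w[truth$soc_coupled["pos"]] <-
          w[truth$soc_coupled["pos"]] * exp(strength * z_soc[s])
        w[truth$soc_coupled["neg"]] <-
          w[truth$soc_coupled["neg"]] * exp(-strength * z_soc[s])
      }
      p <- truth$base_abundance * w
      p <- p / sum(p)
      a <- rgamma(length(p), shape = config$overdispersion * length(p) * p)
      a <- a / sum(a)
      counts[s, ] <- rmultinom(1L, config$depth, a)[, 1L]
    }
    md <- data.frame(sample_id = sample_ids, compartment = comp,
                     stringsAsFactors = FALSE)
    for (v in names(config$env_model)) md[[v]] <- env[[v]]
    md$ph <- pmin(pmax(md$ph, 0), 14)
    truth$true_env <- md
    list(table = counts, metadata = md, truth = truth)
  })
}

#' Simulate a full synthetic community
#'
#' Convenience wrapper chaining [generate_sequences()] and
#' [generate_counts()].
#'
#' @param config a `scenario_config`.
#' @return list with `table`, `seqs`, `tree`, `metadata`, `truth`.
#' @export
simulate_community <- function(config = paper_like_scenario()) {
  gs <- generate_sequences(config)
  gc <- generate_counts(config, gs$truth)
  list(table = gc$table, seqs = gs$seqs, tree = gs$tree,
       metadata = gc$metadata, truth = gc$truth, config = config)
}

#' Write a simulated community to disk
#'
#' Writes `table.tsv`, `seqs.fasta`, `tree.nwk`, `metadata.tsv` and
#' `truth.json` into `dir`.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$config$seed
  write_feature_table(sim$table, file.path(dir, "table.tsv"), seed = seed)
  write_fasta(sim$seqs, file.path(dir, "seqs.fasta"))
  write_tree(sim$tree, file.path(dir, "tree.nwk"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"), seed = seed)
  truth <- sim$truth
  truth$true_preference <- as.data.frame(truth$true_preference)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
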