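# End-to-end orchestration: simulate (or load) -> cluster -> rarefy ->
# diversity -> ordination concordance -> community stats -> microdiversity
# -> ecotypes, with one master seed and per-stage derived seeds.

#' Build a pipeline configuration
#'
#' Either `scenario` (a [scenario_config()] to simulate) or `input` (a
#' named list of paths: `table`, `seqs`, `tree`, `metadata`) must be
#' given.
#'
#' @param scenario optional `scenario_config`.
#' @param input optional list of input file paths.
#' @param depth rarefaction depth (11000 mirrors a 16S survey; use 17000
#'   for an ITS-like survey).
#' @param cutoff OTU clustering cutoff (0.03 = 97% identity).
#' @param n_perm permutations for every permutation test.
#' @param alpha significance level.
#' @param seed master seed; per-stage seeds are derived from it by stage
#'   name, so stage-level reruns are stable.
#' @param output_dir optional directory for on-disk outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, input = NULL, depth = 11000L,
                            cutoff = 0.03, n_perm = 999L, alpha = 0.05,
                            seed = 1L, output_dir = NULL) {
  if (is.null(scenario) && is.null(input))
    stop("either a simulation scenario or input paths must be supplied")
  structure(list(scenario = scenario, input = input,
                 depth = as.integer(depth), cutoff = cutoff,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

otu_presence_on_tips <- function(otu_table, map, asv_ids) {
  pres <- (otu_table >= 1) * 1L
  out <- pres[, map[asv_ids], drop = FALSE]
  colnames(out) <- asv_ids
  storage.mode(out) <- "integer"
  out
}

#' Unweighted UniFrac at the OTU level
#'
#' Uses the ASV tree with OTU abundances assigned to member tips: a tip is
#' present in a sample when its parent OTU is present, and distances are
#' computed on the ASV phylogeny (no OTU tree is re-inferred).
#'
#' @param otu_table OTU feature table.
#' @param map ASV -> OTU map.
#' @param tree rooted ASV `phylo`.
#' @return a `dist` over samples.
#' @export
otu_unifrac <- function(otu_table, map, tree) {
  if (inherits(map, "opticlust")) map <- map$map
  asv_ids <- intersect(tree$tip.label, names(map))
  unweighted_unifrac(otu_presence_on_tips(otu_table, map, asv_ids), tree)
}

run_stage <- function(report, name, fun) {
  if (any(!vapply(report$stages, function(s) isTRUE(s$ok), logical(1L)))) {
    report$stages[[name]] <- list(ok = FALSE, skipped = TRUE)
    return(report)
  }
  res <- tryCatch(list(ok = TRUE, value = fun()),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  report$stages[[name]] <- res
  report
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a simulated or loaded
#' community and assembles a machine-readable report: alpha diversity
#' with Duncan letters per compartment, unweighted-UniFrac PCoAs at ASV
#' and OTU level with their Procrustes and Mantel concordance, ANOSIM and
#' PERMANOVA by compartment, SIMPER top contributors, per-OTU
#' microdiversity records, microdiversity-stability tests, habitat
#' z-scores and ecotype-environment associations.  A failed stage is
#' recorded and everything downstream is skipped.
#'
#' @param config a [pipeline_config()].
#' @return object of class `microdiv_report` (nested list).  When
#'   `config$output_dir` is set, `report.json`, `microdiv.tsv` and
#'   `preferences.tsv` are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(version = pkg_version_string(), seed = seed,
                 depth = config$depth, cutoff = config$cutoff,
                 n_perm = config$n_perm, alpha = config$alpha,
                 stages = list())
  env <- new.env()

  report <- run_stage(report, "input", function() {
    if (!is.null(config$scenario)) {
      sim <- simulate_community(config$scenario)
    } else {
      sim <- list(table = read_feature_table(config$input$table),
                  seqs = read_fasta(config$input$seqs),
                  tree = read_tree(config$input$tree),
                  metadata = read_metadata(config$input$metadata),
                  truth = NULL)
    }
    cross_validate(sim$table, tree = sim$tree, seqs = sim$seqs,
                   metadata = sim$metadata)
    env$sim <- sim
    list(n_samples = nrow(sim$table), n_asvs = ncol(sim$table),
         simulated = !is.null(config$scenario))
  })

  report <- run_stage(report, "cluster", function() {
    sim <- env$sim
    d <- pairwise_distance(sim$seqs)
    cl <- opticlust(d, cutoff = config$cutoff,
                    abundance = colSums(sim$table))
    env$cl <- cl
    list(n_otus = cl$n_otus, mcc = cl$mcc, sweeps = cl$sweeps)
  })

  report <- run_stage(report, "rarefy", function() {
    sim <- env$sim
    env$asv_rare <- rarefy(sim$table, config$depth,
                           seed = derive_seed(seed, "rarefy"))
    env$otu_rare <- collapse_table(env$asv_rare, env$cl)
    env$md <- sim$metadata[match(rownames(env$asv_rare),
                                 sim$metadata$sample_id), , drop = FALSE]
    list(retained_samples = nrow(env$asv_rare), depth = config$depth)
  })

  report <- run_stage(report, "alpha", function() {
    a <- alpha_diversity(env$asv_rare, tree = env$sim$tree)
    comp <- env$md$compartment
    letters <- lapply(setNames(nm = c("shannon", "chao1", "pielou",
                                      "simpson_dominance", "faith_pd")),
                      function(mt) {
                        v <- a[[mt]]
                        ok <- !is.na(v)
                        as.data.frame(anova_duncan(v[ok], comp[ok],
                                                   alpha = config$alpha))
                      })
    env$alpha <- a
    list(table = a, duncan = letters)
  })

  report <- run_stage(report, "beta", function() {
    d_asv <- unweighted_unifrac(env$asv_rare, env$sim$tree)
    d_otu <- otu_unifrac(env$otu_rare, env$cl, env$sim$tree)
    env$d_asv <- d_asv; env$d_otu <- d_otu
    env$ord_asv <- pcoa(d_asv); env$ord_otu <- pcoa(d_otu)
    list(asv_prop_explained = env$ord_asv$proportion_explained[1:2],
         otu_prop_explained = env$ord_otu$proportion_explained[1:2])
  })

  report <- run_stage(report, "concordance", function() {
    pro <- procrustes_test(env$ord_otu, env$ord_asv, k = 2L,
                           n_perm = config$n_perm,
                           seed = derive_seed(seed, "procrustes"))
    man <- mantel_test(env$d_otu, env$d_asv, n_perm = config$n_perm,
                       seed = derive_seed(seed, "mantel"))
    list(procrustes = unclass(pro), mantel = unclass(man))
  })

  report <- run_stage(report, "group_tests", function() {
    comp <- env$md$compartment
    lapply(list(asv = env$d_asv, otu = env$d_otu), function(d)
      list(anosim = unclass(anosim(d, comp, n_perm = config$n_perm,
                                   seed = derive_seed(seed, "anosim"))),
           permanova = unclass(permanova(d, comp, n_perm = config$n_perm,
                                         seed = derive_seed(seed, "adonis")))))
  })

  report <- run_stage(report, "simper", function() {
    comp <- env$md$compartment
    sim_otu <- simper_contrib(env$otu_rare, comp)
    avg <- rowMeans(sapply(sim_otu, function(df)
      df$contribution[match(colnames(env$otu_rare), df$feature)]))
    focal <- colnames(env$otu_rare)[order(-avg)][seq_len(min(3L, ncol(env$otu_rare)))]
    env$focal <- focal
    top_asvs <- select_top_contributors(env$asv_rare, comp, env$cl,
                                        focal, k = 3L)
    list(focal_otus = focal, top_member_asvs = top_asvs,
         otu_contributions = lapply(sim_otu, utils::head, 10L))
  })

  report <- run_stage(report, "microdiversity", function() {
    rec <- microdiversity_records(env$asv_rare, env$cl,
                                  otu_table = env$otu_rare)
    env$records <- rec
    tests <- lapply(setNames(nm = c("n_asvs", "effective")), function(gr)
      tryCatch({
        st <- stability_vs_microdiversity(rec, grouping = gr,
                                          n_perm = config$n_perm,
                                          seed = derive_seed(seed, gr))
        lapply(st, function(x) if (inherits(x, "perm_test")) unclass(x) else x)
      }, error = function(e) list(error = conditionMessage(e))))
    list(records = as.data.frame(rec), stability = tests)
  })

  report <- run_stage(report, "ecotypes", function() {
    prof <- habitat_zscores(env$asv_rare, env$md, map = env$cl)
    assoc <- env_association(env$asv_rare, env$md, map = env$cl,
                             records = env$records, alpha = config$alpha,
                             n_perm = config$n_perm,
                             seed = derive_seed(seed, "ecotypes"))
    env$profile <- prof
    list(preferences = prof$profile, associations = as.data.frame(assoc))
  })

  report$ok <- all(vapply(report$stages, function(s) isTRUE(s$ok), logical(1L)))
  class(report) <- "microdiv_report"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$output_dir, "report.json"))
    if (!is.null(env$records))
      utils::write.table(as.data.frame(env$records),
                         file.path(config$output_dir, "microdiv.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(env$profile))
      utils::write.table(env$profile$profile,
                         file.path(config$output_dir, "preferences.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic (no timestamps), so identical runs give byte-identical
#' files.
#'
#' @param report a `microdiv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.microdiv_report <- function(x, ...) {
  cat("microdivr pipeline report (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    status <- if (isTRUE(s$ok)) "ok" else if (isTRUE(s$skipped)) "skipped"
              else paste("FAILED:", s$error)
    cat(sprintf("  %-14s %s\n", nm, status))
  }
  invisible(x)
}
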