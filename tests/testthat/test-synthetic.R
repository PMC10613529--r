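test_that("generated members stay within divergence bounds of their OTU", {
  cfg <- scenario_config(n_otus = 2L, asvs_per_otu = 2L, seq_length = 100L,
                         within_otu_divergence = 0.02, seed = 42L)
  gs <- generate_sequences(cfg)
  expect_length(gs$seqs, 4L)
  ham <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  map <- gs$truth$true_otu_map
  for (otu in unique(map)) {
    members <- gs$seqs[names(map)[map == otu]]
    ## pairwise identity within OTU >= 0.98
    for (i in seq_along(members)) for (j in seq_along(members))
      expect_lte(ham(members[[i]], members[[j]]), 2)
  }
  ## between-OTU divergence >= 0.10
  a <- gs$seqs[names(map)[map == unique(map)[1]]]
  b <- gs$seqs[names(map)[map == unique(map)[2]]]
  for (x in a) for (y in b) expect_gte(ham(x, y) / 100, 0.10)
})

test_that("identical config and seed give byte-identical artifacts", {
  cfg <- scenario_config(n_otus = 5L, seq_length = 100L, depth = 500L,
                         seed = 9L)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$seqs, f1); write_fasta(s2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every sample's counts sum exactly to the configured depth", {
  cfg <- scenario_config(n_otus = 8L, seq_length = 100L, depth = 1234L,
                         seed = 3L)
  sim <- simulate_community(cfg)
  expect_true(all(rowSums(sim$table) == 1234L))
  expect_identical(nrow(sim$table), 18L)  # 3 compartments x 6 replicates
})

test_that("niche weights steer expected compartment abundances", {
  ## ASV with weights (BS 1, LS 1, TS ~0) must average lower in TS
  w <- matrix(1, 4, 3, dimnames = list(sprintf("ASV%03d", 1:4),
                                       c("BS", "LS", "TS")))
  w["ASV001", "TS"] <- 1e-6
  cfg <- scenario_config(n_otus = 4L, asvs_per_otu = 1L, seq_length = 100L,
                         depth = 2000L, replicates_per_compartment = 7L,
                         niche_model = list(type = "matrix", weights = w),
                         seed = 21L)
  means <- sapply(1:20, function(k) {
    cfg$seed <- 21L + k
    sim <- simulate_community(cfg)
    p <- sim$table / rowSums(sim$table)
    comp <- sim$metadata$compartment
    c(bs = mean(p[comp == "BS", "ASV001"]),
      ts = mean(p[comp == "TS", "ASV001"]))
  })
  expect_lt(mean(means["ts", ]), mean(means["bs", ]))
})

test_that("huge Dirichlet concentration converges to multinomial draws", {
  cfg <- scenario_config(n_otus = 3L, asvs_per_otu = 1L, seq_length = 100L,
                         depth = 5000L, niche_model = list(type = "none"),
                         overdispersion = 1e6, seed = 5L)
  gs <- generate_sequences(cfg)
  p <- gs$truth$base_abundance / sum(gs$truth$base_abundance)
  sims <- sapply(1:40, function(k) {
    cfg2 <- cfg; cfg2$seed <- 100L + k
    generate_counts(cfg2, gs$truth)$table[1L, ]
  })
  ## per-feature variance ratio vs the multinomial oracle near 1
  v_obs <- apply(sims, 1L, var)
  v_mult <- 5000 * p * (1 - p)
  expect_lt(max(abs(v_obs / v_mult - 1)), 0.75)
  expect_equal(unname(rowMeans(sims) / 5000), unname(p), tolerance = 0.02)
})

test_that("the default scenario matches the study design constants", {
  cfg <- paper_like_scenario()
  expect_equal(cfg$env_model$soc, c(7.97, 0.31))
  expect_equal(cfg$env_model$ph[1], 8.36)
  expect_equal(cfg$env_model$tn, c(0.83, 0.05))
  expect_identical(cfg$replicates_per_compartment, 6L)
  expect_identical(cfg$compartments, c("BS", "LS", "TS"))
  expect_silent(validate_scenario(cfg))
  ## multi-ASV OTUs get complementary member niches
  gs <- generate_sequences(scenario_config(n_otus = 6L, asvs_per_otu = 3L,
                                           seq_length = 100L, seed = 2L))
  w <- gs$truth$true_preference
  map <- gs$truth$true_otu_map
  ## skip the planted SOC-coupled pair's OTU: those members are generalists
  coupled_otu <- unique(map[gs$truth$soc_coupled])
  for (otu in setdiff(unique(map), coupled_otu)) {
    members <- names(map)[map == otu]
    pref <- apply(w[members, , drop = FALSE], 1L, which.max)
    expect_identical(sort(unname(unique(pref))), sort(unname(pref)))  # distinct
  }
  ## and the coupled pair is recorded and lives in one OTU
  expect_length(gs$truth$soc_coupled, 2L)
  expect_length(coupled_otu, 1L)
})

test_that("infeasible configs are rejected", {
  expect_error(scenario_config(within_otu_divergence = 0.05), "0, 0.03")
  expect_error(scenario_config(between_otu_divergence = 0.05), ">= 0.10")
  expect_error(scenario_config(depth = 0L), "depth")
  expect_error(generate_sequences(scenario_config(seq_length = 40L,
                                                  within_otu_divergence = 0.01)),
               "infeasible")
})
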