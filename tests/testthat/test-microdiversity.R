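two_otu_fixture <- function() {
  tab <- matrix(c(3L, 1L, 4L, 0L,
                  0L, 0L, 2L, 2L), 2, 4, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("a", "b", "c", "d")))
  map <- c(a = "OTU-1", b = "OTU-1", c = "OTU-2", d = "OTU-2")
  list(tab = tab, map = map)
}

test_that("microdiversity is the exponential Shannon of pooled members", {
  fx <- two_otu_fixture()
  md <- otu_microdiversity(fx$tab, fx$map)
  ## OTU-1 pooled (3, 1): exp(-(0.75 ln 0.75 + 0.25 ln 0.25)) ~ 1.7548
  expect_equal(unname(md["OTU-1"]),
               exp(-(0.75 * log(0.75) + 0.25 * log(0.25))))
  expect_equal(unname(md["OTU-1"]), 1.7548, tolerance = 1e-4)
  ## OTU-2 pooled (6, 2) -> same composition as (3, 1)
  expect_equal(unname(md["OTU-2"]),
               exp(oracle_shannon(c(6, 2))), tolerance = 1e-12)

  ## one-ASV OTU -> exactly 1; equal split -> exactly 2
  tab <- matrix(c(5L, 2L, 2L), 1, 3,
                dimnames = list("S", c("x", "y", "z")))
  md2 <- otu_microdiversity(tab, c(x = "O1", y = "O2", z = "O2"))
  expect_identical(unname(md2["O1"]), 1)
  expect_identical(unname(md2["O2"]), 2)

  ## zero-abundance OTU flagged NA
  tab0 <- matrix(c(5L, 0L), 1, 2, dimnames = list("S", c("x", "y")))
  expect_true(is.na(otu_microdiversity(tab0, c(x = "O1", y = "O2"))["O2"]))
  expect_error(otu_microdiversity(tab0, c(x = "O1")), "unmapped.*y")
})

test_that("microdiversity is invariant to pooling by sample concatenation", {
  set.seed(41)
  tab <- random_table(6L, 10L)
  map <- setNames(paste0("O", rep(1:3, length.out = 10L)), colnames(tab))
  pooled <- matrix(colSums(tab), 1L, dimnames = list("all", colnames(tab)))
  storage.mode(pooled) <- "integer"
  expect_equal(otu_microdiversity(tab, map), otu_microdiversity(pooled, map))
})

test_that("persistence counts occupied samples on the OTU table", {
  tab <- matrix(c(0L, 0L, 5L, 1L, 0L, 2L,
                  1L, 1L, 1L, 1L, 1L, 1L,
                  9L, 9L, 9L, 0L, 9L, 9L), 6, 3,
                dimnames = list(paste0("S", 1:6), c("u", "v", "w")))
  pers <- otu_persistence(tab)
  expect_equal(unname(pers["u"]), 0.5)
  expect_equal(unname(pers["v"]), 1)
  expect_equal(unname(pers["w"]), 5 / 6)
})

test_that("variability is the CV of relative abundance, scale invariant", {
  ## equal sample depths so relative-abundance CV equals count CV
  tab <- matrix(c(2L, 8L,
                  4L, 6L), 2, 2, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("p", "q")))
  v <- otu_variability(tab)
  expect_equal(unname(v["p"]), oracle_cv(c(0.2, 0.4)), tolerance = 1e-12)
  ## same composition as counts (2, 4): sd sqrt(2), mean 3 -> CV 0.4714
  expect_equal(unname(v["p"]), 0.4714, tolerance = 1e-4)

  ## constant relative abundance -> 0; zero mean -> NA
  tabc <- matrix(c(3L, 7L, 0L, 6L, 14L, 0L), 2, 3, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("x", "y", "z")))
  vc <- otu_variability(tabc)
  expect_equal(unname(vc["x"]), 0)
  expect_true(is.na(vc["z"]))

  ## scaling every count by c > 0 leaves the CV unchanged
  expect_equal(otu_variability(tab * 5L), v, tolerance = 1e-12)
})

test_that("the persistent flag applies strict thresholds", {
  rec <- data.frame(otu_id = c("A", "B", "C", "D"),
                    n_asvs = c(1L, 2L, 3L, 2L),
                    microdiversity = c(1, 1.4, 2.7, 2.0),
                    persistence = c(0.75, 1, 0.9, 0.8),
                    variability = c(0.5, 0, 2.5, 2))
  out <- classify_stability(rec)
  expect_identical(out$persistent, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$multi_asv, c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(out$multi_effective, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("records computed from the collapsed table equal member sums", {
  set.seed(43)
  tab <- random_table(8L, 12L)
  map <- setNames(paste0("O", rep(1:4, each = 3L)), colnames(tab))
  rec <- microdiversity_records(tab, map)
  otu_tab <- collapse_table(tab, map)
  expect_equal(setNames(rec$persistence, rec$otu_id),
               otu_persistence(otu_tab)[rec$otu_id])
  expect_equal(setNames(rec$variability, rec$otu_id),
               otu_variability(otu_tab)[rec$otu_id])
  expect_lte(max(rec$microdiversity / rec$n_asvs), 1 + 1e-12)
  expect_gte(min(rec$microdiversity), 1)
})

test_that("stability tests recover a planted monotone relationship", {
  rec <- data.frame(otu_id = paste0("O", 1:10), n_asvs = rep(1:2, 5),
                    microdiversity = seq(1, 3, length.out = 10),
                    persistence = seq(0.1, 1, length.out = 10),
                    variability = seq(2, 0.5, length.out = 10))
  rec <- classify_stability(rec)
  st <- stability_vs_microdiversity(rec, n_perm = 199L, seed = 3L)
  expect_equal(st$cor_persistence$statistic, 1)
  expect_equal(st$cor_variability$statistic, -1)
  expect_lte(st$cor_persistence$p_value, 0.05)
  expect_error(stability_vs_microdiversity(rec[rec$multi_asv, ], "n_asvs"),
               ">= 2 OTUs")
})
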