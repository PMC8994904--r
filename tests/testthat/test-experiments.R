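test_that("scenario runs are deterministic given the seed", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 8, N = 300,
                 generations = 3, pct_interacting = 0.5, seed = 7)
  t1 <- run_scenario(sc)
  t2 <- run_scenario(sc)
  expect_identical(t1$components, t2$components)
  t3 <- run_scenario(sc, seed = 8)
  expect_false(identical(t1$components, t3$components))
  expect_equal(t1$components$generation, 0:3)
  expect_equal(t1$components$F, 1 - 0.5^(0:3))
})

test_that("eval_generations restricts decomposition but not the simulation", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 8, N = 300,
                 generations = 3, pct_interacting = 0.5, seed = 7)
  full <- run_scenario(sc)
  sparse <- run_scenario(sc, eval_generations = c(0, 3))
  expect_equal(sparse$components,
               full$components[full$components$generation %in% c(0, 3), ],
               ignore_attr = TRUE)
})

test_that("flat trajectories arise without epistasis or LD", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 10, N = 4000,
                 generations = 5, epistasis_type = "none",
                 pct_interacting = 0, ld_level = "low", scheme = "random",
                 seed = 11)
  cmp <- run_scenario(sc)$components
  expect_true(all(cmp$epistatic_fraction == 0))
  # low-LD random mating: additive variance roughly stable
  expect_within(cmp$sigma2_A[6] / cmp$sigma2_A[1], 1, 0.2)
})

test_that("selfing raises additive and lowers dominance variance", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 10, N = 3000,
                 generations = 8, epistasis_type = "none",
                 pct_interacting = 0, ld_level = "high", scheme = "selfing",
                 seed = 12)
  cmp <- run_scenario(sc)$components
  expect_gt(cmp$sigma2_A[9], cmp$sigma2_A[1])
  expect_lt(cmp$sigma2_D[9], cmp$sigma2_D[1] / 2)
  s <- summarize_percent_changes(run_scenario(sc))
  expect_gt(s$pct_change[["sigma2_A"]], 0)
})

test_that("high-LD random mating decreases the additive variance", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 10, N = 3000,
                 generations = 8, epistasis_type = "none",
                 pct_interacting = 0, ld_level = "high", scheme = "random",
                 seed = 13)
  cmp <- run_scenario(sc)$components
  expect_lt(cmp$sigma2_A[9], cmp$sigma2_A[1])
})

test_that("percent-change summaries behave on edge cases", {
  cmp <- data.frame(generation = 0:2, sigma2_A = c(2, 2, 2),
                    sigma2_D = c(1, 1, 1), sigma2_AA = 0, sigma2_AD = 0,
                    sigma2_DA = 0, sigma2_DD = 0, sigma2_G = c(3, 3, 3),
                    epistatic_fraction = 0)
  s <- summarize_percent_changes(cmp)
  expect_equal(unname(s$pct_change[["sigma2_A"]]), 0)
  expect_true(is.na(s$pct_change[["sigma2_AA"]]))
  expect_error(summarize_percent_changes(cmp[1, ]), "two")
})

test_that("replicate averaging recomputes the epistatic fraction", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 8, N = 250,
                 generations = 2, pct_interacting = 0.5, seed = 20)
  rr <- run_replicates(sc, reps = 3, base_seed = 100)
  expect_equal(nrow(rr$mean), 3)
  expect_equal(length(rr$runs), 3)
  num <- sapply(rr$runs, function(df) df$sigma2_A[1])
  expect_equal(rr$mean$sigma2_A[1], mean(num))
  ef <- with(rr$mean, (sigma2_AA + sigma2_AD + sigma2_DA + sigma2_DD) /
               sigma2_G)
  expect_equal(rr$mean$epistatic_fraction, ef)
})

test_that("the named experimental grid matches the study design", {
  ps <- paper_scenarios()
  # four founder populations x (7 types + admixture) x 2 percentages x
  # 2 schemes, plus the dense-map LD characterization scenario
  expect_equal(length(ps), 4 * 8 * 2 * 2 + 1)
  founders <- unique(sub("_(complementary|duplicate|dominant|recessive|dominant_and_recessive|duplicate_cumulative|nonepistatic_interaction|admixture).*",
                         "", grep("dense", names(ps), invert = TRUE,
                                  value = TRUE)))
  expect_equal(length(founders), 4)
  expect_true(all(vapply(ps, function(s) s$ratio, numeric(1)) == 1))
  expect_true(all(vapply(ps, function(s) s$H2, numeric(1)) == 0.2))
  expect_true(all(vapply(ps, function(s) s$N, numeric(1)) == 5000))
  expect_equal(ps$high_0.5_dense_ld$chrom_len, 50)
})

test_that("scenarios can be read from configuration files", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("n_chrom: 2", "genes_per_chrom: 5", "\"N\": 100",
               "ld_level: low", "scheme: random", "seed: 3"), cfg)
  sc <- scenario_from_config(cfg)
  expect_s3_class(sc, "scenario")
  expect_equal(sc$n_chrom, 2)
  expect_equal(sc$scheme, "random")
  writeLines("bogus_key: 1", cfg)
  expect_error(scenario_from_config(cfg), "unknown")
})

test_that("the epistatic network table reports every sampled pair", {
  sc <- scenario(n_chrom = 2, genes_per_chrom = 8, N = 200,
                 generations = 1, pct_interacting = 0.5, seed = 9)
  tr <- run_scenario(sc)
  tab <- epistatic_network_table(tr$setup)
  expect_equal(nrow(tab), 4)   # 16 genes, 50% interacting
  expect_true(all(tab$type %in% epistasis_types()))
  expect_true(all(tab$V_I >= 0))
  none <- run_scenario(scenario(n_chrom = 1, genes_per_chrom = 6, N = 100,
                                generations = 0, epistasis_type = "none",
                                pct_interacting = 0, seed = 9))
  expect_equal(nrow(epistatic_network_table(none$setup)), 0)
})

test_that("trajectories export to CSV with scenario metadata", {
  sc <- scenario(n_chrom = 1, genes_per_chrom = 6, N = 150,
                 generations = 1, pct_interacting = 0, seed = 5,
                 epistasis_type = "none")
  tr <- run_scenario(sc)
  out <- tempfile(fileext = ".csv")
  write_trajectory(tr, out)
  back <- utils::read.csv(out)
  expect_equal(nrow(back), 2)
  expect_equal(back$sigma2_A, tr$components$sigma2_A, tolerance = 1e-10)
})
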