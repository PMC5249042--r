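test_that("stress cohorts land on the census grid and respect structure", {
  sc <- stress_scenario()
  cohorts <- gen_stress_cohorts(sc, ages = c(7, 14), n_per_cohort = 30,
                                seed = 11)
  expect_length(cohorts, 2L)
  for (co in cohorts) {
    expect_equal(co$n, 30L)
    expect_true(all(co$death_times %% 12 == 0))
    expect_true(all(co$death_times > 0 & co$death_times <= sc$max_duration))
  }
  expect_equal(vapply(cohorts, function(x) x$age_days, numeric(1)), c(7, 14))

  expect_error(gen_stress_cohorts(sc, ages = c(14, 7), seed = 1),
               "strictly increasing")
  expect_error(gen_stress_cohorts(sc, ages = 7, n_per_cohort = 0, seed = 1),
               ">= 1")
})

test_that("stress generation is deterministic under a fixed seed", {
  sc <- stress_scenario(distribution = "weibull")
  a <- gen_stress_cohorts(sc, seed = 99)
  b <- gen_stress_cohorts(sc, seed = 99)
  expect_identical(a, b)
  c <- gen_stress_cohorts(sc, seed = 100)
  expect_false(identical(a, c))
})

test_that("zero decline rate yields age-invariant mean survival", {
  sc <- stress_scenario(decline_rate = 0, max_duration = 2400)
  cohorts <- gen_stress_cohorts(sc, ages = c(7, 70), n_per_cohort = 2000,
                                seed = 7)
  means <- vapply(cohorts, function(co) mean(co$death_times), numeric(1))
  # exponential with mean 80 h at n = 2000: SEM ~ 1.8 h, so 3 combined SEs
  expect_lt(abs(means[1] - means[2]), 8)
})

test_that("a 4% daily decline produces strong negative age-survival correlation", {
  sc <- stress_scenario(decline_rate = 0.04)
  ages <- seq(7, 70, by = 7)
  rs <- vapply(1:200, function(s) {
    cohorts <- gen_stress_cohorts(sc, ages = ages, n_per_cohort = 150,
                                  seed = s)
    means <- vapply(cohorts, function(co) mean(co$death_times), numeric(1))
    age_survival_correlation(ages, means)$r
  }, numeric(1))
  expect_lt(mean(rs), -0.9)
})

test_that("lifespan cohorts follow the configured Gompertz structure", {
  # null genotype effect: medians agree within sampling error at n = 5000
  ls0 <- lifespan_scenario(genotype_effect = 1, n_per_group = 5000)
  lc0 <- gen_lifespan_cohorts(ls0, seed = 21)
  m <- c(summarize_cohort(lc0$control)$median,
         summarize_cohort(lc0$overexpression)$median)
  expect_lt(abs(m[1] - m[2]) / m[2], 0.05)

  # b = 0 reduces to exponential lifespans with median log(2)/a
  lse <- lifespan_scenario(gompertz_a = 0.02, gompertz_b = 0,
                           n_per_group = 10000)
  lce <- gen_lifespan_cohorts(lse, seed = 22)
  expect_lt(abs(summarize_cohort(lce$control)$median - log(2) / 0.02) /
              (log(2) / 0.02), 0.05)

  # protective hazard factor lengthens the overexpression median
  lsp <- lifespan_scenario(genotype_effect = 0.5, n_per_group = 5000)
  lcp <- gen_lifespan_cohorts(lsp, seed = 23)
  expect_gt(summarize_cohort(lcp$overexpression)$median,
            summarize_cohort(lcp$control)$median)

  # all on the daily grid, reproducible
  expect_true(all(lcp$control$death_times %% 1 == 0))
  expect_identical(gen_lifespan_cohorts(lsp, seed = 23), lcp)
})

test_that("gene-stat tables allocate nulls exactly and keep weights positive", {
  allnull <- gen_gene_stats(expression_scenario(n_genes = 100,
                                                fraction_null = 1), seed = 1)
  expect_true(all(allnull$logfc == 0))

  expect_error(expression_scenario(n_genes = 0), "n_genes")

  half <- gen_gene_stats(expression_scenario(n_genes = 1000,
                                             fraction_null = 0.5), seed = 5)
  expect_identical(sum(half$logfc == 0), 500L)
  expect_true(all(half$cpm > 0))
  expect_identical(anyDuplicated(half$gene_id), 0L)
})

test_that("toy pathways honor membership requests and reject duplicates", {
  one <- gen_toy_pathway(1, 2, seed = 3)
  expect_identical(nrow(one$nodes), 1L)
  expect_length(one$members[[1]], 2L)

  empty <- gen_toy_pathway(1, 0, seed = 3)
  expect_length(empty$members[[1]], 0L)

  expect_error(gen_toy_pathway(2, c(1, 1), seed = 1,
                               node_ids = c("a", "a")), "duplicate")

  pw <- gen_toy_pathway(5, c(2, 0, 3, 1, 4), seed = 8)
  genes <- unlist(pw$members)
  expect_identical(anyDuplicated(genes), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_node_map(pw, path)
  back <- read_node_map(path, pathway_id = pw$pathway_id)
  expect_identical(back$nodes, pw$nodes)
  expect_identical(back$members, pw$members)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(314)
  before <- .Random.seed
  invisible(gen_gene_stats(expression_scenario(n_genes = 10), seed = 4))
  invisible(gen_stress_cohorts(stress_scenario(), ages = 7,
                               n_per_cohort = 5, seed = 4))
  expect_identical(.Random.seed, before)
})
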