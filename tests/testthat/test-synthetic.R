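test_that("spec constructors validate their inputs", {
  expect_error(substate_spec(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(stage_spec("a", 1, substate_spec(c(1, 0))), "n_cells")
  expect_error(stage_spec("a", 10, substate_spec(c(1, 0)), dropout = 1),
               "dropout")
  expect_error(stage_spec("a", 10, list(substate_spec(c(1, 0)),
                                        substate_spec(c(1, 0, 0)))),
               "same number of genes")
  s <- stage_spec("a", 10, list(substate_spec(c(1, 0), weight = 2),
                                substate_spec(c(0, 1), weight = 2)))
  expect_equal(vapply(s$substates, `[[`, numeric(1), "weight"), c(0.5, 0.5))
  expect_error(scenario_spec(list(s, s)), "unique")
})

test_that("sampling is seed-reproducible and seed-sensitive", {
  spec <- stage_spec("P", 50, list(substate_spec(rep(0.7, 8), 1),
                                   substate_spec(rep(0.2, 8), 1)),
                     dropout = 0.1)
  a <- sample_population(spec, seed = 42)
  b <- sample_population(spec, seed = 42)
  expect_identical(a$values, b$values)
  c <- sample_population(spec, seed = 43)
  expect_false(identical(a$values, c$values))

  sc <- commitment_scenario(n_cells = 30, n_genes = 10)
  expect_identical(generate_scenario(sc, 5)$values,
                   generate_scenario(sc, 5)$values)
  expect_false(identical(generate_scenario(sc, 5)$values,
                         generate_scenario(sc, 6)$values))
})

test_that("expression values are strictly positive exactly where calls are on", {
  spec <- stage_spec("P", 200, substate_spec(rep(0.5, 6)), dropout = 0.2)
  m <- sample_population(spec, seed = 8)
  expect_true(all(m$values >= 0))
  b <- binarize(m)
  expect_identical(unname(b$calls), unname((m$values > 0) * 1L))
  expect_true(any(m$values == 0) && any(m$values > 0))
})

test_that("a deterministic single substate yields zero entropy", {
  spec <- stage_spec("P", 100, substate_spec(rep(1, 5)), dropout = 0)
  m <- sample_population(spec, seed = 1)
  expect_true(all(m$values > 0))
  b <- binarize(m)
  expect_equal(population_marginal_entropy(b, "P", se = FALSE)$value, 0)
  expect_equal(true_population_entropy(spec)$marginal, 0)
})

test_that("two complementary substates reproduce the mixed-GRN signature", {
  # mixture of two inverse on/off configurations over 6 genes: every gene
  # half-on, every pair perfectly (anti)correlated
  on_a <- c(1, 1, 1, 0, 0, 0)
  spec <- stage_spec("P", 10000,
                     list(substate_spec(on_a, 0.5),
                          substate_spec(1 - on_a, 0.5)), dropout = 0)
  truth <- true_population_entropy(spec)
  expect_equal(truth$marginal, 1)
  expect_equal(truth$joint, 0.5)

  m <- sample_population(spec, seed = 123)
  b <- binarize(m)
  p1 <- colMeans(b$calls)
  expect_true(all(abs(p1 - 0.5) < 0.02))
  h <- entroscape:::gene_entropies_bits(b$calls, "ml")
  expect_true(all(h > 0.999))
  pairs <- entroscape:::pair_entropies_bits(b$calls, "ml") / 2
  expect_true(all(abs(pairs - 0.5) < 0.01))
})

test_that("dropout censors an always-on gene to the predicted entropy", {
  spec <- stage_spec("P", 10000, substate_spec(rep(1, 3)), dropout = 0.1)
  truth <- true_population_entropy(spec)
  expect_equal(truth$marginal, binary_entropy(0.9), tolerance = 1e-12)
  expect_equal(binary_entropy(0.9), 0.4689955936, tolerance = 1e-9)

  m <- sample_population(spec, seed = 77)
  b <- binarize(m)
  expect_true(all(abs(colMeans(b$calls) - 0.9) < 0.01))
  est <- population_marginal_entropy(b, "P", se = FALSE)$value
  # delta-method bound from the stated +/- 0.01 binomial CI on the
  # on-fraction: |dH/dp| at 0.9 is log2(9) = 3.17 bits per unit
  expect_lt(abs(est - truth$marginal), 0.01 * log2(9))
})

test_that("pipeline estimates converge to the analytic oracle at n = 10000", {
  sc <- commitment_scenario(n_cells = 10000)
  m <- generate_scenario(sc, seed = 31)
  b <- binarize(m)
  for (i in seq_along(sc$stages)) {
    spec <- sc$stages[[i]]
    truth <- true_population_entropy(spec)
    h_est <- entroscape:::gene_entropies_bits(
      entroscape:::population_calls(b, spec$label), "ml")
    h_true <- vapply(truth$p_on, binary_entropy, numeric(1))
    # per-gene binomial-concentration bound via the delta method: 4 sigma
    # on the on-fraction propagated through |dH/dp| = |log2((1-p)/p)|
    slope <- abs(log2((1 - truth$p_on) / truth$p_on))
    tol <- pmax(4 * slope * sqrt(truth$p_on * (1 - truth$p_on) / 10000),
                1e-3)
    expect_true(all(abs(h_est - h_true) < tol))
    marg <- population_marginal_entropy(b, spec$label, se = FALSE)$value
    joint <- population_joint_entropy(b, spec$label, se = FALSE)$value
    expect_lt(abs(marg - truth$marginal), 0.01)
    expect_lt(abs(joint - truth$joint), 0.01)
  }
})

test_that("the default commitment scenario peaks at the commitment stage", {
  sc <- commitment_scenario()
  truths <- vapply(sc$stages, function(s) true_population_entropy(s)$marginal,
                   numeric(1))
  expect_true(truths[2] > truths[1] && truths[2] > truths[3])
  b <- binarize(generate_scenario(sc, seed = 1))
  p <- population_entropy_profile(b)
  tr <- entropy_trajectory(p, sc$ordering)
  expect_identical(tr$peaks, "commit")
})

test_that("a null scenario rarely flags significant entropy changes", {
  # identical specs at all stages: at z = 2 at least 90% of 200 seeded
  # replicates must show no significant per-edge change
  pat <- ifelse(seq_len(20) <= 10, 0.95, 0.05)
  mk <- function(lab) stage_spec(lab, 100, substate_spec(pat), dropout = 0.1)
  sc <- scenario_spec(list(mk("s1"), mk("s2"), mk("s3")))
  quiet <- vapply(1:200, function(s) {
    b <- binarize(generate_scenario(sc, seed = s))
    p <- population_entropy_profile(b)
    !any(entropy_trajectory(p, sc$ordering, z = 2)$edges$significant)
  }, logical(1))
  expect_gte(mean(quiet), 0.9)
})

test_that("the branching scenario mirrors a six-stage tree", {
  sc <- branching_scenario(n_cells = 25, n_genes = 12)
  m <- generate_scenario(sc, seed = 4)
  expect_identical(sort(unique(m$population)),
                   sort(c("root", "multipotent", "branchA", "branchB",
                          "leafA", "leafB")))
  expect_identical(as.integer(table(m$population)[sc$labels]),
                   rep(25L, 6))
  b <- binarize(m)
  p <- population_entropy_profile(b)
  tr <- entropy_trajectory(p, sc$ordering)
  expect_true(all(tr$peaks %in% c("branchA", "branchB")))
})

test_that("Ct-convention outputs invert the io transforms exactly", {
  sc_none <- commitment_scenario(n_cells = 20, n_genes = 6)
  ref <- generate_scenario(sc_none, seed = 9)
  for (conv in c("guo", "pina")) {
    sc <- commitment_scenario(n_cells = 20, n_genes = 6, convention = conv)
    raw <- generate_scenario(sc, seed = 9)
    path <- withr::local_tempfile(fileext = ".csv")
    write_expression_table(raw, path)
    back <- read_expression_table(path, "csv", transform = conv)
    expect_equal(back$values, ref$values, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("scenario files round-trip through write_scenario/read_scenario", {
  sc <- commitment_scenario(n_cells = 15, n_genes = 5, dropout = 0.07)
  path <- withr::local_tempfile()
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_identical(sc2$labels, sc$labels)
  expect_identical(sc2$ordering, sc$ordering)
  for (i in seq_along(sc$stages)) {
    expect_equal(sc2$stages[[i]]$n_cells, sc$stages[[i]]$n_cells)
    expect_equal(sc2$stages[[i]]$dropout, sc$stages[[i]]$dropout)
    expect_equal(
      lapply(sc2$stages[[i]]$substates, `[[`, "on_probability"),
      lapply(sc$stages[[i]]$substates, `[[`, "on_probability"))
  }
  expect_identical(generate_scenario(sc2, 3)$values > 0,
                   generate_scenario(sc, 3)$values > 0)
})
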