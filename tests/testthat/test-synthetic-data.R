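test_that("generated blocks have the requested shapes and positive values", {
  cfg <- sim_config(list(
    sim_block_spec("transcriptomics", 200, 33),
    sim_block_spec("microbiota", 50, 33),
    sim_block_spec("cytokine", 23, 36)), seed = 3)
  sim <- generate_blocks(cfg)
  dims <- lapply(sim$blocks, function(b) dim(b$values))
  expect_equal(dims$transcriptomics, c(200L, 33L))
  expect_equal(dims$microbiota, c(50L, 33L))
  expect_equal(dims$cytokine, c(23L, 36L))
  expect_true(all(vapply(sim$blocks, function(b) all(b$values > 0), logical(1))))
  # retained samples all come from the shared 36-animal design
  expect_true(all(vapply(sim$blocks, function(b)
    all(grepl("^M\\d+$", sample_ids(b))), logical(1))))
})

test_that("generator is reproducible from the seed and varies across seeds", {
  cfg <- sim_config(list(sim_block_spec("cytokine", 10, 20),
                         sim_block_spec("microbiota", 10, 20)), seed = 11)
  a <- generate_blocks(cfg)
  b <- generate_blocks(cfg)
  expect_identical(a$blocks$cytokine$values, b$blocks$cytokine$values)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 12L
  c <- generate_blocks(cfg2)
  expect_false(any(dim(c$blocks$cytokine$values) != dim(a$blocks$cytokine$values)) ||
                 identical(c$blocks$cytokine$values, a$blocks$cytokine$values))
  # the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(generate_blocks(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("planted pairs attain their target correlation on the log scale", {
  # large-n oracle: the generating model's closed-form loading should give
  # an empirical Pearson r within +/-0.05 of the 0.9 target at n = 1000
  pp <- data.frame(block_a = "cytokine", feature_a = 1,
                   block_b = "microbiota", feature_b = 1, r = 0.9)
  cfg <- sim_config(list(sim_block_spec("cytokine", 5, 1000),
                         sim_block_spec("microbiota", 5, 1000)),
                    n_groups = 2, mice_per_group = 500,
                    planted_pairs = pp, seed = 21)
  sim <- generate_blocks(cfg)
  al <- align_samples(log_transform(sim$blocks$cytokine),
                      log_transform(sim$blocks$microbiota))
  expect_equal(cor(al$X[, 1], al$Y[, 1]), 0.9, tolerance = 0.05 / 0.9)

  # negative target
  pp$r <- -0.8
  cfg <- sim_config(list(sim_block_spec("cytokine", 5, 1000),
                         sim_block_spec("microbiota", 5, 1000)),
                    n_groups = 2, mice_per_group = 500,
                    planted_pairs = pp, seed = 22)
  sim <- generate_blocks(cfg)
  al <- align_samples(log_transform(sim$blocks$cytokine),
                      log_transform(sim$blocks$microbiota))
  expect_equal(cor(al$X[, 1], al$Y[, 1]), -0.8, tolerance = 0.05 / 0.8)

  # zero target: the pair is generated independent (sampling noise in r is
  # ~1/sqrt(n), so check at n = 200 where 0.2 is a ~3 sigma bound)
  pp$r <- 0
  cfg <- sim_config(list(sim_block_spec("cytokine", 5, 200),
                         sim_block_spec("microbiota", 5, 200)),
                    n_groups = 2, mice_per_group = 100,
                    planted_pairs = pp, seed = 23)
  sim <- generate_blocks(cfg)
  al <- align_samples(log_transform(sim$blocks$cytokine),
                      log_transform(sim$blocks$microbiota))
  expect_lt(abs(cor(al$X[, 1], al$Y[, 1])), 0.2)
})

test_that("a perfect target correlation is an error, not a clip", {
  pp <- data.frame(block_a = "cytokine", feature_a = 1,
                   block_b = "microbiota", feature_b = 1, r = 1)
  cfg <- sim_config(list(sim_block_spec("cytokine", 5, 20),
                         sim_block_spec("microbiota", 5, 20)),
                    planted_pairs = pp, seed = 1)
  expect_error(generate_blocks(cfg), "infeasible")
  pp$r <- 1.2
  expect_error(sim_config(list(sim_block_spec("cytokine", 5, 20),
                               sim_block_spec("microbiota", 5, 20)),
                          planted_pairs = pp, seed = 1),
               "\\[-1, 1\\]")
})

test_that("config validation rejects malformed designs", {
  expect_error(sim_config(list(sim_block_spec("a", 5, 40),
                               sim_block_spec("b", 5, 20))),
               "retains more samples")
  expect_error(sim_config(list(sim_block_spec("a", 5, 20))), "at least two")
  expect_error(sim_config(list(sim_block_spec("a", 5, 20),
                               sim_block_spec("a", 5, 20))), "distinct")
  pp <- data.frame(block_a = "a", feature_a = c(1, 1), block_b = "b",
                   feature_b = c(1, 2), r = c(0.5, 0.5))
  expect_error(sim_config(list(sim_block_spec("a", 5, 20),
                               sim_block_spec("b", 5, 20)),
                          planted_pairs = pp),
               "at most one planted pair")
})

test_that("non-responsive features have equal group means in expectation", {
  cfg <- sim_config(list(sim_block_spec("cytokine", 200, 200,
                                        prop_responsive = 0),
                         sim_block_spec("microbiota", 5, 200)),
                    n_groups = 2, mice_per_group = 100, seed = 31)
  sim <- generate_blocks(cfg)
  blk <- log_transform(sim$blocks$cytokine)
  g <- blk$groups
  pvals <- apply(blk$values, 1, function(v)
    t.test(v[g == "diet1"], v[g == "diet2"])$p.value)
  expect_lt(mean(pvals < 0.01), 0.05)
})

test_that("responsive features are shifted by the configured effect", {
  cfg <- sim_config(list(sim_block_spec("cytokine", 60, 120,
                                        prop_responsive = 0.5),
                         sim_block_spec("microbiota", 5, 120)),
                    n_groups = 2, mice_per_group = 60,
                    effect_size = 2, seed = 33)
  sim <- generate_blocks(cfg)
  blk <- log_transform(sim$blocks$cytokine)
  resp <- sim$truth$responsive$cytokine
  expect_length(resp, 30)
  g <- blk$groups
  shifts <- abs(rowMeans(blk$values[resp, g == "diet2"]) -
                  rowMeans(blk$values[resp, g == "diet1"]))
  # with 2 groups the single non-reference group always carries the shift
  expect_true(all(shifts > 1))
  expect_equal(median(shifts), 2, tolerance = 0.15)
})
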