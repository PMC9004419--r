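toy_st <- function() {
  read_structure_table(data.frame(
    site = 1:10,
    x = c(0, 3, 20, 40, 60, 80, 100, 120, 140, 160),
    y = c(0, 4, 0, 0, 0, 0, 0, 0, 0, 0),
    z = 0,
    rsa = seq(0.05, 0.95, length.out = 10),
    ss_label = c(rep("alpha helix", 4), rep("strand", 3),
                 rep("no structure", 3)),
    element_id = c(rep("H1", 4), rep("E1", 2), "E2", NA, NA, NA),
    sheet_id = c(rep(NA, 4), "S1", "S1", NA, NA, NA, NA),
    hotloop = c(rep(0, 9), 0.5)))
}

test_that("structure tables are validated and disorder is integrated", {
  st <- toy_st()
  expect_s3_class(st, "structure_table")
  expect_equal(nrow(st), 10L)
  # hotloop > 0.1204 without a motif becomes disordered
  expect_identical(st$ss_label[10], "disordered")
  expect_identical(st$ss_label[9], "no structure")
  bad <- data.frame(site = 1, x = 0, y = 0, z = 0, rsa = 1.2,
                    ss_label = "turn")
  expect_error(read_structure_table(bad), "RSA")
  bad2 <- data.frame(site = 1, x = NaN, y = 0, z = 0, rsa = 0.5,
                     ss_label = "turn")
  expect_error(read_structure_table(bad2), "coordinates")
  bad3 <- data.frame(site = 1, x = 0, y = 0, z = 0, rsa = 0.5,
                     ss_label = "alpha helix")
  expect_error(read_structure_table(bad3), "element id")
})

test_that("mean C-alpha distance matches hand-computed geometry", {
  st <- toy_st()
  expect_equal(mean_ca_distance(c(1, 2), st), 5)          # 3-4-5 triangle
  # collinear sites at 20, 40, 60 on x: pairwise {20, 20, 40}
  expect_equal(mean_ca_distance(c(3, 4, 5), st), 80 / 3)
  st2 <- read_structure_table(data.frame(
    site = 1:2, x = 1, y = 2, z = 3, rsa = 0.5, ss_label = "turn"))
  expect_equal(mean_ca_distance(1:2, st2), 0)
  expect_error(mean_ca_distance(c(1, 99), st), "annotation")
})

test_that("N_sub endpoints and a two-clique case are exact", {
  st <- toy_st()
  expect_equal(n_sub(c(1, 2), st), 0)        # 5 A apart: one component
  expect_equal(n_sub(c(3, 5, 7), st), 1)     # all mutually > 8 A
  # two 2-cliques: sites (1,2) together, (3,4) at 20 A spacing > 8;
  # use custom coordinates
  st3 <- read_structure_table(data.frame(
    site = 1:4, x = c(0, 5, 100, 105), y = 0, z = 0, rsa = 0.5,
    ss_label = "turn"))
  expect_equal(n_sub(1:4, st3), 1 / 3)
  expect_error(n_sub(3, st), "at least 2")
})

test_that("N_sub never increases when the contact threshold grows", {
  set.seed(9)
  for (r in 1:20) {
    n <- sample(3:8, 1)
    st <- read_structure_table(data.frame(
      site = seq_len(n), x = runif(n, 0, 30), y = runif(n, 0, 30),
      z = runif(n, 0, 30), rsa = 0.5, ss_label = "turn"))
    vals <- vapply(c(5, 8, 10, 20), function(thr)
      n_sub(seq_len(n), st, contact_threshold = thr), 0)
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("conditional sampling respects the relative-similarity window", {
  set.seed(31)
  cfg <- sampler_config(conditioning = "rate", similarity = 0.1,
                        min_pool = 5, seed = 2)
  for (r in 1:20) {
    pool <- data.frame(site = 1:60, value = exp(rnorm(60, 0, 0.6)))
    group <- sample(pool$site, 3)
    s <- conditional_sample(group, pool, cfg)
    if (is.null(s)) next
    expect_equal(anyDuplicated(s), 0L)
    v <- pool$value[match(s, pool$site)]
    v0 <- pool$value[match(group, pool$site)]
    expect_true(all(abs(v - v0) / v0 <= 0.1 + 1e-12))
  }
})

test_that("a focus site with fewer than five similar sites excludes the group", {
  pool <- data.frame(site = 1:7,
                     value = c(1, 1.01, 1.05, 0.96, 0.99, 10, 20))
  cfg <- sampler_config(conditioning = "rate", similarity = 0.1,
                        min_pool = 5, seed = 1)
  # site 6 (value 10) has only itself within 10%
  expect_null(conditional_sample(c(1, 6), pool, cfg))
  # all focus sites well-populated: a sample is returned
  expect_false(is.null(conditional_sample(c(1, 2), pool, cfg)))
})

test_that("balanced sampling equalizes draws below and above the focus value", {
  # 2 candidates below, 8 above (within the window): after balancing the
  # probability of drawing below must be ~1/2 (plus the focus value itself)
  pool <- data.frame(site = 1:11,
                     value = c(1, 0.92, 0.94, rep(1.08, 8)))
  cfg <- sampler_config(conditioning = "rate", similarity = 0.1,
                        min_pool = 3, seed = 1)
  set.seed(5)
  draws <- replicate(2000, {
    s <- conditional_sample(1, pool, cfg)
    pool$value[match(s, pool$site)]
  })
  below <- mean(draws < 1)
  above <- mean(draws > 1)
  expect_lt(abs(below - above), 0.1)
})

test_that("uniform sampling is used when conditioning is none", {
  pool <- data.frame(site = 1:10, value = 0)
  cfg <- sampler_config(conditioning = "none", seed = 3)
  set.seed(4)
  s <- conditional_sample(c(1, 2, 3), pool, cfg)
  expect_equal(length(s), 3L)
  expect_equal(anyDuplicated(s), 0L)
})

test_that("proximity test attains the exact floor on planted contacts", {
  # observed pair in contact; every other pool pair far apart and the
  # observed sites excluded from the pool, so no replicate can tie
  n <- 22
  st <- read_structure_table(data.frame(
    site = 1:n, x = c(0, 5, seq(100, by = 25, length.out = n - 2)),
    y = 0, z = 0, rsa = 0.5, ss_label = "turn"))
  pool <- data.frame(site = 3:n, value = 0)
  cfg <- sampler_config(conditioning = "none", replicates = 1000, seed = 7)
  res <- proximity_test(list(c(1, 2)), st, pool, cfg,
                        statistic = "mean_distance")
  expect_equal(res$p, 1 / 1001)
  expect_equal(res$observed, 5)
  resn <- proximity_test(list(c(1, 2)), st, pool, cfg, statistic = "n_sub")
  expect_equal(resn$observed, 0)
  expect_equal(resn$p, 1 / 1001)
})

test_that("proximity test is degenerate-safe and reproducible", {
  st <- read_structure_table(data.frame(
    site = 1:4, x = c(0, 5, 50, 100), y = 0, z = 0, rsa = 0.5,
    ss_label = "turn"))
  pool <- data.frame(site = 1:2, value = 0)
  cfg <- sampler_config(conditioning = "none", replicates = 200, seed = 2)
  # the only possible sample is the observed pair itself
  res <- proximity_test(list(c(1, 2)), st, pool, cfg,
                        statistic = "mean_distance")
  expect_equal(res$p, 1)
  r2 <- proximity_test(list(c(1, 2)), st, pool, cfg,
                       statistic = "mean_distance")
  expect_identical(res$null, r2$null)
})

test_that("secondary-structure co-location statistic counts elements", {
  st <- toy_st()
  pool <- data.frame(site = 1:10, value = 0)
  cfg <- sampler_config(conditioning = "none", replicates = 100, seed = 5)
  # two sites in the same helix: statistic 0
  res <- ss_colocation_test(list(c(1, 2)), st, pool, cfg, motif = "helix")
  expect_equal(res$observed, 0)
  # sites in distinct strand elements: statistic 1
  res2 <- ss_colocation_test(list(c(5, 7)), st, pool, cfg, motif = "strand")
  expect_equal(res2$observed, 1)
  # same sheet: strands E1 and E1/E2 share sheet S1 only for sites 5, 6
  res3 <- ss_colocation_test(list(c(5, 6)), st, pool, cfg, motif = "sheet")
  expect_equal(res3$observed, 0)
  # groups reduced below 2 in-motif sites are dropped
  expect_error(ss_colocation_test(list(c(8, 9)), st, pool, cfg,
                                  motif = "helix"), "no group")
})
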