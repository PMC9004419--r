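test_that("identity permutation reproduces the observed branch profile", {
  set.seed(6)
  X <- matrix(rnorm(3 * 10), 3)
  cm <- fake_cm(X)
  bt <- permute_branches_test(cm, 1:3, n_perm = 50, seed = 1)
  expect_equal(bt$observed,
               vapply(seq_len(10), function(j) branch_compensation(X[, j]),
                      0),
               tolerance = 1e-12)
  expect_error(permute_branches_test(cm, 1:3, n_perm = 5), ">= 20")
})

# frequency with which each branch has defined (non-NA) C_j under the
# branch permutation null, estimated with the same seed
.colperm_defined_freq <- function(cm, n_perm) {
  X <- cm$x
  m <- ncol(X)
  set.seed(3)
  freq <- numeric(m)
  for (b in seq_len(n_perm)) {
    Xp <- t(apply(X, 1, function(v) v[sample.int(m)]))
    freq <- freq + (colSums(abs(Xp)) > 1e-9)
  }
  freq / n_perm
}

test_that("branch permutation collision frequency matches the closed form", {
  # two sites, each with a single nonzero opposite-sign entry: after
  # independent branch randomization they land on the same branch with
  # probability 1/m, in which case exactly one branch has C_j = 1
  m <- 8
  X <- rbind(c(2, rep(0, m - 1)), c(-2, rep(0, m - 1)))
  cm <- fake_cm(X)
  n_perm <- 5000
  bt <- permute_branches_test(cm, 1:2, n_perm = n_perm, seed = 3)
  # when the entries collide, C = 1 on one branch; otherwise every branch
  # with signal has C = 0; so sum over branches of E[C_j | defined] scaled
  # by definition frequency equals P(collision) = 1/m:
  # E[#branches with C_j = 1 per permutation] = 1/m
  collision_rate <- sum(bt$null_mean * .colperm_defined_freq(cm, n_perm))
  # binomial SE at 5000 permutations is ~0.005; allow 3 SE
  expect_lt(abs(collision_rate - 1 / m), 0.015)
})

test_that("site permutation test honors degenerate pools", {
  # all pool sites share the same change on a branch: null C_j is always 0
  X <- matrix(3, 6, 4)
  cm <- fake_cm(X)
  st <- permute_sites_test(cm, 1:2, n_perm = 100, seed = 2)
  expect_true(all(st$per_branch$null_mean == 0))
  # alternating equal-magnitude opposite-sign pool: a drawn pair is either
  # perfectly compensated (C = 1, prob 2/3) or identical (C = 0)
  X2 <- rbind(rep(2, 4), rep(-2, 4), rep(2, 4), rep(-2, 4))
  cm2 <- fake_cm(X2)
  st2 <- permute_sites_test(cm2, 1:2, n_perm = 400, seed = 2)
  expect_true(all(abs(st2$per_branch$null_mean - 2 / 3) < 0.1))
  # insufficient pool
  expect_error(permute_sites_test(fake_cm(matrix(1, 3, 4)), 1:2,
                                  n_perm = 50), "pool")
})

test_that("permutation tests are reproducible under a fixed seed", {
  set.seed(12)
  X <- matrix(rnorm(8 * 12), 8)
  cm <- fake_cm(X)
  a <- permute_branches_test(cm, 1:4, n_perm = 200, seed = 9)
  b <- permute_branches_test(cm, 1:4, n_perm = 200, seed = 9)
  expect_identical(a, b)
  s1 <- permute_sites_test(cm, 1:3, n_perm = 200, seed = 4)
  s2 <- permute_sites_test(cm, 1:3, n_perm = 200, seed = 4)
  expect_identical(s1, s2)
})

test_that("a planted compensating pair exceeds the site-permutation bound", {
  tr <- desk_tree()
  mod <- desk_model()
  vol <- desk_prop()
  wins <- vapply(1:10, function(r) {
    fam <- simulate_family(tr, mod, vol, n_sites = 30, n_pairs = 1,
                           strength = 1, seed = 300 + r)
    cm <- substitution_mapping(fam$alignment, tr, mod, vol, counts = FALSE)
    st <- permute_sites_test(cm, 1:2, n_perm = 300, seed = r)
    j <- which.max(st$per_branch$observed)
    st$per_branch$observed[j] > st$per_branch$null_hi[j]
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("compensograms rank branches and export the requested top table", {
  set.seed(20)
  X <- matrix(rnorm(2 * 12, sd = 3), 2)
  X[, 3] <- c(-5, 5)        # strong perfectly compensated branch
  X[, 7] <- c(0, 0)         # undefined branch
  cm <- fake_cm(X)
  cg <- compensogram(cm, 1:2, n_perm = 100, seed = 1)
  expect_s3_class(cg, "compensogram")
  expect_true(is.na(cg$branches$C_j[cg$branches$branch == 7] |>
                      as.numeric()))
  # weighted ranking: C_j * total |change| decreasing over defined branches
  w <- cg$branches$weight[!is.na(cg$branches$C_j)]
  expect_true(all(diff(w) <= 1e-12))
  tab <- export_compensogram(cg, top = 5)
  expect_equal(nrow(tab), 5 * 2)
  expect_equal(length(unique(tab$branch)), 5L)
  # top > m: all defined branches, no padding
  tab2 <- export_compensogram(cg, top = 50)
  expect_equal(length(unique(tab2$branch)), 11L)
  # display states are refused unless recorded, and never feed statistics
  expect_error(compensogram(cm, 1:2, n_perm = 100, display_states = TRUE),
               "ancestral")
})

test_that("ancestral display states are recorded but do not alter statistics", {
  mod <- subst_model("LG", ncat = 2, gamma_shape = 1)
  vol <- builtin_property("grantham_volume")
  tr <- read_tree(ape::read.tree(text = "((A:0.1,B:0.2):0.1,(C:0.1,D:0.3):0.2);"))
  aln <- aln_from(A = c("I", "K"), B = c("A", "K"), C = c("I", "E"),
                  D = c("V", "E"))
  cm0 <- substitution_mapping(aln, tr, mod, vol, counts = FALSE)
  cm1 <- substitution_mapping(aln, tr, mod, vol, counts = FALSE,
                              ancestral = TRUE)
  expect_identical(cm0$x, cm1$x)
  expect_false(is.null(cm1$node_states))
  # leaf states are the observed residues
  expect_identical(unname(cm1$node_states[1:4, 1]),
                   unname(aln$matrix[tr$tip.label, 1]))
  cg <- compensogram(cm1, 1:2, n_perm = 50, display_states = TRUE)
  expect_false(is.null(cg$display_states))
})
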