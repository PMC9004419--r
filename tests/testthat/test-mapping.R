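test_that("pruning likelihood matches closed forms and is symmetric", {
  mod <- subst_model("Poisson", ncat = 1)
  tr <- read_tree(ape::read.tree(text = "(A:0.3,B:0.5);"))
  aln <- aln_from(A = c("A", "A"), B = c("A", "C"))
  # direct summation over the single internal (root) state
  P1 <- transition_probs(mod, 0.3)
  P2 <- transition_probs(mod, 0.5)
  ia <- match("A", aa_alphabet()); ic <- match("C", aa_alphabet())
  l1 <- sum(mod$freq * P1[, ia] * P2[, ia])
  l2 <- sum(mod$freq * P1[, ia] * P2[, ic])
  ll <- site_loglik(aln, tr, mod)
  expect_equal(as.numeric(ll), log(c(l1, l2)), tolerance = 1e-12)
  # swapping the root's children leaves the likelihood unchanged
  tr2 <- read_tree(ape::read.tree(text = "(B:0.5,A:0.3);"))
  expect_equal(as.numeric(site_loglik(aln, tr2, mod)), as.numeric(ll),
               tolerance = 1e-12)
})

test_that("substitution mapping agrees with brute-force ancestral enumeration", {
  set.seed(7)
  vol <- builtin_property("grantham_volume")
  cases <- list(
    list(tree = "((A:0.1,B:0.3):0.15,C:0.2);",
         aln = aln_from(A = c("I", "A", "K"), B = c("A", "A", "E"),
                        C = c("V", "A", "R")),
         model = subst_model("LG", gamma_shape = 0.7, ncat = 3)),
    list(tree = "((A:0.2,B:0.1):0.1,(C:0.4,D:0.05):0.3);",
         aln = aln_from(A = c("L", "R"), B = c("F", "E"),
                        C = c("I", "K"), D = c("W", "D")),
         model = subst_model("Poisson", ncat = 1))
  )
  for (cs in cases) {
    tr <- read_tree(ape::read.tree(text = cs$tree))
    cm <- substitution_mapping(cs$aln, tr, cs$model, vol)
    or <- oracle_map(cs$aln, tr, cs$model, vol)
    expect_lt(max(abs(cm$x - or$x), na.rm = TRUE), 1e-8)
    expect_equal(cm$loglik, sum(or$loglik), tolerance = 1e-10)
    expect_equal(as.numeric(site_loglik(cs$aln, tr, cs$model)), or$loglik,
                 tolerance = 1e-10)
  }
})

test_that("signed changes telescope to the property difference between leaves", {
  vol <- builtin_property("grantham_volume")
  mod <- subst_model("LG", gamma_shape = 1, ncat = 4)
  for (lens in list(c(0.15, 0.4), c(1e-4, 1e-4))) {
    tr <- read_tree(ape::read.tree(
      text = sprintf("(A:%g,B:%g);", lens[1], lens[2])))
    aln <- aln_from(A = "A", B = "I")
    cm <- substitution_mapping(aln, tr, mod, vol)
    toA <- which(cm$tree$edge[, 2L] == which(cm$tree$tip.label == "A"))
    toB <- which(cm$tree$edge[, 2L] == which(cm$tree$tip.label == "B"))
    # oriented leaf-A -> root -> leaf-I: the per-branch split depends on the
    # branch lengths but the total is forced by telescoping
    expect_equal(-cm$x[1, toA] + cm$x[1, toB], 80, tolerance = 1e-9)
  }
})

test_that("negating the property negates every change exactly", {
  vol <- builtin_property("grantham_volume")
  neg <- aa_property(stats::setNames(-as.numeric(vol), names(vol)),
                     "neg_volume")
  mod <- subst_model("LG", gamma_shape = 0.7, ncat = 3)
  tr <- read_tree(ape::read.tree(text = "((A:0.1,B:0.3):0.15,C:0.2);"))
  aln <- aln_from(A = c("I", "E"), B = c("A", "K"), C = c("V", "K"))
  cm <- substitution_mapping(aln, tr, mod, vol)
  cmn <- substitution_mapping(aln, tr, mod, neg)
  expect_identical(cmn$x, -cm$x)
})

test_that("invariant-site changes vanish as branch lengths shrink", {
  vol <- builtin_property("grantham_volume")
  mod <- subst_model("LG", ncat = 1)
  for (t in c(1e-4, 1e-2)) {
    tr <- read_tree(ape::read.tree(
      text = sprintf("((A:%g,B:%g):%g,C:%g);", t, t, t, t)))
    aln <- aln_from(A = "A", B = "A", C = "A")
    cm <- substitution_mapping(aln, tr, mod, vol)
    expect_lt(max(abs(cm$x[1, ])), 200 * t)
  }
})

test_that("expected substitution counts match a quadrature oracle", {
  mod <- subst_model("LG", ncat = 1)
  vol <- builtin_property("grantham_volume")
  t1 <- 0.05; t2 <- 0.35
  tr <- read_tree(ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2)))
  aln <- aln_from(A = "I", B = "A")
  cm <- substitution_mapping(aln, tr, mod, vol, counts = TRUE)
  # oracle: E[weighted count on branch] by Simpson quadrature of
  # sum_root pi_r P(r -> a at s) q_ab w_ab P(b -> leaf at rest), conditioned
  # on the leaf data
  alpha <- aa_alphabet()
  ia <- match("I", alpha); ja <- match("A", alpha)
  W <- mod$Q * abs(outer(as.numeric(vol[alpha]), as.numeric(vol[alpha]),
                         function(x, y) y - x))
  diag(W) <- 0
  quad_count <- function(tb, other_t, leaf_b, leaf_other) {
    ns <- 400
    ss <- seq(0, tb, length.out = ns + 1)
    wts <- c(1, rep(c(4, 2), length.out = ns - 1), 1) * (tb / ns) / 3
    tot <- 0
    for (i in seq_along(ss)) {
      M <- transition_probs(mod, ss[i]) %*% W %*%
        transition_probs(mod, tb - ss[i])
      # root r: up the other branch to its leaf, down this branch
      tot <- tot + wts[i] *
        sum(mod$freq * transition_probs(mod, other_t)[, leaf_other] *
              M[, leaf_b])
    }
    lik <- sum(mod$freq * transition_probs(mod, other_t)[, leaf_other] *
                 transition_probs(mod, tb)[, leaf_b])
    tot / lik
  }
  toA <- which(cm$tree$edge[, 2L] == which(cm$tree$tip.label == "A"))
  toB <- which(cm$tree$edge[, 2L] == which(cm$tree$tip.label == "B"))
  expect_equal(cm$wcount[1, toA], quad_count(t1, t2, ia, ja),
               tolerance = 1e-5)
  expect_equal(cm$wcount[1, toB], quad_count(t2, t1, ja, ia),
               tolerance = 1e-5)
})

test_that("site rates recover the single-substitution weight and standardize to mean 1", {
  vol <- builtin_property("grantham_volume")
  mod <- subst_model("Poisson", ncat = 1)
  # one near-certain I -> A substitution on one short branch
  tr <- read_tree(ape::read.tree(text = "(A:1e-6,B:0.02);"))
  aln <- aln_from(A = c("I", "G"), B = c("A", "G"))
  cm <- substitution_mapping(aln, tr, mod, vol, counts = TRUE)
  sr <- site_rates(cm)
  expect_equal(sr$raw_rate[1], 80, tolerance = 0.02 * 80)
  expect_equal(sr$raw_rate[2], 0, tolerance = 0.01)
  # family standardization
  mod4 <- subst_model("LG", gamma_shape = 1, ncat = 4)
  tr2 <- sample_tree(10, 0.2, seed = 3)
  aln2 <- simulate_independent(tr2, mod4, 25, seed = 9)
  sr2 <- site_rates(substitution_mapping(aln2, tr2, mod4, vol,
                                         counts = TRUE))
  expect_equal(mean(sr2$std_rate), 1, tolerance = 1e-12)
  expect_true(all(sr2$raw_rate >= 0))
  expect_error(site_rates(substitution_mapping(aln2, tr2, mod4, vol,
                                               counts = FALSE)),
               "counts")
})

test_that("restoring the generating model does not decrease the likelihood", {
  vol <- builtin_property("grantham_volume")
  lg <- subst_model("LG", ncat = 1)
  poisson <- subst_model("Poisson", ncat = 1)
  tr <- sample_tree(15, 0.15, seed = 21)
  diffs <- vapply(1:3, function(r) {
    aln <- simulate_independent(tr, lg, 40, seed = 100 + r)
    substitution_mapping(aln, tr, lg, vol, counts = FALSE)$loglik -
      substitution_mapping(aln, tr, poisson, vol, counts = FALSE)$loglik
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("gamma shape estimation improves over a mismatched shape", {
  vol <- builtin_property("grantham_volume")
  tr <- sample_tree(12, 0.2, seed = 5)
  gen <- subst_model("LG", gamma_shape = 0.4, ncat = 4)
  set.seed(8)
  rates <- sample(discrete_gamma_rates(0.4, 4), 30, replace = TRUE)
  aln <- simulate_independent(tr, gen, 30, rate_multipliers = rates)
  fit <- fit_gamma_shape(aln, tr, subst_model("LG", gamma_shape = 5,
                                              ncat = 4))
  ll <- function(m) sum(site_loglik(aln, tr, m))
  expect_gte(ll(fit) + 1e-6,
             ll(subst_model("LG", gamma_shape = 5, ncat = 4)))
  expect_lt(fit$gamma_shape, 5)
})

test_that("non-analyzable sites are refused and flagged", {
  mod <- subst_model("Poisson", ncat = 1)
  tr <- read_tree(ape::read.tree(text = "(A:0.1,B:0.1);"))
  aln <- aln_from(A = c("A", "-"), B = c("A", "C"))
  expect_error(site_loglik(aln, tr, mod, sites = 2), "not analyzable")
  cm <- substitution_mapping(aln, tr, mod, builtin_property("klein_charge"))
  expect_true(all(is.na(cm$x[2, ])))
  expect_false(anyNA(cm$x[1, ]))
})
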