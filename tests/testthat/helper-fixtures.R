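# Shared fixtures and independent oracles. Heavy objects (the desk-scale
# tree and its null ensemble) are built once per test run and memoised.

.fix <- new.env()

memo <- function(key, expr) {
  if (!exists(key, envir = .fix, inherits = FALSE)) {
    assign(key, force(expr), envir = .fix)
  }
  get(key, envir = .fix, inherits = FALSE)
}

# Study conditions for the simulation experiments: a 100-leaf tree (the
# corpus-minimum number of sequences), mean branch length 0.1, 50-site
# families, LG without rate variation (matching the generator), volume.
desk_tree <- function() memo("desk_tree", sample_tree(100, 0.1, seed = 42))
desk_model <- function() memo("desk_model", subst_model("LG", ncat = 1))
desk_prop <- function() memo("desk_prop", builtin_property("grantham_volume"))

desk_null <- function() {
  memo("desk_null",
       simulate_null(desk_tree(), desk_model(), desk_prop(),
                     site_rates = 1, n_sites = 50, n_sim = 500,
                     seed = 424242))
}

# Small alignment builder.
aln_from <- function(...) {
  rows <- list(...)
  aa_alignment(do.call(rbind, rows))
}

# Independent oracle for substitution mapping: enumerate every assignment
# of ancestral states (feasible for <= 4 leaves), weight by its likelihood,
# and average the signed property change on every branch. Also returns the
# site log-likelihoods.
oracle_map <- function(aln, tree, model, prop) {
  tree <- read_tree(tree, aln)
  edge <- tree$edge
  m <- nrow(edge)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  alpha <- aa_alphabet()
  pvec <- as.numeric(prop[alpha])
  sites <- which(aln$analyzable)
  X <- matrix(NA_real_, aln$n_sites, m)
  LL <- numeric(length(sites))
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  P <- lapply(seq_len(model$ncat), function(cc)
    lapply(seq_len(m), function(e)
      transition_probs(model, tree$edge.length[e], model$rates[cc])))
  for (si in seq_along(sites)) {
    s <- sites[si]
    tipstate <- match(aln$matrix[tree$tip.label, s], alpha)
    tot <- 0
    xs <- numeric(m)
    for (cc in seq_len(model$ncat)) {
      for (g in seq_len(nrow(grid))) {
        st <- c(tipstate, grid[g, ])
        pr <- model$freq[st[ntip + 1L]] / model$ncat
        for (e in seq_len(m)) pr <- pr * P[[cc]][[e]][st[edge[e, 1L]],
                                                      st[edge[e, 2L]]]
        tot <- tot + pr
        for (e in seq_len(m)) {
          xs[e] <- xs[e] + pr * (pvec[st[edge[e, 2L]]] - pvec[st[edge[e, 1L]]])
        }
      }
    }
    X[s, ] <- xs / tot
    LL[si] <- log(tot)
  }
  list(x = X, loglik = LL)
}

# Fake change matrix with full control over the change vectors; tree
# branch lengths default to 1.
fake_cm <- function(X, analyzable = NULL, variable = NULL, property = "toy") {
  n <- nrow(X)
  m <- ncol(X)
  structure(list(
    property = property, x = X, count = NULL, wcount = NULL,
    analyzable = if (is.null(analyzable)) rep(TRUE, n) else analyzable,
    variable = if (is.null(variable)) rep(TRUE, n) else variable,
    tree = list(edge.length = rep(1, m)), model = "toy",
    loglik = NA_real_), class = "change_matrix")
}
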