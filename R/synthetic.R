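# Synthetic data: random trees, site-independent alignments, planted
# compensatory pairs (Gillespie event simulation so that "same branch"
# co-substitution is well defined) and toy structures with configurable
# contact geometry. Every generator is bit-reproducible under a fixed seed.

#' Sample a random rooted tree
#'
#' Random topology by uniform coalescent-style joins of lineages, with
#' independent exponential branch lengths.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param mean_branch_length Mean of the exponential branch lengths.
#' @param seed Integer seed.
#' @return Rooted `ape::phylo` in cladewise order, tips labelled `t1..tn`.
#' @export
sample_tree <- function(n_leaves, mean_branch_length = 0.1, seed = 1L) {
  stopifnot(n_leaves >= 2L, mean_branch_length > 0)
  set.seed(seed)
  tree <- ape::rcoal(n_leaves, tip.label = paste0("t", seq_len(n_leaves)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / mean_branch_length)
  read_tree(tree)
}

# Vectorized transition sampling for one edge: given parent states (indices)
# and per-site rate multipliers, draw child states.
.evolve_edge <- function(model, parent, rates, t) {
  n <- length(parent)
  E2 <- model$U * (1 / model$d12)          # row a: d12^-1[a] * U[a, ]
  E1 <- t(model$U) * rep(model$d12, each = 20L)  # E1[k, b] = U[b,k] d12[b]
  lam <- exp(outer(rates * t, model$lambda))     # n x 20
  probs <- (E2[parent, , drop = FALSE] * lam) %*% E1
  probs[probs < 0] <- 0
  probs <- probs / rowSums(probs)
  cum <- probs %*% upper.tri(diag(20), diag = TRUE)
  u <- stats::runif(n)
  rowSums(cum < u) + 1L
}

#' Simulate independently evolving sites on a fixed tree
#'
#' Each site starts from a stationary-frequency draw at the root and evolves
#' by Markov transitions along every branch, scaled by its rate multiplier.
#'
#' @param tree Rooted `ape::phylo`.
#' @param model A `subst_model`.
#' @param n_sites Number of sites.
#' @param rate_multipliers Per-site rate multipliers (recycled; 0 gives an
#'   invariant column).
#' @param seed Optional integer seed (`NULL`: use the current RNG state, as
#'   when called from [simulate_null()]).
#' @return An `aa_alignment`.
#' @export
simulate_independent <- function(tree, model, n_sites, rate_multipliers = 1,
                                 seed = NULL) {
  tree <- read_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  rates <- rep_len(rate_multipliers, n_sites)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_sites)
  states[ntip + 1L, ] <- sample.int(20L, n_sites, replace = TRUE,
                                    prob = model$freq)
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {     # preorder: parent always resolved
    states[edge[e, 2L], ] <- .evolve_edge(model, states[edge[e, 1L], ],
                                          rates, tree$edge.length[e])
  }
  mat <- matrix(aa_alphabet()[states[seq_len(ntip), , drop = FALSE]],
                ntip, n_sites, dimnames = list(tree$tip.label, NULL))
  aa_alignment(mat)
}

.wtd_quantile <- function(x, w, q) {
  o <- order(x)
  x[o][which.max(cumsum(w[o]) / sum(w) >= q)]
}

# Gillespie simulation of one site along one branch. Returns the state path:
# list(states = vector of visited states (first = entry state), final).
.gillespie_branch <- function(model, state, t, rate) {
  events <- integer()
  if (rate > 0) {
    time <- 0
    repeat {
      out_rate <- -model$Q[state, state] * rate
      time <- time + stats::rexp(1L, out_rate)
      if (time >= t) break
      probs <- model$Q[state, ]
      probs[state] <- 0
      state <- sample.int(20L, 1L, prob = probs)
      events <- c(events, state)
    }
  }
  list(final = state, events = events)
}

#' Simulate a pair of sites with compensatory coevolution
#'
#' Site A evolves freely by Gillespie simulation along every branch. Whenever
#' a substitution event on a branch changes A's property by a nonzero
#' delta, then with probability `strength` site B substitutes on the same
#' branch to the residue whose property change is closest to -delta (ties
#' broken by the higher transition rate, then alphabet order). B's own,
#' uncoupled evolution happens on a branch with probability `1 - strength`
#' (and never on branches where it responded to A): at `strength = 0` the
#' pair is fully independent, at `strength = 1` site B is a pure responder
#' and the realized property changes mirror A's, giving near-perfect
#' compensation.
#'
#' @param tree Rooted `ape::phylo`.
#' @param model A `subst_model`.
#' @param prop An `aa_property`.
#' @param strength Compensation probability s in [0, 1]; 0 reduces to two
#'   independent sites.
#' @param seed Integer seed (`NULL`: use the current RNG state).
#' @param rate Rate multiplier of both sites.
#' @return List with `alignment` (2-column `aa_alignment`, site 1 = A,
#'   site 2 = B) and `truth`: per-branch realized property changes
#'   `delta_A`, `delta_B`, the number of compensatory jumps per branch, and
#'   the planted pair record.
#' @export
simulate_coevolving_pair <- function(tree, model, prop, strength = 1,
                                     seed = 1L, rate = 1) {
  stopifnot(strength >= 0, strength <= 1)
  tree <- read_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  pvec <- as.numeric(prop[names(model$freq)])
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  m <- nrow(edge)
  stA <- stB <- integer(nnode)
  root <- ntip + 1L
  # compensation conserves the pair's total property: B aims to restore
  # the root-state sum, which keeps a pure responder from drifting to the
  # property boundary where no compensating residue is reachable. The root
  # pair is drawn from the stationary distribution conditional on a
  # compensable joint state (pair sum in the central 50% of its stationary
  # distribution), emulating an established compensatory partnership.
  sums <- outer(pvec, pvec, "+")
  wts <- outer(as.numeric(model$freq), as.numeric(model$freq))
  qs <- c(.wtd_quantile(as.vector(sums), as.vector(wts), 0.25),
          .wtd_quantile(as.vector(sums), as.vector(wts), 0.75))
  repeat {
    stA[root] <- sample.int(20L, 1L, prob = model$freq)
    stB[root] <- sample.int(20L, 1L, prob = model$freq)
    sum0 <- pvec[stA[root]] + pvec[stB[root]]
    if (sum0 >= qs[1L] && sum0 <= qs[2L]) break
  }
  delta_A <- delta_B <- numeric(m)
  n_comp <- integer(m)
  for (e in seq_len(m)) {
    u <- edge[e, 1L]; v <- edge[e, 2L]
    t_e <- tree$edge.length[e]
    a <- .gillespie_branch(model, stA[u], t_e, rate)
    stA[v] <- a$final
    b_state <- stB[u]
    comp <- 0L
    triggered <- FALSE
    prev <- stA[u]
    for (ev in a$events) {
      delta <- pvec[ev] - pvec[prev]
      prev <- ev
      if (delta != 0 && stats::runif(1L) < strength) {
        triggered <- TRUE
        cand <- setdiff(which(model$Q[b_state, ] > 0), b_state)
        target <- sum0 - pvec[ev]
        miss <- abs(pvec[cand] - target)
        best <- cand[miss == min(miss)]
        if (length(best) > 1L) {
          best <- best[order(-model$Q[b_state, best], best)][1L]
        }
        if (abs(pvec[best] - target) < abs(pvec[b_state] - target)) {
          b_state <- best
          comp <- comp + 1L
        }
      }
    }
    if (!triggered && stats::runif(1L) >= strength) {
      b_state <- .gillespie_branch(model, stB[u], t_e, rate)$final
    }
    stB[v] <- b_state
    delta_A[e] <- pvec[stA[v]] - pvec[stA[u]]
    delta_B[e] <- pvec[stB[v]] - pvec[stB[u]]
    n_comp[e] <- comp
  }
  alpha <- aa_alphabet()
  mat <- cbind(alpha[stA[seq_len(ntip)]], alpha[stB[seq_len(ntip)]])
  rownames(mat) <- tree$tip.label
  list(alignment = aa_alignment(mat),
       truth = list(pair = c(1L, 2L), property = attr(prop, "name"),
                    strength = strength, delta_A = delta_A,
                    delta_B = delta_B, n_compensated = n_comp))
}

#' Simulate a family with planted compensatory pairs
#'
#' Builds an alignment of `n_sites` sites in which `n_pairs` site pairs are
#' generated by [simulate_coevolving_pair()] (occupying the first
#' `2 * n_pairs` columns, pair k at columns 2k-1, 2k) and the remaining
#' sites evolve independently with the given rate multipliers.
#'
#' @inheritParams simulate_coevolving_pair
#' @param n_sites Total number of sites.
#' @param n_pairs Number of planted pairs.
#' @param rate_multipliers Rate multipliers for the independent sites
#'   (recycled); planted sites evolve at rate 1.
#' @return List with `alignment` and `truth` (list of per-pair truth
#'   records; `truth$pairs` gives the planted column pairs).
#' @export
simulate_family <- function(tree, model, prop, n_sites, n_pairs = 1L,
                            strength = 1, rate_multipliers = 1, seed = 1L) {
  stopifnot(n_sites >= 2L * n_pairs)
  tree <- read_tree(tree)
  set.seed(seed)
  cols <- list(); truths <- list()
  for (k in seq_len(n_pairs)) {
    sim <- simulate_coevolving_pair(tree, model, prop, strength = strength,
                                    seed = NULL)
    cols[[k]] <- sim$alignment$matrix
    truths[[k]] <- sim$truth
  }
  n_ind <- n_sites - 2L * n_pairs
  ind <- if (n_ind > 0) {
    simulate_independent(tree, model, n_ind,
                         rate_multipliers = rate_multipliers)$matrix
  } else NULL
  mat <- do.call(cbind, c(cols, list(ind)))[tree$tip.label, , drop = FALSE]
  pairs <- lapply(seq_len(n_pairs), function(k) c(2L * k - 1L, 2L * k))
  list(alignment = aa_alignment(mat),
       truth = list(pairs = pairs, strength = strength,
                    property = attr(prop, "name"), per_pair = truths))
}

#' Build a toy protein structure table
#'
#' Places C-alpha coordinates so that `planted_contacts` pairs are within
#' 8 A (5 A spacing) and all other pairs are farther than 12 A apart, unless
#' the geometry dictates otherwise: `"clustered"` scatters sites on a wide
#' 3D grid (>= 13 A spacing) and pulls planted partners together;
#' `"helix-like"` uses ideal alpha-helical coordinates (2.3 A radius, 1.5 A
#' rise, 100 degrees per residue), so consecutive residues are in contact;
#' `"extended"` places sites on a line with the given spacing. RSA is drawn
#' uniformly, with `planted_buried` sites below 0.2. Secondary-structure
#' labels and element ids are assigned in contiguous runs according to
#' `ss_runs`.
#'
#' @param n_sites Number of sites (>= 2).
#' @param geometry `"clustered"`, `"helix-like"` or `"extended"`.
#' @param planted_contacts List of site-index pairs to place in contact.
#' @param planted_buried Site indices given RSA < 0.2.
#' @param spacing Consecutive spacing (A) for the extended geometry.
#' @param ss_runs Optional data frame (`label`, `length`) of secondary-
#'   structure runs covering the sites in order; default: all
#'   `"no structure"` for clustered/extended, one helix for helix-like.
#' @param seed Integer seed.
#' @return A `structure_table` data frame (site, x, y, z, rsa, ss_label,
#'   element_id, sheet_id, hotloop).
#' @export
build_toy_structure <- function(n_sites, geometry = c("clustered",
                                                      "helix-like",
                                                      "extended"),
                                planted_contacts = list(),
                                planted_buried = integer(),
                                spacing = 3.8, ss_runs = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_sites >= 2L)
  for (pr in planted_contacts) {
    if (length(pr) != 2L || pr[1L] == pr[2L] || any(pr > n_sites)) {
      stop("infeasible planted contact: ", paste(pr, collapse = ","))
    }
  }
  set.seed(seed)
  if (geometry == "clustered") {
    side <- ceiling(n_sites^(1 / 3))
    grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                  z = seq_len(side))) * 13
    xyz <- grid[seq_len(n_sites), , drop = FALSE]
    for (pr in planted_contacts) {
      # move the second member next to the first (5 A along x)
      xyz[pr[2L], ] <- xyz[pr[1L], ] + c(5, 0, 0)
    }
  } else if (geometry == "helix-like") {
    i <- seq_len(n_sites)
    theta <- (i - 1) * 100 * pi / 180
    xyz <- cbind(x = 2.3 * cos(theta), y = 2.3 * sin(theta),
                 z = (i - 1) * 1.5)
  } else {
    xyz <- cbind(x = (seq_len(n_sites) - 1) * spacing, y = 0, z = 0)
  }
  rsa <- stats::runif(n_sites, 0.2, 1)
  rsa[planted_buried] <- stats::runif(length(planted_buried), 0, 0.2)
  ss <- rep("no structure", n_sites)
  elem <- rep(NA_character_, n_sites)
  if (is.null(ss_runs) && geometry == "helix-like") {
    ss_runs <- data.frame(label = "alpha helix", length = n_sites)
  }
  if (!is.null(ss_runs)) {
    stopifnot(sum(ss_runs$length) == n_sites)
    pos <- 1L
    counter <- c("alpha helix" = 0L, "3-10 helix" = 0L, "pi helix" = 0L,
                 strand = 0L)
    for (r in seq_len(nrow(ss_runs))) {
      lab <- ss_runs$label[r]
      at <- pos:(pos + ss_runs$length[r] - 1L)
      ss[at] <- lab
      if (lab %in% names(counter)) {
        counter[lab] <- counter[lab] + 1L
        prefix <- if (lab == "strand") "E" else "H"
        elem[at] <- paste0(prefix, counter[lab])
      }
      pos <- pos + ss_runs$length[r]
    }
  }
  st <- data.frame(site = seq_len(n_sites), x = xyz[, 1L], y = xyz[, 2L],
                   z = xyz[, 3L], rsa = rsa, ss_label = ss,
                   element_id = elem, sheet_id = NA_character_,
                   hotloop = 0)
  structure(st, class = c("structure_table", "data.frame"))
}
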