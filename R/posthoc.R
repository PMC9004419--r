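# Branch-level characterization of a candidate group: per-branch
# compensation C_j, two permutation tests and the compensogram table.

.group_changes <- function(cm, group) {
  stopifnot(inherits(cm, "change_matrix"))
  group <- sort(unique(as.integer(group)))
  if (length(group) < 2L) stop("a group needs at least 2 sites")
  bad <- group[!cm$analyzable[group]]
  if (length(bad)) stop("non-analyzable site(s) in group: ",
                        paste(bad, collapse = ", "))
  cm$x[group, , drop = FALSE]
}

# C_j for every column of a sites x branches change matrix (NA where the
# branch carries no signal).
.branch_comp_all <- function(X, zero_tol = 1e-9) {
  tot <- colSums(abs(X))
  out <- 1 - abs(colSums(X)) / tot
  out[tot <= zero_tol] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Branch permutation test for a group's compensation profile
#'
#' Randomizes the branch assignment of every site's changes independently
#' (a random permutation of each site's change vector across branches),
#' conditioning on the total amount of change at each site, and recomputes
#' the branch compensation index C_j for every branch. Returns the
#' per-branch null mean and central 95\% interval.
#'
#' @param cm A `change_matrix`.
#' @param group Site indices (>= 2 analyzable sites).
#' @param n_perm Number of permutations (>= 20, otherwise the interval is
#'   meaningless).
#' @param seed Integer seed.
#' @return Data frame with one row per branch: `branch`, `observed` (C_j),
#'   `null_mean`, `null_lo`, `null_hi` (2.5 and 97.5 percentiles).
#' @export
permute_branches_test <- function(cm, group, n_perm = 1000L, seed = 1L) {
  if (n_perm < 20L) stop("n_perm must be >= 20")
  X <- .group_changes(cm, group)
  m <- ncol(X)
  set.seed(seed)
  draws <- matrix(NA_real_, n_perm, m)
  for (b in seq_len(n_perm)) {
    Xp <- t(apply(X, 1L, function(v) v[sample.int(m)]))
    draws[b, ] <- .branch_comp_all(Xp)
  }
  data.frame(
    branch = seq_len(m),
    observed = .branch_comp_all(X),
    null_mean = colMeans(draws, na.rm = TRUE),
    null_lo = apply(draws, 2L, stats::quantile, 0.025, na.rm = TRUE,
                    names = FALSE),
    null_hi = apply(draws, 2L, stats::quantile, 0.975, na.rm = TRUE,
                    names = FALSE)
  )
}

#' Site permutation test for branch-level compensation
#'
#' For each permutation, draws `|G|` sites uniformly without replacement
#' from the family's analyzable variable sites and recomputes C_j from
#' their changes on each branch (branch identity, hence branch length, held
#' fixed). Returns the per-branch null mean and 95\% upper bound, plus the
#' pooled values across branches.
#'
#' @param cm A `change_matrix`.
#' @param group Site indices (the group size sets the draw size).
#' @param branches Branch indices to evaluate (default: all).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `per_branch` (data frame: branch, observed, null_mean,
#'   null_hi = 95th percentile) and `pooled` (mean and 95th percentile of
#'   all branch draws combined).
#' @export
permute_sites_test <- function(cm, group, branches = NULL, n_perm = 1000L,
                               seed = 1L) {
  X <- .group_changes(cm, group)
  g <- nrow(X)
  pool <- setdiff(which(cm$analyzable & cm$variable), integer())
  if (length(pool) < 2L * g) {
    stop("pool of analyzable sites (", length(pool),
         ") too small for groups of size ", g)
  }
  m <- ncol(cm$x)
  if (is.null(branches)) branches <- seq_len(m)
  set.seed(seed)
  idx <- t(replicate(n_perm, sample(pool, g)))
  flat <- cm$x[as.vector(idx), branches, drop = FALSE]
  gid <- rep(seq_len(n_perm), times = g)
  sums <- rowsum(flat, gid)
  abssums <- rowsum(abs(flat), gid)
  Cj <- 1 - abs(sums) / abssums
  Cj[abssums <= 1e-9] <- NA_real_
  Cj <- pmin(pmax(Cj, 0), 1)
  obs <- .branch_comp_all(X)[branches]
  list(
    per_branch = data.frame(
      branch = branches,
      observed = obs,
      null_mean = colMeans(Cj, na.rm = TRUE),
      null_hi = apply(Cj, 2L, stats::quantile, 0.95, na.rm = TRUE,
                      names = FALSE)),
    pooled = c(mean = mean(Cj, na.rm = TRUE),
               upper95 = stats::quantile(Cj, 0.95, na.rm = TRUE,
                                         names = FALSE))
  )
}

#' Compensogram of a candidate group
#'
#' Branch-level characterization: per-branch signed changes, branch
#' compensation C_j, the two permutation nulls, and a ranking of branches
#' by compensation signal. The default ranking score is C_j times the total
#' absolute change on the branch (compensation weighted by signal
#' magnitude); `rank_by = "C"` ranks by the bare index. Branches with no
#' signal (undefined C_j) are flagged and excluded from the ranking.
#'
#' @param cm A `change_matrix`.
#' @param group Site indices of the group.
#' @param n_perm Permutations for each test.
#' @param seed Integer seed.
#' @param rank_by `"weighted"` (C_j x total |change|) or `"C"`.
#' @param display_states If `TRUE` and `cm` was built with
#'   `ancestral = TRUE`, attach the marginal ML states of each branch's
#'   parent and child nodes for the group sites. Display only: these states
#'   never feed any statistic.
#' @return Object of class `compensogram`: list with `branches` (data
#'   frame ranked by decreasing signal: branch, rank, C_j, weight,
#'   branch_length, site changes, permutation-null columns), `changes`
#'   (group sites x branches matrix), `site_test`, `branch_test` (pooled
#'   values), `group`, `property`.
#' @export
compensogram <- function(cm, group, n_perm = 1000L, seed = 1L,
                         rank_by = c("weighted", "C"),
                         display_states = FALSE) {
  rank_by <- match.arg(rank_by)
  X <- .group_changes(cm, group)
  group <- sort(unique(as.integer(group)))
  m <- ncol(X)
  Cj <- .branch_comp_all(X)
  weight <- Cj * colSums(abs(X))
  score <- if (rank_by == "weighted") weight else Cj
  bt <- permute_branches_test(cm, group, n_perm = n_perm, seed = seed)
  # in degenerate families the pool may be too small for the site test
  st <- tryCatch(
    permute_sites_test(cm, group, n_perm = n_perm, seed = seed + 1L),
    error = function(e) list(
      per_branch = data.frame(branch = seq_len(m),
                              observed = NA_real_, null_mean = NA_real_,
                              null_hi = NA_real_),
      pooled = c(mean = NA_real_, upper95 = NA_real_)))
  ord <- order(-score, seq_len(m), na.last = TRUE)
  br <- data.frame(
    branch = ord,
    rank = seq_len(m),
    C_j = Cj[ord],
    weight = weight[ord],
    branch_length = cm$tree$edge.length[ord],
    site_perm_mean = bt$null_mean[ord],
    site_perm_lo = bt$null_lo[ord],
    site_perm_hi = bt$null_hi[ord]
  )
  for (i in seq_along(group)) {
    br[[paste0("change_site", group[i])]] <- X[i, ord]
  }
  states <- NULL
  if (display_states) {
    if (is.null(cm$node_states)) {
      stop("change matrix was built without ancestral = TRUE")
    }
    cols <- match(as.character(group), colnames(cm$node_states))
    states <- list(
      parent = cm$node_states[cm$tree$edge[, 1L], cols, drop = FALSE],
      child = cm$node_states[cm$tree$edge[, 2L], cols, drop = FALSE])
  }
  structure(list(branches = br, changes = X, group = group,
                 property = cm$property,
                 branch_test_pooled = st$pooled,
                 site_test = bt, sites_perm = st$per_branch,
                 display_states = states, seed = seed),
            class = "compensogram")
}

#' @export
print.compensogram <- function(x, top = 10L, ...) {
  cat("Compensogram of group {", paste(x$group, collapse = ", "),
      "} (property '", x$property, "')\n", sep = "")
  cat("Branch permutation null (pooled): mean =",
      format(x$branch_test_pooled["mean"], digits = 3), ", 95% bound =",
      format(x$branch_test_pooled["upper95"], digits = 3), "\n")
  print(utils::head(x$branches, top), digits = 3)
  invisible(x)
}

#' Export the top branches of a compensogram as a long-format table
#'
#' One row per (branch, site): ready for heatmap/compensogram plotting.
#'
#' @param cg A `compensogram`.
#' @param top Number of top-ranked branches to keep (more than available:
#'   all branches, no padding).
#' @return Data frame with columns `rank`, `branch`, `site`, `change`,
#'   `C_j`, `branch_length`, `null_mean`, `null_lo`, `null_hi`.
#' @export
export_compensogram <- function(cg, top = 10L) {
  stopifnot(inherits(cg, "compensogram"))
  br <- cg$branches[!is.na(cg$branches$C_j), , drop = FALSE]
  br <- utils::head(br, top)
  g <- cg$group
  out <- do.call(rbind, lapply(seq_len(nrow(br)), function(i) {
    data.frame(rank = br$rank[i], branch = br$branch[i], site = g,
               change = as.numeric(
                 br[i, paste0("change_site", g), drop = TRUE]),
               C_j = br$C_j[i],
               branch_length = br$branch_length[i],
               null_mean = br$site_perm_mean[i],
               null_lo = br$site_perm_lo[i],
               null_hi = br$site_perm_hi[i])
  }))
  rownames(out) <- NULL
  out
}
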