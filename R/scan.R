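# Candidate-group detection, simulation null, empirical p-values, FDR
# control and the cross-property overlap test.

# Sites eligible for clustering: analyzable, variable, and carrying property
# change signal (vector norm above a relative tolerance).
.signal_sites <- function(cm, tol = 1e-9) {
  idx <- which(cm$analyzable & cm$variable)
  if (!length(idx)) return(integer())
  norms <- sqrt(rowSums(cm$x[idx, , drop = FALSE]^2))
  idx[norms > tol * max(norms, 1e-300)]
}

#' Candidate coevolving groups by hierarchical clustering
#'
#' Builds an agglomerative hierarchy (average linkage) of the variable
#' analyzable sites using the pairwise dissimilarity d(i, k) = 1 - C(\{i, k\})
#' and emits every nested cluster of the requested sizes as a candidate
#' group, together with its full-tree compensation index `C` (the quantity
#' reported for every group), `sum_norm` (the summed Euclidean norms of
#' the member change vectors), `min_norm` (the smallest), and the
#' detection score: the total branch-local mutually cancelled property
#' change,
#' \deqn{score = \sum_j (\sum_i |x_{ij}| - |\sum_i x_{ij}|)
#'   = \sum_j C_j(G) \sum_i |x_{ij}|,}
#' i.e. the sum over branches of the branch compensation index weighted by
#' the amount of change on the branch (the same weight that ranks branches
#' in a compensogram). C alone is scale-invariant, so a pair of sites with
#' negligible change can reach C ~ 1 by chance; the score measures the
#' amount of compensated change supporting the group and is the statistic
#' tested against the simulation null.
#'
#' @param cm A `change_matrix`.
#' @param sizes Candidate group sizes (default 2 to 10).
#' @return Data frame of class `candidate_groups` with columns `group_id`,
#'   `size`, `C`, `min_norm` and a list column `sites` of site-index
#'   vectors. Fewer than two eligible sites yield an empty result.
#' @export
cluster_candidates <- function(cm, sizes = 2:10) {
  stopifnot(inherits(cm, "change_matrix"))
  empty <- data.frame(group_id = integer(), size = integer(), C = numeric(),
                      sum_norm = numeric(), min_norm = numeric(),
                      score = numeric())
  empty$sites <- list()
  idx <- .signal_sites(cm)
  if (length(idx) < 2L) {
    return(structure(empty, class = c("candidate_groups", "data.frame")))
  }
  X <- cm$x[idx, , drop = FALSE]
  norms <- sqrt(rowSums(X^2))
  D <- 1 - .pairwise_compensation(X)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  members <- vector("list", nrow(X) - 1L)
  for (k in seq_len(nrow(X) - 1L)) {
    a <- hc$merge[k, 1L]; b <- hc$merge[k, 2L]
    members[[k]] <- c(if (a < 0) -a else members[[a]],
                      if (b < 0) -b else members[[b]])
  }
  keep <- which(lengths(members) %in% sizes)
  out <- data.frame(
    group_id = seq_along(keep),
    size = lengths(members[keep]),
    C = vapply(members[keep], function(g)
      compensation_index(X[g, , drop = FALSE]), 0),
    sum_norm = vapply(members[keep], function(g) sum(norms[g]), 0),
    min_norm = vapply(members[keep], function(g) min(norms[g]), 0),
    score = vapply(members[keep], function(g) {
      Xg <- X[g, , drop = FALSE]
      sum(colSums(abs(Xg)) - abs(colSums(Xg)))
    }, 0))
  out$sites <- lapply(members[keep], function(g) sort(idx[g]))
  structure(out[order(out$size, out$group_id), , drop = FALSE],
            class = c("candidate_groups", "data.frame"))
}

#' Simulation null ensemble for the compensation statistic
#'
#' Simulates alignments of independently evolving sites on the fixed tree
#' under the fitted model, conserving the phylogeny, the substitution
#' probabilities and the empirical site-rate distribution (each simulated
#' site receives the rate of an empirical site drawn with replacement).
#' Each simulation is passed through the same mapping and clustering
#' search, and every candidate group's size, compensation index and
#' detection score are recorded; the per-simulation maximal score per group
#' size (which controls for the selection effect of the clustering search)
#' provides the null draws.
#'
#' @param tree Rooted `ape::phylo`.
#' @param model A `subst_model`.
#' @param prop An `aa_property`.
#' @param site_rates Numeric vector of empirical site rates to resample
#'   (e.g. `site_rates(cm)$std_rate`).
#' @param n_sites Number of sites per simulated alignment.
#' @param n_sim Number of simulations (>= 1).
#' @param sizes Candidate group sizes.
#' @param seed Integer seed; the ensemble is bit-reproducible given the seed.
#' @return Object of class `null_ensemble`: list with `cand` (data frame
#'   `sim`, `size`, `C`, `score` over all candidates of all simulations),
#'   `stat` (n_sim x sizes matrix of per-simulation maximal score per
#'   size, with a conservative fallback to the overall per-simulation max
#'   when a size stratum is empty), `sizes`, `n_sim`, `seed`.
#' @export
simulate_null <- function(tree, model, prop, site_rates, n_sites, n_sim,
                          sizes = 2:10, seed = 1L) {
  if (n_sim < 1L) stop("n_sim must be >= 1")
  stopifnot(length(site_rates) >= 1L, all(site_rates >= 0))
  tree <- read_tree(tree)
  set.seed(seed)
  stat <- matrix(NA_real_, n_sim, length(sizes), dimnames = list(NULL, sizes))
  cand_list <- vector("list", n_sim)
  for (b in seq_len(n_sim)) {
    rates <- sample(site_rates, n_sites, replace = TRUE)
    aln <- simulate_independent(tree, model, n_sites, rates)
    cm <- substitution_mapping(aln, tree, model, prop, counts = FALSE)
    cand <- cluster_candidates(cm, sizes = sizes)
    if (nrow(cand)) {
      mx <- tapply(cand$score, factor(cand$size, levels = sizes), max)
      stat[b, ] <- ifelse(is.na(mx), max(cand$score), mx)
      cand_list[[b]] <- data.frame(sim = b, size = cand$size, C = cand$C,
                                   score = cand$score)
    } else {
      stat[b, ] <- 0   # no candidate at all: weakest possible draw
    }
  }
  structure(list(cand = do.call(rbind, cand_list), stat = stat,
                 sizes = sizes, n_sim = n_sim, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble:", x$n_sim, "simulations, group sizes",
      paste(range(x$sizes), collapse = "-"), "(seed", x$seed, ")\n")
  invisible(x)
}

#' Empirical p-value of a candidate group
#'
#' In the default pooled mode the null draws for a group of size k are the
#' detection scores of \emph{all} candidate groups of size k found across
#' the null simulations; the p-value is
#' \deqn{p = (\#\{draws \ge score\} + 1) / (n_{draws} + 1),}
#' with ties counting as exceeding (conservative). The selection effect of
#' the clustering search is then corrected at the FDR stage
#' ([simulation_fdr()]), which applies the identical p-value definition to
#' every null simulation. In `"max"` mode the draw for each simulation is
#' its maximal score per size (one draw per simulation, smallest
#' attainable p = 1/(n_sim + 1)); this mode corrects for selection in the
#' raw p itself and is automatically used when the ensemble carries no
#' per-candidate records.
#'
#' @param score Observed detection score(s) (`score` column of
#'   [cluster_candidates()]).
#' @param size Group size(s), matching a stratum of the ensemble.
#' @param null A `null_ensemble`.
#' @param mode `"pooled"` (default) or `"max"`.
#' @return Raw p-value(s).
#' @export
group_pvalue <- function(score, size, null, mode = c("pooled", "max")) {
  stopifnot(inherits(null, "null_ensemble"))
  mode <- match.arg(mode)
  if (is.null(null$cand)) mode <- "max"
  if (length(size) == 1L) size <- rep(size, length(score))
  vapply(seq_along(score), function(i) {
    col <- match(size[i], null$sizes)
    if (is.na(col)) stop("no null stratum for group size ", size[i])
    draws <- if (mode == "pooled") {
      null$cand$score[null$cand$size == size[i]]
    } else {
      null$stat[, col]
    }
    if (!length(draws)) draws <- null$stat[, col]
    (sum(draws >= score[i]) + 1) / (length(draws) + 1)
  }, 0)
}

# P-value of every *null* candidate under the same definition used for
# observed candidates. Pooled mode: rank of the score among all null
# candidates of the size (the candidate counting itself stands in for the
# observed add-one). Max mode: leave-one-out rank among the other
# simulations' per-size maxima. Vectorized per stratum.
.null_candidate_pvalues <- function(null, mode = "pooled") {
  nc <- null$cand
  if (is.null(nc) || !nrow(nc)) return(numeric())
  p <- numeric(nrow(nc))
  for (k in null$sizes) {
    rows <- which(nc$size == k)
    if (!length(rows)) next
    s <- nc$score[rows]
    if (mode == "pooled") {
      srt <- sort(s)
      p[rows] <- (length(s) - findInterval(s, srt, left.open = TRUE)) /
        length(s)
    } else {
      M <- null$stat[, match(k, null$sizes)]
      srt <- sort(M)
      p[rows] <- (null$n_sim -
                    findInterval(s, srt, left.open = TRUE)) / null$n_sim
    }
  }
  p
}

#' Simulation-based FDR for candidate group p-values
#'
#' Estimates, for each raw p-value threshold, the expected number of
#' candidate groups per family reaching it under the null (from the null
#' ensemble itself, each null candidate being assigned a p-value under the
#' identical definition used for observed candidates), and divides by
#' the observed count, monotonizing as in a step-up procedure. This is the
#' appropriate correction for the clustering search: unlike a plain BH
#' step-up over all nested candidates, it accounts for the strong
#' dependence among candidates and does not suffer from the empirical
#' p-value floor.
#'
#' @param pvalues Observed raw p-values.
#' @param null The `null_ensemble` the p-values were computed from.
#' @param mode The p-value mode used in [group_pvalue()]; must match.
#' @return Vector of FDR-adjusted values (same order), clipped to [0, 1].
#' @export
simulation_fdr <- function(pvalues, null, mode = c("pooled", "max")) {
  mode <- match.arg(mode)
  n <- length(pvalues)
  if (!n) return(numeric())
  null_p <- .null_candidate_pvalues(null, mode = mode)
  o <- order(pvalues)
  efp <- vapply(pvalues[o], function(t) sum(null_p <= t), 0) / null$n_sim
  fdr <- efp / seq_len(n)
  adj <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment applied within one family (and one property).
#'
#' @param pvalues Raw p-values in (0, 1].
#' @param fdr Target false discovery rate (default 1\%).
#' @return Data frame with `p`, `p_adj` and logical `significant`
#'   (`p_adj < fdr`).
#' @export
fdr_adjust <- function(pvalues, fdr = 0.01) {
  if (!length(pvalues)) {
    return(data.frame(p = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p_adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adj = p_adj, significant = p_adj < fdr)
}

# Resolve overlaps among significant candidates: order by raw p, then size,
# then lowest site index; greedily keep non-overlapping groups.
.select_groups <- function(cand) {
  if (!nrow(cand)) return(logical(0))
  first_site <- vapply(cand$sites, min, 0L)
  ord <- order(cand$p, cand$size, first_site)
  taken <- integer()
  sel <- logical(nrow(cand))
  for (i in ord) {
    if (!cand$significant[i]) next
    if (!length(intersect(cand$sites[[i]], taken))) {
      sel[i] <- TRUE
      taken <- c(taken, cand$sites[[i]])
    }
  }
  sel
}

#' Scan an alignment for coevolving site groups
#'
#' Full detection pipeline for one protein family: substitution mapping per
#' property, clustering into candidate groups, norm-conditioned
#' simulation-based p-values, FDR control, resolution of overlapping
#' significant groups (smallest raw p, then smallest size, then lowest site
#' index wins) and per-site coevolving flags.
#'
#' @param aln An `aa_alignment`.
#' @param tree Rooted `ape::phylo` (or Newick path).
#' @param model A `subst_model`.
#' @param properties Character vector of built-in property names and/or list
#'   of `aa_property` objects.
#' @param n_sim Simulations per null ensemble.
#' @param fdr Target FDR within family and property.
#' @param fdr_method `"simulation"` (default; expected false candidates
#'   estimated from the null ensemble, see [simulation_fdr()]) or `"BH"`
#'   (plain Benjamini-Hochberg over all candidates).
#' @param sizes Candidate group sizes.
#' @param seed Integer seed.
#' @param null Optional precomputed `null_ensemble` or named list of
#'   ensembles (one per property); when supplied, no simulations are run.
#' @return Object of class `scan_result`: list with `groups` (data frame:
#'   property, group_id, size, sites, C, min_norm, p, p_adj, significant,
#'   selected), `site_flags` (sites x properties logical matrix; a site is
#'   flagged iff it belongs to a selected significant group), `rates` (per
#'   property), `change_matrices`, `fdr`, `seed`.
#' @export
scan_coevolution <- function(aln, tree, model, properties = "klein_charge",
                             n_sim = 1000L, fdr = 0.01,
                             fdr_method = c("simulation", "BH"),
                             sizes = 2:10, seed = 1L, null = NULL) {
  fdr_method <- match.arg(fdr_method)
  properties <- resolve_properties(properties)
  tree <- read_tree(tree, aln)
  if (inherits(null, "null_ensemble")) {
    null <- stats::setNames(rep(list(null), length(properties)),
                            names(properties))
  }
  flags <- matrix(FALSE, aln$n_sites, length(properties),
                  dimnames = list(NULL, names(properties)))
  groups <- list(); cms <- list(); rates <- list()
  for (k in seq_along(properties)) {
    pname <- names(properties)[k]
    prop <- properties[[k]]
    cm <- substitution_mapping(aln, tree, model, prop, counts = TRUE)
    sr <- site_rates(cm)
    cand <- cluster_candidates(cm, sizes = sizes)
    nl <- if (!is.null(null)) null[[pname]] else
      simulate_null(tree, model, prop, sr$std_rate, n_sites = aln$n_sites,
                    n_sim = n_sim, sizes = sizes, seed = seed + k)
    if (is.null(nl)) stop("no null ensemble for property ", pname)
    if (nrow(cand)) {
      cand$p <- group_pvalue(cand$score, cand$size, nl)
      if (fdr_method == "simulation") {
        cand$p_adj <- simulation_fdr(cand$p, nl)
        cand$significant <- cand$p_adj < fdr
      } else {
        adj <- fdr_adjust(cand$p, fdr = fdr)
        cand$p_adj <- adj$p_adj
        cand$significant <- adj$significant
      }
      cand$selected <- .select_groups(cand)
      for (g in cand$sites[cand$selected]) flags[g, k] <- TRUE
      cand <- cbind(property = pname, cand)
    }
    groups[[pname]] <- cand
    cms[[pname]] <- cm
    rates[[pname]] <- sr
  }
  groups <- do.call(rbind, groups[vapply(groups, nrow, 0L) > 0])
  structure(list(groups = groups, site_flags = flags, rates = rates,
                 change_matrices = cms, analyzable = aln$analyzable,
                 fdr = fdr, seed = seed),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  nsel <- if (is.null(x$groups)) 0L else sum(x$groups$selected)
  cat("Coevolution scan:", ncol(x$site_flags), "properties,",
      sum(x$analyzable), "analyzable sites,", nsel,
      "significant non-overlapping groups,",
      sum(rowSums(x$site_flags) > 0), "coevolving sites\n")
  invisible(x)
}

#' Cross-property overlap of coevolving sites
#'
#' The statistic S is the number of sites flagged as coevolving by at least
#' two properties. Its null distribution is obtained by independently
#' permuting each property's flagged positions among the analyzable sites;
#' p = (x + 1)/(n_rand + 1), where x counts randomizations with S at least
#' as large as observed.
#'
#' @param flags Logical matrix (sites x properties), e.g.
#'   `scan_result$site_flags`, or a `scan_result`.
#' @param analyzable Logical mask of analyzable sites (taken from the scan
#'   result if one is supplied).
#' @param n_rand Number of randomizations (>= 1).
#' @param seed Integer seed.
#' @return List with `S`, `p`, `null` (the randomized S values).
#' @export
overlap_test <- function(flags, analyzable = NULL, n_rand = 10000L,
                         seed = 1L) {
  if (inherits(flags, "scan_result")) {
    analyzable <- flags$analyzable
    flags <- flags$site_flags
  }
  stopifnot(is.matrix(flags), ncol(flags) >= 2L)
  if (n_rand < 1L) stop("n_rand must be >= 1")
  if (is.null(analyzable)) analyzable <- rep(TRUE, nrow(flags))
  pool <- which(analyzable)
  counts <- colSums(flags)
  S_obs <- sum(rowSums(flags) >= 2L)
  set.seed(seed)
  S_null <- vapply(seq_len(n_rand), function(b) {
    hits <- integer(nrow(flags))
    for (k in seq_along(counts)) {
      if (counts[k] > 0) {
        drawn <- sample(pool, counts[k])
        hits[drawn] <- hits[drawn] + 1L
      }
    }
    sum(hits >= 2L)
  }, 0L)
  list(S = S_obs, p = (sum(S_null >= S_obs) + 1) / (n_rand + 1),
       null = S_null)
}
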