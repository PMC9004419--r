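# Structural statistics for detected groups: mean C-alpha distance,
# contact-graph connectivity (N_sub), secondary-structure co-location, and
# the Monte-Carlo conditional randomization machinery matched on
# evolutionary rate or solvent accessibility.

.ss_labels <- c("no structure", "alpha helix", "3-10 helix", "pi helix",
                "strand", "beta bridge", "turn", "bend", "disordered")
.ss_element_labels <- c("alpha helix", "3-10 helix", "pi helix", "strand")

#' Read a per-site structure annotation table
#'
#' Tab-separated, one row per analyzable site, columns `site`, `x`, `y`,
#' `z` (C-alpha coordinates, Angstrom), `rsa` (relative solvent
#' accessibility in [0, 1]), `ss_label` (one of no structure, alpha helix,
#' 3-10 helix, pi helix, strand, beta bridge, turn, bend, disordered),
#' optional `element_id` (helix/strand element; required for helix and
#' strand labels), `sheet_id` and `hotloop` (intrinsic-disorder index).
#' When a `hotloop` column is present, sites with hotloop > 0.1204 and no
#' secondary-structure motif are relabelled `disordered`.
#'
#' @param path TSV file path, or a data frame with the same columns.
#' @return A `structure_table` data frame. Alignment sites absent from the
#'   table are simply not annotated; downstream tests exclude groups
#'   containing them.
#' @export
read_structure_table <- function(path) {
  st <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  need <- c("site", "x", "y", "z", "rsa", "ss_label")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("structure table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"element_id" %in% names(st)) st$element_id <- NA_character_
  if (!"sheet_id" %in% names(st)) st$sheet_id <- NA_character_
  if (!"hotloop" %in% names(st)) st$hotloop <- NA_real_
  st$element_id[!is.na(st$element_id) & st$element_id == ""] <- NA
  st$sheet_id[!is.na(st$sheet_id) & st$sheet_id == ""] <- NA
  if (anyDuplicated(st$site)) stop("duplicated site in structure table")
  if (!all(is.finite(st$x) & is.finite(st$y) & is.finite(st$z))) {
    stop("malformed C-alpha coordinates (non-finite values)")
  }
  if (any(st$rsa < 0 | st$rsa > 1)) {
    stop("RSA outside [0, 1] at site(s): ",
         paste(st$site[st$rsa < 0 | st$rsa > 1], collapse = ", "))
  }
  if (!all(st$ss_label %in% .ss_labels)) {
    stop("unknown secondary-structure label(s): ",
         paste(unique(setdiff(st$ss_label, .ss_labels)), collapse = ", "))
  }
  needs_elem <- st$ss_label %in% .ss_element_labels
  if (any(needs_elem & is.na(st$element_id))) {
    stop("helix/strand site(s) without element id: ",
         paste(st$site[needs_elem & is.na(st$element_id)], collapse = ", "))
  }
  # disorder integration: hotloop > 0.1204 and no DSSP motif
  motif <- st$ss_label != "no structure"
  dis <- !is.na(st$hotloop) & st$hotloop > 0.1204 & !motif
  st$ss_label[dis] <- "disordered"
  class(st) <- c("structure_table", "data.frame")
  st
}

.st_lookup <- function(st, sites) {
  idx <- match(sites, st$site)
  if (anyNA(idx)) {
    stop("site(s) without structure annotation: ",
         paste(sites[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Mean pairwise C-alpha distance of a group
#'
#' @param group Site indices (>= 2).
#' @param st A `structure_table`.
#' @return Mean over all unordered site pairs of the Euclidean C-alpha
#'   distance, in Angstrom.
#' @export
mean_ca_distance <- function(group, st) {
  if (length(group) < 2L) stop("a group needs at least 2 sites")
  idx <- .st_lookup(st, group)
  mean(stats::dist(as.matrix(st[idx, c("x", "y", "z")])))
}

#' Standardized number of contact subgraphs of a group
#'
#' Builds the contact graph of the group (edge iff C-alpha distance <=
#' `contact_threshold`), counts its connected components c and returns
#' (c - 1)/(|G| - 1): 0 when all residues are in (possibly indirect)
#' contact, 1 when all are isolated. Adding an edge never increases the
#' value.
#'
#' @param group Site indices (>= 2).
#' @param st A `structure_table`.
#' @param contact_threshold Contact distance in Angstrom (default 8; 5 and
#'   10 are conventional alternatives for contact-count annotation).
#' @return N_sub in [0, 1].
#' @export
n_sub <- function(group, st, contact_threshold = 8) {
  if (length(group) < 2L) stop("a group needs at least 2 sites")
  idx <- .st_lookup(st, group)
  D <- as.matrix(stats::dist(as.matrix(st[idx, c("x", "y", "z")])))
  A <- (D <= contact_threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  (igraph::components(g)$no - 1) / (length(group) - 1)
}

#' Sampler configuration for conditional randomization
#'
#' @param conditioning `"none"`, `"rate"` or `"rsa"`.
#' @param similarity Relative similarity threshold (default 0.1 = 10\%):
#'   candidate sites must satisfy |v - v0| / v0 <= similarity, v0 being the
#'   focus site's conditioning value.
#' @param min_pool Minimum number of similar sites per focus site (default
#'   5); groups with a smaller pool are excluded from the test.
#' @param replicates Monte-Carlo replicates (default 1000).
#' @param max_retry Resampling attempts before a group is excluded because
#'   within-group duplication could not be avoided.
#' @param seed Integer seed.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(conditioning = c("none", "rate", "rsa"),
                           similarity = 0.1, min_pool = 5L,
                           replicates = 1000L, max_retry = 100L, seed = 1L) {
  conditioning <- match.arg(conditioning)
  stopifnot(similarity > 0, replicates >= 1L, min_pool >= 1L)
  structure(list(conditioning = conditioning, similarity = similarity,
                 min_pool = as.integer(min_pool),
                 replicates = as.integer(replicates),
                 max_retry = as.integer(max_retry), seed = as.integer(seed)),
            class = "sampler_config")
}

# Candidate sites for one focus value: similarity filter plus balancing of
# the below/above counts (the larger side is uniformly downsampled; ties at
# the focus value are always kept; a one-sided candidate set is retained).
.similar_sites <- function(pool_sites, pool_values, v0, similarity) {
  if (v0 == 0) {
    keep <- pool_values == 0
  } else {
    keep <- abs(pool_values - v0) / abs(v0) <= similarity
  }
  pool_sites[keep]
}

.balance_sides <- function(cand_sites, cand_values, v0) {
  below <- cand_sites[cand_values < v0]
  above <- cand_sites[cand_values > v0]
  equal <- cand_sites[cand_values == v0]
  k <- min(length(below), length(above))
  if (length(below) > k) below <- sample(below, k)
  if (length(above) > k) above <- sample(above, k)
  c(equal, below, above)
}

#' Conditionally sample a pseudo-group matched to an observed group
#'
#' For each focus site of the group, candidate sites are the pool sites
#' whose conditioning value differs from the focus value by at most the
#' relative similarity threshold; the candidate set is balanced so that it
#' holds as many values below as above the focus value (the larger side is
#' uniformly downsampled; if all candidates fall on one side they are
#' retained), and one candidate is drawn uniformly. No site may appear
#' twice within one sampled group (bounded resampling, then exclusion).
#' With conditioning `"none"`, sites are drawn uniformly from the pool
#' without replacement.
#'
#' @param group Focus site indices.
#' @param pool Data frame with columns `site` and `value` (conditioning
#'   values of the family's analyzable sites).
#' @param cfg A `sampler_config`.
#' @return Integer vector of sampled sites, or `NULL` if the group is
#'   excluded (a focus site with fewer than `min_pool` similar sites, or
#'   irreducible duplication).
#' @export
conditional_sample <- function(group, pool, cfg = sampler_config()) {
  if (cfg$conditioning == "none") {
    if (nrow(pool) < length(group)) return(NULL)
    return(sample(pool$site, length(group)))
  }
  v <- stats::setNames(pool$value, pool$site)
  cands <- lapply(group, function(s) {
    v0 <- v[as.character(s)]
    if (is.na(v0)) return(integer())
    .similar_sites(pool$site, pool$value, v0, cfg$similarity)
  })
  if (any(lengths(cands) < cfg$min_pool)) return(NULL)
  for (attempt in seq_len(cfg$max_retry)) {
    drawn <- integer(length(group))
    ok <- TRUE
    for (i in seq_along(group)) {
      set <- .balance_sides(cands[[i]], v[as.character(cands[[i]])],
                            v[as.character(group[i])])
      set <- setdiff(set, drawn[seq_len(i - 1L)])
      if (!length(set)) { ok <- FALSE; break }
      drawn[i] <- if (length(set) == 1L) set else sample(set, 1L)
    }
    if (ok) return(drawn)
  }
  NULL
}

# Shared Monte-Carlo engine: observed statistic averaged over non-excluded
# groups vs. replicates where every group is replaced by a conditional
# sample. One-sided lower-tail p with the add-one estimator.
.mc_group_test <- function(groups, pool, cfg, stat_fun) {
  obs <- vapply(groups, function(g) tryCatch(stat_fun(g),
                                             error = function(e) NA_real_),
                0)
  usable <- !is.na(obs)
  set.seed(cfg$seed)
  keep <- usable & vapply(groups, function(g)
    !is.null(conditional_sample(g, pool, cfg)), TRUE)
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("all groups excluded from the randomization test")
  groups <- groups[keep]
  observed <- mean(obs[keep])
  set.seed(cfg$seed + 1L)
  null <- vapply(seq_len(cfg$replicates), function(b) {
    vals <- vapply(groups, function(g) {
      s <- conditional_sample(g, pool, cfg)
      if (is.null(s)) return(NA_real_)
      stat_fun(s)
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  if (all(is.na(null))) stop("no successful replicate")
  p <- (sum(null <= observed, na.rm = TRUE) + 1) / (sum(!is.na(null)) + 1)
  list(observed = observed, null = null, p = p, n_groups = sum(keep),
       n_excluded = n_excluded)
}

#' Structural proximity test for detected groups
#'
#' Tests whether groups of coevolving sites are closer in the 3D structure
#' than conditionally matched random groups: the observed statistic (mean
#' pairwise C-alpha distance, or the standardized contact-subgraph count
#' N_sub averaged over groups) is compared with `cfg$replicates` Monte-
#' Carlo replicates in which every group is replaced by a conditional
#' sample matched on rate or RSA. One-sided lower tail (proximity
#' hypothesis); p = (N + 1)/(replicates + 1).
#'
#' @param groups List of site-index vectors (>= 1 group).
#' @param st A `structure_table`.
#' @param pool Data frame `site`, `value` of conditioning values (e.g.
#'   standardized rates, or RSA) over the family's analyzable sites; for
#'   conditioning `"none"` only `site` is used.
#' @param cfg A `sampler_config`.
#' @param statistic `"mean_distance"` or `"n_sub"`.
#' @param contact_threshold Contact threshold for `"n_sub"` (default 8 A).
#' @return List of class `structure_test`: `statistic`, `observed`, `null`
#'   (replicate values), `p`, `n_groups`, `n_excluded`.
#' @export
proximity_test <- function(groups, st, pool, cfg = sampler_config(),
                           statistic = c("mean_distance", "n_sub"),
                           contact_threshold = 8) {
  statistic <- match.arg(statistic)
  stopifnot(length(groups) >= 1L)
  fun <- switch(statistic,
                mean_distance = function(g) mean_ca_distance(g, st),
                n_sub = function(g) n_sub(g, st, contact_threshold))
  res <- .mc_group_test(groups, pool, cfg, fun)
  structure(c(list(statistic = statistic), res), class = "structure_test")
}

#' @export
print.structure_test <- function(x, ...) {
  cat("Structural randomization test (", x$statistic, "): observed = ",
      format(x$observed, digits = 4), ", null mean = ",
      format(mean(x$null, na.rm = TRUE), digits = 4), ", p = ",
      format(x$p, digits = 4), " (", x$n_groups, " groups, ",
      x$n_excluded, " excluded)\n", sep = "")
  invisible(x)
}

# Element ids for the co-location statistic: within-motif "contact" means
# sharing an element (helix or strand number, or sheet; strands without a
# sheet id count as singleton sheets).
.motif_elements <- function(st, motif) {
  if (motif == "helix") {
    sel <- st$ss_label %in% c("alpha helix", "3-10 helix", "pi helix")
    elem <- st$element_id
  } else if (motif == "strand") {
    sel <- st$ss_label == "strand"
    elem <- st$element_id
  } else {
    sel <- st$ss_label == "strand"
    elem <- ifelse(is.na(st$sheet_id),
                   paste0("singleton_", st$element_id), st$sheet_id)
  }
  stats::setNames(elem[sel], st$site[sel])
}

#' Secondary-structure co-location test
#'
#' Restricts each group (and the sampling pool) to sites within the motif
#' class (`"helix"`: alpha/3-10/pi helices; `"strand"`; `"sheet"`: strand
#' sites grouped by sheet id, strands without a sheet id counting as
#' singleton sheets), treats two sites as "in contact" when they share an
#' element, and computes the same (c - 1)/(size - 1) statistic: 0 when all
#' sites of a group lie in the same element, 1 when each site is in a
#' distinct element. Conditional sampling and the one-sided lower-tail p
#' as in [proximity_test()]. Groups with fewer than 2 in-motif sites are
#' dropped.
#'
#' @param groups List of site-index vectors.
#' @param st A `structure_table`.
#' @param pool Data frame `site`, `value` of conditioning values; it is
#'   intersected with the in-motif sites.
#' @param cfg A `sampler_config`.
#' @param motif `"helix"`, `"strand"` or `"sheet"`.
#' @return A `structure_test` (statistic `"ss_colocation"`), plus
#'   `n_dropped`, the number of groups with fewer than 2 in-motif sites.
#' @export
ss_colocation_test <- function(groups, st, pool, cfg = sampler_config(),
                               motif = c("helix", "strand", "sheet")) {
  motif <- match.arg(motif)
  elem <- .motif_elements(st, motif)
  insites <- as.integer(names(elem))
  red <- lapply(groups, function(g) intersect(g, insites))
  keep <- lengths(red) >= 2L
  if (!any(keep)) stop("no group with >= 2 sites in motif class '",
                       motif, "'")
  pool <- pool[pool$site %in% insites, , drop = FALSE]
  fun <- function(g) {
    e <- elem[as.character(g)]
    (length(unique(e)) - 1) / (length(g) - 1)
  }
  res <- .mc_group_test(red[keep], pool, cfg, fun)
  structure(c(list(statistic = "ss_colocation", motif = motif),
              res, n_dropped = sum(!keep)),
            class = "structure_test")
}
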