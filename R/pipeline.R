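# End-to-end orchestration: scan a family, post-hoc characterization and
# structural tests, with deterministic TSV outputs that embed the seed and
# a configuration hash.

# Small polynomial hash of a deparsed object; enough to fingerprint a run
# configuration in output headers.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

.write_tsv <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed, "  config: ", cfg_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.flatten_groups <- function(groups) {
  if (is.null(groups) || !nrow(groups)) {
    return(data.frame(property = character(), group_id = integer(),
                      size = integer(), sites = character(), C = numeric(),
                      score = numeric(), p = numeric(), p_adj = numeric(),
                      significant = logical(), selected = logical()))
  }
  data.frame(property = groups$property, group_id = groups$group_id,
             size = groups$size,
             sites = vapply(groups$sites, paste, "", collapse = ","),
             C = groups$C, score = groups$score, p = groups$p,
             p_adj = groups$p_adj, significant = groups$significant,
             selected = groups$selected)
}

#' Run a coevolution scan and export its tables
#'
#' Thin orchestration over [scan_coevolution()]: reads the alignment and
#' tree if paths are given, runs the per-property scan, and (optionally)
#' writes two TSV files to `out_dir`: `sites.tsv` (per analyzable site:
#' raw and standardized rate per property, coevolving flags, and RSA /
#' secondary structure when a structure table is supplied — the per-site
#' table a downstream regression would consume) and `groups.tsv` (one row
#' per candidate group). Output files embed the seed and a configuration
#' hash; identical inputs give byte-identical files.
#'
#' @param alignment FASTA path or `aa_alignment`.
#' @param tree Newick path or `ape::phylo`.
#' @param model A `subst_model` (default LG with four gamma categories).
#' @param properties Built-in property names and/or `aa_property` list.
#' @param structure Optional structure table (TSV path or
#'   `structure_table`); if missing, structural columns are omitted with a
#'   warning.
#' @param n_sim,fdr,sizes,seed,null Passed to [scan_coevolution()].
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return The `scan_result`, invisibly augmented with `site_table` and
#'   `group_table` data frames and `files` (paths written).
#' @export
run_scan <- function(alignment, tree, model = subst_model("LG"),
                     properties = c("grantham_volume", "klein_charge"),
                     structure = NULL, n_sim = 1000L, fdr = 0.01,
                     sizes = 2:10, seed = 1L, null = NULL, out_dir = NULL) {
  aln <- if (inherits(alignment, "aa_alignment")) alignment else
    read_alignment(alignment)
  tree <- read_tree(tree, aln)
  st <- NULL
  if (!is.null(structure)) {
    st <- if (inherits(structure, "structure_table")) structure else
      read_structure_table(structure)
  } else {
    warning("no structure table supplied; structural columns omitted")
  }
  cfg <- list(properties = properties, n_sim = n_sim, fdr = fdr,
              sizes = sizes, seed = seed, model = model$name,
              gamma_shape = model$gamma_shape, ncat = model$ncat)
  hash <- .config_hash(cfg)
  scan <- scan_coevolution(aln, tree, model, properties = properties,
                           n_sim = n_sim, fdr = fdr, sizes = sizes,
                           seed = seed, null = null)
  sites <- data.frame(site = which(aln$analyzable))
  for (pname in names(scan$rates)) {
    sr <- scan$rates[[pname]]
    sites[[paste0("rate_", pname)]] <- sr$raw_rate[match(sites$site, sr$site)]
    sites[[paste0("std_rate_", pname)]] <-
      sr$std_rate[match(sites$site, sr$site)]
    sites[[paste0("coevolving_", pname)]] <- scan$site_flags[sites$site, pname]
  }
  if (!is.null(st)) {
    idx <- match(sites$site, st$site)
    sites$rsa <- st$rsa[idx]
    sites$ss_label <- st$ss_label[idx]
    sites$element_id <- st$element_id[idx]
  }
  gt <- .flatten_groups(scan$groups)
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(sites = .write_tsv(sites, file.path(out_dir, "sites.tsv"),
                                  seed, hash),
               groups = .write_tsv(gt, file.path(out_dir, "groups.tsv"),
                                   seed, hash))
  }
  scan$site_table <- sites
  scan$group_table <- gt
  scan$config_hash <- hash
  scan$files <- files
  invisible(scan)
}

#' Post-hoc branch-level characterization of one detected group
#'
#' Builds the compensogram of a group from a finished scan and optionally
#' writes `compensogram_<property>_<id>.tsv` (long format, top branches).
#'
#' @param scan A `scan_result` from [run_scan()]/[scan_coevolution()].
#' @param group_id Group id within `property` (as in the groups table).
#' @param property Property name (default: the scan's first property).
#' @param n_perm Permutations for the two tests.
#' @param top Branches to export (default 10).
#' @param seed Integer seed.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return The `compensogram`, invisibly augmented with `table` and `file`.
#' @export
run_posthoc <- function(scan, group_id, property = NULL, n_perm = 1000L,
                        top = 10L, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (is.null(property)) property <- colnames(scan$site_flags)[1L]
  g <- scan$groups[scan$groups$property == property &
                     scan$groups$group_id == group_id, ]
  if (!nrow(g)) stop("unknown group id ", group_id, " for property ",
                     property)
  cg <- compensogram(scan$change_matrices[[property]], g$sites[[1L]],
                     n_perm = n_perm, seed = seed)
  tab <- export_compensogram(cg, top = top)
  cg$table <- tab
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cg$file <- .write_tsv(tab, file.path(out_dir,
                                         sprintf("compensogram_%s_%d.tsv",
                                                 property, group_id)),
                          seed, scan$config_hash %||% "none")
  }
  invisible(cg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structural tests for all detected groups of a scan
#'
#' Runs the proximity tests (mean C-alpha distance and N_sub) and the
#' secondary-structure co-location tests for the selected significant
#' groups of each property, with conditioning `"none"`, `"rate"` and
#' `"rsa"`, and reports exclusion counts. Optionally writes
#' `structure_tests.tsv`.
#'
#' @param scan A `scan_result`.
#' @param structure Structure table (path or `structure_table`).
#' @param cfg Base `sampler_config`; its `conditioning` field is
#'   overridden by each requested mode.
#' @param conditioning Conditioning modes to run.
#' @param motifs Motif classes for the co-location tests (set to
#'   `character()` to skip).
#' @param property Properties to test (default: all scanned).
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return Data frame of class `structure_test_table`: one row per
#'   (property, test, conditioning): observed, null mean, null 2.5/97.5
#'   percentiles, p, n_groups, n_excluded.
#' @export
run_structure_tests <- function(scan, structure, cfg = sampler_config(),
                                conditioning = c("none", "rate", "rsa"),
                                motifs = c("helix", "strand", "sheet"),
                                property = NULL, out_dir = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  st <- if (inherits(structure, "structure_table")) structure else
    read_structure_table(structure)
  if (is.null(property)) property <- colnames(scan$site_flags)
  rows <- list()
  for (pname in property) {
    gr <- scan$groups[scan$groups$property == pname & scan$groups$selected, ]
    if (!nrow(gr)) next
    groups <- gr$sites
    sr <- scan$rates[[pname]]
    for (cond in conditioning) {
      pool <- switch(cond,
        none = data.frame(site = sr$site, value = 0),
        rate = data.frame(site = sr$site, value = sr$std_rate),
        rsa = data.frame(site = st$site, value = st$rsa))
      pool <- pool[pool$site %in% st$site, , drop = FALSE]
      ccfg <- cfg
      ccfg$conditioning <- cond
      for (statname in c("mean_distance", "n_sub")) {
        res <- tryCatch(
          proximity_test(groups, st, pool, ccfg, statistic = statname),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- .st_row(pname, statname, cond, res)
      }
      for (motif in motifs) {
        res <- tryCatch(
          ss_colocation_test(groups, st, pool, ccfg, motif = motif),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- .st_row(pname,
                                             paste0("colocation_", motif),
                                             cond, res)
      }
    }
  }
  if (!length(rows)) stop("no selected group to test")
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(out, file.path(out_dir, "structure_tests.tsv"),
               cfg$seed, scan$config_hash %||% "none")
  }
  class(out) <- c("structure_test_table", "data.frame")
  out
}

.st_row <- function(property, test, conditioning, res) {
  if (is.null(res)) {
    return(data.frame(property = property, test = test,
                      conditioning = conditioning, observed = NA_real_,
                      null_mean = NA_real_, null_lo = NA_real_,
                      null_hi = NA_real_, p = NA_real_, n_groups = 0L,
                      n_excluded = NA_integer_))
  }
  data.frame(property = property, test = test, conditioning = conditioning,
             observed = res$observed,
             null_mean = mean(res$null, na.rm = TRUE),
             null_lo = stats::quantile(res$null, 0.025, na.rm = TRUE,
                                       names = FALSE),
             null_hi = stats::quantile(res$null, 0.975, na.rm = TRUE,
                                       names = FALSE),
             p = res$p, n_groups = res$n_groups,
             n_excluded = res$n_excluded)
}
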