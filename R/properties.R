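# Amino-acid biochemical property tables and per-substitution weights.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues in the conventional order used throughout the
#' package (the same ordering as empirical substitution-model matrices).
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Load an amino-acid property table
#'
#' Reads a two-column TSV (header required; columns: one-letter residue code,
#' numeric value) into an `aa_property` object. The table must cover all 20
#' standard residues exactly once. Non-standard residues (B, Z, X, U, O) and
#' gaps are never given property values; sites containing them are treated as
#' missing data upstream.
#'
#' @param path Path to the TSV file.
#' @param name Short identifier for the property (e.g. `"grantham_volume"`).
#' @param kind `"continuous"` or `"discrete"`. Discrete properties may take at
#'   most 3 distinct values.
#' @return An object of class `aa_property`: a named numeric vector of length
#'   20 with attributes `name` and `kind`.
#' @export
load_aa_property <- function(path, name, kind = c("continuous", "discrete")) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  if (ncol(tab) < 2L) stop("property table must have two columns")
  res <- toupper(trimws(tab[[1L]]))
  suppressWarnings(val <- as.numeric(tab[[2L]]))
  if (anyNA(val)) {
    stop("non-numeric property value for residue(s): ",
         paste(res[is.na(val)], collapse = ", "))
  }
  aa_property(stats::setNames(val, res), name = name, kind = kind)
}

#' Construct an amino-acid property from a named vector
#'
#' @param values Named numeric vector; names are one-letter residue codes and
#'   must cover the 20 standard residues exactly.
#' @param name Property identifier.
#' @param kind `"continuous"` or `"discrete"`.
#' @return An `aa_property` object.
#' @export
aa_property <- function(values, name, kind = c("continuous", "discrete")) {
  kind <- match.arg(kind)
  alpha <- aa_alphabet()
  if (is.null(names(values))) stop("property values must be named by residue")
  if (anyDuplicated(names(values))) stop("duplicated residue in property table")
  missing <- setdiff(alpha, names(values))
  if (length(missing)) {
    stop("property table incomplete; missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(values), alpha)
  if (length(extra)) {
    stop("unknown residue(s) in property table: ", paste(extra, collapse = ", "))
  }
  values <- values[alpha]
  if (!all(is.finite(values))) stop("property values must be finite")
  if (kind == "discrete" && length(unique(values)) > 3L) {
    stop("discrete properties may take at most 3 distinct values")
  }
  structure(values, name = name, kind = kind, class = "aa_property")
}

#' Built-in amino-acid properties
#'
#' Returns one of the property tables shipped with the package:
#' `"grantham_volume"` (residue volume), `"grantham_polarity"` (polarity),
#' `"klein_charge"` (net charge, a three-state discrete property taking values
#' in \{-1, 0, +1\}), or `"synthetic_index_example"`, a placeholder continuous
#' index illustrating how user-supplied synthetic indices (e.g. centers of
#' AAindex property clusters) plug into the pipeline via [load_aa_property()].
#'
#' @param name Property identifier.
#' @return An `aa_property` object.
#' @export
builtin_property <- function(name = c("grantham_volume", "grantham_polarity",
                                      "klein_charge",
                                      "synthetic_index_example")) {
  name <- match.arg(name)
  kind <- if (name == "klein_charge") "discrete" else "continuous"
  path <- system.file("extdata", paste0(name, ".tsv"), package = "compmap",
                      mustWork = TRUE)
  load_aa_property(path, name = name, kind = kind)
}

#' @export
print.aa_property <- function(x, ...) {
  cat("Amino-acid property '", attr(x, "name"), "' (", attr(x, "kind"), ")\n",
      sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

.check_residue <- function(aa) {
  bad <- setdiff(aa, aa_alphabet())
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "),
         " (only the 20 standard residues carry property values)")
  }
  invisible(aa)
}

#' Signed property weight of a substitution
#'
#' The signed change `P(to) - P(from)` of a biochemical property for a single
#' substitution. Antisymmetric by construction: `substitution_weight(p, a, b)
#' == -substitution_weight(p, b, a)`, and zero on the diagonal. Evolutionary
#' rate computations take the absolute value of this weight.
#'
#' @param prop An `aa_property`.
#' @param from,to One-letter residue codes (vectorized).
#' @return Numeric vector of signed property differences.
#' @export
substitution_weight <- function(prop, from, to) {
  stopifnot(inherits(prop, "aa_property"))
  from <- toupper(from); to <- toupper(to)
  .check_residue(c(from, to))
  as.numeric(prop[to]) - as.numeric(prop[from])
}

# Category assignments for the three-state discretization of volume and
# polarity. Codes 0/1/2 follow increasing property order.
.volume_categories <- list(
  small  = c("G", "A", "S", "P"),
  medium = c("D", "C", "N", "T", "E", "Q", "V"),
  large  = c("H", "M", "I", "L", "K", "R", "F", "Y", "W")
)
.polarity_categories <- list(
  hydrophobic  = c("L", "I", "F", "W", "C", "M", "V", "Y"),
  intermediate = c("P", "A", "T", "G", "S"),
  polar        = c("H", "Q", "R", "K", "N", "E", "D")
)

#' Discretize the volume or polarity property into three categories
#'
#' Residue volume is coded small/medium/large and polarity
#' hydrophobic/intermediate/polar, with numeric codes 0/1/2 assigned in
#' increasing property order. Volume: G, A, S, P small; D, C, N, T, E, Q, V
#' medium; H, M, I, L, K, R, F, Y, W large. Polarity: L, I, F, W, C, M, V, Y
#' hydrophobic; P, A, T, G, S intermediate; H, Q, R, K, N, E, D polar. Charge
#' is intrinsically three-state and needs no discretization.
#'
#' @param prop_name `"volume"` or `"polarity"`.
#' @return A discrete `aa_property` with values 0/1/2 and a `categories`
#'   attribute mapping each residue to its category label.
#' @export
discretize_property <- function(prop_name = c("volume", "polarity")) {
  prop_name <- match.arg(prop_name)
  cats <- switch(prop_name,
                 volume = .volume_categories,
                 polarity = .polarity_categories)
  labels <- rep(names(cats), lengths(cats))
  residues <- unlist(cats, use.names = FALSE)
  code <- stats::setNames(rep(seq_along(cats) - 1, lengths(cats)), residues)
  out <- aa_property(code, name = paste0(prop_name, "_discrete"),
                     kind = "discrete")
  attr(out, "categories") <- stats::setNames(labels, residues)[aa_alphabet()]
  out
}

#' Resolve a list of property specifications
#'
#' Accepts a character vector of built-in names and/or a named list of
#' `aa_property` objects, returning a named list of `aa_property` objects.
#'
#' @param properties Character vector, a single `aa_property`, or a list.
#' @return Named list of `aa_property` objects.
#' @export
resolve_properties <- function(properties) {
  if (inherits(properties, "aa_property")) properties <- list(properties)
  if (is.character(properties)) properties <- lapply(properties, builtin_property)
  stopifnot(all(vapply(properties, inherits, TRUE, "aa_property")))
  names(properties) <- vapply(properties, attr, "", "name")
  properties
}
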