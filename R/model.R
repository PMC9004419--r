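# Amino-acid substitution models: rate matrix assembly, eigendecomposition,
# transition probabilities and the integrals needed for expected substitution
# counts along a branch.

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of a mean-one gamma distribution, each
#' category represented by the mean rate within its quantile bin.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  stopifnot(shape > 0, ncat >= 1L)
  if (ncat == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape = shape,
                     rate = shape)
  # mean within each bin: incomplete-gamma identity with shape + 1
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  ncat * diff(p)
}

#' Build an amino-acid substitution model
#'
#' Assembles a time-reversible 20-state substitution model from
#' exchangeabilities and stationary frequencies, scaled to one expected
#' substitution per unit branch length at rate 1, with discrete-gamma
#' rate variation across sites.
#'
#' `"LG"` uses the LG empirical exchangeability matrix and its stationary
#' frequencies; `"Poisson"` uses equal exchangeabilities and equal
#' frequencies (useful for tests and closed-form oracles).
#'
#' @param model `"LG"` or `"Poisson"`.
#' @param frequencies Optional length-20 stationary frequency vector
#'   (ordered as [aa_alphabet()]); defaults to the model's own frequencies.
#' @param gamma_shape Shape of the gamma distribution of site rates.
#' @param ncat Number of discrete gamma categories (1 disables rate
#'   variation).
#' @return An object of class `subst_model` with elements `name`, `freq`,
#'   `Q` (scaled rate matrix), the spectral decomposition used for matrix
#'   exponentials, `gamma_shape`, `ncat` and `rates` (category rates).
#' @export
subst_model <- function(model = c("LG", "Poisson"), frequencies = NULL,
                        gamma_shape = 1, ncat = 4L) {
  model <- match.arg(model)
  alpha <- aa_alphabet()
  if (model == "LG") {
    # getModelAA assigns `Q` (lower-triangle exchangeabilities) and `bf`
    # into its calling frame; evaluate it in a scratch frame
    lg <- local({
      Q <- bf <- NULL
      utils::getFromNamespace("getModelAA", "phangorn")("LG", bf = TRUE,
                                                        Q = TRUE)
      list(ex = Q, bf = bf)
    })
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- lg$ex
    S <- S + t(S)
    freq <- if (is.null(frequencies)) as.numeric(lg$bf) else frequencies
  } else {
    S <- matrix(1, 20, 20); diag(S) <- 0
    freq <- if (is.null(frequencies)) rep(1 / 20, 20) else frequencies
  }
  stopifnot(length(freq) == 20L, all(freq > 0))
  freq <- freq / sum(freq)
  dimnames(S) <- list(alpha, alpha)
  Q <- S * rep(freq, each = 20)      # Q[a, b] = S[a, b] * freq[b]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))      # expected substitutions per unit time
  Q <- Q / scale
  # reversible: symmetrize with sqrt(freq) and eigendecompose
  d12 <- sqrt(freq)
  sym <- Q * (d12 / rep(d12, each = 20))   # sym[a,b] = d12[a] Q[a,b] / d12[b]
  eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  structure(list(
    name = model, freq = stats::setNames(freq, alpha), Q = Q,
    U = eig$vectors, lambda = eig$values, d12 = d12,
    gamma_shape = gamma_shape, ncat = as.integer(ncat),
    rates = discrete_gamma_rates(gamma_shape, ncat)
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name, "\n")
  cat("Gamma rate variation: shape =", format(x$gamma_shape),
      "with", x$ncat, "categories\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site at rate 1).
#' @param rate Rate multiplier.
#' @return 20 x 20 matrix of transition probabilities.
#' @export
transition_probs <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"), t >= 0, rate >= 0)
  U <- model$U
  P <- (U * rep(exp(model$lambda * t * rate), each = 20)) %*% t(U)
  P <- P * (rep(model$d12, each = 20) / model$d12)
  P[P < 0] <- 0
  dimnames(P) <- list(names(model$freq), names(model$freq))
  P / rowSums(P)
}

# Integral int_0^t exp(Q r s) W' exp(Q r (t-s)) ds with W' = r * W, i.e. the
# joint-expectation kernel for Markov rewards: entry (a, b) is
# E[ sum of W-weighted jumps on the branch ; end state b | start state a ].
# Used with W = off-diagonal Q (expected counts) or W = Q * |dP| (property-
# weighted counts). Computed in the symmetrized eigenbasis.
.count_integral <- function(model, W, t, rate = 1) {
  lam <- model$lambda * rate
  U <- model$U
  d12 <- model$d12
  # symmetrized weight matrix in the eigenbasis
  SW <- W * (d12 / rep(d12, each = 20))
  B <- crossprod(U, SW %*% U)
  el <- exp(lam * t)
  dl <- outer(lam, lam, "-")
  H <- (outer(el, el, "-")) / dl
  same <- abs(dl) < 1e-10
  H[same] <- (t * el)[row(H)[same]]
  M <- (U %*% (B * H * rate)) %*% t(U)
  M * (rep(d12, each = 20) / d12)
}

# Weight matrices for expected-count computations.
.count_weight <- function(model) {
  W <- model$Q
  diag(W) <- 0
  W
}

.property_weight <- function(model, prop) {
  p <- as.numeric(prop[names(model$freq)])
  W <- model$Q * abs(outer(p, p, function(a, b) b - a))
  diag(W) <- 0
  W
}
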