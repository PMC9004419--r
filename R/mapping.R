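# Probabilistic substitution mapping: per-site, per-branch expected signed
# property changes and expected substitution counts, integrating over all
# ancestral states (and gamma rate categories) by a two-pass pruning
# algorithm. No single ancestral reconstruction is ever used for the
# statistics: the expectation is taken under the joint posterior of the two
# branch endpoint states.

# Shared down-pass (Felsenstein pruning), vectorized over sites.
# Returns per-category conditional likelihood arrays and per-site
# log-likelihoods, on the cladewise-ordered tree.
.prune <- function(aln, tree, model, sites) {
  alpha <- aa_alphabet()
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  m <- nrow(edge)
  ns <- length(sites)
  states <- matrix(match(aln$matrix[tree$tip.label, sites, drop = FALSE],
                         alpha), ntip, ns)
  ncat <- model$ncat
  tipL <- lapply(seq_len(ntip), function(i) {
    L <- matrix(0, 20, ns)
    L[cbind(states[i, ], seq_len(ns))] <- 1
    L
  })
  out <- vector("list", ncat)
  sll <- matrix(0, ncat, ns)
  for (cc in seq_len(ncat)) {
    P <- lapply(seq_len(m), function(e)
      transition_probs(model, tree$edge.length[e], model$rates[cc]))
    L <- vector("list", nnode)
    L[seq_len(ntip)] <- tipL
    PL <- vector("list", m)
    logscale <- matrix(0, nnode, ns)
    for (e in rev(seq_len(m))) {      # postorder
      u <- edge[e, 1L]; v <- edge[e, 2L]
      PL[[e]] <- P[[e]] %*% L[[v]]
      if (is.null(L[[u]])) {
        L[[u]] <- PL[[e]]
        logscale[u, ] <- logscale[v, ]
      } else {
        L[[u]] <- L[[u]] * PL[[e]]
        logscale[u, ] <- logscale[u, ] + logscale[v, ]
      }
      s <- colSums(L[[u]])            # rescale to avoid underflow
      if (any(s <= 0)) stop("numerical underflow in pruning")
      L[[u]] <- L[[u]] / rep(s, each = 20L)
      logscale[u, ] <- logscale[u, ] + log(s)
    }
    root <- ntip + 1L
    sll[cc, ] <- log(colSums(model$freq * L[[root]])) + logscale[root, ]
    out[[cc]] <- list(L = L, PL = PL, P = P)
  }
  list(cat = out, sll = sll, edge = edge, ntip = ntip, m = m, sites = sites)
}

#' Per-site log-likelihoods under the substitution model
#'
#' Felsenstein pruning with rescaling, integrating over the discrete gamma
#' rate categories with equal prior weight.
#'
#' @param aln An `aa_alignment`.
#' @param tree A rooted `ape::phylo` with branch lengths (see [read_tree()]).
#' @param model A `subst_model`.
#' @param sites Site indices (default: all analyzable sites).
#' @return Named numeric vector of log-likelihoods, one per requested site.
#' @export
site_loglik <- function(aln, tree, model, sites = NULL) {
  sites <- .check_sites(aln, sites)
  tree <- read_tree(tree, aln)
  pr <- .prune(aln, tree, model, sites)
  mx <- apply(pr$sll, 2L, max)
  ll <- mx + log(colMeans(exp(sweep(pr$sll, 2L, mx))))
  stats::setNames(ll, sites)
}

.check_sites <- function(aln, sites) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (is.null(sites)) return(which(aln$analyzable))
  bad <- sites[!aln$analyzable[sites]]
  if (length(bad)) {
    stop("site(s) not analyzable (gap or non-standard character): ",
         paste(bad, collapse = ", "))
  }
  as.integer(sites)
}

#' Estimate the gamma shape parameter by maximum likelihood
#'
#' One-dimensional optimization (golden-section based, tolerance 1e-4) of the
#' total log-likelihood over the gamma shape, all other model components held
#' fixed.
#'
#' @inheritParams site_loglik
#' @param interval Search interval for the shape.
#' @return A `subst_model` identical to `model` but with the fitted shape.
#' @export
fit_gamma_shape <- function(aln, tree, model, interval = c(0.05, 20)) {
  tree <- read_tree(tree, aln)
  f <- function(a) {
    m2 <- subst_model(model$name, frequencies = as.numeric(model$freq),
                      gamma_shape = a, ncat = model$ncat)
    -sum(site_loglik(aln, tree, m2))
  }
  opt <- stats::optimize(f, interval = interval, tol = 1e-4)
  subst_model(model$name, frequencies = as.numeric(model$freq),
              gamma_shape = opt$minimum, ncat = model$ncat)
}

#' Map property changes and substitution counts onto the phylogeny
#'
#' For every analyzable site i and branch j, computes the expected signed
#' property change
#' \deqn{x_{ij} = \sum_{a,b} \Pr(\mathrm{parent}=a, \mathrm{child}=b \mid
#'   \mathrm{data}) \, (P(b) - P(a)),}
#' where the endpoint-pair posterior is obtained by a two-pass pruning
#' algorithm and integrates over gamma rate categories. Within-branch
#' multiple hits cancel by telescoping in the signed change; the
#' \emph{unweighted} and \emph{|dP|-weighted} expected substitution counts
#' (used for evolutionary rates) instead use the exact Markov-reward
#' expectation computed from the spectral decomposition of the rate matrix.
#'
#' @inheritParams site_loglik
#' @param prop An `aa_property` supplying the biochemical property P.
#' @param counts If `TRUE`, also compute expected (weighted) substitution
#'   counts per site and branch; required for [site_rates()].
#' @param ancestral If `TRUE`, record the marginal maximum-likelihood state of
#'   every node for every site. These states are for display only and never
#'   feed any statistic.
#' @return An object of class `change_matrix`: list with `x` (sites x
#'   branches signed change; rows of non-analyzable sites are `NA`), `count`
#'   and `wcount` (expected and property-weighted expected counts, if
#'   requested), `analyzable`, `variable`, `tree`, `property`, `loglik`, and
#'   optionally `node_states`.
#' @export
substitution_mapping <- function(aln, tree, model, prop, counts = TRUE,
                                 ancestral = FALSE) {
  stopifnot(inherits(prop, "aa_property"))
  tree <- read_tree(tree, aln)
  sites <- .check_sites(aln, NULL)
  if (!length(sites)) stop("no analyzable site in the alignment")
  pr <- .prune(aln, tree, model, sites)
  edge <- pr$edge; m <- pr$m; ntip <- pr$ntip; ns <- length(sites)
  ncat <- model$ncat
  pvec <- as.numeric(prop[names(model$freq)])

  # posterior weight of each rate category, per site (equal priors)
  mx <- apply(pr$sll, 2L, max)
  ex <- exp(sweep(pr$sll, 2L, mx))
  post <- sweep(ex, 2L, colSums(ex), "/")
  loglik <- sum(mx + log(colMeans(ex)))

  x <- matrix(0, ns, m)
  cnt <- if (counts) matrix(0, ns, m) else NULL
  wcnt <- if (counts) matrix(0, ns, m) else NULL
  marg <- if (ancestral) vector("list", ntip + tree$Nnode) else NULL
  Wc <- if (counts) .count_weight(model) else NULL
  Wp <- if (counts) .property_weight(model, prop) else NULL

  children <- split(seq_len(m), edge[, 1L])   # edges grouped by parent node
  root <- ntip + 1L
  for (cc in seq_len(ncat)) {
    dat <- pr$cat[[cc]]
    G <- vector("list", ntip + tree$Nnode)
    G[[root]] <- matrix(model$freq, 20L, ns)
    w <- post[cc, ]
    for (e in seq_len(m)) {          # preorder
      u <- edge[e, 1L]; v <- edge[e, 2L]
      A <- G[[u]]
      for (e2 in children[[as.character(u)]]) {
        if (e2 != e) A <- A * dat$PL[[e2]]
      }
      A <- A / rep(colSums(A), each = 20L)
      denom <- colSums(A * dat$PL[[e]])
      Lv <- dat$L[[v]]
      nx <- colSums(A * (dat$P[[e]] %*% (Lv * pvec))) -
        colSums((A * pvec) * dat$PL[[e]])
      x[, e] <- x[, e] + w * nx / denom
      if (counts) {
        r <- model$rates[cc]; t_e <- tree$edge.length[e]
        Mc <- .count_integral(model, Wc, t_e, r)
        Mw <- .count_integral(model, Wp, t_e, r)
        cnt[, e] <- cnt[, e] + w * colSums(A * (Mc %*% Lv)) / denom
        wcnt[, e] <- wcnt[, e] + w * colSums(A * (Mw %*% Lv)) / denom
      }
      if (v > ntip) {
        G[[v]] <- crossprod(dat$P[[e]], A)
        G[[v]] <- G[[v]] / rep(colSums(G[[v]]), each = 20L)
      }
      if (ancestral) {
        pm <- A * dat$PL[[e]]        # marginal posterior of the parent node
        marg[[u]] <- .acc_marg(marg[[u]], w * sweep(pm, 2L, denom, "/"))
        if (v <= ntip) {
          marg[[v]] <- .acc_marg(marg[[v]], w * dat$L[[v]])
        } else {
          pc <- crossprod(dat$P[[e]], A) * Lv
          marg[[v]] <- .acc_marg(marg[[v]], w * sweep(pc, 2L, colSums(pc), "/"))
        }
      }
    }
  }

  full <- function(mat) {
    if (is.null(mat)) return(NULL)
    out <- matrix(NA_real_, aln$n_sites, m)
    out[sites, ] <- mat
    out
  }
  node_states <- NULL
  if (ancestral) {
    alpha <- aa_alphabet()
    node_states <- do.call(rbind, lapply(marg, function(p) {
      if (is.null(p)) rep(NA_character_, ns) else alpha[max.col(t(p))]
    }))
    colnames(node_states) <- sites
  }
  variable <- rep(FALSE, aln$n_sites)
  variable[sites] <- apply(aln$matrix[, sites, drop = FALSE], 2L,
                           function(col) length(unique(col)) > 1L)
  structure(list(
    property = attr(prop, "name"), x = full(x), count = full(cnt),
    wcount = full(wcnt), analyzable = aln$analyzable, variable = variable,
    tree = tree, model = model$name, gamma_shape = model$gamma_shape,
    ncat = model$ncat, loglik = loglik, node_states = node_states
  ), class = "change_matrix")
}

.acc_marg <- function(acc, p) if (is.null(acc)) p else acc + p

#' @export
print.change_matrix <- function(x, ...) {
  cat("Substitution mapping (property '", x$property, "'): ",
      nrow(x$x), " sites x ", ncol(x$x), " branches; ",
      sum(x$analyzable), " analyzable, ", sum(x$variable), " variable; ",
      "log-likelihood ", format(x$loglik), "\n", sep = "")
  invisible(x)
}

#' Site-specific evolutionary rates from a change matrix
#'
#' The raw rate of a site is the Euclidean norm, over branches, of the vector
#' of expected substitution counts weighted by the absolute property
#' difference of each substitution type. Standardized rates divide by the
#' family mean over analyzable sites, so their mean is exactly 1.
#'
#' @param cm A `change_matrix` built with `counts = TRUE`.
#' @return Data frame with columns `site`, `raw_rate`, `std_rate` (rows:
#'   analyzable sites).
#' @export
site_rates <- function(cm) {
  stopifnot(inherits(cm, "change_matrix"))
  if (is.null(cm$wcount)) {
    stop("change matrix was built with counts = FALSE; rerun ",
         "substitution_mapping() with counts = TRUE")
  }
  idx <- which(cm$analyzable)
  if (!length(idx)) stop("no analyzable site")
  raw <- sqrt(rowSums(cm$wcount[idx, , drop = FALSE]^2))
  data.frame(site = idx, raw_rate = raw, std_rate = raw / mean(raw))
}

#' Export a change matrix as a long-format table
#'
#' @param x A `change_matrix`.
#' @param ... Unused.
#' @return Data frame with columns `site`, `branch`, `expected_count`,
#'   `signed_change` (analyzable sites only).
#' @export
as.data.frame.change_matrix <- function(x, ...) {
  idx <- which(x$analyzable)
  m <- ncol(x$x)
  out <- data.frame(
    site = rep(idx, each = m),
    branch = rep(seq_len(m), length(idx)),
    signed_change = as.vector(t(x$x[idx, , drop = FALSE]))
  )
  if (!is.null(x$count)) {
    out$expected_count <- as.vector(t(x$count[idx, , drop = FALSE]))
  }
  out
}
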