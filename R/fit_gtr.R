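#' Fit a GTR+Gamma model and branch lengths on a fixed topology
#'
#' Maximum-likelihood estimation of the exchangeabilities, the gamma
#' shape and all branch lengths by bounded quasi-Newton optimization
#' (L-BFGS-B on log-transformed parameters) from a small set of fixed
#' starting points, keeping the best. Base frequencies are taken as the
#' empirical frequencies of the alignment (the usual +F convention).
#' The procedure is deterministic for given inputs.
#'
#' @param aln an `nt_alignment`.
#' @param tree fixed topology (ape `phylo`); input branch lengths, when
#'   present and positive, seed one of the starting points.
#' @param n_categories discrete gamma categories; 1 disables rate
#'   variation.
#' @param equal_exchangeabilities constrain all six exchangeabilities to
#'   be equal (useful for closed-form checks).
#' @param base_freqs optional fixed base frequencies; default empirical.
#' @return object of class `gtr_fit` with elements `model`, `tree`
#'   (fitted branch lengths), `loglik`, `convergence`.
#' @export
fit_gtr <- function(aln, tree, n_categories = 4L,
                    equal_exchangeabilities = FALSE, base_freqs = NULL) {
  check_tree_aln(tree, aln)
  cp <- compress_patterns(aln)
  paln <- cp$alignment
  w <- cp$weights
  if (is.null(base_freqs)) base_freqs <- empirical_base_freqs(aln)

  if (all_rows_identical(aln)) {
    warning("alignment has a single distinct sequence; branch lengths set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
    model <- gtr_model(base_freqs = base_freqs, gamma_shape = Inf)
    return(structure(list(model = model, tree = tree,
                          loglik = loglik_gtr(aln, tree, model),
                          convergence = 0L),
                     class = "gtr_fit"))
  }

  nb <- nrow(tree$edge)
  use_gamma <- n_categories > 1L
  n_exch <- if (equal_exchangeabilities) 0L else 5L

  build <- function(th) {
    i <- 0L
    exch <- if (equal_exchangeabilities) rep(1, 6) else {
      e <- exp(th[1:5]); i <- 5L; c(e, 1)
    }
    shape <- if (use_gamma) { i <- i + 1L; exp(th[i]) } else Inf
    bl <- exp(th[(i + 1L):(i + nb)])
    model <- gtr_model(exch, base_freqs, shape, n_categories)
    tr <- tree
    tr$edge.length <- bl
    list(model = model, tree = tr)
  }
  nll <- function(th) {
    b <- build(th)
    ll <- tryCatch(loglik_gtr(paln, b$tree, b$model, site_weights = w),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  bl0 <- tree$edge.length
  bl_starts <- list(rep(0.1, nb), rep(0.5, nb))
  if (!is.null(bl0) && all(is.finite(bl0)) && any(bl0 > 0))
    bl_starts <- c(list(pmax(bl0, 1e-4)), bl_starts)
  starts <- lapply(bl_starts, function(bl)
    c(rep(0, n_exch), if (use_gamma) 0 else NULL, log(bl)))

  npar <- n_exch + use_gamma + nb
  lower <- c(rep(-7, n_exch), if (use_gamma) log(0.05) else NULL, rep(-18, nb))
  upper <- c(rep(7, n_exch), if (use_gamma) log(100) else NULL, rep(log(30), nb))
  best <- NULL
  for (th0 in starts) {
    o <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500,
                                                    factr = 1e7))
    if (is.null(best) || o$value < best$value) best <- o
  }
  b <- build(best$par)
  structure(list(model = b$model, tree = b$tree, loglik = -best$value,
                 convergence = best$convergence),
            class = "gtr_fit")
}

empirical_base_freqs <- function(aln) {
  cnt <- vapply(NT_STATES, function(s) sum(aln$mat == s), 0)
  cnt <- cnt + 0.5  # guard against absent states
  cnt / sum(cnt)
}

all_rows_identical <- function(aln) {
  s <- alignment_strings(aln)
  length(unique(s)) == 1L
}

#' @export
print.gtr_fit <- function(x, ...) {
  cat("GTR+Gamma fit\n")
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  print(x$model)
  cat(sprintf("  tree length: %.4f over %d branches\n",
              sum(x$tree$edge.length), nrow(x$tree$edge)))
  invisible(x)
}

#' @export
logLik.gtr_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik",
            df = 5L + 1L + nrow(object$tree$edge))
}

#' @export
coef.gtr_fit <- function(object, ...) {
  c(ac = object$model$exchangeabilities[1],
    ag = object$model$exchangeabilities[2],
    at = object$model$exchangeabilities[3],
    cg = object$model$exchangeabilities[4],
    ct = object$model$exchangeabilities[5],
    gt = object$model$exchangeabilities[6],
    gamma_shape = object$model$gamma_shape)
}

# --- marginal ancestral reconstruction ---------------------------------

#' Marginal ancestral sequence reconstruction under GTR+Gamma
#'
#' Computes, for every internal node and site, the marginal posterior
#' distribution over the four nucleotides by an inside-outside pass,
#' averaged over discrete-gamma categories with empirical-Bayes weights
#' (per-site category posteriors). The MAP state per node/site is
#' reported, with ties broken in the fixed order A < C < G < T. Ancestral
#' presence/absence of each site (indels) is reconstructed separately by
#' a two-state Markov model (see [reconstruct_indels()]).
#'
#' @param aln an `nt_alignment`.
#' @param tree rooted ape `phylo`, or any `phylo` plus an `outgroup` to
#'   root on (midpoint of the outgroup's pendant branch).
#' @param model a `gtr_model`.
#' @param outgroup optional tip label used for rooting.
#' @return object of class `ancestral_recon`: `tree` (rooted tree used),
#'   `node_seq` (character matrix, nodes x sites; tips hold the observed
#'   residues), `posteriors` (list over internal nodes of 4 x S
#'   matrices), `indel_presence` (logical nodes x sites), `site_loglik`.
#' @export
reconstruct_ancestral <- function(aln, tree, model, outgroup = NULL) {
  if (!is.null(outgroup)) tree <- root_at_outgroup_midpoint(tree, outgroup)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (or provide an outgroup)")
  check_tree_aln(tree, aln)
  nt <- length(tree$tip.label)
  nn <- n_nodes(tree)
  S <- n_sites(aln)
  ord <- match(tree$tip.label, aln$ids)
  tipL <- lapply(ord, function(i) nt_tip_partials(aln$mat[i, ]))
  Q <- gtr_rate_matrix(model)
  ed <- reversible_eigen(Q, model$base_freqs)
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  k <- length(rates)

  ll <- matrix(0, S, k)
  posts <- vector("list", k)
  for (c in seq_len(k)) {
    Plist <- lapply(tree$edge.length, function(t)
      prob_matrix(ed, rates[c] * t))
    pr <- prune_engine(tree, tipL, Plist, model$base_freqs, keep = TRUE)
    ll[, c] <- pr$site_ll
    posts[[c]] <- marginal_engine(tree, pr, Plist, model$base_freqs)
  }
  mx <- apply(ll, 1L, max)
  wcat <- exp(ll - mx)
  wcat <- wcat / rowSums(wcat)          # empirical-Bayes category weights

  internal <- (nt + 1L):nn
  posteriors <- vector("list", length(internal))
  names(posteriors) <- node_name(tree, internal)
  node_seq <- matrix("-", nn, S)
  for (i in seq_len(nt)) node_seq[i, ] <- aln$mat[ord[i], ]
  for (v in internal) {
    P <- matrix(0, 4L, S)
    for (c in seq_len(k)) P <- P + posts[[c]][[v]] * rep(wcat[, c], each = 4L)
    rownames(P) <- NT_STATES
    posteriors[[node_name(tree, v)]] <- P
    node_seq[v, ] <- NT_STATES[max.col(t(P), ties.method = "first")]
  }
  rownames(node_seq) <- node_name(tree, seq_len(nn))

  indels <- reconstruct_indels(aln, tree)

  structure(list(tree = tree, model = model, node_seq = node_seq,
                 posteriors = posteriors,
                 indel_presence = indels$presence,
                 indel_rates = indels$rates,
                 site_loglik = log_mean_exp_rows(ll)),
            class = "ancestral_recon")
}

node_name <- function(tree, v) {
  nt <- length(tree$tip.label)
  nlab <- tree$node.label
  use_nlab <- !is.null(nlab) && all(nzchar(nlab)) && !anyDuplicated(nlab)
  out <- character(length(v))
  tip <- v <= nt
  out[tip] <- tree$tip.label[v[tip]]
  out[!tip] <- if (use_nlab) nlab[v[!tip] - nt] else paste0("node", v[!tip])
  out
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat(sprintf("ancestral_recon: %d nodes x %d sites (%d internal)\n",
              nrow(x$node_seq), ncol(x$node_seq), length(x$posteriors)))
  invisible(x)
}

#' Write internal-node MAP sequences as FASTA
#' @param recon an `ancestral_recon`.
#' @param path output path.
#' @export
write_ancestral_fasta <- function(recon, path) {
  nt <- length(recon$tree$tip.label)
  seqs <- apply(recon$node_seq, 1L, paste0, collapse = "")
  set <- Biostrings::BStringSet(seqs[(nt + 1L):length(seqs)])
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# --- ancestral indel reconstruction ------------------------------------

#' Two-state ML reconstruction of ancestral site presence
#'
#' Each alignment site is coded present (any residue, including N) or
#' gap per taxon. A two-state continuous-time model with gain and loss
#' rates shared across sites (estimated once per alignment by ML over
#' the gapped site patterns) is used to compute marginal posteriors of
#' presence at every internal node; a node is called present when the
#' posterior exceeds 0.5. Constant patterns short-circuit: a gap-free
#' site is present everywhere, an all-gap site absent everywhere.
#'
#' @param aln an `nt_alignment`.
#' @param tree rooted ape `phylo`.
#' @return list with `presence` (logical matrix, nodes x sites, tip rows
#'   first) and `rates` (gain, loss).
#' @export
reconstruct_indels <- function(aln, tree) {
  check_tree_aln(tree, aln)
  nt <- length(tree$tip.label)
  nn <- n_nodes(tree)
  S <- n_sites(aln)
  ord <- match(tree$tip.label, aln$ids)
  tip_present <- aln$mat[ord, , drop = FALSE] != "-"

  presence <- matrix(TRUE, nn, S)
  presence[seq_len(nt), ] <- tip_present
  rownames(presence) <- node_name(tree, seq_len(nn))

  n_pres <- colSums(tip_present)
  all_present <- n_pres == nt
  all_absent <- n_pres == 0L
  mixed <- which(!all_present & !all_absent)
  presence[, all_absent] <- FALSE
  if (length(mixed) == 0L)
    return(list(presence = presence, rates = c(gain = NA, loss = NA)))

  pat <- apply(tip_present[, mixed, drop = FALSE], 2L, paste0, collapse = "")
  u <- !duplicated(pat)
  idx <- match(pat, pat[u])
  wts <- tabulate(idx, sum(u))
  um <- tip_present[, mixed[u], drop = FALSE]

  tipL <- lapply(seq_len(nt), function(i) {
    L <- matrix(0, 2L, ncol(um))
    L[1L, !um[i, ]] <- 1   # state 1 = absent
    L[2L, um[i, ]] <- 1    # state 2 = present
    L
  })
  two_state_ll <- function(gain, loss) {
    Plist <- lapply(tree$edge.length, function(t)
      two_state_P(gain, loss, t))
    prior <- c(loss, gain) / (gain + loss)  # stationary (absent, present)
    prune_engine(tree, tipL, Plist, prior)$site_ll
  }
  nll <- function(th) {
    g <- exp(th[1]); l <- exp(th[2])
    v <- -sum(two_state_ll(g, l) * wts)
    if (!is.finite(v)) 1e10 else v
  }
  o <- stats::optim(c(log(0.1), log(0.5)), nll, method = "L-BFGS-B",
                    lower = c(-8, -8), upper = c(4, 4))
  gain <- exp(o$par[1]); loss <- exp(o$par[2])
  Plist <- lapply(tree$edge.length, function(t) two_state_P(gain, loss, t))
  prior <- c(loss, gain) / (gain + loss)
  pr <- prune_engine(tree, tipL, Plist, prior, keep = TRUE)
  post <- marginal_engine(tree, pr, Plist, prior)
  for (v in (nt + 1L):nn)
    presence[v, mixed] <- (post[[v]][2L, ] > 0.5)[idx]
  list(presence = presence, rates = c(gain = gain, loss = loss))
}

# transition matrix of the absent(1)/present(2) chain:
# absent -> present at rate `gain`, present -> absent at rate `loss`
two_state_P <- function(gain, loss, t) {
  tot <- gain + loss
  pi1 <- loss / tot  # stationary absent
  pi2 <- gain / tot
  e <- exp(-tot * t)
  matrix(c(pi1 + pi2 * e, pi1 - pi1 * e,
           pi2 - pi2 * e, pi2 + pi1 * e),
         2L, 2L)
}
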