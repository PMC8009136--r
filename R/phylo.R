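# Tree utilities and the generic Felsenstein pruning engine used by both
# the nucleotide (GTR+Gamma) and codon (GY94 branch-model) likelihoods.
# Trees are ape "phylo" objects; tips 1..n, root n+1.

check_tree_aln <- function(tree, aln) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!setequal(tree$tip.label, aln$ids))
    stop("taxon mismatch between tree and alignment")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree must have finite non-negative branch lengths")
  invisible(TRUE)
}

n_nodes <- function(tree) tree$Nnode + length(tree$tip.label)

root_node <- function(tree) length(tree$tip.label) + 1L

# Edges ordered so every child is visited before its parent
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder")$edge
}

#' Root a tree on the midpoint of the branch leading to an outgroup
#'
#' Used before ancestral reconstruction: for a reversible model the
#' likelihood is invariant to root placement, but reconstruction and
#' branch-wise substitution counting need a rooted tree. The outgroup's
#' pendant branch is split in half by the new root.
#'
#' @param tree an ape `phylo` object.
#' @param outgroup a tip label.
#' @return a rooted `phylo` object.
#' @export
root_at_outgroup_midpoint <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree: ", outgroup)
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  og <- match(outgroup, tr$tip.label)
  r <- root_node(tr)
  e_og <- which(tr$edge[, 2L] == og & tr$edge[, 1L] == r)
  e_in <- which(tr$edge[, 1L] == r & tr$edge[, 2L] != og)
  if (length(e_og) == 1L && length(e_in) == 1L) {
    tot <- tr$edge.length[e_og] + tr$edge.length[e_in]
    tr$edge.length[e_og] <- tot / 2
    tr$edge.length[e_in] <- tot / 2
  }
  tr
}

#' Paint tree branches into regime classes
#'
#' Labels every branch (edge) of the tree as `"ingroup"` (branches inside
#' the clade spanned by `ingroup_tips`), `"transition"` (the stem branch
#' connecting that clade to the rest of the tree) or `"other"`.
#'
#' @param tree an ape `phylo` object.
#' @param ingroup_tips tip labels of the focal (e.g. heterotrophic) clade.
#' @param transition if `FALSE`, the stem branch is labelled `"other"`.
#' @return character vector of length `nrow(tree$edge)`.
#' @export
paint_branches <- function(tree, ingroup_tips, transition = TRUE) {
  stopifnot(all(ingroup_tips %in% tree$tip.label))
  tips <- match(ingroup_tips, tree$tip.label)
  if (length(tips) == 1L) {
    mrca <- tips
  } else {
    mrca <- ape::getMRCA(tree, tips)
  }
  desc <- clade_nodes(tree, mrca)
  painting <- rep("other", nrow(tree$edge))
  inside <- tree$edge[, 1L] %in% desc & tree$edge[, 2L] %in% desc
  painting[inside] <- "ingroup"
  stem <- which(tree$edge[, 2L] == mrca)
  if (length(stem) == 1L)
    painting[stem] <- if (transition) "transition" else "other"
  painting
}

# All nodes in the clade rooted at `node` (including it)
clade_nodes <- function(tree, node) {
  edges <- tree$edge
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- edges[edges[, 1L] %in% frontier, 2L]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# --- tip partial likelihoods -------------------------------------------

# k x S matrix of partial likelihoods for one tip sequence (nucleotides)
nt_tip_partials <- function(chars) {
  S <- length(chars)
  L <- matrix(0, 4L, S, dimnames = list(NT_STATES, NULL))
  for (sym in unique(chars)) {
    sets <- IUPAC_SETS[[sym]]
    if (is.null(sets)) sets <- NT_STATES  # unknown symbol -> missing
    L[sets, chars == sym] <- 1
  }
  L
}

col_max <- function(m) {
  if (nrow(m) == 4L) pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
  else m[cbind(max.col(t(m)), seq_len(ncol(m)))]
}

# --- generic pruning ----------------------------------------------------

# tipL: list over tips of k x S partial-likelihood matrices
# Plist: list over edges (indexed like tree$edge rows) of k x k matrices
# Returns per-site log-likelihood vector, and optionally all node partials
# and per-edge messages (needed for marginal reconstruction).
prune_engine <- function(tree, tipL, Plist, root_prior, keep = FALSE) {
  nt <- length(tree$tip.label)
  nn <- n_nodes(tree)
  S <- ncol(tipL[[1L]])
  k <- nrow(tipL[[1L]])
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  edge_ids <- match(paste(edges[, 1L], edges[, 2L]),
                    paste(tree$edge[, 1L], tree$edge[, 2L]))
  L <- vector("list", nn)
  for (i in seq_len(nt)) L[[i]] <- tipL[[i]]
  logscale <- numeric(S)
  msgs <- if (keep) vector("list", nrow(tree$edge)) else NULL
  for (j in seq_len(nrow(edges))) {
    par <- edges[j, 1L]; chd <- edges[j, 2L]
    M <- Plist[[edge_ids[j]]] %*% L[[chd]]
    if (keep) msgs[[edge_ids[j]]] <- M
    L[[par]] <- if (is.null(L[[par]])) M else L[[par]] * M
    # rescale parent partials once all children are in; cheap to do per edge
    cm <- col_max(L[[par]])
    bad <- cm <= 0
    if (any(bad)) cm[bad] <- 1   # impossible sites; caught at root
    L[[par]] <- L[[par]] / rep(cm, each = k)
    logscale <- logscale + log(cm)
  }
  rootL <- L[[root_node(tree)]]
  site_lik <- colSums(root_prior * rootL)
  site_ll <- log(site_lik) + logscale
  if (keep)
    list(site_ll = site_ll, L = L, msgs = msgs, logscale = logscale)
  else
    list(site_ll = site_ll)
}

# Marginal posterior state probabilities for every node, one rate class.
# Outside pass built on the stored inside messages.
marginal_engine <- function(tree, pr, Plist, root_prior) {
  nn <- n_nodes(tree)
  k <- length(root_prior)
  S <- length(pr$site_ll)
  O <- vector("list", nn)
  O[[root_node(tree)]] <- matrix(root_prior, k, S)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  edge_ids <- match(paste(edges[, 1L], edges[, 2L]),
                    paste(tree$edge[, 1L], tree$edge[, 2L]))
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  for (j in seq_len(nrow(edges))) {
    par <- edges[j, 1L]; chd <- edges[j, 2L]; eid <- edge_ids[j]
    sibs <- setdiff(children[[as.character(par)]], eid)
    Opar <- O[[par]]
    for (sb in sibs) Opar <- Opar * pr$msgs[[sb]]
    Ov <- crossprod(Plist[[eid]], Opar)
    cm <- col_max(Ov)
    cm[cm <= 0] <- 1
    O[[chd]] <- Ov / rep(cm, each = k)
  }
  post <- vector("list", nn)
  for (v in seq_len(nn)) {
    P <- O[[v]] * pr$L[[v]]
    cs <- colSums(P)
    cs[cs <= 0] <- 1
    post[[v]] <- P / rep(cs, each = k)
  }
  post
}

# --- GTR+Gamma likelihood ----------------------------------------------

#' Log-likelihood of an alignment under GTR+Gamma on a fixed tree
#'
#' Felsenstein pruning over the four nucleotide states with per-site
#' rescaling, averaged over equal-prior discrete gamma categories.
#' Gap/ambiguity symbols contribute a partial likelihood of 1 over their
#' compatible states (missing data).
#'
#' @param aln an `nt_alignment`.
#' @param tree an ape `phylo` with branch lengths in substitutions/site.
#' @param model a `gtr_model`.
#' @param site_weights optional per-site multiplicities (pattern weights).
#' @param per_site return the per-site log-likelihood vector instead of
#'   the sum.
#' @return total log-likelihood (or per-site vector).
#' @export
loglik_gtr <- function(aln, tree, model, site_weights = NULL,
                       per_site = FALSE) {
  check_tree_aln(tree, aln)
  ord <- match(tree$tip.label, aln$ids)
  tipL <- lapply(ord, function(i) nt_tip_partials(aln$mat[i, ]))
  Q <- gtr_rate_matrix(model)
  ed <- reversible_eigen(Q, model$base_freqs)
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  ll_cat <- vapply(rates, function(r) {
    Plist <- lapply(tree$edge.length, function(t) prob_matrix(ed, r * t))
    prune_engine(tree, tipL, Plist, model$base_freqs)$site_ll
  }, numeric(n_sites(aln)))
  ll_cat <- matrix(ll_cat, ncol = length(rates))
  site_ll <- log_mean_exp_rows(ll_cat)
  if (any(!is.finite(site_ll))) stop("numerical underflow in likelihood")
  if (per_site) return(site_ll)
  if (is.null(site_weights)) sum(site_ll) else sum(site_ll * site_weights)
}

log_mean_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowMeans(exp(m - mx)))
}

# Unique site patterns of an alignment: pattern alignment + weights + map
compress_patterns <- function(aln, block = 1L) {
  S <- n_sites(aln)
  stopifnot(S %% block == 0L)
  cols <- apply(aln$mat, 2L, paste0, collapse = "")
  if (block > 1L)
    cols <- apply(matrix(cols, nrow = block), 2L, paste0, collapse = "|")
  u <- !duplicated(cols)
  idx <- match(cols, cols[u])
  keep_sites <- as.vector(outer(seq_len(block), (which(u) - 1L) * block, `+`))
  list(alignment = nt_alignment(aln$mat[, keep_sites, drop = FALSE]),
       weights = tabulate(idx, sum(u)),
       index = idx)
}
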