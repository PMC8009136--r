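# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles enumerate internal-node states directly and
# never call the pruning engine.

NT <- c("A", "C", "G", "T")

balanced_tree <- function(n, bl, prefix = "t") {
  tr <- ape::stree(n, "balanced")
  tr$tip.label <- paste0(prefix, seq_len(n))
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

random_alignment <- function(taxa, n_sites) {
  seqs <- vapply(taxa, function(x)
    paste0(sample(NT, n_sites, TRUE), collapse = ""), "")
  nt_alignment(seqs)
}

# exhaustive GTR+Gamma log-likelihood for a 4-taxon rooted/unrooted tree
# (3 internal nodes assumed: works for ((a,b),(c,d)); style trees)
brute_loglik_nt <- function(aln, tree, model) {
  Q <- plastevol:::gtr_rate_matrix(model)
  ed <- plastevol:::reversible_eigen(Q, model$base_freqs)
  rates <- plastevol:::discrete_gamma_rates(model$gamma_shape,
                                            model$n_categories)
  E <- tree$edge
  nt <- length(tree$tip.label)
  ni <- tree$Nnode
  states <- c(A = 1, C = 2, G = 3, T = 4)
  grid <- as.matrix(expand.grid(rep(list(1:4), ni)))
  root <- nt + 1L
  total <- 0
  for (s in seq_len(n_sites(aln))) {
    obs <- states[aln$mat[match(tree$tip.label, aln$ids), s]]
    likc <- vapply(rates, function(r) {
      P <- lapply(seq_len(nrow(E)), function(e)
        plastevol:::prob_matrix(ed, r * tree$edge.length[e]))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- c(obs, grid[g, ])
        pr <- model$base_freqs[st[root]]
        for (e in seq_len(nrow(E)))
          pr <- pr * P[[e]][st[E[e, 1L]], st[E[e, 2L]]]
        tot <- tot + pr
      }
      tot
    }, 0)
    total <- total + log(mean(likc))
  }
  total
}

# exhaustive marginal posteriors (all internal nodes) for small trees,
# empirical-Bayes averaged over gamma categories
brute_marginals_nt <- function(aln, tree, model, site) {
  Q <- plastevol:::gtr_rate_matrix(model)
  ed <- plastevol:::reversible_eigen(Q, model$base_freqs)
  rates <- plastevol:::discrete_gamma_rates(model$gamma_shape,
                                            model$n_categories)
  E <- tree$edge
  nt <- length(tree$tip.label)
  ni <- tree$Nnode
  states <- c(A = 1, C = 2, G = 3, T = 4)
  grid <- as.matrix(expand.grid(rep(list(1:4), ni)))
  root <- nt + 1L
  obs <- states[aln$mat[match(tree$tip.label, aln$ids), site]]
  post <- matrix(0, ni, 4L)
  for (r in rates) {
    P <- lapply(seq_len(nrow(E)), function(e)
      plastevol:::prob_matrix(ed, r * tree$edge.length[e]))
    for (g in seq_len(nrow(grid))) {
      st <- c(obs, grid[g, ])
      pr <- model$base_freqs[st[root]]
      for (e in seq_len(nrow(E)))
        pr <- pr * P[[e]][st[E[e, 1L]], st[E[e, 2L]]]
      for (k in seq_len(ni)) post[k, grid[g, k]] <- post[k, grid[g, k]] + pr
    }
  }
  post / rowSums(post)
}

# exhaustive codon log-likelihood for an unrooted 3-taxon tree (one
# internal node)
brute_loglik_codon <- function(codon_aln, tree, model, painting = NULL) {
  if (is.null(painting))
    painting <- rep(names(model$omega_map)[1L], nrow(tree$edge))
  pi <- model$codon_freqs
  E <- tree$edge
  SC <- plastevol:::SENSE_CODONS
  Ps <- lapply(seq_len(nrow(E)), function(e) {
    Q <- plastevol:::codon_rate_matrix(model$kappa,
                                       model$omega_map[[painting[e]]], pi)
    edc <- plastevol:::reversible_eigen(Q, pi)
    plastevol:::prob_matrix(edc, tree$edge.length[e])
  })
  mat <- codon_aln$mat[match(tree$tip.label, codon_aln$ids), , drop = FALSE]
  S <- ncol(mat) %/% 3L
  total <- 0
  for (s in seq_len(S)) {
    cods <- apply(mat[, (3L * s - 2L):(3L * s), drop = FALSE], 1L,
                  paste0, collapse = "")
    oi <- match(cods, SC)
    lik <- 0
    for (r in 1:61) {
      pr <- pi[r]
      for (e in seq_len(nrow(E))) {
        tgt <- if (is.na(oi[E[e, 2L]])) 1 else Ps[[e]][r, oi[E[e, 2L]]]
        pr <- pr * tgt
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# fabricate an ancestral_recon for a 2-taxon tree with a known parent
# (root) sequence; used to unit-test substitution counting in isolation
fake_recon_pair <- function(parent, child_a, child_b = NULL) {
  if (is.null(child_b)) child_b <- parent
  tr <- ape::read.tree(text = "(a:1,b:1);")
  S <- nchar(parent)
  node_seq <- rbind(a = strsplit(child_a, "")[[1L]],
                    b = strsplit(child_b, "")[[1L]],
                    node3 = strsplit(parent, "")[[1L]])
  pres <- node_seq != "-"
  structure(list(tree = tr, node_seq = node_seq, indel_presence = pres),
            class = "ancestral_recon")
}
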