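# Seed-deterministic simulators for every stage: nucleotide and codon
# evolution on a tree, OU traits with regime shifts, irreversible gene
# loss, and toy quadripartite plastomes with an exact inverted repeat.
# Each simulator returns its generating truth alongside the data.

#' Simulate nucleotide evolution under GTR+Gamma
#'
#' The root sequence is drawn from `root_freqs` (default: the model's
#' stationary frequencies); each site is assigned a gamma rate category;
#' evolution along every branch uses the exact transition probabilities
#' of the rescaled rate matrix. Sites evolve independently (no indels).
#'
#' @param tree rooted ape `phylo`, branch lengths in expected
#'   substitutions/site.
#' @param model a `gtr_model`.
#' @param length number of sites.
#' @param seed integer seed; the same seed reproduces the data exactly.
#' @param root_freqs optional root composition differing from the
#'   stationary distribution (to simulate a sequence still drifting
#'   toward equilibrium).
#' @return list with `alignment` (tips) and `truth`: `node_seq`
#'   (all-node character matrix), `branch_counts` (endpoint strong/weak
#'   difference counts per edge), `categories`, `model`, `seed`.
#' @export
simulate_nucleotide_evolution <- function(tree, model, length, seed,
                                          root_freqs = NULL) {
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  S <- as.integer(length)
  if (is.null(root_freqs)) root_freqs <- model$base_freqs
  Q <- gtr_rate_matrix(model)
  ed <- reversible_eigen(Q, model$base_freqs)
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  cat_of_site <- sample.int(length(rates), S, replace = TRUE)
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  states <- matrix(0L, nn, S)
  states[root_node(tree), ] <- sample.int(4L, S, replace = TRUE,
                                          prob = root_freqs)
  po <- postorder_edges(tree)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  eid <- match(paste(pre[, 1L], pre[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (j in seq_len(nrow(pre))) {
    par <- pre[j, 1L]; chd <- pre[j, 2L]
    t <- tree$edge.length[eid[j]]
    for (c in seq_along(rates)) {
      sel <- which(cat_of_site == c)
      if (!length(sel)) next
      P <- prob_matrix(ed, rates[c] * t)
      ps <- states[par, sel]
      # sample child states grouped by parent state
      for (s in 1:4) {
        here <- sel[ps == s]
        if (length(here))
          states[chd, here] <- sample.int(4L, length(here), replace = TRUE,
                                          prob = P[s, ])
      }
    }
  }
  node_seq <- matrix(NT_STATES[states], nn, S)
  rownames(node_seq) <- node_name(tree, seq_len(nn))
  seqs <- apply(node_seq[seq_len(nt), , drop = FALSE], 1L, paste0,
                collapse = "")
  names(seqs) <- tree$tip.label
  strong <- matrix(node_seq %in% c("G", "C"), nn, S)
  bc <- data.frame(edge = seq_len(nrow(tree$edge)),
                   child = node_name(tree, tree$edge[, 2L]))
  bc$n_sw <- vapply(seq_len(nrow(tree$edge)), function(e)
    sum(strong[tree$edge[e, 1L], ] & !strong[tree$edge[e, 2L], ]), 0L)
  bc$n_ws <- vapply(seq_len(nrow(tree$edge)), function(e)
    sum(!strong[tree$edge[e, 1L], ] & strong[tree$edge[e, 2L], ]), 0L)
  list(alignment = nt_alignment(seqs),
       truth = list(node_seq = node_seq, branch_counts = bc,
                    categories = cat_of_site, model = model,
                    root_freqs = root_freqs, seed = seed))
}

#' Simulate codon evolution under a branch-class GY94 model
#'
#' Generator matched exactly to [codon_loglik()]: per-branch transition
#' probabilities from the class-specific rescaled rate matrix.
#'
#' @param tree rooted ape `phylo`, branch lengths in expected
#'   substitutions per codon.
#' @param model a `codon_model`.
#' @param painting per-edge class labels (entries of `model$omega_map`);
#'   default single class.
#' @param n_codons number of codon sites.
#' @param seed integer seed.
#' @return list with `alignment` (a `codon_alignment`) and `truth`.
#' @export
simulate_codon_evolution <- function(tree, model, n_codons, seed,
                                     painting = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(painting))
    painting <- rep(names(model$omega_map)[1L], nrow(tree$edge))
  set.seed(seed)
  pi <- model$codon_freqs
  eds <- lapply(model$omega_map, function(w)
    reversible_eigen(codon_rate_matrix(model$kappa, w, pi), pi))
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  states <- matrix(0L, nn, n_codons)
  states[root_node(tree), ] <- sample.int(61L, n_codons, replace = TRUE,
                                          prob = pi)
  po <- postorder_edges(tree)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  eid <- match(paste(pre[, 1L], pre[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (j in seq_len(nrow(pre))) {
    par <- pre[j, 1L]; chd <- pre[j, 2L]
    P <- prob_matrix(eds[[painting[eid[j]]]], tree$edge.length[eid[j]])
    ps <- states[par, ]
    for (s in unique(ps)) {
      here <- which(ps == s)
      states[chd, here] <- sample.int(61L, length(here), replace = TRUE,
                                      prob = P[s, ])
    }
  }
  node_cod <- matrix(SENSE_CODONS[states], nn, n_codons)
  seqs <- apply(node_cod[seq_len(nt), , drop = FALSE], 1L, paste0,
                collapse = "")
  names(seqs) <- tree$tip.label
  aln <- codonize(nt_alignment(seqs), stop_policy = "allow")
  list(alignment = aln,
       truth = list(node_codons = node_cod, painting = painting,
                    model = model, seed = seed))
}

#' Simulate an OU trait with regime-specific optima
#'
#' Exact Gaussian transition sampling: along a branch of length `t`,
#' `x_child ~ Normal(theta + (x_parent - theta) e^(-alpha t),
#' sigma2 (1 - e^(-2 alpha t)) / (2 alpha))` with the branch's regime
#' optimum theta. The root starts at the ancestral regime's optimum.
#'
#' @param tree rooted ape `phylo`.
#' @param painting per-edge regime labels.
#' @param theta named numeric: optimum per regime (the `"transition"`
#'   label, if painted, uses the `"ingroup"` optimum).
#' @param alpha selection strength (>= 0; 0 gives Brownian motion).
#' @param sigma2 diffusion variance.
#' @param seed integer seed.
#' @return list with `trait` (named per tip) and `truth` (node values).
#' @export
simulate_ou_traits <- function(tree, painting, theta, alpha, sigma2, seed) {
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  painting <- ifelse(painting == "transition", "ingroup", painting)
  stopifnot(all(painting %in% names(theta)))
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  x <- numeric(nn)
  x[root_node(tree)] <- theta[[ancestral_regime(tree, painting)]]
  po <- postorder_edges(tree)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  eid <- match(paste(pre[, 1L], pre[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (j in seq_len(nrow(pre))) {
    par <- pre[j, 1L]; chd <- pre[j, 2L]
    t <- tree$edge.length[eid[j]]
    th <- theta[[painting[eid[j]]]]
    if (alpha > 0) {
      m <- th + (x[par] - th) * exp(-alpha * t)
      v <- sigma2 * (1 - exp(-2 * alpha * t)) / (2 * alpha)
    } else {
      m <- x[par]
      v <- sigma2 * t
    }
    x[chd] <- stats::rnorm(1L, m, sqrt(v))
  }
  trait <- x[seq_len(nt)]
  names(trait) <- tree$tip.label
  list(trait = trait,
       truth = list(node_values = stats::setNames(x, node_name(tree, seq_len(nn))),
                    theta = theta, alpha = alpha, sigma2 = sigma2,
                    seed = seed))
}

#' Simulate irreversible gene loss on a tree
#'
#' Each gene starts present at the root; along every branch a present
#' gene is lost with probability `loss_prob`; a lost gene stays lost.
#'
#' @param tree rooted ape `phylo`.
#' @param loss_prob per-branch loss probability.
#' @param n_genes number of independent genes.
#' @param seed integer seed.
#' @return list with `matrix` (a `gene_matrix` of intact/absent) and
#'   `truth` (`loss_edges` per gene, `n_events` per gene).
#' @export
simulate_gene_loss <- function(tree, loss_prob, n_genes, seed) {
  stopifnot(inherits(tree, "phylo"), loss_prob >= 0, loss_prob <= 1)
  set.seed(seed)
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  po <- postorder_edges(tree)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  eid <- match(paste(pre[, 1L], pre[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  genes <- paste0("g", seq_len(n_genes))
  st <- matrix("intact", nt, n_genes, dimnames = list(tree$tip.label, genes))
  loss_edges <- vector("list", n_genes)
  names(loss_edges) <- genes
  for (g in seq_len(n_genes)) {
    present <- rep(TRUE, nn)
    ev <- integer(0)
    for (j in seq_len(nrow(pre))) {
      par <- pre[j, 1L]; chd <- pre[j, 2L]
      if (present[par]) {
        if (stats::runif(1L) < loss_prob) {
          present[chd] <- FALSE
          ev <- c(ev, eid[j])
        }
      } else present[chd] <- FALSE
    }
    st[, g] <- ifelse(present[seq_len(nt)], "intact", "absent")
    loss_edges[[g]] <- ev
  }
  list(matrix = gene_matrix(st),
       truth = list(loss_edges = loss_edges,
                    n_events = vapply(loss_edges, length, 0L),
                    loss_prob = loss_prob, seed = seed))
}

random_orf <- function(n_codons, gc, rng_states) {
  # random sense codons without stops, start ATG, end TAA
  mid <- character(n_codons - 2L)
  probs <- vapply(strsplit(SENSE_CODONS, ""), function(cd)
    prod(ifelse(cd %in% c("G", "C"), gc / 2, (1 - gc) / 2)), 0)
  mid <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE, prob = probs)
  paste0("ATG", paste0(mid, collapse = ""), "TAA")
}

random_nt <- function(n, gc) {
  paste0(sample(NT_STATES, n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

#' Build a toy quadripartite plastome with known structure
#'
#' Constructs a circular sequence LSC + IRa + SSC + revcomp(IRa) with a
#' known GC content and CDS/rRNA genes placed in a given order, for
#' exercising [detect_ir()], [classify_gene()] and the gene matrix
#' pipeline against construction truth.
#'
#' @param lsc_len,ssc_len,ir_len region lengths (bp).
#' @param gene_order optional character vector of gene names laid out
#'   left-to-right in the LSC (CDS genes of 300 bp each by default).
#' @param gc GC fraction of the random background.
#' @param seed integer seed.
#' @return list with `record` (a `plastome`) and `truth` (the region
#'   intervals and lengths).
#' @export
make_toy_plastome <- function(lsc_len, ssc_len, ir_len, gene_order = NULL,
                              gc = 0.3, seed = 1L) {
  set.seed(seed)
  gene_len <- 300L
  if (is.null(gene_order)) gene_order <- character(0)
  if (lsc_len < length(gene_order) * (gene_len + 20L))
    stop("infeasible packing: LSC too short for the gene order")
  lsc <- random_nt(lsc_len, gc)
  ir <- random_nt(ir_len, gc)
  ssc <- random_nt(ssc_len, gc)
  # boundary guards: make the IR exactly maximal, so that extension by
  # chance complementarity across a region border is impossible (a base
  # never equals its own complement)
  substr(ssc, ssc_len, ssc_len) <- substr(ssc, 1L, 1L)
  substr(lsc, lsc_len, lsc_len) <- substr(lsc, 1L, 1L)
  features <- data.frame(gene = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         kind = character(0), stringsAsFactors = FALSE)
  pos <- 10L
  for (g in gene_order) {
    orf <- random_orf(gene_len %/% 3L, gc)
    substr(lsc, pos + 1L, pos + gene_len) <- orf
    features <- rbind(features,
                      data.frame(gene = g, start = pos,
                                 end = pos + gene_len, strand = "+",
                                 kind = "CDS", stringsAsFactors = FALSE))
    pos <- pos + gene_len + 20L
  }
  seq <- paste0(lsc, ir, ssc, revcomp(ir))
  rec <- plastome(seq, features, circular = TRUE, id = "toy")
  truth <- list(lsc = c(0L, lsc_len),
                ira = c(lsc_len, lsc_len + ir_len),
                ssc = c(lsc_len + ir_len, lsc_len + ir_len + ssc_len),
                irb = c(lsc_len + ir_len + ssc_len,
                        lsc_len + 2L * ir_len + ssc_len),
                lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
                seed = seed)
  list(record = rec, truth = truth)
}

#' Pseudogenize a gene in a toy plastome (inject an internal stop)
#' @param rec a `plastome` with the gene annotated as CDS on `+`.
#' @param gene gene name.
#' @return the modified `plastome`.
#' @export
inject_internal_stop <- function(rec, gene) {
  i <- which(rec$features$gene == gene)
  if (!length(i)) stop("unknown gene: ", gene)
  f <- rec$features[i[1L], ]
  mid <- f$start + 3L * ((f$end - f$start) %/% 6L)  # in-frame middle codon
  substr(rec$seq, mid + 1L, mid + 3L) <- "TAA"
  rec
}

#' Delete a gene's feature (and optionally its sequence) from a plastome
#' @param rec a `plastome`.
#' @param gene gene name.
#' @return the modified `plastome`.
#' @export
delete_gene <- function(rec, gene) {
  rec$features <- rec$features[rec$features$gene != gene, , drop = FALSE]
  rec
}
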