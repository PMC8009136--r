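# Maximum-parsimony mapping of gene losses on a fixed rooted tree.
#
# Leaf coding: intact -> present; pseudogene and absent -> lost (complete
# absence and pseudogenization are both loss of the functional gene);
# unsampled -> missing data. "Independent losses" is the number of
# present->lost transitions, minimized over all most-parsimonious
# reconstructions (a conservative count).

#' Gene presence/pseudogene/absence matrix
#'
#' @param states character matrix (taxa x genes) over
#'   `{"intact","pseudogene","absent","unsampled"}`, with taxon rownames
#'   and gene colnames.
#' @param partial_taxa taxa with partial assemblies; `"unsampled"` cells
#'   are only allowed in these rows.
#' @return object of class `gene_matrix`.
#' @export
gene_matrix <- function(states, partial_taxa = character(0)) {
  stopifnot(is.matrix(states), !is.null(rownames(states)),
            !is.null(colnames(states)))
  ok <- states %in% c("intact", "pseudogene", "absent", "unsampled")
  if (!all(ok)) stop("invalid gene state: ", states[!ok][1L])
  uns <- rownames(states)[rowSums(states == "unsampled") > 0L]
  bad <- setdiff(uns, partial_taxa)
  if (length(bad))
    stop("'unsampled' only allowed for partial assemblies: ",
         paste(bad, collapse = ", "))
  structure(list(states = states, partial_taxa = partial_taxa),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix: %d taxa x %d genes (%d partial assemblies)\n",
              nrow(x$states), ncol(x$states), length(x$partial_taxa)))
  invisible(x)
}

#' Genes intact in every completely assembled plastome
#'
#' @param matrix a `gene_matrix`.
#' @param complete_taxa taxa with complete assemblies.
#' @return character vector of core gene names.
#' @export
core_gene_set <- function(matrix, complete_taxa) {
  stopifnot(length(complete_taxa) > 0L,
            all(complete_taxa %in% rownames(matrix$states)))
  sub <- matrix$states[complete_taxa, , drop = FALSE]
  colnames(sub)[colSums(sub == "intact") == nrow(sub)]
}

leaf_loss_codes <- function(matrix, gene, taxa) {
  st <- matrix$states[taxa, gene]
  code <- ifelse(st == "intact", "present",
                 ifelse(st == "unsampled", "missing", "lost"))
  names(code) <- taxa
  code
}

#' Parsimony reconstruction of a gene's loss history
#'
#' Binary coding uses unordered (Fitch) parsimony over
#' `{present, lost}`; Dollo coding forbids regains, so the history is a
#' set of irreversible loss events. `min_changes` is the parsimony
#' length; `n_independent_losses` counts present-to-lost transitions in
#' the preferred most-parsimonious reconstructions: among MPRs, those
#' with the fewest lost-to-present regains are retained first (plastid
#' gene loss is effectively irreversible, so an MPR that trades a loss
#' for a regain is not biologically credible), and the minimum loss
#' count within that class is reported. `mpr_count` is the number of
#' equally parsimonious reconstructions (all MPRs).
#'
#' @param matrix a `gene_matrix`.
#' @param tree rooted ape `phylo` whose tips match the matrix taxa.
#' @param gene gene name (a column of the matrix).
#' @param coding `"binary"` (Fitch, default) or `"dollo"`.
#' @return object of class `loss_recon` with `node_states`
#'   (`present`/`lost`/`ambiguous` per node), `min_changes`,
#'   `n_independent_losses`, `mpr_count`.
#' @export
parsimony_reconstruct <- function(matrix, tree, gene,
                                  coding = c("binary", "dollo")) {
  coding <- match.arg(coding)
  if (!gene %in% colnames(matrix$states)) stop("unknown gene: ", gene)
  if (!all(tree$tip.label %in% rownames(matrix$states)))
    stop("tree/matrix taxon mismatch")
  code <- leaf_loss_codes(matrix, gene, tree$tip.label)
  if (coding == "dollo") return(dollo_reconstruct(tree, code, gene))
  fitch_reconstruct(tree, code, gene)
}

# Sankoff DP over {present=1, lost=2}; missing leaves admit both states.
# A combined cost (changes * B^2 + gains * B + losses) with B larger than
# the edge count makes one DP return the lexicographic minimum: among
# most-parsimonious reconstructions, those with the fewest lost->present
# regains are preferred (gene loss is effectively irreversible, so a
# reconstruction that invokes a regain to save a loss is not credible),
# and the present->lost transitions of that preferred class are counted.
fitch_reconstruct <- function(tree, code, gene) {
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  B <- nn + 1L
  cost_change <- matrix(c(0, 1, 1, 0), 2L)              # plain changes
  # [from, to]: present->lost = B^2 + 1 (a change and a loss),
  #             lost->present = B^2 + B (a change and a regain)
  cost_comb <- matrix(c(0, B^2 + B, B^2 + 1, 0), 2L)
  edges <- postorder_edges(tree)

  dp_pass <- function(cost) {
    D <- matrix(0, nn, 2L)
    Cnt <- matrix(1, nn, 2L)  # reconstruction counts (for min-change cost)
    for (i in seq_len(nt)) {
      if (code[i] == "present") { D[i, 2L] <- Inf; Cnt[i, 2L] <- 0 }
      if (code[i] == "lost") { D[i, 1L] <- Inf; Cnt[i, 1L] <- 0 }
    }
    for (j in seq_len(nrow(edges))) {
      par <- edges[j, 1L]; chd <- edges[j, 2L]
      for (s in 1:2) {
        alt <- D[chd, ] + cost[s, ]
        m <- min(alt)
        D[par, s] <- D[par, s] + m
        Cnt[par, s] <- Cnt[par, s] * sum(Cnt[chd, which(alt == m)])
      }
    }
    list(D = D, Cnt = Cnt)
  }

  plain <- dp_pass(cost_change)
  root <- root_node(tree)
  min_changes <- min(plain$D[root, ])
  mpr_count <- sum(plain$Cnt[root, plain$D[root, ] == min_changes])

  comb <- dp_pass(cost_comb)
  best <- min(comb$D[root, ])
  stopifnot(best %/% B^2 == min_changes)
  n_losses <- best %% B

  # node states across all MPRs (minimum-change criterion): a node is
  # "present"/"lost" if every MPR assigns that state, else "ambiguous"
  node_states <- mpr_state_sets(tree, code, plain$D, cost_change,
                                min_changes)
  structure(list(gene = gene, coding = "binary",
                 node_states = node_states,
                 min_changes = as.integer(min_changes),
                 n_independent_losses = as.integer(n_losses),
                 mpr_count = mpr_count),
            class = "loss_recon")
}

# Top-down feasibility: which states at each node occur in >= 1 MPR
mpr_state_sets <- function(tree, code, D, cost, min_changes) {
  nn <- n_nodes(tree)
  edges <- postorder_edges(tree)
  pre <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]
  root <- root_node(tree)
  # U[v, s] = minimal total tree cost achievable with node v in state s
  U <- matrix(Inf, nn, 2L)
  U[root, ] <- D[root, ]
  for (j in seq_len(nrow(pre))) {
    par <- pre[j, 1L]; chd <- pre[j, 2L]
    # cost of the rest of the tree if chd has state t:
    # min_s [ U[par,s] - min_t'(D[chd,t']+cost[s,t']) + cost[s,t] ] + D[chd,t]
    for (t in 1:2) {
      rest <- vapply(1:2, function(s) {
        U[par, s] - min(D[chd, ] + cost[s, ]) + cost[s, t]
      }, 0)
      U[chd, t] <- min(rest) + D[chd, t]
    }
  }
  states <- character(nn)
  for (v in seq_len(nn)) {
    feas <- which(U[v, ] <= min_changes + 1e-9)
    states[v] <- if (length(feas) == 2L) "ambiguous"
                 else c("present", "lost")[feas]
  }
  names(states) <- node_name(tree, seq_len(nn))
  states
}

# Dollo: a single present->lost transition per loss lineage, no regains.
# With the gene ancestrally present, the minimal history places one loss
# on every maximal subtree whose sampled tips are all lost.
dollo_reconstruct <- function(tree, code, gene) {
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  edges <- postorder_edges(tree)
  has_present <- logical(nn)   # subtree contains a "present" tip
  has_lost <- logical(nn)
  for (i in seq_len(nt)) {
    has_present[i] <- code[i] == "present"
    has_lost[i] <- code[i] == "lost"
  }
  for (j in seq_len(nrow(edges))) {
    par <- edges[j, 1L]; chd <- edges[j, 2L]
    has_present[par] <- has_present[par] || has_present[chd]
    has_lost[par] <- has_lost[par] || has_lost[chd]
  }
  root <- root_node(tree)
  if (!has_lost[root]) {
    states <- rep("present", nn)
    names(states) <- node_name(tree, seq_len(nn))
    return(structure(list(gene = gene, coding = "dollo",
                          node_states = states, min_changes = 0L,
                          n_independent_losses = 0L, mpr_count = 1L),
                     class = "loss_recon"))
  }
  # loss roots: deepest nodes with lost tips below and no present tips
  loss_root <- logical(nn)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
    if (!has_present[chd] && has_lost[chd] && has_present[par])
      loss_root[chd] <- TRUE
  }
  if (!has_present[root]) loss_root[root] <- TRUE  # loss precedes the root
  n_losses <- sum(loss_root)
  states <- rep("present", nn)
  for (v in which(loss_root)) states[clade_nodes(tree, v)] <- "lost"
  for (i in seq_len(nt)) if (code[i] == "lost") states[i] <- "lost"
  names(states) <- node_name(tree, seq_len(nn))
  structure(list(gene = gene, coding = "dollo", node_states = states,
                 min_changes = as.integer(n_losses),
                 n_independent_losses = as.integer(n_losses),
                 mpr_count = 1L),
            class = "loss_recon")
}

#' @export
print.loss_recon <- function(x, ...) {
  cat(sprintf("%s parsimony for %s: %d change(s), %d independent loss(es), %d MPR(s)\n",
              x$coding, x$gene, x$min_changes, x$n_independent_losses,
              x$mpr_count))
  invisible(x)
}

#' Write a gene matrix as a NEXUS-style character block
#'
#' States: 0 = intact, 1 = pseudogene, 2 = absent, ? = unsampled; one
#' character per gene, suitable for downstream parsimony programs.
#'
#' @param matrix a `gene_matrix`.
#' @param path output file.
#' @export
write_gene_matrix_nexus <- function(matrix, path) {
  st <- matrix$states
  code <- c(intact = "0", pseudogene = "1", absent = "2", unsampled = "?")
  rows <- vapply(rownames(st), function(tx)
    paste0(tx, "  ", paste0(code[st[tx, ]], collapse = "")), "")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=?;",
               sprintf("  [characters: %s]",
                       paste(colnames(st), collapse = " ")),
               "  MATRIX", paste0("    ", rows), "  ;", "END;"), path)
  invisible(path)
}

#' Exhaustive-enumeration oracle for loss counting
#'
#' Enumerates every assignment of `{present, lost}` to internal nodes
#' (and to missing-data tips), finds the minimum-change assignments and
#' returns the minimum number of present-to-lost transitions among them.
#' Intended as an independent check of [parsimony_reconstruct()] on
#' small trees.
#'
#' @param matrix a `gene_matrix`.
#' @param tree rooted ape `phylo` (<= 24 taxa).
#' @param gene gene name.
#' @return list with `min_changes` and `n_independent_losses`.
#' @export
count_losses_exhaustive <- function(matrix, tree, gene) {
  if (length(tree$tip.label) > 24L) stop("oracle limit: > 24 taxa")
  code <- leaf_loss_codes(matrix, gene, tree$tip.label)
  nn <- n_nodes(tree)
  nt <- length(tree$tip.label)
  free <- c(which(code == "missing"), (nt + 1L):nn)
  if (length(free) > 20L) stop("oracle limit: too many free nodes")
  fixed <- integer(nn)  # 1 present, 2 lost, 0 free
  fixed[which(code == "present")] <- 1L
  fixed[which(code == "lost")] <- 2L
  E <- tree$edge
  best <- c(Inf, Inf, Inf)  # (changes, gains, losses), lexicographic
  for (m in 0:(2^length(free) - 1L)) {
    st <- fixed
    st[free] <- 1L + bitwAnd(m %/% 2^(seq_along(free) - 1L), 1L)
    lo <- sum(st[E[, 1L]] == 1L & st[E[, 2L]] == 2L)
    ga <- sum(st[E[, 1L]] == 2L & st[E[, 2L]] == 1L)
    cand <- c(lo + ga, ga, lo)
    for (i in 1:3) {
      if (cand[i] < best[i]) { best <- cand; break }
      if (cand[i] > best[i]) break
    }
  }
  list(min_changes = as.integer(best[1L]),
       n_independent_losses = as.integer(best[3L]))
}
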