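# Equilibrium AT content from strong/weak substitution counts.
#
# Writing [GC] for the strong bases and [AT] for the weak ones, the
# per-branch substitution frequencies are
#   k1 = n([GC]->[AT]) / N_GC   and   k2 = n([AT]->[GC]) / N_AT ,
# with N_GC and N_AT counted on the parent (ancestral) sequence over the
# sites present at both branch endpoints. At equilibrium dN_GC/dt = 0 and
# the AT fraction tends to alpha_eq = k1 / (k1 + k2); branch time divides
# both k's and cancels, so it is never computed.

#' Count strong/weak substitutions on a branch
#'
#' Compares the reconstructed (or observed, for a tip) sequences at the
#' two endpoints of a branch. Only sites whose ancestral-indel
#' reconstruction marks both endpoints present, and where both endpoint
#' states are unambiguous bases, are used. A parent G/C with child A/T
#' increments `n_sw`; parent A/T with child G/C increments `n_ws`;
#' within-class changes (G<->C, A<->T) increment neither.
#'
#' @param recon an `ancestral_recon`.
#' @param branch either an edge index into `recon$tree$edge`, or the name
#'   of a child node (tip label or internal node name) identifying its
#'   parent branch.
#' @return list of class `branch_subst_counts`: `n_sw`, `n_ws`, `N_GC`,
#'   `N_AT`, `sites_used`.
#' @export
count_strong_weak <- function(recon, branch) {
  e <- resolve_branch(recon$tree, branch)
  par <- recon$tree$edge[e, 1L]
  chd <- recon$tree$edge[e, 2L]
  p <- recon$node_seq[par, ]
  c_ <- recon$node_seq[chd, ]
  ok <- recon$indel_presence[par, ] & recon$indel_presence[chd, ] &
    p %in% NT_STATES & c_ %in% NT_STATES
  p <- p[ok]; c_ <- c_[ok]
  strong_p <- p %in% c("G", "C")
  strong_c <- c_ %in% c("G", "C")
  structure(list(branch = e,
                 n_sw = sum(strong_p & !strong_c),
                 n_ws = sum(!strong_p & strong_c),
                 N_GC = sum(strong_p),
                 N_AT = sum(!strong_p),
                 sites_used = length(p)),
            class = "branch_subst_counts")
}

resolve_branch <- function(tree, branch) {
  if (is.numeric(branch)) {
    e <- as.integer(branch)
    if (e < 1L || e > nrow(tree$edge)) stop("unknown branch: ", branch)
    return(e)
  }
  nn <- node_name(tree, seq_len(n_nodes(tree)))
  v <- match(branch, nn)
  if (is.na(v)) stop("unknown branch: ", branch)
  e <- which(tree$edge[, 2L] == v)
  if (length(e) != 1L) stop("node has no parent branch: ", branch)
  e
}

sum_counts <- function(counts) {
  structure(list(branch = NA,
                 n_sw = sum(vapply(counts, `[[`, 0, "n_sw")),
                 n_ws = sum(vapply(counts, `[[`, 0, "n_ws")),
                 N_GC = sum(vapply(counts, `[[`, 0, "N_GC")),
                 N_AT = sum(vapply(counts, `[[`, 0, "N_AT")),
                 sites_used = sum(vapply(counts, `[[`, 0, "sites_used"))),
            class = "branch_subst_counts")
}

#' Equilibrium AT content from substitution counts
#'
#' Point estimate `alpha_eq = k1 / (k1 + k2)` with `k1 = n_sw / N_GC`
#' and `k2 = n_ws / N_AT`. Branch duration cancels and is not needed.
#'
#' @param counts a `branch_subst_counts` (possibly aggregated).
#' @return object of class `at_equilibrium` with `k1`, `k2`, `alpha_eq`.
#' @export
equilibrium_at <- function(counts) {
  if (counts$n_sw + counts$n_ws == 0L)
    stop("no informative substitutions on this branch set")
  k1 <- if (counts$N_GC > 0) counts$n_sw / counts$N_GC else 0
  k2 <- if (counts$N_AT > 0) counts$n_ws / counts$N_AT else 0
  structure(list(k1 = k1, k2 = k2, alpha_eq = k1 / (k1 + k2),
                 counts = counts),
            class = "at_equilibrium")
}

#' @export
print.at_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium AT content: %.4f (k1 = %.5f, k2 = %.5f)\n",
              x$alpha_eq, x$k1, x$k2))
  if (!is.null(x$ci))
    cat(sprintf("  %d%% CI [%.4f, %.4f] from %d bootstrap replicates\n",
                round(100 * diff(x$ci_level)), x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

# Branch set for a taxon under the two per-species scopes
taxon_branches <- function(tree, taxon, scope, ingroup_root = NULL) {
  tip <- match(taxon, tree$tip.label)
  if (is.na(tip)) stop("unknown taxon: ", taxon)
  if (scope == "terminal_branch") return(which(tree$edge[, 2L] == tip))
  if (is.null(ingroup_root)) ingroup_root <- root_node(tree)
  path <- integer(0)
  v <- tip
  while (v != ingroup_root) {
    e <- which(tree$edge[, 2L] == v)
    if (length(e) != 1L) break
    path <- c(path, e)
    v <- tree$edge[e, 1L]
  }
  path
}

#' Per-taxon equilibrium AT content from a reconstruction
#'
#' @param recon an `ancestral_recon`.
#' @param taxon tip label.
#' @param scope `"terminal_branch"` counts substitutions on the taxon's
#'   own pendant branch only; `"clade_path"` pools counts over all
#'   branches from `ingroup_root` (default: the root) down to the tip.
#' @param ingroup_root optional node number bounding the clade path.
#' @return an `at_equilibrium`.
#' @export
taxon_equilibrium_at <- function(recon, taxon,
                                 scope = c("terminal_branch", "clade_path"),
                                 ingroup_root = NULL) {
  scope <- match.arg(scope)
  br <- taxon_branches(recon$tree, taxon, scope, ingroup_root)
  cnt <- sum_counts(lapply(br, function(e) count_strong_weak(recon, e)))
  out <- equilibrium_at(cnt)
  out$taxon <- taxon
  out$scope <- scope
  out
}

#' Bootstrap confidence interval for the equilibrium AT content
#'
#' Resamples alignment columns with replacement, repeats ancestral
#' reconstruction and substitution counting on each pseudoreplicate
#' (model and branch lengths held at their full-data estimates) and takes
#' percentile bounds of `alpha_eq`. Because the marginal reconstruction
#' of a site depends only on its own column pattern under a fixed model,
#' per-pattern counts are computed once and replicates reduce to
#' reweighting patterns; this is exactly equivalent to rerunning the
#' reconstruction per replicate. Deterministic given `seed`.
#'
#' @param aln concatenated `nt_alignment` to resample.
#' @param tree rooted tree (or tree plus `outgroup`).
#' @param model fitted `gtr_model`.
#' @param taxon tip whose equilibrium is estimated.
#' @param scope see [taxon_equilibrium_at()].
#' @param n_boot number of pseudoreplicates (the reference analysis uses
#'   1000).
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95: 2.5th/97.5th percentiles).
#' @param outgroup optional rooting tip.
#' @param ingroup_root optional clade-path bound.
#' @return an `at_equilibrium` with `ci`, `n_boot`, `seed`,
#'   `n_skipped` (replicates without informative substitutions).
#' @export
bootstrap_equilibrium <- function(aln, tree, model, taxon,
                                  scope = c("terminal_branch", "clade_path"),
                                  n_boot = 1000L, seed = 1L, level = 0.95,
                                  outgroup = NULL, ingroup_root = NULL) {
  scope <- match.arg(scope)
  cp <- compress_patterns(aln)
  recon <- reconstruct_ancestral(cp$alignment, tree, model,
                                 outgroup = outgroup)
  br <- taxon_branches(recon$tree, taxon, scope, ingroup_root)
  # per-pattern indicator counts over the selected branches
  np <- n_sites(cp$alignment)
  per_pat <- matrix(0, np, 4L,
                    dimnames = list(NULL, c("n_sw", "n_ws", "N_GC", "N_AT")))
  for (e in br) {
    par <- recon$tree$edge[e, 1L]; chd <- recon$tree$edge[e, 2L]
    p <- recon$node_seq[par, ]; c_ <- recon$node_seq[chd, ]
    ok <- recon$indel_presence[par, ] & recon$indel_presence[chd, ] &
      p %in% NT_STATES & c_ %in% NT_STATES
    sp <- p %in% c("G", "C"); sc <- c_ %in% c("G", "C")
    per_pat[, "n_sw"] <- per_pat[, "n_sw"] + (ok & sp & !sc)
    per_pat[, "n_ws"] <- per_pat[, "n_ws"] + (ok & !sp & sc)
    per_pat[, "N_GC"] <- per_pat[, "N_GC"] + (ok & sp)
    per_pat[, "N_AT"] <- per_pat[, "N_AT"] + (ok & !sp)
  }
  S <- n_sites(aln)
  point <- colSums(per_pat * tabulate(cp$index, np))
  est <- equilibrium_at(as_counts(point))
  set.seed(seed)
  alphas <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    w <- tabulate(cp$index[sample.int(S, S, replace = TRUE)], np)
    tot <- colSums(per_pat * w)
    if (tot[["n_sw"]] + tot[["n_ws"]] == 0) next  # skipped replicate
    k1 <- if (tot[["N_GC"]] > 0) tot[["n_sw"]] / tot[["N_GC"]] else 0
    k2 <- if (tot[["N_AT"]] > 0) tot[["n_ws"]] / tot[["N_AT"]] else 0
    alphas[b] <- k1 / (k1 + k2)
  }
  n_skipped <- sum(is.na(alphas))
  if (n_skipped > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates had no informative substitutions",
                    n_skipped, n_boot))
  qs <- stats::quantile(alphas, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  est$taxon <- taxon
  est$scope <- scope
  est$ci <- qs
  est$ci_level <- c((1 - level) / 2, 1 - (1 - level) / 2)
  est$n_boot <- as.integer(n_boot)
  est$n_skipped <- n_skipped
  est$seed <- as.integer(seed)
  est$replicates <- alphas
  est
}

as_counts <- function(x) {
  structure(list(branch = NA, n_sw = x[["n_sw"]], n_ws = x[["n_ws"]],
                 N_GC = x[["N_GC"]], N_AT = x[["N_AT"]],
                 sites_used = NA_integer_),
            class = "branch_subst_counts")
}

#' Per-branch strong/weak substitution report
#'
#' @param recon an `ancestral_recon`.
#' @return data.frame with one row per branch: child node name, counts,
#'   `k1`, `k2`.
#' @export
branch_counts_table <- function(recon) {
  tree <- recon$tree
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    cnt <- count_strong_weak(recon, e)
    data.frame(child = node_name(tree, tree$edge[e, 2L]),
               n_sw = cnt$n_sw, n_ws = cnt$n_ws,
               N_GC = cnt$N_GC, N_AT = cnt$N_AT,
               sites_used = cnt$sites_used,
               k1 = if (cnt$N_GC > 0) cnt$n_sw / cnt$N_GC else NA,
               k2 = if (cnt$N_AT > 0) cnt$n_ws / cnt$N_AT else NA)
  })
  do.call(rbind, rows)
}
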