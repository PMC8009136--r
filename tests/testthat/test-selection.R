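test_that("codon pruning equals exhaustive enumeration on 3-taxon instances", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.1,c:0.3);")
  set.seed(5)
  for (i in 1:2) {
    simt <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,c:0.25);")
    cm <- codon_model(kappa = runif(1, 1, 4),
                      omega_map = c(all = runif(1, 0.05, 1)),
                      codon_freqs = as.numeric(stats::rgamma(61, 4)))
    sim <- simulate_codon_evolution(simt, cm, 5, seed = 30 + i)
    expect_lt(abs(codon_loglik(sim$alignment, tr, cm) -
                    brute_loglik_codon(sim$alignment, tr, cm)), 1e-6)
  }
})

test_that("codon likelihood closed forms and root invariance hold", {
  cm <- codon_model(2, c(all = 0.3), rep(1 / 61, 61))
  aln <- codonize(nt_alignment(c(a = "ATGAAATTT", b = "ATGAAATTT",
                                 c = "ATGAAATTT")), "allow")
  tr0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  obs <- c("ATG", "AAA", "TTT")
  expect_equal(codon_loglik(aln, tr0, cm),
               sum(log(cm$codon_freqs[obs])), tolerance = 1e-10)
  # same unrooted tree, different root placements along one branch
  aln2 <- codonize(nt_alignment(c(a = "ATGAAATTTCCG", b = "ATGAAGTTTCCG",
                                  c = "ATGGAATTACCG")), "allow")
  t1 <- ape::read.tree(text = "(a:0.2,b:0.1,c:0.3);")
  t2 <- ape::read.tree(text = "((a:0.2,b:0.1):0.12,c:0.18);")
  t3 <- ape::read.tree(text = "((a:0.2,b:0.1):0.3,c:0.0);")
  lls <- c(codon_loglik(aln2, t1, cm), codon_loglik(aln2, t2, cm),
           codon_loglik(aln2, t3, cm))
  expect_lt(max(lls) - min(lls), 1e-8)
  # gap codons are missing data: removing branch info keeps finiteness
  alng <- codonize(nt_alignment(c(a = "ATG---TTT", b = "ATGAAATTT",
                                  c = "ATGAAGTTT")), "allow")
  expect_true(is.finite(codon_loglik(alng, t1, cm)))
})

test_that("a degenerate painting reproduces the one-ratio fit", {
  tr <- balanced_tree(4, 0.15, "t")
  cm <- codon_model(2, c(all = 0.4), rep(1 / 61, 61))
  sim <- simulate_codon_evolution(tr, cm, 60, seed = 2)
  same <- rep("ingroup", nrow(tr$edge))
  f1 <- fit_branch_model(sim$alignment, tr, same, "one_ratio")
  f3 <- fit_branch_model(sim$alignment, tr, same, "three_ratio")
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-4)
  # adding omega classes never decreases the maximized likelihood
  painting <- paint_branches(tr, c("t1", "t2"))
  fo <- fit_branch_model(sim$alignment, tr, painting, "one_ratio")
  fn <- fit_branch_model(sim$alignment, tr, painting, "null_equal",
                         init = list(kappa = fo$kappa,
                                     omega = mean(fo$omega),
                                     bl = fo$tree$edge.length))
  fa <- fit_branch_model(sim$alignment, tr, painting, "three_ratio",
                         init = list(kappa = fn$kappa,
                                     omega = mean(fn$omega),
                                     bl = fn$tree$edge.length))
  expect_gte(fn$loglik, fo$loglik - 1e-4)
  expect_gte(fa$loglik, fn$loglik - 1e-4)
  tt <- lrt_dnds(fa, fn)
  expect_gte(tt$lrt, 0)
  expect_true(tt$p_value >= 0 && tt$p_value <= 1)
})

test_that("Benjamini-Hochberg matches the step-up formula and the published q-values", {
  # single test: q = p
  expect_equal(benjamini_hochberg(0.03), 0.03)
  # independent step-up oracle on random vectors
  set.seed(6)
  for (i in 1:5) {
    p <- runif(8)
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- numeric(m)
    oracle[o] <- pmin(q_sorted, 1)
    expect_equal(benjamini_hochberg(p), oracle)
  }
  # monotone along sorted p's
  p <- sort(runif(10))
  expect_true(all(diff(benjamini_hochberg(p)) >= -1e-12))
  expect_error(benjamini_hochberg(numeric(0)), "empty")
  # published table: recoverable q-values reproduced at printed precision
  # (relative comparison; the rank-1 row is printed as p*m/rank)
  bh <- thismia_bh_worked_example()
  expect_lt(abs(bh$q_value[bh$label == "rps2"] / 4.54e-7 - 1), 0.005)
  expect_lt(abs(bh$q_rank[bh$label == "rps4_atypical_start_excluded"] /
                  7.48e-7 - 1), 0.005)
  expect_lt(abs(bh$q_value[bh$label == "rps3"] / 2.40e-6 - 1), 0.005)
})

test_that("branch-class omegas are recovered from simulated data", {
  tr <- balanced_tree(8, 0, "t")
  set.seed(2)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.25)
  painting <- paint_branches(tr, paste0("t", 1:4))
  cm <- codon_model(2.5, c(ingroup = 0.5, transition = 0.1, other = 0.1),
                    rep(1 / 61, 61))
  sim <- simulate_codon_evolution(tr, cm, 300, seed = 11,
                                  painting = painting)
  fit <- fit_branch_model(sim$alignment, tr, painting, "three_ratio")
  expect_lt(abs(fit$omega[["ingroup"]] - 0.5), 0.15)
  expect_lt(abs(fit$omega[["other"]] - 0.1), 0.15)
})
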