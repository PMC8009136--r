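test_that("simulators are seed-deterministic", {
  tr <- balanced_tree(4, 0.1, "t")
  m <- gtr_model(gamma_shape = 0.5)
  a1 <- simulate_nucleotide_evolution(tr, m, 200, seed = 3)
  a2 <- simulate_nucleotide_evolution(tr, m, 200, seed = 3)
  expect_identical(alignment_strings(a1$alignment),
                   alignment_strings(a2$alignment))
  cm <- codon_model(2, c(all = 0.3), rep(1 / 61, 61))
  c1 <- simulate_codon_evolution(tr, cm, 50, seed = 4)
  c2 <- simulate_codon_evolution(tr, cm, 50, seed = 4)
  expect_identical(alignment_strings(c1$alignment),
                   alignment_strings(c2$alignment))
  pnt <- rep("other", nrow(tr$edge))
  o1 <- simulate_ou_traits(tr, pnt, c(other = 1), 2, 0.5, seed = 5)
  o2 <- simulate_ou_traits(tr, pnt, c(other = 1), 2, 0.5, seed = 5)
  expect_identical(o1$trait, o2$trait)
  g1 <- simulate_gene_loss(tr, 0.2, 20, seed = 6)
  g2 <- simulate_gene_loss(tr, 0.2, 20, seed = 6)
  expect_identical(g1$matrix$states, g2$matrix$states)
  t1 <- make_toy_plastome(3000, 900, 1200, seed = 7)
  t2 <- make_toy_plastome(3000, 900, 1200, seed = 7)
  expect_identical(t1$record$seq, t2$record$seq)
})

test_that("zero branch lengths copy the root everywhere", {
  tr <- balanced_tree(4, 0, "t")
  m <- gtr_model()
  sim <- simulate_nucleotide_evolution(tr, m, 300, seed = 9)
  root <- sim$truth$node_seq[5, ]
  for (i in 1:4)
    expect_identical(unname(sim$alignment$mat[i, ]), unname(root))
})

test_that("single-branch divergence matches the Jukes-Cantor closed form", {
  t <- 0.1
  tr <- ape::read.tree(text = sprintf("(a:%f,b:0);", t))
  m <- gtr_model()   # equal rates, equal frequencies
  n <- 60000
  sim <- simulate_nucleotide_evolution(tr, m, n, seed = 12)
  pdiff <- mean(sim$alignment$mat[1, ] != sim$alignment$mat[2, ])
  p_expect <- 3 / 4 * (1 - exp(-4 * t / 3))
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(pdiff - p_expect), 3 * se)
})

test_that("long branches reach the stationary AT content", {
  tr <- ape::read.tree(text = "(a:20,b:20);")
  m <- gtr_model(base_freqs = c(.4, .1, .1, .4), gamma_shape = Inf)
  sim <- simulate_nucleotide_evolution(tr, m, 50000, seed = 13,
                                       root_freqs = rep(0.25, 4))
  at_tip <- mean(sim$alignment$mat[1, ] %in% c("A", "T"))
  expect_lt(abs(at_tip - 0.8), 0.02)
})

test_that("omega = 0 forbids nonsynonymous endpoint changes", {
  tr <- ape::read.tree(text = "(a:1.5,b:1.5);")
  cm <- codon_model(2, c(all = 1e-9), rep(1 / 61, 61))
  sim <- simulate_codon_evolution(tr, cm, 800, seed = 14)
  aa_a <- translate_codon(apply(matrix(sim$alignment$mat[1, ], nrow = 3),
                                2, paste0, collapse = ""))
  aa_b <- translate_codon(apply(matrix(sim$alignment$mat[2, ], nrow = 3),
                                2, paste0, collapse = ""))
  expect_true(all(aa_a == aa_b))
})

test_that("generator and likelihood agree (self-consistency)", {
  tr <- balanced_tree(4, 0.1, "t")
  m <- gtr_model(base_freqs = c(.35, .15, .15, .35), gamma_shape = Inf)
  worse <- gtr_model(base_freqs = c(.15, .35, .35, .15), gamma_shape = Inf)
  wins <- mean(vapply(1:20, function(i) {
    sim <- simulate_nucleotide_evolution(tr, m, 2000, seed = 100 + i)
    loglik_gtr(sim$alignment, tr, m) > loglik_gtr(sim$alignment, tr, worse)
  }, TRUE))
  expect_gte(wins, 0.95)
})

test_that("OU simulation matches its closed-form limits", {
  # huge alpha: tips sit at the regime optimum with variance sigma2/(2 alpha)
  tr <- balanced_tree(16, 1, "t")
  painting <- paint_branches(tr, paste0("t", 1:4))
  s <- simulate_ou_traits(tr, painting, c(ingroup = 2, other = -1),
                          alpha = 400, sigma2 = 0.4, seed = 15)
  expect_lt(max(abs(s$trait[paste0("t", 1:4)] - 2)), 0.3)
  expect_lt(max(abs(s$trait[paste0("t", 5:16)] + 1)), 0.3)
  # star tree: iid normal with stationary-transition moments
  st <- ape::stree(3000)
  st$tip.label <- paste0("s", seq_len(3000))
  st$edge.length <- rep(1, 3000)
  s2 <- simulate_ou_traits(st, rep("r", 3000), c(r = 1), alpha = 2,
                           sigma2 = 0.5, seed = 16)
  v_exp <- 0.5 * (1 - exp(-4)) / 4
  expect_lt(abs(mean(s2$trait) - 1), 0.02)
  expect_lt(abs(var(s2$trait) / v_exp - 1), 0.1)
  # alpha -> 0: contrast variance matches the Brownian expectation
  two <- ape::read.tree(text = "(a:1,b:1);")
  s3 <- vapply(1:4000, function(i)
    diff(simulate_ou_traits(two, c("r", "r"), c(r = 0), alpha = 1e-8,
                            sigma2 = 1, seed = 2000 + i)$trait), 0)
  expect_lt(abs(var(s3) / 2 - 1), 0.05)
})

test_that("gene-loss simulation respects irreversibility and its truth", {
  tr <- balanced_tree(8, 1, "t")
  none <- simulate_gene_loss(tr, 0, 10, seed = 17)
  expect_true(all(none$matrix$states == "intact"))
  expect_true(all(none$truth$n_events == 0))
  all_lost <- simulate_gene_loss(tr, 1, 5, seed = 18)
  expect_true(all(all_lost$matrix$states == "absent"))
  # with probability 1 the two root branches lose; descendants are
  # already lost, so exactly 2 events per gene
  expect_true(all(all_lost$truth$n_events == 2L))
})

test_that("toy plastomes pack genes and expose construction truth", {
  toy <- make_toy_plastome(5000, 1500, 3000, gene_order = c("g1", "g2"),
                           seed = 4)
  expect_equal(nchar(toy$record$seq), 5000 + 1500 + 2 * 3000)
  expect_equal(toy$truth$ir_len, 3000)
  expect_equal(classify_gene(toy$record, "g1"), "intact")
  expect_error(make_toy_plastome(500, 300, 400,
                                 gene_order = paste0("g", 1:5)),
               "infeasible packing")
})
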