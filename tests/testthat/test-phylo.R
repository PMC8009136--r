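test_that("pruning likelihood equals exhaustive enumeration on 4-taxon instances", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2);")
  set.seed(11)
  for (i in 1:5) {
    aln <- random_alignment(letters[1:4], 8)
    m <- gtr_model(exchangeabilities = runif(6, 0.5, 3),
                   base_freqs = as.numeric(stats::rgamma(4, 5) |>
                                             (\(x) x / sum(x))()),
                   gamma_shape = runif(1, 0.4, 2), n_categories = 4)
    expect_lt(abs(loglik_gtr(aln, tr, m) - brute_loglik_nt(aln, tr, m)),
              1e-8)
  }
})

test_that("likelihood basics: site independence, closed forms, taxon checks", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2);")
  m <- gtr_model(base_freqs = c(.3, .2, .2, .3), gamma_shape = 0.7)
  aln <- nt_alignment(c(a = "ACGTA", b = "ACGTT", c = "GCGTA", d = "ACTTA"))
  ll <- loglik_gtr(aln, tr, m)
  dbl <- nt_alignment(c(a = "ACGTAACGTA", b = "ACGTTACGTT",
                        c = "GCGTAGCGTA", d = "ACTTAACTTA"))
  expect_equal(loglik_gtr(dbl, tr, m), 2 * ll, tolerance = 1e-10)
  # zero branch lengths + identical sequences: sum of log stationary freqs
  tr0 <- tr
  tr0$edge.length[] <- 0
  ident <- nt_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_equal(loglik_gtr(ident, tr0, m), sum(log(m$base_freqs)),
               tolerance = 1e-10)
  bad <- nt_alignment(c(a = "ACGT", b = "ACGT", x = "ACGT", y = "ACGT"))
  expect_error(loglik_gtr(bad, tr, m), "taxon mismatch")
})

test_that("likelihood is invariant to root placement of the same unrooted tree", {
  aln <- nt_alignment(c(a = "ACGTACGGTT", b = "ACTTACGGAT",
                        c = "GCGTACAGTT"))
  m <- gtr_model(exchangeabilities = c(1.5, 3, 0.8, 1, 4, 1),
                 base_freqs = c(.35, .15, .2, .3), gamma_shape = 1)
  t1 <- ape::read.tree(text = "(a:0.2,b:0.1,c:0.3);")
  t2 <- ape::read.tree(text = "((a:0.2,b:0.1):0.12,c:0.18);")
  t3 <- ape::read.tree(text = "((a:0.2,b:0.1):0.25,c:0.05);")
  lls <- c(loglik_gtr(aln, t1, m), loglik_gtr(aln, t2, m),
           loglik_gtr(aln, t3, m))
  expect_lt(max(lls) - min(lls), 1e-8)
})

test_that("GTR+Gamma likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2);")
  m <- gtr_model(exchangeabilities = c(1.2, 2.5, 0.8, 1.1, 3, 1),
                 base_freqs = c(.3, .2, .2, .3), gamma_shape = 0.7,
                 n_categories = 4)
  sim <- simulate_nucleotide_evolution(tr, m, 300, seed = 2)
  dat <- phangorn::phyDat(sim$alignment$mat)
  ref <- phangorn::pml(tr, dat, bf = m$base_freqs,
                       Q = m$exchangeabilities, k = 4, shape = 0.7)$logLik
  expect_equal(loglik_gtr(sim$alignment, tr, m), ref, tolerance = 1e-8)
})

test_that("fitted two-taxon distance matches the Jukes-Cantor closed form", {
  p <- 0.15
  n <- 4000
  set.seed(8)
  s1 <- sample(NT, n, TRUE)
  s2 <- s1
  flip <- sample(n, round(p * n))
  for (i in flip) s2[i] <- sample(setdiff(NT, s1[i]), 1)
  aln <- nt_alignment(rbind(a = s1, b = s2))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  f <- fit_gtr(aln, tr, n_categories = 1, equal_exchangeabilities = TRUE,
               base_freqs = rep(0.25, 4))
  d_jc <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(sum(f$tree$edge.length), d_jc, tolerance = 1e-3)
})

test_that("degenerate and simulated alignments are fitted sensibly", {
  tr <- balanced_tree(4, 0.1, "s")
  ident <- nt_alignment(stats::setNames(rep("ACGTACGT", 4),
                                        paste0("s", 1:4)))
  expect_warning(f0 <- fit_gtr(ident, tr), "single distinct")
  expect_true(all(f0$tree$edge.length == 0))
  # parameter recovery at 5 kb on 8 taxa (Monte-Carlo tolerances)
  tr8 <- balanced_tree(8, 0, "t")
  set.seed(5)
  tr8$edge.length <- runif(nrow(tr8$edge), 0.05, 0.3)
  mtrue <- gtr_model(c(1.5, 3, 0.7, 1.2, 4, 1), c(.35, .15, .18, .32),
                     gamma_shape = 0.8, n_categories = 4)
  sim <- simulate_nucleotide_evolution(tr8, mtrue, 5000, seed = 6)
  ft <- fit_gtr(sim$alignment, tr8)
  expect_lt(max(abs(ft$model$exchangeabilities - mtrue$exchangeabilities) /
                  mtrue$exchangeabilities), 0.35)
  expect_lt(max(abs(ft$model$base_freqs - mtrue$base_freqs)), 0.02)
  expect_lt(abs(ft$model$gamma_shape - 0.8) / 0.8, 0.4)
  # monotone improvement over a neutral starting model
  expect_gte(ft$loglik,
             loglik_gtr(sim$alignment, tr8,
                        gtr_model(gamma_shape = 1, n_categories = 4)))
})

test_that("marginal ancestral posteriors match exhaustive enumeration", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2);")
  m <- gtr_model(exchangeabilities = c(1.2, 2.5, 0.8, 1.1, 3, 1),
                 base_freqs = c(.3, .2, .2, .3), gamma_shape = 0.7)
  set.seed(13)
  aln <- random_alignment(letters[1:4], 6)
  rec <- reconstruct_ancestral(aln, tr, m)
  for (s in 1:6) {
    oracle <- brute_marginals_nt(aln, tr, m, s)
    got <- t(vapply(paste0("node", 5:7),
                    function(nd) rec$posteriors[[nd]][, s], numeric(4)))
    expect_lt(max(abs(oracle - got)), 1e-10)
    # MAP state maximizes the posterior
    expect_equal(unname(rec$node_seq["node5", s]),
                 NT[which.max(rec$posteriors[["node5"]][, s])])
  }
})

test_that("invariant columns reconstruct to the shared state with high confidence", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2);")
  m <- gtr_model(base_freqs = c(.3, .2, .2, .3), gamma_shape = 1)
  aln <- nt_alignment(stats::setNames(rep("AAAA", 4), letters[1:4]))
  rec <- reconstruct_ancestral(aln, tr, m)
  expect_true(all(rec$node_seq[5:7, ] == "A"))
  expect_gt(min(vapply(rec$posteriors, function(p) min(p["A", ]), 0)), 0.95)
})

test_that("root MAP accuracy beats the majority-state floor and is calibrated", {
  tr <- balanced_tree(8, 0.15, "t")
  m <- gtr_model(c(1.2, 2.5, 0.8, 1.1, 3, 1), c(.3, .2, .2, .3),
                 gamma_shape = Inf)
  sim <- simulate_nucleotide_evolution(tr, m, 5000, seed = 21)
  rec <- reconstruct_ancestral(sim$alignment, tr, m)
  root <- "node9"
  truth <- sim$truth$node_seq[root, ]
  map <- rec$node_seq[root, ]
  acc <- mean(map == truth)
  majority <- max(table(factor(unlist(
    lapply(1:8, function(i) sim$alignment$mat[i, ])), levels = NT))) / 40000
  expect_gt(acc, majority)
  conf <- rec$posteriors[[root]][cbind(match(map, NT), seq_along(map))]
  hi <- conf >= 0.9
  expect_gte(mean((map == truth)[hi]), 0.85)
})

test_that("ancestral indel reconstruction handles the boundary cases", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2);")
  gapless <- nt_alignment(stats::setNames(rep("ACGT", 4), letters[1:4]))
  ri <- reconstruct_indels(gapless, tr)
  expect_true(all(ri$presence))
  mixed <- nt_alignment(c(a = "A-G----T", b = "ACG----T", c = "ACG----A",
                          d = "ACG----T"))
  rm_ <- reconstruct_indels(mixed, tr)
  # gap confined to one leaf: internal nodes present at that site
  expect_true(all(rm_$presence[5:7, 2]))
  # all-gap sites: absent everywhere
  expect_true(all(!rm_$presence[, 4:7]))
  # two-state posterior against direct enumeration on a 3-taxon tree
  tr3 <- ape::read.tree(text = "((a:0.3,b:0.3):0.2,c:0.5);")
  aln3 <- nt_alignment(c(a = "A-A", b = "AAA", c = "A-A"))
  r3 <- reconstruct_indels(aln3, tr3)
  g <- r3$rates[["gain"]]
  l <- r3$rates[["loss"]]
  P <- function(t) plastevol:::two_state_P(g, l, t)
  prior <- c(l, g) / (g + l)
  # enumerate internal nodes (4 = root, 5 = ab ancestor) for site 2
  obs <- c(a = 1L, b = 2L, c = 1L)  # 1 absent, 2 present
  post <- matrix(0, 2, 2)
  for (r4 in 1:2) for (r5 in 1:2) {
    pr <- prior[r4] * P(0.5)[r4, obs["c"]] * P(0.2)[r4, r5] *
      P(0.3)[r5, obs["a"]] * P(0.3)[r5, obs["b"]]
    post[1, r4] <- post[1, r4] + pr
    post[2, r5] <- post[2, r5] + pr
  }
  post <- post / rowSums(post)
  expect_equal(unname(r3$presence[4:5, 2]), unname(post[, 2] > 0.5))
})

test_that("rooting on the outgroup midpoint halves the pendant branch", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.1,(c:0.3,d:0.1):0.15);")
  rt <- root_at_outgroup_midpoint(tr, "a")
  expect_true(ape::is.rooted(rt))
  e <- which(rt$edge[, 2L] == match("a", rt$tip.label))
  other <- setdiff(which(rt$edge[, 1L] == rt$edge[e, 1L]), e)
  expect_equal(rt$edge.length[e], rt$edge.length[other])
})
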