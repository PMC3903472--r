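# 4-taxon trees over A,B,C,D = taxa 1..4
tree_AB_CD <- matrix(c(5L, 1L, 5L, 2L, 5L, 6L, 6L, 3L, 6L, 4L),
                     ncol = 2, byrow = TRUE)
tree_AC_BD <- matrix(c(5L, 1L, 5L, 3L, 5L, 6L, 6L, 2L, 6L, 4L),
                     ncol = 2, byrow = TRUE)

test_that("Fitch counting matches the enumerate-all-assignments oracle", {
  X <- matrix(c(1, 1, 0, 0), ncol = 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_length(tree_AB_CD, X), 1)
  expect_equal(fitch_length(tree_AC_BD, X), 2)
  expect_equal(fitch_length(tree_AC_BD, X),
               oracle_length(tree_AC_BD, 4, X))
  # constant matrix: zero steps on any tree
  Xc <- matrix(1L, 4, 3, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_length(tree_AB_CD, Xc), 0)
  # random matrices against the oracle
  for (r in 1:10) {
    Xr <- random_matrix(6, 8, seed = 100 + r)
    fit <- exhaustive_search(Xr)
    for (tr in fit$trees[1])
      expect_equal(fitch_length(tr, Xr), oracle_length(tr, 6, Xr))
  }
  expect_error(fitch_length(tree_AB_CD, random_matrix(5, 3)), "match")
})

test_that("Fitch length is invariant under taxon permutation and accepts phylo", {
  X <- random_matrix(7, 12, seed = 2)
  fit <- exhaustive_search(X)
  tr <- fit$trees[[1]]
  len <- fitch_length(tr, X)
  # permute taxon labels and relabel the tree accordingly
  perm <- sample(7)
  Xp <- X[perm, , drop = FALSE]
  trp <- tr
  trp[trp <= 7] <- match(trp[trp <= 7], perm)
  expect_equal(fitch_length(trp, Xp), len)
  # the same topology via ape round-trips to the same length
  clad <- root_and_annotate(fit)
  expect_equal(fitch_length(clad$phylo, X), len)
})

test_that("exhaustive search finds the known 4-taxon optimum and refuses n > 9", {
  X <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0))
  rownames(X) <- c("A", "B", "C", "D")
  fit <- exhaustive_search(X)
  expect_equal(fit$best_length, 4L)
  expect_equal(fit$n_examined, 3L)
  expect_equal(length(fit$trees), 1L)
  # the winning topology pairs A with B
  expect_equal(oncoclade:::.split_signature(fit$trees[[1]], 4),
               oncoclade:::.split_signature(tree_AB_CD, 4))
  expect_error(exhaustive_search(random_matrix(10, 4)), "> 9 taxa")
  # 3 taxa: the single topology
  fit3 <- exhaustive_search(random_matrix(3, 5, seed = 3))
  expect_equal(length(fit3$trees), 1L)
  expect_equal(fit3$n_examined, 1L)
})

test_that("a perfect phylogeny is scored at one step per character", {
  pp <- make_perfect_phylogeny(8, seed = 6)
  fit <- exhaustive_search(pp$X)
  expect_equal(fit$best_length, ncol(pp$X))
})

test_that("branch-and-bound equals exhaustive search on random matrices", {
  for (r in 1:20) {
    X <- random_matrix(7, 20, seed = 200 + r)
    expect_equal(branch_and_bound_search(X)$best_length,
                 exhaustive_search(X)$best_length)
  }
  # constant matrix: all topologies optimal at length 0
  Xc <- matrix(1L, 5, 4, dimnames = list(paste0("t", 1:5), NULL))
  fitc <- branch_and_bound_search(Xc)
  expect_equal(fitc$best_length, 0L)
  expect_equal(length(fitc$trees), 15L)  # all 5-taxon topologies
})

test_that("branch-and-bound recovers a 15-taxon perfect phylogeny", {
  pp <- make_perfect_phylogeny(15, seed = 9)
  fit <- branch_and_bound_search(pp$X)
  expect_true(fit$complete)
  expect_equal(fit$best_length, ncol(pp$X))
  clad <- root_and_annotate(fit)
  got <- cladogram_clades(clad)
  for (cl in pp$clades)
    expect_true(clade_string(paste0("t", cl)) %in% got)
})

test_that("the node budget guard surfaces incomplete searches", {
  X <- random_matrix(8, 20, seed = 4)
  fit <- branch_and_bound_search(X, node_budget = 20)
  expect_false(fit$complete)
})

test_that("heuristic search is seed-deterministic and never beats the optimum", {
  X <- random_matrix(7, 20, seed = 5)
  a <- heuristic_search(X, seed = 42, n_starts = 5)
  b <- heuristic_search(X, seed = 42, n_starts = 5)
  expect_identical(a$trees, b$trees)
  expect_identical(a$best_length, b$best_length)
  opt <- exhaustive_search(X)$best_length
  expect_gte(a$best_length, opt)
  hits <- 0L
  for (r in 1:20) {
    Xr <- random_matrix(7, 20, seed = 400 + r)
    if (heuristic_search(Xr, seed = r, n_starts = 10)$best_length ==
        exhaustive_search(Xr)$best_length) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("parsimony-uninformative characters do not change the optimal set", {
  X <- random_matrix(6, 10, seed = 7)
  fit1 <- exhaustive_search(X)
  extra <- cbind(rep(1L, 6), rep(0L, 6), c(1L, rep(0L, 5)))
  X2 <- cbind(X, extra)
  rownames(X2) <- rownames(X)
  fit2 <- exhaustive_search(X2)
  expect_equal(fit2$best_length, fit1$best_length + 1L)  # singleton adds 1
  sig <- function(f) sort(vapply(f$trees, oncoclade:::.split_signature,
                                 character(1), ntaxa = 6))
  expect_equal(sig(fit2), sig(fit1))
})

test_that("Camin-Sokal counts irreversible origins", {
  # character 1100 on ((A,B),(C,D)): one origin either model
  X <- matrix(c(1, 1, 0, 0), ncol = 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_length(tree_AB_CD, X, model = "caminsokal"), 1)
  # 1010 on ((A,B),(C,D)) needs two origins without reversals
  X2 <- matrix(c(1, 0, 1, 0), ncol = 1,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_length(tree_AB_CD, X2, model = "caminsokal"), 2)
  # Camin-Sokal length is never below Wagner length
  for (r in 1:5) {
    Xr <- random_matrix(6, 8, seed = 500 + r)
    tr <- exhaustive_search(Xr)$trees[[1]]
    expect_gte(fitch_length(tr, Xr, model = "caminsokal"),
               fitch_length(tr, Xr))
  }
  fit_cs <- exhaustive_search(make_perfect_phylogeny(6, 2)$X,
                              model = "caminsokal")
  expect_equal(fit_cs$best_length,
               ncol(make_perfect_phylogeny(6, 2)$X))
})

test_that("parsimony lengths agree with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  for (r in 1:5) {
    X <- random_matrix(7, 15, seed = 600 + r)
    fit <- exhaustive_search(X)
    clad <- root_and_annotate(fit)
    dat <- phangorn::phyDat(X, type = "USER", levels = c(0, 1))
    expect_equal(phangorn::parsimony(clad$phylo, dat),
                 fit$best_length)
  }
})

test_that("rooting assigns synapomorphies where the characters demand", {
  pp <- make_perfect_phylogeny(10, seed = 11)
  # name characters after their clades for readability
  colnames(pp$X) <- paste0("c", seq_len(ncol(pp$X)))
  fit <- branch_and_bound_search(pp$X)
  clad <- root_and_annotate(fit)
  nt <- clad$node_table
  for (i in seq_along(pp$clades)) {
    want_leaves <- clade_string(paste0("t", pp$clades[[i]]))
    row <- nt[vapply(strsplit(nt$leaves, ","), function(x)
      clade_string(x) == want_leaves, logical(1)), ]
    expect_true(nrow(row) >= 1)
    expect_true(any(grepl(paste0("\\bc", i, "\\b"), row$synapomorphies)))
  }
  # a character shared by all taxa belongs to the root
  Xall <- cbind(pp$X, everyone = 1L)
  clad2 <- root_and_annotate(fit$trees[[1]], Xall)
  root_row <- clad2$node_table[clad2$node_table$node == "Nd1", ]
  expect_match(root_row$synapomorphies, "everyone")
  expect_match(root_row$reconstructed_gains, "everyone")
  # a private character is an autapomorphy of its leaf, not of any node
  Xpriv <- cbind(pp$X, private = as.integer(seq_len(10) == 3))
  clad3 <- root_and_annotate(fit$trees[[1]], Xpriv)
  leaf_row <- clad3$node_table[clad3$node_table$node == "t3", ]
  expect_match(leaf_row$synapomorphies, "private")
  internal <- clad3$node_table[grepl("^Nd", clad3$node_table$node), ]
  expect_false(any(grepl("private", internal$synapomorphies)))
})

test_that("strict consensus keeps exactly the shared clades", {
  X <- random_matrix(4, 6, seed = 13)
  rownames(X) <- c("A", "B", "C", "D")
  # identical trees: consensus is that tree
  cons1 <- strict_consensus(list(tree_AB_CD, tree_AB_CD), X)
  expect_true(clade_string(c("A", "B")) %in% cladogram_clades(cons1) ||
                clade_string(c("C", "D")) %in% cladogram_clades(cons1))
  # all three 4-taxon topologies: star tree
  tree_AD_BC <- matrix(c(5L, 1L, 5L, 4L, 5L, 6L, 6L, 2L, 6L, 3L),
                       ncol = 2, byrow = TRUE)
  cons_star <- strict_consensus(list(tree_AB_CD, tree_AC_BD, tree_AD_BC), X)
  expect_equal(cladogram_clades(cons_star), clade_string(c("A", "B", "C", "D")))
  expect_error(strict_consensus(list(), X), "at least one")
  # 5-taxon trees sharing only the (A,B) clade
  X5 <- random_matrix(5, 6, seed = 14)
  rownames(X5) <- c("A", "B", "C", "D", "E")
  t1 <- matrix(c(6L, 1L, 6L, 2L, 6L, 7L, 7L, 3L, 7L, 8L, 8L, 4L, 8L, 5L),
               ncol = 2, byrow = TRUE)  # (A,B) with (D,E)
  t2 <- matrix(c(6L, 1L, 6L, 2L, 6L, 7L, 7L, 4L, 7L, 8L, 8L, 3L, 8L, 5L),
               ncol = 2, byrow = TRUE)  # (A,B) with (C,E)
  # give the characters a signal placing AB as a real clade
  X5[, 1] <- c(1L, 1L, 0L, 0L, 0L)
  cons <- strict_consensus(list(t1, t2), X5)
  got <- cladogram_clades(cons)
  # the shared AB|CDE split is present (as one of its sides) ...
  expect_true(clade_string(c("A", "B")) %in% got ||
                clade_string(c("C", "D", "E")) %in% got)
  # ... and the conflicting DE|ABC split of t1 is not
  expect_false(clade_string(c("D", "E")) %in% got)
  expect_false(clade_string(c("A", "B", "C")) %in% got)
})

test_that("the central fit function dispatches and prints", {
  X <- random_matrix(5, 8, seed = 15)
  fit <- parsimony_search(X)
  expect_equal(fit$method, "exhaustive")
  expect_output(print(fit), "Maximum-parsimony fit")
  expect_output(print(root_and_annotate(fit)), "Cladogram")
  fit2 <- parsimony_search(random_matrix(11, 10, seed = 16))
  expect_equal(fit2$method, "branch_and_bound")
})
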