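# Maximum-parsimony inference on the binary aberration matrix. Trees are
# unrooted binary topologies stored as 2-column integer edge matrices:
# leaves 1..n index the matrix rows, internal nodes n+1 and up. Wagner
# (free-reversal) counting is the default character model; Camin-Sokal
# (irreversible 0->1, rooted at the aberration-free ancestor) is optional.

.as_binary_matrix <- function(X) {
  if (inherits(X, "aberration_matrix")) X <- unclass(X)
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (length(X) && !all(X %in% c(0L, 1L)))
    stop("character matrix must be binary 0/1")
  X
}

# split search work from uninformative characters whose cost is the same
# on every topology: under Wagner, characters present in exactly 1 or
# exactly n-1 taxa cost 1 step on any binary tree and constant characters
# cost 0; under Camin-Sokal, characters present in 1 or in all n taxa
# cost 1 origin on any rooted tree.
.reduce_matrix <- function(X, model) {
  cs <- colSums(X)
  n <- nrow(X)
  if (model == "wagner") {
    const_cost <- sum(cs == 1 | cs == n - 1)
    keep <- cs >= 2 & cs <= n - 2
  } else {
    const_cost <- sum(cs == 1 | cs == n)
    keep <- cs >= 2 & cs <= n - 1
  }
  list(X = X[, keep, drop = FALSE], offset = const_cost)
}

.tree_length <- function(edge, ntaxa, X, model) {
  if (ncol(X) == 0) return(0L)
  if (model == "wagner") .fitch_len_cpp(edge, ntaxa, X)
  else .cs_length(edge, ntaxa, X)
}

# ---- tree utilities ------------------------------------------------------

.adjacency <- function(edge) {
  mx <- max(edge)
  adj <- vector("list", mx)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1]; b <- edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# canonical signature of an unrooted topology: the set of internal-edge
# bipartitions, each written as the side not containing taxon 1 (the tree
# is rooted on taxon 1's pendant edge, so every non-root internal node's
# descendant leaf set is such a side)
.split_signature <- function(edge, ntaxa) {
  adj <- .adjacency(edge)
  tr <- .rooted_arrays(edge, c(1L, adj[[1]][1]))
  sets <- .node_leafsets(tr, ntaxa)
  internal <- tr$preorder[tr$preorder > ntaxa & tr$preorder != tr$root]
  sizes <- lengths(sets[internal])
  sig <- vapply(internal[sizes >= 2 & sizes <= ntaxa - 2L],
                function(v) paste(sets[[v]], collapse = ","), character(1))
  paste(sort(sig), collapse = "|")
}

.insert_leaf <- function(edge, at, leaf, new_internal) {
  v <- edge[at, 2]
  edge[at, 2] <- new_internal
  rbind(edge, c(new_internal, v), c(new_internal, leaf))
}

.three_taxon_tree <- function(t1, t2, t3, internal) {
  matrix(c(internal, t1, internal, t2, internal, t3), ncol = 2, byrow = TRUE)
}

# ---- Camin-Sokal scoring -------------------------------------------------

# origins needed for irreversible 0->1 evolution when the tree is rooted
# by the all-zero ancestor on its best edge: a character's cost is the
# number of maximal subtrees whose leaves all carry state 1 (each such
# subtree takes exactly one 0->1 change on its stem)
.cs_length <- function(edge, ntaxa, X) {
  adj <- .adjacency(edge)
  best <- Inf
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    nodes_a1 <- new.env()
    fill <- function(node, parent) {  # all-1 indicator per character
      a1 <- if (node <= ntaxa) X[node, ] == 1L else {
        res <- rep(TRUE, ncol(X))
        for (w in adj[[node]]) if (w != parent)
          res <- res & fill(w, node)
        res
      }
      assign(paste(node, parent), a1, envir = nodes_a1)
      a1
    }
    aw <- fill(u, v) & fill(v, u)  # root junction covers the whole tree
    origins <- sum(aw)
    add <- function(node, parent, parent_a1) {
      a1 <- get(paste(node, parent), envir = nodes_a1)
      origins <<- origins + sum(a1 & !parent_a1)
      if (node > ntaxa)
        for (w in adj[[node]]) if (w != parent) add(w, node, a1)
    }
    add(u, v, aw)
    add(v, u, aw)
    if (origins < best) best <- origins
  }
  as.integer(best)
}

# ---- public scoring ------------------------------------------------------

#' Parsimony length of a tree for a binary character matrix
#'
#' Counts the minimal number of character-state changes the tree requires:
#' Fitch counting for the Wagner model (free reversals; independent of
#' rooting) or minimal 0->1 origins for the irreversible Camin-Sokal model
#' (rooted at the all-zero ancestor on its best edge).
#'
#' @param tree A 2-column integer edge matrix (leaves `1..n` indexing the
#'   matrix rows, internal nodes above) or an `ape::phylo` whose tip
#'   labels match `rownames(X)`.
#' @param X Binary character matrix (specimens x characters), e.g. from
#'   [build_matrix()].
#' @param model `"wagner"` (default) or `"caminsokal"`.
#' @return Integer step count.
#' @export
#' @examples
#' X <- rbind(A = c(1, 1), B = c(1, 1), C = c(0, 0), D = c(0, 0))
#' tr <- matrix(c(5, 1, 5, 2, 5, 6, 6, 3, 6, 4), ncol = 2, byrow = TRUE)
#' fitch_length(tr, X)  # 2: one origin per character
fitch_length <- function(tree, X, model = c("wagner", "caminsokal")) {
  model <- match.arg(model)
  X <- .as_binary_matrix(X)
  if (inherits(tree, "phylo")) {
    perm <- match(tree$tip.label, rownames(X))
    if (anyNA(perm))
      stop("tree tips not found in the character matrix: ",
           paste(tree$tip.label[is.na(perm)], collapse = ", "))
    X <- X[perm, , drop = FALSE]
    tree <- tree$edge
  }
  storage.mode(tree) <- "integer"
  ntaxa <- nrow(X)
  leaves <- unique(tree[tree <= ntaxa])
  deg <- tabulate(tree, nbins = max(tree))
  if (length(leaves) != ntaxa || max(tree) <= ntaxa ||
      any(deg[seq_len(ntaxa)] != 1L))
    stop("tree leaves do not match the matrix taxa")
  .tree_length(tree, ntaxa, X, model)
}

.new_fit <- function(best_length, trees, X, method, model, seed = NA,
                     n_examined = 0, complete = TRUE, cap = 1000L) {
  capped <- length(trees) > cap
  if (capped) trees <- trees[seq_len(cap)]
  structure(list(best_length = as.integer(best_length), trees = trees,
                 matrix = X, taxa = rownames(X), method = method,
                 model = model, seed = seed, n_examined = n_examined,
                 complete = complete, capped = capped),
            class = "parsimony_fit")
}

# ---- searches ------------------------------------------------------------

# enumerate all unrooted binary topologies by recursive leaf insertion;
# visit(edge) is called for each complete topology
.enumerate_topologies <- function(ntaxa, visit) {
  base <- .three_taxon_tree(1L, 2L, 3L, ntaxa + 1L)
  rec <- function(edge, nxt_taxon, nxt_internal) {
    if (nxt_taxon > ntaxa) { visit(edge); return(invisible()) }
    for (e in seq_len(nrow(edge)))
      rec(.insert_leaf(edge, e, nxt_taxon, nxt_internal),
          nxt_taxon + 1L, nxt_internal + 1L)
  }
  if (ntaxa == 3) visit(base) else rec(base, 4L, ntaxa + 2L)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology (refusing more than 9 taxa,
#' i.e. 135135 topologies) and returns all trees attaining the minimum
#' length.
#'
#' @param X Binary character matrix with specimen rownames.
#' @param model Character model, see [fitch_length()].
#' @param tree_cap Maximum number of tied optimal trees retained.
#' @return A `parsimony_fit`.
#' @export
exhaustive_search <- function(X, model = c("wagner", "caminsokal"),
                              tree_cap = 1000L) {
  model <- match.arg(model)
  X <- .as_binary_matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need >= 3 taxa")
  if (n > 9)
    stop("exhaustive search refuses > 9 taxa; use branch_and_bound_search",
         " or heuristic_search")
  red <- .reduce_matrix(X, model)
  best <- Inf
  trees <- list()
  examined <- 0L
  .enumerate_topologies(n, function(edge) {
    examined <<- examined + 1L
    len <- .tree_length(edge, n, red$X, model)
    if (len < best) { best <<- len; trees <<- list(edge) }
    else if (len == best && length(trees) < tree_cap + 1L)
      trees <<- c(trees, list(edge))
  })
  .new_fit(best + red$offset, trees, X, "exhaustive", model,
           n_examined = examined, cap = tree_cap)
}

#' Branch-and-bound maximum-parsimony search
#'
#' Exact search for mid-sized cohorts: taxa are added one at a time on
#' every edge of every partial tree, and a partial tree is pruned as soon
#' as its length exceeds the best complete length found so far (tree
#' length never decreases when a taxon is added). The first upper bound
#' comes from a quick heuristic search. A node budget guards resource use;
#' if it is exhausted the best-so-far result is returned flagged
#' `complete = FALSE`.
#'
#' @param X Binary character matrix with specimen rownames.
#' @param model Character model, see [fitch_length()].
#' @param node_budget Maximum number of partial trees to examine.
#' @param tree_cap Maximum number of tied optimal trees retained.
#' @return A `parsimony_fit`.
#' @export
branch_and_bound_search <- function(X, model = c("wagner", "caminsokal"),
                                    node_budget = 2e6, tree_cap = 1000L) {
  model <- match.arg(model)
  X <- .as_binary_matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need >= 3 taxa")
  red <- .reduce_matrix(X, model)
  ub <- if (ncol(red$X) && n >= 4 && model == "wagner") {
    hs <- heuristic_search(X, seed = 1L, n_starts = 1L, model = model)
    hs$best_length - red$offset
  } else Inf
  best <- ub
  trees <- list()
  examined <- 0L
  out_of_budget <- FALSE
  rec <- function(edge, nxt_taxon, nxt_internal) {
    if (out_of_budget) return(invisible())
    examined <<- examined + 1L
    if (examined > node_budget) { out_of_budget <<- TRUE; return(invisible()) }
    len <- .tree_length(edge, n, red$X, model)
    if (len > best) return(invisible())
    if (nxt_taxon > n) {
      if (len < best) { best <<- len; trees <<- list(edge) }
      else if (length(trees) == 0 && len == best) trees <<- list(edge)
      else if (len == best && length(trees) < tree_cap + 1L)
        trees <<- c(trees, list(edge))
      return(invisible())
    }
    for (e in seq_len(nrow(edge)))
      rec(.insert_leaf(edge, e, nxt_taxon, nxt_internal),
          nxt_taxon + 1L, nxt_internal + 1L)
  }
  base <- .three_taxon_tree(1L, 2L, 3L, n + 1L)
  if (n == 3) rec(base, 4L, n + 2L) else rec(base, 4L, n + 2L)
  .new_fit(best + red$offset, trees, X, "branch_and_bound", model,
           n_examined = examined, complete = !out_of_budget, cap = tree_cap)
}

# R fallback stepwise addition + NNI used for the Camin-Sokal model
.stepwise_r <- function(X, ord, model) {
  n <- nrow(X)
  edge <- .three_taxon_tree(ord[1], ord[2], ord[3], n + 1L)
  nxt <- n + 2L
  for (k in seq_len(n)[-(1:3)]) {
    cand_len <- vapply(seq_len(nrow(edge)), function(e)
      .tree_length(.insert_leaf(edge, e, ord[k], nxt), n, X, model),
      integer(1))
    edge <- .insert_leaf(edge, which.min(cand_len), ord[k], nxt)
    nxt <- nxt + 1L
  }
  edge
}

.nni_r <- function(edge, ntaxa, X, model, max_sweeps = 50L) {
  cur <- .tree_length(edge, ntaxa, X, model)
  for (s in seq_len(max_sweeps)) {
    improved <- FALSE
    for (e in seq_len(nrow(edge))) {
      u <- edge[e, 1]; v <- edge[e, 2]
      if (u <= ntaxa || v <= ntaxa) next
      eu <- which((edge[, 1] == u | edge[, 2] == u) &
                    seq_len(nrow(edge)) != e)[1]
      evs <- which((edge[, 1] == v | edge[, 2] == v) &
                     seq_len(nrow(edge)) != e)
      for (g in evs) {
        alt <- edge
        fu_col <- if (alt[eu, 1] == u) 2L else 1L
        gv_col <- if (alt[g, 1] == v) 2L else 1L
        tmp <- alt[eu, fu_col]
        alt[eu, fu_col] <- alt[g, gv_col]
        alt[g, gv_col] <- tmp
        len <- .tree_length(alt, ntaxa, X, model)
        if (len < cur) { edge <- alt; cur <- len; improved <- TRUE; break }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(edge = edge, length = cur)
}

#' Heuristic maximum-parsimony search
#'
#' Stepwise addition with a random taxon addition order followed by
#' nearest-neighbor-interchange hill climbing, repeated from `n_starts`
#' random starts. Deterministic given the seed; the returned length is
#' never better than the exact optimum.
#'
#' @param X Binary character matrix with specimen rownames.
#' @param seed Integer seed for the addition orders.
#' @param n_starts Number of random-addition starts.
#' @param model Character model, see [fitch_length()].
#' @param tree_cap Maximum number of tied best trees retained.
#' @return A `parsimony_fit` with the distinct best topologies found.
#' @export
heuristic_search <- function(X, seed = 1L, n_starts = 10L,
                             model = c("wagner", "caminsokal"),
                             tree_cap = 1000L) {
  model <- match.arg(model)
  X <- .as_binary_matrix(X)
  n <- nrow(X)
  if (n < 4) stop("heuristic search needs >= 4 taxa; use exhaustive_search")
  red <- .reduce_matrix(X, model)
  Xr <- red$X
  best <- Inf
  trees <- list()
  sigs <- character()
  examined <- 0
  .with_seed(seed, {
    for (s in seq_len(n_starts)) {
      ord <- sample.int(n)
      if (model == "wagner") {
        if (ncol(Xr) == 0) {
          # every topology is optimal; build one deterministically
          edge <- .three_taxon_tree(ord[1], ord[2], ord[3], n + 1L)
          nxt <- n + 2L
          for (k in seq_len(n)[-(1:3)]) {
            edge <- .insert_leaf(edge, 1L, ord[k], nxt)
            nxt <- nxt + 1L
          }
          res <- list(edge = edge, length = 0L)
        } else {
          sw <- .stepwise_addition_cpp(Xr, ord)
          nn <- .nni_search_cpp(sw$edge, n, Xr, 100L)
          examined <- examined + nn$examined
          res <- list(edge = nn$edge, length = nn$length)
        }
      } else {
        edge <- .stepwise_r(Xr, ord, model)
        res <- .nni_r(edge, n, Xr, model)
      }
      if (res$length < best) {
        best <- res$length
        trees <- list(res$edge)
        sigs <- .split_signature(res$edge, n)
      } else if (res$length == best && length(trees) < tree_cap + 1L) {
        sig <- .split_signature(res$edge, n)
        if (!sig %in% sigs) {
          trees <- c(trees, list(res$edge))
          sigs <- c(sigs, sig)
        }
      }
    }
  })
  .new_fit(best + red$offset, trees, X, "heuristic", model, seed = seed,
           n_examined = examined, cap = tree_cap)
}

#' Fit a maximum-parsimony cladogram to a binary aberration matrix
#'
#' The package's central fitting function. Chooses (or is told) a search
#' strategy, runs it, and returns a `parsimony_fit` holding all optimal
#' trees found (up to a cap), from which [root_and_annotate()] and
#' [strict_consensus()] derive rooted, annotated cladograms. `method =
#' "auto"` uses exhaustive enumeration up to 7 taxa, branch-and-bound up
#' to 15, and the heuristic above that.
#'
#' @param X Binary character matrix, e.g. from [build_matrix()].
#' @param method `"auto"`, `"exhaustive"`, `"bb"` or `"heuristic"`.
#' @param model `"wagner"` (free reversals, default) or `"caminsokal"`
#'   (irreversible gains).
#' @param seed Seed for the heuristic's random addition orders.
#' @param n_starts Number of heuristic starts.
#' @param ... Passed on to the chosen search.
#' @return A `parsimony_fit`: list with `best_length`, `trees` (edge
#'   matrices), `matrix`, `taxa`, `method`, `model`, `seed`,
#'   `n_examined`, `complete`.
#' @export
#' @examples
#' X <- rbind(A = c(1, 1, 0), B = c(1, 1, 0), C = c(0, 0, 1),
#'            D = c(0, 0, 1), E = c(0, 0, 1))
#' fit <- parsimony_search(X)
#' fit$best_length
parsimony_search <- function(X, method = c("auto", "exhaustive", "bb",
                                           "heuristic"),
                             model = c("wagner", "caminsokal"),
                             seed = 1L, n_starts = 10L, ...) {
  method <- match.arg(method)
  model <- match.arg(model)
  X <- .as_binary_matrix(X)
  n <- nrow(X)
  if (method == "auto")
    method <- if (n <= 7) "exhaustive" else if (n <= 15) "bb" else "heuristic"
  switch(method,
         exhaustive = exhaustive_search(X, model, ...),
         bb = branch_and_bound_search(X, model, ...),
         heuristic = heuristic_search(X, seed = seed, n_starts = n_starts,
                                      model = model, ...))
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf("Maximum-parsimony fit (%s, %s model)\n", x$method, x$model))
  cat(sprintf("  %d taxa, %d characters; best length %d steps\n",
              length(x$taxa), ncol(x$matrix), x$best_length))
  cat(sprintf("  optimal trees retained: %d%s; %s examined: %g\n",
              length(x$trees), if (isTRUE(x$capped)) " (capped)" else "",
              if (x$method == "heuristic") "rearrangements" else "trees",
              x$n_examined))
  if (!isTRUE(x$complete)) cat("  NOTE: search budget exhausted;",
                               "result may be suboptimal\n")
  invisible(x)
}

#' @export
summary.parsimony_fit <- function(object, ...) {
  print(object)
  cons <- strict_consensus(object)
  cat("\nStrict consensus of the optimal trees:\n")
  print(cons)
  invisible(object)
}

#' @export
plot.parsimony_fit <- function(x, which = 1L, ...) {
  plot(root_and_annotate(x, which = which), ...)
}
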