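# Rooted, annotated cladograms. The root is the aberration-free normal
# genome: an all-zero outgroup is attached on the edge where it costs
# least, the tree is rooted there, internal nodes are numbered in
# preorder (Nd1 = root), and each node is annotated with its defining
# aberrations (synapomorphies). All traversals are iterative (stack
# loops), so cohorts of hundreds of specimens stay within stack limits.

# best attachment edge for the all-zero ancestor, in the canonical edge
# order (rows sorted by (min, max) endpoint); ties -> first. Characters
# present in exactly one taxon or in all taxa cost the same on every
# attachment edge, so only the remaining characters are scored.
.root_edge <- function(edge, ntaxa, X) {
  storage.mode(edge) <- "integer"
  ord <- order(pmin(edge[, 1], edge[, 2]), pmax(edge[, 1], edge[, 2]))
  edge <- edge[ord, , drop = FALSE]
  cs <- colSums(X)
  Xv <- X[, cs >= 2 & cs <= ntaxa - 1, drop = FALSE]
  if (ncol(Xv) == 0) return(edge[1, ])
  shifted <- edge
  shifted[shifted > ntaxa] <- shifted[shifted > ntaxa] + 1L
  costs <- .attach_costs_cpp(shifted, ntaxa, rbind(Xv, 0L))
  edge[which.min(costs), ]
}

# root an unrooted tree on the edge (root_edge[1], root_edge[2]): a fresh
# root node is spliced into that edge. Returns parent/children arrays and
# a preorder; every traversal below iterates over these arrays.
.rooted_arrays <- function(edge, root_edge) {
  m <- max(edge)
  root <- m + 1L
  keep <- !(pmin(edge[, 1], edge[, 2]) == min(root_edge) &
              pmax(edge[, 1], edge[, 2]) == max(root_edge))
  e2 <- rbind(edge[keep, , drop = FALSE],
              c(root, root_edge[1]), c(root, root_edge[2]))
  adj <- .adjacency(e2)
  parent <- integer(root)
  preorder <- integer(root)
  k <- 0L
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    preorder[k] <- v
    for (w in adj[[v]]) if (w != parent[v]) {
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  preorder <- preorder[seq_len(k)]
  children <- vector("list", root)
  for (v in preorder[-1])
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  list(root = root, parent = parent, preorder = preorder,
       children = children)
}

# leaf sets below every node (list indexed by node id), children first
.node_leafsets <- function(tr, ntaxa) {
  sets <- vector("list", tr$root)
  for (v in rev(tr$preorder))
    sets[[v]] <- if (v <= ntaxa) v else
      sort(unlist(sets[tr$children[[v]]], use.names = FALSE))
  sets
}

# Fitch downpass + final pass on a rooted binary tree with the root state
# forced ancestral (0) wherever the downpass allows; returns the integer
# node x character state matrix
.fitch_states <- function(tr, ntaxa, X) {
  nch <- ncol(X)
  d0 <- matrix(FALSE, tr$root, nch)
  d1 <- matrix(FALSE, tr$root, nch)
  for (v in rev(tr$preorder)) {
    if (v <= ntaxa) {
      d0[v, ] <- X[v, ] == 0L
      d1[v, ] <- X[v, ] == 1L
    } else {
      a0 <- a1 <- NULL
      for (w in tr$children[[v]]) {
        if (is.null(a0)) { a0 <- d0[w, ]; a1 <- d1[w, ]; next }
        i0 <- a0 & d0[w, ]; i1 <- a1 & d1[w, ]
        empty <- !(i0 | i1)
        a0 <- ifelse(empty, a0 | d0[w, ], i0)
        a1 <- ifelse(empty, a1 | d1[w, ], i1)
      }
      d0[v, ] <- a0
      d1[v, ] <- a1
    }
  }
  state <- matrix(NA_integer_, tr$root, nch)
  state[tr$root, ] <- ifelse(d0[tr$root, ], 0L, 1L)
  for (v in tr$preorder[-1]) {
    ps <- state[tr$parent[v], ]
    state[v, ] <- ifelse(d0[v, ] & d1[v, ], ps, ifelse(d1[v, ], 1L, 0L))
  }
  state
}

# assemble a cladogram object from rooted arrays; `state` (from
# .fitch_states) adds reconstructed 0->1 gains, NULL skips them
.assemble_cladogram <- function(tr, ntaxa, X, state = NULL) {
  taxa <- rownames(X)
  keys <- colnames(X)
  if (is.null(keys)) keys <- paste0("char", seq_len(ncol(X)))
  counts <- colSums(X)
  sets <- .node_leafsets(tr, ntaxa)
  internal <- tr$preorder[tr$preorder > ntaxa]
  label <- character(tr$root)
  label[internal] <- paste0("Nd", seq_along(internal))
  label[seq_len(ntaxa)] <- gsub("[ ():;,]", "_", taxa)
  rows <- vector("list", length(tr$preorder))
  for (i in seq_along(tr$preorder)) {
    v <- tr$preorder[i]
    lv <- sets[[v]]
    strict <- keys[counts == length(lv) &
                     colSums(X[lv, , drop = FALSE]) == length(lv)]
    gains <- if (!is.null(state)) {
      ps <- if (v == tr$root) rep(0L, ncol(X)) else state[tr$parent[v], ]
      keys[state[v, ] == 1L & ps == 0L]
    } else character()
    rows[[i]] <- data.frame(
      node = if (v <= ntaxa) taxa[v] else label[v],
      n_leaves = length(lv), leaves = paste(taxa[lv], collapse = ","),
      synapomorphies = paste(strict, collapse = ","),
      reconstructed_gains = paste(gains, collapse = ","),
      stringsAsFactors = FALSE)
  }
  # newick: children-first string assembly
  str <- character(tr$root)
  for (v in rev(tr$preorder))
    str[v] <- if (v <= ntaxa) label[v] else
      paste0("(", paste(str[tr$children[[v]]], collapse = ","), ")",
             label[v])
  nwk <- paste0(str[tr$root], ";")
  tab <- do.call(rbind, rows)
  is_int <- grepl("^Nd[0-9]+$", tab$node)
  tab <- rbind(tab[is_int, , drop = FALSE],
               tab[!is_int, , drop = FALSE][order(tab$node[!is_int]), ,
                                            drop = FALSE])
  rownames(tab) <- NULL
  structure(list(phylo = ape::read.tree(text = nwk), newick = nwk,
                 node_table = tab, taxa = taxa),
            class = "cladogram")
}

#' Root an optimal tree at the normal genome and annotate its nodes
#'
#' Attaches a hypothetical all-zero ancestor (the aberration-free normal
#' genome) on the edge where it adds the fewest steps, roots the tree
#' there, numbers internal nodes in preorder (`Nd1` = root) and lists each
#' node's defining aberrations in two modes: *strict* synapomorphies --
#' characters present in exactly the node's leaves and no others -- and
#' *reconstructed* gains -- characters whose Fitch reconstruction (root
#' forced to the ancestral absent state where possible) places a 0 to 1
#' change on the node's stem. Characters private to one specimen appear as
#' that leaf's autapomorphies; characters shared by every specimen are
#' assigned to the root.
#'
#' @param tree A `parsimony_fit` (uses tree `which`) or an unrooted edge
#'   matrix.
#' @param X Binary character matrix; taken from the fit when omitted.
#' @param which Index of the optimal tree to root when `tree` is a fit.
#' @return An object of class `cladogram`: list with `phylo` (an
#'   `ape::phylo` with node labels), `newick`, `node_table` (one row per
#'   node: `node`, `n_leaves`, `leaves`, `synapomorphies`,
#'   `reconstructed_gains`) and `taxa`.
#' @export
root_and_annotate <- function(tree, X = NULL, which = 1L) {
  if (inherits(tree, "parsimony_fit")) {
    if (is.null(X)) X <- tree$matrix
    tree <- tree$trees[[which]]
  }
  X <- .as_binary_matrix(X)
  ntaxa <- nrow(X)
  storage.mode(tree) <- "integer"
  re <- .root_edge(tree, ntaxa, X)
  tr <- .rooted_arrays(tree, re)
  state <- .fitch_states(tr, ntaxa, X)
  .assemble_cladogram(tr, ntaxa, X, state)
}

# root a (possibly polytomous) edge list at an existing node
.rooted_at_node <- function(edge, root) {
  adj <- .adjacency(edge)
  nnode <- length(adj)
  parent <- integer(nnode)
  preorder <- integer(nnode)
  k <- 0L
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    preorder[k] <- v
    for (w in adj[[v]]) if (w != parent[v] && w != root) {
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  preorder <- preorder[seq_len(k)]
  children <- vector("list", nnode)
  for (v in preorder[-1])
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  list(root = root, parent = parent, preorder = preorder,
       children = children)
}

# exact minimal state changes of binary characters on an arbitrary
# (possibly polytomous) tree: unit-cost Sankoff recursion, vectorized
# over characters; rooting-independent
.binary_sankoff <- function(edge, ntaxa, X) {
  tr <- .rooted_at_node(edge, max(edge))
  nch <- ncol(X)
  big <- nrow(X) + 1
  c0 <- c1 <- matrix(0, tr$root, nch)
  for (v in rev(tr$preorder)) {
    if (v <= ntaxa) {
      c0[v, ] <- ifelse(X[v, ] == 0L, 0, big)
      c1[v, ] <- ifelse(X[v, ] == 1L, 0, big)
    } else {
      for (w in tr$children[[v]]) {
        c0[v, ] <- c0[v, ] + pmin(c0[w, ], c1[w, ] + 1)
        c1[v, ] <- c1[v, ] + pmin(c1[w, ], c0[w, ] + 1)
      }
    }
  }
  r <- tr$preorder[1]
  sum(pmin(c0[r, ], c1[r, ]))
}

# unrooted splits of a binary tree, as canonical strings (the side not
# containing taxon 1; non-trivial sizes only)
.tree_splits <- function(edge, ntaxa) {
  adj <- .adjacency(edge)
  tr <- .rooted_arrays(edge, c(1L, adj[[1]][1]))
  sets <- .node_leafsets(tr, ntaxa)
  internal <- tr$preorder[tr$preorder > ntaxa & tr$preorder != tr$root]
  sizes <- lengths(sets[internal])
  vapply(internal[sizes >= 2 & sizes <= ntaxa - 2L],
         function(v) paste(sets[[v]], collapse = ","), character(1))
}

#' Strict consensus cladogram of tied optimal trees
#'
#' Intersects the unrooted bipartitions of the input trees (the classic
#' strict consensus: exactly the splits present in every tree are kept;
#' everything else collapses into polytomies), then roots the consensus at
#' the all-zero ancestor, attached at the node or edge where it adds the
#' fewest changes (ties prefer node placement, so an unresolved consensus
#' is not artificially resolved by the root). Strict synapomorphies are
#' annotated; the Fitch reconstruction is not defined on polytomies and
#' is left empty.
#'
#' @param trees A `parsimony_fit` (all retained optimal trees) or a list
#'   of unrooted edge matrices over the same taxa.
#' @param X Binary character matrix; taken from the fit when omitted.
#' @return A `cladogram`.
#' @export
strict_consensus <- function(trees, X = NULL) {
  if (inherits(trees, "parsimony_fit")) {
    if (is.null(X)) X <- trees$matrix
    trees <- trees$trees
  }
  if (!length(trees)) stop("need at least one tree")
  X <- .as_binary_matrix(X)
  ntaxa <- nrow(X)
  split_sets <- lapply(trees, function(tr) {
    storage.mode(tr) <- "integer"
    if (length(unique(tr[tr <= ntaxa])) != ntaxa)
      stop("trees must share the full leaf set of the matrix")
    .tree_splits(tr, ntaxa)
  })
  shared <- Reduce(intersect, split_sets)
  clades <- c(lapply(strsplit(shared, ","), as.integer),
              list(seq_len(ntaxa)))
  sizes <- vapply(clades, length, integer(1))
  ord <- order(-sizes)
  clades <- clades[ord]
  sizes <- sizes[ord]
  # node ids: tips 1..n, clade i -> n + i (root = n + 1 = full set)
  nnode <- ntaxa + length(clades)
  parent <- integer(nnode)
  for (i in seq_along(clades)[-1]) {
    for (j in rev(seq_len(i - 1L))) {
      if (sizes[j] > sizes[i] && all(clades[[i]] %in% clades[[j]])) {
        parent[ntaxa + i] <- ntaxa + j
        break
      }
    }
  }
  for (t in seq_len(ntaxa)) {
    parent[t] <- ntaxa + 1L
    for (j in rev(seq_along(clades))) {
      if (t %in% clades[[j]]) { parent[t] <- ntaxa + j; break }
    }
  }
  edge <- cbind(parent[parent > 0], which(parent > 0))
  storage.mode(edge) <- "integer"
  # attach the all-zero ancestor at the internal node where it adds the
  # fewest changes: node placement can never add a clade that is not a
  # shared split, so the root never resolves what the inputs left open.
  # Consensus trees are polytomous, so placements are scored with the
  # exact unit-cost (Sankoff) recursion, not the binary-tree Fitch fold.
  # Only characters with placement-dependent cost are scored.
  cs <- colSums(X)
  Xv <- X[, cs >= 2 & cs <= ntaxa - 1, drop = FALSE]
  internal_nodes <- sort(unique(edge[edge > ntaxa]))
  if (ncol(Xv) == 0 || length(internal_nodes) == 1) {
    tr <- .rooted_at_node(edge, ntaxa + 1L)
  } else {
    anc <- ntaxa + 1L
    Xa <- rbind(Xv, 0L)
    shift <- edge
    shift[shift > ntaxa] <- shift[shift > ntaxa] + 1L
    node_costs <- vapply(internal_nodes + 1L, function(v)
      .binary_sankoff(rbind(shift, c(v, anc)), anc, Xa), numeric(1))
    tr <- .rooted_at_node(edge, internal_nodes[which.min(node_costs)])
  }
  .assemble_cladogram(tr, ntaxa, X, state = NULL)
}

#' @export
print.cladogram <- function(x, ...) {
  ni <- sum(grepl("^Nd", x$node_table$node))
  cat(sprintf("Cladogram: %d specimens, %d internal nodes (root Nd1 = normal genome)\n",
              length(x$taxa), ni))
  defined <- x$node_table[grepl("^Nd", x$node_table$node) &
                            nzchar(x$node_table$synapomorphies), ]
  if (nrow(defined)) {
    cat("Nodes with strict synapomorphies:\n")
    for (i in seq_len(min(nrow(defined), 10L)))
      cat(sprintf("  %s (n=%d): %s\n", defined$node[i],
                  defined$n_leaves[i], defined$synapomorphies[i]))
    if (nrow(defined) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
plot.cladogram <- function(x, show.node.label = TRUE, ...) {
  ape::plot.phylo(x$phylo, show.node.label = show.node.label, ...)
}

#' Write a cladogram as Newick plus a per-node annotation table
#'
#' @param clad A `cladogram`.
#' @param prefix Output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>_nodes.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_cladogram <- function(clad, prefix) {
  nwk <- paste0(prefix, ".nwk")
  tsv <- paste0(prefix, "_nodes.tsv")
  writeLines(clad$newick, nwk)
  write.table(clad$node_table, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(newick = nwk, nodes = tsv))
}
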