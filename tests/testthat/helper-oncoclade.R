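# shared fixtures and independent oracles, all built in code

# random binary character matrix with named taxa
random_matrix <- function(ntaxa, nchar, p = 0.4, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(ntaxa * nchar, 1, p), nrow = ntaxa)
  rownames(X) <- paste0("t", seq_len(ntaxa))
  X
}

# brute-force parsimony length: enumerate every assignment of 0/1 states
# to the internal nodes and count state-changing edges; independent of the
# package's Fitch implementation
oracle_length <- function(edge, ntaxa, X) {
  internals <- sort(unique(edge[edge > ntaxa]))
  k <- length(internals)
  total <- 0L
  for (ch in seq_len(ncol(X))) {
    best <- Inf
    for (mask in 0:(2^k - 1)) {
      st <- integer(max(edge))
      st[seq_len(ntaxa)] <- X[, ch]
      st[internals] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
      changes <- sum(st[edge[, 1]] != st[edge[, 2]])
      if (changes < best) best <- changes
    }
    total <- total + best
  }
  total
}

# a random perfect phylogeny: recursive splits, one character per planted
# clade (clades of size 2..n-1)
make_perfect_phylogeny <- function(n, seed = 1) {
  set.seed(seed)
  clades <- list()
  rec <- function(members) {
    if (length(members) < 2) return(invisible())
    k <- if (length(members) == 2) 1 else
      sample(seq_len(length(members) - 1), 1)
    a <- members[1:k]
    b <- members[-(1:k)]
    for (s in list(a, b)) if (length(s) >= 2 && length(s) < n)
      clades[[length(clades) + 1L]] <<- sort(s)
    rec(a)
    rec(b)
  }
  rec(sample(n))
  X <- vapply(clades, function(s) as.integer(seq_len(n) %in% s),
              integer(n))
  rownames(X) <- paste0("t", seq_len(n))
  list(X = X, clades = clades)
}

# leaf sets of a cladogram's internal nodes, as canonical strings
cladogram_clades <- function(clad) {
  nt <- clad$node_table[grepl("^Nd", clad$node_table$node), , drop = FALSE]
  vapply(strsplit(nt$leaves, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
}

clade_string <- function(members) paste(sort(members), collapse = ",")

# one synthetic-cohort recovery replicate shared by the acceptance checks:
# returns whether the planted MSI-H aberration deficit, the planted P16
# methylation-MSI association, and the planted clade were each detected
recovery_replicate <- function(seed, n_samples = 200) {
  cfg <- cohort_config(
    n_samples = n_samples, seed = seed,
    planted_clades = list(list(members = 1:8, n_shared = 6)))
  coh <- generate_cohort(cfg)
  clin <- coh$samples
  p_ab <- suppressWarnings(
    wilcox.test(clin$aberration_count ~ (clin$msi == "MSI-H"))$p.value)
  sa <- stratified_association(coh$methylation_calls, clin, "P16", "msi")
  calls <- filter_by_fold(coh$interval_reports)
  m <- build_matrix(calls)
  fit <- heuristic_search(m, seed = seed, n_starts = 2)
  cons <- strict_consensus(fit)
  want <- clade_string(coh$truth$clades[[1]]$members)
  c(aberration = p_ab < 0.05,
    methylation = !is.na(sa$p) && sa$p < 0.05,
    clade = want %in% cladogram_clades(cons))
}
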