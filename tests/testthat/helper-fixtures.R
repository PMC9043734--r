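# Shared fixtures and independent oracles for the test suite.  Everything
# is generated in code; nothing is read from disk.

# small multi-locus bundle used by several files (cached per session)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 10, n_loci = 3, locus_length = 200)
      cache <<- simulate_dataset(cfg, seed = 5, dropout = FALSE)
    }
    cache
  }
})

# labelled distance matrix from random points (helper for Mantel tests)
random_dist <- function(n, seed, kind = "genetic", dim = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * dim), n)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  dist_matrix(d, kind = kind)
}

# graft a new tip at the midpoint of edge e with pendant length t, by
# direct structural surgery (independent of the placement engine's own
# attachment arithmetic)
graft_mid <- function(tree, e, t, lab = "q") {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  old2new <- c(seq_len(ntip), seq_len(nn) + ntip + 1L)
  edge <- matrix(old2new[tree$edge], ncol = 2)
  elen <- tree$edge.length
  newtip <- ntip + 1L
  newnode <- ntip + 1L + nn + 1L
  child <- edge[e, 2]
  half <- elen[e] / 2
  out <- list(edge = rbind(edge[-e, , drop = FALSE],
                           c(edge[e, 1], newnode),
                           c(newnode, child), c(newnode, newtip)),
              edge.length = c(elen[-e], half, half, t),
              tip.label = c(tree$tip.label, lab), Nnode = nn + 1L)
  class(out) <- "phylo"
  out
}

# brute-force DEC likelihood: enumerate every internal-node state and
# cladogenetic outcome explicitly, with dense series matrix exponentials
dec_enum_loglik <- function(tree, rd, d, e, j) {
  states <- rd$states
  ns <- length(states)
  nR <- length(rd$regions)
  Q <- yartsa:::dec_qmatrix(states, nR, d, e)
  clado <- yartsa:::dec_clado_table(states, nR, j)
  P <- lapply(tree$edge.length, function(t) yartsa:::expm_series(Q * t))
  ntip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  tipst <- rd$tip_states[tree$tip.label]
  lik_node <- function(nd, s) {
    if (nd <= ntip) return(as.numeric(s == tipst[nd]))
    es <- kids[[as.character(nd)]]
    tb <- clado[[s]]
    tot <- 0
    for (row in seq_len(nrow(tb))) {
      l1 <- sum(vapply(seq_len(ns), function(s1)
        P[[es[1]]][tb[row, 1], s1] * lik_node(tree$edge[es[1], 2], s1),
        numeric(1)))
      l2 <- sum(vapply(seq_len(ns), function(s2)
        P[[es[2]]][tb[row, 2], s2] * lik_node(tree$edge[es[2], 2], s2),
        numeric(1)))
      tot <- tot + tb[row, 3] * l1 * l2
    }
    tot
  }
  root <- ntip + 1L
  log(mean(vapply(seq_len(ns), function(s) lik_node(root, s), numeric(1))))
}

# site likelihood by explicit summation over all internal-node states,
# with its own Q-matrix exponential (independent of the C++ engine)
enum_tree_loglik <- function(tree, m, model) {
  bf <- model$base_freq
  kap <- model$kappa
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (jj in 1:4) {
    if (i != jj) Q[i, jj] <- bf[jj] * if ((i %% 2) == (jj %% 2)) kap else 1
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))
  P <- lapply(tree$edge.length, function(t) yartsa:::expm_series(Q * t))
  code <- yartsa:::encode_dna(m[tree$tip.label, , drop = FALSE])
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  combos <- as.matrix(expand.grid(rep(list(1:4), nint)))
  root <- ntip + 1L
  site_lik <- function(s) {
    tot <- 0
    for (ci in seq_len(nrow(combos))) {
      st <- integer(ntip + nint)
      st[(ntip + 1):(ntip + nint)] <- combos[ci, ]
      p <- bf[st[root]]
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
        if (b <= ntip) {
          c_b <- code[b, s]
          if (c_b >= 4) {
            pe <- 1 # missing tip state: marginalize (P rows sum to 1)
          } else {
            pe <- P[[e]][st[a], c_b + 1]
          }
        } else {
          pe <- P[[e]][st[a], st[b]]
        }
        p <- p * pe
        if (p == 0) { ok <- FALSE; break }
      }
      if (ok) tot <- tot + p
    }
    tot
  }
  sum(log(vapply(seq_len(ncol(code)), site_lik, numeric(1))))
}
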