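# Mk-model stochastic character mapping of single-region tip states:
# equal-rates ML fit, conditional node-state sampling from the pruning
# partials, branch histories by uniformization conditioned on endpoint
# states, and mean directional transition-count summaries.

# equal-rates Mk transition probability: k states, rate q between each
# ordered pair; P_same = 1/k + (k-1)/k e^{-kqt}, P_diff = 1/k - 1/k e^{-kqt}
mk_pmatrix <- function(k, q, t) {
  ek <- exp(-k * q * t)
  P <- matrix((1 - ek) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * ek
  P
}

# pruning partials for the ER Mk model; returns list(partials, logscale, lnl)
mk_partials <- function(tree, tip_idx, k, q) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  L <- matrix(0, nn, k)
  L[cbind(seq_len(ntip), tip_idx)] <- 1
  logscale <- numeric(nn)
  seen <- logical(nn)
  for (e in ape::postorder(tree)) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- mk_pmatrix(k, q, tree$edge.length[e])
    up <- as.vector(P %*% L[ch, ])
    if (!seen[pa]) { L[pa, ] <- 1; seen[pa] <- TRUE }
    L[pa, ] <- L[pa, ] * up
    logscale[pa] <- logscale[pa] + logscale[ch]
    mx <- max(L[pa, ])
    if (mx > 0 && mx < 1e-100) {
      L[pa, ] <- L[pa, ] / mx
      logscale[pa] <- logscale[pa] + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- mean(L[root, ]) # uniform root prior
  list(L = L, logscale = logscale,
       lnl = if (lik > 0) log(lik) + logscale[root] else -Inf)
}

# ML single-rate fit
mk_fit_rate <- function(tree, tip_idx, k) {
  f <- function(lq) -mk_partials(tree, tip_idx, k, exp(lq))$lnl
  op <- optimize(f, c(-15, 5))
  list(q = exp(op$minimum), lnl = -op$objective)
}

# sample the number of uniformized jumps and the intermediate states on one
# branch conditioned on endpoints; with mu = k q the jump chain is uniform
# over states, so intermediates are iid uniform.  Returns the state
# sequence (including endpoints).
sample_branch_history <- function(k, q, t, a, b) {
  mu <- k * q
  if (mu * t == 0) {
    if (a != b) stop("zero-rate branch with differing endpoints")
    return(c(a, b))
  }
  pab <- mk_pmatrix(k, q, t)[a, b]
  # P(N = n | a, b) propto dpois(n, mu t) * R^n[a,b]; R = J/k so R^n[a,b] =
  # 1/k for n >= 1 and [a==b] for n = 0
  u <- runif(1) * pab
  n <- 0L
  acc <- if (a == b) exp(-mu * t) else 0
  while (acc < u && n < 10000L) {
    n <- n + 1L
    acc <- acc + exp(dpois(n, mu * t, log = TRUE)) / k
  }
  if (n == 0L) return(c(a, b))
  states <- c(a, if (n > 1) sample.int(k, n - 1L, replace = TRUE), b)
  states
}

#' Stochastic character maps of regional transitions under an Mk model
#'
#' Fits a single-rate (equal-rates) Mk model to one-region-per-tip states
#' by maximum likelihood, then samples `n_maps` full character histories:
#' node states are drawn from the conditional distributions given the
#' pruning partials (root from the uniform prior times its partials), and
#' branch histories are drawn by uniformization conditioned on the branch's
#' endpoint states.  The summary is the mean directional transition-count
#' matrix across maps.
#'
#' @param tree Binary rooted `"phylo"` with branch lengths.
#' @param tip_states Named character vector: one region per tip.
#' @param regions Region set (defines the matrix dimensions and order).
#' @param n_maps Number of maps (default 3000).
#' @param seed Integer seed.
#' @param q Fixed transition rate; `NULL` (default) fits it by maximum
#'   likelihood.
#' @return A list of class `"simmap_summary"`: `mean_counts` (regions x
#'   regions, zero diagonal), `mean_total`, `q`, `loglik`, `n_maps`,
#'   `seed`, and `histories` (per-map per-branch state sequences for the
#'   first `keep_histories` maps).
#' @param keep_histories Store full histories for this many maps (for
#'   endpoint-consistency checks; default 10).
#' @export
mk_stochastic_maps <- function(tree, tip_states, regions = YARTSA_REGIONS,
                               n_maps = 3000, seed = 1L, keep_histories = 10,
                               q = NULL) {
  validate_tree(tree)
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss) > 0) stop("tip(s) without state: ", paste(miss, collapse = ", "))
  idx <- match(tip_states[tree$tip.label], regions)
  if (anyNA(idx)) stop("unknown region state(s): ",
                       paste(setdiff(tip_states, regions), collapse = ", "))
  if (length(unique(idx)) < 2) {
    stop("fewer than 2 distinct tip states: Mk rate unidentifiable")
  }
  k <- length(regions)
  if (is.null(q)) {
    fit <- mk_fit_rate(tree, idx, k)
    q <- fit$q
    lnl <- fit$lnl
  } else {
    lnl <- mk_partials(tree, idx, k, q)$lnl
  }
  pr <- mk_partials(tree, idx, k, q)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  pre <- rev(ape::postorder(tree))
  Plist <- lapply(tree$edge.length, function(t) mk_pmatrix(k, q, t))
  set.seed(seed)
  counts <- matrix(0, k, k, dimnames = list(regions, regions))
  histories <- list()
  for (m in seq_len(n_maps)) {
    node_state <- integer(ntip + tree$Nnode)
    node_state[seq_len(ntip)] <- idx
    w <- pr$L[root, ]
    node_state[root] <- sample.int(k, 1, prob = w / sum(w))
    branch_states <- vector("list", nrow(tree$edge))
    for (e in pre) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      a <- node_state[pa]
      if (ch > ntip) {
        w <- Plist[[e]][a, ] * pr$L[ch, ]
        node_state[ch] <- sample.int(k, 1, prob = w / sum(w))
      }
      b <- node_state[ch]
      seqs <- sample_branch_history(k, q, tree$edge.length[e], a, b)
      branch_states[[e]] <- seqs
      if (length(seqs) > 1) {
        real <- seqs[-length(seqs)] != seqs[-1]
        if (any(real)) {
          fr <- seqs[-length(seqs)][real]; to <- seqs[-1][real]
          for (i in seq_along(fr)) counts[fr[i], to[i]] <- counts[fr[i], to[i]] + 1
        }
      }
    }
    if (m <= keep_histories) {
      histories[[m]] <- list(node_state = node_state,
                             branch_states = branch_states)
    }
  }
  mean_counts <- counts / n_maps
  diag(mean_counts) <- 0
  structure(list(mean_counts = mean_counts, mean_total = sum(mean_counts),
                 q = q, loglik = lnl, n_maps = n_maps, seed = seed,
                 histories = histories),
            class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat(sprintf("stochastic mapping: %d maps, q = %.4g, mean total changes = %.2f\n",
              x$n_maps, x$q, x$mean_total))
  print(round(x$mean_counts, 2))
  invisible(x)
}

#' Conditional expected number of state changes on a single branch
#'
#' Numerical oracle for the uniformization sampler: for the equal-rates Mk
#' model, the expected number of i->j real changes on a branch of length t
#' conditioned on endpoint states (a, b) is
#' \eqn{\sum_{i \ne j} q \int_0^t P_{ai}(s) P_{jb}(t-s) ds / P_{ab}(t)},
#' evaluated by quadrature with the closed-form transition probabilities.
#'
#' @param k Number of states; `q` rate; `t` branch length; `a,b` endpoint
#'   state indices.
#' @param n_grid Quadrature grid size.
#' @return Expected number of changes (a single number).
#' @export
mk_expected_changes <- function(k, q, t, a, b, n_grid = 2000) {
  pab <- mk_pmatrix(k, q, t)[a, b]
  s <- seq(0, t, length.out = n_grid)
  total <- 0
  for (i in seq_len(k)) for (jj in seq_len(k)) {
    if (i == jj) next
    Pai <- vapply(s, function(x) mk_pmatrix(k, q, x)[a, i], numeric(1))
    Pjb <- vapply(s, function(x) mk_pmatrix(k, q, t - x)[jj, b], numeric(1))
    integ <- sum((Pai * Pjb)[-1] + (Pai * Pjb)[-n_grid]) / 2 * (t / (n_grid - 1))
    total <- total + q * integ
  }
  total / pab
}
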