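# Discrete-range biogeography: dispersal-extinction-cladogenesis (DEC)
# likelihood with optional founder-event (+J) cladogenesis, model fitting
# by Nelder-Mead over transformed parameters, and AIC comparison.

#' Tip range data for DEC models
#'
#' @param ranges Named list: per tip, a character vector of occupied
#'   regions (non-empty, at most `max_size` regions).
#' @param regions Ordered region set (default the four mountain blocks).
#' @param max_size Maximum allowed range size K (default 2).
#' @return A list of class `"range_data"`: `regions`, `max_size`, `tip_states`
#'   (named integer index into the state space), `states` (list of region
#'   index vectors).
#' @export
range_data <- function(ranges, regions = YARTSA_REGIONS, max_size = 2) {
  stopifnot(is.list(ranges), length(ranges) >= 1, !is.null(names(ranges)))
  states <- range_states(length(regions), max_size)
  key <- vapply(states, paste, character(1), collapse = ",")
  tip_states <- vapply(names(ranges), function(id) {
    r <- ranges[[id]]
    if (length(r) == 0) stop("empty range for tip ", id)
    idx <- match(r, regions)
    if (anyNA(idx)) stop("unknown region for tip ", id, ": ",
                         paste(setdiff(r, regions), collapse = ", "))
    idx <- sort(idx)
    if (length(idx) > max_size) {
      stop("range of tip ", id, " exceeds max size ", max_size)
    }
    match(paste(idx, collapse = ","), key)
  }, integer(1))
  structure(list(regions = regions, max_size = max_size,
                 tip_states = tip_states, states = states),
            class = "range_data")
}

# non-empty subsets of 1..n_regions with size <= K, ordered by size then
# lexicographically
range_states <- function(n_regions, K) {
  out <- list()
  for (k in seq_len(min(K, n_regions))) {
    cmb <- combn(n_regions, k)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}

# anagenetic DEC generator: gain area a at rate d * |range| (all pairs
# equal), lose a non-last area at rate e each
dec_qmatrix <- function(states, n_regions, d, e) {
  ns <- length(states)
  key <- vapply(states, paste, character(1), collapse = ",")
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    r <- states[[i]]
    if (length(r) < max(lengths(states))) {
      for (a in setdiff(seq_len(n_regions), r)) {
        j <- match(paste(sort(c(r, a)), collapse = ","), key)
        if (!is.na(j)) Q[i, j] <- Q[i, j] + d * length(r)
      }
    }
    if (length(r) > 1) {
      for (a in r) {
        j <- match(paste(setdiff(r, a), collapse = ","), key)
        Q[i, j] <- Q[i, j] + e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# cladogenetic event table per ancestor state: list of (left, right, weight)
# matrices.  Subset sympatry and size-1 vicariance weight 1; founder events
# weight j (one daughter keeps the range, the other jumps to a single area
# outside it).  Ordered daughter pairs are enumerated.
dec_clado_table <- function(states, n_regions, j) {
  key <- vapply(states, paste, character(1), collapse = ",")
  sid <- function(r) match(paste(sort(r), collapse = ","), key)
  lapply(seq_along(states), function(i) {
    r <- states[[i]]
    ev <- list()
    add <- function(l, rr, w) {
      li <- sid(l); ri <- sid(rr)
      if (!is.na(li) && !is.na(ri) && w > 0) {
        ev[[length(ev) + 1L]] <<- c(li, ri, w)
      }
    }
    if (length(r) == 1) {
      add(r, r, 1)
    } else {
      for (a in r) {
        add(a, r, 1); add(r, a, 1)                 # subset sympatry
        add(a, setdiff(r, a), 1); add(setdiff(r, a), a, 1) # vicariance
      }
    }
    if (j > 0) {
      for (a in setdiff(seq_len(n_regions), r)) {
        add(r, a, j); add(a, r, j)                 # founder event
      }
    }
    m <- do.call(rbind, ev)
    m[, 3] <- m[, 3] / sum(m[, 3])
    m
  })
}

# transition matrices for all branch lengths via one eigendecomposition;
# falls back to series expm if Q is near-defective
dec_pmatrices <- function(Q, lens) {
  eg <- eigen(Q)
  ok <- TRUE
  Vi <- tryCatch(solve(eg$vectors), error = function(e) { ok <<- FALSE; NULL })
  if (ok && is.finite(max(abs(Vi)))) {
    lapply(lens, function(t) {
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
      P[P < 0] <- 0
      P
    })
  } else {
    lapply(lens, function(t) expm_series(Q * t))
  }
}

# scaling-and-squaring series matrix exponential (fallback only)
expm_series <- function(M) {
  n <- nrow(M)
  s <- max(0, ceiling(log2(max(1, max(abs(M))))))
  A <- M / 2^s
  P <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% A / k
    P <- P + term
    if (max(abs(term)) < 1e-16) break
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' DEC / DEC+J log-likelihood
#'
#' State space: non-empty region subsets of size at most K.  Along
#' branches, ranges gain an area at rate `d` times the current range size
#' and lose a non-last area at rate `e`.  At cladogenesis, a single-area
#' range is copied to both daughters; a widespread range undergoes subset
#' sympatry or single-area vicariance (weight 1 per ordered elementary
#' event); `j > 0` adds founder events (weight `j`) in which one daughter
#' jumps to a single unoccupied area.  Event probabilities are normalized
#' per ancestor state; the root prior is uniform over states.
#'
#' @param tree Binary rooted `"phylo"` with branch lengths.
#' @param ranges A `"range_data"` whose tips cover the tree's tips.
#' @param d,e Anagenetic dispersal and extirpation rates (>= 0).
#' @param j Founder-event weight in `[0, 3]` (0 recovers plain DEC).
#' @return The log-likelihood.
#' @export
dec_loglik <- function(tree, ranges, d, e, j = 0) {
  validate_tree(tree)
  stopifnot(inherits(ranges, "range_data"), d >= 0, e >= 0, j >= 0)
  ntip <- ape::Ntip(tree)
  if (any(tabulate(tree$edge[, 1]) > 2)) stop("tree must be binary")
  miss <- setdiff(tree$tip.label, names(ranges$tip_states))
  if (length(miss) > 0) stop("tip(s) without range data: ",
                             paste(miss, collapse = ", "))
  states <- ranges$states
  ns <- length(states)
  nR <- length(ranges$regions)
  if (ns == 1) return(0) # degenerate single-state space
  Q <- dec_qmatrix(states, nR, d, e)
  clado <- dec_clado_table(states, nR, j)
  Pm <- dec_pmatrices(Q, tree$edge.length)
  nn <- ntip + tree$Nnode
  L <- matrix(0, nn, ns)
  logscale <- numeric(nn)
  for (i in seq_len(ntip)) {
    L[i, ranges$tip_states[tree$tip.label[i]]] <- 1
  }
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # nodes in child-before-parent order: last occurrence of each parent in
  # the postorder edge sequence
  pa_seq <- tree$edge[ape::postorder(tree), 1]
  po_nodes <- rev(unique(rev(pa_seq)))
  for (nd in po_nodes) {
    es <- kids[[as.character(nd)]]
    # conditional likelihood at the top of each daughter branch
    up <- lapply(es, function(e) {
      ch <- tree$edge[e, 2]
      as.vector(Pm[[e]] %*% L[ch, ])
    })
    lv <- numeric(ns)
    for (si in seq_len(ns)) {
      tb <- clado[[si]]
      lv[si] <- sum(tb[, 3] * up[[1]][tb[, 1]] * up[[2]][tb[, 2]])
    }
    L[nd, ] <- lv
    logscale[nd] <- sum(vapply(es, function(e) logscale[tree$edge[e, 2]],
                               numeric(1)))
    mx <- max(lv)
    if (mx > 0 && mx < 1e-200) {
      L[nd, ] <- lv / mx
      logscale[nd] <- logscale[nd] + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- mean(L[root, ]) # uniform root prior
  if (lik <= 0) return(-Inf)
  log(lik) + logscale[root]
}

#' Fit a DEC or DEC+J model by maximum likelihood
#'
#' Nelder-Mead from `starts` jittered initial points; `d` and `e` are
#' optimized on a log scale inside box bounds and `j` on a logit scale
#' over its bound.  For DEC+J the fitted DEC optimum (with a small `j`) is
#' added as an extra start, so the nested model's likelihood is never left
#' below its special case by a local optimum.
#'
#' @param tree,ranges As in [dec_loglik()].
#' @param model `"DEC"` or `"DEC+J"`.
#' @param starts Number of jittered starts (default 5).
#' @param seed Integer seed for the jitter.
#' @param init Initial `(d, e)` rates.
#' @param bounds List with elements `d`, `e` (each `c(lo, hi)`, defaults
#'   `c(1e-6, 5)` events per unit branch length) and `j` (`c(0, jmax)`,
#'   default upper 3).
#' @return A list of class `"range_model_fit"`: `model`, `d`, `e`, `j`,
#'   `loglik`, `k_params`, `aic`, `convergence`, `trace` (per-start
#'   data.frame), `assumptions` (state-space metadata).
#' @export
fit_range_model <- function(tree, ranges, model = c("DEC", "DEC+J"),
                            starts = 5, seed = 1L, init = c(0.1, 0.1),
                            bounds = list(d = c(1e-6, 5), e = c(1e-6, 5),
                                          j = c(0, 3))) {
  model <- match.arg(model)
  plus_j <- model == "DEC+J"
  jmax <- bounds$j[2]
  # log-scale logistic between the box bounds
  to_rate <- function(x, b) exp(log(b[1]) + (log(b[2]) - log(b[1])) / (1 + exp(-x)))
  from_rate <- function(r, b) {
    f <- (log(r) - log(b[1])) / (log(b[2]) - log(b[1]))
    f <- min(max(f, 1e-6), 1 - 1e-6)
    log(f / (1 - f))
  }
  unpack <- function(par) {
    c(d = to_rate(par[1], bounds$d), e = to_rate(par[2], bounds$e),
      j = if (plus_j) jmax / (1 + exp(-par[3])) else 0)
  }
  obj <- function(par) {
    p <- unpack(par)
    ll <- dec_loglik(tree, ranges, p["d"], p["e"], p["j"])
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  base <- c(from_rate(init[1], bounds$d), from_rate(init[2], bounds$e),
            if (plus_j) 0 else NULL)
  start_list <- lapply(seq_len(starts), function(s) {
    if (s == 1) base else base + rnorm(length(base), sd = 1.5)
  })
  if (plus_j) {
    # seed from the DEC optimum with a near-zero founder weight
    dec_fit <- fit_range_model(tree, ranges, "DEC", starts = starts,
                               seed = seed, init = init, bounds = bounds)
    start_list <- c(start_list,
                    list(c(from_rate(dec_fit$d, bounds$d),
                           from_rate(dec_fit$e, bounds$e), -8)))
  }
  best <- NULL
  trace <- list()
  for (s in seq_along(start_list)) {
    fit <- tryCatch(
      optim(start_list[[s]], obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) {
      trace[[s]] <- data.frame(start = s, loglik = NA, convergence = NA)
      next
    }
    trace[[s]] <- data.frame(start = s, loglik = -fit$value,
                             convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- unpack(best$par)
  d <- p[["d"]]; e <- p[["e"]]; j <- p[["j"]]
  ll <- -best$value
  k <- if (plus_j) 3L else 2L
  structure(list(model = model, d = d, e = e, j = j, loglik = ll,
                 k_params = k, aic = 2 * k - 2 * ll,
                 convergence = best$convergence == 0,
                 trace = do.call(rbind, trace),
                 assumptions = list(regions = ranges$regions,
                                    max_range_size = ranges$max_size,
                                    root_prior = "uniform",
                                    dispersal = "equal between all pairs")),
            class = "range_model_fit")
}

#' @export
print.range_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: d = %.4g, e = %.4g%s, lnL = %.4f, AIC = %.3f%s\n",
              x$model, x$d, x$e,
              if (x$model == "DEC+J") sprintf(", j = %.4g", x$j) else "",
              x$loglik, x$aic,
              if (x$convergence) "" else " (NOT converged)"))
  invisible(x)
}

#' Simulate tip ranges under a DEC / DEC+J process
#'
#' Forward simulation down the tree: the root range is a uniformly drawn
#' state; branches evolve by the anagenetic CTMC (gain at `d` x range
#' size, loss at `e`); at each node a cladogenetic event is drawn from the
#' normalized event table.  Used for model-adequacy experiments.
#'
#' @param tree Binary rooted `"phylo"`.
#' @param regions Region set.
#' @param d,e,j Model parameters.
#' @param max_size Maximum range size K.
#' @param seed Integer seed.
#' @return A `"range_data"` of simulated tip ranges.
#' @export
simulate_ranges <- function(tree, regions = YARTSA_REGIONS, d = 0.1, e = 0.05,
                            j = 0, max_size = 2, seed = 1L) {
  validate_tree(tree)
  set.seed(seed)
  states <- range_states(length(regions), max_size)
  ns <- length(states)
  Q <- dec_qmatrix(states, length(regions), d, e)
  clado <- dec_clado_table(states, length(regions), j)
  ntip <- ape::Ntip(tree)
  state_at <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  state_at[root] <- sample.int(ns, 1)
  evolve <- function(s0, t) {
    s <- s0; left <- t
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) return(s)
      w <- rexp(1, rate)
      if (w > left) return(s)
      left <- left - w
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(ns, 1, prob = probs)
    }
  }
  ord <- rev(ape::postorder(tree))
  # cladogenesis at each internal node, then anagenesis along each edge
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  daughters <- list()
  for (nd in unique(tree$edge[ord, 1])) {
    es <- kids[[as.character(nd)]]
    tb <- clado[[state_at[nd]]]
    pick <- tb[sample.int(nrow(tb), 1, prob = tb[, 3]), ]
    tops <- c(pick[1], pick[2])
    for (i in seq_along(es)) {
      e_i <- es[i]
      ch <- tree$edge[e_i, 2]
      state_at[ch] <- evolve(tops[i], tree$edge.length[e_i])
    }
  }
  ranges <- lapply(seq_len(ntip), function(i) regions[states[[state_at[i]]]])
  names(ranges) <- tree$tip.label
  range_data(ranges, regions = regions, max_size = max_size)
}
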