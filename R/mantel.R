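# Mantel test of matrix correlation with a simultaneous row/column
# permutation null.  Small instances (n <= 7) are enumerated exactly.

#' Mantel test between two labelled distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a null built by
#' simultaneously permuting the rows and columns of the *second* matrix.
#' The permutation p-value uses the (1 + k) / (1 + N) estimator so p is
#' never zero; with `n <= 7` and `n_perm >= n!` every permutation is
#' enumerated and the exact p = #\{perm r >= observed\} / n! is returned
#' (the identity permutation counts, so exact p >= 1/n!).
#'
#' @param d1,d2 `"dist_matrix"` objects with identical labels in the same
#'   order, `n >= 4`, both with non-zero off-diagonal variance.
#' @param n_perm Number of random permutations (ignored when enumerating).
#' @param tail `"greater"` (directional, the default: isolation by distance
#'   and codivergence predict positive correlation) or `"two-sided"`
#'   (absolute values compared).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `"mantel_result"`: `r`, `p`, `n_perm`, `n`,
#'   `exact`, `tail`, `seed`.
#' @export
#' @examples
#' set.seed(1)
#' xy <- matrix(rnorm(20), 10)
#' rownames(xy) <- paste0("s", 1:10)
#' d <- as.matrix(dist(xy)); g <- as.matrix(dist(xy + rnorm(20, sd = .2)))
#' dimnames(g) <- dimnames(d)
#' mantel_test(dist_matrix(d), dist_matrix(g, "geographic"), n_perm = 99, seed = 1)
mantel_test <- function(d1, d2, n_perm = 999, tail = c("greater", "two-sided"),
                        seed = 1L) {
  tail <- match.arg(tail)
  if (!identical(rownames(d1), rownames(d2))) {
    stop("label mismatch between the two matrices")
  }
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples for a Mantel test")
  v1 <- upper_vec(unclass(d1))
  v2 <- upper_vec(unclass(d2))
  if (sd(v1) == 0 || sd(v2) == 0) {
    stop("zero off-diagonal variance; Mantel correlation undefined")
  }
  r_obs <- cor(v1, v2)
  stat <- function(r) if (tail == "greater") r else abs(r)
  m2 <- unclass(d2)
  exact <- n <= 7 && n_perm >= factorial(n)
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      cor(v1, upper_vec(m2[p, p]))
    }, numeric(1))
    p_val <- sum(stat(rs) >= stat(r_obs)) / nrow(perms)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    count <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      r_p <- cor(v1, upper_vec(m2[p, p]))
      if (stat(r_p) >= stat(r_obs)) count <- count + 1L
    }
    p_val <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_used, n = n,
                 exact = exact, tail = tail, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%s%d permutations, n = %d)\n",
              x$tail, x$r, x$p, if (x$exact) "exact, all " else "", x$n_perm, x$n))
  invisible(x)
}

# all n! permutations of 1..n as a matrix (rows); n <= 8 guarded
all_permutations <- function(n) {
  stopifnot(n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  k <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[seq(k, k + nrow(sub) - 1L), ] <- as.matrix(block)
    k <- k + nrow(sub)
  }
  out
}
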