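# Host-parasite congruence tests.  ParaFit links host and parasite
# principal coordinates through the association matrix (global trace
# statistic + per-link leave-one-out contributions); PACo superimposes the
# two Cailliez-corrected PCoA configurations by least-squares Procrustes
# and measures the residual sum of squares m2.  Both carry permutation
# nulls in their original papers' conventions.

# Gower double-centering of a squared-distance matrix
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a); gm <- mean(a)
  a - outer(rm, rm, "+") + gm
}

# PCoA keeping axes with eigenvalue > eps * max eigenvalue
pcoa_axes <- function(d, eps = 1e-8) {
  g <- gower_center(unclass(d))
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > eps * max(e$values)
  if (!any(keep)) stop("no positive principal coordinate axes")
  ax <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                 nrow = sum(keep))
  rownames(ax) <- rownames(d)
  ax
}

# Cailliez additive correction: smallest c making D + c embeddable
cailliez_pcoa <- function(d, eps = 1e-8) {
  dm <- unclass(d)
  g <- gower_center(dm)
  if (min(eigen(g, symmetric = TRUE, only.values = TRUE)$values) >=
      -eps * max(abs(g))) {
    return(pcoa_axes(dm, eps))
  }
  n <- nrow(dm)
  # Cailliez (1983): c = largest eigenvalue of the 2n x 2n companion matrix
  del1 <- gower_center(dm)
  del2 <- {
    a <- -0.5 * dm
    rm <- rowMeans(a); gm <- mean(a)
    a - outer(rm, rm, "+") + gm
  }
  M <- rbind(cbind(matrix(0, n, n), 2 * del1),
             cbind(-diag(n), -4 * del2))
  cc <- max(Re(eigen(M, only.values = TRUE)$values))
  dc <- dm + cc
  diag(dc) <- 0
  pcoa_axes(dc, eps)
}

# links (parasite, host index pairs) of an association matrix
assoc_links <- function(A) which(unclass(A) == 1, arr.ind = TRUE)

#' ParaFit test of host-parasite cophylogenetic congruence
#'
#' The global statistic is `trace(t(D) D)` with `D = t(C) A B`, where `B`
#' and `C` are the principal coordinates of the host and parasite distance
#' matrices and `A` is the binary association matrix.  The null permutes,
#' independently for each parasite (row of `A`), which hosts it links to;
#' p = (1 + #\{perm >= obs\}) / (1 + n_perm).  Per-link statistics (F1 =
#' the drop in the global statistic when the link is removed) get p-values
#' under the same null.
#'
#' @param d_host,d_par `"dist_matrix"` objects for hosts and parasites
#'   (sequence or patristic distances; record which in `distance_kind`).
#' @param A An `"assoc_matrix"` with rows = parasites (labels matching
#'   `d_par`) and columns = hosts (matching `d_host`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param per_link Compute per-link F1 statistics and p-values.
#' @param exact If `TRUE`, enumerate the full row-permutation null (every
#'   combination of per-parasite host permutations) instead of sampling;
#'   only feasible for tiny instances (the product of per-row permutation
#'   counts is capped at 500000).  p is then #\{perm >= obs\} / n_total.
#' @return A list of class `"parafit_result"`: `global`, `p_global`,
#'   `links` (data.frame parasite/host/f1/p), `n_perm`, `seed`,
#'   `distance_kind`.
#' @export
parafit_test <- function(d_host, d_par, A, n_perm = 999, seed = 1L,
                         per_link = TRUE, exact = FALSE) {
  if (!identical(colnames(A), rownames(d_host))) {
    stop("association columns must match host distance labels")
  }
  if (!identical(rownames(A), rownames(d_par))) {
    stop("association rows must match parasite distance labels")
  }
  if (nrow(d_host) < 2 || nrow(d_par) < 2) stop("need >= 2 hosts and parasites")
  B <- pcoa_axes(d_host)
  C <- pcoa_axes(d_par)
  Am <- unclass(A)
  gstat <- function(Ax) {
    D <- crossprod(C, Ax %*% B)
    sum(D^2)
  }
  g_obs <- gstat(Am)
  links <- assoc_links(A)
  f1 <- function(Ax, lk) {
    # trace drop when link lk is removed: 2 c' D b - |c|^2 |b|^2
    D <- crossprod(C, Ax %*% B)
    vapply(seq_len(nrow(lk)), function(i) {
      cv <- C[lk[i, 1], ]; bv <- B[lk[i, 2], ]
      2 * drop(cv %*% D %*% bv) - sum(cv^2) * sum(bv^2)
    }, numeric(1))
  }
  f1_obs <- if (per_link) f1(Am, links) else NULL
  ge_global <- 0L
  ge_link <- if (per_link) integer(nrow(links)) else NULL
  if (exact) {
    nh <- ncol(Am)
    if (factorial(nh)^nrow(Am) > 5e5) stop("exact null too large to enumerate")
    perms <- all_permutations(nh)
    idx <- rep(1L, nrow(Am))
    n_total <- 0L
    repeat {
      Ap <- t(vapply(seq_len(nrow(Am)),
                     function(r) Am[r, perms[idx[r], ]], numeric(nh)))
      if (gstat(Ap) >= g_obs - 1e-12) ge_global <- ge_global + 1L
      if (per_link) ge_link <- ge_link + as.integer(f1(Ap, links) >= f1_obs - 1e-12)
      n_total <- n_total + 1L
      r <- 1L
      while (r <= nrow(Am)) {
        idx[r] <- idx[r] + 1L
        if (idx[r] <= nrow(perms)) break
        idx[r] <- 1L; r <- r + 1L
      }
      if (r > nrow(Am)) break
    }
    p_global <- ge_global / n_total
    if (per_link) {
      link_p <- ge_link / n_total
    }
    link_df <- NULL
    if (per_link) {
      link_df <- data.frame(parasite = rownames(A)[links[, 1]],
                            host = colnames(A)[links[, 2]],
                            f1 = f1_obs, p = link_p)
    }
    return(structure(list(global = g_obs, p_global = p_global, links = link_df,
                          n_perm = n_total, seed = seed, exact = TRUE,
                          distance_kind = c(host = attr(d_host, "kind"),
                                            parasite = attr(d_par, "kind"))),
                     class = "parafit_result"))
  }
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    Ap <- Am
    for (r in seq_len(nrow(Ap))) Ap[r, ] <- Ap[r, sample.int(ncol(Ap))]
    if (gstat(Ap) >= g_obs) ge_global <- ge_global + 1L
    if (per_link) {
      ge_link <- ge_link + as.integer(f1(Ap, links) >= f1_obs)
    }
  }
  p_global <- (1 + ge_global) / (1 + n_perm)
  link_df <- NULL
  if (per_link) {
    link_df <- data.frame(parasite = rownames(A)[links[, 1]],
                          host = colnames(A)[links[, 2]],
                          f1 = f1_obs,
                          p = (1 + ge_link) / (1 + n_perm))
  }
  structure(list(global = g_obs, p_global = p_global, links = link_df,
                 n_perm = n_perm, seed = seed,
                 distance_kind = c(host = attr(d_host, "kind"),
                                   parasite = attr(d_par, "kind"))),
            class = "parafit_result")
}

#' @export
print.parafit_result <- function(x, ...) {
  cat(sprintf("ParaFit: global = %.6g, p = %.4g (%d permutations)\n",
              x$global, x$p_global, x$n_perm))
  if (!is.null(x$links)) {
    cat(sprintf("%d links; %d with p <= 0.05\n", nrow(x$links),
                sum(x$links$p <= 0.05)))
  }
  invisible(x)
}

# least-squares Procrustes of Y onto X (translation, scaling, rotation);
# returns residual sum of squares and per-row squared residuals
procrustes_m2 <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  # pad to common dimensionality
  k <- max(ncol(Xc), ncol(Yc))
  if (ncol(Xc) < k) Xc <- cbind(Xc, matrix(0, nrow(Xc), k - ncol(Xc)))
  if (ncol(Yc) < k) Yc <- cbind(Yc, matrix(0, nrow(Yc), k - ncol(Yc)))
  sv <- svd(crossprod(Xc, Yc))
  rot <- sv$v %*% t(sv$u)
  scl <- sum(sv$d) / sum(Yc^2)
  fit <- scl * Yc %*% rot
  res2 <- rowSums((Xc - fit)^2)
  list(m2 = sum(res2), residuals = res2)
}

#' PACo (Procrustean Approach to Cophylogeny) test
#'
#' Hosts and parasites are embedded by Cailliez-corrected principal
#' coordinates; rows are replicated per association link to form matched
#' configurations; the parasite configuration is superimposed on the host
#' configuration by least-squares Procrustes (translation, scaling,
#' rotation).  Small residual m2 indicates congruence, so the null
#' (shuffling the parasite rows of the association) counts permutations
#' with m2 <= observed.
#'
#' @inheritParams parafit_test
#' @return A list of class `"paco_result"`: `m2`, `p`, `residuals`
#'   (per-link squared residuals, named `parasite|host`), `n_perm`, `seed`,
#'   `distance_kind`.
#' @export
paco_test <- function(d_host, d_par, A, n_perm = 999, seed = 1L) {
  if (!identical(colnames(A), rownames(d_host))) {
    stop("association columns must match host distance labels")
  }
  if (!identical(rownames(A), rownames(d_par))) {
    stop("association rows must match parasite distance labels")
  }
  X <- cailliez_pcoa(d_host)
  Y <- cailliez_pcoa(d_par)
  Am <- unclass(A)
  links <- assoc_links(A)
  m2_of <- function(lk) procrustes_m2(X[lk[, 2], , drop = FALSE],
                                      Y[lk[, 1], , drop = FALSE])
  obs <- m2_of(links)
  set.seed(seed)
  le <- 0L
  for (i in seq_len(n_perm)) {
    Ap <- Am[sample.int(nrow(Am)), , drop = FALSE]
    lk <- which(Ap == 1, arr.ind = TRUE)
    if (m2_of(lk)$m2 <= obs$m2) le <- le + 1L
  }
  res <- obs$residuals
  names(res) <- paste(rownames(A)[links[, 1]], colnames(A)[links[, 2]],
                      sep = "|")
  structure(list(m2 = obs$m2, p = (1 + le) / (1 + n_perm), residuals = res,
                 n_perm = n_perm, seed = seed,
                 distance_kind = c(host = attr(d_host, "kind"),
                                   parasite = attr(d_par, "kind"))),
            class = "paco_result")
}

#' @export
print.paco_result <- function(x, ...) {
  cat(sprintf("PACo: m2 = %.6g, p = %.4g (%d permutations, %d links)\n",
              x$m2, x$p, x$n_perm, length(x$residuals)))
  invisible(x)
}
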