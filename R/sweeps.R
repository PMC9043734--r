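# Signal-localization sweeps: geographic cluster radius ("width") and
# phylogenetic time slice ("depth").  Each control value summarizes Mantel
# correlations as mean/min/max r and mean p.

#' Mantel signal across geographic cluster radii
#'
#' Complete-linkage hierarchical clustering of the samples on their
#' geographic distances is cut at each radius (so a cut at h bounds cluster
#' diameter by h); within every cluster of at least `min_cluster` samples a
#' Mantel test between `d1` and `d2` is run, and mean/min/max r and mean p
#' are recorded per radius.
#'
#' @param d1,d2 `"dist_matrix"` objects with identical labels; the Mantel
#'   pair (e.g. genetic vs geographic for IBD, or host vs parasite genetic
#'   distances for the cophylogeny-by-radius variant).
#' @param radii Increasing cut heights in km (default 100..2000 by 100, the
#'   sweep grid of the study).
#' @param min_cluster Minimum cluster size entering a Mantel test (default
#'   5, i.e. at least 10 distance pairs).
#' @param n_perm Permutations per Mantel test.
#' @param seed Integer seed.
#' @param cluster_on Matrix whose distances drive the clustering; defaults
#'   to `d2` (the plain geographic sweep).
#' @param linkage Agglomeration method (default `"complete"`).
#' @return A `"sweep_result"`: data.frame with columns `control`, `mean_r`,
#'   `min_r`, `max_r`, `mean_p`, `n_clusters`, `n_skipped`; attribute
#'   `empty` flags a sweep where no radius produced a usable cluster.
#' @export
geographic_cluster_sweep <- function(d1, d2, radii = seq(100, 2000, by = 100),
                                     min_cluster = 5, n_perm = 199, seed = 1L,
                                     cluster_on = d2,
                                     linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  if (!identical(rownames(d1), rownames(d2))) stop("label mismatch")
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be strictly increasing")
  hc <- hclust(as.dist(unclass(cluster_on)), method = linkage)
  rows <- lapply(seq_along(radii), function(i) {
    h <- radii[i]
    cl <- cutree(hc, h = h)
    rs <- numeric(0); ps <- numeric(0); skipped <- 0L
    for (k in unique(cl)) {
      ids <- names(cl)[cl == k]
      if (length(ids) < min_cluster) { skipped <- skipped + 1L; next }
      mt <- tryCatch(
        mantel_test(subset_dist(d1, ids), subset_dist(d2, ids),
                    n_perm = n_perm, seed = stage_seed(seed, paste0("radius", h, "c", k))),
        error = function(e) NULL) # zero-variance clusters are skipped
      if (is.null(mt)) { skipped <- skipped + 1L; next }
      rs <- c(rs, mt$r); ps <- c(ps, mt$p)
    }
    data.frame(control = h,
               mean_r = if (length(rs)) mean(rs) else NA_real_,
               min_r = if (length(rs)) min(rs) else NA_real_,
               max_r = if (length(rs)) max(rs) else NA_real_,
               mean_p = if (length(ps)) mean(ps) else NA_real_,
               n_clusters = length(rs), n_skipped = skipped)
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("sweep_result", "data.frame"),
            mode = "radius", empty = all(res$n_clusters == 0))
}

#' Mantel signal across phylogenetic time slices
#'
#' At each age t the lineages alive at t partition the tips into clades;
#' each clade is represented by its medoid tip under `d_other` (ties broken
#' lexicographically).  The Mantel pair at depth t is the sliced patristic
#' matrix (branch lengths truncated at t, i.e. patristic distance between
#' the crossing lineages) against the `d_other` submatrix on the medoids.
#' Ages with fewer than 4 surviving lineages are skipped and flagged.
#'
#' @param tree Ultrametric `"phylo"`; tip labels must be a subset of
#'   `d_other`'s labels.
#' @param d_other A `"dist_matrix"` (e.g. geographic for IBD depth,
#'   parasite genetic distances for cophylogeny depth).
#' @param ages Increasing slice ages (0 = present); must not exceed the
#'   root height.
#' @param n_perm,seed As in [mantel_test()].
#' @return A `"sweep_result"` data.frame (one row per age; `n_clusters` is
#'   the number of lineages at that age, 0 where skipped).
#' @export
time_slice_sweep <- function(tree, d_other, ages, n_perm = 199, seed = 1L) {
  validate_tree(tree, ultrametric = TRUE)
  miss <- setdiff(tree$tip.label, rownames(d_other))
  if (length(miss) > 0) stop("tips missing from distance matrix: ",
                             paste(miss, collapse = ", "))
  H <- tree_height(tree)
  if (any(ages > H)) stop("slice age exceeds root height")
  if (is.unsorted(ages, strictly = TRUE)) stop("ages must be strictly increasing")
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  pat <- ape::cophenetic.phylo(tree)
  rows <- lapply(ages, function(t) {
    # lineages alive at t: edges whose child is younger (age < t) and parent older
    if (t == 0) {
      clades <- as.list(seq_len(ntip))
    } else {
      cross <- which(age[tree$edge[, 2]] < t & age[tree$edge[, 1]] >= t)
      clades <- lapply(tree$edge[cross, 2], function(nd) desc[[nd]])
    }
    if (length(clades) < 4) {
      return(data.frame(control = t, mean_r = NA_real_, min_r = NA_real_,
                        max_r = NA_real_, mean_p = NA_real_,
                        n_clusters = 0L, n_skipped = 1L))
    }
    med <- vapply(clades, function(tt) {
      labs <- sort(tree$tip.label[tt])
      if (length(labs) == 1) return(labs)
      sub <- unclass(d_other)[labs, labs, drop = FALSE]
      labs[which.min(rowMeans(sub))] # ties: first of the sorted labels
    }, character(1))
    sliced <- pat[med, med, drop = FALSE] - 2 * t
    diag(sliced) <- 0
    sliced[sliced < 0] <- 0 # numerical guard; lineages distinct at t
    mt <- tryCatch(
      mantel_test(dist_matrix(sliced, kind = "patristic"),
                  subset_dist(d_other, med),
                  n_perm = n_perm, seed = stage_seed(seed, paste0("slice", t))),
      error = function(e) NULL)
    if (is.null(mt)) {
      return(data.frame(control = t, mean_r = NA_real_, min_r = NA_real_,
                        max_r = NA_real_, mean_p = NA_real_,
                        n_clusters = length(clades), n_skipped = 1L))
    }
    data.frame(control = t, mean_r = mt$r, min_r = mt$r, max_r = mt$r,
               mean_p = mt$p, n_clusters = length(clades), n_skipped = 0L)
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("sweep_result", "data.frame"),
            mode = "timeslice", empty = all(res$n_clusters == 0))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("%s sweep over %d control values%s\n",
              attr(x, "mode") %||% "signal", nrow(x),
              if (isTRUE(attr(x, "empty"))) " (EMPTY: no usable clusters)" else ""))
  print(as.data.frame(x))
  invisible(x)
}
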