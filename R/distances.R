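# All distance matrices feeding the Mantel / cophylogeny machinery:
# sequence p-distances (optionally JC-corrected), great-circle geography,
# climatic differences, least-cost landscape resistance, and patristic
# distances on trees.

EARTH_RADIUS_KM <- 6371.0088

#' Pairwise genetic distances over a multi-locus alignment
#'
#' Uncorrected p-distance (or its Jukes-Cantor correction) over the
#' concatenation of the selected loci.  Sites where either sequence carries
#' `-` or `N` are deleted pairwise, matching how degraded market samples
#' must be handled; pairs with no comparable site are an error.
#'
#' @param aln A `"multilocus"` alignment.
#' @param loci Locus subset (default all).
#' @param correction `"none"` (p-distance) or `"JC"`
#'   (\eqn{-\frac{3}{4}\log(1 - \frac{4p}{3})}).
#' @param samples Samples to include (default all).
#' @return A `"dist_matrix"` of kind `"genetic"`.
#' @export
genetic_distance <- function(aln, loci = names(aln$loci),
                             correction = c("none", "JC"),
                             samples = aln$samples) {
  correction <- match.arg(correction)
  codes <- encode_dna(concat_loci(aln, loci = loci, samples = samples))
  n <- nrow(codes)
  if (n < 2) stop("need at least 2 samples")
  valid <- codes != 4L
  storage.mode(valid) <- "double"
  comp <- tcrossprod(valid) # comparable sites per pair
  match_cnt <- matrix(0, n, n)
  for (b in 0:3) {
    xb <- (codes == b) & (valid > 0)
    storage.mode(xb) <- "double"
    match_cnt <- match_cnt + tcrossprod(xb)
  }
  off <- upper.tri(comp)
  if (any(comp[off] == 0)) {
    ij <- which(comp == 0 & off, arr.ind = TRUE)[1, ]
    stop(sprintf("no overlapping sites for pair %s / %s",
                 rownames(codes)[ij[1]], rownames(codes)[ij[2]]))
  }
  p <- (comp - match_cnt) / comp
  diag(p) <- 0
  if (correction == "JC") {
    if (any(p[off] >= 0.75)) {
      ij <- which(p >= 0.75 & off, arr.ind = TRUE)[1, ]
      stop(sprintf("JC correction undefined (p >= 0.75) for pair %s / %s",
                   rownames(codes)[ij[1]], rownames(codes)[ij[2]]))
    }
    p <- -0.75 * log(1 - 4 * p / 3)
    diag(p) <- 0
  }
  dimnames(p) <- list(rownames(codes), rownames(codes))
  dist_matrix(p, kind = "genetic")
}

#' Great-circle distance matrix between samples (km)
#'
#' Haversine distances on a sphere of radius 6371.0088 km.  An
#' equirectangular planar option (projection at the mean latitude) is
#' available for fidelity checks at small extents.
#'
#' @param samples A `"sample_table"`.
#' @param method `"haversine"` (default) or `"equirectangular"`.
#' @return A `"dist_matrix"` of kind `"geographic"`, in km.
#' @export
haversine_matrix <- function(samples, method = c("haversine", "equirectangular")) {
  method <- match.arg(method)
  lat <- samples$latitude * pi / 180
  lon <- samples$longitude * pi / 180
  n <- length(lat)
  if (method == "haversine") {
    dlat <- outer(lat, lat, "-") / 2
    dlon <- outer(lon, lon, "-") / 2
    a <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
    a <- pmin(pmax(a, 0), 1)
    d <- 2 * EARTH_RADIUS_KM * asin(sqrt(a))
  } else {
    mlat <- mean(lat)
    x <- lon * cos(mlat) * EARTH_RADIUS_KM
    y <- lat * EARTH_RADIUS_KM
    d <- as.matrix(stats::dist(cbind(x, y)))
  }
  dimnames(d) <- list(samples$id, samples$id)
  diag(d) <- 0
  dist_matrix(d, kind = "geographic")
}

#' Climatic distance matrix (absolute difference of the climate covariate)
#'
#' @param samples A `"sample_table"` with a `climate` column (e.g. mean
#'   temperature of the coldest quarter, deg C).
#' @return A `"dist_matrix"` of kind `"climatic"`.
#' @export
climate_distance_matrix <- function(samples) {
  if (anyNA(samples$climate)) {
    stop("missing climate values for: ",
         paste(samples$id[is.na(samples$climate)], collapse = ", "))
  }
  d <- abs(outer(samples$climate, samples$climate, "-"))
  dimnames(d) <- list(samples$id, samples$id)
  dist_matrix(d, kind = "climatic")
}

#' Least-cost-path landscape resistance distances
#'
#' Shortest-path cost between the raster cells containing each pair of
#' samples, on the 8-connected cell lattice; the weight of a lattice edge is
#' the mean of its two endpoint cell costs times the great-circle length
#' between the cell centers (km).  A stand-in for circuit-theory resistance:
#' cheap, monotone under barriers, and exactly checkable.
#'
#' @param samples A `"sample_table"`; all samples must fall inside the
#'   raster extent and not on an infinite-cost cell.
#' @param raster A `"cost_raster"`.
#' @return A `"dist_matrix"` of kind `"resistance"`.
#' @export
least_cost_distance <- function(samples, raster) {
  costs <- raster$costs
  nr <- nrow(costs); nc <- ncol(costs)
  cs <- raster$cellsize
  # cell centers: row 1 is northernmost
  lat0 <- raster$origin["lat"]; lon0 <- raster$origin["lon"]
  cell_lat <- lat0 + (rev(seq_len(nr)) - 1) * cs # by row index
  cell_lon <- lon0 + (seq_len(nc) - 1) * cs
  # locate samples
  ri <- nr - round((samples$latitude - lat0) / cs)
  ci <- round((samples$longitude - lon0) / cs) + 1
  out <- ri < 1 | ri > nr | ci < 1 | ci > nc
  if (any(out)) stop("sample(s) outside raster extent: ",
                     paste(samples$id[out], collapse = ", "))
  onbar <- !is.finite(costs[cbind(ri, ci)])
  if (any(onbar)) stop("sample(s) on an impassable cell: ",
                       paste(samples$id[onbar], collapse = ", "))
  vid <- function(r, c) (r - 1L) * nc + c
  # 8-neighbour edges (4 directions suffice for an undirected graph)
  steps <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  gc_km <- function(la1, lo1, la2, lo2) {
    la1 <- la1 * pi / 180; la2 <- la2 * pi / 180
    dlo <- (lo2 - lo1) * pi / 180
    a <- sin((la2 - la1) / 2)^2 + cos(la1) * cos(la2) * sin(dlo / 2)^2
    2 * EARTH_RADIUS_KM * asin(sqrt(pmin(pmax(a, 0), 1)))
  }
  for (s in seq_len(nrow(steps))) {
    dr <- steps[s, 1]; dc <- steps[s, 2]
    rr <- seq_len(nr); cc <- seq_len(nc)
    r1 <- rr[rr + dr >= 1 & rr + dr <= nr]
    c1 <- cc[cc + dc >= 1 & cc + dc <= nc]
    if (length(r1) == 0 || length(c1) == 0) next
    g <- expand.grid(r = r1, c = c1)
    r2 <- g$r + dr; c2 <- g$c + dc
    cost1 <- costs[cbind(g$r, g$c)]; cost2 <- costs[cbind(r2, c2)]
    ok <- is.finite(cost1) & is.finite(cost2)
    if (!any(ok)) next
    len <- gc_km(cell_lat[g$r[ok]], cell_lon[g$c[ok]],
                 cell_lat[r2[ok]], cell_lon[c2[ok]])
    from <- c(from, vid(g$r[ok], g$c[ok]))
    to <- c(to, vid(r2[ok], c2[ok]))
    w <- c(w, (cost1[ok] + cost2[ok]) / 2 * len)
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  src <- vid(ri, ci)
  usrc <- unique(src)
  du <- igraph::distances(g, v = usrc, to = usrc,
                          weights = igraph::E(g)$weight,
                          algorithm = "dijkstra")
  idx <- match(src, usrc)
  d <- du[idx, idx, drop = FALSE] # samples sharing a cell have distance 0
  if (any(!is.finite(d))) stop("sample pair(s) separated by impassable barrier")
  dimnames(d) <- list(samples$id, samples$id)
  diag(d) <- 0
  dist_matrix(d, kind = "resistance")
}

#' Patristic distance matrix (sum of branch lengths between tips)
#'
#' @param tree A `"phylo"` object.
#' @param labels Tip subset (default all tips).
#' @return A `"dist_matrix"` of kind `"patristic"`.
#' @export
patristic_matrix <- function(tree, labels = tree$tip.label) {
  validate_tree(tree)
  miss <- setdiff(labels, tree$tip.label)
  if (length(miss) > 0) stop("unknown label(s): ", paste(miss, collapse = ", "))
  d <- ape::cophenetic.phylo(tree)[labels, labels, drop = FALSE]
  dist_matrix(d, kind = "patristic")
}
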