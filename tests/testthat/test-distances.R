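test_that("genetic distances match a site-by-site brute-force count", {
  d <- small_bundle()
  aln <- d$host_aln
  gd <- genetic_distance(aln)
  m <- concat_loci(aln)
  ids <- rownames(m)
  for (i in 1:4) for (j in (i + 1):5) {
    a <- m[i, ]; b <- m[j, ]
    ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
    expect_equal(gd[ids[i], ids[j]], sum(a[ok] != b[ok]) / sum(ok),
                 tolerance = 1e-12)
  }
  # hand examples
  toy <- multilocus(list(l1 = matrix(c("A", "A", "A", "A",
                                       "A", "A", "T", "T"), 2, byrow = TRUE,
                                     dimnames = list(c("x", "y"), NULL))))
  expect_equal(unname(genetic_distance(toy)["x", "y"]), 0.5)
  expect_equal(unname(genetic_distance(toy, correction = "JC")["x", "y"]),
               -0.75 * log(1 - 4 * 0.5 / 3))
})

test_that("genetic distance errors: no overlap, saturation under JC", {
  toy <- multilocus(list(l1 = matrix(c("A", "C", "N", "N",
                                       "N", "N", "G", "T"), 2, byrow = TRUE,
                                     dimnames = list(c("x", "y"), NULL))))
  expect_error(genetic_distance(toy), "no overlapping sites.*x.*y")
  sat <- multilocus(list(l1 = matrix(c("A", "A", "A", "A",
                                       "C", "C", "C", "C"), 2, byrow = TRUE,
                                     dimnames = list(c("x", "y"), NULL))))
  expect_error(genetic_distance(sat, correction = "JC"), "p >= 0.75")
  expect_error(genetic_distance(sat, loci = character(0)), "empty locus subset")
})

test_that("haversine distances hit analytic values and agree with geosphere", {
  df <- data.frame(id = c("o", "q", "anti"),
                   latitude = c(0, 0, 0), longitude = c(0, 90, 180),
                   region = "QTP", climate = 0, year = 2000)
  st <- sample_table(df)
  h <- haversine_matrix(st)
  expect_equal(unname(h["o", "q"]), pi / 2 * 6371.0088, tolerance = 1e-9)
  expect_equal(unname(h["o", "anti"]), pi * 6371.0088, tolerance = 1e-9)
  st2 <- sample_table(data.frame(id = c("a", "b"), latitude = c(30, 33.5),
                                 longitude = c(100, 92), region = "QTP",
                                 climate = 0, year = 2000))
  h2 <- haversine_matrix(st2)
  ref <- geosphere::distHaversine(c(100, 30), c(92, 33.5), r = 6371008.8) / 1000
  expect_equal(unname(h2["a", "b"]), ref, tolerance = 1e-9)
})

test_that("climate distances are absolute differences and metric", {
  st <- sample_table(data.frame(id = c("a", "b", "c"),
                                latitude = 30, longitude = 95, region = "QTP",
                                climate = c(-5, 0, 10), year = 2000))
  cd <- climate_distance_matrix(st)
  expect_equal(max(cd), 15)
  # triangle inequality over all triples
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    expect_lte(cd[i, j], cd[i, k] + cd[k, j] + 1e-12)
  }
  st$climate[2] <- NA
  expect_error(climate_distance_matrix(st), "missing climate.*b")
})

test_that("least-cost distances equal a Bellman-Ford oracle on a random raster", {
  set.seed(21)
  nr <- 12; nc <- 12
  costs <- matrix(runif(nr * nc, 0.5, 3), nr, nc)
  ras <- cost_raster(costs, cellsize = 0.1, origin = c(lat = 30, lon = 95))
  ids <- sprintf("p%d", 1:5)
  rows <- sample(nr, 5); cols <- sample(nc, 5)
  st <- sample_table(data.frame(
    id = ids, latitude = 30 + (nr - rows) * 0.1,
    longitude = 95 + (cols - 1) * 0.1, region = "QTP", climate = 0,
    year = 2000))
  lc <- least_cost_distance(st, ras)

  # oracle: Bellman-Ford relaxation over the same 8-connected lattice
  gc_km <- function(la1, lo1, la2, lo2) {
    la1 <- la1 * pi / 180; la2 <- la2 * pi / 180
    dlo <- (lo2 - lo1) * pi / 180
    a <- sin((la2 - la1) / 2)^2 + cos(la1) * cos(la2) * sin(dlo / 2)^2
    2 * 6371.0088 * asin(sqrt(a))
  }
  lat_of <- function(r) 30 + (nr - r) * 0.1
  lon_of <- function(c) 95 + (c - 1) * 0.1
  bellman <- function(sr, sc) {
    dist <- matrix(Inf, nr, nc); dist[sr, sc] <- 0
    repeat {
      changed <- FALSE
      for (r in 1:nr) for (c in 1:nc) {
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- c + dc
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          w <- (costs[r, c] + costs[r2, c2]) / 2 *
            gc_km(lat_of(r), lon_of(c), lat_of(r2), lon_of(c2))
          if (dist[r, c] + w < dist[r2, c2] - 1e-12) {
            dist[r2, c2] <- dist[r, c] + w; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    dist
  }
  d1 <- bellman(rows[1], cols[1])
  for (k in 2:5) {
    expect_equal(unname(lc[ids[1], ids[k]]), d1[rows[k], cols[k]],
                 tolerance = 1e-9)
  }
})

test_that("a barrier row forces a detour or an error, and costs are monotone", {
  base <- matrix(1, 7, 7)
  ras0 <- cost_raster(base, cellsize = 0.1, origin = c(lat = 30, lon = 95))
  st <- sample_table(data.frame(id = c("n", "s"),
                                latitude = c(30.6, 30.0),
                                longitude = c(95.3, 95.3),
                                region = "QTP", climate = 0, year = 2000))
  d0 <- least_cost_distance(st, ras0)
  # full barrier row -> no path
  wall <- base; wall[4, ] <- Inf
  expect_error(least_cost_distance(st, cost_raster(wall, 0.1,
                                                   c(lat = 30, lon = 95))),
               "barrier")
  # partial barrier -> strictly longer detour
  gap <- base; gap[4, 1:6] <- Inf
  d1 <- least_cost_distance(st, cost_raster(gap, 0.1, c(lat = 30, lon = 95)))
  expect_gt(d1["n", "s"], d0["n", "s"])
  # raising any single cell's cost never shortens any path
  up <- base; up[3, 3] <- 5
  d2 <- least_cost_distance(st, cost_raster(up, 0.1, c(lat = 30, lon = 95)))
  expect_gte(d2["n", "s"], d0["n", "s"] - 1e-12)
  expect_error(least_cost_distance(
    sample_table(data.frame(id = "far", latitude = 50, longitude = 95,
                            region = "QTP", climate = 0, year = 2000)), ras0),
    "outside raster")
})

test_that("patristic distances equal a naive LCA path-sum oracle", {
  set.seed(31)
  tr <- ape::rtree(30)
  pm <- patristic_matrix(tr)
  depth <- node_depths(tr)
  desc <- yartsa:::descendant_tips(tr)
  ntip <- ape::Ntip(tr)
  lca <- function(i, j) {
    anc <- (ntip + 1):(ntip + tr$Nnode)
    cand <- anc[vapply(anc, function(a) i %in% desc[[a]] && j %in% desc[[a]],
                       logical(1))]
    cand[which.max(depth[cand])]
  }
  idx <- cbind(sample(30, 6), sample(30, 6))
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    a <- lca(i, j)
    expect_equal(unname(pm[tr$tip.label[i], tr$tip.label[j]]),
                 depth[i] + depth[j] - 2 * depth[a], tolerance = 1e-9)
  }
  # sister tips with pendant lengths 1 and 1 -> 2; ultrametric pairs 2*height
  toy <- parse_newick("((A:1,B:1):1,C:2);")
  tm <- patristic_matrix(toy)
  expect_equal(unname(tm["A", "B"]), 2)
  expect_equal(unname(tm["A", "C"]), 2 * tree_height(toy))
  expect_error(patristic_matrix(toy, labels = c("A", "Z")), "unknown label")
})
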