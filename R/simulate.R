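# Synthetic study generator.  Emulates the statistical structure of the
# market-sample data: ~90 host samples in 4 mountain regions, a birth-death
# host tree, Brownian-motion geography (isolation by distance + a tunable
# tendency to regional monophyly), a parasite tree that co-diverges except
# where host switches re-graft lineages, 14 target-capture loci at ~5% mean
# host divergence vs ~1% parasite divergence, and per-sample locus dropout
# averaging ~13.2 recovered loci out of 14.

#' Simulation configuration
#'
#' Defaults encode the study conditions: 90 samples, 4 regions (Qinghai-
#' Tibet Plateau, Hengduan Mountains, Himalaya, and the transition zone),
#' 14 loci of 600 bp, 5% target mean pairwise host divergence with the
#' parasite at 0.2 of the host rate (~1%), locus dropout probability 0.057
#' (mean 13.2/14 loci recovered), host-switch probability 0.1 per
#' cladogenesis.
#'
#' @param n_samples Number of extant host samples (tips).
#' @param regions Named list of region centroids, each `c(lat=, lon=)`.
#' @param birth,death Birth-death rates (time units arbitrary); `birth >
#'   death >= 0`.
#' @param sigma2 Brownian dispersal rate (degrees^2 per unit time).
#' @param root_location `c(lat=, lon=)` of the root lineage.
#' @param n_loci,locus_length Locus panel geometry.
#' @param model `"JC69"` or `"HKY85"`.
#' @param kappa Transition/transversion ratio (HKY85 only).
#' @param base_freq Equilibrium base frequencies (A, C, G, T).
#' @param locus_rates Per-locus rate multipliers (recycled to `n_loci`).
#' @param target_divergence Target mean pairwise uncorrected host distance.
#' @param parasite_scaler Parasite branch-length scaler relative to host.
#' @param p_switch Host-switch probability per parasite cladogenesis.
#' @param dropout Per sample-locus dropout probability.
#' @param climate_intercept,climate_slope,climate_sd Climate covariate as a
#'   linear function of latitude plus Gaussian noise (deg C).
#' @param year_range Collection years drawn uniformly from this range.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 90,
                       regions = list(
                         QTP = c(lat = 33.5, lon = 92.0),
                         Hengduan = c(lat = 30.0, lon = 100.0),
                         Himalaya = c(lat = 28.0, lon = 86.0),
                         Transition = c(lat = 29.0, lon = 96.0)),
                       birth = 1, death = 0,
                       sigma2 = 10,
                       root_location = c(lat = 30.0, lon = 96.0),
                       n_loci = 14, locus_length = 600,
                       model = c("JC69", "HKY85"), kappa = 2,
                       base_freq = c(0.25, 0.25, 0.25, 0.25),
                       locus_rates = 1,
                       target_divergence = 0.05,
                       parasite_scaler = 0.2,
                       p_switch = 0.1,
                       dropout = 0.057,
                       climate_intercept = 25, climate_slope = -1,
                       climate_sd = 1,
                       year_range = c(1995L, 2020L)) {
  model <- match.arg(model)
  if (!(birth > death && death >= 0)) stop("require birth > death >= 0")
  if (p_switch < 0 || p_switch > 1) stop("p_switch must be in [0, 1]")
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (any(locus_length <= 0)) stop("locus lengths must be positive")
  if (length(regions) < 1) stop("at least one region is required")
  if (is.null(names(regions))) stop("regions must be named")
  cfg <- list(n_samples = n_samples, regions = regions, birth = birth,
              death = death, sigma2 = sigma2, root_location = root_location,
              n_loci = n_loci,
              locus_length = rep_len(locus_length, n_loci),
              model = model, kappa = kappa, base_freq = base_freq,
              locus_rates = rep_len(locus_rates, n_loci),
              target_divergence = target_divergence,
              parasite_scaler = parasite_scaler, p_switch = p_switch,
              dropout = dropout, climate_intercept = climate_intercept,
              climate_slope = climate_slope, climate_sd = climate_sd,
              year_range = year_range)
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric birth-death host tree
#'
#' Conditioned on `n_samples` surviving tips (via [ape::rphylo()]); tips
#' are renamed `s001..`.
#'
#' @param config A `"sim_config"`.
#' @param seed Integer seed.
#' @return An ultrametric `"phylo"`.
#' @export
simulate_host_tree <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tr <- tryCatch(
    ape::rphylo(config$n_samples, birth = config$birth, death = config$death,
                fossils = FALSE),
    error = function(e) stop("birth-death simulation failed: ",
                             conditionMessage(e)))
  tr$tip.label <- sprintf("s%03d", seq_len(config$n_samples))
  validate_tree(tr, ultrametric = TRUE)
  tr
}

#' Simulate tip geography by Brownian motion on the tree
#'
#' Latitude and longitude evolve independently by Brownian motion with rate
#' `sigma2` from the root location; each tip's region is the nearest
#' configured centroid by great-circle distance; the climate covariate is a
#' linear function of latitude plus Gaussian noise.
#'
#' @param tree Ultrametric host tree.
#' @param config A `"sim_config"`.
#' @param seed Integer seed.
#' @return A `"sample_table"` with one row per tip.
#' @export
simulate_geography <- function(tree, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_tree(tree, ultrametric = TRUE)
  set.seed(seed)
  sg <- sqrt(config$sigma2)
  lat <- ape::rTraitCont(tree, model = "BM", sigma = sg,
                         root.value = config$root_location["lat"])
  lon <- ape::rTraitCont(tree, model = "BM", sigma = sg,
                         root.value = config$root_location["lon"])
  lat <- pmin(pmax(lat, -90), 90)
  lon <- pmin(pmax(lon, -180), 180)
  cents <- do.call(rbind, config$regions)
  gc <- function(la1, lo1, la2, lo2) {
    la1 <- la1 * pi / 180; la2 <- la2 * pi / 180
    dlo <- (lo2 - lo1) * pi / 180
    a <- sin((la2 - la1) / 2)^2 + cos(la1) * cos(la2) * sin(dlo / 2)^2
    2 * asin(sqrt(pmin(pmax(a, 0), 1)))
  }
  region <- vapply(seq_along(lat), function(i) {
    d <- gc(lat[i], lon[i], cents[, "lat"], cents[, "lon"])
    names(config$regions)[which.min(d)]
  }, character(1))
  climate <- config$climate_intercept + config$climate_slope * lat +
    rnorm(length(lat), sd = config$climate_sd)
  yr <- sample(seq(config$year_range[1], config$year_range[2]),
               length(lat), replace = TRUE)
  sample_table(data.frame(id = tree$tip.label, latitude = as.numeric(lat),
                          longitude = as.numeric(lon), region = region,
                          climate = climate, year = yr),
               regions = names(config$regions))
}

#' Simulate a co-diverging parasite tree with host switches
#'
#' The parasite tree starts as a copy of the host tree.  Each host
#' cladogenesis event, visited from the root toward the tips, triggers a
#' host switch with probability `p_switch`: one daughter lineage is pruned
#' at its origin time and re-grafted onto a uniformly chosen contemporary
#' lineage at the same height, so the tree stays ultrametric while its
#' topology drifts away from the host's.  Parasite branch lengths are the
#' host lengths times `parasite_scaler`.  The association links each
#' parasite tip to its namesake host tip (total and one-to-one for any
#' `p_switch`).
#'
#' @param host_tree Ultrametric host tree.
#' @param config A `"sim_config"`.
#' @param seed Integer seed.
#' @return A list: `tree` (parasite `"phylo"`, tips named `f.<host tip>`),
#'   `assoc` (an `"assoc_matrix"`), `n_switches`.
#' @export
simulate_parasite_system <- function(host_tree, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_tree(host_tree, ultrametric = TRUE)
  p_switch <- config$p_switch
  set.seed(seed)
  ntip <- ape::Ntip(host_tree)
  nn <- ntip + host_tree$Nnode
  age <- node_ages(host_tree)
  parent <- integer(nn); parent[] <- NA_integer_
  parent[host_tree$edge[, 2]] <- host_tree$edge[, 1]
  root <- ntip + 1L
  alive <- rep(TRUE, nn) # nodes still present (internal nodes can be suppressed)
  next_id <- nn
  # grow arrays as new graft nodes appear
  grow <- function() {
    parent <<- c(parent, NA_integer_)
    age <<- c(age, NA_real_)
    alive <<- c(alive, TRUE)
    next_id <<- next_id + 1L
    next_id
  }
  children_of <- function(v) which(alive & !is.na(parent) & parent == v)
  n_switches <- 0L
  # host cladogenesis events, oldest first (root's split excluded: a switch
  # there regrafts onto the only other root lineage, a no-op)
  events <- order(age[(ntip + 1L):nn], decreasing = TRUE) + ntip
  events <- setdiff(events, root)
  for (v in events) {
    if (runif(1) >= p_switch) next
    if (!alive[v]) next # can happen only via bookkeeping errors; guard
    kids <- children_of(v)
    if (length(kids) != 2) next
    d <- kids[sample.int(2, 1)]
    t <- age[v]
    # contemporary lineages: edges (p -> c) with age[c] < t <= age[p], c != d
    cand <- which(alive & !is.na(parent) & age < t &
                    age[pmax(parent, 1L)] >= t & seq_along(alive) != d)
    cand <- cand[alive[parent[cand]]]
    # exclude lineages inside d's own subtree (they are strictly younger
    # than t on the path, so only d itself could qualify; already excluded)
    if (length(cand) == 0) next
    target <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    if (parent[target] == v) next # regrafting onto the sister: no-op
    # prune: suppress v
    s <- setdiff(kids, d)
    parent[s] <- parent[v]
    alive[v] <- FALSE
    # graft: new node u at age t on edge above target
    u <- grow()
    age[u] <- t
    parent[u] <- parent[target]
    parent[target] <- u
    parent[d] <- u
    n_switches <- n_switches + 1L
  }
  # rebuild a phylo from the parent table
  tip_ids <- seq_len(ntip)
  labels <- paste0("f.", host_tree$tip.label)
  newick_of <- function(v) {
    kids <- children_of(v)
    if (length(kids) == 0) {
      return(sprintf("%s:%.10g", labels[v], (age[parent[v]] - age[v]) *
                       config$parasite_scaler))
    }
    inner <- paste(vapply(kids, newick_of, character(1)), collapse = ",")
    len <- if (is.na(parent[v]) || !alive[parent[v]]) 0 else
      (age[parent[v]] - age[v]) * config$parasite_scaler
    sprintf("(%s):%.10g", inner, len)
  }
  root_now <- which(alive & is.na(parent))
  ptree <- parse_newick(paste0(newick_of(root_now), ";"))
  A <- diag(ntip)
  rownames(A) <- paste0("f.", host_tree$tip.label)
  colnames(A) <- host_tree$tip.label
  list(tree = ptree, assoc = assoc_matrix(A), n_switches = n_switches)
}

# analytic transition matrix and expected p-distance for JC69/HKY85
# (normalized to one expected substitution per site per unit length)
model_pmatrix <- function(model, t, kappa = 2, bf = rep(0.25, 4)) {
  piR <- bf[1] + bf[3]; piY <- bf[2] + bf[4]
  if (model == "JC69") { kappa <- 1; bf <- rep(0.25, 4); piR <- piY <- 0.5 }
  beta <- 1 / (2 * (bf[1] * bf[2] + bf[1] * bf[4] + bf[2] * bf[3] +
                      bf[3] * bf[4]) + 2 * kappa * (bf[1] * bf[3] + bf[2] * bf[4]))
  P <- matrix(0, 4, 4)
  grp <- c(piR, piY, piR, piY) # A C G T
  e2 <- exp(-beta * t)
  for (i in 1:4) for (j in 1:4) {
    Aj <- 1 + grp[j] * (kappa - 1)
    e3 <- exp(-beta * t * Aj)
    same_grp <- (i %% 2) == (j %% 2) # A,G odd; C,T even
    P[i, j] <- if (i == j) {
      bf[j] + bf[j] * (1 / grp[j] - 1) * e2 + ((grp[j] - bf[j]) / grp[j]) * e3
    } else if (same_grp) {
      bf[j] + bf[j] * (1 / grp[j] - 1) * e2 - (bf[j] / grp[j]) * e3
    } else {
      bf[j] * (1 - e2)
    }
  }
  P
}

# expected uncorrected p-distance after t substitutions/site; vectorized
# over t: 1 - sum_j pi_j P_jj(t) with the closed-form diagonal entries
expected_pdist <- function(model, t, kappa = 2, bf = rep(0.25, 4)) {
  if (model == "JC69") { kappa <- 1; bf <- rep(0.25, 4) }
  piR <- bf[1] + bf[3]; piY <- bf[2] + bf[4]
  beta <- 1 / (2 * (bf[1] * bf[2] + bf[1] * bf[4] + bf[2] * bf[3] +
                      bf[3] * bf[4]) + 2 * kappa * (bf[1] * bf[3] + bf[2] * bf[4]))
  grp <- c(piR, piY, piR, piY)
  e2 <- exp(-beta * t)
  acc <- 0
  for (j in 1:4) {
    e3 <- exp(-beta * t * (1 + grp[j] * (kappa - 1)))
    acc <- acc + bf[j] * (bf[j] + bf[j] * (1 / grp[j] - 1) * e2 +
                            ((grp[j] - bf[j]) / grp[j]) * e3)
  }
  1 - acc
}

#' Simulate multi-locus sequences along a tree
#'
#' i.i.d. sites per locus evolve by the configured substitution process
#' (root state from the stationary frequencies) via [phangorn::simSeq()].
#' The global rate scaler is calibrated so the realized mean pairwise
#' uncorrected distance is within 10% of `target`: the scaler solving the
#' closed-form expectation given the patristic distances is found by
#' bisection, the realized distance is then measured, and a multiplicative
#' correction is applied if it falls outside the band.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param config A `"sim_config"`.
#' @param seed Integer seed.
#' @param rate Fixed rate scaler; skips calibration when supplied (used for
#'   parasite sequences, which must evolve at the host-calibrated rate on
#'   the already-scaled parasite tree).
#' @param target Calibration target (default `config$target_divergence`).
#' @return A `"multilocus"` alignment with attribute `rate_scaler`.
#' @export
simulate_sequences <- function(tree, config, seed = 1L, rate = NULL,
                               target = config$target_divergence) {
  stopifnot(inherits(config, "sim_config"))
  validate_tree(tree)
  model <- config$model
  if (!model %in% c("JC69", "HKY85")) stop("unknown substitution model: ", model)
  bf <- config$base_freq
  pat <- ape::cophenetic.phylo(tree)
  dvec <- pat[upper.tri(pat)]
  wts <- config$locus_length / sum(config$locus_length)
  mean_expected <- function(mu) {
    el <- vapply(config$locus_rates, function(r) {
      mean(expected_pdist(model, mu * r * dvec, config$kappa, bf))
    }, numeric(1))
    sum(wts * el)
  }
  sim_once <- function(mu, sd) {
    set.seed(sd)
    Q <- if (model == "JC69") rep(1, 6) else c(1, config$kappa, 1, 1, config$kappa, 1)
    loci <- setNames(vector("list", config$n_loci),
                     sprintf("locus%02d", seq_len(config$n_loci)))
    for (l in seq_len(config$n_loci)) {
      pd <- phangorn::simSeq(tree, l = config$locus_length[l],
                             Q = Q, bf = bf,
                             rate = mu * config$locus_rates[l])
      m <- toupper(as.character(pd))
      rownames(m) <- names(pd)
      loci[[l]] <- m
    }
    multilocus(loci)
  }
  if (is.null(rate)) {
    if (max(dvec) == 0) stop("cannot calibrate: all patristic distances are zero")
    f <- function(mu) mean_expected(mu) - target
    upper <- 1
    while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
    mu <- uniroot(f, c(1e-9, upper), tol = 1e-9)$root
    aln <- sim_once(mu, seed)
    for (tries in 1:5) {
      realized <- mean_pairwise_distance(aln)
      if (abs(realized - target) <= 0.1 * target) break
      mu <- mu * target / realized
      aln <- sim_once(mu, seed)
    }
  } else {
    mu <- rate
    aln <- sim_once(mu, seed)
  }
  attr(aln, "rate_scaler") <- mu
  aln
}

#' Mean pairwise uncorrected distance of an alignment
#' @param aln A `"multilocus"` alignment.
#' @return A single number.
#' @export
mean_pairwise_distance <- function(aln) {
  d <- genetic_distance(aln)
  mean(d[upper.tri(d)])
}

#' Apply per-sample-locus dropout
#'
#' Each sample-locus pair is masked independently with probability
#' `config$dropout`; every sample always retains at least one locus
#' (mirroring the retention of partial market samples).
#'
#' @param aln A `"multilocus"` alignment.
#' @param config A `"sim_config"`.
#' @param seed Integer seed.
#' @return A `"multilocus"` with rows removed from dropped loci.
#' @export
apply_locus_dropout <- function(aln, config, seed = 1L) {
  stopifnot(inherits(aln, "multilocus"), inherits(config, "sim_config"))
  p <- config$dropout
  if (p == 0) return(aln)
  set.seed(seed)
  samples <- aln$samples
  L <- length(aln$loci)
  drop <- matrix(runif(length(samples) * L) < p, nrow = length(samples),
                 dimnames = list(samples, names(aln$loci)))
  # floor rule: keep at least one locus per sample
  all_dropped <- rowSums(!drop) == 0
  for (s in which(all_dropped)) {
    keep <- sample.int(L, 1)
    drop[s, keep] <- FALSE
  }
  loci <- aln$loci
  for (l in names(loci)) {
    gone <- samples[drop[, l]]
    keep_rows <- setdiff(rownames(loci[[l]]), gone)
    loci[[l]] <- loci[[l]][keep_rows, , drop = FALSE]
  }
  if (any(vapply(loci, nrow, 1L) == 0)) {
    # a locus lost entirely (possible only at extreme dropout); restore one
    for (l in names(loci)[vapply(loci, nrow, 1L) == 0]) {
      s <- sample(samples, 1)
      loci[[l]] <- aln$loci[[l]][s, , drop = FALSE]
    }
  }
  multilocus(loci)
}

#' Simulate a complete synthetic study bundle
#'
#' Host tree, geography, parasite system, calibrated host sequences,
#' parasite sequences (single ITS-like locus at the host-calibrated rate on
#' the scaled parasite tree), and locus dropout — every stage seeded from
#' `seed` by [stage_seed()].
#'
#' @param config A `"sim_config"`.
#' @param seed Integer global seed.
#' @param dropout Apply locus dropout to the host alignment.
#' @return A list: `tree` (time units), `tree_subs` (branch lengths in
#'   substitutions/site, for placement), `samples`, `parasite` (`$tree`,
#'   `$assoc`), `host_aln`, `parasite_aln`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L, dropout = TRUE) {
  tree <- simulate_host_tree(config, stage_seed(seed, "host_tree"))
  samples <- simulate_geography(tree, config, stage_seed(seed, "geography"))
  para <- simulate_parasite_system(tree, config, stage_seed(seed, "parasite"))
  host_aln <- simulate_sequences(tree, config, stage_seed(seed, "host_seq"))
  pcfg <- config
  pcfg$n_loci <- 1L
  pcfg$locus_length <- 600L
  pcfg$locus_rates <- 1
  parasite_aln <- simulate_sequences(para$tree, pcfg,
                                     stage_seed(seed, "parasite_seq"),
                                     rate = attr(host_aln, "rate_scaler"))
  # host tree in expected-substitutions-per-site units (the molecular-tree
  # analogue of the time tree): time x calibrated rate x mean locus rate
  rate <- attr(host_aln, "rate_scaler")
  mu <- rate * sum(config$locus_rates * config$locus_length) /
    sum(config$locus_length)
  tree_subs <- tree
  tree_subs$edge.length <- tree$edge.length * mu
  if (dropout) {
    host_aln <- apply_locus_dropout(host_aln, config, stage_seed(seed, "dropout"))
    attr(host_aln, "rate_scaler") <- rate
  }
  list(tree = tree, tree_subs = tree_subs, samples = samples,
       parasite = para, host_aln = host_aln, parasite_aln = parasite_aln,
       config = config, seed = seed)
}
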