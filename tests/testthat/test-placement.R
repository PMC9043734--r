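placement_fixture <- function() {
  d <- small_bundle()
  tip <- "s003"
  pruned <- ape::drop.tip(d$tree_subs, tip)
  qry <- lapply(d$host_aln$loci, function(m) m[tip, ])
  list(d = d, tip = tip, pruned = pruned, qry = qry)
}

test_that("per-edge log-likelihoods equal graft-and-score recomputation", {
  fx <- placement_fixture()
  mod <- substitution_model("HKY85", c(0.3, 0.2, 0.25, 0.25), kappa = 2.5)
  pl <- place_query(fx$pruned, fx$d$host_aln, fx$qry, query_id = "q",
                    model = mod)
  m <- concat_loci(fx$d$host_aln, samples = fx$pruned$tip.label)
  qm <- matrix(unlist(fx$qry), nrow = 1, dimnames = list("q", NULL))
  for (e in seq_len(nrow(fx$pruned$edge))) {
    g <- graft_mid(fx$pruned, e, pl$edges$pendant[e])
    expect_lt(abs(pl$edges$loglik[e] - tree_loglik(g, rbind(m, qm), mod)),
              1e-8)
  }
  expect_equal(sum(pl$edges$lwr), 1, tolerance = 1e-9)
  expect_equal(which.max(pl$edges$loglik), pl$best_edge)
})

test_that("self-placement recovers the pruned tip's edge with high confidence", {
  fx <- placement_fixture()
  pl <- place_query(fx$pruned, fx$d$host_aln, fx$qry, query_id = "q")
  ok <- yartsa:::correct_edge_set(fx$d$tree_subs, fx$pruned, fx$tip)
  expect_true(pl$best_edge %in% ok)
  expect_gte(sum(pl$edges$lwr[ok]), 0.99)
})

test_that("an all-missing query yields uniform likelihood weight ratios", {
  fx <- placement_fixture()
  blank <- lapply(fx$qry, function(s) rep("N", length(s)))
  pl <- place_query(fx$pruned, fx$d$host_aln, blank, query_id = "q")
  expect_equal(pl$edges$lwr, rep(1 / nrow(fx$pruned$edge),
                                 nrow(fx$pruned$edge)), tolerance = 1e-9)
  # tie-break: among equal likelihoods the root-nearest edge is chosen
  depth <- node_depths(fx$pruned)
  expect_equal(depth[fx$pruned$edge[pl$best_edge, 1]],
               min(depth[fx$pruned$edge[, 1]]), tolerance = 1e-12)
})

test_that("query validation errors are typed", {
  fx <- placement_fixture()
  expect_error(place_query(fx$pruned, fx$d$host_aln, fx$qry,
                           query_id = "s005"), "collides")
  nolocus <- list(zzz = strrep("A", 10))
  expect_error(place_query(fx$pruned, fx$d$host_aln, nolocus), "no locus")
  short <- list(locus01 = "ACGT")
  expect_error(place_query(fx$pruned, fx$d$host_aln, short), "length")
})

test_that("loci subsets drop the missing loci for all taxa", {
  fx <- placement_fixture()
  two <- fx$qry[c("locus01", "locus03")]
  pl <- place_query(fx$pruned, fx$d$host_aln, two, query_id = "q")
  expect_setequal(pl$loci, c("locus01", "locus03"))
  expect_equal(pl$n_sites, sum(vapply(fx$d$host_aln$loci[pl$loci], ncol, 1L)))
})

test_that("leave-one-out sensitivity is perfect with all loci on well-separated tips", {
  # balanced 8-tip tree, every branch 0.04 subs/site: all tips >= 8%
  # apart, so midpoint attachment cannot confuse neighbouring edges
  tr <- parse_newick(paste0(
    "(((A:0.04,B:0.04):0.04,(C:0.04,D:0.04):0.04):0.04,",
    "((E:0.04,F:0.04):0.04,(G:0.04,H:0.04):0.04):0.04);"))
  cfg <- sim_config(n_loci = 3, locus_length = 400)
  aln <- simulate_sequences(tr, cfg, seed = 71, rate = 1)
  sens <- loci_sensitivity(tr, aln, loci_counts = 3, reps_per_count = 8,
                           seed = 3)
  expect_equal(sens$frac_correct, 1)
  expect_gte(sens$mean_confidence, 0.95)
  expect_error(loci_sensitivity(tr, aln, loci_counts = 9), "exceeds")
})

test_that("jplace export carries every edge with consistent weights", {
  fx <- placement_fixture()
  pl <- place_query(fx$pruned, fx$d$host_aln, fx$qry, query_id = "q")
  p <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(pl, fx$pruned, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$version, 3)
  expect_equal(unlist(j$fields),
               c("edge_num", "likelihood", "like_weight_ratio",
                 "pendant_length"))
  recs <- j$placements[[1]]$p
  expect_length(recs, nrow(fx$pruned$edge))
  lwrs <- vapply(recs, function(r) r[[3]], numeric(1))
  expect_equal(sum(lwrs), 1, tolerance = 1e-9)
  # every edge number appears exactly once in the tagged tree
  ntags <- lengths(regmatches(j$tree, gregexpr("\\{[0-9]+\\}", j$tree)))
  expect_equal(ntags, nrow(fx$pruned$edge))
})

test_that("origin assignment: nested, sister, outgroup and outcome classes", {
  # 8-tip ultrametric tree; clade {D,E,F} labelled Himalaya
  tr <- parse_newick(paste0("(((A:1,B:1):1,C:2):2,((D:1,E:1):1,F:2):2,",
                            "(G:1,H:1):3);"))
  tr <- label_clade(tr, c("D", "E", "F"), "Himalaya")
  edges <- data.frame(edge = seq_len(nrow(tr$edge)),
                      parent = tr$edge[, 1], child = tr$edge[, 2])
  mkplace <- function(best_child, lwr = 0.95) {
    e <- which(tr$edge[, 2] == best_child)
    lwrs <- rep((1 - lwr) / (nrow(edges) - 1), nrow(edges))
    lwrs[e] <- lwr
    structure(list(query = "q", loci = "locus01",
                   edges = transform(edges, loglik = -100 + lwrs,
                                     pendant = 0.01, lwr = lwrs),
                   best_edge = e, n_sites = 100, model = "JC69"),
              class = "placement_result")
  }
  ntip <- ape::Ntip(tr)
  him <- ape::getMRCA(tr, c("D", "E", "F"))

  nested <- assign_origin(tr, mkplace(match("E", tr$tip.label)))
  expect_equal(nested$assigned, "Himalaya")
  expect_equal(nested$relation, "nested")

  sister <- assign_origin(tr, mkplace(him))
  expect_equal(sister$assigned, "Himalaya")
  expect_equal(sister$relation, "sister")

  out <- assign_origin(tr, mkplace(match("G", tr$tip.label)))
  expect_equal(out$assigned, "unassigned")
  expect_equal(out$relation, "none")

  # outcome classes against known truth
  expect_equal(assign_origin(tr, mkplace(match("E", tr$tip.label)),
                             truth = "Himalaya")$outcome, "true positive")
  expect_equal(assign_origin(tr, mkplace(match("E", tr$tip.label)),
                             truth = "QTP")$outcome, "false positive")
  expect_equal(assign_origin(tr, mkplace(match("G", tr$tip.label)),
                             truth = "Himalaya")$outcome, "false negative")
  expect_equal(assign_origin(tr, mkplace(match("G", tr$tip.label)),
                             truth = "QTP")$outcome, "true negative")

  # a weak best edge leaves the query unassigned
  weak <- assign_origin(tr, mkplace(match("E", tr$tip.label), lwr = 0.3))
  expect_equal(weak$assigned, "unassigned")

  # conflicting overlapping labels raise an ambiguity error
  tr2 <- label_clade(tr, c("D", "E"), "Transition")
  expect_error(assign_origin(tr2, mkplace(match("E", tr$tip.label))),
               "ambiguous")
})
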