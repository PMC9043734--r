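# Evolutionary placement: exhaustive per-edge maximum-likelihood placement
# of a query on a fixed reference tree, the loci-count sensitivity
# experiment, and the monophyly/sister origin-assignment rule.

#' Place a query sample on every edge of a reference tree
#'
#' The query is attached at the midpoint of each edge in turn by a pendant
#' branch whose length is optimized by golden-section search; the
#' likelihood weight ratio (LWR) of an edge is its likelihood relative to
#' the sum over all edges.  Only loci shared between query and reference
#' enter the concatenation (the query's missing loci are excluded for all
#' taxa, so log-likelihoods are comparable across edges).
#'
#' @param ref_tree Reference `"phylo"` with fixed branch lengths.
#' @param ref_aln Reference `"multilocus"` alignment.
#' @param query Named list or character vector: per-locus query sequence
#'   strings (or character vectors), names = locus names; loci absent from
#'   the query are dropped.
#' @param query_id Label for the query (must not collide with a reference
#'   tip).
#' @param model A `"subst_model"`.
#' @param pendant_bounds Search interval for the pendant length
#'   (substitutions/site).
#' @param tol Golden-section tolerance.
#' @return A list of class `"placement_result"`: `query`, `loci`,
#'   `edges` (data.frame edge/parent/child/loglik/pendant/lwr), `best_edge`
#'   (row index into `ref_tree$edge`), `n_sites`.
#' @export
place_query <- function(ref_tree, ref_aln, query, query_id = "query",
                        model = substitution_model("JC69"),
                        pendant_bounds = c(1e-8, 2), tol = 1e-6) {
  validate_tree(ref_tree)
  stopifnot(inherits(ref_aln, "multilocus"))
  if (query_id %in% ref_tree$tip.label) {
    stop("query label collides with a reference tip: ", query_id)
  }
  if (is.null(names(query))) stop("query must be a named per-locus list")
  shared <- intersect(names(ref_aln$loci), names(query))
  if (length(shared) == 0) stop("query shares no locus with the reference")
  qseq <- unlist(lapply(shared, function(l) {
    s <- query[[l]]
    s <- if (length(s) == 1) strsplit(toupper(s), "")[[1]] else toupper(s)
    if (length(s) != ncol(ref_aln$loci[[l]])) {
      stop(sprintf("query locus '%s' length %d does not match reference %d",
                   l, length(s), ncol(ref_aln$loci[[l]])))
    }
    s
  }))
  refm <- align_to_tree(ref_tree, concat_loci(ref_aln, loci = shared,
                                              samples = ref_tree$tip.label))
  codes <- rbind(encode_dna(refm), encode_dna(matrix(qseq, nrow = 1)))
  res <- cpp_place_query(ref_tree$edge, ref_tree$edge.length,
                         ape::Ntip(ref_tree), codes, model$kappa,
                         model$base_freq, pendant_bounds[1],
                         pendant_bounds[2], tol)
  lnl <- res$loglik
  lwr <- exp(lnl - max(lnl))
  lwr <- lwr / sum(lwr)
  best <- best_edge_rule(ref_tree, lnl)
  edges <- data.frame(edge = seq_along(lnl),
                      parent = ref_tree$edge[, 1], child = ref_tree$edge[, 2],
                      loglik = lnl, pendant = res$pendant, lwr = lwr)
  structure(list(query = query_id, loci = shared, edges = edges,
                 best_edge = best, n_sites = length(qseq),
                 model = model$name),
            class = "placement_result")
}

# maximal-likelihood edge; ties broken toward the root, then by the
# lexicographically smallest descendant tip label
best_edge_rule <- function(tree, lnl, tol = 1e-9) {
  cand <- which(lnl >= max(lnl) - tol)
  if (length(cand) == 1) return(cand)
  depth <- node_depths(tree)
  d <- depth[tree$edge[cand, 1]]
  cand <- cand[d == min(d)]
  if (length(cand) == 1) return(cand)
  desc <- descendant_tips(tree)
  labs <- vapply(cand, function(e) min(tree$tip.label[desc[[tree$edge[e, 2]]]]),
                 character(1))
  cand[order(labs)][1]
}

#' @export
print.placement_result <- function(x, ...) {
  b <- x$edges[x$best_edge, ]
  cat(sprintf("placement of '%s' (%d loci, %d sites, %s)\n",
              x$query, length(x$loci), x$n_sites, x$model))
  cat(sprintf("best edge %d (-> node %d): lnL = %.3f, LWR = %.3f, pendant = %.4g\n",
              b$edge, b$child, b$loglik, b$lwr, b$pendant))
  invisible(x)
}

#' Write placements to a jplace-compatible JSON file
#'
#' The reference tree is serialized with edge numbers in braces after each
#' branch length (`{n}`, matching the row of `ref_tree$edge`), and each
#' placement carries `edge_num`, `likelihood`, `like_weight_ratio` and
#' `pendant_length`.
#'
#' @param placements A `"placement_result"` or list of them.
#' @param ref_tree The reference tree the placements were computed on.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jplace <- function(placements, ref_tree, path) {
  if (inherits(placements, "placement_result")) placements <- list(placements)
  # newick with {edge} tags: rewrite by appending to each branch length
  tag <- function(node) {
    kids <- which(ref_tree$edge[, 1] == node)
    inner <- if (length(kids) == 0) {
      ref_tree$tip.label[node]
    } else {
      paste0("(", paste(vapply(ref_tree$edge[kids, 2], tag, character(1)),
                        collapse = ","), ")")
    }
    e <- which(ref_tree$edge[, 2] == node)
    if (length(e) == 1) {
      sprintf("%s:%.10g{%d}", inner, ref_tree$edge.length[e], e)
    } else inner
  }
  root <- ape::Ntip(ref_tree) + 1L
  tree_str <- paste0(tag(root), ";")
  pl <- lapply(placements, function(p) {
    list(p = lapply(seq_len(nrow(p$edges)), function(i) {
      r <- p$edges[i, ]
      list(r$edge, r$loglik, r$lwr, r$pendant)
    }),
    n = list(p$query))
  })
  obj <- list(tree = tree_str, placements = pl,
              fields = list("edge_num", "likelihood", "like_weight_ratio",
                            "pendant_length"),
              version = 3,
              metadata = list(software = "yartsa"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- leave-one-out sensitivity ------------------------------------------

# edges of the pruned tree that correspond to the original attachment
# neighbourhood of tip `tip`: the merged parent-sibling edge plus, when the
# sibling is an internal node, its two child edges.
correct_edge_set <- function(ref_tree, pruned, tip) {
  ntip <- ape::Ntip(ref_tree)
  tipn <- match(tip, ref_tree$tip.label)
  v <- ref_tree$edge[ref_tree$edge[, 2] == tipn, 1]
  kids <- ref_tree$edge[ref_tree$edge[, 1] == v, 2]
  sib <- setdiff(kids, tipn)
  desc <- descendant_tips(ref_tree)
  sib_tips <- sort(unlist(lapply(sib, function(nd) ref_tree$tip.label[desc[[nd]]])))
  pdesc <- descendant_tips(pruned)
  key <- vapply(seq_len(nrow(pruned$edge)), function(e) {
    paste(sort(pruned$tip.label[pdesc[[pruned$edge[e, 2]]]]), collapse = "\r")
  }, character(1))
  sib_key <- paste(sib_tips, collapse = "\r")
  merged <- which(key == sib_key)
  out <- merged
  if (length(merged) == 1) {
    sibnode <- pruned$edge[merged, 2]
    out <- c(out, which(pruned$edge[, 1] == sibnode))
  } else {
    # tip attached at the root: the sibling clade is the whole pruned tree;
    # its two root edges are the correct neighbourhood
    rootn <- ape::Ntip(pruned) + 1L
    out <- which(pruned$edge[, 1] == rootn)
  }
  out
}

#' Loci-count sensitivity of placement confidence
#'
#' Leave-one-out protocol: per replicate a reference tip is pruned and
#' re-placed using a uniformly drawn subset of k loci.  Correct-placement
#' confidence is the LWR mass on the edges of the pruned tree that
#' correspond to the original attachment (the merged parent-sibling edge
#' plus the sibling's two child edges); a replicate's best edge is correct
#' when it falls in that set.
#'
#' @param ref_tree Reference tree (>= 10 tips recommended).
#' @param ref_aln Reference `"multilocus"` alignment.
#' @param loci_counts Values of k to test (default 1..L).
#' @param reps_per_count Replicates per k.
#' @param model A `"subst_model"`.
#' @param seed Integer seed (replicates are deterministic given it).
#' @return A data.frame of class `"loci_sensitivity"`: columns `k`,
#'   `mean_confidence`, `frac_correct`, `n_reps`.
#' @export
loci_sensitivity <- function(ref_tree, ref_aln,
                             loci_counts = seq_along(ref_aln$loci),
                             reps_per_count = 100,
                             model = substitution_model("JC69"), seed = 1L) {
  validate_tree(ref_tree)
  L <- length(ref_aln$loci)
  if (any(loci_counts > L)) stop("k exceeds the number of available loci")
  if (ape::Ntip(ref_tree) < 4) stop("reference tree too small")
  set.seed(seed)
  # one replicate schedule shared across k so curves differ only in k
  tips <- sample(ref_tree$tip.label, reps_per_count, replace = TRUE)
  rows <- lapply(loci_counts, function(k) {
    conf <- numeric(reps_per_count)
    corr <- logical(reps_per_count)
    for (r in seq_len(reps_per_count)) {
      set.seed(stage_seed(seed, sprintf("k%dr%d", k, r)))
      tip <- tips[r]
      loci_r <- sample(names(ref_aln$loci), k)
      pruned <- ape::drop.tip(ref_tree, tip)
      qry <- lapply(loci_r, function(l) {
        m <- ref_aln$loci[[l]]
        if (tip %in% rownames(m)) m[tip, ] else rep("N", ncol(m))
      })
      names(qry) <- loci_r
      pl <- place_query(pruned, ref_aln, qry, query_id = paste0(tip, ".q"),
                        model = model)
      ok <- correct_edge_set(ref_tree, pruned, tip)
      conf[r] <- sum(pl$edges$lwr[ok])
      corr[r] <- pl$best_edge %in% ok
    }
    data.frame(k = k, mean_confidence = mean(conf),
               frac_correct = mean(corr), n_reps = reps_per_count)
  })
  structure(do.call(rbind, rows), class = c("loci_sensitivity", "data.frame"))
}

# ---- origin assignment ---------------------------------------------------

#' Assign a geographic origin from a placement and labelled clades
#'
#' A query is assigned label L when its best placement edge is nested
#' strictly inside a clade labelled L, or lies on that clade's root edge
#' (grafting there makes the query sister to the clade).  A best-edge LWR
#' below `lwr_floor` leaves the query unassigned.  With a known truth
#' label the outcome class is computed: assignment to the true label is a
#' true positive, to any other label a false positive; an unassigned query
#' whose truth is one of the tree's clade labels is a false negative,
#' otherwise a true negative.
#'
#' @param ref_tree Reference tree whose internal node labels carry clade
#'   labels (see [label_clade()]).
#' @param placement A `"placement_result"` computed on `ref_tree`.
#' @param lwr_floor Minimum best-edge LWR for assignment (default 0.5).
#' @param truth Optional true origin label of the query.
#' @return A list of class `"assignment_report"`: `query`, `assigned`
#'   (label or `"unassigned"`), `relation` (`"nested"`, `"sister"`,
#'   `"none"`), `lwr_in_clade`, `best_lwr`, `truth`, `outcome`.
#' @export
assign_origin <- function(ref_tree, placement, lwr_floor = 0.5, truth = NULL) {
  validate_tree(ref_tree)
  stopifnot(inherits(placement, "placement_result"))
  ntip <- ape::Ntip(ref_tree)
  labs <- ref_tree$node.label
  if (is.null(labs) || all(labs == "" | is.na(labs))) {
    stop("reference tree has no labelled clades")
  }
  clade_nodes <- which(!is.na(labs) & labs != "") + ntip
  clade_labels <- labs[clade_nodes - ntip]
  best <- placement$best_edge
  best_lwr <- placement$edges$lwr[best]
  bu <- ref_tree$edge[best, 1]; bv <- ref_tree$edge[best, 2]
  desc <- descendant_tips(ref_tree)
  # membership helper: node inside clade rooted at m (m itself included)
  inside <- function(node, m) {
    if (node == m) return(TRUE)
    if (node <= ntip) return(node %in% desc[[m]])
    all(desc[[node]] %in% desc[[m]])
  }
  nested_in <- clade_labels[vapply(clade_nodes, function(m)
    inside(bu, m) && inside(bv, m), logical(1))]
  sister_to <- clade_labels[vapply(clade_nodes, function(m) bv == m, logical(1))]
  assigned <- "unassigned"; relation <- "none"; lwr_in <- 0
  if (best_lwr >= lwr_floor) {
    if (length(unique(nested_in)) > 1) {
      stop("ambiguous assignment: best edge lies in clades labelled ",
           paste(unique(nested_in), collapse = ", "))
    }
    if (length(nested_in) >= 1) {
      assigned <- nested_in[1]; relation <- "nested"
    } else if (length(sister_to) >= 1) {
      if (length(unique(sister_to)) > 1) {
        stop("ambiguous assignment: best edge is the root edge of clades ",
             paste(unique(sister_to), collapse = ", "))
      }
      assigned <- sister_to[1]; relation <- "sister"
    }
  }
  if (relation != "none") {
    m <- clade_nodes[match(assigned, clade_labels)]
    in_clade <- vapply(seq_len(nrow(ref_tree$edge)), function(e) {
      inside(ref_tree$edge[e, 1], m) && inside(ref_tree$edge[e, 2], m) ||
        ref_tree$edge[e, 2] == m
    }, logical(1))
    lwr_in <- sum(placement$edges$lwr[in_clade])
  }
  outcome <- NA_character_
  if (!is.null(truth)) {
    outcome <- if (assigned != "unassigned") {
      if (identical(assigned, truth)) "true positive" else "false positive"
    } else {
      if (truth %in% clade_labels) "false negative" else "true negative"
    }
  }
  structure(list(query = placement$query, assigned = assigned,
                 relation = relation, lwr_in_clade = lwr_in,
                 best_lwr = best_lwr, truth = truth, outcome = outcome),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("query '%s': %s (%s, best-edge LWR %.3f)%s\n", x$query,
              x$assigned, x$relation, x$best_lwr,
              if (!is.na(x$outcome %||% NA)) paste0(" [", x$outcome, "]") else ""))
  invisible(x)
}
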