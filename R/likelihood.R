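# Substitution models and the tree likelihood interface to the compiled
# pruning engine.

#' Define a nucleotide substitution model
#'
#' @param name `"JC69"` or `"HKY85"`.
#' @param base_freq Equilibrium frequencies (A, C, G, T); must be positive
#'   and sum to 1 (ignored for JC69, which fixes them at 1/4).
#' @param kappa Transition/transversion rate ratio (HKY85 only; > 0).
#' @return A list of class `"subst_model"`.
#' @export
substitution_model <- function(name = c("JC69", "HKY85"),
                               base_freq = c(0.25, 0.25, 0.25, 0.25),
                               kappa = 2) {
  name <- match.arg(name)
  if (name == "JC69") {
    base_freq <- rep(0.25, 4)
    kappa <- 1
  }
  if (length(base_freq) != 4 || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-12) {
    stop("base frequencies must be positive and sum to 1")
  }
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(name = name, base_freq = base_freq, kappa = kappa),
            class = "subst_model")
}

# alignment matrix with rows reordered to tree tips; errors on missing tips
align_to_tree <- function(tree, m) {
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss) > 0) {
    stop("tip(s) without sequence: ", paste(miss, collapse = ", "))
  }
  m[tree$tip.label, , drop = FALSE]
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Missing characters (`-`, `N`) are uninformative; site patterns are
#' compressed; the model is time-reversible, so the value is invariant
#' under re-rooting.
#'
#' @param tree A `"phylo"` with branch lengths; every tip needs a row in
#'   the alignment.
#' @param alignment Character matrix (samples x sites) over `A,C,G,T,-,N`,
#'   or a `"multilocus"` object (concatenated over `loci`).
#' @param model A `"subst_model"`.
#' @param loci Locus subset when `alignment` is `"multilocus"`.
#' @return The log-likelihood (a single number).
#' @export
tree_loglik <- function(tree, alignment, model = substitution_model("JC69"),
                        loci = NULL) {
  validate_tree(tree)
  stopifnot(inherits(model, "subst_model"))
  if (inherits(alignment, "multilocus")) {
    alignment <- concat_loci(alignment, loci = loci %||% names(alignment$loci))
  }
  m <- align_to_tree(tree, alignment)
  cpp_tree_loglik(tree$edge, tree$edge.length, ape::Ntip(tree),
                  encode_dna(m), model$kappa, model$base_freq)
}
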