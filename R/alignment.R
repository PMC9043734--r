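# Multi-locus alignment container: a list of per-locus character matrices
# (rows = samples, columns = aligned sites) plus a sample x locus presence
# mask.  Gaps '-' and 'N' are treated as missing data throughout.

DNA_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a multi-locus alignment
#'
#' @param loci Named list; each element a character matrix (samples x sites)
#'   over the alphabet `A,C,G,T,-,N` with rownames = sample IDs.  A sample
#'   absent from a locus is simply not a row of that matrix.
#' @return An object of class `"multilocus"` with elements `loci` (the
#'   matrices), `samples` (union of sample IDs), `mask` (logical samples x
#'   loci presence matrix).
#' @export
multilocus <- function(loci) {
  stopifnot(is.list(loci), length(loci) >= 1)
  nm <- names(loci)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("loci must have unique non-empty names")
  }
  for (l in nm) {
    m <- loci[[l]]
    if (!is.matrix(m) || !is.character(m)) stop("locus ", l, " is not a character matrix")
    if (is.null(rownames(m))) stop("locus ", l, " has no sample IDs (rownames)")
    bad <- setdiff(unique(as.vector(m)), DNA_ALPHABET)
    if (length(bad) > 0) {
      stop("locus ", l, ": invalid character(s) ", paste(bad, collapse = " "))
    }
  }
  samples <- sort(unique(unlist(lapply(loci, rownames))))
  mask <- vapply(nm, function(l) samples %in% rownames(loci[[l]]), logical(length(samples)))
  mask <- matrix(mask, nrow = length(samples), dimnames = list(samples, nm))
  structure(list(loci = loci, samples = samples, mask = mask),
            class = "multilocus")
}

#' @export
print.multilocus <- function(x, ...) {
  cat(sprintf("multilocus alignment: %d samples, %d loci (%s sites total)\n",
              length(x$samples), length(x$loci),
              sum(vapply(x$loci, ncol, 1L))))
  cat(sprintf("mean loci per sample: %.2f\n", mean(rowSums(x$mask))))
  invisible(x)
}

#' Read one FASTA file per locus into a multi-locus alignment
#'
#' FASTA headers are sample IDs; all sequences within a file must have the
#' same (aligned) length.  Lowercase is normalized to uppercase; characters
#' outside `A,C,G,T,-,N` are rejected.
#'
#' @param paths Character vector of FASTA paths, one per locus.  Locus names
#'   are taken from `names(paths)` or from the file base names.
#' @return A `"multilocus"` object.
#' @export
read_multilocus_fasta <- function(paths) {
  stopifnot(length(paths) >= 1)
  nm <- names(paths)
  if (is.null(nm)) nm <- sub("\\.(fa|fasta|fas)$", "", basename(paths))
  loci <- setNames(vector("list", length(paths)), nm)
  for (i in seq_along(paths)) {
    # BStringSet keeps the raw characters, so invalid symbols are caught
    # here instead of being silently dropped
    seqs <- Biostrings::readBStringSet(paths[i])
    if (length(seqs) == 0) stop("empty FASTA file: ", paths[i])
    chr <- lapply(as.character(seqs), function(s) strsplit(toupper(s), "")[[1]])
    lens <- lengths(chr)
    if (length(unique(lens)) != 1) {
      bad <- names(chr)[which(lens != lens[1])[1]]
      stop(sprintf("ragged alignment in locus '%s': sample '%s' has length %d, expected %d",
                   nm[i], bad, lens[names(chr) == bad][1], lens[1]))
    }
    if (anyDuplicated(names(chr))) {
      stop("duplicate sample ID in locus ", nm[i])
    }
    m <- do.call(rbind, chr)
    m[m == "?"] <- "N"
    bad <- setdiff(unique(as.vector(m)), DNA_ALPHABET)
    if (length(bad) > 0) {
      stop(sprintf("locus '%s': invalid character(s) %s", nm[i],
                   paste(bad, collapse = " ")))
    }
    loci[[i]] <- m
  }
  multilocus(loci)
}

#' Write a multi-locus alignment as one FASTA per locus
#'
#' @param aln A `"multilocus"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths (named by locus).
#' @export
write_multilocus_fasta <- function(aln, dir) {
  stopifnot(inherits(aln, "multilocus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(names(aln$loci), ".fasta")), names(aln$loci))
  for (l in names(aln$loci)) {
    m <- aln$loci[[l]]
    con <- file(paths[l], "w")
    for (s in rownames(m)) {
      writeLines(c(paste0(">", s), paste(m[s, ], collapse = "")), con)
    }
    close(con)
  }
  invisible(paths)
}

#' Concatenate selected loci for a set of samples
#'
#' Samples missing a locus are padded with `N` across that locus, so the
#' result is a rectangular matrix; missing sites are ignored pairwise by the
#' distance and likelihood code.
#'
#' @param aln A `"multilocus"` object.
#' @param loci Locus names to use (default all).
#' @param samples Sample IDs to include (default all).
#' @param pad Fill character for absent sample-locus pairs.
#' @return Character matrix samples x sites.
#' @export
concat_loci <- function(aln, loci = names(aln$loci), samples = aln$samples,
                        pad = "N") {
  stopifnot(inherits(aln, "multilocus"))
  miss <- setdiff(loci, names(aln$loci))
  if (length(miss) > 0) stop("unknown locus: ", paste(miss, collapse = ", "))
  if (length(loci) == 0) stop("empty locus subset")
  blocks <- lapply(loci, function(l) {
    m <- aln$loci[[l]]
    out <- matrix(pad, nrow = length(samples), ncol = ncol(m),
                  dimnames = list(samples, NULL))
    keep <- intersect(samples, rownames(m))
    out[keep, ] <- m[keep, , drop = FALSE]
    out
  })
  do.call(cbind, blocks)
}

# encode A,C,G,T -> 0..3 and '-'/'N' -> 4L (missing)
encode_dna <- function(m) {
  codes <- matrix(4L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  codes[m == "A"] <- 0L
  codes[m == "C"] <- 1L
  codes[m == "G"] <- 2L
  codes[m == "T"] <- 3L
  codes
}
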