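# Labelled symmetric distance matrices and binary host-parasite association
# matrices: the common currency of the Mantel, ParaFit and PACo machinery.

#' Construct/validate a labelled distance matrix
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param kind One of `"genetic"`, `"geographic"`, `"climatic"`,
#'   `"resistance"`, `"patristic"`.
#' @param tol Symmetry tolerance.
#' @return The matrix with class `"dist_matrix"` and a `kind` attribute.
#' @export
dist_matrix <- function(m, kind = "genetic", tol = 1e-9) {
  kinds <- c("genetic", "geographic", "climatic", "resistance", "patristic")
  kind <- match.arg(kind, kinds)
  if (!is.matrix(m) || !is.numeric(m)) stop("not a numeric matrix")
  if (nrow(m) != ncol(m) || nrow(m) < 2) stop("matrix must be square, n >= 2")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("row and column labels must be present and identical")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate labels")
  if (any(!is.finite(m))) stop("non-finite entries")
  if (any(m < 0)) stop("negative entries")
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) stop("matrix not symmetric")
  if (any(abs(diag(m)) > tol)) stop("diagonal not zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("dist_matrix", "matrix"), kind = kind)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d labels\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

# subset rows/cols keeping class + kind
subset_dist <- function(m, labels) {
  miss <- setdiff(labels, rownames(m))
  if (length(miss) > 0) stop("unknown label(s): ", paste(miss, collapse = ", "))
  dist_matrix(unclass(m)[labels, labels, drop = FALSE], kind = attr(m, "kind"))
}

# off-diagonal upper-triangle vector
upper_vec <- function(m) m[upper.tri(m)]

#' Read / write a labelled distance matrix CSV (header row = labels)
#' @param path CSV path.
#' @param kind Matrix kind, see [dist_matrix()].
#' @return A `"dist_matrix"`.
#' @export
read_dist_csv <- function(path, kind = "genetic") {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(df), kind = kind)
}

#' @rdname read_dist_csv
#' @param m A `"dist_matrix"` to write.
#' @export
write_dist_csv <- function(m, path) {
  write.csv(as.data.frame(unclass(m)), path, quote = FALSE)
  invisible(path)
}

#' Construct/validate a binary host-parasite association matrix
#'
#' Rows are parasites, columns are hosts; entry 1 links a parasite to a
#' host.  Every row and every column must carry at least one link.
#'
#' @param m Binary matrix with parasite rownames and host colnames.
#' @return The matrix with class `"assoc_matrix"`.
#' @export
assoc_matrix <- function(m) {
  if (!is.matrix(m)) stop("not a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("association matrix needs parasite rownames and host colnames")
  }
  if (!all(m %in% c(0, 1))) stop("association entries must be 0/1")
  if (any(rowSums(m) == 0)) stop("parasite row(s) without any host link")
  if (any(colSums(m) == 0)) stop("host column(s) without any parasite link")
  structure(m, class = c("assoc_matrix", "matrix"))
}

#' Read / write an association CSV (rows = parasites, cols = hosts)
#' @param path CSV path.
#' @return An `"assoc_matrix"`.
#' @export
read_assoc_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  assoc_matrix(as.matrix(df))
}

#' @rdname read_assoc_csv
#' @param m An `"assoc_matrix"` to write.
#' @export
write_assoc_csv <- function(m, path) {
  write.csv(as.data.frame(unclass(m)), path, quote = FALSE)
  invisible(path)
}

#' Read a plain-text cost raster (ASCII grid)
#'
#' Header lines `ncols`, `nrows`, `xllcenter`, `yllcenter`, `cellsize`
#' followed by `nrows` rows of non-negative costs (top row first).  `Inf`
#' marks an impassable barrier cell.
#'
#' @param path Path to the grid file.
#' @return A list of class `"cost_raster"`: `costs` (nrows x ncols matrix,
#'   row 1 = northernmost), `cellsize` (degrees), `origin` (lat, lon of the
#'   lower-left cell center).
#' @export
read_cost_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcenter", "yllcenter", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0) stop("raster header missing: ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE, na.strings = character(0))
  if (length(vals) != hdr$ncols * hdr$nrows) stop("raster data size mismatch")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  cost_raster(m, cellsize = hdr$cellsize,
              origin = c(lat = hdr$yllcenter, lon = hdr$xllcenter))
}

#' Construct a cost raster from a matrix
#'
#' @param costs Matrix of non-negative costs (`Inf` = barrier); row 1 is the
#'   northernmost row.
#' @param cellsize Cell size in degrees.
#' @param origin Named vector `c(lat=, lon=)` of the lower-left cell center.
#' @return A `"cost_raster"` object.
#' @export
cost_raster <- function(costs, cellsize, origin) {
  if (!is.matrix(costs) || nrow(costs) < 2 || ncol(costs) < 2) {
    stop("raster must be at least 2x2")
  }
  if (any(is.na(costs)) || any(costs[is.finite(costs)] < 0)) {
    stop("raster costs must be non-negative (Inf allowed)")
  }
  stopifnot(cellsize > 0, all(c("lat", "lon") %in% names(origin)))
  structure(list(costs = costs, cellsize = cellsize, origin = origin),
            class = "cost_raster")
}

#' Write a cost raster to the plain-text grid format
#' @param raster A `"cost_raster"`.
#' @param path Output path.
#' @export
write_cost_raster <- function(raster, path) {
  con <- file(path, "w")
  writeLines(c(
    paste("ncols", ncol(raster$costs)),
    paste("nrows", nrow(raster$costs)),
    paste("xllcenter", raster$origin["lon"]),
    paste("yllcenter", raster$origin["lat"]),
    paste("cellsize", raster$cellsize)
  ), con)
  write.table(raster$costs, con, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
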