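# Sample metadata table: id, latitude, longitude, region, climate, year.
# Regions default to the four mountain blocks of the study system.

#' Construct and validate a sample table
#'
#' @param df A data.frame with columns `id`, `latitude`, `longitude`,
#'   `region`, `climate` (e.g. mean temperature of the coldest quarter, deg
#'   C), `year`.
#' @param regions Allowed region labels.
#' @return The validated data.frame, classed `"sample_table"`.
#' @export
sample_table <- function(df, regions = YARTSA_REGIONS) {
  req <- c("id", "latitude", "longitude", "region", "climate", "year")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate sample id(s)")
  for (col in c("latitude", "longitude", "climate")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v))) {
      stop("unparseable numeric value in column ", col)
    }
    df[[col]] <- v
  }
  if (any(is.na(df$latitude)) || any(df$latitude < -90 | df$latitude > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(is.na(df$longitude)) || any(df$longitude < -180 | df$longitude > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  bad <- setdiff(unique(df$region), regions)
  if (length(bad) > 0) {
    stop("unknown region value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(regions, collapse = ", "), ")")
  }
  df$year <- as.integer(df$year)
  rownames(df) <- df$id
  attr(df, "regions") <- regions
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample metadata CSV
#'
#' @param path CSV path with a header row naming at least `id`, `latitude`,
#'   `longitude`, `region`, `climate`, `year`.
#' @inheritParams sample_table
#' @return A `"sample_table"`.
#' @export
read_sample_table <- function(path, regions = YARTSA_REGIONS) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sample_table(df, regions = regions)
}

#' Write a sample table to CSV
#' @param samples A `"sample_table"`.
#' @param path Output CSV path.
#' @export
write_sample_table <- function(samples, path) {
  write.csv(as.data.frame(samples), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
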