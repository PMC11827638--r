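#' Write a movie stack as 16-bit multi-page TIFF with a JSON sidecar
#'
#' @param movie Integer array \code{[rows, cols, frames]} with values in
#'   0..65535.
#' @param path Output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @param imaging Optional \code{\link{imaging_spec}} recorded in the
#'   sidecar (pixel size, frame interval).
#' @return \code{path}, invisibly.
#' @export
write_movie_tiff <- function(movie, path, imaging = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  frames <- lapply(seq_len(dim(movie)[3]),
                   function(f) movie[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(n_frames = dim(movie)[3], height_px = dim(movie)[1],
               width_px = dim(movie)[2])
  if (!is.null(imaging)) {
    meta$pixel_size_nm <- imaging$pixel_size_nm
    meta$frame_interval_s <- imaging$frame_interval_s
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a movie stack written by \code{\link{write_movie_tiff}}
#'
#' @param path TIFF path.
#' @return Integer array \code{[rows, cols, frames]}; the sidecar metadata
#'   (if present) is attached as attribute \code{"meta"}.
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  movie <- array(0L, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                             length(frames)))
  for (f in seq_along(frames)) movie[, , f] <- as.integer(frames[[f]])
  sc <- paste0(path, ".json")
  if (file.exists(sc))
    attr(movie, "meta") <- jsonlite::read_json(sc, simplifyVector = TRUE)
  movie
}

.check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("malformed ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "))
  df[, cols, drop = FALSE]
}

.loc_cols <- c("frame", "x_nm", "y_nm", "photons", "sigma_nm",
               "background", "precision_nm")
.event_cols <- c("start_frame", "n_frames", "dwell_s", "x_nm", "y_nm",
                 "censored")
.site_cols <- c("x_nm", "y_nm", "n_events", "kd_per_s", "ka_per_s",
                "dG_kJ_mol")

#' Localization, event, site and chromatogram table I/O
#'
#' Plain CSV with a header row; positions in nm, times in s. Readers
#' validate the schema and fail naming the offending columns.
#'
#' @param x Table to write.
#' @param path CSV path.
#' @return Readers return the validated data frame; writers return
#'   \code{path} invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_localizations <- function(x, path) {
  utils::write.csv(.check_schema(x, .loc_cols, "localization"), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_localizations <- function(path)
  .check_schema(utils::read.csv(path), .loc_cols, "localization")

#' @rdname table_io
#' @export
write_events <- function(x, path) {
  utils::write.csv(.check_schema(x, .event_cols, "event"), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_events <- function(path)
  .check_schema(utils::read.csv(path), .event_cols, "event")

#' @rdname table_io
#' @export
write_sites <- function(x, path) {
  utils::write.csv(.check_schema(x, .site_cols, "site"), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sites <- function(path)
  .check_schema(utils::read.csv(path), .site_cols, "site")

#' @rdname table_io
#' @export
read_chromatogram <- function(path)
  .check_schema(utils::read.csv(path), c("time_s", "signal"), "chromatogram")

#' @rdname table_io
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "elution_profile"))
  utils::write.csv(data.frame(time_s = x$time_s, density = x$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a super-resolution map as TIFF plus JSON sidecar
#'
#' @param srmap An \code{srmap}.
#' @param path Output TIFF path (32-bit float).
#' @return \code{path}, invisibly.
#' @export
write_srmap <- function(srmap, path) {
  stopifnot(inherits(srmap, "srmap"))
  m <- srmap$counts
  storage.mode(m) <- "double"
  tiff::writeTIFF(m / max(max(m), 1), path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_nm = srmap$pixel_nm, origin_nm = srmap$origin_nm,
         max_count = max(m)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write an accessibility results bundle as JSON
#'
#' @param result List with fields such as \code{d99_percent_r},
#'   \code{Ap_um2}, \code{Ai_um2}, \code{ratio}, \code{r_nm}, \code{n_loc},
#'   \code{excluded}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_results_json <- function(result, path) {
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
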