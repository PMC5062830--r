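# Plain-text suitability rasters (ESRI-ASCII-style grid format).
# Values live in [0, 1]; the grid is cell-centre registered, row 1 of the
# value matrix is the NORTHERNMOST row (as in the file format).

#' Construct a suitability raster
#'
#' @param values numeric matrix in `[0, 1]` (rows north to south).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell size in degrees (default 0.5).
#' @param tag time-slice tag (e.g. `"21ka"`, `"6ka"`, `"present"`).
#' @param nodata nodata sentinel written to files.
#' @return Object of class `suitability_raster`.
#' @export
suitability_raster <- function(values, xll, yll, cellsize = 0.5,
                               tag = "present", nodata = -9999) {
  if (!is.matrix(values)) stop_invalid("values must be a matrix")
  fin <- values[is.finite(values)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1)) {
    stop_invalid("suitability values must lie in [0, 1]")
  }
  structure(list(ncols = ncol(values), nrows = nrow(values),
                 xll = xll, yll = yll, cellsize = cellsize,
                 nodata = nodata, values = values, tag = tag),
            class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  cat(sprintf("Suitability raster '%s': %d x %d cells of %g deg, origin (%g, %g)\n",
              x$tag, x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  invisible(x)
}

raster_cell_centers <- function(r) {
  lon <- r$xll + (seq_len(r$ncols) - 0.5) * r$cellsize
  lat <- r$yll + (r$nrows - seq_len(r$nrows) + 0.5) * r$cellsize
  list(lat = matrix(lat, r$nrows, r$ncols),
       lon = matrix(lon, r$nrows, r$ncols, byrow = TRUE))
}

#' Read an ESRI-ASCII-style raster file
#'
#' @param path file path.
#' @param tag time-slice tag to attach.
#' @return A [suitability_raster()].
#' @export
read_raster <- function(path, tag = "present") {
  ln <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_invalid("raster header missing keys: %s",
                 paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(text = paste(ln[i:length(ln)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop_invalid("raster body has %d values, expected %d",
                 length(vals), nr * nc)
  }
  nd <- hdr$nodata_value %||% -9999
  vals[vals == nd] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  suitability_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                     cellsize = hdr$cellsize, tag = tag, nodata = nd)
}

#' Write a raster to an ESRI-ASCII-style file
#'
#' @param r a [suitability_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "suitability_raster"))
  hdr <- c(sprintf("ncols %d", r$ncols),
           sprintf("nrows %d", r$nrows),
           sprintf("xllcorner %.10g", r$xll),
           sprintf("yllcorner %.10g", r$yll),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", r$nodata))
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  body <- apply(v, 1, function(row) paste(sprintf("%.6g", row),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
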