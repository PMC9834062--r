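#' @include AllGenerics.R
NULL

#' Construct a LocalizationSet
#'
#' @param coords K x D numeric matrix of positions, nm (D = 2 or 3).
#' @param precisions K x D numeric matrix of per-axis localization precisions,
#'   nm; strictly positive.
#' @param channel optional integer color label per localization (default 0).
#' @param frame optional integer acquisition frame per localization.
#' @param photons optional photon count per localization.
#' @return a \linkS4class{LocalizationSet}.
#' @examples
#' locs <- LocalizationSet(cbind(x = rnorm(5), y = rnorm(5)),
#'                         matrix(5, 5, 2))
#' nLocs(locs)
#' @export
LocalizationSet <- function(coords, precisions,
                            channel = integer(0), frame = integer(0),
                            photons = numeric(0)) {
  coords <- as.matrix(coords)
  precisions <- as.matrix(precisions)
  storage.mode(coords) <- "double"
  storage.mode(precisions) <- "double"
  k <- nrow(coords)
  if (length(channel) == 0) channel <- rep(0L, k)
  new("LocalizationSet", coords = coords, precisions = precisions,
      channel = as.integer(channel), frame = as.integer(frame),
      photons = as.numeric(photons))
}

## subset a LocalizationSet by row index
#' @rdname LocalizationSet
#' @param x a LocalizationSet.
#' @param i row (localization) index.
#' @param j,drop,... ignored (included for generic compatibility).
#' @export
setMethod("[", "LocalizationSet", function(x, i, j, ..., drop = FALSE) {
  LocalizationSet(x@coords[i, , drop = FALSE],
                  x@precisions[i, , drop = FALSE],
                  channel = x@channel[i],
                  frame = if (length(x@frame)) x@frame[i] else integer(0),
                  photons = if (length(x@photons)) x@photons[i] else numeric(0))
})

#' Pool several LocalizationSets into one
#'
#' @param ... LocalizationSet objects (or a single list of them).
#' @return a LocalizationSet holding all rows. Frames/photons are kept only
#'   when present in every input.
#' @export
bindLocalizations <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !is(xs[[1]], "LocalizationSet"))
    xs <- xs[[1]]
  keep_frame <- all(vapply(xs, function(x) length(x@frame) > 0, TRUE))
  keep_phot <- all(vapply(xs, function(x) length(x@photons) > 0, TRUE))
  LocalizationSet(
    do.call(rbind, lapply(xs, coords)),
    do.call(rbind, lapply(xs, precisions)),
    channel = unlist(lapply(xs, channels)),
    frame = if (keep_frame) unlist(lapply(xs, frames)) else integer(0),
    photons = if (keep_phot) unlist(lapply(xs, photons)) else numeric(0))
}

.default_column_map <- c(
  x = "x_nm", y = "y_nm", z = "z_nm",
  sx = "sigma_x_nm", sy = "sigma_y_nm", sz = "sigma_z_nm",
  channel = "channel", frame = "frame", photons = "photons")

#' Read a localization table
#'
#' Reads a delimited-text localization table (one row per localization) into a
#' \linkS4class{LocalizationSet}. All lengths are in nm. The dimensionality is
#' inferred from the presence of a z column: x/y/sx/sy give 2D, adding z/sz
#' gives 3D. Column names are configurable through \code{columnMap}; defaults
#' are \code{x_nm, y_nm, z_nm, sigma_x_nm, sigma_y_nm, sigma_z_nm, channel,
#' frame, photons}.
#'
#' Only \code{format = "csv"} is supported: there is no HDF5 reader among the
#' package's dependencies, so \code{format = "hdf5"} raises an error.
#'
#' @param path file path.
#' @param format "csv".
#' @param columnMap named character vector mapping the internal names
#'   \code{x, y, z, sx, sy, sz, channel, frame, photons} to file column names;
#'   merged over the defaults.
#' @return a \linkS4class{LocalizationSet}.
#' @export
readLocalizations <- function(path, format = c("csv", "hdf5"),
                              columnMap = character(0)) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("format 'hdf5' is not supported by this build (no HDF5 reader ",
         "available); use 'csv'")
  if (!file.exists(path)) stop("file not found: ", path)
  cmap <- .default_column_map
  if (length(columnMap)) cmap[names(columnMap)] <- columnMap
  tab <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                           data.table = FALSE)
  need <- c("x", "y", "sx", "sy")
  has_z <- all(cmap[c("z", "sz")] %in% names(tab))
  if (has_z) need <- c("x", "y", "z", "sx", "sy", "sz")
  missing_cols <- cmap[need][!cmap[need] %in% names(tab)]
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  axes <- if (has_z) c("x", "y", "z") else c("x", "y")
  xm <- as.matrix(tab[, cmap[axes], drop = FALSE])
  sm <- as.matrix(tab[, cmap[paste0("s", axes)], drop = FALSE])
  colnames(xm) <- axes
  colnames(sm) <- paste0("s", axes)
  if (nrow(sm) > 0) {
    bad <- which(apply(sm, 1L, function(r) any(!is.finite(r) | r <= 0)))
    if (length(bad))
      stop(sprintf("non-positive precision at row %d", bad[1]))
  }
  getcol <- function(nm, as_fun) {
    if (cmap[nm] %in% names(tab)) as_fun(tab[[cmap[nm]]]) else NULL
  }
  LocalizationSet(
    xm, sm,
    channel = getcol("channel", as.integer) %||% rep(0L, nrow(xm)),
    frame = getcol("frame", as.integer) %||% integer(0),
    photons = getcol("photons", as.numeric) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a localization table
#'
#' Writes a \linkS4class{LocalizationSet} to a comma-separated file using the
#' default column names of \code{\link{readLocalizations}}. Numeric values are
#' written with 17 significant digits so that a read/write round trip is
#' bit-exact.
#'
#' @param locs a \linkS4class{LocalizationSet}.
#' @param path output file path.
#' @param format "csv" (see \code{\link{readLocalizations}} regarding hdf5).
#' @return \code{path}, invisibly.
#' @export
writeLocalizations <- function(locs, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("format 'hdf5' is not supported by this build (no HDF5 writer ",
         "available); use 'csv'")
  stopifnot(is(locs, "LocalizationSet"))
  validObject(locs)
  d <- locDim(locs)
  axes <- if (d == 3) c("x", "y", "z") else c("x", "y")
  cols <- c(.default_column_map[axes], .default_column_map[paste0("s", axes)])
  fmt <- function(v) sprintf("%.17g", v)
  out <- c(
    stats::setNames(lapply(seq_len(d), function(i) fmt(locs@coords[, i])),
                    cols[seq_len(d)]),
    stats::setNames(lapply(seq_len(d), function(i) fmt(locs@precisions[, i])),
                    cols[d + seq_len(d)]))
  out$channel <- locs@channel
  if (length(locs@frame)) out$frame <- locs@frame
  if (length(locs@photons)) out$photons <- fmt(locs@photons)
  df <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  if (nLocs(locs) == 0) {
    # header-only file
    df <- df[0, c(cols, "channel"), drop = FALSE]
  }
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Crop a site from a localization set
#'
#' Extracts all localizations inside the closed axis-aligned box of side
#' \code{sideLength} centered at \code{center} (boundary points are included)
#' and re-expresses their coordinates relative to the center.
#'
#' @param locs a \linkS4class{LocalizationSet}.
#' @param center numeric vector (length D), box center in nm.
#' @param sideLength box side d in nm (> 0).
#' @param id optional site label.
#' @return a \linkS4class{Site}; empty sites are permitted.
#' @export
cropSite <- function(locs, center, sideLength, id = "") {
  stopifnot(is(locs, "LocalizationSet"))
  if (sideLength <= 0) stop("sideLength must be > 0")
  d <- locDim(locs)
  if (length(center) != d) stop("center must have length ", d)
  half <- sideLength / 2
  rel <- sweep(locs@coords, 2L, center)
  inside <- rowSums(abs(rel) <= half + 1e-12) == d
  sub <- locs[inside]
  sub@coords <- sweep(locs@coords[inside, , drop = FALSE], 2L, center)
  new("Site", localizations = sub, sideLength = sideLength,
      center = as.numeric(center), id = as.character(id))
}

#' Wrap a LocalizationSet that is already site-centered into a Site
#'
#' @param locs localizations in site-local coordinates (box centered at 0).
#' @param sideLength box side, nm.
#' @param center original center (defaults to the origin).
#' @param id site label.
#' @return a \linkS4class{Site}.
#' @export
asSite <- function(locs, sideLength, center = rep(0, locDim(locs)), id = "") {
  new("Site", localizations = locs, sideLength = sideLength,
      center = as.numeric(center), id = as.character(id))
}
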