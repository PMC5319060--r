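#' Labeled segmentation volumes
#'
#' A labeled volume is a 3-D integer grid of tissue labels (0 = background,
#' 1 = parenchyma, 2 = vessel, 3 = tumor) together with its voxel spacing and
#' world origin. Files carry millimetres (medical-imaging convention); in
#' memory everything is SI metres so forces and the coupling coefficients
#' (printed in N/m) compose without silent unit scaling. Voxel indexing is
#' 0-based: voxel (i,j,k) occupies the half-open box
#' \code{[origin + i*s, origin + (i+1)*s)} along each axis.
#'
#' @param labels integer 3-D array with values in \{0,1,2,3\}; the first
#'   array index is x (fastest-varying), then y, then z
#' @param spacing numeric length-3, voxel edge lengths in metres
#' @param origin numeric length-3, world position (m) of the corner of voxel
#'   (0,0,0)
#' @return an object of class \code{labeled_volume}
#' @export
labeled_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive lengths")
  labels <- array(as.integer(labels), dim(labels))  # strip foreign attributes
  bad <- which(!(labels %in% 0:3))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(labels)) - 1L
    stopf("unknown label %d at voxel (%d, %d, %d)",
          labels[bad[1]], idx[1], idx[2], idx[3])
  }
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing * 1e3, 4), collapse = " x ")))
  tab <- table(factor(x$labels, levels = 0:3))
  cat(sprintf("  labels: background %d, parenchyma %d, vessel %d, tumor %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Per-label voxel counts of a labeled volume
#' @param volume a \code{labeled_volume}
#' @return named integer vector over labels 0..3
#' @export
label_counts <- function(volume) {
  counts <- tabulate(volume$labels + 1L, nbins = 4L)
  names(counts) <- c("background", "parenchyma", "vessel", "tumor")
  counts
}

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.nrrd$", lp)) "nrrd"
  else if (grepl("\\.json$", lp)) "rawjson"
  else stopf("unrecognised volume format: %s", path)
}

#' Read a labeled segmentation volume
#'
#' Supports NIfTI (.nii/.nii.gz), a minimal NRRD dialect (.nrrd; attached
#' header, raw/ascii/gzip encodings), and a raw-grid + JSON-header dialect
#' (.json) used for plain-text fixtures. Spacing is read from the header in
#' millimetres and converted to metres; labels are validated against the
#' known set \{0,1,2,3\}.
#'
#' @param path file path
#' @param spacing_mm optional length-3 override (mm) when the header carries
#'   no spacing
#' @return a \code{labeled_volume}
#' @export
read_labeled_volume <- function(path, spacing_mm = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  switch(volume_format(path),
         nifti = read_volume_nifti(path, spacing_mm),
         nrrd = read_volume_nrrd(path, spacing_mm),
         rawjson = read_volume_rawjson(path, spacing_mm))
}

#' Write a labeled segmentation volume
#'
#' The format follows the file extension (see [read_labeled_volume()]).
#' For the JSON dialect, per-label voxel counts are recorded in the header
#' at write time.
#'
#' @param volume a \code{labeled_volume}
#' @param path destination path
#' @param encoding data encoding for NRRD/JSON dialects ("ascii", "raw" or,
#'   for NRRD, "gzip")
#' @return \code{path}, invisibly
#' @export
write_labeled_volume <- function(volume, path, encoding = "ascii") {
  stopifnot(inherits(volume, "labeled_volume"))
  switch(volume_format(path),
         nifti = write_volume_nifti(volume, path),
         nrrd = write_volume_nrrd(volume, path, encoding),
         rawjson = write_volume_rawjson(volume, path, encoding))
  invisible(path)
}

read_volume_nifti <- function(path, spacing_mm) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stopf("expected a 3-D NIfTI volume: %s", path)
  sp <- attr(img, "pixdim")[1:3]
  if (is.null(sp) || any(!is.finite(sp)) || any(sp <= 0)) {
    if (is.null(spacing_mm))
      stopf("NIfTI header of %s carries no usable spacing; pass spacing_mm", path)
    sp <- spacing_mm
  }
  labeled_volume(arr, spacing = sp * 1e-3)
}

write_volume_nifti <- function(volume, path) {
  arr <- volume$labels
  attr(arr, "pixdim") <- volume$spacing * 1e3
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
}

read_volume_rawjson <- function(path, spacing_mm) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("dims", "data")) if (is.null(hdr[[f]]))
    stopf("JSON volume header %s lacks field '%s'", path, f)
  sp <- hdr$spacing_mm %||% spacing_mm
  if (is.null(sp)) stopf("%s carries no spacing_mm; pass spacing_mm", path)
  datafile <- file.path(dirname(path), hdr$data)
  if (!file.exists(datafile)) stopf("data file missing: %s", datafile)
  dims <- as.integer(hdr$dims)
  nvox <- prod(dims)
  vals <- switch(hdr$encoding %||% "ascii",
    ascii = as.integer(scan(datafile, what = integer(), quiet = TRUE)),
    raw = as.integer(readBin(datafile, what = "integer", size = 1L,
                             n = nvox, signed = FALSE)),
    stopf("unknown encoding '%s' in %s", hdr$encoding, path))
  if (length(vals) != nvox)
    stopf("%s: expected %d voxels, found %d", datafile, nvox, length(vals))
  out <- labeled_volume(array(vals, dims), spacing = as.numeric(sp) * 1e-3,
                        origin = as.numeric(hdr$origin_mm %||% c(0, 0, 0)) * 1e-3)
  if (!is.null(hdr$provenance)) out$provenance <- hdr$provenance
  out
}

write_volume_rawjson <- function(volume, path, encoding = "ascii") {
  base <- sub("\\.json$", "", basename(path))
  ext <- if (encoding == "ascii") ".txt" else ".raw"
  datafile <- paste0(base, ext)
  hdr <- list(dims = dim(volume$labels),
              spacing_mm = volume$spacing * 1e3,
              origin_mm = volume$origin * 1e3,
              encoding = encoding,
              data = datafile,
              label_counts = as.list(label_counts(volume)))
  if (!is.null(volume$provenance)) hdr$provenance <- volume$provenance
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  dest <- file.path(dirname(path), datafile)
  if (encoding == "ascii") {
    writeLines(paste(as.vector(volume$labels), collapse = " "), dest)
  } else {
    writeBin(as.raw(as.vector(volume$labels)), dest)
  }
}

# --- minimal NRRD (attached header) ---------------------------------------

read_volume_nrrd <- function(path, spacing_mm) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stopf("%s is not an NRRD file", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(tolower(kv[2]))]] <- kv[3]
  }
  dims <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(dims) != 3L) stopf("%s: only 3-D NRRD volumes are supported", path)
  sp <- spacing_mm
  if (!is.null(fields$`space directions`)) {
    vecs <- regmatches(fields$`space directions`,
                       gregexpr("\\(([^)]*)\\)", fields$`space directions`))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    sp <- sqrt(rowSums(m^2))
  } else if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  }
  if (is.null(sp)) stopf("%s carries no spacing; pass spacing_mm", path)
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields$`space origin`), ",")[[1]])
  type <- trimws(fields$type %||% "uint8")
  enc <- trimws(fields$encoding %||% "raw")
  nvox <- prod(dims)
  read_vals <- function(rawbytes) {
    size <- switch(type, uint8 = 1L, `unsigned char` = 1L, int8 = 1L,
                   int16 = 2L, short = 2L, int32 = 4L, int = 4L,
                   stopf("unsupported NRRD type '%s'", type))
    readBin(rawbytes, what = "integer", size = size, n = nvox,
            signed = !(size == 1L), endian = "little")
  }
  vals <- switch(enc,
    ascii = as.integer(scan(con, what = integer(), quiet = TRUE)),
    raw = read_vals(readBin(con, what = "raw", n = nvox * 4L + 64L)),
    gzip = read_vals(memDecompress(readBin(con, what = "raw",
                                           n = file.size(path)), type = "gzip")),
    stopf("unsupported NRRD encoding '%s'", enc))
  if (length(vals) < nvox)
    stopf("%s: expected %d voxels, found %d", path, nvox, length(vals))
  labeled_volume(array(vals[seq_len(nvox)], dims),
                 spacing = as.numeric(sp) * 1e-3, origin = origin * 1e-3)
}

write_volume_nrrd <- function(volume, path, encoding = "raw") {
  sp <- volume$spacing * 1e3
  org <- volume$origin * 1e3
  hdr <- c("NRRD0004",
           "type: uint8",
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(volume$labels), collapse = " ")),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   sp[1], sp[2], sp[3]),
           sprintf("space origin: (%g,%g,%g)", org[1], org[2], org[3]),
           sprintf("encoding: %s", encoding),
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  bytes <- as.raw(as.vector(volume$labels))
  switch(encoding,
         raw = writeBin(bytes, con),
         gzip = writeBin(memCompress(bytes, type = "gzip"), con),
         ascii = writeLines(paste(as.vector(volume$labels), collapse = " "), con),
         stopf("unsupported NRRD encoding '%s'", encoding))
}
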