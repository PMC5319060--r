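LANDMARK_CATEGORIES <- c("surface", "internal-tumor", "internal-vessel")

#' Construct a landmark set
#'
#' Landmarks are the registration ground truth: named points with a category
#' recording whether they sit on the organ surface or on an internal lesion
#' boundary. Positions are stored in metres; CSV files carry millimetres.
#'
#' @param id character vector of unique landmark ids
#' @param x,y,z world coordinates in metres
#' @param category one of "surface", "internal-tumor", "internal-vessel"
#' @return a tibble of class \code{landmark_set} with columns
#'   \code{id, x, y, z, category}
#' @export
landmark_set <- function(id, x, y, z, category) {
  id <- as.character(id)
  if (anyDuplicated(id)) stopf("duplicate landmark id: %s",
                               paste(unique(id[duplicated(id)]), collapse = ", "))
  pos <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (anyNA(pos) || any(!is.finite(pos))) stopf("landmark positions must be finite")
  category <- as.character(category)
  bad <- setdiff(unique(category), LANDMARK_CATEGORIES)
  if (length(bad)) stopf("unknown landmark category: %s", paste(bad, collapse = ", "))
  out <- tibble::tibble(id = id, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        category = category)
  class(out) <- c("landmark_set", class(out))
  out
}

landmark_matrix <- function(landmarks) {
  m <- as.matrix(landmarks[, c("x", "y", "z")])
  rownames(m) <- landmarks$id
  m
}

#' Read a landmark table from CSV
#'
#' Expects the header \code{id,x,y,z,category} with coordinates in
#' millimetres; they are converted to metres in memory. Malformed rows are
#' reported with their line number; duplicate ids are an error.
#'
#' @param path CSV file path
#' @return a \code{landmark_set} tibble
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "x", "y", "z", "category")
  if (!all(need %in% names(df)))
    stopf("%s: landmark CSV must have header id,x,y,z,category", path)
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stopf("%s line %d: non-numeric %s value '%s'",
            path, bad[1] + 1L, col, df[[col]][bad[1]])
    df[[col]] <- v
  }
  landmark_set(df$id, df$x * 1e-3, df$y * 1e-3, df$z * 1e-3, df$category)
}

#' Write a landmark table to CSV
#'
#' Positions are written in millimetres. A write-then-read round trip is the
#' identity to well below 1e-12 m.
#'
#' @param landmarks a \code{landmark_set}
#' @param path destination CSV path
#' @return \code{path}, invisibly
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(id = landmarks$id,
                   x = sprintf("%.12g", landmarks$x * 1e3),
                   y = sprintf("%.12g", landmarks$y * 1e3),
                   z = sprintf("%.12g", landmarks$z * 1e3),
                   category = landmarks$category)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
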