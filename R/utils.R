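# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of an R object
#'
#' MD5 of the canonical serialization (version 2, no header ties to the
#' running R version). Used to stamp meshes and configs into database and
#' result provenance so stale databases are detected at query time.
#'
#' @param x any serializable R object
#' @return a 32-character hexadecimal string
#' @export
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# labels used throughout: 0 background, 1 parenchyma, 2 vessel, 3 tumor
LABEL_BACKGROUND <- 0L
LABEL_PARENCHYMA <- 1L
LABEL_VESSEL <- 2L
LABEL_TUMOR <- 3L

label_name <- function(label) {
  c(`0` = "background", `1` = "parenchyma", `2` = "vessel",
    `3` = "tumor")[as.character(label)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stopf("%s must be a finite numeric matrix", what)
  invisible(x)
}
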