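#' Write a numeric array as a text-encoded NRRD file
#'
#' Minimal NRRD0004 writer (encoding: ascii) for exchanging property and
#' signal volumes. Voxel spacing and arbitrary `key:=value` metadata are
#' stored in the header. Text encoding keeps the files portable and
#' diffable; it is not meant for very large volumes.
#'
#' @param a numeric array (1-, 2- or 3-D)
#' @param path output file
#' @param spacing voxel spacing (scalar or per-axis), in mm
#' @param meta named character vector of extra key/value metadata
#' @export
write_nrrd <- function(a, path, spacing = 1, meta = character()) {
  d <- dim(a) %||% length(a)
  sp <- rep(spacing, length.out = length(d))
  hdr <- c(
    "NRRD0004",
    "# generated by cepaq",
    "type: double",
    sprintf("dimension: %d", length(d)),
    sprintf("sizes: %s", paste(d, collapse = " ")),
    sprintf("spacings: %s", paste(format(sp, digits = 15), collapse = " ")),
    "encoding: ascii")
  if (length(meta))
    hdr <- c(hdr, sprintf("%s:=%s", names(meta), as.character(meta)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  writeLines(paste(format(as.vector(a), digits = 17), collapse = " "), con)
  invisible(path)
}

#' Read a text-encoded NRRD file written by [write_nrrd()]
#'
#' @param path NRRD file
#' @return numeric array with attributes `spacing` and `meta`
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[[1]], "NRRD")) stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD header (no blank separator)")
  hdr <- lines[2:(blank - 1)]
  hdr <- hdr[!startsWith(hdr, "#")]
  field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0(name, ":"))]
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", name, ":"), "", ln[[1]]))
  }
  enc <- field("encoding")
  if (!identical(enc, "ascii")) stop("unsupported NRRD encoding: ", enc)
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(field("spacings") %||% "1", "\\s+")[[1]])
  kv <- hdr[grepl(":=", hdr, fixed = TRUE)]
  meta <- if (length(kv)) {
    parts <- regmatches(kv, regexpr(":=", kv), invert = TRUE)
    stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
  } else character()
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != prod(sizes)) stop("NRRD payload size mismatch")
  a <- array(vals, dim = sizes)
  attr(a, "spacing") <- sp
  attr(a, "meta") <- meta
  a
}
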