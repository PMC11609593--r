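# Intrinsic hydrophobicity scales. The scale is data: any two-column TSV
# (3-letter code, value) can be swapped in, with an optional header line
# '# cutoff=<Angstroms>' overriding the default interaction cutoff.

#' Load an intrinsic hydrophobicity scale from a TSV file
#'
#' The file holds one residue per line: a 3-letter amino-acid code and a
#' non-negative hydrophobicity value, tab- or whitespace-separated. Comment
#' lines start with `#`; a comment of the form `# cutoff=9.0` sets the
#' interaction cutoff carried by the scale.
#'
#' @param path path to the scale file.
#' @param name scale identifier; defaults to the file name.
#' @param cutoff interaction cutoff in Angstroms; overrides any value in the
#'   file header. Defaults to the header value or 9.0.
#' @return a [ScaleTable-class] object.
#' @export
loadScale <- function(path, name = basename(path), cutoff = NULL) {
  lines <- readLines(path)
  if (is.null(cutoff)) {
    hit <- grep("^#\\s*cutoff\\s*=", lines, value = TRUE)
    cutoff <- if (length(hit))
      as.numeric(sub("^#\\s*cutoff\\s*=\\s*", "", hit[1])) else 9.0
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad))
    stop("malformed scale entry at data line ", bad[1])
  values <- as.numeric(vapply(parts, `[`, "", 2L))
  names(values) <- toupper(vapply(parts, `[`, "", 1L))
  if (anyNA(values))
    stop("non-numeric hydrophobicity value in scale file")
  new("ScaleTable", values = values, name = name, cutoff = cutoff)
}

#' Default intrinsic hydrophobicity scale
#'
#' The scale bundled with the package: Kyte-Doolittle hydropathy rescaled
#' linearly to \eqn{[0, 1]} (Ile = 1, Arg = 0), with a 9.0 Angstrom
#' interaction cutoff. Both choices are configuration, not model
#' constants: use [loadScale()] to substitute any other scale.
#'
#' @return a [ScaleTable-class] object.
#' @examples
#' sc <- defaultScale()
#' scaleValue(sc, "GLY")
#' @export
defaultScale <- function() {
  path <- system.file("extdata", "kyte_doolittle_normalized.tsv",
                      package = "fodm", mustWork = TRUE)
  loadScale(path, name = "kyte_doolittle_normalized")
}

#' Look up intrinsic hydrophobicity for residue codes
#'
#' Non-standard residues with a known parent (e.g. MSE, selenomethionine)
#' are mapped to the parent standard residue before lookup.
#'
#' @param scale a [ScaleTable-class].
#' @param aa character vector of 3-letter codes.
#' @param strict error on unknown codes (default) instead of returning NA.
#' @return numeric vector of \eqn{H^r} values.
#' @export
scaleValue <- function(scale, aa, strict = TRUE) {
  stopifnot(is(scale, "ScaleTable"))
  aa <- toupper(aa)
  mapped <- ifelse(aa %in% names(NONSTANDARD_PARENT) &
                     !aa %in% names(scale@values),
                   NONSTANDARD_PARENT[aa], aa)
  v <- unname(scale@values[mapped])
  if (strict && anyNA(v))
    stop("residue code(s) absent from scale '", scale@name, "': ",
         paste(unique(aa[is.na(v)]), collapse = ", "))
  v
}

#' @rdname scaleValue
#' @export
scaleCutoff <- function(scale) {
  stopifnot(is(scale, "ScaleTable"))
  scale@cutoff
}

# parent standard residue for common modified residues
NONSTANDARD_PARENT <- c(
  MSE = "MET", FME = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS",
  OCS = "CYS", HYP = "PRO", SEP = "SER", TPO = "THR", PTR = "TYR",
  MLY = "LYS", KCX = "LYS", PYL = "LYS", PCA = "GLU"
)
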