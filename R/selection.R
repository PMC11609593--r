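# Unit selections: the grammar is `A:198-221+C:224-298` -- chain, colon,
# inclusive author-numbered range; `+` joins fragments, possibly across
# chains. A bare chain id selects the whole chain.

#' Build or parse a structural-unit selection
#'
#' `unitSelection()` builds a [UnitSelection-class] from explicit vectors;
#' `parseSelection()` parses the string grammar used in manifests and on the
#' command line: `"A:198-221+C:224-298"` composes two fragments from chains
#' A and C; a bare `"A"` selects all of chain A. Ranges are inclusive on
#' both ends and use author (PDB) numbering.
#'
#' @param chain character vector of chain identifiers, one per fragment.
#' @param first,last integer vectors of inclusive range bounds (`NA` for a
#'   whole chain).
#' @param label unit label used in reports; for `parseSelection()` defaults
#'   to the selection string itself.
#' @return a [UnitSelection-class].
#' @examples
#' parseSelection("A:198-221+C:224-298")
#' unitSelection("B", 5, 49, label = "hostB")
#' @export
unitSelection <- function(chain, first = NA_integer_, last = NA_integer_,
                          label = "unit") {
  n <- length(chain)
  fr <- data.frame(chain = as.character(chain),
                   first = as.integer(rep_len(first, n)),
                   last = as.integer(rep_len(last, n)),
                   stringsAsFactors = FALSE)
  new("UnitSelection", fragments = fr, label = label)
}

#' @rdname unitSelection
#' @param text selection string.
#' @export
parseSelection <- function(text, label = text) {
  parts <- strsplit(trimws(text), "+", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (!length(parts) || any(parts == ""))
    stop("empty selection string")
  parse1 <- function(p) {
    if (!grepl(":", p, fixed = TRUE))
      return(list(chain = p, first = NA_integer_, last = NA_integer_))
    m <- regmatches(p, regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (length(m) != 4L)
      stop("cannot parse selection fragment '", p,
           "' (expected CHAIN or CHAIN:FIRST-LAST)")
    list(chain = m[2], first = as.integer(m[3]), last = as.integer(m[4]))
  }
  got <- lapply(parts, parse1)
  unitSelection(chain = vapply(got, `[[`, "", "chain"),
                first = vapply(got, `[[`, 0L, "first"),
                last = vapply(got, `[[`, 0L, "last"),
                label = label)
}

#' @rdname unitSelection
#' @param selection a [UnitSelection-class].
#' @export
selectionString <- function(selection) {
  fr <- selection@fragments
  paste(ifelse(is.na(fr$first), fr$chain,
               sprintf("%s:%d-%d", fr$chain, fr$first, fr$last)),
        collapse = "+")
}

# coerce a selection given as string or object
as_selection <- function(x, label = NULL) {
  if (is.character(x)) x <- parseSelection(x, label = if (is.null(label)) x else label)
  stopifnot(is(x, "UnitSelection"))
  if (!is.null(label)) x@label <- label
  x
}
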