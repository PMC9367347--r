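#' Restriction enzyme definitions
#'
#' A restriction enzyme is described by its recognition sequence (top strand,
#' 5'->3') and the cut offset: the number of bases 5' of the cut within the
#' recognition site on the top strand.  `HindIII` (A^AGCTT, offset 1) and
#' `ApaI` (GGGCC^C, offset 5) are the standard REBASE definitions.
#'
#' Only palindromic recognition sites are supported: digestion scans the top
#' strand only, which is complete for palindromes but would silently miss
#' bottom-strand sites of a non-palindromic enzyme.  Non-palindromic
#' definitions are rejected at construction.
#'
#' @param name Enzyme name, e.g. `"HindIII"`.
#' @param recognition Recognition sequence over `{A,C,G,T}`.
#' @param cut_offset Integer in `[0, nchar(recognition)]`: the cut falls
#'   after this many bases of the site on the top strand.
#' @return An object of class `cg_enzyme` (a named list).
#' @examples
#' enzyme("HindIII", "AAGCTT", 1L)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition)) {
    cg_abort("recognition sequence must be over {A,C,G,T}", "assay_definition")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    cg_abort("cut_offset must lie within the recognition site", "assay_definition")
  }
  if (!is_palindromic(recognition)) {
    cg_abort(
      sprintf("enzyme %s: non-palindromic recognition sites are not supported", name),
      "assay_definition"
    )
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "cg_enzyme"
  )
}

#' @export
print.cg_enzyme <- function(x, ...) {
  site <- paste0(
    substr(x$recognition, 1, x$cut_offset), "^",
    substr(x$recognition, x$cut_offset + 1L, nchar(x$recognition))
  )
  cat(sprintf("<cg_enzyme> %s (%s)\n", x$name, site))
  invisible(x)
}

is_palindromic <- function(seq) {
  seq == revcomp(seq)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Built-in restriction enzymes
#'
#' Small built-in table of blunt/sticky cutters used by the shipped assays,
#' user-extensible via [enzyme()].
#'
#' @param name Optional single enzyme name to look up.
#' @return A named list of `cg_enzyme` objects, or a single `cg_enzyme`
#'   when `name` is given.
#' @export
restriction_enzymes <- function(name = NULL) {
  tab <- list(
    HindIII = enzyme("HindIII", "AAGCTT", 1L),
    ApaI    = enzyme("ApaI",    "GGGCCC", 5L),
    EcoRI   = enzyme("EcoRI",   "GAATTC", 1L),
    BamHI   = enzyme("BamHI",   "GGATCC", 1L),
    PstI    = enzyme("PstI",    "CTGCAG", 5L)
  )
  if (is.null(name)) {
    return(tab)
  }
  if (!name %in% names(tab)) {
    cg_abort(sprintf("unknown enzyme '%s'; define it with enzyme()", name),
             "assay_definition")
  }
  tab[[name]]
}
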