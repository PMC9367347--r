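#' Amplicon length implied by a primer pair
#'
#' With 1-based inclusive spans the amplified product runs from the forward
#' primer's 5' end to the reverse primer's 5' end on the top strand, i.e.
#' `reverse_span[2] - forward_span[1] + 1` bp.
#'
#' @param pair A [primer_pair()].
#' @return Integer amplicon length in bp.
#' @examples
#' p <- kat2b_assays()$g.T61908C$primers
#' amplicon_length(p)  # 78
#' @export
amplicon_length <- function(pair) {
  stopifnot(inherits(pair, "cg_primer_pair"))
  pair$reverse_span[2] - pair$forward_span[1] + 1L
}

#' Locate a primer pair on a reference and extract the amplicon
#'
#' Exact matching only: the forward primer must occur exactly once on the
#' top strand, and the reverse complement of the reverse primer exactly once
#' downstream of it.  Zero matches raise a `no_amplification` error;
#' multiple matches raise an `ambiguous_priming` error.
#'
#' @param reference Reference sequence: a character scalar or
#'   [Biostrings::DNAString].
#' @param pair A [primer_pair()].
#' @return A list with `seq` (the amplicon, character), `start`, `end`
#'   (1-based inclusive positions on the reference).
#' @export
find_amplicon <- function(reference, pair) {
  stopifnot(inherits(pair, "cg_primer_pair"))
  ref <- if (inherits(reference, "DNAString")) reference else {
    reference <- toupper(as.character(reference))
    if (!grepl("^[ACGT]+$", reference)) {
      cg_abort("reference must be over {A,C,G,T}", "data")
    }
    Biostrings::DNAString(reference)
  }
  fwd_hits <- Biostrings::matchPattern(pair$forward_seq, ref)
  rev_top <- revcomp(pair$reverse_seq)
  rev_hits <- Biostrings::matchPattern(rev_top, ref)
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) {
    cg_abort("no amplification: a primer has no exact match on the reference",
             "no_amplification")
  }
  if (length(fwd_hits) > 1L || length(rev_hits) > 1L) {
    cg_abort("ambiguous priming: a primer matches the reference more than once",
             "ambiguous_priming")
  }
  start <- Biostrings::start(fwd_hits)[1]
  end <- Biostrings::end(rev_hits)[1]
  if (end <= start) {
    cg_abort("no amplification: primers face away from each other",
             "no_amplification")
  }
  list(
    seq = as.character(Biostrings::subseq(ref, start, end)),
    start = start,
    end = end
  )
}

#' Digest a sequence with a restriction enzyme
#'
#' Scans the top strand for exact occurrences of the recognition site and
#' cuts each at `site_start + cut_offset`.  Palindromic enzymes only (a
#' top-strand scan finds every site of a palindrome); overlapping site
#' occurrences each produce a cut.  Zero sites yield a single full-length
#' band.
#'
#' @param amplicon Sequence to digest (character scalar).
#' @param enzyme A [enzyme()] or a name known to [restriction_enzymes()].
#' @return A `cg_band_pattern`: integer vector of fragment lengths (bp),
#'   sorted decreasing, summing to `nchar(amplicon)`.
#' @examples
#' digest("AAAAAGCTTTT", "HindIII")  # A^AGCTT cut: fragments 4 + 7
#' @export
digest <- function(amplicon, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzymes(enzyme)
  stopifnot(inherits(enzyme, "cg_enzyme"))
  amplicon <- toupper(as.character(amplicon))
  if (nchar(amplicon) < 1L) cg_abort("amplicon must be non-empty", "data")
  hits <- Biostrings::matchPattern(enzyme$recognition, Biostrings::DNAString(amplicon))
  cuts <- sort(unique(Biostrings::start(hits) + enzyme$cut_offset - 1L))
  # cut after position k; drop degenerate cuts at the very ends
  cuts <- cuts[cuts >= 1L & cuts < nchar(amplicon)]
  band_pattern(diff(c(0L, cuts, nchar(amplicon))))
}

band_pattern <- function(lengths) {
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) cg_abort("band lengths must be >= 1", "data")
  structure(sort(lengths, decreasing = TRUE), class = "cg_band_pattern")
}

#' @export
print.cg_band_pattern <- function(x, ...) {
  cat(sprintf("<cg_band_pattern> {%s} bp\n", paste(unclass(x), collapse = ", ")))
  invisible(x)
}

# Gel band set expected for a diploid genotype under an assay.  Duplicate
# lengths collapse everywhere: a gel reports presence of a length, not
# dosage, and heterozygotes show the union of both alleles' patterns.
expected_bands <- function(assay, genotype) {
  g <- assay_genotypes(assay)
  cutcut <- genotype_label(assay, rep(assay$cut_allele, 2L))
  uncutuncut <- genotype_label(assay, rep(assay$uncut_allele, 2L))
  if (genotype == cutcut) {
    band_pattern(unique(assay$expected_cut_fragments))
  } else if (genotype == uncutuncut) {
    band_pattern(assay$amplicon_length)
  } else if (genotype == g[["het"]]) {
    band_pattern(unique(c(assay$amplicon_length, assay$expected_cut_fragments)))
  } else {
    cg_abort(sprintf("unknown genotype '%s' for marker %s", genotype, assay$marker_id),
             "data")
  }
}

#' Call a diploid genotype from a gel band pattern
#'
#' The full-length band alone is the uncut homozygote; the assay's cut
#' fragments alone are the cut homozygote; their union (duplicate lengths
#' collapsed) is the heterozygote.  Any other multiset raises an
#' `uncallable_pattern` error.
#'
#' @param bands Band lengths (bp): a `cg_band_pattern` or integer vector.
#' @param assay A [marker_assay()].
#' @return Genotype label, e.g. `"TC"`.
#' @examples
#' call_genotype(c(78), kat2b_assays()$g.T61908C)            # "CC"
#' call_genotype(c(21, 57, 78), kat2b_assays()$g.T61908C)    # "TC"
#' @export
call_genotype <- function(bands, assay) {
  stopifnot(inherits(assay, "cg_marker_assay"))
  obs <- sort(unique(as.integer(bands)), decreasing = TRUE)
  g <- assay_genotypes(assay)
  for (geno in unname(g)) {
    if (identical(obs, unclass(expected_bands(assay, geno)))) {
      return(geno)
    }
  }
  cg_abort(sprintf(
    "band pattern {%s} matches no genotype of marker %s",
    paste(obs, collapse = ", "), assay$marker_id
  ), "uncallable_pattern")
}

#' Genotype an individual by in-silico PCR-RFLP
#'
#' Runs the full wet-lab analogue for one diploid individual: amplify each
#' haplotype reference with the assay's primers, digest both amplicons,
#' pool the bands on one virtual gel lane (duplicate lengths collapse), and
#' call the genotype from the pooled pattern.
#'
#' @param haplotype_refs Named character vector of reference sequences, one
#'   per allele carried (names are allele symbols; a homozygote may supply
#'   one sequence or two identical ones).
#' @param assay A [marker_assay()].
#' @return Genotype label.
#' @export
rflp_genotype <- function(haplotype_refs, assay) {
  stopifnot(inherits(assay, "cg_marker_assay"))
  bands <- integer(0)
  for (ref in haplotype_refs) {
    amp <- find_amplicon(ref, assay$primers)
    bands <- c(bands, unclass(digest(amp$seq, assay$enzyme)))
  }
  call_genotype(unique(bands), assay)
}

#' Genotype a simulated population by in-silico PCR-RFLP
#'
#' For every individual and marker, selects the allele haplotype references
#' matching the individual's true genotype, and genotypes it with
#' [rflp_genotype()].  Used to exercise the genotyping chain end to end;
#' by construction the calls must equal the generating genotypes.
#'
#' @param pop A population data frame (see [simulate_population()]).
#' @param assays Named list of [marker_assay()] objects.
#' @param references Named list (by marker id) of named character vectors
#'   (by allele) of haplotype reference sequences, as produced by
#'   [synthesize_reference()].
#' @return `pop` with one `<marker>_rflp` column of called genotypes per
#'   marker.
#' @export
rflp_genotype_population <- function(pop, assays, references) {
  for (mid in names(assays)) {
    assay <- assays[[mid]]
    refs <- references[[mid]]
    # the wet-lab chain is deterministic per genotype: run it once per
    # distinct genotype and map over individuals
    call_map <- vapply(unique(pop[[mid]]), function(geno) {
      alleles <- strsplit(geno, "")[[1]]
      rflp_genotype(refs[alleles], assay)
    }, character(1))
    pop[[paste0(mid, "_rflp")]] <- unname(call_map[pop[[mid]]])
  }
  pop
}
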