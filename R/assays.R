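#' Primer pair for PCR amplification
#'
#' Coordinates are 1-based inclusive on the reference top strand, matching
#' the convention of published primer tables ("Position 61,883-61,907").
#' The reverse primer sequence is given 5'->3' on the bottom strand, i.e.
#' its reverse complement appears on the top strand at `reverse_span`.
#'
#' @param forward_seq,reverse_seq Primer sequences 5'->3' over `{A,C,G,T}`.
#' @param forward_span,reverse_span Integer length-2 vectors `(start, end)`,
#'   1-based inclusive reference coordinates.
#' @param annealing_temp_c Annealing temperature in degrees Celsius
#'   (bookkeeping only; matching is exact, not thermodynamic).
#' @return An object of class `cg_primer_pair`.
#' @export
primer_pair <- function(forward_seq, reverse_seq, forward_span, reverse_span,
                        annealing_temp_c = NA_real_) {
  forward_seq <- toupper(forward_seq)
  reverse_seq <- toupper(reverse_seq)
  for (s in c(forward_seq, reverse_seq)) {
    if (!grepl("^[ACGT]+$", s)) {
      cg_abort("primer sequences must be over {A,C,G,T}", "assay_definition")
    }
  }
  forward_span <- as.integer(forward_span)
  reverse_span <- as.integer(reverse_span)
  if (length(forward_span) != 2L || length(reverse_span) != 2L) {
    cg_abort("primer spans must be (start, end) pairs", "assay_definition")
  }
  if (diff(forward_span) + 1L != nchar(forward_seq) ||
      diff(reverse_span) + 1L != nchar(reverse_seq)) {
    cg_abort("primer span length must equal primer length", "assay_definition")
  }
  if (forward_span[2] >= reverse_span[1]) {
    cg_abort("primer spans overlap or are inverted", "assay_definition")
  }
  structure(
    list(
      forward_seq = forward_seq, reverse_seq = reverse_seq,
      forward_span = forward_span, reverse_span = reverse_span,
      annealing_temp_c = annealing_temp_c
    ),
    class = "cg_primer_pair"
  )
}

#' Marker assay: one SNP genotyped by PCR-RFLP
#'
#' Bundles a biallelic SNP with its primer pair, restriction enzyme and the
#' allele -> cut-state map.  One allele (the cut allele) completes the
#' enzyme's recognition site inside the amplicon, so its amplicon digests
#' into `expected_cut_fragments`; the other allele's amplicon is refractory
#' and runs as a single full-length band.
#'
#' `expected_cut_fragments` is given 5'->3': its first element is the length
#' of the fragment carrying the forward primer, which fixes the cut position
#' and hence where the recognition site sits in the amplicon.  `snp_offset`
#' is the SNP position within the amplicon (1-based); it must fall inside
#' the recognition site, and the site base at that position must equal
#' `cut_allele`.
#'
#' @param marker_id Marker name, e.g. `"g.T61908C"`.  When the id follows
#'   the `g.<ref><pos><alt>` convention the heterozygote genotype label is
#'   written ref-then-alt (so `"TC"` for g.T61908C but `"CT"` for
#'   g.C73406T, as in published genotype tables).
#' @param primers A [primer_pair()].
#' @param enzyme A [enzyme()] or a name known to [restriction_enzymes()].
#' @param cut_allele,uncut_allele Single-base allele symbols.
#' @param expected_cut_fragments Integer fragment lengths (bp), 5'->3',
#'   summing to the amplicon length.
#' @param snp_offset SNP position within the amplicon, 1-based.
#' @return An object of class `cg_marker_assay`.
#' @export
marker_assay <- function(marker_id, primers, enzyme, cut_allele, uncut_allele,
                         expected_cut_fragments, snp_offset) {
  stopifnot(inherits(primers, "cg_primer_pair"))
  if (is.character(enzyme)) enzyme <- restriction_enzymes(enzyme)
  stopifnot(inherits(enzyme, "cg_enzyme"))
  cut_allele <- toupper(cut_allele)
  uncut_allele <- toupper(uncut_allele)
  if (cut_allele == uncut_allele) {
    cg_abort("cut and uncut alleles must differ", "assay_definition")
  }
  amp_len <- amplicon_length(primers)
  expected_cut_fragments <- as.integer(expected_cut_fragments)
  if (any(expected_cut_fragments < 1L)) {
    cg_abort("fragment lengths must be >= 1", "assay_definition")
  }
  if (sum(expected_cut_fragments) != amp_len) {
    cg_abort(sprintf(
      "expected cut fragments sum to %d but amplicon length is %d",
      sum(expected_cut_fragments), amp_len
    ), "assay_definition")
  }
  if (length(expected_cut_fragments) != 2L) {
    cg_abort("single-cut assays expected: give exactly two fragments", "assay_definition")
  }
  site_len <- nchar(enzyme$recognition)
  site_start <- expected_cut_fragments[1] - enzyme$cut_offset + 1L
  if (site_start < 1L || site_start + site_len - 1L > amp_len) {
    cg_abort("recognition site implied by fragment lengths falls outside the amplicon",
             "assay_definition")
  }
  snp_offset <- as.integer(snp_offset)
  if (snp_offset < site_start || snp_offset > site_start + site_len - 1L) {
    cg_abort("snp_offset must fall inside the recognition site", "assay_definition")
  }
  site_base <- substr(enzyme$recognition, snp_offset - site_start + 1L,
                      snp_offset - site_start + 1L)
  if (site_base != cut_allele) {
    cg_abort(sprintf(
      "recognition-site base at the SNP is %s, not the declared cut allele %s",
      site_base, cut_allele
    ), "assay_definition")
  }

  m <- regmatches(marker_id, regexec("^g\\.([ACGT])[0-9]+([ACGT])$", marker_id))[[1]]
  allele_order <- if (length(m) == 3L) c(m[2], m[3]) else sort(c(cut_allele, uncut_allele))
  if (!setequal(allele_order, c(cut_allele, uncut_allele))) {
    cg_abort("marker_id alleles disagree with cut/uncut alleles", "assay_definition")
  }

  structure(
    list(
      marker_id = marker_id, primers = primers, enzyme = enzyme,
      cut_allele = cut_allele, uncut_allele = uncut_allele,
      expected_cut_fragments = expected_cut_fragments,
      amplicon_length = amp_len,
      site_start = site_start,
      snp_offset = snp_offset,
      allele_order = allele_order
    ),
    class = "cg_marker_assay"
  )
}

#' @export
print.cg_marker_assay <- function(x, ...) {
  cat(sprintf(
    "<cg_marker_assay> %s: %d bp amplicon, %s digest -> {%s} for allele %s (allele %s uncut)\n",
    x$marker_id, x$amplicon_length, x$enzyme$name,
    paste(x$expected_cut_fragments, collapse = ", "),
    x$cut_allele, x$uncut_allele
  ))
  invisible(x)
}

#' Diploid genotype labels of an assay
#'
#' @param assay A [marker_assay()].
#' @return Named character vector with elements `hom_ref`, `het`, `hom_alt`
#'   following the assay's allele order (e.g. `"TT" "TC" "CC"` for
#'   g.T61908C).
#' @export
assay_genotypes <- function(assay) {
  a <- assay$allele_order
  c(
    hom_ref = strrep(a[1], 2L),
    het     = paste0(a[1], a[2]),
    hom_alt = strrep(a[2], 2L)
  )
}

# Canonicalise an unordered allele pair into the assay's genotype label.
genotype_label <- function(assay, alleles) {
  g <- assay_genotypes(assay)
  key <- paste(sort(alleles), collapse = "")
  hit <- g[vapply(g, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = "") == key, logical(1))]
  if (length(hit) != 1L) {
    cg_abort(sprintf("alleles {%s} are not valid for marker %s",
                     paste(alleles, collapse = ","), assay$marker_id), "data")
  }
  unname(hit)
}

#' The three KAT2B PCR-RFLP assays
#'
#' Assay definitions for the KAT2B SNPs g.T61908C, g.T62131C and g.C73406T
#' (coordinates on the bovine reference AC_000158.1).  g.T61908C is digested
#' by HindIII when the T allele is present (the site is completed by the
#' forward primer's 3' end plus the SNP base), giving 21 + 57 bp fragments
#' of the 78 bp amplicon; g.T62131C and g.C73406T are ApaI assays whose C
#' alleles digest into 27 + 191 bp of 218 bp and 27 + 287 bp of 314 bp
#' respectively.
#'
#' @return Named list of three [marker_assay()] objects.
#' @export
kat2b_assays <- function() {
  p1 <- primer_pair(
    forward_seq = "GGGTTCCCACTGCACAGGCCAAGCT",
    reverse_seq = "GTCCATCAGACGCCCCCACACAGAG",
    forward_span = c(61883L, 61907L),
    reverse_span = c(61936L, 61960L),
    annealing_temp_c = 68
  )
  p2 <- primer_pair(
    forward_seq = "ACCTTCAAGGCCTTTTACATGCGGG",
    reverse_seq = "TCAAAGAGGAATGGACACAGGCAGA",
    forward_span = c(62105L, 62129L),
    reverse_span = c(62298L, 62322L),
    annealing_temp_c = 64
  )
  p3 <- primer_pair(
    forward_seq = "CTCTTCCCAGTCTCACTTTTGTGGG",
    reverse_seq = "AGGCACACTGTTTGATGAGTTTCTA",
    forward_span = c(73379L, 73403L),
    reverse_span = c(73668L, 73692L),
    annealing_temp_c = 61
  )
  list(
    g.T61908C = marker_assay(
      "g.T61908C", p1, "HindIII",
      cut_allele = "T", uncut_allele = "C",
      expected_cut_fragments = c(21L, 57L),
      snp_offset = 61908L - 61883L + 1L
    ),
    g.T62131C = marker_assay(
      "g.T62131C", p2, "ApaI",
      cut_allele = "C", uncut_allele = "T",
      expected_cut_fragments = c(27L, 191L),
      snp_offset = 62131L - 62105L + 1L
    ),
    g.C73406T = marker_assay(
      "g.C73406T", p3, "ApaI",
      cut_allele = "C", uncut_allele = "T",
      expected_cut_fragments = c(27L, 287L),
      snp_offset = 73406L - 73379L + 1L
    )
  )
}

#' Breed panel of the genotyped study population
#'
#' Sample sizes of the four Chinese cattle breeds in the genotyping panel
#' (827 two-year-old females in total), with the published alternative-allele
#' frequency of each KAT2B marker per breed.  These frequencies parameterise
#' the default synthetic populations.
#'
#' @return A data frame with columns `breed`, `n` and one allele-frequency
#'   column per marker (frequency of the marker id's second allele).
#' @export
study_breeds <- function() {
  data.frame(
    breed = c("Qinchuan", "Fu", "Yak", "Chaidam"),
    n = c(658L, 52L, 48L, 69L),
    # frequency of the alt allele (C for g.T61908C/g.T62131C, T for g.C73406T)
    g.T61908C = c(0.43, 0.51, 0.56, 0.62),
    g.T62131C = c(0.61, 0.47, 0.84, 0.48),
    g.C73406T = c(0.31, 0.43, 0.76, 0.49),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}
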