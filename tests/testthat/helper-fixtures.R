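# Shared fixtures: everything is generated in code at test time.

# Random DNA string without a given forbidden substring.
random_dna <- function(len, forbid = character(0)) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if (!any(vapply(forbid, function(f) grepl(f, s, fixed = TRUE), logical(1)))) {
      return(s)
    }
  }
}

# A random but internally consistent single-cut marker assay: primers free
# of the recognition site, the site strictly between the primers, the SNP
# at a random base of the site.
random_assay <- function(id = "mX", enzyme_name = NULL) {
  enz_tab <- restriction_enzymes()
  if (is.null(enzyme_name)) enzyme_name <- sample(names(enz_tab), 1)
  enz <- enz_tab[[enzyme_name]]
  site_len <- nchar(enz$recognition)
  plen <- 22L
  amp_len <- sample(120:200, 1)
  fwd <- random_dna(plen, forbid = enz$recognition)
  rev_top <- random_dna(plen, forbid = enz$recognition)
  rev_primer <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_top)))
  site_start <- sample((plen + 2L):(amp_len - plen - site_len - 1L), 1)
  snp_in_site <- sample(seq_len(site_len), 1)
  cut_allele <- substr(enz$recognition, snp_in_site, snp_in_site)
  uncut_allele <- sample(setdiff(c("A", "C", "G", "T"), cut_allele), 1)
  f1 <- site_start + enz$cut_offset - 1L
  start <- sample(1000:9000, 1)
  marker_assay(
    id,
    primer_pair(fwd, rev_primer,
                forward_span = c(start, start + plen - 1L),
                reverse_span = c(start + amp_len - plen, start + amp_len - 1L)),
    enz,
    cut_allele = cut_allele, uncut_allele = uncut_allele,
    expected_cut_fragments = c(f1, amp_len - f1),
    snp_offset = site_start + snp_in_site - 1L
  )
}

# Independent digestion oracle: locate sites with base-R gregexpr and split
# the string at the implied indices.
digest_oracle <- function(s, enz) {
  hits <- gregexpr(enz$recognition, s, fixed = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) + enz$cut_offset - 1L
  cuts <- cuts[cuts >= 1L & cuts < nchar(s)]
  sort(diff(c(0L, sort(cuts), nchar(s))), decreasing = TRUE)
}

# Tiny two-gene Ct table with configurable per-sample mean Cts.
make_ct <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(
      sample_id = s$id, tissue = s$tissue, stage = s$stage,
      gene = c(s$target_gene %||% "KAT2B", s$ref_gene %||% "beta_actin"),
      ct_rep1 = c(s$target, s$reference),
      ct_rep2 = c(s$target, s$reference),
      ct_rep3 = c(s$target, s$reference),
      stringsAsFactors = FALSE
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
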