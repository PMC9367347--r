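#' Genotype counts for one marker in one breed
#'
#' @param counts Named integer vector of genotype counts, names being
#'   diploid genotype labels (two allele symbols, e.g. `"TC"`).
#' @param marker_id,breed Optional labels carried into summaries.
#' @return An object of class `cg_genotype_counts`.
#' @export
genotype_counts <- function(counts, marker_id = NA_character_, breed = NA_character_) {
  counts <- round(counts)
  if (any(counts < 0)) cg_abort("genotype counts must be >= 0", "data")
  n <- sum(counts)
  if (n < 1) cg_abort("empty sample: total genotype count is 0", "empty_sample")
  bad <- nchar(names(counts)) != 2L
  if (is.null(names(counts)) || any(bad)) {
    cg_abort("genotype labels must be two allele symbols (e.g. 'TC')", "data")
  }
  structure(
    list(marker_id = marker_id, breed = breed,
         counts = stats::setNames(as.integer(counts), names(counts)),
         n = as.integer(n)),
    class = "cg_genotype_counts"
  )
}

as_genotype_counts <- function(x) {
  if (inherits(x, "cg_genotype_counts")) x else genotype_counts(x)
}

#' Allele frequencies from genotype counts
#'
#' `p_allele = (2 x hom count + het count) / 2n`, generalised by counting
#' allele copies over every genotype label.
#'
#' @param counts A [genotype_counts()] or named count vector.
#' @return Named numeric vector of allele frequencies summing to 1, sorted
#'   by decreasing frequency then allele symbol.
#' @examples
#' allele_frequencies(c(CC = 25, TC = 50, TT = 25))
#' @export
allele_frequencies <- function(counts) {
  gc <- as_genotype_counts(counts)
  copies <- list()
  for (geno in names(gc$counts)) {
    for (al in strsplit(geno, "")[[1]]) {
      copies[[al]] <- (copies[[al]] %||% 0L) + gc$counts[[geno]]
    }
  }
  p <- unlist(copies) / (2 * gc$n)
  p[order(-p, names(p))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_freqs <- function(freqs) {
  if (any(freqs < 0 | freqs > 1) || abs(sum(freqs) - 1) > 1e-12) {
    cg_abort("allele frequencies must lie in [0,1] and sum to 1", "invalid_frequency")
  }
  freqs
}

#' Gene heterozygosity (gene diversity)
#'
#' `He = 1 - sum(p_i^2)`: the expected heterozygote proportion under random
#' mating.
#'
#' @param freqs Allele frequencies summing to 1.
#' @return He in `[0, 1 - 1/k]`.
#' @export
gene_heterozygosity <- function(freqs) {
  freqs <- check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Effective allele number
#'
#' `Ne = 1 / sum(p_i^2)`: the number of equifrequent alleles giving the
#' same gene diversity.
#'
#' @param freqs Allele frequencies summing to 1.
#' @return Ne in `[1, k]`.
#' @export
effective_allele_number <- function(freqs) {
  freqs <- check_freqs(freqs)
  s <- sum(freqs^2)
  if (s == 0) cg_abort("all-zero allele frequencies", "invalid_frequency")
  1 / s
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (the Botstein
#' expression); for a biallelic marker this reduces to `He - 2 p^2 q^2`.
#' Always `PIC <= He`.
#'
#' @param freqs Allele frequencies summing to 1.
#' @return PIC, with the marker's diversity class
#'   (see [diversity_class()]) attached as attribute `class_label`.
#' @export
pic <- function(freqs) {
  freqs <- check_freqs(freqs)
  s2 <- sum(freqs^2)
  cross <- (s2^2 - sum(freqs^4)) / 2  # sum_{i<j} p_i^2 p_j^2
  val <- 1 - s2 - 2 * cross
  structure(val, class_label = diversity_class(val))
}

#' Diversity class of a PIC value
#'
#' Standard classification: low (`PIC < 0.25`), mid
#' (`0.25 <= PIC <= 0.50`), high (`PIC > 0.50`).
#'
#' @param pic_value Numeric PIC value(s).
#' @return Character vector of `"low"`, `"mid"`, `"high"`.
#' @export
diversity_class <- function(pic_value) {
  ifelse(pic_value < 0.25, "low", ifelse(pic_value > 0.50, "high", "mid"))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Expected genotype counts `(n p^2, 2 n p q, n q^2)` are formed from the
#' observed allele frequencies; the statistic is `sum((O - E)^2 / E)` over
#' the three genotype classes with 1 degree of freedom (biallelic).  With
#' `correction = TRUE`, Yates' continuity correction
#' `sum((max(|O - E| - 0.5, 0))^2 / E)` is applied.  Markers with more than
#' two alleles use all `k(k+1)/2` genotype classes and `k(k-1)/2` degrees
#' of freedom (experimental; a warning is raised).
#'
#' @param counts A [genotype_counts()] or named count vector.
#' @param correction Apply Yates' continuity correction (default `FALSE`).
#' @return List with `chi2`, `df`, `p`.
#' @examples
#' hwe_chi_square(c(CC = 30, TC = 40, TT = 30))  # chi2 = 4, df = 1
#' @export
hwe_chi_square <- function(counts, correction = FALSE) {
  gc <- as_genotype_counts(counts)
  p <- allele_frequencies(gc)
  alleles <- names(p)
  k <- length(alleles)
  if (k < 2L) cg_abort("monomorphic marker: HWE test undefined", "degenerate_marker")
  if (k > 2L) cg_warn("HWE chi-square for >2 alleles is experimental", "experimental")

  observed <- numeric(0)
  expected <- numeric(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      e <- if (i == j) gc$n * p[i]^2 else 2 * gc$n * p[i] * p[j]
      key <- paste(sort(c(alleles[i], alleles[j])), collapse = "")
      o <- 0
      for (geno in names(gc$counts)) {
        if (paste(sort(strsplit(geno, "")[[1]]), collapse = "") == key) {
          o <- o + gc$counts[[geno]]
        }
      }
      observed <- c(observed, o)
      expected <- c(expected, e)
    }
  }
  if (any(expected == 0 & observed > 0)) {
    cg_abort("degenerate marker: a genotype class has expected count 0 but was observed",
             "degenerate_marker")
  }
  keep <- expected > 0
  dev <- abs(observed[keep] - expected[keep])
  if (correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected[keep])
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Diversity summary for one marker x breed
#'
#' One row of a diversity table: genotype and allele frequencies, HWE
#' chi-square, PIC, He, Ne and the diversity class.
#'
#' @param counts A [genotype_counts()] or named count vector.
#' @param correction Passed to [hwe_chi_square()].
#' @return One-row data frame.
#' @export
diversity_summary <- function(counts, correction = FALSE) {
  gc <- as_genotype_counts(counts)
  p <- allele_frequencies(gc)
  he <- gene_heterozygosity(p)
  hwe <- hwe_chi_square(gc, correction = correction)
  pic_v <- pic(p)
  data.frame(
    marker = gc$marker_id, breed = gc$breed, n = gc$n,
    genotypes = paste(names(gc$counts), collapse = "/"),
    genotype_freqs = paste(sprintf("%.4f", gc$counts / gc$n), collapse = "/"),
    alleles = paste(names(p), collapse = "/"),
    allele_freqs = paste(sprintf("%.4f", p), collapse = "/"),
    hwe_chi2 = hwe$chi2, hwe_df = hwe$df, hwe_p = hwe$p,
    pic = as.numeric(pic_v), he = he,
    ne = effective_allele_number(p),
    diversity_class = attr(pic_v, "class_label"),
    stringsAsFactors = FALSE
  )
}

#' Diversity table over a genotyped population
#'
#' Tabulates genotype counts per marker within each group (breed by
#' default) and computes [diversity_summary()] rows for all combinations.
#'
#' @param pop Population data frame with genotype columns.
#' @param markers Marker ids (default: every column matching `g.<...>`)
#'   or a list of [marker_assay()] objects.
#' @param by Grouping column, default `"breed"`; `NULL` pools everything.
#' @param correction Passed to [hwe_chi_square()].
#' @return Data frame, one row per marker x group.
#' @export
diversity_table <- function(pop, markers = NULL, by = "breed", correction = FALSE) {
  if (is.null(markers)) {
    markers <- grep("^g\\.", names(pop), value = TRUE)
  } else if (is.list(markers)) {
    markers <- vapply(markers, function(a) a$marker_id, character(1))
  }
  groups <- if (is.null(by)) list(all = pop) else split(pop, pop[[by]])
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (m in markers) {
      tab <- table(g[[m]])
      gc <- genotype_counts(stats::setNames(as.integer(tab), names(tab)),
                            marker_id = m, breed = gname)
      rows[[length(rows) + 1L]] <- diversity_summary(gc, correction = correction)
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$marker, markers)), , drop = FALSE]
}

#' Reconstruct integer genotype counts from published frequencies
#'
#' `counts = round(freq x n)`, then the largest class absorbs the rounding
#' remainder so the counts sum exactly to `n` (minimal perturbation).
#'
#' @param freqs Named genotype frequencies.
#' @param n Sample size.
#' @return Named integer vector of counts summing to `n`.
#' @export
counts_from_frequencies <- function(freqs, n) {
  cnt <- round(freqs * n)
  slack <- n - sum(cnt)
  if (slack != 0) {
    i <- which.max(cnt)
    cnt[i] <- cnt[i] + slack
  }
  if (any(cnt < 0)) cg_abort("reconstructed counts are negative", "data")
  stats::setNames(as.integer(cnt), names(freqs))
}

#' Published diversity table for the three KAT2B markers
#'
#' The published genotype/allele frequencies, HWE verdicts and diversity
#' statistics of the three KAT2B SNPs across the four study breeds (12
#' marker x breed rows), shipped as plain text.  Used as the golden
#' reference for the diversity statistics and as the source of the default
#' simulation frequencies.
#'
#' @return Data frame with one row per marker x breed.
#' @export
reported_diversity <- function() {
  path <- system.file("extdata", "kat2b_reported_diversity.csv",
                      package = "cgassoc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Decimal rounding as printed tables do it (0.375 -> 0.38), unlike R's
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
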