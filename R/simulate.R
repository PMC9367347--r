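# All generators take explicit seeds and restore the caller's RNG state:
# no global random state is consumed or left behind.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of one synthetic breed population
#'
#' Genotypes at a biallelic marker are drawn from the inbreeding-adjusted
#' Hardy-Weinberg proportions
#' `(q^2 + F p q, 2 p q (1 - F), p^2 + F p q)` for (ref hom, het, alt hom),
#' where `p` is the alternative-allele frequency and `F` the inbreeding
#' coefficient: `F = 0` is exact HWE, `F > 0` a heterozygote deficit,
#' `F < 0` an excess.  `F` must keep all three probabilities non-negative.
#'
#' @param breed_label Breed name.
#' @param n_individuals Number of individuals (>= 1).
#' @param allele_freq_alt Alternative-allele frequency in `[0, 1]`; a named
#'   vector gives one frequency per marker.
#' @param inbreeding_f Inbreeding coefficient in `[-1, 1]` (recycled per
#'   marker like `allele_freq_alt`).
#' @param n_farms Number of farms; individuals are assigned uniformly.
#' @param seed Integer seed.
#' @return An object of class `cg_population_spec`.
#' @export
population_spec <- function(breed_label, n_individuals, allele_freq_alt,
                            inbreeding_f = 0, n_farms = 3L, seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  if (n_individuals < 1L) cg_abort("n_individuals must be >= 1", "parameter")
  if (any(allele_freq_alt < 0 | allele_freq_alt > 1)) {
    cg_abort("allele_freq_alt must lie in [0, 1]", "parameter")
  }
  if (any(inbreeding_f < -1 | inbreeding_f > 1)) {
    cg_abort("inbreeding_f must lie in [-1, 1]", "parameter")
  }
  structure(
    list(
      breed_label = breed_label, n_individuals = n_individuals,
      allele_freq_alt = allele_freq_alt, inbreeding_f = inbreeding_f,
      n_farms = as.integer(n_farms), seed = as.integer(seed)
    ),
    class = "cg_population_spec"
  )
}

# Genotype class probabilities (ref hom, het, alt hom) under inbreeding F.
genotype_probs <- function(p_alt, f) {
  q <- 1 - p_alt
  pr <- c(q^2 + f * p_alt * q, 2 * p_alt * q * (1 - f), p_alt^2 + f * p_alt * q)
  if (any(pr < -1e-12)) {
    cg_abort(sprintf(
      "inbreeding F = %g is infeasible for allele frequency p = %g", f, p_alt
    ), "parameter")
  }
  pr <- pmax(pr, 0)
  pr / sum(pr)
}

#' Simulate a diploid breed population
#'
#' Draws per-marker genotypes i.i.d. from the inbreeding-adjusted
#' Hardy-Weinberg class probabilities of [population_spec()], assigns each
#' individual uniformly to a farm, and labels genotypes with the assay's
#' conventions (e.g. `"TC"` heterozygotes for g.T61908C).
#'
#' @param spec A [population_spec()].
#' @param markers List of [marker_assay()] objects (named or not).
#' @return A data frame with columns `individual_id`, `breed`, `farm` and
#'   one genotype column per marker.
#' @export
simulate_population <- function(spec, markers) {
  stopifnot(inherits(spec, "cg_population_spec"))
  if (inherits(markers, "cg_marker_assay")) markers <- list(markers)
  if (length(markers) == 0L) cg_abort("marker list must be non-empty", "parameter")
  ids <- vapply(markers, function(a) a$marker_id, character(1))
  names(markers) <- ids

  p <- rep(spec$allele_freq_alt, length.out = length(markers))
  if (!is.null(names(spec$allele_freq_alt))) {
    missing <- setdiff(ids, names(spec$allele_freq_alt))
    if (length(missing)) {
      cg_abort(paste("no allele frequency for marker(s):",
                     paste(missing, collapse = ", ")), "parameter")
    }
    p <- spec$allele_freq_alt[ids]
  }
  f <- rep(spec$inbreeding_f, length.out = length(markers))

  with_seed(spec$seed, {
    n <- spec$n_individuals
    out <- data.frame(
      individual_id = sprintf("%s_%04d", spec$breed_label, seq_len(n)),
      breed = spec$breed_label,
      farm = sprintf("farm%d", sample.int(spec$n_farms, n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    for (i in seq_along(markers)) {
      a <- markers[[i]]
      labels <- unname(assay_genotypes(a))
      cls <- sample.int(3L, n, replace = TRUE, prob = genotype_probs(p[i], f[i]))
      out[[a$marker_id]] <- labels[cls]
    }
    out
  })
}

#' Specification of one synthetic trait
#'
#' Generating model for one body-measure trait:
#' `Y = mu + G(genotype) + F(farm) + B(breed) + e`, with fixed genotype,
#' farm and breed offsets and Gaussian residuals `e ~ N(0, sigma_e^2)` --
#' the same fixed-effects structure the association stage fits.
#'
#' @param trait_name One of `BM, BH, BL, CW, CCB, HIW, CG, WH` (body mass,
#'   body height, body length, chest width, cannon-bone circumference, hip
#'   width, chest girth, withers height), or any other trait label.
#' @param mu Overall mean (trait units: cm, or kg for BM).
#' @param marker Marker id whose genotype drives `genotype_effects`.
#' @param genotype_effects Named numeric map genotype -> offset; must cover
#'   every genotype class present in the data.
#' @param farm_effects,breed_effects Named numeric maps (missing levels
#'   default to 0).
#' @param sigma_e Residual standard deviation (> 0).
#' @return An object of class `cg_phenotype_spec`.
#' @export
phenotype_spec <- function(trait_name, mu, marker, genotype_effects,
                           farm_effects = numeric(0),
                           breed_effects = numeric(0), sigma_e = 1) {
  if (sigma_e <= 0) cg_abort("sigma_e must be > 0", "parameter")
  structure(
    list(
      trait_name = trait_name, mu = mu, marker = marker,
      genotype_effects = genotype_effects, farm_effects = farm_effects,
      breed_effects = breed_effects, sigma_e = sigma_e
    ),
    class = "cg_phenotype_spec"
  )
}

#' Simulate trait values onto a population
#'
#' Applies the generating model of [phenotype_spec()] to every individual.
#'
#' @param pop Population data frame from [simulate_population()].
#' @param spec A [phenotype_spec()] or a list of them (one trait column is
#'   added per spec).
#' @param seed Integer seed.
#' @return `pop` with one numeric column per trait.
#' @export
simulate_phenotypes <- function(pop, spec, seed = 1L) {
  specs <- if (inherits(spec, "cg_phenotype_spec")) list(spec) else spec
  with_seed(seed, {
    for (sp in specs) {
      stopifnot(inherits(sp, "cg_phenotype_spec"))
      geno <- pop[[sp$marker]]
      if (is.null(geno)) {
        cg_abort(sprintf("population has no genotype column '%s'", sp$marker), "data")
      }
      unknown <- setdiff(unique(geno), names(sp$genotype_effects))
      if (length(unknown)) {
        cg_abort(sprintf("no genotype effect defined for class(es): %s",
                         paste(unknown, collapse = ", ")), "data")
      }
      lookup <- function(map, keys) {
        v <- rep(0, length(keys))
        hit <- keys %in% names(map)
        v[hit] <- unname(map[keys[hit]])
        v
      }
      pop[[sp$trait_name]] <- sp$mu +
        unname(sp$genotype_effects[geno]) +
        lookup(sp$farm_effects, pop$farm) +
        lookup(sp$breed_effects, pop$breed) +
        stats::rnorm(nrow(pop), 0, sp$sigma_e)
    }
    pop
  })
}

#' Synthesize allele-specific haplotype references for an assay
#'
#' Builds two reference sequences (one per allele) on which the assay's
#' PCR-RFLP chain behaves exactly as declared: both primers match exactly
#' once, the cut allele's amplicon contains the enzyme's recognition site
#' exactly once at the offset implied by the declared fragment lengths, and
#' the uncut allele's amplicon (identical except at the SNP base) contains
#' none.  The background is uniform-random sequence, rejection-resampled to
#' remove accidental primer matches or recognition sites.
#'
#' @param assay A [marker_assay()].
#' @param flank_padding Random flank length added on each side of the
#'   amplicon.
#' @param seed Integer seed.
#' @return An object of class `cg_reference`: list with `marker_id`,
#'   `sequences` (named character vector, one reference per allele),
#'   `amplicon_start`, `amplicon_length`, `flank_padding`.
#' @export
synthesize_reference <- function(assay, flank_padding = 150L, seed = 1L) {
  stopifnot(inherits(assay, "cg_marker_assay"))
  flank_padding <- as.integer(flank_padding)
  enz <- assay$enzyme
  amp_len <- assay$amplicon_length
  fwd <- strsplit(assay$primers$forward_seq, "")[[1]]
  rc_rev <- strsplit(revcomp(assay$primers$reverse_seq), "")[[1]]
  site <- strsplit(enz$recognition, "")[[1]]
  rev_start <- amp_len - length(rc_rev) + 1L
  if (length(fwd) + length(rc_rev) > amp_len) {
    cg_abort("primers overlap inside the amplicon", "assay_definition")
  }
  snp <- assay$snp_offset
  if (snp <= length(fwd) || snp >= rev_start) {
    cg_abort("SNP falls inside a primer: allele-specific priming is not modelled",
             "assay_definition")
  }

  # Fixed positions of the cut-allele amplicon; conflicting constraints
  # (primer base vs recognition-site base) are an assay-definition error.
  fixed <- rep(NA_character_, amp_len)
  place <- function(chars, at) {
    idx <- seq(at, length.out = length(chars))
    clash <- !is.na(fixed[idx]) & fixed[idx] != chars
    if (any(clash)) {
      cg_abort("recognition site conflicts with a primer sequence", "assay_definition")
    }
    fixed[idx] <<- chars
    invisible(NULL)
  }
  place(fwd, 1L)
  place(rc_rev, rev_start)
  place(site, assay$site_start)

  bases <- c("A", "C", "G", "T")
  count_hits <- function(pat, subject) {
    Biostrings::countPattern(pat, Biostrings::DNAString(subject))
  }

  with_seed(seed, {
    free <- which(is.na(fixed))
    amp_cut <- NULL
    amp_uncut <- NULL
    for (try in seq_len(500L)) {
      cand <- fixed
      cand[free] <- sample(bases, length(free), replace = TRUE)
      cut_seq <- paste(cand, collapse = "")
      cand[snp] <- assay$uncut_allele
      uncut_seq <- paste(cand, collapse = "")
      ok <- count_hits(enz$recognition, cut_seq) == 1L &&
        count_hits(enz$recognition, uncut_seq) == 0L &&
        count_hits(assay$primers$forward_seq, cut_seq) == 1L &&
        count_hits(assay$primers$forward_seq, uncut_seq) == 1L &&
        count_hits(paste(rc_rev, collapse = ""), cut_seq) == 1L &&
        count_hits(paste(rc_rev, collapse = ""), uncut_seq) == 1L
      if (ok) {
        amp_cut <- cut_seq
        amp_uncut <- uncut_seq
        break
      }
    }
    if (is.null(amp_cut)) {
      cg_abort("could not realise an amplicon satisfying the assay constraints",
               "assay_definition")
    }

    refs <- NULL
    for (try in seq_len(500L)) {
      left <- paste(sample(bases, flank_padding, replace = TRUE), collapse = "")
      right <- paste(sample(bases, flank_padding, replace = TRUE), collapse = "")
      r_cut <- paste0(left, amp_cut, right)
      r_uncut <- paste0(left, amp_uncut, right)
      ok <- all(vapply(c(r_cut, r_uncut), function(r) {
        count_hits(assay$primers$forward_seq, r) == 1L &&
          count_hits(paste(rc_rev, collapse = ""), r) == 1L
      }, logical(1)))
      if (ok) {
        refs <- c(r_cut, r_uncut)
        names(refs) <- c(assay$cut_allele, assay$uncut_allele)
        break
      }
    }
    if (is.null(refs)) {
      cg_abort("could not realise flanks free of spurious primer matches",
               "assay_definition")
    }
    structure(
      list(
        marker_id = assay$marker_id,
        sequences = refs,
        amplicon_start = flank_padding + 1L,
        amplicon_length = amp_len,
        flank_padding = flank_padding
      ),
      class = "cg_reference"
    )
  })
}

#' Default synthetic study design
#'
#' Population specifications mirroring the genotyped panel: the four breeds
#' at their published sample sizes, with per-marker alternative-allele
#' frequencies set to the published breed frequencies ([study_breeds()]),
#' no inbreeding, and three farms per breed.
#'
#' @param seed Integer seed; each breed gets a sub-seed derived from it.
#' @return Named list of [population_spec()] objects.
#' @export
study_population_specs <- function(seed = 1L) {
  sb <- study_breeds()
  marker_ids <- setdiff(names(sb), c("breed", "n"))
  specs <- lapply(seq_len(nrow(sb)), function(i) {
    freqs <- unlist(sb[i, marker_ids])
    population_spec(
      breed_label = sb$breed[i],
      n_individuals = sb$n[i],
      allele_freq_alt = freqs,
      inbreeding_f = 0,
      n_farms = 3L,
      seed = as.integer(seed) + i
    )
  })
  names(specs) <- sb$breed
  specs
}

#' Default synthetic trait models
#'
#' One [phenotype_spec()] per body-measure trait at realistic scales for
#' two-year-old cattle (BM in kg, all others in cm).  By default all
#' genotype effects are zero (a null model); `effects` overrides the
#' genotype-effect map of selected traits, e.g.
#' `list(BH = c(CC = 0, TC = 3, TT = 3))`.
#'
#' @param marker Marker id driving genotype effects.
#' @param effects Optional named list of genotype-effect maps per trait.
#' @return Named list of [phenotype_spec()] objects.
#' @export
default_phenotype_specs <- function(marker = "g.T62131C", effects = list()) {
  scales <- list(  # trait = c(mu, sigma_e)
    BM = c(250, 30), BH = c(128, 6.5), BL = c(86, 8), CW = c(38, 4.5),
    CCB = c(15, 1.3), HIW = c(42, 5), CG = c(145, 9), WH = c(127, 7.5)
  )
  farm_eff <- c(farm1 = 0, farm2 = 0.4, farm3 = -0.4)
  genotypes <- c("CC", "TC", "TT", "CT")
  null_eff <- stats::setNames(rep(0, length(genotypes)), genotypes)
  specs <- lapply(names(scales), function(tr) {
    ge <- if (!is.null(effects[[tr]])) effects[[tr]] else null_eff
    phenotype_spec(
      trait_name = tr, mu = scales[[tr]][1], marker = marker,
      genotype_effects = ge,
      farm_effects = farm_eff * scales[[tr]][2],
      sigma_e = scales[[tr]][2]
    )
  })
  names(specs) <- names(scales)
  specs
}

#' Simulate a qPCR cycle-threshold table
#'
#' Emulates the expression-profiling design: seven tissues at two
#' developmental stages, a handful of biological replicates each, a target
#' and a reference gene, technical-triplicate Ct values.  The built-in
#' tissue pattern has the target most abundant in fetal liver and adult
#' kidney and nearly absent in adult heart and muscle; the reference gene
#' is stable across tissues.
#'
#' @param seed Integer seed.
#' @param n_biological Biological replicates per tissue x stage.
#' @param target,reference Gene labels.
#' @param ct_sd_technical,ct_sd_biological Ct noise standard deviations.
#' @return Data frame with columns `sample_id`, `tissue`, `stage`, `gene`,
#'   `ct_rep1`, `ct_rep2`, `ct_rep3`.
#' @export
simulate_ct_table <- function(seed = 1L, n_biological = 3L,
                              target = "KAT2B", reference = "beta_actin",
                              ct_sd_technical = 0.15, ct_sd_biological = 0.3) {
  # log2 fold change of the target relative to fetal heart (the calibrator)
  lfc <- rbind(
    fetal = c(heart = 0, spleen = 2.2, lung = 1.0, kidney = 1.5,
              muscle = 1.8, liver = 3.0, adipose = -1.0),
    adult = c(heart = -3.5, spleen = 2.5, lung = 0.8, kidney = 3.3,
              muscle = -3.2, liver = 1.4, adipose = 2.8)
  )
  ref_ct_mean <- 18
  calib_delta_ct <- 8  # target trails the reference gene by 8 cycles in the calibrator
  with_seed(seed, {
    rows <- list()
    for (stage in rownames(lfc)) {
      for (tissue in colnames(lfc)) {
        for (b in seq_len(n_biological)) {
          sample_id <- sprintf("%s_%s_%d", stage, tissue, b)
          bio_shift <- stats::rnorm(1, 0, ct_sd_biological)
          ref_ct <- ref_ct_mean + stats::rnorm(1, 0, ct_sd_biological)
          dct <- calib_delta_ct - lfc[stage, tissue] + bio_shift
          for (gene in c(target, reference)) {
            centre <- if (gene == target) ref_ct + dct else ref_ct
            cts <- centre + stats::rnorm(3, 0, ct_sd_technical)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sample_id, tissue = tissue, stage = stage,
              gene = gene, ct_rep1 = cts[1], ct_rep2 = cts[2], ct_rep3 = cts[3],
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a population table to CSV
#'
#' @param pop Population data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population table from CSV
#'
#' @param path CSV written by [write_population_csv()].
#' @return Data frame.
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write haplotype references as FASTA
#'
#' @param reference A `cg_reference` from [synthesize_reference()], or a
#'   list of them.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  refs <- if (inherits(reference, "cg_reference")) list(reference) else reference
  seqs <- do.call(c, unname(lapply(refs, function(r) {
    stats::setNames(r$sequences, paste0(r$marker_id, "_", names(r$sequences)))
  })))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
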