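#' Pipeline configuration
#'
#' Collects everything the end-to-end pipeline needs.  With no arguments
#' this is the bundled demo design: the four study breeds at their
#' published sample sizes and allele frequencies, the three KAT2B assays,
#' null trait models plus a genotype effect on CCB, and a simulated
#' expression profile.
#'
#' @param assays Named list of [marker_assay()] objects.
#' @param population_specs Named list of [population_spec()] objects, or
#'   `NULL` to build [study_population_specs()] from the run seed.
#' @param phenotype_effects Named list of genotype-effect maps passed to
#'   [default_phenotype_specs()].
#' @param effect_marker Marker whose genotype drives the phenotype effects.
#' @param population_csv Optional path to an existing population table; when
#'   given, simulation is skipped and the file must exist.
#' @param ct_csv Optional path to an existing Ct table.
#' @param with_expression Run the expression stage (default `TRUE`).
#' @param per_breed,hwe_correction,alpha Analysis options.
#' @param flank_padding Reference flank length for [synthesize_reference()].
#' @return An object of class `cg_pipeline_config`.
#' @export
pipeline_config <- function(assays = kat2b_assays(),
                            population_specs = NULL,
                            phenotype_effects = list(CCB = c(CC = 0, TC = 0, TT = 0.8, CT = 0)),
                            effect_marker = "g.T62131C",
                            population_csv = NULL,
                            ct_csv = NULL,
                            with_expression = TRUE,
                            per_breed = TRUE,
                            hwe_correction = FALSE,
                            alpha = c(0.05, 0.01),
                            flank_padding = 150L) {
  if (any(alpha <= 0 | alpha >= 1)) cg_abort("alpha levels must be in (0, 1)", "configuration")
  structure(
    list(
      assays = assays, population_specs = population_specs,
      phenotype_effects = phenotype_effects, effect_marker = effect_marker,
      population_csv = population_csv, ct_csv = ct_csv,
      with_expression = with_expression, per_breed = per_breed,
      hwe_correction = hwe_correction, alpha = alpha,
      flank_padding = as.integer(flank_padding)
    ),
    class = "cg_pipeline_config"
  )
}

#' Run the full pipeline
#'
#' simulate (or ingest) -> in-silico PCR-RFLP genotyping -> diversity
#' statistics -> association analysis -> expression profiling, writing all
#' tables plus a run manifest under `out_dir`.  Deterministic: the same
#' config and seed give byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @return Invisibly, a list with the in-memory results (`population`,
#'   `diversity`, `association`, `expression`) and `paths` of the files
#'   written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  stopifnot(inherits(config, "cg_pipeline_config"))
  seed <- as.integer(seed)
  for (p in c(config$population_csv, config$ct_csv)) {
    if (!is.null(p) && !file.exists(p)) {
      cg_abort(sprintf("configuration error: input file '%s' does not exist", p),
               "configuration")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  assays <- config$assays

  # --- stage 1: population (simulate or ingest) -------------------------
  if (!is.null(config$population_csv)) {
    pop <- read_population_csv(config$population_csv)
    message(sprintf("[simulate] ingested %d individuals from %s",
                    nrow(pop), config$population_csv))
  } else {
    specs <- config$population_specs %||% study_population_specs(seed)
    pop <- do.call(rbind, lapply(specs, simulate_population, markers = assays))
    rownames(pop) <- NULL
    ph_specs <- default_phenotype_specs(marker = config$effect_marker,
                                        effects = config$phenotype_effects)
    pop <- simulate_phenotypes(pop, ph_specs, seed = seed + 1000L)
    message(sprintf("[simulate] %d individuals across %d breeds",
                    nrow(pop), length(specs)))
  }

  # --- stage 2: in-silico PCR-RFLP genotyping ---------------------------
  refs <- lapply(assays, synthesize_reference,
                 flank_padding = config$flank_padding, seed = seed + 2000L)
  references <- lapply(refs, function(r) r$sequences)
  pop <- rflp_genotype_population(pop, assays, references)
  mismatch <- 0L
  for (mid in names(assays)) {
    mismatch <- mismatch + sum(pop[[mid]] != pop[[paste0(mid, "_rflp")]])
  }
  message(sprintf("[rflp] genotyped %d individuals x %d markers (%d call mismatches)",
                  nrow(pop), length(assays), mismatch))
  paths$references <- file.path(out_dir, "references.fa")
  write_reference_fasta(refs, paths$references)
  paths$genotypes <- file.path(out_dir, "genotypes.csv")
  write_population_csv(pop, paths$genotypes)
  paths$vcf <- file.path(out_dir, "genotypes.vcf")
  write_genotypes_vcf(pop, assays, paths$vcf)

  # --- stage 3: diversity statistics ------------------------------------
  div <- diversity_table(pop, assays, by = "breed",
                         correction = config$hwe_correction)
  message(sprintf("[popgen] %d marker x breed diversity rows", nrow(div)))
  paths$diversity <- file.path(out_dir, "table2_diversity.csv")
  utils::write.csv(render_diversity_table(div), paths$diversity,
                   row.names = FALSE, quote = FALSE)

  # --- stage 4: association analysis ------------------------------------
  traits <- intersect(c("BM", "BH", "BL", "CW", "CCB", "HIW", "CG", "WH"), names(pop))
  assoc <- NULL
  if (length(traits)) {
    assoc <- withCallingHandlers(
      association_table(pop, assays, traits, per_breed = config$per_breed,
                        alpha = config$alpha),
      cgassoc_dropped_class = function(w) {
        message("[assoc] ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    message(sprintf("[assoc] %d marker x breed x trait rows, %d flagged at alpha = %g",
                    nrow(unique(assoc[, c("marker", "breed", "trait")])),
                    sum(unique(assoc[, c("marker", "breed", "trait", "significant")])$significant),
                    config$alpha[1]))
    paths$association <- file.path(out_dir, "table3_association.csv")
    utils::write.csv(render_association_table(assoc), paths$association,
                     row.names = FALSE, quote = FALSE)
  }

  # --- stage 5: expression ----------------------------------------------
  rex <- NULL
  if (isTRUE(config$with_expression)) {
    ct <- if (!is.null(config$ct_csv)) {
      utils::read.csv(config$ct_csv, stringsAsFactors = FALSE)
    } else {
      simulate_ct_table(seed = seed + 3000L)
    }
    rex <- relative_expression(ct, "KAT2B", "beta_actin", c("heart", "fetal"))
    message(sprintf("[expr] %d tissue x stage groups quantified", nrow(rex$groups)))
    paths$expression <- file.path(out_dir, "expression.csv")
    utils::write.csv(rex$groups, paths$expression, row.names = FALSE, quote = FALSE)
  }

  # --- manifest ----------------------------------------------------------
  manifest <- run_manifest(config, seed, paths)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(population = pop, diversity = div, association = assoc,
                 expression = rex, paths = paths))
}

run_manifest <- function(config, seed, paths) {
  cfg_json <- jsonlite::toJSON(
    list(
      assays = names(config$assays),
      per_breed = config$per_breed, hwe_correction = config$hwe_correction,
      alpha = config$alpha, with_expression = config$with_expression,
      effect_marker = config$effect_marker,
      flank_padding = config$flank_padding
    ),
    auto_unbox = TRUE
  )
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  out_files <- unlist(paths)
  list(
    tool = "cgassoc",
    version = as.character(utils::packageVersion("cgassoc")),
    seed = seed,
    config_hash = cfg_hash,
    output_checksums = as.list(tools::md5sum(out_files[file.exists(out_files)])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Render a diversity table for reporting
#'
#' Two-decimal, half-up rounding of the diversity statistics at the
#' reporting layer (full precision is kept upstream), with the HWE verdict
#' in the published categorical style.
#'
#' @param div Result of [diversity_table()].
#' @return Data frame ready for CSV export.
#' @export
render_diversity_table <- function(div) {
  if (nrow(div) == 0L) return(div)
  data.frame(
    marker = div$marker, breed = div$breed, n = div$n,
    genotypes = div$genotypes, genotype_freqs = div$genotype_freqs,
    alleles = div$alleles, allele_freqs = div$allele_freqs,
    hwe_chi2 = round_half_up(div$hwe_chi2, 2),
    hwe = ifelse(div$hwe_p < 0.01, "p<0.01",
                 ifelse(div$hwe_p < 0.05, "p<0.05", "p>0.05")),
    pic = sprintf("%.2f", round_half_up(div$pic, 2)),
    he = sprintf("%.2f", round_half_up(div$he, 2)),
    ne = sprintf("%.2f", round_half_up(div$ne, 2)),
    class = div$diversity_class,
    stringsAsFactors = FALSE
  )
}

#' Render an association table for reporting
#'
#' LS means +- SE at two decimals with the Duncan letters as plain suffix
#' columns (`letters_05`, `letters_01`), one row per genotype.
#'
#' @param assoc Result of [association_table()].
#' @return Data frame ready for CSV export.
#' @export
render_association_table <- function(assoc) {
  if (is.null(assoc) || nrow(assoc) == 0L) return(assoc)
  data.frame(
    marker = assoc$marker, breed = assoc$breed, trait = assoc$trait,
    genotype = assoc$genotype, n = assoc$n,
    lsmean = sprintf("%.2f", round_half_up(assoc$lsmean, 2)),
    se = sprintf("%.2f", round_half_up(assoc$se, 2)),
    letters_05 = assoc$letters_05, letters_01 = assoc$letters_01,
    p_genotype = signif(assoc$p_genotype, 3),
    significant = assoc$significant,
    stringsAsFactors = FALSE
  )
}

#' Export called genotypes as a minimal VCF
#'
#' One record per marker (GT field only), with the marker id's first allele
#' as REF.  Positions are the assay's SNP coordinates on its reference
#' accession; the contig is reported as the assay's amplicon coordinate
#' system.
#'
#' @param pop Genotyped population data frame.
#' @param assays Named list of [marker_assay()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(pop, assays, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=cgassoc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            pop$individual_id), collapse = "\t")
  ), con)
  for (a in assays) {
    ref <- a$allele_order[1]
    alt <- a$allele_order[2]
    pos <- a$primers$forward_span[1] + a$snp_offset - 1L
    gt <- vapply(pop[[a$marker_id]], function(g) {
      n_alt <- sum(strsplit(g, "")[[1]] == alt)
      c("0/0", "0/1", "1/1")[n_alt + 1L]
    }, character(1), USE.NAMES = FALSE)
    writeLines(paste(c("AC_000158.1", pos, a$marker_id, ref, alt, ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
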