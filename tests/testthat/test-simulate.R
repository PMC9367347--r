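test_that("genotype draws converge to the inbreeding-adjusted HW proportions", {
  assay <- kat2b_assays()$g.T62131C
  spec <- population_spec("Sim", 1e5, allele_freq_alt = 0.5, seed = 21)
  pop <- simulate_population(spec, list(assay))
  freqs <- table(pop$g.T62131C) / nrow(pop)
  expected <- c(CC = 0.25, TC = 0.5, TT = 0.25)
  for (g in names(expected)) {
    se <- sqrt(expected[g] * (1 - expected[g]) / 1e5)
    expect_lt(abs(freqs[[g]] - expected[[g]]), 3 * se)
  }

  # class probabilities sum to 1 over a grid of feasible (p, F)
  for (p in c(0.1, 0.3, 0.5, 0.9)) {
    for (f in c(-0.1, 0, 0.3, 0.8)) {
      pr <- cgassoc:::genotype_probs(p, f)
      expect_equal(sum(pr), 1)
      expect_true(all(pr >= 0))
    }
  }
})

test_that("degenerate and infeasible parameter cases behave", {
  assay <- kat2b_assays()$g.T62131C
  fixed <- simulate_population(population_spec("Fix", 50, 1.0, seed = 3), list(assay))
  expect_true(all(fixed$g.T62131C == "CC"))  # C is the alt allele here
  # at p = 0.2, F < -p/q = -0.25 drives the alt-homozygote class negative
  expect_error(
    simulate_population(population_spec("Bad", 10, 0.2, inbreeding_f = -0.9, seed = 1),
                        list(assay)),
    class = "cgassoc_parameter"
  )
})

test_that("same seed gives bit-identical populations, phenotypes and references", {
  assays <- kat2b_assays()
  spec <- population_spec("Rep", 200, c(g.T61908C = 0.4, g.T62131C = 0.6, g.C73406T = 0.3),
                          seed = 99)
  p1 <- simulate_population(spec, assays)
  p2 <- simulate_population(spec, assays)
  expect_identical(p1, p2)

  ph <- phenotype_spec("BM", 250, "g.T61908C", c(CC = 0, TC = 2, TT = 4), sigma_e = 30)
  expect_identical(simulate_phenotypes(p1, ph, seed = 5),
                   simulate_phenotypes(p2, ph, seed = 5))

  r1 <- synthesize_reference(assays$g.T61908C, seed = 12)
  r2 <- synthesize_reference(assays$g.T61908C, seed = 12)
  expect_identical(r1, r2)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(2024)
  before <- .Random.seed
  invisible(simulate_population(population_spec("S", 10, 0.5, seed = 1),
                                list(kat2b_assays()$g.T61908C)))
  expect_identical(.Random.seed, before)
})

test_that("phenotypes follow Y = mu + G + F + B + e", {
  assay <- kat2b_assays()$g.T61908C
  pop <- simulate_population(population_spec("P", 600, 0.5, seed = 8), list(assay))
  # noise-free limit: group means sit at mu + effect
  ph <- phenotype_spec("BL", 86, "g.T61908C", c(TT = 0, TC = 5, CC = 10),
                       sigma_e = 1e-8)
  sim <- simulate_phenotypes(pop, ph, seed = 9)
  mm <- tapply(sim$BL, sim$g.T61908C, mean)
  expect_lt(abs(mm[["TT"]] - 86), 0.1)
  expect_lt(abs(mm[["TC"]] - 91), 0.1)
  expect_lt(abs(mm[["CC"]] - 96), 0.1)

  # null model: i.i.d. Gaussian(mu, sigma^2)
  ph0 <- phenotype_spec("WH", 127, "g.T61908C", c(TT = 0, TC = 0, CC = 0), sigma_e = 4)
  sim0 <- simulate_phenotypes(pop, ph0, seed = 10)
  expect_lt(abs(mean(sim0$WH) - 127), 3 * 4 / sqrt(600))
  expect_lt(abs(sd(sim0$WH) - 4), 0.5)

  expect_error(
    simulate_phenotypes(pop, phenotype_spec("X", 0, "g.T61908C", c(TT = 0), sigma_e = 1)),
    class = "cgassoc_data"
  )
})

test_that("a strong heterozygote deficit is detected by the HWE test in most samples", {
  # allele frequency 0.84 with F tuned so class probabilities are near
  # (0.80, 0.10, 0.10); at n = 48 the chi-square test should reject at 0.01
  # in the clear majority of replicates
  p <- 0.84
  f <- 1 - 0.10 / (2 * p * (1 - p))
  assay <- kat2b_assays()$g.T62131C
  reject <- vapply(1:400, function(i) {
    pop <- simulate_population(
      population_spec("Yk", 48, p, inbreeding_f = f, seed = 10000 + i),
      list(assay)
    )
    tab <- table(factor(pop$g.T62131C, levels = c("CC", "TC", "TT")))
    cnt <- setNames(as.integer(tab), names(tab))[tab > 0]
    if (length(unique(unlist(strsplit(names(cnt), "")))) < 2) return(NA)
    hwe_chi_square(cnt)$p < 0.01
  }, logical(1))
  expect_gt(mean(reject, na.rm = TRUE), 0.5)
})

test_that("synthesized references satisfy the assay's digestion contract", {
  assays <- kat2b_assays()
  expected <- list(
    g.T61908C = c(57L, 21L),
    g.T62131C = c(191L, 27L),
    g.C73406T = c(287L, 27L)
  )
  for (mid in names(assays)) {
    a <- assays[[mid]]
    ref <- synthesize_reference(a, seed = 31)
    cut_amp <- find_amplicon(ref$sequences[[a$cut_allele]], a$primers)
    uncut_amp <- find_amplicon(ref$sequences[[a$uncut_allele]], a$primers)
    expect_identical(nchar(cut_amp$seq), a$amplicon_length)
    expect_identical(nchar(uncut_amp$seq), a$amplicon_length)
    expect_identical(unclass(digest(cut_amp$seq, a$enzyme)), expected[[mid]])
    expect_identical(unclass(digest(uncut_amp$seq, a$enzyme)), a$amplicon_length)
  }
})

test_that("population and reference writers round-trip", {
  assays <- kat2b_assays()
  pop <- simulate_population(population_spec("IO", 20, 0.5, seed = 2), assays)
  csv <- tempfile(fileext = ".csv")
  write_population_csv(pop, csv)
  expect_identical(read_population_csv(csv), pop)

  fa <- tempfile(fileext = ".fa")
  ref <- synthesize_reference(assays$g.T61908C, seed = 4)
  write_reference_fasta(ref, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back[["g.T61908C_T"]]),
                   unname(ref$sequences[["T"]]))
})
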