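test_that("allele frequencies are allele-copy proportions", {
  expect_equal(allele_frequencies(c(CC = 25, TC = 50, TT = 25)),
               c(C = 0.5, T = 0.5))
  expect_equal(allele_frequencies(c(CC = 100, TC = 0, TT = 0)),
               c(C = 1, T = 0))
  expect_equal(allele_frequencies(c(CC = 38, TC = 5, TT = 5)),
               c(C = 0.84375, T = 0.15625))
  expect_error(genotype_counts(c(CC = 0, TT = 0)), class = "cgassoc_empty_sample")
})

test_that("He, Ne and PIC follow the Nei/Botstein formulas", {
  expect_equal(gene_heterozygosity(c(0.51, 0.49)), 0.4998)
  expect_equal(gene_heterozygosity(1), 0)
  expect_equal(gene_heterozygosity(c(0.84, 0.16)), 0.2688)
  expect_equal(effective_allele_number(c(0.43, 0.57)), 1 / (0.43^2 + 0.57^2))
  expect_equal(effective_allele_number(1), 1)
  expect_equal(as.numeric(pic(c(0.5, 0.5))), 0.375)
  # biallelic identity PIC = He - 2 p^2 q^2
  for (p in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(as.numeric(pic(c(p, 1 - p))),
                 gene_heterozygosity(c(p, 1 - p)) - 2 * p^2 * (1 - p)^2)
  }
  expect_identical(attr(pic(c(0.43, 0.57)), "class_label"), "mid")
  expect_identical(attr(pic(c(0.84, 0.16)), "class_label"), "low")
  expect_identical(diversity_class(c(0.1, 0.3, 0.6)), c("low", "mid", "high"))
})

test_that("diversity identities and relabelling invariance hold", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    p <- as.numeric(rmultinom(1, 1000, rep(1, k))) / 1000
    p <- p[p > 0]
    he <- gene_heterozygosity(p)
    expect_equal(he + sum(p^2), 1)
    expect_equal(effective_allele_number(p) * sum(p^2), 1)
    v <- as.numeric(pic(p))
    expect_gte(v, 0)
    expect_lte(v, he + 1e-12)
    # invariance under allele relabelling
    expect_equal(as.numeric(pic(rev(p))), v)
  }
  # PIC = He only when at most one allele segregates
  expect_equal(as.numeric(pic(1)), gene_heterozygosity(1))
})

test_that("HWE chi-square matches hand computation and closed forms", {
  res0 <- hwe_chi_square(c(CC = 25, TC = 50, TT = 25))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  # hand oracle: counts (30, 40, 30), p = q = 0.5, E = (25, 50, 25)
  res <- hwe_chi_square(c(CC = 30, TC = 40, TT = 30))
  expect_equal(res$chi2, 4)
  expect_identical(res$df, 1)
  expect_equal(res$p, pchisq(4, 1, lower.tail = FALSE))
  # strong heterozygote deficit is called far from equilibrium
  expect_lt(hwe_chi_square(c(CC = 38, TC = 5, TT = 5))$p, 0.01)
  # chi2 is invariant under allele relabelling
  a <- hwe_chi_square(c(CC = 30, TC = 40, TT = 30))
  b <- hwe_chi_square(c(TT = 30, TC = 40, CC = 30))
  expect_equal(a$chi2, b$chi2)
  # Yates correction shrinks the statistic
  expect_lt(hwe_chi_square(c(CC = 31, TC = 24, TT = 14), correction = TRUE)$chi2,
            hwe_chi_square(c(CC = 31, TC = 24, TT = 14))$chi2)
})

test_that("chi2 is zero iff counts sit exactly at HW proportions", {
  set.seed(31)
  for (i in 1:10) {
    nc <- sample(5:40, 1); nt <- sample(5:40, 1)
    cnt <- c(CC = nc^2, CT = 2 * nc * nt, TT = nt^2)
    expect_equal(hwe_chi_square(cnt)$chi2, 0)
    cnt["CT"] <- cnt["CT"] + 4
    expect_gt(hwe_chi_square(cnt)$chi2, 0)
  }
})

test_that("count reconstruction from rounded frequencies sums to n", {
  cnt <- counts_from_frequencies(c(CC = 0.23, CT = 0.55, TT = 0.21), 69)
  expect_identical(sum(cnt), 69L)
  expect_identical(cnt, c(CC = 16L, CT = 39L, TT = 14L))
})

test_that("published diversity rows are reproduced at 2-decimal rounding", {
  rep_tab <- reported_diversity()
  expect_identical(nrow(rep_tab), 12L)
  for (i in seq_len(nrow(rep_tab))) {
    p <- c(rep_tab$allele1_freq[i], rep_tab$allele2_freq[i])
    expect_equal(round_half_up(gene_heterozygosity(p), 2), rep_tab$he[i],
                 label = sprintf("He row %d", i))
    expect_equal(round_half_up(effective_allele_number(p), 2), rep_tab$ne[i],
                 label = sprintf("Ne row %d", i))
    expect_equal(round_half_up(as.numeric(pic(p)), 2), rep_tab$pic[i],
                 label = sprintf("PIC row %d", i))
  }
})

test_that("diversity_table produces one coherent row per marker x breed", {
  assays <- kat2b_assays()
  specs <- study_population_specs(seed = 5)
  specs <- specs[c("Yak", "Chaidam")]  # small breeds keep this quick
  pop <- do.call(rbind, lapply(specs, simulate_population, markers = assays))
  div <- diversity_table(pop, assays, by = "breed")
  expect_identical(nrow(div), 6L)
  expect_true(all(div$pic <= div$he + 1e-12))
  expect_equal(div$ne, 1 / (1 - div$he))
  expect_true(all(div$hwe_p >= 0 & div$hwe_p <= 1))
  rendered <- render_diversity_table(div)
  expect_identical(nrow(rendered), 6L)
  expect_match(rendered$hwe, "^p[<>]0\\.0[15]$")
})

test_that("half-up rounding differs from banker's rounding where it should", {
  expect_equal(round_half_up(0.375, 2), 0.38)
  expect_equal(round_half_up(-0.375, 2), -0.38)
  expect_equal(round_half_up(1.005, 2), 1.01)
})
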