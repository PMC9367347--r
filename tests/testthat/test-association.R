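make_oneway <- function(means, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  data.frame(
    geno = rep(names(means), each = n_per),
    farm = "farm1",
    y = rnorm(n_per * length(means), rep(unlist(means), each = n_per), sd),
    stringsAsFactors = FALSE
  )
}

test_that("balanced one-way LS means equal arithmetic group means", {
  d <- make_oneway(c(CC = 10, TC = 12, TT = 15), 30, sd = 2, seed = 4)
  fit <- fit_fixed_effects(d, "y", "geno")
  gm <- tapply(d$y, d$geno, mean)
  expect_equal(fit$ls_means$lsmean, as.numeric(gm[fit$ls_means$genotype]))
  expect_equal(fit$ls_means$se,
               rep(sqrt(fit$residual_ms / 30), 3))
  expect_identical(fit$residual_df, 87L)
})

test_that("LS means with covariates match emmeans", {
  skip_if_not_installed("emmeans")
  assay <- kat2b_assays()$g.T62131C
  pop <- simulate_population(population_spec("E", 150, 0.4, n_farms = 3, seed = 6),
                             list(assay))
  ph <- phenotype_spec("CW", 38, "g.T62131C", c(CC = 0, TC = 1, TT = 2),
                       farm_effects = c(farm1 = -2, farm2 = 0, farm3 = 2),
                       sigma_e = 3)
  pop <- simulate_phenotypes(pop, ph, seed = 7)
  fit <- fit_fixed_effects(pop, "CW", "g.T62131C", fixed_terms = "farm")
  lmfit <- lm(CW ~ g.T62131C + farm, data = pop)
  em <- as.data.frame(emmeans::emmeans(lmfit, "g.T62131C"))
  expect_equal(fit$ls_means$lsmean, em$emmean, tolerance = 1e-10)
  expect_equal(fit$ls_means$se, em$SE, tolerance = 1e-10)
})

test_that("simulated genotype effects are recovered within 3 SE", {
  assay <- kat2b_assays()$g.T62131C
  pop <- simulate_population(population_spec("R", 300, 0.5, seed = 14), list(assay))
  ph <- phenotype_spec("BH", 128, "g.T62131C", c(CC = 0, TC = 5, TT = 10), sigma_e = 1)
  pop <- simulate_phenotypes(pop, ph, seed = 15)
  fit <- fit_fixed_effects(pop, "BH", "g.T62131C", fixed_terms = "farm")
  lsm <- setNames(fit$ls_means$lsmean, fit$ls_means$genotype)
  se <- setNames(fit$ls_means$se, fit$ls_means$genotype)
  expect_lt(abs((lsm["TC"] - lsm["CC"]) - 5), 3 * sqrt(se["TC"]^2 + se["CC"]^2))
  expect_lt(abs((lsm["TT"] - lsm["CC"]) - 10), 3 * sqrt(se["TT"]^2 + se["CC"]^2))
})

test_that("degenerate fits are flagged or rejected", {
  d <- make_oneway(c(CC = 5, TT = 5), 10, sd = 1, seed = 2)
  d$y <- 7  # constant response
  fit <- fit_fixed_effects(d, "y", "geno")
  expect_true(fit$saturated)
  expect_equal(fit$residual_ms, 0)
  expect_equal(fit$ls_means$lsmean, c(7, 7))
  lets <- duncan_groups(fit)
  expect_identical(unname(lets), c("a", "a"))

  d2 <- data.frame(geno = c("CC", "TT"), farm = "f1", y = c(1, 2))
  expect_error(fit_fixed_effects(d2, "y", "geno"), class = "cgassoc_saturation")
})

test_that("Duncan letters: identical means share, separated means split", {
  expect_identical(
    duncan_from_summary(c(A = 10, B = 10), n = c(20, 20), ms = 4, df = 38),
    c(A = "a", B = "a")
  )
  expect_identical(
    duncan_from_summary(c(lo = 0, mid = 50, hi = 100), n = c(20, 20, 20),
                        ms = 1, df = 57),
    c(lo = "c", mid = "b", hi = "a")
  )
  # single group: no letters
  expect_identical(duncan_from_summary(c(CC = 5), n = 9, ms = 1, df = 8),
                   c(CC = ""))
})

test_that("two-group Duncan coincides with the t-test on the mean difference", {
  # identity q(alpha, 2, df) = t(alpha/2, df) * sqrt(2), checked both as a
  # numeric identity and as decision agreement on simulated fits
  for (df in c(3, 8, 20, 45, 120)) {
    for (a in c(0.01, 0.05, 0.10)) {
      expect_equal(studentized_range_q(1 - a, 2, df), qt(1 - a / 2, df) * sqrt(2),
                   tolerance = 1e-6)
    }
  }
  set.seed(55)
  agree <- vapply(1:60, function(i) {
    delta <- runif(1, 0, 1.5)
    d <- make_oneway(c(CC = 0, TT = delta), n_per = sample(8:25, 1), sd = 1,
                     seed = 1000 + i)
    fit <- fit_fixed_effects(d, "y", "geno")
    lets <- duncan_groups(fit, alpha = 0.05)
    duncan_sep <- lets[["CC"]] != lets[["TT"]]
    tt <- t.test(y ~ geno, data = d, var.equal = TRUE)
    duncan_sep == (tt$p.value < 0.05)
  }, logical(1))
  expect_true(all(agree))
})

test_that("letters at 0.01 are never finer than at 0.05", {
  set.seed(91)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    means <- setNames(cumsum(runif(k, 0, 2)), paste0("g", seq_len(k)))
    n <- sample(5:30, k, replace = TRUE)
    ms <- runif(1, 0.5, 4)
    df <- sum(n) - k
    l05 <- duncan_from_summary(means, n, ms, df, alpha = 0.05)
    l01 <- duncan_from_summary(means, n, ms, df, alpha = 0.01)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        share05 <- length(intersect(strsplit(l05[a], "")[[1]],
                                    strsplit(l05[b], "")[[1]])) > 0
        share01 <- length(intersect(strsplit(l01[a], "")[[1]],
                                    strsplit(l01[b], "")[[1]])) > 0
        # separated at 0.01 implies separated at 0.05
        if (!share01) expect_false(share05)
      }
    }
  }
})

test_that("fit is invariant to genotype label permutation up to relabelling", {
  d <- make_oneway(c(AA = 3, AB = 5, BB = 6), 15, sd = 1.5, seed = 33)
  fit1 <- fit_fixed_effects(d, "y", "geno")
  d2 <- d
  d2$geno <- chartr("AB", "BA", d$geno)  # AA<->BB, AB->BA
  d2$geno[d2$geno == "BA"] <- "AB"
  fit2 <- fit_fixed_effects(d2, "y", "geno")
  m1 <- setNames(fit1$ls_means$lsmean, fit1$ls_means$genotype)
  m2 <- setNames(fit2$ls_means$lsmean, fit2$ls_means$genotype)
  expect_equal(unname(m1[c("AA", "AB", "BB")]), unname(m2[c("BB", "AB", "AA")]))
  expect_equal(fit1$residual_ms, fit2$residual_ms)
})

test_that("association_table assembles rows, flags, and handles missing classes", {
  assays <- kat2b_assays()
  pop <- simulate_population(population_spec("A", 200, 0.5, seed = 61),
                             assays["g.T62131C"])
  specs <- default_phenotype_specs(marker = "g.T62131C",
                                   effects = list(CCB = c(CC = 0, TC = 0, TT = 8, CT = 0)))
  # sigma for CCB default is 1.3 but the effect is 8: overwhelming signal
  pop <- simulate_phenotypes(pop, specs[c("CCB", "WH")], seed = 62)
  tab <- association_table(pop, "g.T62131C", c("CCB", "WH"))
  expect_identical(sort(unique(tab$trait)), c("CCB", "WH"))
  ccb <- tab[tab$trait == "CCB", ]
  expect_true(all(ccb$significant))
  expect_false(grepl("a", ccb$letters_05[ccb$genotype == "TT"]) &&
                 grepl("a", ccb$letters_05[ccb$genotype == "CC"]))

  # genotype class absent in a subgroup: dropped with a warning, row still emitted
  sub <- pop[pop$g.T62131C != "TT", ]
  expect_warning(
    tab2 <- association_table(sub, "g.T62131C", "WH"),
    class = "cgassoc_dropped_class"
  )
  expect_identical(sort(unique(tab2$genotype)), c("CC", "TC"))

  # single-genotype group: one row, no letters
  single <- pop[pop$g.T62131C == "TC", ]
  expect_warning(
    tab3 <- association_table(single, "g.T62131C", "WH"),
    class = "cgassoc_dropped_class"
  )
  expect_identical(tab3$letters_05, "")
  expect_true(is.na(tab3$p_genotype))
})

test_that("a strong single-genotype effect is separated by Duncan in most replicates", {
  assay <- kat2b_assays()$g.T62131C
  hits <- vapply(1:150, function(i) {
    pop <- simulate_population(population_spec("Pw", 150, 0.5, seed = 4000 + i),
                               list(assay))
    ph <- phenotype_spec("CG", 145, "g.T62131C", c(CC = 0, TC = 0, TT = 8), sigma_e = 2)
    pop <- simulate_phenotypes(pop, ph, seed = 5000 + i)
    if (length(unique(pop$g.T62131C)) < 3) return(NA)
    fit <- fit_fixed_effects(pop, "CG", "g.T62131C")
    lets <- duncan_groups(fit, 0.05)
    sep <- function(a, b) {
      length(intersect(strsplit(lets[[a]], "")[[1]], strsplit(lets[[b]], "")[[1]])) == 0
    }
    sep("TT", "CC") && sep("TT", "TC")
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.9)
})
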