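#' Fit the fixed-effects association model for one trait
#'
#' Ordinary least squares for `Y = mu + G + F (+ B) + e` with treatment
#' (reference-level) coding: genotype, farm and breed all enter as fixed
#' factors.  Missing trait values are dropped casewise.  Genotype
#' least-squares means are predictions averaged with equal weight over the
#' levels of the other fixed terms; their standard errors come from the
#' design-based covariance of the corresponding estimable function (for a
#' one-way balanced design this reduces to the group mean with
#' `sqrt(MS/n)`).
#'
#' @param data Data frame with the response, genotype and fixed-term
#'   columns.
#' @param response Trait column name.
#' @param genotype Genotype column name (marker id).
#' @param fixed_terms Additional fixed factors, a subset of
#'   `c("farm", "breed")` (or any factor columns present).  Terms with a
#'   single observed level are dropped.
#' @return An object of class `cg_model_fit`: list with `lm`, `ls_means`
#'   (data frame: genotype, n, lsmean, se), `residual_ms`, `residual_df`,
#'   `group_sizes`, `saturated` flag and the term names.
#' @export
fit_fixed_effects <- function(data, response, genotype,
                              fixed_terms = character(0)) {
  if (!response %in% names(data)) {
    cg_abort(sprintf("no response column '%s'", response), "data")
  }
  if (!genotype %in% names(data)) {
    cg_abort(sprintf("no genotype column '%s'", genotype), "data")
  }
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  d$.y <- d[[response]]
  d$.geno <- droplevels(factor(d[[genotype]]))
  terms_used <- character(0)
  for (tm in fixed_terms) {
    if (!tm %in% names(d)) cg_abort(sprintf("no fixed-term column '%s'", tm), "data")
    f <- droplevels(factor(d[[tm]]))
    if (nlevels(f) >= 2L) {
      d[[paste0(".", tm)]] <- f
      terms_used <- c(terms_used, tm)
    }
  }
  k <- nlevels(d$.geno)
  rhs <- c(if (k >= 2L) ".geno",
           if (length(terms_used)) paste0(".", terms_used))
  fml <- stats::as.formula(paste(".y ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
  fit <- stats::lm(fml, data = d)
  if (stats::df.residual(fit) < 1L) {
    cg_abort("saturated model: zero residual degrees of freedom", "saturation")
  }
  if (any(is.na(stats::coef(fit)))) {
    cg_abort("rank-deficient design: genotype LS means are not estimable", "aliasing")
  }
  res_df <- stats::df.residual(fit)
  res_ms <- sum(stats::residuals(fit)^2) / res_df
  # a residual MS at floating-point noise level is a saturated (exact) fit
  if (res_ms < .Machine$double.eps * max(1, mean(d$.y^2))) res_ms <- 0
  # summary.lm warns on essentially perfect fits; saturation is already
  # flagged explicitly via res_ms
  V <- suppressWarnings(stats::vcov(fit))

  # equal-weight prediction grid over the other fixed terms
  levs <- levels(d$.geno)
  grid_terms <- lapply(terms_used, function(tm) levels(d[[paste0(".", tm)]]))
  names(grid_terms) <- if (length(terms_used)) paste0(".", terms_used) else character(0)
  lsm <- lapply(levs, function(g) {
    grid <- do.call(expand.grid, c(list(.geno = g), grid_terms,
                                   list(stringsAsFactors = FALSE)))
    grid$.geno <- factor(grid$.geno, levels = levs)
    for (tm in terms_used) {
      grid[[paste0(".", tm)]] <- factor(grid[[paste0(".", tm)]],
                                        levels = levels(d[[paste0(".", tm)]]))
    }
    grid$.y <- 0
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid,
                             contrasts.arg = fit$contrasts)
    cvec <- colMeans(X)
    data.frame(
      genotype = g,
      lsmean = drop(cvec %*% stats::coef(fit)),
      se = sqrt(drop(t(cvec) %*% V %*% cvec)),
      stringsAsFactors = FALSE
    )
  })
  lsm <- do.call(rbind, lsm)
  sizes <- table(d$.geno)
  lsm$n <- as.integer(sizes[lsm$genotype])
  lsm <- lsm[, c("genotype", "n", "lsmean", "se")]

  structure(
    list(
      lm = fit, response = response, genotype_term = genotype,
      fixed_terms = terms_used, ls_means = lsm,
      group_sizes = stats::setNames(as.integer(sizes), names(sizes)),
      residual_ms = res_ms, residual_df = res_df,
      saturated = res_ms == 0, n_used = nrow(d)
    ),
    class = "cg_model_fit"
  )
}

#' @export
print.cg_model_fit <- function(x, ...) {
  cat(sprintf("<cg_model_fit> %s ~ %s%s (n = %d, residual MS = %.4g on %d df)\n",
              x$response, x$genotype_term,
              if (length(x$fixed_terms)) paste0(" + ", paste(x$fixed_terms, collapse = " + ")) else "",
              x$n_used, x$residual_ms, x$residual_df))
  print(x$ls_means)
  invisible(x)
}

#' F-test for the genotype term
#'
#' Marginal F-test comparing the fitted model against the same model
#' without the genotype term (extra sum of squares).
#'
#' @param fit A `cg_model_fit`.
#' @return The p-value, or `NA` when the genotype term is absent or the
#'   residual variance is 0.
#' @export
genotype_f_test <- function(fit) {
  stopifnot(inherits(fit, "cg_model_fit"))
  labs <- attr(stats::terms(fit$lm), "term.labels")
  if (!".geno" %in% labs) return(NA_real_)
  if (fit$residual_ms == 0) return(NA_real_)
  # refit from the stored model frame (extra-sum-of-squares F test)
  mf <- stats::model.frame(fit$lm)
  rhs0 <- setdiff(labs, ".geno")
  fml0 <- stats::reformulate(if (length(rhs0)) rhs0 else "1", response = ".y")
  reduced <- stats::lm(fml0, data = mf)
  rss0 <- sum(stats::residuals(reduced)^2)
  rss1 <- sum(stats::residuals(fit$lm)^2)
  df0 <- stats::df.residual(reduced)
  df1 <- stats::df.residual(fit$lm)
  fstat <- ((rss0 - rss1) / (df0 - df1)) / (rss1 / df1)
  stats::pf(fstat, df0 - df1, df1, lower.tail = FALSE)
}

#' Studentized-range quantile
#'
#' Upper quantile of the studentized range distribution, computed by
#' root-finding on the distribution function (`stats::ptukey`) to a
#' tolerance of 1e-8 on the quantile -- tighter than `stats::qtukey`'s
#' iteration, so that the two-group identity
#' `q(alpha, 2, df) = t(alpha/2, df) * sqrt(2)` holds to ~1e-6.
#'
#' @param p Cumulative probability.
#' @param nmeans Number of means spanned.
#' @param df Residual degrees of freedom.
#' @return The quantile `q` with `ptukey(q, nmeans, df) = p`.
#' @export
studentized_range_q <- function(p, nmeans, df) {
  f <- function(q) stats::ptukey(q, nmeans, df) - p
  q0 <- stats::qtukey(p, nmeans, df)
  lo <- max(q0 - 0.5, 1e-10)
  hi <- q0 + 0.5
  while (f(lo) > 0 && lo > 1e-10) lo <- lo / 2
  while (f(hi) < 0) hi <- hi + 1
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Duncan's multiple range test from summary statistics
#'
#' Stepwise range testing of `k` means sorted descending.  For a span of
#' `p` ordered means the critical range is
#' `R_p = q(1 - alpha_p, p, df) * sqrt(ms / n_h)`, with Duncan's protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)`, `q` the studentized-range
#' quantile, and `n_h` the harmonic mean of the group sizes in the span
#' (`n_method = "harmonic"`, the classical unequal-n behaviour) or of the
#' two extreme groups (`"pairwise"`).  A span whose range does not exceed
#' its critical range is declared homogeneous and none of its sub-spans is
#' tested (the protection rule).  Letters are assigned to the maximal
#' homogeneous spans, in descending-mean order.
#'
#' With `ms = 0` comparisons are exact: unequal means are distinct.
#'
#' @param means Named numeric vector of group means.
#' @param n Group sizes (same order/names).
#' @param ms Residual mean square.
#' @param df Residual degrees of freedom.
#' @param alpha Significance level in (0, 1).
#' @param n_method `"harmonic"` or `"pairwise"`.
#' @param letter_symbols Alphabet used for the letters (`letters` at 0.05,
#'   `LETTERS` for the 0.01 display level).
#' @return Named character vector mapping each group to its letter set
#'   (e.g. `c(TT = "a", CC = "ab", TC = "b")`).
#' @export
duncan_from_summary <- function(means, n, ms, df, alpha = 0.05,
                                n_method = c("harmonic", "pairwise"),
                                letter_symbols = letters) {
  n_method <- match.arg(n_method)
  if (alpha <= 0 || alpha >= 1) cg_abort("alpha must be in (0, 1)", "parameter")
  k <- length(means)
  if (k == 0L) cg_abort("no groups", "data")
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  if (k == 1L) return(stats::setNames("", names(means)))
  if (ms > 0 && df < 1L) cg_abort("Duncan test needs residual df >= 1", "parameter")
  n <- rep(as.numeric(n), length.out = k)

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nn <- n[ord]

  differ <- matrix(FALSE, k, k)
  homog <- matrix(FALSE, k, k)  # pair inside an accepted (homogeneous) span
  diag(homog) <- TRUE
  for (p in k:2) {
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      if (homog[i, j]) next
      if (ms == 0) {
        tol0 <- sqrt(.Machine$double.eps) * max(1, abs(m[i]), abs(m[j]))
        if (m[i] - m[j] > tol0) {
          differ[i, j] <- TRUE
        } else {
          homog[i:j, i:j] <- TRUE
        }
        next
      }
      alpha_p <- 1 - (1 - alpha)^(p - 1)
      nh <- if (n_method == "harmonic") p / sum(1 / nn[i:j]) else 2 / (1 / nn[i] + 1 / nn[j])
      r_p <- studentized_range_q(1 - alpha_p, p, df) * sqrt(ms / nh)
      if (m[i] - m[j] > r_p) {
        differ[i, j] <- TRUE
      } else {
        homog[i:j, i:j] <- TRUE
      }
    }
  }

  # maximal homogeneous spans -> letters
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !differ[i, j + 1L]) j <- j + 1L
    spans[[i]] <- c(i, j)
  }
  maximal <- spans[vapply(seq_along(spans), function(i) {
    !any(vapply(spans[-i], function(s) s[1] <= spans[[i]][1] && s[2] >= spans[[i]][2],
                logical(1)))
  }, logical(1))]
  if (length(maximal) > length(letter_symbols)) {
    cg_abort("more homogeneous groups than letter symbols", "parameter")
  }
  lab <- character(k)
  for (s in seq_along(maximal)) {
    idx <- maximal[[s]][1]:maximal[[s]][2]
    lab[idx] <- paste0(lab[idx], letter_symbols[s])
  }
  out <- stats::setNames(lab, names(m))
  out[names(means)]
}

#' Duncan letter grouping of genotype LS means
#'
#' @param fit A `cg_model_fit` from [fit_fixed_effects()].
#' @param alpha Significance level.
#' @param n_method,letter_symbols Passed to [duncan_from_summary()].
#' @return Named character vector genotype -> letters.
#' @export
duncan_groups <- function(fit, alpha = 0.05, n_method = "harmonic",
                          letter_symbols = letters) {
  stopifnot(inherits(fit, "cg_model_fit"))
  means <- stats::setNames(fit$ls_means$lsmean, fit$ls_means$genotype)
  duncan_from_summary(means, fit$ls_means$n, fit$residual_ms, fit$residual_df,
                      alpha = alpha, n_method = n_method,
                      letter_symbols = letter_symbols)
}

#' Marker x breed x trait association table
#'
#' For every combination, fits the fixed-effects model, computes genotype
#' LS means with standard errors, assigns Duncan letters at the 0.05
#' (lower-case) and 0.01 (upper-case) display levels, and flags the row by
#' the genotype term's F-test.  Per-breed analyses drop the breed term
#' (inestimable within one breed); the pooled analysis (`per_breed =
#' FALSE`) keeps it.
#'
#' @param pop Population data frame with genotype and trait columns.
#' @param markers Marker ids or list of [marker_assay()] objects.
#' @param traits Trait column names.
#' @param per_breed Analyse each breed separately (default `TRUE`).
#' @param fixed_terms Additional fixed factors beyond genotype; default
#'   `"farm"`, with `"breed"` added automatically when `per_breed = FALSE`.
#' @param alpha Two display levels for letters, default `c(0.05, 0.01)`.
#' @param bonferroni Divide the F-test flag level by the number of
#'   marker x trait combinations (off by default).
#' @return Data frame, one row per marker x breed x trait x genotype, with
#'   columns `marker, breed, trait, genotype, n, lsmean, se, letters_05,
#'   letters_01, p_genotype, significant`.
#' @export
association_table <- function(pop, markers, traits, per_breed = TRUE,
                              fixed_terms = "farm", alpha = c(0.05, 0.01),
                              bonferroni = FALSE) {
  if (is.list(markers)) markers <- vapply(markers, function(a) a$marker_id, character(1))
  groups <- if (per_breed) split(pop, pop$breed) else list(pooled = pop)
  if (!per_breed && "breed" %in% names(pop) &&
      length(unique(pop$breed)) > 1L && !"breed" %in% fixed_terms) {
    fixed_terms <- c(fixed_terms, "breed")
  }
  n_tests <- length(markers) * length(traits)
  flag_level <- if (bonferroni) alpha[1] / n_tests else alpha[1]

  rows <- list()
  for (bname in names(groups)) {
    g <- groups[[bname]]
    for (m in markers) {
      classes <- unique(g[[m]])
      if (length(classes) < 3L) {
        cg_warn(sprintf("%s / %s: only %d genotype class(es) observed; absent classes dropped",
                        bname, m, length(classes)), "dropped_class")
      }
      for (tr in traits) {
        fit <- fit_fixed_effects(g, tr, m, fixed_terms = fixed_terms)
        l05 <- duncan_groups(fit, alpha = alpha[1], letter_symbols = letters)
        l01 <- duncan_groups(fit, alpha = alpha[2], letter_symbols = LETTERS)
        p <- genotype_f_test(fit)
        df <- fit$ls_means
        df$marker <- m
        df$breed <- bname
        df$trait <- tr
        df$letters_05 <- unname(l05[df$genotype])
        df$letters_01 <- unname(l01[df$genotype])
        df$p_genotype <- p
        df$significant <- !is.na(p) & p < flag_level
        rows[[length(rows) + 1L]] <- df[, c("marker", "breed", "trait", "genotype",
                                            "n", "lsmean", "se", "letters_05",
                                            "letters_01", "p_genotype", "significant")]
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      marker = character(0), breed = character(0), trait = character(0),
      genotype = character(0), n = integer(0), lsmean = numeric(0),
      se = numeric(0), letters_05 = character(0), letters_01 = character(0),
      p_genotype = numeric(0), significant = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
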