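#' Relative expression by the 2^-ddCt method
#'
#' Livak quantification: technical replicates are averaged on the Ct scale;
#' per sample, `dCt = mean(target Ct) - mean(reference Ct)`; per sample,
#' `ddCt = dCt - mean dCt of the calibrator group`; the fold change is
#' `2^-ddCt` (amplification efficiency fixed at perfect doubling).  The
#' calibrator group's mean fold change is 1 by construction.
#'
#' @param ct Ct table: data frame with columns `sample_id`, `tissue`,
#'   `stage`, `gene` and one or more `ct_rep*` replicate columns (or a
#'   single `ct` column).
#' @param target Target gene label.
#' @param reference Reference (normalizer) gene label.
#' @param calibrator Length-2 character vector `c(tissue, stage)` of the
#'   calibrator group.
#' @return A list with `samples` (per biological sample: `dct`, `ddct`,
#'   `fold_change`) and `groups` (per tissue x stage: mean fold change,
#'   its SE over biological replicates, and n).
#' @examples
#' ct <- simulate_ct_table(seed = 7)
#' rex <- relative_expression(ct, "KAT2B", "beta_actin", c("heart", "fetal"))
#' head(rex$groups)
#' @export
relative_expression <- function(ct, target, reference, calibrator) {
  rep_cols <- grep("^ct(_rep[0-9]+)?$", names(ct), value = TRUE)
  if (length(rep_cols) == 0L) cg_abort("no Ct replicate columns found", "data")
  cts <- as.matrix(ct[, rep_cols, drop = FALSE])
  if (any(cts <= 0 | cts >= 50, na.rm = TRUE)) {
    cg_abort("Ct values must lie in (0, 50)", "data")
  }
  ct$.mean_ct <- rowMeans(cts, na.rm = TRUE)

  tgt <- ct[ct$gene == target, c("sample_id", "tissue", "stage", ".mean_ct")]
  ref <- ct[ct$gene == reference, c("sample_id", ".mean_ct")]
  if (nrow(tgt) == 0L) cg_abort(sprintf("no Ct records for target gene '%s'", target), "data")
  m <- merge(tgt, ref, by = "sample_id", suffixes = c("_target", "_reference"))
  if (nrow(m) < nrow(tgt)) {
    cg_abort("normalization error: some samples lack reference-gene Ct records",
             "normalization")
  }
  m$dct <- m$.mean_ct_target - m$.mean_ct_reference

  cal <- m$tissue == calibrator[1] & m$stage == calibrator[2]
  if (!any(cal)) {
    cg_abort(sprintf("calibrator group %s/%s has no samples",
                     calibrator[1], calibrator[2]), "calibrator")
  }
  dct_cal <- mean(m$dct[cal])
  m$ddct <- m$dct - dct_cal
  m$fold_change <- 2^(-m$ddct)
  samples <- m[, c("sample_id", "tissue", "stage", "dct", "ddct", "fold_change")]

  grp <- split(samples, interaction(samples$tissue, samples$stage, drop = TRUE))
  groups <- do.call(rbind, lapply(grp, function(g) {
    data.frame(
      tissue = g$tissue[1], stage = g$stage[1], n = nrow(g),
      fold_change = mean(g$fold_change),
      se = if (nrow(g) > 1L) stats::sd(g$fold_change) / sqrt(nrow(g)) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(groups) <- NULL
  groups <- groups[order(groups$stage, groups$tissue), ]
  list(samples = samples, groups = groups, calibrator = calibrator)
}

#' Per-tissue stage comparison of expression
#'
#' Two-sample t-test of the fold changes between developmental stages
#' within each tissue: a descriptive companion to the expression profile
#' (which tissues change between fetal and adult animals).
#'
#' @param rex Result of [relative_expression()].
#' @return Data frame with one row per tissue: the two stage means, the
#'   t-test p-value, and a `significant` flag at 0.05.
#' @export
stage_comparison <- function(rex) {
  s <- rex$samples
  stages <- sort(unique(s$stage))
  if (length(stages) != 2L) cg_abort("stage comparison needs exactly two stages", "data")
  rows <- lapply(split(s, s$tissue), function(g) {
    a <- g$fold_change[g$stage == stages[1]]
    b <- g$fold_change[g$stage == stages[2]]
    p <- if (length(a) > 1L && length(b) > 1L) stats::t.test(a, b)$p.value else NA_real_
    data.frame(
      tissue = g$tissue[1],
      mean_1 = mean(a), mean_2 = mean(b),
      p_value = p, significant = !is.na(p) & p < 0.05,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", stages[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", stages[2])
  rownames(out) <- NULL
  out
}
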