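# Relative qPCR quantification (2^-ddCt) and group statistics.
#
# Ct tables carry one row per (sample, cell type, condition, gene). Each
# sample's target Ct is paired with its housekeeping Ct within the same
# sample (Livak procedure): dCt = Ct_target - Ct_housekeeping,
# ddCt = mean dCt(condition) - mean dCt(reference), fold = 2^-ddCt,
# normalised to the flat condition by construction. Group comparisons use
# one-way ANOVA followed by Scheffe's post-hoc test.

#' Validate a Ct table
#'
#' Checks the column layout, that every (sample, cell type, condition)
#' carrying a target gene also has a housekeeping Ct, that the reference
#' condition is present in every (cell type, gene) stratum, and warns for
#' Ct values outside the typical 10-40 cycle range.
#'
#' @param ct_table data.frame with columns `sample_id`, `cell_type`,
#'   `condition`, `gene`, `ct`.
#' @param housekeeping housekeeping gene name (default `"GAPDH"`).
#' @param reference reference condition name (default `"flat"`).
#' @return the table, invisibly, if valid; otherwise an error listing the
#'   offending strata.
#' @export
validate_ct_table <- function(ct_table, housekeeping = "GAPDH", reference = "flat") {
  need <- c("sample_id", "cell_type", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(ct_table$ct))) stop("non-finite Ct values")
  if (any(ct_table$ct < 10 | ct_table$ct > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  if (!housekeeping %in% ct_table$gene)
    stop("housekeeping gene '", housekeeping, "' absent from table")
  tgt <- ct_table[ct_table$gene != housekeeping, ]
  hk <- ct_table[ct_table$gene == housekeeping, ]
  key <- function(d) paste(d$sample_id, d$cell_type, d$condition)
  missing_hk <- setdiff(unique(key(tgt)), unique(key(hk)))
  if (length(missing_hk))
    stop("samples without housekeeping Ct: ", paste(missing_hk, collapse = "; "))
  strata <- unique(tgt[, c("cell_type", "gene")])
  for (i in seq_len(nrow(strata))) {
    sub <- tgt[tgt$cell_type == strata$cell_type[i] & tgt$gene == strata$gene[i], ]
    if (!reference %in% sub$condition)
      stop("reference condition '", reference, "' missing for stratum ",
           strata$cell_type[i], "/", strata$gene[i])
  }
  invisible(ct_table)
}

#' Relative expression by the 2^-ddCt method
#'
#' @inheritParams validate_ct_table
#' @return data.frame with one row per (cell_type, gene, condition):
#'   `n` samples, `dct_mean`, `ddct`, `fold` (= `2^-ddct`; exactly 1 for the
#'   reference condition), and `fold_sd`, the s.d. of per-sample
#'   `2^-(dCt_i - mean dCt_ref)` values.
#' @export
ddct <- function(ct_table, housekeeping = "GAPDH", reference = "flat") {
  validate_ct_table(ct_table, housekeeping, reference)
  hk <- ct_table[ct_table$gene == housekeeping, ]
  tgt <- ct_table[ct_table$gene != housekeeping, ]
  key <- function(d) paste(d$sample_id, d$cell_type, d$condition)
  hk_ct <- tapply(hk$ct, key(hk), mean)
  tgt$dct <- tgt$ct - as.numeric(hk_ct[key(tgt)])
  out <- list()
  for (ctype in unique(tgt$cell_type)) for (g in unique(tgt$gene[tgt$cell_type == ctype])) {
    sub <- tgt[tgt$cell_type == ctype & tgt$gene == g, ]
    ref_mean <- mean(sub$dct[sub$condition == reference])
    for (cond in unique(sub$condition)) {
      d <- sub$dct[sub$condition == cond]
      dd <- mean(d) - ref_mean
      if (cond == reference) dd <- 0  # exact by definition
      out[[length(out) + 1]] <- data.frame(
        cell_type = ctype, gene = g, condition = cond, n = length(d),
        dct_mean = mean(d), ddct = dd, fold = 2^-dd,
        fold_sd = stats::sd(2^-(d - ref_mean)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Significance stars at the 0.05 / 0.01 / 0.001 tiers
#'
#' @param p numeric p-values.
#' @return character vector: `"***"`, `"**"`, `"*"` or `""`.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' One-way ANOVA with Scheffe post-hoc comparisons
#'
#' Two-sided one-way ANOVA across condition groups followed by Scheffe's
#' all-pairs post-hoc test: for a pairwise contrast the statistic
#' `F_s = (m_i - m_j)^2 / (MSE (1/n_i + 1/n_j) (k - 1))` is referred to the
#' `F(k - 1, N - k)` distribution.
#'
#' @param values numeric response values.
#' @param groups group labels (coerced to factor), >= 2 groups with >= 2
#'   observations each.
#' @return object of class `group_stats`: `groups` data.frame (group, n,
#'   mean, sd), `anova` list (F, p, df1, df2), `scheffe` data.frame
#'   (group1, group2, diff, F, p, stars).
#' @export
anova_scheffe <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n_i <- tabulate(groups)
  if (any(n_i < 2)) stop("every group needs at least 2 observations")
  k <- nlevels(groups); N <- length(values)
  aov_res <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  m <- tapply(values, groups, mean)
  s <- tapply(values, groups, stats::sd)
  mse <- sum((n_i - 1) * s^2) / (N - k)  # pooled within-group variance
  df2 <- N - k
  pairs <- utils::combn(levels(groups), 2)
  sch <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    dif <- m[[i]] - m[[j]]
    Fs <- dif^2 / (mse * (1 / n_i[match(i, levels(groups))] +
                            1 / n_i[match(j, levels(groups))]) * (k - 1))
    data.frame(group1 = i, group2 = j, diff = dif, F = Fs,
               p = stats::pf(Fs, k - 1, df2, lower.tail = FALSE))
  })
  sch <- do.call(rbind, sch)
  sch$stars <- signif_stars(sch$p)
  rownames(sch) <- NULL
  structure(list(
    groups = data.frame(group = levels(groups), n = n_i,
                        mean = as.numeric(m), sd = as.numeric(s)),
    anova = list(F = unname(aov_res$statistic), p = aov_res$p.value,
                 df1 = k - 1, df2 = df2, mse = mse),
    scheffe = sch), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$groups)
  cat("Scheffe post-hoc:\n")
  print(x$scheffe)
  invisible(x)
}

#' Read a Ct table from CSV
#'
#' @param path CSV with columns `sample_id`, `cell_type`, `condition`,
#'   `gene`, `ct`.
#' @param ... passed to [utils::read.csv()].
#' @return data.frame suitable for [ddct()].
#' @export
read_ct_table <- function(path, ...) {
  utils::read.csv(path, stringsAsFactors = FALSE, ...)
}
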