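#' LDH viability percentage
#'
#' Viability relative to control from optical densities of the LDH lysate
#' assay: `100 * mean(sample OD) / mean(control OD)`.
#'
#' @param sample_ods optical densities of the treated sample
#' @param control_ods optical densities of the control
#' @return viability in percent
#' @examples
#' viability_percent(c(0.45, 0.47), c(0.50, 0.52))
#' @export
viability_percent <- function(sample_ods, control_ods) {
  if (!length(sample_ods) || !length(control_ods))
    .stopf("sample and control ODs must be non-empty")
  if (any(!is.finite(sample_ods)) || any(!is.finite(control_ods)) ||
      any(sample_ods < 0) || any(control_ods < 0))
    .stopf("ODs must be finite and non-negative")
  ctrl <- mean(control_ods)
  if (ctrl <= 0) .stopf("control mean OD is zero; viability undefined")
  100 * mean(sample_ods) / ctrl
}

.ct_lookup <- function(table, sample, gene) {
  hit <- table$ct[table$sample == sample & table$gene == gene]
  hit <- hit[is.finite(hit)]
  if (!length(hit))
    .stopf("no Ct value for gene '%s' in sample '%s'", gene, sample)
  mean(hit)  # technical replicates are averaged
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `dCt = Ct(target) - Ct(reference)` in the treated and
#' calibrator samples, `ddCt = dCt(treated) - dCt(calibrator)`, and the
#' fold change `2^(-ddCt)`, normalised to the endogenous reference gene
#' (GAPDH by convention).
#'
#' @param table a data.frame with columns `sample`, `gene`, `ct`
#' @param target_gene gene of interest
#' @param treated_sample,calibrator_sample sample labels
#' @param reference_gene endogenous control gene
#' @return a one-row data.frame with the per-sample dCt, ddCt and fold
#'   change
#' @examples
#' ct <- synth_ct_table(c(ACAN = 8), seed = 1)
#' delta_delta_ct(ct, "ACAN", "treated", "control")
#' @export
delta_delta_ct <- function(table, target_gene, treated_sample,
                           calibrator_sample, reference_gene = "GAPDH") {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(table)))
    .stopf("Ct table needs columns: %s", paste(need, collapse = ", "))
  d_treat <- .ct_lookup(table, treated_sample, target_gene) -
    .ct_lookup(table, treated_sample, reference_gene)
  d_cal <- .ct_lookup(table, calibrator_sample, target_gene) -
    .ct_lookup(table, calibrator_sample, reference_gene)
  ddct <- d_treat - d_cal
  data.frame(gene = target_gene, treated = treated_sample,
             calibrator = calibrator_sample,
             dct_treated = d_treat, dct_calibrator = d_cal,
             ddct = ddct, fold_change = 2^(-ddct))
}

.check_deg_table <- function(table) {
  need <- c("gene", "fold_change", "p_value")
  if (!all(need %in% names(table)))
    .stopf("DEG table needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(table$fold_change)) || any(table$fold_change <= 0))
    .stopf("fold changes must be positive ratios (< 1 means down)")
  if (any(!is.finite(table$p_value)) || any(table$p_value < 0) ||
      any(table$p_value > 1))
    .stopf("p-values must lie in [0, 1]")
  invisible(table)
}

#' Filter differentially expressed genes
#'
#' Applies the study's DEG criterion, |fold change| > 1.5 and p < 0.05,
#' read symmetrically on the ratio scale: upregulated when
#' `fold_change >= fc_threshold`, downregulated when
#' `fold_change <= 1 / fc_threshold`, each with `p_value < p_threshold`.
#' Boundary rule: the fold-change magnitude is inclusive (>=), the p-value
#' strict (<).
#'
#' @param table a data.frame with columns `gene`, `fold_change` (ratio to
#'   control), `p_value`
#' @param fc_threshold fold-change magnitude threshold
#' @param p_threshold p-value threshold
#' @return a list of class `espray_deg` with character vectors
#'   `upregulated` and `downregulated`
#' @examples
#' deg <- synth_deg_table(n_null = 50, seed = 1)
#' lengths(deg_filter(deg))
#' @export
deg_filter <- function(table, fc_threshold = 1.5, p_threshold = 0.05) {
  .check_deg_table(table)
  if (fc_threshold < 1) .stopf("fc_threshold must be >= 1")
  sig <- table$p_value < p_threshold
  up <- table$gene[sig & table$fold_change >= fc_threshold]
  down <- table$gene[sig & table$fold_change <= 1 / fc_threshold]
  structure(list(upregulated = as.character(up),
                 downregulated = as.character(down),
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 n_genes = nrow(table)),
            class = "espray_deg")
}

#' @export
print.espray_deg <- function(x, ...) {
  cat(sprintf("<espray DEG filter> |FC| >= %.2g, p < %.2g over %d genes\n",
              x$fc_threshold, x$p_threshold, x$n_genes))
  cat(sprintf("  upregulated: %d; downregulated: %d\n",
              length(x$upregulated), length(x$downregulated)))
  invisible(x)
}

#' Tally a gene-ontology term against the DEG filter
#'
#' Counts how many member genes of an ontology term are up- or
#' downregulated under [deg_filter()]; members absent from the table count
#' as unchanged, with a warning. The partition always sums to the term
#' size.
#'
#' @param table a DEG table as for [deg_filter()]
#' @param term_genes character vector of member genes
#' @param term_name label for the report
#' @param fc_threshold,p_threshold thresholds passed to [deg_filter()]
#' @return a one-row data.frame: term, n_members, n_up, n_down,
#'   n_unchanged
#' @export
go_term_summary <- function(table, term_genes, term_name = "GO term",
                            fc_threshold = 1.5, p_threshold = 0.05) {
  if (!length(term_genes)) .stopf("term gene list is empty")
  .check_deg_table(table)
  deg <- deg_filter(table, fc_threshold, p_threshold)
  absent <- setdiff(term_genes, table$gene)
  if (length(absent))
    .warnf("%d of %d term genes absent from the table; counted as unchanged",
           length(absent), length(term_genes))
  n_up <- sum(term_genes %in% deg$upregulated)
  n_down <- sum(term_genes %in% deg$downregulated)
  data.frame(term = term_name, n_members = length(term_genes),
             n_up = n_up, n_down = n_down,
             n_unchanged = length(term_genes) - n_up - n_down)
}

#' Per-group absorbance summary
#'
#' Mean and sd of optical density per group, plus each group's ratio to
#' the control-group mean. Wavelength is metadata only and never alters
#' the computation.
#'
#' @param table a data.frame with columns `group` and `od`
#' @param control_group label of the control group
#' @return a data.frame with one row per group: n, mean_od, sd_od,
#'   ratio_to_control
#' @export
absorbance_summary <- function(table, control_group = "control") {
  need <- c("group", "od")
  if (!all(need %in% names(table)))
    .stopf("OD table needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(table$od)) || any(table$od < 0))
    .stopf("ODs must be finite and non-negative")
  if (!control_group %in% table$group)
    .stopf("control group '%s' not present in the table", control_group)
  groups <- unique(table$group)
  ctrl_mean <- mean(table$od[table$group == control_group])
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- table$od[table$group == g]
    data.frame(group = g, n = length(v), mean_od = mean(v),
               sd_od = if (length(v) > 1) sd(v) else 0,
               ratio_to_control = mean(v) / ctrl_mean)
  }))
  rownames(out) <- NULL
  out
}

#' Compare groups with the study's standard tests
#'
#' Convenience layer over the standard machinery: unpaired two-tailed
#' t-test for two groups, one-way ANOVA for several, two-way ANOVA when a
#' second factor is given, with Tukey's honestly-significant-difference
#' post hoc on significant ANOVAs. Significance is declared at p <= 0.05,
#' the study's criterion. Nothing here is novel; it exists so pipelines
#' can report the same statistics end to end.
#'
#' @param values numeric response
#' @param group primary grouping factor
#' @param group2 optional second factor (two-way ANOVA)
#' @param test `"auto"` (t for two groups, ANOVA otherwise), `"t"` or
#'   `"anova"`
#' @param posthoc run Tukey HSD after a significant ANOVA?
#' @param alpha significance level
#' @return a list of class `espray_comparison`: test label, statistic,
#'   p-value(s), significance flag, and the Tukey table when computed
#' @export
group_compare <- function(values, group, group2 = NULL,
                          test = c("auto", "t", "anova"),
                          posthoc = TRUE, alpha = 0.05) {
  test <- match.arg(test)
  group <- as.factor(group)
  if (length(values) != length(group))
    .stopf("values and group lengths differ")
  counts <- table(group)
  if (length(counts) < 2) .stopf("need at least two groups")
  if (any(counts < 2)) .stopf("every group needs at least two replicates")
  if (!is.null(group2)) {
    group2 <- as.factor(group2)
    fit <- aov(values ~ group * group2)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))[!is.na(tab[["Pr(>F)"]])]
    p <- setNames(tab[["Pr(>F)"]][!is.na(tab[["Pr(>F)"]])], terms)
    out <- list(test = "two-way ANOVA", statistic = tab[["F value"]][1],
                p_value = p, significant = any(p <= alpha),
                posthoc = if (posthoc) TukeyHSD(fit) else NULL)
  } else if (test == "t" || (test == "auto" && length(counts) == 2)) {
    if (length(counts) != 2) .stopf("t-test needs exactly two groups")
    ht <- t.test(values ~ group, var.equal = FALSE)
    out <- list(test = "Welch two-sample t-test",
                statistic = unname(ht$statistic),
                p_value = ht$p.value, significant = ht$p.value <= alpha,
                posthoc = NULL)
  } else {
    fit <- aov(values ~ group)
    tab <- summary(fit)[[1]]
    p <- tab[["Pr(>F)"]][1]
    out <- list(test = "one-way ANOVA", statistic = tab[["F value"]][1],
                p_value = p, significant = p <= alpha,
                posthoc = if (posthoc && p <= alpha) TukeyHSD(fit) else NULL)
  }
  structure(c(out, list(alpha = alpha)), class = "espray_comparison")
}

#' @export
print.espray_comparison <- function(x, ...) {
  cat(sprintf("<espray group comparison> %s\n", x$test))
  if (length(x$p_value) == 1)
    cat(sprintf("  statistic %.3f, p = %.4g (%ssignificant at %.2g)\n",
                x$statistic, x$p_value,
                if (x$significant) "" else "not ", x$alpha))
  else {
    for (nm in names(x$p_value))
      cat(sprintf("  %-14s p = %.4g\n", nm, x$p_value[[nm]]))
    cat(sprintf("  %ssignificant at %.2g\n",
                if (x$significant) "" else "not ", x$alpha))
  }
  invisible(x)
}
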