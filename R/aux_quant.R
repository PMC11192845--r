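# Closed-form auxiliary quantifications: internal-standard lipid amounts and
# the PA/PE ratio, 2^-ddCt relative expression, and group-comparison tests.

#' Internal-standard lipid quantification and the PA/PE ratio
#'
#' Converts LC-MS/MS peak areas to amounts by dividing each species' peak
#' area by the peak area of its class's internal surrogate standard and
#' multiplying by the spiked standard amount (default 20 pmol per class).
#' Class totals are the per-class sums, and the PA/PE ratio is the ratio of
#' the phosphatidic acid (PA) total to the phosphatidylethanolamine (PE)
#' total.
#'
#' @param data Data frame with columns `species`, `lipid_class` (`"PA"` or
#'   `"PE"`), `peak_area` (>= 0), `standard_area` (> 0) and optionally
#'   `standard_amount` (pmol; default 20).
#' @return Object of class `lipid_quant`: list with `per_species` (tibble
#'   including `amount_pmol`), `class_totals` (tibble `lipid_class`,
#'   `total_pmol`) and `pa_pe_ratio`.
#' @export
quantify_lipids <- function(data) {
  data <- as_tibble(data)
  required <- c("species", "lipid_class", "peak_area", "standard_area")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!nrow(data)) abort("empty lipid table")
  if (!all(data$lipid_class %in% c("PA", "PE")))
    abort("lipid_class must be \"PA\" or \"PE\"")
  if (any(data$standard_area <= 0)) abort("standard_area must be > 0")
  if (any(data$peak_area < 0)) abort("peak_area must be >= 0")
  if (!"standard_amount" %in% names(data)) data$standard_amount <- 20
  per_species <- data %>%
    mutate(amount_pmol = .data$standard_amount * .data$peak_area /
             .data$standard_area)
  totals <- per_species %>%
    group_by(.data$lipid_class) %>%
    summarise(total_pmol = sum(.data$amount_pmol), .groups = "drop")
  for (cls in c("PA", "PE")) {
    if (!cls %in% totals$lipid_class)
      abort(sprintf("class absent: %s", cls))
  }
  pa <- totals$total_pmol[totals$lipid_class == "PA"]
  pe <- totals$total_pmol[totals$lipid_class == "PE"]
  if (pe <= 0) abort("PE total is zero; PA/PE ratio undefined")
  structure(list(per_species = per_species, class_totals = totals,
                 pa_pe_ratio = pa / pe),
            class = "lipid_quant")
}

#' @export
print.lipid_quant <- function(x, ...) {
  cat(sprintf("<lipid_quant> %d species; PA = %.3g pmol, PE = %.3g pmol, PA/PE = %.4g\n",
              nrow(x$per_species),
              x$class_totals$total_pmol[x$class_totals$lipid_class == "PA"],
              x$class_totals$total_pmol[x$class_totals$lipid_class == "PE"],
              x$pa_pe_ratio))
  invisible(x)
}

#' @rdname quantify_lipids
#' @param x A `lipid_quant`.
#' @param ... Unused.
#' @export
tidy.lipid_quant <- function(x, ...) x$per_species

#' @rdname quantify_lipids
#' @export
glance.lipid_quant <- function(x, ...) {
  tibble(
    total_pa_pmol = x$class_totals$total_pmol[x$class_totals$lipid_class == "PA"],
    total_pe_pmol = x$class_totals$total_pmol[x$class_totals$lipid_class == "PE"],
    pa_pe_ratio = x$pa_pe_ratio
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, the target gene's cycle threshold (Ct) is referenced to the
#' housekeeping gene (`delta_ct = ct_target - ct_reference`; technical
#' replicate rows are averaged per sample first), differenced against the
#' calibrator sample's delta Ct, and exponentiated:
#' `fold_change = 2^-(delta_ct - delta_ct_calibrator)`. The calibrator's own
#' fold change is 1 by construction.
#'
#' @param data Data frame with columns `sample`, `ct_target`,
#'   `ct_reference` and logical `calibrator` (exactly one sample flagged).
#' @return Tibble with one row per sample: `sample`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `calibrator`.
#' @export
ddct_fold_change <- function(data) {
  data <- as_tibble(data)
  required <- c("sample", "ct_target", "ct_reference", "calibrator")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!all(is.finite(data$ct_target)) || !all(is.finite(data$ct_reference)))
    abort("Ct values must be finite")
  per_sample <- data %>%
    group_by(.data$sample) %>%
    summarise(delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
              calibrator = any(.data$calibrator), .groups = "drop")
  if (sum(per_sample$calibrator) != 1)
    abort("exactly one sample must be flagged as the calibrator")
  cal_dct <- per_sample$delta_ct[per_sample$calibrator]
  per_sample %>%
    mutate(delta_delta_ct = .data$delta_ct - cal_dct,
           fold_change = 2^(-.data$delta_delta_ct)) %>%
    select("sample", "delta_ct", "delta_delta_ct", "fold_change", "calibrator")
}

#' Compare measurement groups as in the source study design
#'
#' Two groups are compared by a two-tailed unpaired t test (equal-variance
#' Student by default; set `var_equal = FALSE` for Welch). More than two
#' groups are compared by one-way ANOVA followed by Dunnett's multiple
#' comparisons test of every group against the named control. Significance
#' is conventionally read at p < 0.05.
#'
#' @param data Data frame of measurements.
#' @param value,group Names of the measurement and grouping columns;
#'   defaults `"value"` and `"group"`.
#' @param control Control group label, required when there are more than two
#'   groups.
#' @param var_equal Assume equal variances for the two-group t test; default
#'   `TRUE`.
#' @return Object of class `group_test`: list with `test` (one of
#'   `"t_unpaired_two_tailed"`, `"anova_dunnett"`), `statistic`, `p_value`,
#'   and for Dunnett a `comparisons` tibble (`group`, `control`, `estimate`,
#'   `statistic`, `p_adjusted`).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           control = NULL, var_equal = TRUE) {
  data <- as_tibble(data)
  if (!value %in% names(data) || !group %in% names(data))
    abort("value/group columns not found in data")
  y <- data[[value]]
  g <- as.character(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  tab <- table(g)
  if (any(tab < 2)) abort("each group needs at least 2 observations")
  levels <- names(tab)

  if (length(levels) == 2) {
    tt <- t.test(y[g == levels[1]], y[g == levels[2]],
                 var.equal = var_equal, alternative = "two.sided")
    out <- list(test = "t_unpaired_two_tailed",
                statistic = unname(tt$statistic),
                p_value = tt$p.value,
                comparisons = tibble(
                  group = levels[1], control = levels[2],
                  estimate = unname(diff(rev(tt$estimate))),
                  statistic = unname(tt$statistic),
                  p_adjusted = tt$p.value),
                fit = tt)
  } else {
    if (is.null(control)) abort("more than two groups: a control label is required")
    if (!control %in% levels) abort(sprintf("control group %s not found", control))
    gf <- stats::relevel(factor(g), ref = control)
    df <- data.frame(y = y, g = gf)
    fit <- aov(y ~ g, data = df)
    an <- summary(fit)[[1]]
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(glt)
    comps <- tibble(
      group = sub(" - .*$", "", names(sm$test$coefficients)),
      control = control,
      estimate = unname(sm$test$coefficients),
      statistic = unname(sm$test$tstat),
      p_adjusted = unname(as.numeric(sm$test$pvalues))
    )
    out <- list(test = "anova_dunnett",
                statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1],
                comparisons = comps,
                fit = fit)
  }
  structure(out, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (x$test == "anova_dunnett") {
    for (i in seq_len(nrow(x$comparisons))) {
      cat(sprintf("  %s vs %s: p_adj = %.4g\n", x$comparisons$group[i],
                  x$comparisons$control[i], x$comparisons$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_test`.
#' @param ... Unused.
#' @export
tidy.group_test <- function(x, ...) x$comparisons

#' @rdname compare_groups
#' @export
glance.group_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_comparisons = nrow(x$comparisons))
}
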