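# Replicate-aware summaries, the statistical tests used for imaging
# measurement tables, and the peptide-count interactor filter. Measurement tables are long-format data
# frames with columns condition, replicate, field (optional), value.

.check_replicate_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("condition", "replicate", "value")
  if (!all(need %in% names(table))) {
    stop("table needs columns condition, replicate, value", call. = FALSE)
  }
  if (anyNA(table$value) || any(!is.finite(table$value))) {
    stop("values must be finite", call. = FALSE)
  }
  table
}

#' Normalize measurements to a control condition
#'
#' Divides every value by the mean of the control-condition values within
#' its normalization scope, so the control maps to mean 1. Scope
#' `"replicate"` (the default) uses each replicate's own control mean —
#' the usual choice when replicates are pooled after normalization;
#' `"global"` uses one control mean across all replicates.
#'
#' @param table Long-format data frame `condition, replicate, value` (plus
#'   any extra columns, carried through).
#' @param control_condition Label of the control condition.
#' @param scope `"replicate"` or `"global"`.
#' @return The table with `value` replaced by its normalized version.
#' @export
normalize_counts <- function(table, control_condition,
                             scope = c("replicate", "global")) {
  table <- .check_replicate_table(table)
  scope <- match.arg(scope)
  is_ctrl <- table$condition == control_condition
  if (!any(is_ctrl)) {
    stop(sprintf("control condition '%s' not present", control_condition),
         call. = FALSE)
  }
  if (scope == "global") {
    m <- mean(table$value[is_ctrl])
    if (m == 0) stop("control mean is zero", call. = FALSE)
    table$value <- table$value / m
  } else {
    for (rep in unique(table$replicate)) {
      sel <- table$replicate == rep
      ctrl <- table$value[sel & is_ctrl]
      if (!length(ctrl)) {
        stop(sprintf("replicate '%s' has no control rows", rep),
             call. = FALSE)
      }
      m <- mean(ctrl)
      if (m == 0) stop(sprintf("control mean is zero in replicate '%s'", rep),
                       call. = FALSE)
      table$value[sel] <- table$value[sel] / m
    }
  }
  table
}

#' SuperPlot-style replicate summary
#'
#' Separates biological-replicate means from individual measurements: per
#' (condition, replicate) the mean and n, and per condition both the mean
#' of replicate means (the unit of inference that avoids pseudoreplication)
#' and the pooled mean over all points. The two coincide for balanced
#' designs.
#'
#' @param table Long-format data frame `condition, replicate, value`.
#' @return `list(replicates = data.frame(condition, replicate, mean, n),
#'   conditions = data.frame(condition, mean_of_replicate_means,
#'   pooled_mean, n_replicates, n_points))`.
#' @export
superplot_summary <- function(table) {
  table <- .check_replicate_table(table)
  key <- interaction(table$condition, table$replicate, drop = TRUE)
  reps <- do.call(rbind, lapply(split(table, key), function(d) {
    data.frame(condition = d$condition[1], replicate = d$replicate[1],
               mean = mean(d$value), n = nrow(d))
  }))
  rownames(reps) <- NULL
  conds <- do.call(rbind, lapply(split(table, table$condition), function(d) {
    rm <- tapply(d$value, d$replicate, mean)
    data.frame(condition = d$condition[1],
               mean_of_replicate_means = mean(rm),
               pooled_mean = mean(d$value),
               n_replicates = length(rm), n_points = nrow(d))
  }))
  rownames(conds) <- NULL
  list(replicates = reps[order(reps$condition, reps$replicate), ],
       conditions = conds)
}

# Dunn's post-test: pairwise z comparisons of mean ranks after a
# Kruskal-Wallis test, with the usual tie correction, against a designated
# control group. Adjustment defaults to Bonferroni.
.dunn_test <- function(values, groups, control,
                       p_adjust_method = "bonferroni") {
  groups <- as.character(groups)
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  var_term <- n * (n + 1) / 12 - tie_corr
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  others <- setdiff(names(mean_rank), control)
  z <- vapply(others, function(g) {
    (mean_rank[[g]] - mean_rank[[control]]) /
      sqrt(var_term * (1 / n_g[[g]] + 1 / n_g[[control]]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(others, "vs", control),
             statistic = unname(z), p_raw = unname(p_raw),
             p_adjusted = unname(stats::p.adjust(p_raw,
                                                 p_adjust_method)))
}

#' Run the statistical test matching an experimental design
#'
#' The four designs used for this kind of data: two-sample t-test (Welch by
#' default), Mann-Whitney (Wilcoxon rank-sum), Kruskal-Wallis with Dunn's
#' post-tests against the control, and one-way ANOVA with Dunnett's
#' post-tests against the control. Tests can be run on individual data
#' points (`unit = "points"`) or on biological-replicate means
#' (`unit = "replicate_means"`), which first collapses the table with
#' [superplot_summary()].
#'
#' @param table Long-format data frame `condition, replicate, value`.
#' @param design One of `"t"`, `"mann_whitney"`, `"kruskal_dunn"`,
#'   `"anova_dunnett"`.
#' @param unit `"points"` or `"replicate_means"`.
#' @param control Control condition for post-tests (and the reference group
#'   of two-sample designs); defaults to the first condition.
#' @param var_equal Use Student's instead of Welch's t-test.
#' @param p_adjust_method Adjustment for Dunn's post-tests (default
#'   Bonferroni; Dunnett uses its own single-step adjustment).
#' @return Data frame `comparison, statistic, p_raw, p_adjusted` (one row
#'   per comparison; `p_adjusted = p_raw` for two-sample designs).
#' @export
run_test <- function(table,
                     design = c("t", "mann_whitney", "kruskal_dunn",
                                "anova_dunnett"),
                     unit = c("points", "replicate_means"), control = NULL,
                     var_equal = FALSE, p_adjust_method = "bonferroni") {
  table <- .check_replicate_table(table)
  design <- match.arg(design)
  unit <- match.arg(unit)
  if (unit == "replicate_means") {
    reps <- superplot_summary(table)$replicates
    table <- data.frame(condition = reps$condition,
                        replicate = reps$replicate, value = reps$mean)
  }
  groups <- unique(as.character(table$condition))
  if (length(groups) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (is.null(control)) control <- groups[1]
  if (!control %in% groups) stop("control condition not present",
                                 call. = FALSE)

  if (design %in% c("t", "mann_whitney")) {
    if (length(groups) != 2L) {
      stop("two-sample designs need exactly 2 conditions", call. = FALSE)
    }
    other <- setdiff(groups, control)
    x <- table$value[table$condition == other]
    y <- table$value[table$condition == control]
    if (design == "t") {
      if (length(x) < 2L || length(y) < 2L) {
        stop("parametric test needs >= 2 observations per group",
             call. = FALSE)
      }
      ht <- stats::t.test(x, y, var.equal = var_equal)
    } else {
      ht <- stats::wilcox.test(x, y, exact = NULL)
    }
    return(data.frame(comparison = paste(other, "vs", control),
                      statistic = unname(ht$statistic),
                      p_raw = ht$p.value, p_adjusted = ht$p.value))
  }

  if (design == "kruskal_dunn") {
    kw <- stats::kruskal.test(table$value, factor(table$condition))
    out <- .dunn_test(table$value, table$condition, control,
                      p_adjust_method)
    attr(out, "omnibus") <- kw
    return(out)
  }

  # one-way ANOVA + Dunnett
  sizes <- table(table$condition)
  if (any(sizes < 2L)) {
    stop("parametric test needs >= 2 observations per group", call. = FALSE)
  }
  d <- data.frame(value = table$value,
                  condition = stats::relevel(factor(table$condition),
                                             ref = control))
  fit <- stats::aov(value ~ condition, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  # the single-step multivariate-t adjustment is computed by randomized
  # quasi-Monte-Carlo integration; pin the RNG locally so results are
  # deterministic given the table
  sm <- .with_seed(20201L, summary(gl))
  comp <- names(sm$test$coefficients)
  out <- data.frame(comparison = sub(" - ", " vs ", comp),
                    statistic = unname(sm$test$tstat),
                    p_raw = NA_real_,
                    p_adjusted = as.numeric(sm$test$pvalues))
  attr(out, "omnibus") <- summary(fit)
  out
}

#' Filter co-immunoprecipitation interactors by peptide counts
#'
#' A protein passes when, in each of at least `required_replicates`
#' replicates, it is (i) represented by at least `min_peptides` peptides in
#' the bait pull-down and (ii) represented by at least `min_ratio` times
#' more peptides in the bait pull-down than in the control pull-down (a
#' control count of 0 passes the ratio rule whenever the peptide minimum
#' holds). A protein missing from a replicate fails that replicate. Raising
#' either threshold can only shrink the result.
#'
#' @param table Data frame `protein, replicate, peptides_bait,
#'   peptides_control` (one row per protein per replicate).
#' @param min_peptides Minimum bait peptide count (default 10).
#' @param min_ratio Minimum bait/control enrichment (default 2).
#' @param required_replicates Number of replicates in which both rules must
#'   hold (default 2).
#' @return Sorted character vector of retained protein names.
#' @export
filter_interactors <- function(table, min_peptides = 10, min_ratio = 2,
                               required_replicates = 2) {
  stopifnot(is.data.frame(table),
            all(c("protein", "replicate", "peptides_bait",
                  "peptides_control") %in% names(table)))
  cnt <- table[c("peptides_bait", "peptides_control")]
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("peptide counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(table[c("protein", "replicate")])) {
    stop("each protein may appear once per replicate", call. = FALSE)
  }
  pass <- table$peptides_bait >= min_peptides &
    table$peptides_bait >= min_ratio * table$peptides_control
  n_pass <- tapply(pass, table$protein, sum)
  sort(names(n_pass)[n_pass >= required_replicates])
}
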