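#' Paired t-test on a vector of differences
#'
#' @param differences numeric vector of within-subject differences (>= 2
#'   values).
#' @param level confidence level for the interval.
#' @return List: `t`, `df`, `p` (two-sided), `ci` (ascending), `mean`, `sd`,
#'   `se`, `n`.
#' @export
paired_t <- function(differences, level = 0.95) {
  n <- length(differences)
  if (n < 2) stop("need at least 2 differences", call. = FALSE)
  s <- sd(differences)
  if (s == 0) stop("zero-variance differences", call. = FALSE)
  m <- mean(differences)
  se <- s / sqrt(n)
  t <- m / se
  df <- n - 1
  tc <- qt((1 + level) / 2, df)
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       ci = c(m - tc * se, m + tc * se), mean = m, sd = s, se = se, n = n)
}

#' t statistic from a printed mean difference and its standard error
#'
#' Consistency identity `t = mean / SE`, used to recompute printed t columns
#' from the summary rows of published tables.
#'
#' @param mean_diff mean of the paired differences.
#' @param se standard error of the mean difference (> 0).
#' @return The t statistic.
#' @export
t_from_summary <- function(mean_diff, se) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  mean_diff / se
}

#' Confidence interval from summary statistics
#'
#' `mean +/- t_{(1+level)/2, df} * se`, returned ascending.
#'
#' @param mean point estimate.
#' @param se its standard error (>= 0; 0 collapses the interval to the mean).
#' @param df degrees of freedom (>= 1).
#' @param level confidence level.
#' @return `c(lo, hi)`.
#' @export
ci_from_summary <- function(mean, se, df, level = 0.95) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (se < 0) stop("se must be nonnegative", call. = FALSE)
  tc <- qt((1 + level) / 2, df)
  c(mean - tc * se, mean + tc * se)
}

#' Recover a group size from printed SD and SE
#'
#' Uses the identity `se = sd / sqrt(n)`, i.e. `n = (sd/se)^2`. This is how
#' the per-group n of the published deformation tables is recovered from
#' their printed rows.
#'
#' @param sd,se printed standard deviation and standard error (> 0).
#' @return List: `n` (rounded) and `raw` (the unrounded `(sd/se)^2`).
#' @export
infer_n_from_summary <- function(sd, se) {
  stopifnot(sd > 0, se > 0)
  raw <- (sd / se)^2
  list(n = as.integer(round(raw)), raw = raw)
}

#' One-way ANOVA from group summary statistics
#'
#' Balanced one-way ANOVA reconstructed from per-group means and SDs:
#' `SSB = n * sum((m_i - m_bar)^2)`, `MSW = mean(sd_i^2)` (equal n),
#' `F = MSB / MSW`.
#'
#' @param means,sds per-group means and standard deviations (>= 2 groups).
#' @param n_per_group common group size (>= 2).
#' @return List: `F`, `df_between`, `df_within`, `p`, `msb`, `msw`.
#' @export
anova_from_summary <- function(means, sds, n_per_group) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, n_per_group >= 2)
  msw <- mean(sds^2)
  if (msw == 0) stop("zero within-group variance", call. = FALSE)
  msb <- n_per_group * sum((means - mean(means))^2) / (k - 1)
  df1 <- k - 1
  df2 <- k * (n_per_group - 1)
  Fv <- msb / msw
  list(F = Fv, df_between = df1, df_within = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE), msb = msb, msw = msw)
}

#' One-way ANOVA on raw groups
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List as in [anova_from_summary()].
#' @export
anova_raw <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  k <- length(groups)
  ns <- lengths(groups)
  grand <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- sum(ns) - k
  if (ssw == 0) stop("zero within-group variance", call. = FALSE)
  msb <- ssb / df1
  msw <- ssw / df2
  Fv <- msb / msw
  list(F = Fv, df_between = df1, df_within = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE), msb = msb, msw = msw)
}

#' Construct raw groups matching given summary statistics exactly
#'
#' Affine-transforms a fixed base sample so that each group's sample mean and
#' SD equal the requested values exactly; used to cross-check the
#' summary-level ANOVA against the raw-data decomposition.
#'
#' @param means,sds target per-group sample means and SDs.
#' @param n group size.
#' @param base optional base sample of length `n` (default `1:n`).
#' @return List of numeric vectors.
#' @export
groups_from_summary <- function(means, sds, n, base = NULL) {
  if (is.null(base)) base <- as.numeric(seq_len(n))
  stopifnot(length(base) == n, sd(base) > 0)
  z <- (base - mean(base)) / sd(base)
  Map(function(m, s) m + s * z, means, sds)
}

#' Fisher LSD post-hoc comparisons
#'
#' Unprotected pairwise t-tests after a one-way ANOVA, using the pooled
#' within-group mean square. Also builds a compressed ordering string: group
#' means are ordered descending and split into blocks whose members are
#' mutually non-significantly different, with `>` between adjacent blocks;
#' groups that are non-significantly different from members of more than one
#' block cannot be placed in the strict ordering and are listed separately
#' (`unplaced`).
#'
#' @param groups list of numeric vectors.
#' @param alpha significance level for the pairwise tests.
#' @param labels group labels (default `1..k`).
#' @return List of class `lsd_result`: `p_matrix`, `significant` (logical
#'   matrix), `ordering` (the compressed string), `blocks` (list of label
#'   vectors, descending mean order), `unplaced`, `means`, `msw`, `df_within`.
#' @export
lsd_posthoc <- function(groups, alpha = 0.05, labels = NULL) {
  an <- anova_raw(groups)
  lsd_core(vapply(groups, mean, 0), lengths(groups), an$msw, an$df_within,
           alpha, labels)
}

#' @rdname lsd_posthoc
#' @param means,sds,n balanced-design summary statistics, as in
#'   [anova_from_summary()].
#' @export
lsd_from_summary <- function(means, sds, n, alpha = 0.05, labels = NULL) {
  an <- anova_from_summary(means, sds, n)
  lsd_core(means, rep(n, length(means)), an$msw, an$df_within, alpha, labels)
}

lsd_core <- function(means, ns, msw, df_w, alpha, labels) {
  k <- length(means)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  pm <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    t <- (means[i] - means[j]) / se
    pm[i, j] <- pm[j, i] <- 2 * pt(-abs(t), df_w)
  }
  sig <- pm < alpha
  ord <- order(means, decreasing = TRUE)
  blocks <- list()
  cur <- ord[1]
  for (g in ord[-1]) {
    if (all(!sig[g, cur])) cur <- c(cur, g)
    else { blocks[[length(blocks) + 1]] <- cur; cur <- g }
  }
  blocks[[length(blocks) + 1]] <- cur
  # a group tied (non-significant) across block boundaries has no strict rank
  block_of <- integer(k)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  unplaced <- integer(0)
  for (g in seq_len(k)) {
    others <- setdiff(seq_len(k), g)
    if (any(!sig[g, others] & block_of[others] != block_of[g], na.rm = TRUE))
      unplaced <- c(unplaced, g)
  }
  blocks_clean <- lapply(blocks, setdiff, y = unplaced)
  blocks_clean <- Filter(length, blocks_clean)
  ordering <- if (all(!sig, na.rm = TRUE)) ""
  else paste(vapply(blocks_clean,
                    function(b) paste(labels[b], collapse = ", "), ""),
             collapse = " > ")
  structure(list(p_matrix = pm, significant = sig, ordering = ordering,
                 blocks = lapply(blocks, function(b) labels[b]),
                 unplaced = labels[unplaced], means = setNames(means, labels),
                 msw = msw, df_within = df_w),
            class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  cat("Fisher LSD post-hoc comparisons\n")
  cat(sprintf("  MSW = %.4f on %d df\n", x$msw, x$df_within))
  cat(sprintf("  ordering: %s\n",
              if (nzchar(x$ordering)) x$ordering else "(no significant pairs)"))
  if (length(x$unplaced))
    cat(sprintf("  unplaced: %s\n", paste(x$unplaced, collapse = ", ")))
  invisible(x)
}

#' Independent two-sample t-test
#'
#' @param group_a,group_b numeric vectors (each >= 2 values).
#' @param var_equal pooled-variance test (default); `FALSE` gives Welch.
#' @return List: `t`, `df`, `p` (two-sided). The sign follows
#'   `mean(group_a) - mean(group_b)`.
#' @export
independent_t <- function(group_a, group_b, var_equal = TRUE) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  va <- var(group_a); vb <- var(group_b)
  md <- mean(group_a) - mean(group_b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
    t <- md / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va == 0 && vb == 0) stop("zero pooled variance", call. = FALSE)
    se2 <- va / na + vb / nb
    t <- md / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohort deformation tables
#'
#' From a long per-gland table (one row per subject, eye and gland) produces
#' the three standard cohort tables: per-gland paired differences
#' (treatment - control, matched within subject) with t/CI/p; and, per group,
#' the per-site summary with a one-way ANOVA across the ten gland positions
#' and a Fisher LSD ordering string. Subjects with incomplete 10-gland
#' records in either eye are listed and excluded with a warning; a zero-
#' variance paired difference is surfaced per gland as a warning with NA
#' statistics.
#'
#' @param per_gland data.frame with columns `subject_id`, `group`
#'   (`"treatment"`/`"control"`), `gland_index` (1..10) and `D`.
#' @param alpha significance level.
#' @param p_adjust optional multiple-testing correction for the ten paired
#'   tests (`"none"`, default as in the emulated analysis, or any
#'   [stats::p.adjust()] method such as `"BH"`).
#' @return List of class `cohort_tables`: `paired`, `treatment_sites`,
#'   `control_sites` (data.frames), `anova` (per-group F/df/p), `lsd`
#'   (per-group `lsd_result`), `meta`.
#' @export
emit_tables <- function(per_gland, alpha = 0.05, p_adjust = "none") {
  need <- c("subject_id", "group", "gland_index", "D")
  stopifnot(all(need %in% names(per_gland)))
  complete <- vapply(split(per_gland, per_gland$subject_id), function(d) {
    all(vapply(c("treatment", "control"), function(g)
      setequal(d$gland_index[d$group == g], 1:10), TRUE))
  }, TRUE)
  if (any(!complete)) {
    bad <- names(complete)[!complete]
    warning(sprintf("excluding %d subject(s) with incomplete records: %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    per_gland <- per_gland[!per_gland$subject_id %in% bad, ]
  }
  if (length(unique(per_gland$subject_id)) < 2)
    stop("need at least 2 subjects with complete records", call. = FALSE)

  paired <- do.call(rbind, lapply(1:10, function(g) {
    d <- per_gland[per_gland$gland_index == g, ]
    wide <- merge(d[d$group == "treatment", c("subject_id", "D")],
                  d[d$group == "control", c("subject_id", "D")],
                  by = "subject_id", suffixes = c("_t", "_c"))
    diffs <- wide$D_t - wide$D_c
    res <- tryCatch(paired_t(diffs), error = function(e) {
      warning(sprintf("gland %d: %s", g, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res))
      return(data.frame(gland_index = g, mean_diff = mean(diffs),
                        sd = sd(diffs), se = NA, ci_lo = NA, ci_hi = NA,
                        t = NA, df = length(diffs) - 1, p = NA))
    data.frame(gland_index = g, mean_diff = res$mean, sd = res$sd,
               se = res$se, ci_lo = res$ci[1], ci_hi = res$ci[2],
               t = res$t, df = res$df, p = res$p)
  }))
  paired$p_adj <- if (p_adjust == "none") paired$p
  else stats::p.adjust(paired$p, method = p_adjust)

  site_table <- function(grp) {
    d <- per_gland[per_gland$group == grp, ]
    groups <- lapply(1:10, function(g) d$D[d$gland_index == g])
    an <- tryCatch(anova_raw(groups), error = function(e) {
      warning(sprintf("%s sites ANOVA: %s", grp, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    lsd <- if (is.null(an)) NULL
    else lsd_posthoc(groups, alpha = alpha, labels = as.character(1:10))
    tab <- do.call(rbind, lapply(1:10, function(g) {
      x <- groups[[g]]
      ci <- ci_from_summary(mean(x), sd(x) / sqrt(length(x)), length(x) - 1)
      data.frame(gland_index = g, mean = mean(x), sd = sd(x),
                 ci_lo = ci[1], ci_hi = ci[2], n = length(x))
    }))
    list(table = tab, anova = an, lsd = lsd)
  }
  trt <- site_table("treatment")
  ctl <- site_table("control")
  structure(list(paired = paired,
                 treatment_sites = trt$table, control_sites = ctl$table,
                 anova = list(treatment = trt$anova, control = ctl$anova),
                 lsd = list(treatment = trt$lsd, control = ctl$lsd),
                 meta = list(n_subjects = length(unique(per_gland$subject_id)),
                             alpha = alpha, p_adjust = p_adjust)),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("cohort_tables: %d subjects, alpha = %g\n",
              x$meta$n_subjects, x$meta$alpha))
  cat("\nPaired differences (treatment - control) per gland:\n")
  print(format(x$paired, digits = 4), row.names = FALSE)
  cat(sprintf("\nTreatment sites ANOVA: F = %.3f (df %d, %d), p = %.3g; LSD: %s\n",
              x$anova$treatment$F, x$anova$treatment$df_between,
              x$anova$treatment$df_within, x$anova$treatment$p,
              x$lsd$treatment$ordering))
  cat(sprintf("Control sites ANOVA:   F = %.3f (df %d, %d), p = %.3g; LSD: %s\n",
              x$anova$control$F, x$anova$control$df_between,
              x$anova$control$df_within, x$anova$control$p,
              x$lsd$control$ordering))
  invisible(x)
}
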