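# Slice-restricted Dice evaluation, group summaries, normality-gated
# two-sample testing with Bonferroni familywise correction, and the
# comparison plan over mask kinds and participant groups.

#' Slice-restricted Dice similarity coefficient
#'
#' Before computing the Dice overlap, the candidate mask is limited to the
#' axial slices (third axis) where the manual reference is present: all
#' candidate voxels on reference-free slices are cropped. This keeps the
#' evaluation focused on the chiasm and not perturbed by neighboring white
#' matter along the nerves and tracts. If the restriction empties the
#' candidate, the value is 0.
#'
#' @param candidate a binary mask.
#' @param manual the nonempty manual reference mask, same shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
slice_restricted_dsc <- function(candidate, manual) {
  cand <- as_mask_array(candidate)
  man <- as_mask_array(manual)
  if (!identical(dim(cand), dim(man))) stop("mask shapes differ")
  if (sum(man) == 0L) stop("manual mask is empty")
  present <- apply(man, 3, sum) > 0
  cand[, , !present] <- 0L
  if (sum(cand) == 0L) return(0)
  dsc(binary_mask(cand), binary_mask(man))
}

#' Group summary: mean and standard error of the mean
#'
#' @param values numeric vector with at least 2 entries.
#' @return Named vector `c(mean, sem)` with `sem = sd / sqrt(n)` (sample
#'   standard deviation, n - 1 denominator).
#' @export
group_summary <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  c(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into the K^2
#' statistic, chi-squared with 2 degrees of freedom under normality. Valid
#' for n >= 8.
#'
#' @param x numeric vector, n >= 8.
#' @return List with `statistic` (K^2) and `p.value`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) stop("zero variance sample")
  # skewness component (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xx * sqrt(2 / (A - 4))
  term2 <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Normality-gated two-sample comparison
#'
#' Both samples are first tested for normality with the
#' [dagostino_pearson()] test. If neither rejects at `alpha`, a two-tailed
#' pooled-variance two-sample t-test is used; otherwise the two-sided
#' Wilcoxon rank-sum test. The path actually taken is recorded. Samples
#' smaller than 8 are rejected unless a path is forced explicitly (the
#' normality test is undefined below that).
#'
#' @param a,b numeric samples.
#' @param alpha significance level of the normality gate (default 0.05).
#' @param force `NULL` (gate decides), `"t_test"` or `"rank_sum"`.
#' @param label optional comparison label carried into the result.
#' @return An object of class `chiasm_test`: list with `label`, `test`
#'   (`"t_test"` or `"rank_sum"`), `statistic`, `p_raw`, `normality_p`, `n`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, force = NULL, label = NULL) {
  if (is.null(force)) {
    if (length(a) < 8L || length(b) < 8L)
      stop("samples with n < 8 require an explicitly forced test path")
    if (stats::var(a) == 0 || stats::var(b) == 0) {
      # degenerate (constant) sample: normality is untestable and clearly
      # violated; fall through to the distribution-free path
      test <- "rank_sum"
      norm_p <- c(a = NA_real_, b = NA_real_)
    } else {
      pa <- dagostino_pearson(a)$p.value
      pb <- dagostino_pearson(b)$p.value
      test <- if (pa > alpha && pb > alpha) "t_test" else "rank_sum"
      norm_p <- c(a = pa, b = pb)
    }
  } else {
    test <- match.arg(force, c("t_test", "rank_sum"))
    norm_p <- c(a = NA_real_, b = NA_real_)
  }
  if (test == "t_test") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    p_raw <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    statistic <- unname(wt$statistic)
    p_raw <- wt$p.value
    # complete ties leave the normal approximation 0/0; no evidence either way
    if (is.nan(p_raw)) p_raw <- 1
  }
  structure(list(label = label %||% "", test = test, statistic = statistic,
                 p_raw = p_raw, normality_p = norm_p,
                 n = c(a = length(a), b = length(b))),
            class = "chiasm_test")
}

#' Bonferroni familywise correction
#'
#' Each corrected p-value is `min(1, raw * m)` for family size `m`.
#'
#' @param raw_ps raw p-values in \[0, 1\].
#' @param m family size, at least `length(raw_ps)`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(raw_ps, m = length(raw_ps)) {
  if (any(raw_ps < 0 | raw_ps > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(raw_ps)) stop("family size m smaller than number of p-values")
  pmin(1, raw_ps * m)
}

study_groups <- function() c("hcp_test_control", "chiasm_control", "chiasm_albinism")
study_mask_kinds <- function() c("atlas_initial", "atlas_corrected", "cnn")

#' Build the family-structured comparison plan
#'
#' Emits the labeled list of planned two-sample comparisons in three
#' families: (a) cross-comparison of initial and corrected atlas-mask
#' quality for the control groups — within-group initial vs corrected for
#' each control group, plus between-control-group comparisons of the
#' initial masks and of the corrected masks; (b) corrected vs network mask
#' within every group; (c) cross-group comparisons of the network mask for
#' all group pairs. For the reference configuration of three groups (two of
#' them controls) and three mask kinds this yields exactly 10 tests
#' (4 + 3 + 3). The Bonferroni family size is the full plan length.
#'
#' @param groups participant groups.
#' @param kinds candidate mask kinds; family membership keys on
#'   `"atlas_initial"`, `"atlas_corrected"` and `"cnn"`.
#' @param control_groups subset of `groups` regarded as controls (default:
#'   those whose name contains "control").
#' @return data.frame of class `chiasm_plan` with columns `label`, `family`,
#'   `group_a`, `kind_a`, `group_b`, `kind_b`.
#' @export
comparison_plan <- function(groups = study_groups(), kinds = study_mask_kinds(),
                            control_groups = grep("control", groups, value = TRUE)) {
  if (!all(control_groups %in% groups)) stop("unknown control group")
  rows <- list()
  add <- function(family, ga, ka, gb, kb) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = sprintf("%s:%s_vs_%s:%s", ga, ka, gb, kb),
      family = family, group_a = ga, kind_a = ka, group_b = gb, kind_b = kb,
      stringsAsFactors = FALSE)
  }
  has <- function(k) k %in% kinds
  # family a: atlas-initial vs atlas-corrected quality across control groups
  if (has("atlas_initial") && has("atlas_corrected")) {
    for (g in control_groups) add("a", g, "atlas_initial", g, "atlas_corrected")
    if (length(control_groups) >= 2) {
      cp <- utils::combn(control_groups, 2)
      for (j in seq_len(ncol(cp))) {
        add("a", cp[1, j], "atlas_initial", cp[2, j], "atlas_initial")
        add("a", cp[1, j], "atlas_corrected", cp[2, j], "atlas_corrected")
      }
    }
  }
  # family b: atlas-corrected vs network mask for all groups
  if (has("atlas_corrected") && has("cnn")) {
    for (g in groups) add("b", g, "atlas_corrected", g, "cnn")
  }
  # family c: cross-group comparisons of the network mask
  if (has("cnn") && length(groups) >= 2) {
    gp <- utils::combn(groups, 2)
    for (j in seq_len(ncol(gp))) add("c", gp[1, j], "cnn", gp[2, j], "cnn")
  }
  plan <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), family = character(),
               group_a = character(), kind_a = character(),
               group_b = character(), kind_b = character(),
               stringsAsFactors = FALSE)
  class(plan) <- c("chiasm_plan", "data.frame")
  plan
}

#' Evaluate a cohort of Dice records
#'
#' Takes one Dice record per (subject, mask kind) — columns `id`, `group`,
#' `kind`, `dsc` — and reproduces the results-table structure: per-cell
#' mean and SEM summaries plus the planned group comparisons, each run
#' through the normality-gated test with Bonferroni correction over the
#' whole plan.
#'
#' @param records data.frame with columns `id`, `group`, `kind`, `dsc`.
#' @param plan a [comparison_plan()]; defaults to the plan spanned by the
#'   groups and kinds present in `records`.
#' @param alpha normality-gate level.
#' @param force optional forced test path passed to [compare_groups()].
#' @return List of class `chiasm_eval` with `summary` (data.frame: group,
#'   kind, n, mean, sem) and `tests` (data.frame: label, family, test,
#'   statistic, p_raw, p_fwe, m).
#' @export
evaluate_cohort <- function(records, plan = NULL, alpha = 0.05, force = NULL) {
  stopifnot(all(c("id", "group", "kind", "dsc") %in% names(records)))
  if (any(records$dsc < 0 | records$dsc > 1)) stop("dsc values must be in [0, 1]")
  if (anyDuplicated(records[, c("id", "kind")]))
    stop("one record per (subject, kind) expected")
  groups <- sort(unique(records$group))   # stable under record order
  kinds <- sort(unique(records$kind))
  cells <- expand.grid(group = groups, kind = kinds, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    vals <- records$dsc[records$group == cells$group[i] &
                          records$kind == cells$kind[i]]
    if (length(vals) < 2L)
      stop(sprintf("cell (%s, %s) has fewer than 2 records",
                   cells$group[i], cells$kind[i]))
    gs <- group_summary(vals)
    data.frame(group = cells$group[i], kind = cells$kind[i],
               n = length(vals), mean = gs[["mean"]], sem = gs[["sem"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(plan)) plan <- comparison_plan(groups, kinds)
  m <- nrow(plan)
  tests <- do.call(rbind, lapply(seq_len(m), function(i) {
    va <- records$dsc[records$group == plan$group_a[i] &
                        records$kind == plan$kind_a[i]]
    vb <- records$dsc[records$group == plan$group_b[i] &
                        records$kind == plan$kind_b[i]]
    ct <- compare_groups(va, vb, alpha = alpha, force = force,
                         label = plan$label[i])
    data.frame(label = ct$label, family = plan$family[i], test = ct$test,
               statistic = ct$statistic, p_raw = ct$p_raw,
               p_fwe = NA_real_, m = m, stringsAsFactors = FALSE)
  }))
  if (!is.null(tests)) tests$p_fwe <- bonferroni(tests$p_raw, m)
  structure(list(summary = summ, tests = tests), class = "chiasm_eval")
}

#' @export
print.chiasm_eval <- function(x, ...) {
  cat("Per-group Dice summaries (mean +/- SEM):\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("\nPlanned comparisons (Bonferroni family size",
        x$tests$m[1], "):\n")
    print(x$tests[, c("label", "family", "test", "p_raw", "p_fwe")],
          row.names = FALSE)
  }
  invisible(x)
}
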