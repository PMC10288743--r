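# Rank-based group statistics: tie-corrected Mann-Whitney U with a normal
# approximation (no continuity correction), Kruskal-Wallis with tie
# correction, a Kolmogorov-Smirnov normality screen, and the comparison grid
# over the feature table.

# One TestResult row.
test_result <- function(test, groups, sizes, statistic, z_value = NA_real_,
                        p_value, tie_corrected) {
  stopifnot(p_value >= 0, p_value <= 1, all(sizes >= 1))
  tibble::tibble(
    test = test, groups = paste(groups, collapse = " vs "),
    sizes = paste(sizes, collapse = ","),
    statistic = statistic, z_value = z_value, p_value = p_value,
    tie_corrected = tie_corrected
  )
}

# Sum of (t^3 - t) over tie groups of the pooled sample.
tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' `U` is computed from midrank sums for the first sample
#' (`U = R_x - n_x (n_x + 1) / 2`); the standardized statistic is
#' `Z = (U - n_x n_y / 2) / sigma_U` with the tie-corrected `sigma_U` and no
#' continuity correction, and the two-sided p-value comes from the normal
#' approximation. `Z` is negative when the first sample's ranks are lower.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble: `test = "MWU"`, `statistic` (U of `x`),
#'   `z_value`, `p_value`, `tie_corrected`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4, 5))   # U = 0, Z < 0
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  N <- nx + ny
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- tie_term(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - ties / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  test_result("MWU", c("x", "y"), c(nx, ny), U, z, min(p, 1), ties > 0)
}

#' Exact two-sided Mann-Whitney p by permutation enumeration
#'
#' Enumerates all assignments of the pooled values to the two group sizes and
#' returns the fraction whose `|U - mu|` is at least the observed one. Only
#' feasible for small total n; used as the testing oracle for the normal
#' approximation.
#'
#' @param x,y Numeric samples with `choose(n, nx)` small enough to enumerate.
#' @return List with `U` (observed, for `x`) and `p` (exact two-sided).
#' @export
mwu_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  N <- nx + ny
  if (choose(N, nx) > 2e5) stop("sample too large for full enumeration")
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- nx * ny / 2
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(N, nx)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-12)
  list(U = U_obs, p = p)
}

#' Kruskal-Wallis rank test (tie-corrected)
#'
#' `H = 12 / (N (N + 1)) * sum n_i (rbar_i - rbar)^2`, divided by the tie
#' correction factor `1 - sum(t^3 - t) / (N^3 - N)`; p from the chi-squared
#' distribution with `k - 1` degrees of freedom. When every pooled value is
#' identical the tie factor vanishes and the declared convention `H = 0,
#' p = 1` applies.
#'
#' @param samples List of 2 or more numeric group samples.
#' @return A one-row tibble: `test = "KW"`, `statistic` (H), `p_value`,
#'   `tie_corrected`.
#' @export
kruskal_wallis <- function(samples) {
  samples <- lapply(samples, function(s) s[!is.na(s)])
  k <- length(samples)
  if (k < 2) stop("need at least two groups")
  sizes <- lengths(samples)
  if (any(sizes < 1)) stop("every group must be non-empty")
  N <- sum(sizes)
  if (N < 3) stop("need total n >= 3")
  pooled <- unlist(samples)
  r <- rank(pooled)
  grp <- rep(seq_len(k), sizes)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- tie_term(pooled)
  C <- 1 - ties / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  test_result("KW", names(samples) %||% paste0("g", seq_len(k)), sizes,
              H, NA_real_, p, ties > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample two-sided KS statistic of the sample against a normal
#' distribution with the sample's own mean and standard deviation; p from the
#' asymptotic KS distribution. (Estimating the parameters from the sample
#' makes the screen conservative.)
#'
#' @param x Numeric sample, `n >= 5`.
#' @return A one-row tibble: `test = "KS"`, `statistic` (D), `p_value`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need n >= 5")
  if (sd(x) == 0) stop("KS normality screen undefined for constant sample")
  k <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x), exact = FALSE))
  test_result("KS", "x vs normal", length(x), unname(k$statistic),
              NA_real_, k$p.value, anyDuplicated(x) > 0)
}

#' Group summaries (mean and SEM)
#'
#' Mean and standard error of the mean (`sd / sqrt(n)`) per grouping cell,
#' excluding missing features; excluded counts are reported.
#'
#' @param features Feature table (long or wide; any tibble).
#' @param value Column to summarize (tidy-eval).
#' @param ... Grouping columns (tidy-eval).
#' @return Tibble with `n`, `n_missing`, `mean`, `sem` per group; `sem` is
#'   `NA` when `n < 2`.
#' @export
summarize_features <- function(features, value, ...) {
  features |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n = sum(!is.na({{ value }})),
      n_missing = sum(is.na({{ value }})),
      mean = mean({{ value }}, na.rm = TRUE),
      sem = if (sum(!is.na({{ value }})) >= 2) {
        sd({{ value }}, na.rm = TRUE) / sqrt(sum(!is.na({{ value }})))
      } else NA_real_,
      .groups = "drop"
    )
}

#' Demographic summary of a subject table
#'
#' Mean and sample (n-1) standard deviation of age, rounded to 2 decimals
#' for reporting, diagnosis counts, and the range of impairment duration.
#'
#' @param subjects Tibble with columns `age`, `diagnosis` (or `group`) and
#'   `duration_months`.
#' @return List with `n`, `mean_age`, `sd_age`, `counts`, `duration_min`,
#'   `duration_max`.
#' @export
demographic_summary <- function(subjects) {
  if (nrow(subjects) == 0) stop("empty subject table")
  diag_col <- if ("diagnosis" %in% names(subjects)) "diagnosis" else "group"
  list(
    n = nrow(subjects),
    mean_age = round(mean(subjects$age), 2),
    sd_age = round(sd(subjects$age), 2),
    counts = table(subjects[[diag_col]]),
    duration_min = min(subjects$duration_months),
    duration_max = max(subjects$duration_months)
  )
}

#' The paper-style comparison grid over a feature table
#'
#' For each feature (`mean_conc`, `slope`) and chromophore, runs the group
#' comparisons of the study design: within-group condition contrasts
#' (healthy controls SON vs MI, patients SON vs MI; Mann-Whitney U),
#' two-group contrasts (controls vs pooled patients per condition;
#' Mann-Whitney U), and three-group contrasts (HC vs MCS vs VS per
#' condition; Kruskal-Wallis). Channels (and, in per-epoch mode, retained
#' trials) are pooled as observations; every result row carries the mode so
#' the observation unit is never implicit. Empty cells are skipped with a
#' warning.
#'
#' @param features Feature table from [build_feature_table()].
#' @param mode Label recorded in the results (`"per-epoch"` or
#'   `"block-avg"`).
#' @param alpha Significance level recorded alongside (default 0.05).
#' @return Tibble of test results with contrast provenance columns.
#' @export
run_comparisons <- function(features, mode = "per-epoch", alpha = 0.05) {
  long <- tidyr::pivot_longer(features, c("mean_conc", "slope"),
                              names_to = "feature", values_to = "value")
  long <- long[!is.na(long$value), ]
  long$coarse <- ifelse(long$group == "HC", "HC", "pDoC")
  pull_cell <- function(groups, cond, feat, chrom, by = "group") {
    lapply(stats::setNames(groups, groups), function(g) {
      long$value[long[[by]] == g & long$condition == cond &
                   long$feature == feat & long$chromophore == chrom]
    })
  }
  rows <- list()
  add <- function(res, contrast, feature, chromophore, condition) {
    res$contrast <- contrast; res$feature <- feature
    res$chromophore <- chromophore; res$condition <- condition
    res$mode <- mode; res$alpha <- alpha
    rows[[length(rows) + 1]] <<- res
  }
  for (feat in c("mean_conc", "slope")) {
    for (chrom in c("HbO", "HbR")) {
      # within-group condition contrasts
      for (g in c("HC", "pDoC")) {
        cells <- lapply(stats::setNames(.conditions, .conditions), function(cond) {
          long$value[long$coarse == g & long$condition == cond &
                       long$feature == feat & long$chromophore == chrom]
        })
        if (any(lengths(cells) == 0)) {
          warning("empty cell, skipping ", g, " SON vs MI for ", feat, "/", chrom)
          next
        }
        add(mann_whitney_u(cells$SON, cells$MI),
            paste0(g, ": SON vs MI"), feat, chrom, "SON vs MI")
      }
      for (cond in .conditions) {
        two <- pull_cell(c("HC", "pDoC"), cond, feat, chrom, by = "coarse")
        if (all(lengths(two) > 0)) {
          add(mann_whitney_u(two$HC, two$pDoC),
              "HC vs pDoC", feat, chrom, cond)
        } else {
          warning("empty cell, skipping HC vs pDoC at ", cond)
        }
        three <- pull_cell(.groups, cond, feat, chrom)
        if (all(lengths(three) > 0)) {
          add(kruskal_wallis(three), "HC vs MCS vs VS", feat, chrom, cond)
        } else {
          warning("empty cell, skipping three-group contrast at ", cond)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Export test results as JSON
#'
#' @param results Tibble from [run_comparisons()].
#' @param path Output path.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
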