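# Per-well aggregation and the nonparametric testing scheme: Shapiro-Wilk
# normality checks, a Kruskal-Wallis omnibus gate, then either a Steel
# many-to-one comparison against control or Dunn all-pairs joint-rank tests.
# The statistical unit is always the well mean, never the field.

#' Average field-level metrics per well
#'
#' Data are averaged per well before any statistical testing; fields whose
#' value is undefined (ND, stored as `NA`) are excluded from the mean with
#' their count reported. A well whose fields are all ND stays ND and is
#' excluded from tests downstream.
#'
#' @param field_metrics Tibble with one row per field: a `well_id` column,
#'   a `field` column, and one numeric column per metric.
#' @param layout Optional [read_plate_layout()] tibble to attach treatment
#'   labels.
#' @return Long tibble (class `well_summary`): `well_id`, `metric`, `mean`,
#'   `n_used`, `n_nd`, plus layout columns when supplied.
#' @export
aggregate_per_well <- function(field_metrics, layout = NULL) {
  stopifnot(all(c("well_id", "field") %in% names(field_metrics)))
  metric_cols <- setdiff(names(field_metrics)[vapply(field_metrics,
                                                     is.numeric, logical(1))],
                         c("field"))
  long <- tidyr::pivot_longer(
    field_metrics[, c("well_id", "field", metric_cols)],
    cols = dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(.data$well_id, .data$metric) |>
    dplyr::summarise(
      mean = if (any(is.finite(.data$value))) {
        base::mean(.data$value[is.finite(.data$value)])
      } else NA_real_,
      n_used = sum(is.finite(.data$value)),
      n_nd = sum(!is.finite(.data$value)),
      .groups = "drop"
    )
  if (!is.null(layout)) {
    out <- dplyr::left_join(out, layout, by = "well_id")
  }
  class(out) <- c("well_summary", class(out))
  out
}

#' Shapiro-Wilk normality check per group
#'
#' @param data Data frame of well-level values.
#' @param value,group Column names (tidy-eval) of the value and group.
#' @return Tibble: `group`, `n`, `shapiro_w`, `shapiro_p` (`NA` with a
#'   degenerate or too-small sample).
#' @export
shapiro_by_group <- function(data, value, group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      shapiro_w = tryCatch(
        stats::shapiro.test({{ value }})$statistic[[1]],
        error = function(e) NA_real_),
      shapiro_p = tryCatch(
        stats::shapiro.test({{ value }})$p.value,
        error = function(e) NA_real_),
      .groups = "drop"
    )
}

#' Kruskal-Wallis rank-sums test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom; used as the omnibus gate for the post-hoc tests.
#'
#' @inheritParams shapiro_by_group
#' @return One-row tibble: `kruskal_h`, `df`, `kruskal_p`, `n`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) stop("Need >= 2 groups.", call. = FALSE)
  if (length(v) < 3) stop("Need >= 3 observations in total.", call. = FALSE)
  kt <- stats::kruskal.test(v, g)
  tibble::tibble(kruskal_h = kt$statistic[[1]], df = kt$parameter[[1]],
                 kruskal_p = kt$p.value, n = length(v))
}

# Family-wise tail of max |Z| for equicorrelated many-to-one comparisons
# (one-factor representation: Z_i = lambda_i U + sqrt(1 - lambda_i^2) e_i,
# lambda_i = sqrt(n_i / (n_i + n0))), evaluated by Gaussian quadrature.
steel_mvn_tail <- function(q, n_treat, n_ctrl) {
  if (q <= 0) return(1)
  lam <- sqrt(n_treat / (n_treat + n_ctrl))
  s <- sqrt(1 - lam^2)
  f <- function(u) {
    p <- rep(1, length(u))
    for (i in seq_along(lam)) {
      p <- p * (stats::pnorm((q - lam[i] * u) / s[i]) -
                  stats::pnorm((-q - lam[i] * u) / s[i]))
    }
    p * stats::dnorm(u)
  }
  1 - stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
}

#' Steel many-to-one rank test
#'
#' Nonparametric analogue of Dunnett's test: each treatment is compared with
#' the control by a standardized pairwise rank-sum statistic (midranks,
#' tie-corrected variance), and the family-wise p-value of each comparison is
#' the tail probability of the maximum absolute statistic over all
#' comparisons under the joint null. The default reference distribution is a
#' Monte-Carlo permutation of that maximum (exact in the limit of
#' permutations); `method = "normal"` uses the correlated multivariate-normal
#' approximation instead.
#'
#' @inheritParams shapiro_by_group
#' @param control Label of the control group.
#' @param method `"permutation"` (default) or `"normal"`.
#' @param n_perm Number of permutations (default 10000).
#' @return Tibble (class `steel_test`): one row per treatment with
#'   `comparison`, `statistic` (standardized rank-sum z), `p_unadjusted`
#'   (two-sided normal, for reference) and `p_adjusted` (family-wise).
#'   Attributes record the method, permutation count and control label.
#' @export
steel_test <- function(data, value, group, control,
                       method = c("permutation", "normal"), n_perm = 10000) {
  method <- match.arg(method)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  if (!control %in% g) stop("Control group '", control, "' is empty.",
                            call. = FALSE)
  treatments <- setdiff(unique(g), control)
  if (!length(treatments)) stop("Need >= 1 treatment group.", call. = FALSE)
  gi <- integer(length(g))
  for (j in seq_along(treatments)) gi[g == treatments[j]] <- j
  z <- steel_observed_z(v, gi, length(treatments))
  p_un <- 2 * stats::pnorm(-abs(z))
  if (method == "permutation") {
    null_max <- steel_perm_null(v, gi, length(treatments), n_perm)
    p_adj <- vapply(abs(z), function(zz) {
      (sum(null_max >= zz - 1e-12) + 1) / (n_perm + 1)
    }, numeric(1))
  } else {
    n0 <- sum(gi == 0)
    nt <- vapply(seq_along(treatments), function(j) sum(gi == j), numeric(1))
    p_adj <- vapply(abs(z), steel_mvn_tail, numeric(1),
                    n_treat = nt, n_ctrl = n0)
  }
  out <- tibble::tibble(
    comparison = paste(treatments, "-", control),
    statistic = as.numeric(z),
    p_unadjusted = p_un,
    p_adjusted = pmin(1, p_adj)
  )
  attr(out, "method") <- method
  attr(out, "n_perm") <- if (method == "permutation") n_perm else NA_integer_
  attr(out, "control") <- control
  class(out) <- c("steel_test", class(out))
  out
}

#' Dunn all-pairs joint-rank test
#'
#' All observations are ranked jointly (midranks); each pair of groups is
#' compared by the standardized difference of mean ranks with tie-corrected
#' variance, and p-values are Bonferroni-adjusted over all pairs.
#'
#' @inheritParams shapiro_by_group
#' @return Tibble (class `dunn_test`): `comparison`, `statistic` (z),
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_all_pairs <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  groups <- sort(unique(g))
  if (length(groups) < 2) stop("Need >= 2 groups.", call. = FALSE)
  if (any(table(g) == 0)) stop("Empty group.", call. = FALSE)
  n <- length(v)
  r <- rank(v) # midranks
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_corr
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    na <- sum(g == a); nb <- sum(g == b)
    zden <- sqrt(var_base * (1 / na + 1 / nb))
    z <- (mean(r[g == a]) - mean(r[g == b])) / zden
    tibble::tibble(comparison = paste(a, "-", b), statistic = z,
                   p_unadjusted = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_unadjusted * ncol(pairs))
  class(out) <- c("dunn_test", class(out))
  out
}

significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.005 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Group comparison with omnibus gatekeeping
#'
#' The full per-metric testing scheme: Shapiro-Wilk per group (normality
#' record), a Kruskal-Wallis omnibus test, and - only when the omnibus test
#' rejects at `alpha` - a post-hoc procedure: Steel's many-to-one test when a
#' control group is designated, otherwise Dunn's all-pairs test. Significance
#' tiers follow the two-star convention (`*` p < 0.05, `**` p < 0.005).
#'
#' @inheritParams shapiro_by_group
#' @param control Optional control-group label; selects the Steel post-hoc.
#' @param alpha Gatekeeping level for the omnibus test (default 0.05).
#' @param metric Optional metric name carried into the output.
#' @param ... Passed to [steel_test()] (e.g. `method`, `n_perm`).
#' @return A `group_comparison` object: list with `metric`, `shapiro`,
#'   `kruskal`, `posthoc` (NULL when the gate does not reject), `alpha`.
#' @export
compare_groups <- function(data, value, group, control = NULL, alpha = 0.05,
                           metric = NULL, ...) {
  sh <- shapiro_by_group(data, {{ value }}, {{ group }})
  kw <- kruskal_wallis(data, {{ value }}, {{ group }})
  posthoc <- NULL
  if (is.finite(kw$kruskal_p) && kw$kruskal_p <= alpha) {
    posthoc <- if (!is.null(control)) {
      steel_test(data, {{ value }}, {{ group }}, control = control, ...)
    } else {
      dunn_all_pairs(data, {{ value }}, {{ group }})
    }
    posthoc$tier <- significance_tier(posthoc$p_adjusted)
  }
  structure(
    list(metric = metric %||% "value", shapiro = sh, kruskal = kw,
         posthoc = posthoc, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> metric: %s\n", x$metric))
  cat(sprintf("  Kruskal-Wallis H = %.3f (df %d), p = %.4g\n",
              x$kruskal$kruskal_h, x$kruskal$df, x$kruskal$kruskal_p))
  if (is.null(x$posthoc)) {
    cat(sprintf("  omnibus p > %.3g: no post-hoc tests performed\n", x$alpha))
  } else {
    print(as.data.frame(x$posthoc))
  }
  invisible(x)
}

#' Tidy a group comparison into one row per post-hoc contrast
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble: `metric`, `comparison`, `statistic`, `p_unadjusted`,
#'   `p_adjusted`, `tier` (empty when the omnibus gate did not reject).
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) {
    return(tibble::tibble(metric = character(), comparison = character(),
                          statistic = numeric(), p_unadjusted = numeric(),
                          p_adjusted = numeric(), tier = character()))
  }
  dplyr::mutate(tibble::as_tibble(x$posthoc), metric = x$metric,
                .before = 1)
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble: `metric`, `kruskal_h`, `df`, `kruskal_p`, `n`,
#'   `posthoc_performed`, `n_significant`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    kruskal_h = x$kruskal$kruskal_h, df = x$kruskal$df,
    kruskal_p = x$kruskal$kruskal_p, n = x$kruskal$n,
    posthoc_performed = !is.null(x$posthoc),
    n_significant = if (is.null(x$posthoc)) 0L
                    else sum(x$posthoc$p_adjusted < 0.05)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
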