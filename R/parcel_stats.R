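#' Build a long-format metric table
#'
#' Combines per-vertex metric maps with a surface parcellation and a cohort
#' row into the long per-(participant, hemisphere, parcel, metric) table that
#' feeds the parcel-level statistics.
#'
#' @param values Named list of per-vertex numeric vectors (one per metric).
#' @param surface The [build_midthickness_surface()] the maps live on.
#' @param participant One-row data frame with `participant`, `age`, `sex`,
#'   `hemisphere`.
#' @param parcellation `"subfield"` or `"longaxis"`.
#' @returns Tibble with columns `participant`, `age`, `sex`, `hemisphere`,
#'   `parcel`, `metric`, `value` (parcel means over valid vertices).
#' @export
metric_table <- function(values, surface, participant,
                         parcellation = c("subfield", "longaxis")) {
  parcellation <- match.arg(parcellation)
  lab <- surface$vertices[[parcellation]]
  p_id <- participant$participant[1]
  p_age <- participant$age[1]
  p_sex <- participant$sex[1]
  p_hemi <- participant$hemisphere[1]
  purrr::imap_dfr(values, function(v, nm) {
    tibble::tibble(parcel = lab, value = v) |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::group_by(.data$parcel) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(metric = nm)
  }) |>
    dplyr::mutate(participant = p_id, age = p_age, sex = p_sex,
                  hemisphere = p_hemi) |>
    dplyr::select("participant", "age", "sex", "hemisphere", "parcel",
                  "metric", "value")
}

#' Average hemispheres within participants
#'
#' Averages each (participant, parcel, metric) across the two hemispheres.
#' Averaging is only appropriate when the hemisphere-by-age interaction is
#' not significant; pass the corresponding [nested_f_test()] results (or set
#' `force = TRUE`) — metrics whose interaction is significant are refused and
#' kept hemisphere-resolved, with a message. Participants missing a
#' hemisphere are excluded (logged via a message).
#'
#' @param table A metric table (long format, both hemispheres present).
#' @param interaction_results Optional tibble with columns `metric` and
#'   `p_adj` (or `p`) from the age-by-hemisphere F-tests.
#' @param alpha Significance level for the refusal (default 0.05).
#' @param force Average regardless of interaction significance.
#' @returns The table with `hemisphere` collapsed to `"both"` for averaged
#'   metrics.
#' @export
hemisphere_average <- function(table, interaction_results = NULL,
                               alpha = 0.05, force = FALSE) {
  counts <- table |>
    dplyr::distinct(.data$participant, .data$hemisphere) |>
    dplyr::count(.data$participant)
  incomplete <- counts$participant[counts$n < 2]
  if (length(incomplete)) {
    message("excluding ", length(incomplete),
            " participant(s) with a missing hemisphere")
    table <- dplyr::filter(table, !.data$participant %in% incomplete)
  }
  refuse <- character(0)
  if (!force && !is.null(interaction_results)) {
    pcol <- if ("p_adj" %in% names(interaction_results)) "p_adj" else "p"
    refuse <- interaction_results$metric[interaction_results[[pcol]] < alpha]
    if (length(refuse))
      message("hemisphere-by-age interaction significant for ",
              paste(refuse, collapse = ", "),
              "; keeping hemispheres separate for those metrics")
  }
  keep <- dplyr::filter(table, .data$metric %in% refuse)
  avg <- table |>
    dplyr::filter(!.data$metric %in% refuse) |>
    dplyr::group_by(.data$participant, .data$age, .data$sex, .data$parcel,
                    .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(hemisphere = factor("both"))
  dplyr::bind_rows(avg, keep) |>
    dplyr::select("participant", "age", "sex", "hemisphere", "parcel",
                  "metric", "value")
}

#' Pearson age correlation within a parcel
#'
#' Two-sided Pearson correlation between age and a metric within one parcel,
#' with the study's significance ladder: the minimum alpha is 0.01
#' (the Bonferroni per-test level for 5 subfield tests at family-wise 0.05),
#' with more conservative thresholds 0.005 and 0.0005 also reported.
#'
#' @param table Long metric table (hemisphere-averaged).
#' @param parcel,metric Which parcel/metric to test.
#' @returns One-row tibble: `parcel`, `metric`, `n`, `r`, `p`, `asterisk`
#'   (`""`, `"*"`, `"**"`, `"***"` for p < 0.01 / 0.005 / 0.0005).
#' @export
age_correlation <- function(table, parcel, metric) {
  d <- dplyr::filter(table, .data$parcel == !!parcel, .data$metric == !!metric)
  if (nrow(d) < 3) stop("need at least 3 participants")
  if (sd(d$age) == 0 || sd(d$value) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(d$age, d$value, method = "pearson")
  tibble::tibble(parcel = parcel, metric = metric, n = nrow(d),
                 r = unname(ct$estimate), p = ct$p.value,
                 asterisk = asterisk_level(ct$p.value))
}

asterisk_level <- function(p) {
  dplyr::case_when(p < 0.0005 ~ "***", p < 0.005 ~ "**", p < 0.01 ~ "*",
                   TRUE ~ "")
}

#' All parcel-by-metric age correlations
#' @param table Long metric table.
#' @returns Tibble of [age_correlation()] rows for every (parcel, metric).
#' @export
age_correlation_all <- function(table) {
  combos <- dplyr::distinct(table, .data$parcel, .data$metric)
  purrr::pmap_dfr(combos, function(parcel, metric)
    age_correlation(table, parcel, metric))
}

#' Nested-model F-test
#'
#' Fits full and reduced linear models of the metric value and tests whether
#' the extra terms of the full model explain significant variance:
#' `F = ((SSE_red - SSE_full) / df_diff) / (SSE_full / df_full)`. Categorical
#' predictors use treatment coding with alphabetical (factor-level) reference
#' levels. Typical use follows the study design: full model
#' `value ~ age + parcel + sex + age:parcel + sex:parcel + age:sex` against
#' the same model without `age:sex` (or `age:parcel`, or `age:hemisphere`).
#'
#' @param table Long metric table for a single metric.
#' @param full_terms,reduced_terms Character vectors of model terms (the
#'   reduced terms must be a subset of the full terms).
#' @param response Response column (default `"value"`).
#' @returns One-row tibble of class `f_test_result`: `F`, `df1`, `df2`, `p`,
#'   `sse_full`, `sse_reduced`, `full`, `reduced`.
#' @export
nested_f_test <- function(table, full_terms, reduced_terms,
                          response = "value") {
  if (!all(reduced_terms %in% full_terms))
    stop("reduced terms must be a subset of full terms")
  f_full <- stats::reformulate(full_terms, response = response)
  f_red <- stats::reformulate(reduced_terms, response = response)
  m_full <- lm(f_full, data = table)
  m_red <- lm(f_red, data = table)
  if (any(is.na(coef(m_full))) || any(is.na(coef(m_red))))
    stop("rank-deficient design")
  sse_f <- sum(stats::residuals(m_full)^2)
  sse_r <- sum(stats::residuals(m_red)^2)
  df1 <- m_red$df.residual - m_full$df.residual
  df2 <- m_full$df.residual
  if (df1 == 0) stop("models have identical degrees of freedom")
  if (sse_f <= .Machine$double.eps * sse_r) {
    warning("full model fits exactly; F is infinite")
    Fv <- Inf; p <- 0
  } else {
    Fv <- ((sse_r - sse_f) / df1) / (sse_f / df2)
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  out <- tibble::tibble(F = Fv, df1 = df1, df2 = df2, p = p,
                        sse_full = sse_f, sse_reduced = sse_r,
                        full = paste(full_terms, collapse = " + "),
                        reduced = paste(reduced_terms, collapse = " + "))
  class(out) <- c("f_test_result", class(out))
  out
}

#' Age-interaction F-tests across metrics with FDR correction
#'
#' Runs the full-vs-reduced F-test for one interaction of interest
#' (`"age:sex"`, `"age:hemisphere"` or `"age:parcel"`) separately for each
#' metric in the table, then applies Benjamini-Hochberg correction across the
#' metric family.
#'
#' @param table Long metric table (all metrics).
#' @param interaction The term dropped from the full model.
#' @param base_terms Terms shared by both models; defaults to the study
#'   design `age + parcel + sex + age:parcel + sex:parcel` (with `parcel`
#'   swapped for `hemisphere` where appropriate).
#' @returns Tibble, one row per metric: F, dfs, `p`, `p_adj`.
#' @export
interaction_f_tests <- function(table,
                                interaction = c("age:sex", "age:hemisphere",
                                                "age:parcel"),
                                base_terms = NULL) {
  interaction <- match.arg(interaction)
  if (is.null(base_terms)) {
    # the shared design: age + parcel + sex + age:parcel + sex:parcel (+
    # age:sex when it is not itself under test); at n = 88 participants and
    # 5 parcels this reproduces the study's F(1,424) / F(4,424) shapes
    base_terms <- switch(interaction,
      "age:sex" = c("age", "parcel", "sex", "age:parcel", "sex:parcel"),
      "age:parcel" = c("age", "parcel", "sex", "sex:parcel", "age:sex"),
      "age:hemisphere" = c("age", "parcel", "sex", "age:parcel",
                           "sex:parcel", "age:sex", "hemisphere"))
  }
  metrics <- unique(table$metric)
  res <- purrr::map_dfr(metrics, function(m) {
    d <- dplyr::filter(table, .data$metric == m)
    ft <- nested_f_test(d, c(base_terms, interaction), base_terms)
    dplyr::mutate(ft, metric = m, .before = 1)
  })
  res$p_adj <- fdr_bh(res$p)
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment within one declared test family (monotonicity
#' enforced); a thin, named wrapper so the correction applied to each family
#' is explicit in analysis code.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @returns Adjusted p-values, `>=` the raw values.
#' @export
fdr_bh <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value family")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Bonferroni per-test alpha
#'
#' The per-test significance level that controls the family-wise error rate
#' at `alpha` across `n_tests` tests; with the study's five subfield tests at
#' family-wise 0.05 this gives the 0.01 minimum alpha of the significance
#' ladder.
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise level (default 0.05).
#' @returns `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}
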