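#' Variance-stabilizing transforms for vital rates
#'
#' Proportions (germination `g`, survival to flowering `s`) are arcsine
#' square root transformed; fecundity `f` and `lambda` are log10
#' transformed. `inverse_transform_vitals` undoes the transforms exactly.
#'
#' @param table a vital-rate table (one row per population; see
#'   [vital_rate_table()]); only the columns named in `proportions` /
#'   `log10_cols` that are present are transformed.
#' @param proportions columns to arcsine-sqrt transform.
#' @param log10_cols columns to log10 transform (must be positive).
#' @return the table with transformed columns.
#' @export
transform_vitals <- function(table, proportions = c("g", "s"),
                             log10_cols = c("f", "lambda")) {
  proportions <- intersect(proportions, names(table))
  log10_cols <- intersect(log10_cols, names(table))
  for (col in proportions) {
    x <- table[[col]]
    if (any(x < 0 | x > 1, na.rm = TRUE))
      stop("column ", col, " must lie in [0, 1] for arcsine-sqrt transform")
    table[[col]] <- asin(sqrt(x))
  }
  for (col in log10_cols) {
    x <- table[[col]]
    if (any(x <= 0, na.rm = TRUE))
      stop("column ", col, " must be positive for log10 transform")
    table[[col]] <- log10(x)
  }
  table
}

#' @rdname transform_vitals
#' @export
inverse_transform_vitals <- function(table, proportions = c("g", "s"),
                                     log10_cols = c("f", "lambda")) {
  proportions <- intersect(proportions, names(table))
  log10_cols <- intersect(log10_cols, names(table))
  for (col in proportions) table[[col]] <- sin(table[[col]])^2
  for (col in log10_cols) table[[col]] <- 10^table[[col]]
  table
}

design_factors <- function(table) {
  data.frame(
    biotype = factor(table$biotype, levels = BIOTYPES),
    selection = factor(table$selection, levels = SELECTIONS))
}

#' Two-way fixed-effect ANOVA on a vital-rate response
#'
#' Fits `response ~ biotype * selection` on the per-population table and
#' reports F tests for the biotype main effect (B), the selection main
#' effect (S), and their interaction (B x S) under two error-term
#' conventions:
#' \describe{
#'   \item{`"interaction"` (default)}{main effects are tested against the
#'     B x S interaction mean square (denominator df 2 in the full
#'     2 x 3 x 3 design) and the interaction against the within-cell
#'     residual (df 12) — the convention that reproduces a
#'     published-table df structure of (1,2), (2,2), (2,12).}
#'   \item{`"residual"`}{every effect is tested against the within-cell
#'     residual mean square (df 12 throughout), the plain fixed-effects
#'     convention.}
#' }
#' Sums of squares are Type III; in the balanced full design they coincide
#' with the sequential decomposition, and are computed from
#' [stats::aov()]. Both conventions are returned; `error` picks which one
#' the `F`/`p` columns report.
#'
#' @param table vital-rate table (transform first with
#'   [transform_vitals()] if desired).
#' @param response name of the response column.
#' @param error error-term convention for the reported F.
#' @return data frame with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p` (chosen convention) plus `F_residual`, `p_residual`,
#'   `df2_residual` (the all-over-residual alternative) and the
#'   underlying sums of squares.
#' @export
anova_two_way <- function(table, response,
                          error = c("interaction", "residual")) {
  error <- match.arg(error)
  if (!response %in% names(table))
    stop("response column not found: ", response)
  df <- design_factors(table)
  df$y <- table[[response]]
  if (any(is.na(df$y))) stop("response contains missing values")
  fit <- stats::aov(y ~ biotype * selection, data = df)
  ss <- summary(fit)[[1]]
  rn <- trimws(rownames(ss))
  get <- function(term, col) ss[rn == term, col]
  terms <- c("biotype", "selection", "biotype:selection")
  SS <- vapply(terms, get, numeric(1), col = "Sum Sq")
  DF <- vapply(terms, get, numeric(1), col = "Df")
  SS_res <- get("Residuals", "Sum Sq")
  DF_res <- get("Residuals", "Df")
  if (DF_res <= 0) stop("zero residual degrees of freedom")
  MS <- SS / DF
  MS_res <- SS_res / DF_res
  MS_int <- MS[["biotype:selection"]]
  DF_int <- DF[["biotype:selection"]]

  denom_MS <- c(MS_int, MS_int, MS_res)
  denom_DF <- c(DF_int, DF_int, DF_res)
  F_conv <- MS / denom_MS
  p_conv <- stats::pf(F_conv, DF, denom_DF, lower.tail = FALSE)
  F_res <- MS / MS_res
  p_res <- stats::pf(F_res, DF, DF_res, lower.tail = FALSE)

  out <- data.frame(
    effect = c("B", "S", "BxS"),
    df1 = unname(DF),
    df2 = unname(if (error == "interaction") denom_DF else
      rep(DF_res, 3)),
    F = unname(if (error == "interaction") F_conv else F_res),
    p = unname(if (error == "interaction") p_conv else p_res),
    F_residual = unname(F_res),
    p_residual = unname(p_res),
    df2_residual = rep(unname(DF_res), 3),
    sum_sq = unname(SS),
    mean_sq = unname(MS),
    stringsAsFactors = FALSE)
  attr(out, "residual") <- c(df = unname(DF_res), sum_sq = unname(SS_res),
                             mean_sq = unname(MS_res))
  attr(out, "response") <- response
  out
}

#' Two-way MANOVA on the vital rates
#'
#' Multivariate test of the biotype and selection effects (and their
#' interaction) across several responses jointly, on the transformed
#' per-population table. The default responses are the three vital rates
#' `g`, `s`, `f`; in the full design with 3 responses the selection effect
#' has an approximate F on (6, 22) df and the biotype effect on (3, 10) df
#' under Pillai's trace. The statistic family is configurable because a
#' published multivariate F is not always traceable to one family;
#' Pillai's trace is the default, Wilks' lambda and Hotelling-Lawley are
#' available.
#'
#' @param table transformed vital-rate table.
#' @param responses response columns entering jointly.
#' @param statistic `"Pillai"` (default), `"Wilks"`, or
#'   `"Hotelling-Lawley"`.
#' @return data frame with one row per effect: `effect`, `statistic`,
#'   `approx_F`, `df1`, `df2`, `p`.
#' @export
vital_manova <- function(table, responses = c("g", "s", "f"),
                         statistic = c("Pillai", "Wilks",
                                       "Hotelling-Lawley")) {
  statistic <- match.arg(statistic)
  missing_r <- setdiff(responses, names(table))
  if (length(missing_r) > 0L)
    stop("response column(s) not found: ", paste(missing_r, collapse = ", "))
  if (length(responses) < 2L) stop("need at least 2 responses for MANOVA")
  df <- design_factors(table)
  Y <- as.matrix(table[, responses, drop = FALSE])
  if (qr(stats::cov(Y))$rank < ncol(Y))
    stop("singular within-group covariance: responses are collinear; ",
         "drop a response or use fewer, independent responses")
  fit <- stats::manova(Y ~ biotype * selection, data = df)
  sm <- summary(fit, test = statistic)$stats
  rn <- trimws(rownames(sm))
  terms <- c("biotype", "selection", "biotype:selection")
  out <- data.frame(
    effect = c("B", "S", "BxS"),
    statistic = sm[match(terms, rn), statistic],
    approx_F = sm[match(terms, rn), "approx F"],
    df1 = sm[match(terms, rn), "num Df"],
    df2 = sm[match(terms, rn), "den Df"],
    p = sm[match(terms, rn), "Pr(>F)"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "family") <- statistic
  attr(out, "responses") <- responses
  out
}

#' Tukey post hoc pairwise comparisons
#'
#' All pairwise comparisons of the levels of one design factor on one
#' response, with p-values adjusted by the studentized range distribution
#' (Tukey's honest significant difference). The error mean square defaults
#' to the within-cell residual of the two-way model; the interaction mean
#' square can be chosen to match a main-effect test performed over the
#' interaction term.
#'
#' Intended as a follow-up to a significant omnibus effect; the function
#' warns (but does not refuse) when the omnibus F is not significant.
#'
#' @param table (transformed) vital-rate table.
#' @param response response column name.
#' @param factor `"selection"` or `"biotype"`.
#' @param error error mean square convention, as in [anova_two_way()].
#' @param omnibus_alpha level used for the non-significance warning.
#' @return data frame with one row per level pair: `level1`, `level2`,
#'   `diff` (level1 - level2 mean difference), `se`, `q`, `p_adj`.
#' @export
tukey_posthoc <- function(table, response,
                          factor = c("selection", "biotype"),
                          error = c("residual", "interaction"),
                          omnibus_alpha = 0.05) {
  factor <- match.arg(factor)
  error <- match.arg(error)
  aov_tab <- anova_two_way(table, response,
                           error = if (error == "interaction")
                             "interaction" else "residual")
  eff_row <- if (factor == "biotype") 1L else 2L
  if (is.na(aov_tab$p[eff_row]) || aov_tab$p[eff_row] > omnibus_alpha)
    warning("omnibus ", aov_tab$effect[eff_row], " effect on ", response,
            " is not significant (p = ",
            format(aov_tab$p[eff_row], digits = 3),
            "); post hoc comparisons are exploratory")

  fac <- design_factors(table)[[factor]]
  y <- table[[response]]
  lv <- levels(fac)
  if (length(lv) < 2L) stop("need at least 2 factor levels")
  means <- tapply(y, fac, mean)
  ns <- tapply(y, fac, length)
  if (error == "interaction") {
    MS_err <- aov_tab$mean_sq[3L]
    df_err <- aov_tab$df1[3L]  # interaction df
  } else {
    res <- attr(aov_tab, "residual")
    MS_err <- res[["mean_sq"]]
    df_err <- res[["df"]]
  }
  pairs <- utils::combn(lv, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(MS_err / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = length(lv), df = df_err,
                       lower.tail = FALSE)
    data.frame(level1 = i, level2 = j, diff = diff, se = se, q = q,
               p_adj = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "df_error") <- df_err
  out
}

#' Table of F tests for all standard responses
#'
#' Convenience wrapper running [anova_two_way()] on the transformed
#' germination, survival-to-flowering, fecundity (number of seeds) and
#' lambda responses, in the layout of a published F-statistic summary
#' (one column block per response, rows B, S, BxS).
#'
#' @param table untransformed vital-rate table (transforms are applied
#'   internally).
#' @inheritParams anova_two_way
#' @return data frame with columns `effect`, `df1`, `df2`, then
#'   `F_<response>`, `p_<response>` for each response.
#' @export
anova_summary_table <- function(table, error = c("interaction",
                                                 "residual")) {
  error <- match.arg(error)
  tt <- transform_vitals(table)
  responses <- intersect(c("g", "s", "f", "lambda"), names(tt))
  base <- NULL
  for (r in responses) {
    a <- anova_two_way(tt, r, error = error)
    if (is.null(base))
      base <- a[, c("effect", "df1", "df2")]
    base[[paste0("F_", r)]] <- a$F
    base[[paste0("p_", r)]] <- a$p
  }
  base
}
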