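check_cells_table <- function(table, response) {
  stopifnot(is.data.frame(table))
  need <- c("species", "eye_region", response)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("cells table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  table <- table[stats::complete.cases(table[, need]), , drop = FALSE]
  table$species <- factor(table$species, levels = c("Apis", "Bombus"))
  table$eye_region <- factor(table$eye_region,
                             levels = c("main_retina", "marginal_DRA", "DRA"))
  table$species <- droplevels(table$species)
  table$eye_region <- droplevels(table$eye_region)
  table
}

#' Two-way ANOVA on a cell-property table
#'
#' Fits `response ~ species + eye_region` (no interaction by default) by
#' ordinary least squares and reports Type-II sums of squares, appropriate
#' for the unbalanced group counts typical of single-cell recording
#' datasets: each factor's SS is the reduction in residual SS when it is
#' added last to the model containing the other factor.
#'
#' @param table Data frame with columns `species`, `eye_region` and the
#'   response (`ps` or `fwhm_circ`); incomplete rows are dropped.
#' @param response Response column name.
#' @param interaction Include the species:eye_region interaction term?
#' @return List: `table` (data frame with `term, sum_sq, df, f, p`),
#'   `residuals`, `df_residual`, `fit` (the underlying `lm`).
#' @export
two_way_anova <- function(table, response = c("ps", "fwhm_circ"),
                          interaction = FALSE) {
  response <- match.arg(response)
  table <- check_cells_table(table, response)
  if (nlevels(table$species) < 2L || nlevels(table$eye_region) < 2L) {
    stop("need >= 2 levels per factor (empty factor level?)", call. = FALSE)
  }
  rss_of <- function(rhs) {
    sum(stats::residuals(
      stats::lm(stats::reformulate(rhs, response = response),
                data = table))^2)
  }
  rhs_full <- if (interaction) "species * eye_region" else
    "species + eye_region"
  full <- stats::lm(stats::reformulate(rhs_full, response = response),
                    data = table)
  rss_full <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  ms_res <- rss_full / df_res
  rss_add <- if (interaction) rss_of("species + eye_region") else rss_full
  # Type II obeying marginality: each main effect added last to the
  # additive model; interaction (if any) tested against the full model
  terms <- data.frame(
    term = c("species", "eye_region"),
    sum_sq = c(rss_of("eye_region") - rss_add,
               rss_of("species") - rss_add),
    df = c(nlevels(table$species) - 1L, nlevels(table$eye_region) - 1L))
  if (interaction) {
    terms <- rbind(terms, data.frame(
      term = "species:eye_region",
      sum_sq = rss_add - rss_full,
      df = (nlevels(table$species) - 1L) * (nlevels(table$eye_region) - 1L)))
  }
  terms$f <- (terms$sum_sq / terms$df) / ms_res
  terms$p <- stats::pf(terms$f, terms$df, df_res, lower.tail = FALSE)
  list(table = terms, residuals = unname(stats::residuals(full)),
       df_residual = df_res, fit = full)
}

#' Shapiro-Wilk normality test on model residuals
#'
#' @param residuals Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(residuals) < 1e-12 * max(abs(residuals), 1)) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  sw <- stats::shapiro.test(residuals)
  list(W = unname(sw$statistic), p = sw$p.value)
}

# compact letter display: groups sharing a letter are not significantly
# different (insert-and-absorb over the significance graph)
letter_display <- function(groups, pairs, alpha = 0.05) {
  g <- length(groups)
  # connectivity: TRUE when NOT significantly different
  ok <- matrix(TRUE, g, g, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$group1[i]; b <- pairs$group2[i]
    if (pairs$p_adj[i] < alpha) ok[a, b] <- ok[b, a] <- FALSE
  }
  letters_out <- stats::setNames(rep("", g), groups)
  sets <- list()
  for (gr in groups) {
    placed <- FALSE
    for (si in seq_along(sets)) {
      if (all(ok[gr, sets[[si]]])) {
        sets[[si]] <- c(sets[[si]], gr)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- gr
  }
  # absorb redundant sets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]])) {
      keep[i] <- FALSE
    }
  }
  sets <- sets[keep]
  for (si in seq_along(sets)) {
    for (gr in sets[[si]]) {
      letters_out[gr] <- paste0(letters_out[gr], letters[si])
    }
  }
  letters_out
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Studentized-range-based pairwise comparisons of group means with
#' family-wise adjusted p-values, plus a compact letter display at
#' `alpha`: groups sharing a letter do not differ significantly. Groups
#' with fewer than 2 observations are flagged and excluded.
#'
#' @param table Data frame with the grouping column and response.
#' @param response Response column name.
#' @param group Grouping column (default `eye_region`).
#' @param alpha Significance level for the letter display.
#' @return List: `comparisons` (data frame `group1, group2, mean_diff, lwr,
#'   upr, p_adj`), `letters` (named character), `group_means`,
#'   `flagged_groups` (those excluded for n < 2).
#' @export
tukey_hsd <- function(table, response = "fwhm_circ", group = "eye_region",
                      alpha = 0.05) {
  stopifnot(is.data.frame(table), response %in% names(table),
            group %in% names(table))
  tab <- table[stats::complete.cases(table[, c(response, group)]), ]
  counts <- table(tab[[group]])
  flagged <- names(counts)[counts < 2L]
  tab <- tab[!(tab[[group]] %in% flagged), , drop = FALSE]
  tab[[group]] <- factor(as.character(tab[[group]]))
  if (nlevels(tab[[group]]) < 2L) {
    stop("need >= 2 groups with >= 2 observations", call. = FALSE)
  }
  fml <- stats::reformulate(group, response = response)
  fit <- stats::aov(fml, data = tab)
  tk <- stats::TukeyHSD(fit, which = group)[[group]]
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  cmp <- data.frame(
    group1 = vapply(nm, `[`, "", 1L),
    group2 = vapply(nm, `[`, "", 2L),
    mean_diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"], row.names = NULL
  )
  gm <- tapply(tab[[response]], tab[[group]], mean)
  list(comparisons = cmp,
       letters = letter_display(levels(tab[[group]]), cmp, alpha),
       group_means = gm,
       flagged_groups = flagged)
}

#' Linear model of RF size against polarization sensitivity
#'
#' Ordinary least squares `fwhm_circ ~ ps + species + eye_region` with
#' treatment coding and reference levels (Apis, main_retina), so
#' coefficients read as the PS slope (deg per PS unit), the species offset
#' and the eye-region offsets relative to the main retina.
#'
#' @param table Data frame with complete cases on `fwhm_circ`, `ps`,
#'   `species`, `eye_region`.
#' @return List: `coefficients` (data frame `term, estimate, se, t, p`),
#'   `residuals`, `fit`.
#' @export
fit_fwhm_ps_model <- function(table) {
  tab <- check_cells_table(table, "fwhm_circ")
  if (!"ps" %in% names(tab)) stop("cells table missing column: ps",
                                  call. = FALSE)
  tab <- tab[stats::complete.cases(tab[, c("fwhm_circ", "ps", "species",
                                           "eye_region")]), ]
  X <- stats::model.matrix(~ ps + species + eye_region, data = tab)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fwhm_circ ~ ps + species + eye_region, data = tab)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      se = sm[, 2], t = sm[, 3], p = sm[, 4],
                      row.names = NULL)
  list(coefficients = coefs, residuals = unname(stats::residuals(fit)),
       fit = fit)
}

#' Full statistics report for a cells table
#'
#' Convenience wrapper running the two-way ANOVAs on PS and FWHM (with
#' Shapiro-Wilk residual checks), Tukey HSD across eye regions for both
#' responses, and the FWHM ~ PS linear model. PS-excluded cells are dropped
#' from the PS analyses but keep contributing their FWHM.
#'
#' @param table Cells table (see [cells_table()]).
#' @return Nested list mirroring the report JSON schema.
#' @export
stats_report <- function(table) {
  ps_tab <- table
  if ("excluded" %in% names(ps_tab)) ps_tab <- ps_tab[!ps_tab$excluded, ]
  res <- list()
  run_block <- function(tab, resp) {
    an <- two_way_anova(tab, resp)
    list(anova = an$table,
         shapiro = shapiro_wilk(an$residuals),
         tukey = tukey_hsd(tab, response = resp)[c("comparisons", "letters",
                                                   "group_means")])
  }
  res$ps <- tryCatch(run_block(ps_tab, "ps"), error = function(e)
    list(error = conditionMessage(e)))
  res$fwhm <- tryCatch(run_block(table, "fwhm_circ"), error = function(e)
    list(error = conditionMessage(e)))
  res$fwhm_ps_model <- tryCatch(
    fit_fwhm_ps_model(ps_tab)["coefficients"],
    error = function(e) list(error = conditionMessage(e)))
  res
}
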