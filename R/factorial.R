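#' Between-subjects factorial ANOVA with generalized eta-squared
#'
#' Decomposes a balanced factorial response table into effect sums of
#' squares (via `stats::aov`), then reports the generalized eta-squared
#' effect size, F statistic and p-value per effect. With all factors
#' manipulated (the study design), generalized eta-squared reduces to
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' Single-replicate designs have no residual degrees of freedom; following
#' standard unreplicated-factorial practice the highest-order interaction is
#' pooled into the error term (`error_strategy = "pool_highest"`, the
#' default under `"auto"` when the residual df is zero).
#'
#' @param table Data frame containing the factors and the response.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (each must have at
#'   least two levels in the table).
#' @param error_strategy `"auto"`, `"pool_highest"` or `"residual"`.
#' @param log_transform If `TRUE`, analyse `log(response)` (the study
#'   responses span orders of magnitude; default off, matching analysis on
#'   the raw normalized scale).
#' @return A data frame of class `anova_effects`: columns `effect`, `df1`,
#'   `df2`, `ss`, `eta2_G`, `F`, `p`.
#' @export
anova_effects <- function(table, response, factors,
                          error_strategy = c("auto", "pool_highest",
                                             "residual"),
                          log_transform = FALSE) {
  error_strategy <- match.arg(error_strategy)
  stopifnot(is.data.frame(table), response %in% names(table),
            all(factors %in% names(table)))
  df <- table
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2)
      stop(sprintf("factor '%s' has fewer than 2 levels", f))
  }
  y <- df[[response]]
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires positive responses")
    y <- log(y)
  }
  df$.y <- y
  counts <- table(df[, factors, drop = FALSE])
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    stop("design is not balanced: unequal or empty cells")

  form <- stats::as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  fit <- stats::aov(form, data = df)
  ss_tab <- summary(fit)[[1]]
  terms <- trimws(rownames(ss_tab))
  ss <- ss_tab[["Sum Sq"]]
  dfs <- ss_tab[["Df"]]
  is_resid <- terms == "Residuals"
  err_ss <- sum(ss[is_resid])
  err_df <- sum(dfs[is_resid])
  eff <- terms[!is_resid]
  eff_ss <- ss[!is_resid]
  eff_df <- dfs[!is_resid]

  pool <- error_strategy == "pool_highest" ||
    (error_strategy == "auto" && err_df == 0)
  if (err_df == 0 && error_strategy == "residual")
    stop(paste("saturated model with no error term;",
               "use error_strategy = 'pool_highest' to pool the",
               "highest-order interaction"))
  if (pool) {
    order_k <- lengths(strsplit(eff, ":", fixed = TRUE))
    hi <- which(order_k == max(order_k))
    if (max(order_k) < 2 && err_df == 0)
      stop("cannot pool: no interaction term available as error")
    if (max(order_k) >= 2) {
      err_ss <- err_ss + sum(eff_ss[hi])
      err_df <- err_df + sum(eff_df[hi])
      eff <- eff[-hi]; eff_ss <- eff_ss[-hi]; eff_df <- eff_df[-hi]
    }
  }
  if (err_df == 0) stop("no error degrees of freedom after pooling")
  ms_err <- err_ss / err_df
  Fv <- (eff_ss / eff_df) / ms_err
  out <- data.frame(
    effect = eff, df1 = eff_df, df2 = err_df, ss = eff_ss,
    eta2_G = eff_ss / (eff_ss + err_ss),
    F = Fv, p = stats::pf(Fv, eff_df, err_df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  attr(out, "error_ss") <- err_ss
  attr(out, "error_df") <- err_df
  attr(out, "pooled") <- pool
  class(out) <- c("anova_effects", "data.frame")
  out
}

# expected design cells for each study subset
.subset_design <- function(which) {
  switch(which,
    centre = expand.grid(gauge = c("18G", "20G"), angle = c(5, 10),
                         rate = c(2.1, 50, 300), stringsAsFactors = FALSE),
    edge = expand.grid(gauge = c("18G", "20G"), angle = c(10, 15, 20),
                       rate = c(2.1, 50, 300), stringsAsFactors = FALSE),
    position = expand.grid(gauge = c("18G", "20G"),
                           position = c("centre", "edge"),
                           rate = c(2.1, 50, 300), stringsAsFactors = FALSE)
  )
}

#' Study subset analyses
#'
#' Runs the study's three subset ANOVAs on a metrics table: (1) centre tip
#' position (5 and 10 degree angles) with factors gauge, angle and rate;
#' (2) edge tip position (10, 15, 20 degrees) with the same factors;
#' (3) the position contrast at the 10 degree angle (the only angle with
#' both positions) with factors position, gauge and rate. Each subset is a
#' single-replicate design, so the highest-order interaction is pooled as
#' the error term.
#'
#' @param table Data frame with columns `gauge`, `angle`, `position`,
#'   `rate` and the response.
#' @param response Name of the response column.
#' @param ... Passed to [anova_effects()].
#' @return A list of class `study_effects` with elements `centre`, `edge`
#'   and `position_at_10`.
#' @export
study_subsets <- function(table, response, ...) {
  need <- c("gauge", "angle", "position", "rate", response)
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  check_cells <- function(sub, design, label) {
    key_t <- do.call(paste, c(sub[names(design)], sep = "|"))
    key_d <- do.call(paste, c(design, sep = "|"))
    missing <- setdiff(key_d, key_t)
    if (length(missing))
      stop(sprintf("%s subset is missing design cells: %s", label,
                   paste(missing, collapse = "; ")))
  }
  centre <- table[table$position == "centre", , drop = FALSE]
  check_cells(centre, .subset_design("centre"), "centre")
  edge <- table[table$position == "edge", , drop = FALSE]
  check_cells(edge, .subset_design("edge"), "edge")
  pos <- table[table$angle == 10, , drop = FALSE]
  check_cells(pos, .subset_design("position"), "position-at-10")
  structure(list(
    centre = anova_effects(centre, response,
                           c("gauge", "angle", "rate"), ...),
    edge = anova_effects(edge, response, c("gauge", "angle", "rate"), ...),
    position_at_10 = anova_effects(pos, response,
                                   c("position", "gauge", "rate"), ...)
  ), class = "study_effects", response = response)
}

#' @export
print.study_effects <- function(x, ...) {
  cat(sprintf("Study subset ANOVAs (response: %s)\n",
              attr(x, "response")))
  for (nm in names(x)) {
    cat(sprintf("-- %s --\n", nm))
    print.data.frame(x[[nm]], digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten study effects to a tidy table
#'
#' @param x A `study_effects` object.
#' @return A data frame with a `subset` column prepended.
#' @export
effects_table <- function(x) {
  stopifnot(inherits(x, "study_effects"))
  do.call(rbind, lapply(names(x), function(nm) {
    cbind(subset = nm, as.data.frame(x[[nm]]))
  }))
}
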