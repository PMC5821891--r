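#' Quadratic wall-shear surrogate model
#'
#' A quadratic model `WSS = a x^2 + b x + c` of wall shear stress over the
#' infusion rate `x` in mL/s, valid on `x` in `[0, 10]` mL/s (600 mL/min).
#' Objects support `coef`, `predict`, `print` and `plot`.
#'
#' @param a,b,c Model coefficients.
#' @param label Model label (e.g. `"20G-edge"`).
#' @param validity Validity interval of the rate in mL/s.
#' @return An object of class `wss_quad`.
#' @export
wss_quadratic <- function(a, b, c, label = "custom", validity = c(0, 10)) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  structure(list(coefficients = c(a = a, b = b, c = c), label = label,
                 validity = validity),
            class = "wss_quad")
}

#' Catalogue of the published infusion-rate/WSS models
#'
#' The four quadratic surrogates relating wall shear stress to the saline
#' infusion rate (mL/s) for each catheter gauge and tip position, with the
#' published coefficients kept verbatim:
#' \itemize{
#'   \item 18G-central: `4.0746 x^2 + 6.0725 x + 3.1187`
#'   \item 18G-edge:    `31.182 x^2 + 20.322 x + 4.196`
#'   \item 20G-central: `6.4093 x^2 + 20.513 x + 1.4294`
#'   \item 20G-edge:    `71.599 x^2 + 117.92 x - 1.1518`
#' }
#' The 20G-edge intercept is negative; evaluation near `x = 0` warns rather
#' than clamping so the printed coefficients stay bit-faithful.
#'
#' @return A named list of four `wss_quad` models.
#' @examples
#' coef(printed_models()[["20G-edge"]])
#' @export
printed_models <- function() {
  list(
    "18G-central" = wss_quadratic(4.0746, 6.0725, 3.1187, "18G-central"),
    "18G-edge" = wss_quadratic(31.182, 20.322, 4.196, "18G-edge"),
    "20G-central" = wss_quadratic(6.4093, 20.513, 1.4294, "20G-central"),
    "20G-edge" = wss_quadratic(71.599, 117.92, -1.1518, "20G-edge")
  )
}

#' @export
coef.wss_quad <- function(object, ...) object$coefficients

#' Evaluate a quadratic WSS model
#'
#' @param object A `wss_quad` model.
#' @param x Infusion rate(s) in mL/s, non-negative; values outside the
#'   model's validity interval trigger a warning.
#' @param ... Unused.
#' @return Predicted WSS at `x`.
#' @examples
#' predict(printed_models()[["18G-central"]], 1)  # 13.2658
#' @export
predict.wss_quad <- function(object, x, ...) {
  if (any(x < 0)) stop("infusion rate must be non-negative")
  if (any(x < object$validity[1] | x > object$validity[2]))
    warning(sprintf("evaluating '%s' outside its validity range [%g, %g] mL/s",
                    object$label, object$validity[1], object$validity[2]))
  cf <- object$coefficients
  out <- cf["a"] * x^2 + cf["b"] * x + cf["c"]
  if (any(out < 0))
    warning(sprintf("'%s' predicts negative WSS (negative intercept); %s",
                    object$label, "values returned unclamped"))
  out
}

#' @export
print.wss_quad <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("WSS surrogate '%s': WSS = %.6g x^2 + %.6g x + %.6g  (x in mL/s, valid [%g, %g])\n",
              x$label, cf["a"], cf["b"], cf["c"],
              x$validity[1], x$validity[2]))
  invisible(x)
}

#' @export
plot.wss_quad <- function(x, threshold = NULL, ...) {
  xs <- seq(x$validity[1], x$validity[2], length.out = 200)
  ys <- suppressWarnings(predict(x, xs))
  graphics::plot(xs, pmax(ys, 1e-3), type = "l", log = "y",
                 xlab = "infusion rate [mL/s]", ylab = "WSS [Pa]",
                 main = x$label, ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Fit a quadratic WSS surrogate to rate/WSS samples
#'
#' Ordinary least squares fit of `WSS = a x^2 + b x + c`; with exactly three
#' distinct rates the fit interpolates. At least three distinct `x` values
#' are required.
#'
#' @param x Infusion rates in mL/s.
#' @param wss Wall shear stress values (same length, typically normalized).
#' @param label Label for the fitted model.
#' @param validity Validity interval recorded on the model.
#' @return A `wss_quad` model.
#' @export
fit_wss_model <- function(x, wss, label = "fitted",
                          validity = range(c(0, 10, x))) {
  stopifnot(length(x) == length(wss))
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct infusion rates to fit a quadratic")
  fit <- stats::lm(wss ~ x + I(x^2))
  cf <- stats::coef(fit)
  wss_quadratic(unname(cf[3]), unname(cf[2]), unname(cf[1]),
                label = label, validity = validity)
}

#' Critical infusion rate at a shear threshold
#'
#' Inverts a quadratic WSS model against a critical wall-shear threshold
#' (default 38 Pa, the level above which endothelial cells are injured):
#' the smallest non-negative root of `a x^2 + b x + c = threshold`. Roots
#' outside the model's validity interval count as "never reached". The
#' exact root is returned together with a one-decimal presentation value.
#'
#' @param model A `wss_quad` model with `a > 0` or `b > 0`.
#' @param threshold Critical WSS in Pa.
#' @return A list of class `critical_rate` with elements `rate` (exact root
#'   in mL/s, `NA` if the threshold is not reached within validity),
#'   `presented` (rounded to one decimal), `threshold` and `label`.
#' @examples
#' critical_rate(printed_models()[["20G-edge"]])$presented  # 0.3
#' @export
critical_rate <- function(model, threshold = 38) {
  stopifnot(inherits(model, "wss_quad"), threshold > 0)
  cf <- model$coefficients
  a <- unname(cf["a"]); b <- unname(cf["b"]); c0 <- unname(cf["c"]) - threshold
  if (a == 0 && b == 0) stop("degenerate model: a = b = 0")
  roots <- if (a == 0) -c0 / b else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) numeric(0) else {
      # numerically stable quadratic roots
      q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
      unique(c(q / a, if (q != 0) c0 / q else -b / a))
    }
  }
  roots <- sort(roots[roots >= 0 & roots <= model$validity[2]])
  rate <- if (length(roots)) roots[1] else NA_real_
  structure(list(rate = rate,
                 presented = if (is.na(rate)) NA_real_ else round(rate, 1),
                 threshold = threshold, label = model$label),
            class = "critical_rate")
}

#' @export
print.critical_rate <- function(x, ...) {
  if (is.na(x$rate)) {
    cat(sprintf("'%s' does not reach %g Pa within its validity range\n",
                x$label, x$threshold))
  } else {
    cat(sprintf("'%s' reaches %g Pa at %.4g mL/s (presented: %.1f mL/s)\n",
                x$label, x$threshold, x$rate, x$presented))
  }
  invisible(x)
}

#' Export a model catalogue as JSON
#'
#' Writes the quadratic models with their coefficients as strings, so the
#' published values survive round-tripping verbatim.
#'
#' @param path Output file path.
#' @param models A list of `wss_quad` models.
#' @return The path, invisibly.
#' @export
write_models_json <- function(path, models = printed_models()) {
  out <- lapply(models, function(m) list(
    label = m$label,
    a = format(m$coefficients[["a"]], digits = 15),
    b = format(m$coefficients[["b"]], digits = 15),
    c = format(m$coefficients[["c"]], digits = 15),
    validity_mL_s = m$validity))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Critical-rate report for a model catalogue
#'
#' @param models A list of `wss_quad` models (default: the printed
#'   catalogue).
#' @param threshold Critical WSS in Pa.
#' @return A data frame with one row per model: label, threshold, exact and
#'   presented critical rate.
#' @export
critical_rate_table <- function(models = printed_models(), threshold = 38) {
  do.call(rbind, lapply(models, function(m) {
    cr <- critical_rate(m, threshold)
    data.frame(label = m$label, threshold_Pa = threshold,
               rate_mL_s = cr$rate, presented_mL_s = cr$presented,
               stringsAsFactors = FALSE)
  }))
}
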