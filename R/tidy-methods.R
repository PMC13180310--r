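# broom-style accessors and ggplot2 autoplot methods for the fit objects

#' @export
tidy.gls_fit <- function(x, ...) x$coefficients

#' @export
glance.gls_fit <- function(x, ...) {
  slope <- x$coefficients$estimate[x$coefficients$term == "x"]
  tibble::tibble(
    method = x$method,
    slope = if (length(slope)) slope else NA_real_,
    lambda = x$lambda, sigma2 = x$sigma2, r = x[["r"]] %||% NA_real_,
    logLik = x$logLik, AICc = x$AICc, n = x$n
  )
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("<gls_fit> method:", x$method,
      if (!is.na(x$lambda)) sprintf("(lambda = %.3f)", x$lambda) else "", "\n")
  print(x$coefficients)
  if (!is.null(x$contrasts)) {
    cat("group contrasts:\n"); print(x$contrasts)
  }
  invisible(x)
}

#' @export
tidy.ou_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("theta_", names(x$theta)), "alpha", "sigma2"),
    estimate = c(unname(x$theta), x$alpha, x$sigma2),
    std_error = c(unname(x$theta_se), NA_real_, NA_real_)
  )
}

#' @export
glance.ou_fit <- function(x, ...) {
  tibble::tibble(model = x$model, alpha = x$alpha, sigma2 = x$sigma2,
                 half_life = x$half_life,
                 stationary_variance = x$stationary_variance,
                 logLik = x$logLik, AICc = x$AICc, k = x$k, n = x$n)
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("<ou_fit> %s: alpha = %.4g /MY (half-life %.1f MY), sigma2 = %.4g\n",
              x$model, x$alpha, x$half_life, x$sigma2))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.bm_fit <- function(x, ...) {
  tibble::tibble(term = c(paste0("sigma2_", names(x$sigma2)), "root"),
                 estimate = c(unname(x$sigma2), x$root))
}

#' @export
glance.bm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, root = x$root, logLik = x$logLik,
                 AICc = x$AICc, k = x$k, n = x$n)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  s <- x$states
  tibble::tibble(
    term = c(paste0(s[1], "->", s[2]), paste0(s[2], "->", s[1])),
    estimate = unname(x$rates)
  )
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, AICc = x$AICc,
                 k = x$k, n = x$n)
}

#' @export
tidy.shift_posterior <- function(x, ...) x$branch

#' @export
glance.shift_posterior <- function(x, ...) {
  tibble::tibble(
    flavour = x$flavour,
    k_median = x$k_median, k_mode = x$k_mode,
    k_hpd_low = x$k_hpd[1], k_hpd_high = x$k_hpd[2],
    alpha_mean = mean(x$samples$alpha), sigma2_mean = mean(x$samples$sigma2),
    half_life_mean = mean(log(2) / x$samples$alpha),
    root_theta = x$root_theta,
    root_beta = x$root_beta %||% NA_real_,
    rhat_flag = x$rhat_flag
  )
}

#' @export
print.shift_posterior <- function(x, ...) {
  cat(sprintf("<shift_posterior> %s flavour: %d retained samples\n",
              x$flavour, nrow(x$samples)))
  cat(sprintf("k median %.1f (95%% HPD %d-%d); %d branch(es) with pp >= 0.2\n",
              x$k_median, x$k_hpd[1], x$k_hpd[2], sum(x$branch$pp >= 0.2)))
  invisible(x)
}

#' @export
tidy.path_model_set <- function(x, ...) x$table

#' @export
glance.path_model_set <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$table),
                 n_supported = length(x$supported),
                 best = x$table$model[1],
                 best_CICc = x$table$CICc[1])
}

#' Plot an allometry fit
#'
#' Species-mean scatter with the fitted regression line (and the isometric
#' slope-one reference, dotted).
#'
#' @param object A `gls_fit` from [fit_ols()], [fit_pgls()] or
#'   [fit_pgls_ives()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gls_fit <- function(object, ...) {
  cf <- object$coefficients
  a <- cf$estimate[cf$term == "(Intercept)"]
  b <- cf$estimate[cf$term == "x"]
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(intercept = a, slope = b) +
    ggplot2::geom_abline(intercept = mean(object$data$y) - mean(object$data$x),
                         slope = 1, linetype = "dotted") +
    ggplot2::labs(x = "log10 body mass (g)", y = "log10 SMR",
                  title = sprintf("%s: slope %.2f", object$method, b)) +
    ggplot2::theme_minimal()
}

#' Plot a shift posterior
#'
#' @param object A `shift_posterior`.
#' @param type `"pp"` (per-branch shift probabilities) or `"k"` (posterior of
#'   the shift count).
#' @param pp_threshold Reference line for the reporting threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shift_posterior <- function(object, type = c("pp", "k"),
                                     pp_threshold = 0.2, ...) {
  type <- match.arg(type)
  if (type == "pp") {
    ggplot2::ggplot(object$branch,
                    ggplot2::aes(x = .data$edge, y = .data$pp)) +
      ggplot2::geom_segment(ggplot2::aes(xend = .data$edge, yend = 0)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = pp_threshold, linetype = "dashed") +
      ggplot2::labs(x = "edge", y = "posterior shift probability") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$k_posterior,
                    ggplot2::aes(x = .data$k, y = .data$prob)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "number of shifts k", y = "posterior probability") +
      ggplot2::theme_minimal()
  }
}

#' Plot a macroevolutionary model table
#'
#' @param object A `model_table` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot of Akaike weights.
#' @export
autoplot.model_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}
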