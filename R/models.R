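#' Percentage root-mean-square deviation
#'
#' The model-comparison metric used throughout: the root-mean-square of
#' the relative deviations between observed and predicted solubilities,
#' as a percentage,
#' \deqn{RMSD\% = 100\sqrt{\frac{1}{N}\sum_i
#'   \left(\frac{obs_i - pred_i}{obs_i}\right)^2}}
#' Per-series values are aggregated into an overall figure by an
#' unweighted mean across composition series (see [compare_models()]).
#'
#' @param observed Strictly positive observed solubilities.
#' @param predicted Predicted solubilities, same length.
#' @return Nonnegative percentage; zero iff predictions match exactly.
#' @export
#' @examples
#' rmsd_percent(c(1, 2), c(1.1, 1.8))   # 10
rmsd_percent <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  if (any(observed == 0)) {
    stop("observed solubilities must be nonzero (relative deviations)",
         call. = FALSE)
  }
  100 * sqrt(mean(((observed - predicted) / observed)^2))
}

#' Van't Hoff solubility correlation for one composition series
#'
#' Fits ln x = a + b/T by ordinary least squares of ln x on 1/T. The two
#' coefficients correlate the temperature dependence of solubility within
#' one solvent composition; the fit quality is summarised by R^2 of the
#' log-space regression and the [rmsd_percent()] of the back-transformed
#' predictions.
#'
#' @param temperature Temperatures in K (>= 2 distinct).
#' @param x Mole-fraction solubilities in (0, 1), same length.
#' @return Object of class `vant_hoff_fit`: list with `a`, `b` (K),
#'   `r_squared`, `rmsd_percent`, `n`.
#' @seealso [fit_apelblat()], [predict.vant_hoff_fit()]
#' @export
#' @examples
#' s <- reference_grid(); s <- s[s$mass_fraction_cosolvent == 1, ]
#' fit_vant_hoff(s$temperature_K, s$x_exp)   # a ~ 18.2, b ~ -6450
fit_vant_hoff <- function(temperature, x) {
  if (length(temperature) != length(x)) {
    stop("temperature and x must have equal length", call. = FALSE)
  }
  if (length(unique(temperature)) < 2) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  if (any(x <= 0 | x >= 1)) {
    stop("x must lie in the open interval (0, 1)", call. = FALSE)
  }
  fit <- stats::lm(log(x) ~ I(1 / temperature))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  pred <- exp(a + b / temperature)
  structure(list(a = a, b = b,
                 r_squared = r_squared_of(log(x), a + b / temperature),
                 rmsd_percent = rmsd_percent(x, pred),
                 n = length(x)),
            class = "vant_hoff_fit")
}

#' @param object A fitted model object.
#' @param temperature Temperatures (K) at which to predict.
#' @param ... Unused.
#' @return Predicted mole-fraction solubilities.
#' @rdname fit_vant_hoff
#' @export
predict.vant_hoff_fit <- function(object, temperature, ...) {
  exp(object$a + object$b / temperature)
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> ln x = %.4f %+.2f/T (R2 = %.4f, RMSD = %.2f%%)\n",
              x$a, x$b, x$r_squared, x$rmsd_percent))
  invisible(x)
}

#' Modified Apelblat solubility correlation for one composition series
#'
#' Fits ln x = A + B/T + C ln T. The model is linear in its three
#' parameters, so it is estimated by least squares in the basis
#' (1, 1/T, ln T) rather than by iterative nonlinear search. Over a narrow
#' temperature window 1/T and ln T are nearly collinear, so individual
#' coefficients are poorly determined even when predictions are excellent;
#' judge the fit in prediction space (`rmsd_percent`), not coefficient
#' space. A conditioning note is attached when the basis is numerically
#' near-singular.
#'
#' @param temperature Temperatures in K (>= 3 distinct, or 2 with
#'   `fix_C = 0`).
#' @param x Mole-fraction solubilities in (0, 1), same length.
#' @param fix_C If 0, constrains C and the fit reduces exactly to
#'   [fit_vant_hoff()] with (a, b) = (A, B); `NULL` (default) estimates C.
#' @return Object of class `apelblat_fit`: list with `A`, `B` (K), `C`,
#'   `r_squared`, `rmsd_percent`, `n`, `conditioning` (reciprocal
#'   condition estimate of the basis).
#' @export
#' @examples
#' s <- reference_grid(); s <- s[s$mass_fraction_cosolvent == 1, ]
#' fit_apelblat(s$temperature_K, s$x_exp)$rmsd_percent
fit_apelblat <- function(temperature, x, fix_C = NULL) {
  if (length(temperature) != length(x)) {
    stop("temperature and x must have equal length", call. = FALSE)
  }
  if (any(x <= 0 | x >= 1)) {
    stop("x must lie in the open interval (0, 1)", call. = FALSE)
  }
  n_distinct <- length(unique(temperature))
  if (is.null(fix_C)) {
    if (n_distinct < 3) {
      stop("need at least 3 distinct temperatures for the 3-parameter ",
           "Apelblat model", call. = FALSE)
    }
    fit <- stats::lm(log(x) ~ I(1 / temperature) + log(temperature))
    cf <- stats::coef(fit)
    A <- unname(cf[1]); B <- unname(cf[2]); C <- unname(cf[3])
    X <- cbind(1, 1 / temperature, log(temperature))
  } else {
    if (!identical(as.numeric(fix_C), 0)) {
      stop("only fix_C = 0 (the nested van't Hoff model) is supported",
           call. = FALSE)
    }
    vh <- fit_vant_hoff(temperature, x)
    A <- vh$a; B <- vh$b; C <- 0
    X <- cbind(1, 1 / temperature)
  }
  kappa_inv <- 1 / kappa(X, exact = TRUE)
  lnpred <- A + B / temperature + C * log(temperature)
  pred <- exp(lnpred)
  out <- structure(list(A = A, B = B, C = C,
                        r_squared = r_squared_of(log(x), lnpred),
                        rmsd_percent = rmsd_percent(x, pred),
                        n = length(x),
                        conditioning = kappa_inv),
                   class = "apelblat_fit")
  if (kappa_inv < 1e-12) {
    warning("Apelblat basis is numerically near-singular; coefficients ",
            "are not individually interpretable", call. = FALSE)
  }
  out
}

#' @rdname fit_apelblat
#' @param object A fitted `apelblat_fit`.
#' @param ... Unused.
#' @export
predict.apelblat_fit <- function(object, temperature, ...) {
  exp(object$A + object$B / temperature + object$C * log(temperature))
}

#' @export
print.apelblat_fit <- function(x, ...) {
  cat(sprintf("<apelblat_fit> ln x = %.2f %+.2f/T %+.2f ln T (R2 = %.4f, RMSD = %.2f%%)\n",
              x$A, x$B, x$C, x$r_squared, x$rmsd_percent))
  invisible(x)
}

#' Yalkowsky-Roseman log-linear mixed-solvent prediction
#'
#' The log-linear co-solvency rule: the base-10 logarithm of the mixed
#' solubility is the mass-fraction-weighted blend of the pure-solvent
#' log-solubilities at the same temperature,
#' \deqn{\log_{10} x^{Yal} = m_1 \log_{10} x_1 + m_2 \log_{10} x_2,}
#' with m2 = 1 - m1. It has no fitted parameter; the two pure-solvent
#' solubilities are its inputs.
#'
#' @param x1 Solubility in pure co-solvent, in (0, 1).
#' @param x2 Solubility in pure anti-solvent, in (0, 1).
#' @param m1 Co-solvent mass fraction(s) in \[0, 1\].
#' @return Base-10 logarithm(s) of the predicted mole-fraction
#'   solubility.
#' @export
#' @examples
#' predict_yalkowsky(3.15e-2, 2.23e-5, 0.8)   # -2.13
predict_yalkowsky <- function(x1, x2, m1) {
  if (any(x1 <= 0 | x1 >= 1) || any(x2 <= 0 | x2 >= 1)) {
    stop("pure-solvent solubilities must lie in (0, 1)", call. = FALSE)
  }
  if (any(m1 < 0 | m1 > 1)) {
    stop("m1 must lie in [0, 1]", call. = FALSE)
  }
  m1 * log10(x1) + (1 - m1) * log10(x2)
}

# Measured endpoint log-solubilities by temperature; errors if either
# pure-solvent series is absent or misses a temperature used by the grid.
endpoint_lookup <- function(grid) {
  ms <- grid$mass_fraction_cosolvent
  if (!any(ms == 1) || !any(ms == 0)) {
    stop("grid must contain both pure-solvent series (m = 0 and m = 1)",
         call. = FALSE)
  }
  temps <- sort(unique(grid$temperature_K))
  s1 <- grid_series(grid, 1); s2 <- grid_series(grid, 0)
  if (!all(temps %in% s1$temperature_K) || !all(temps %in% s2$temperature_K)) {
    stop("pure-solvent series must cover every temperature in the grid",
         call. = FALSE)
  }
  list(temps = temps,
       lnx1 = log(s1$x_exp[match(temps, s1$temperature_K)]),
       lnx2 = log(s2$x_exp[match(temps, s2$temperature_K)]))
}

#' Jouyban-Acree co-solvency model (pure and van't Hoff-combined forms)
#'
#' Fits the Jouyban-Acree model of mixed-solvent solubility across the
#' whole (composition x temperature) grid:
#' \deqn{\ln x_{m,T} = m_1 \ln x_1 + m_2 \ln x_2 +
#'   \frac{m_1 m_2}{T}\sum_{i=0}^{ord} J_i (m_1 - m_2)^i}
#' The interaction coefficients J_i are estimated by no-intercept least
#' squares of the excess log-solubility (the measured mixed-cell ln x
#' minus the blended endpoint terms) on the basis functions
#' m1 m2 (m1 - m2)^i / T. The interaction term vanishes identically at
#' the endpoints, and at m = 0.5 only J0 contributes.
#'
#' In the pure form the endpoint terms use the measured pure-solvent
#' solubilities at each temperature. In the combined
#' Jouyban-Acree-van't Hoff form each endpoint series is first summarised
#' by its own [fit_vant_hoff()] correlation,
#' \deqn{\ln x_{m,T} = m_1 (A_1 + B_1/T) + m_2 (A_2 + B_2/T) +
#'   \frac{m_1 m_2}{T}\sum_i J_i (m_1 - m_2)^i,}
#' making the model fully parametric in (A1, B1, A2, B2, J).
#'
#' Per-series RMSD covers the mixed compositions in the pure form (the
#' endpoints are reproduced identically by construction there) and all
#' compositions in the combined form; the overall figure is the
#' unweighted mean of the per-series values.
#'
#' @param grid A [solubility_grid()] containing both pure-solvent series
#'   and at least one mixed composition.
#' @param order Highest power of (m1 - m2) in the interaction sum: 0, 1
#'   or 2 (default 2).
#' @param combined_with_vant_hoff `TRUE` for the
#'   Jouyban-Acree-van't Hoff form.
#' @return Object of class `jouyban_acree_fit`: list with `j_coeffs`
#'   (named J0..), `order`, `combined_with_vant_hoff`, endpoint
#'   coefficients `A1`, `B1`, `A2`, `B2` (combined form only), a
#'   `per_series` tibble of RMSDs and `overall_rmsd_percent`.
#' @export
#' @examples
#' fit_jouyban_acree(reference_grid())$overall_rmsd_percent
fit_jouyban_acree <- function(grid, order = 2,
                              combined_with_vant_hoff = FALSE) {
  stopifnot(inherits(grid, "solubility_grid"))
  if (!order %in% 0:2) stop("order must be 0, 1 or 2", call. = FALSE)
  ep <- endpoint_lookup(grid)
  ms <- grid_compositions(grid)
  if (length(setdiff(ms, c(0, 1))) == 0) {
    stop("grid has no mixed composition to fit the interaction term on",
         call. = FALSE)
  }
  m1 <- grid$mass_fraction_cosolvent
  m2 <- 1 - m1
  temps <- grid$temperature_K
  lnx <- log(grid$x_exp)
  if (combined_with_vant_hoff) {
    s1 <- grid_series(grid, 1); s2 <- grid_series(grid, 0)
    vh1 <- fit_vant_hoff(s1$temperature_K, s1$x_exp)
    vh2 <- fit_vant_hoff(s2$temperature_K, s2$x_exp)
    lnx1 <- vh1$a + vh1$b / temps
    lnx2 <- vh2$a + vh2$b / temps
    endpoints <- list(A1 = vh1$a, B1 = vh1$b, A2 = vh2$a, B2 = vh2$b)
  } else {
    idx <- match(temps, ep$temps)
    lnx1 <- ep$lnx1[idx]
    lnx2 <- ep$lnx2[idx]
    endpoints <- list(A1 = NULL, B1 = NULL, A2 = NULL, B2 = NULL)
  }
  y <- lnx - m1 * lnx1 - m2 * lnx2
  X <- sapply(0:order, function(i) m1 * m2 * (m1 - m2)^i / temps)
  X <- matrix(X, ncol = order + 1)
  keep <- m1 > 0 & m1 < 1   # endpoint rows carry a zero basis; drop them
  J <- unname(stats::coef(stats::lm.fit(X[keep, , drop = FALSE], y[keep])))
  names(J) <- paste0("J", 0:order)
  pred_lnx <- m1 * lnx1 + m2 * lnx2 + drop(X %*% J)
  series_set <- if (combined_with_vant_hoff) ms else setdiff(ms, c(0, 1))
  per_series <- tibble::tibble(
    mass_fraction_cosolvent = series_set,
    rmsd_percent = vapply(series_set, function(m) {
      sel <- m1 == m
      rmsd_percent(grid$x_exp[sel], exp(pred_lnx[sel]))
    }, numeric(1))
  )
  structure(c(list(j_coeffs = J, order = order,
                   combined_with_vant_hoff = combined_with_vant_hoff,
                   per_series = per_series,
                   overall_rmsd_percent = mean(per_series$rmsd_percent),
                   endpoint_temps = ep$temps,
                   endpoint_lnx1 = ep$lnx1, endpoint_lnx2 = ep$lnx2),
              endpoints),
            class = "jouyban_acree_fit")
}

#' @rdname fit_jouyban_acree
#' @param object A fitted `jouyban_acree_fit`.
#' @param m Co-solvent mass fraction(s) in \[0, 1\].
#' @param temperature Temperatures in K. For the pure form these must be
#'   temperatures at which the endpoint series were measured.
#' @param ... Unused.
#' @export
predict.jouyban_acree_fit <- function(object, m, temperature, ...) {
  n <- max(length(m), length(temperature))
  m1 <- rep_len(m, n); temps <- rep_len(temperature, n)
  m2 <- 1 - m1
  if (object$combined_with_vant_hoff) {
    lnx1 <- object$A1 + object$B1 / temps
    lnx2 <- object$A2 + object$B2 / temps
  } else {
    idx <- match(temps, object$endpoint_temps)
    if (anyNA(idx)) {
      stop("pure-form prediction requires a measured endpoint ",
           "temperature", call. = FALSE)
    }
    lnx1 <- object$endpoint_lnx1[idx]
    lnx2 <- object$endpoint_lnx2[idx]
  }
  terms <- vapply(seq_along(object$j_coeffs), function(k) {
    object$j_coeffs[k] * m1 * m2 * (m1 - m2)^(k - 1) / temps
  }, numeric(n))
  interaction <- rowSums(matrix(terms, nrow = n))
  exp(m1 * lnx1 + m2 * lnx2 + interaction)
}

#' @export
print.jouyban_acree_fit <- function(x, ...) {
  form <- if (x$combined_with_vant_hoff) "Jouyban-Acree-van't Hoff" else "Jouyban-Acree"
  cat(sprintf("<jouyban_acree_fit> %s, order %d: J = [%s], overall RMSD = %.2f%%\n",
              form, x$order, paste(sprintf("%.2f", x$j_coeffs), collapse = ", "),
              x$overall_rmsd_percent))
  invisible(x)
}

# Yalkowsky-Roseman per-series RMSD against measured endpoints.
yalkowsky_series <- function(grid) {
  ep <- endpoint_lookup(grid)
  mixed <- setdiff(grid_compositions(grid), c(0, 1))
  tibble::tibble(
    mass_fraction_cosolvent = mixed,
    rmsd_percent = vapply(mixed, function(m) {
      s <- grid_series(grid, m)
      idx <- match(s$temperature_K, ep$temps)
      logpred <- predict_yalkowsky(exp(ep$lnx1[idx]), exp(ep$lnx2[idx]), m)
      rmsd_percent(s$x_exp, 10^logpred)
    }, numeric(1))
  )
}

#' Fit and compare the five co-solvency models on a grid
#'
#' Runs the van't Hoff, Apelblat, Yalkowsky-Roseman, Jouyban-Acree and
#' Jouyban-Acree-van't Hoff models on a solubility grid and reports, for
#' each, the per-composition-series [rmsd_percent()] and the overall
#' value (unweighted mean over series). Van't Hoff and Apelblat are fit
#' per series and their RMSDs cover every composition; Yalkowsky-Roseman
#' and the pure Jouyban-Acree form cover the mixed compositions (their
#' endpoint terms are the measured pure-solvent data); the combined
#' Jouyban-Acree-van't Hoff form covers all compositions.
#'
#' If the grid has no mixed composition, the three mixture models are
#' reported as `NA` with an explanatory `status`.
#'
#' @param grid A [solubility_grid()] containing both pure-solvent series.
#' @param jouyban_order Interaction polynomial order for the
#'   Jouyban-Acree forms (0, 1 or 2; default 2).
#' @return Object of class `model_comparison_set`: list with
#'   `comparisons` (tibble: `model`, `overall_rmsd_percent`, `n_series`,
#'   `status`), `per_series` (tibble: `model`,
#'   `mass_fraction_cosolvent`, `rmsd_percent`) and `fits` (named list of
#'   the underlying fit objects).
#' @export
#' @examples
#' cmp <- compare_models(reference_grid())
#' cmp$comparisons
compare_models <- function(grid, jouyban_order = 2) {
  stopifnot(inherits(grid, "solubility_grid"))
  ms <- grid_compositions(grid)
  mixed <- setdiff(ms, c(0, 1))
  per_series <- list(); fits <- list()
  comparisons <- list()
  add <- function(model, series_tbl, fit, status = "ok") {
    if (is.null(series_tbl)) {
      comparisons[[model]] <<- tibble::tibble(
        model = model, overall_rmsd_percent = NA_real_,
        n_series = 0L, status = status)
    } else {
      comparisons[[model]] <<- tibble::tibble(
        model = model,
        overall_rmsd_percent = mean(series_tbl$rmsd_percent),
        n_series = nrow(series_tbl), status = status)
      per_series[[model]] <<- tibble::tibble(model = model, series_tbl)
    }
    fits[[model]] <<- fit
  }

  per_comp_fit <- function(fitter) {
    fits_by_m <- lapply(ms, function(m) {
      s <- grid_series(grid, m)
      fitter(s$temperature_K, s$x_exp)
    })
    names(fits_by_m) <- format(ms)
    tbl <- tibble::tibble(
      mass_fraction_cosolvent = ms,
      rmsd_percent = vapply(fits_by_m, function(f) f$rmsd_percent, numeric(1)))
    list(tbl = tbl, fits = fits_by_m)
  }

  vh <- per_comp_fit(fit_vant_hoff)
  add("vanthoff", vh$tbl, vh$fits)
  ap <- per_comp_fit(fit_apelblat)
  add("apelblat", ap$tbl, ap$fits)

  if (length(mixed) == 0) {
    msg <- "no mixed composition: mixture models not applicable"
    add("yalkowsky", NULL, NULL, msg)
    add("jouyban_acree", NULL, NULL, msg)
    add("jouyban_acree_vanthoff", NULL, NULL, msg)
  } else {
    add("yalkowsky", yalkowsky_series(grid), NULL)
    ja <- fit_jouyban_acree(grid, order = jouyban_order,
                            combined_with_vant_hoff = FALSE)
    add("jouyban_acree", ja$per_series, ja)
    javh <- fit_jouyban_acree(grid, order = jouyban_order,
                              combined_with_vant_hoff = TRUE)
    add("jouyban_acree_vanthoff", javh$per_series, javh)
  }

  structure(list(
    comparisons = do.call(rbind, comparisons),
    per_series = do.call(rbind, per_series),
    fits = fits
  ), class = "model_comparison_set")
}

#' @export
print.model_comparison_set <- function(x, ...) {
  cat("<model_comparison_set>\n")
  print(x$comparisons)
  invisible(x)
}

# R^2 of a least-squares fit in log space, computed directly so that
# noiseless (perfect-fit) data does not trigger summary.lm warnings.
r_squared_of <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum((y - fitted)^2) / ss_tot
}
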