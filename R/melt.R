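#' Fit a four-parameter logistic melting curve
#'
#' Signals are first normalised to the on-ice reference, then fitted
#' with the variable-slope four-parameter logistic
#' `y(T) = bottom + (top - bottom) / (1 + exp(h * (T - Tm)))`
#' by nonlinear least squares. The inflection point `Tm` is the apparent
#' melting temperature. A multi-start strategy is used: `Tm` starts at
#' the temperature of half-maximal normalised signal, the slope at 0.2,
#' 0.5 and 1.0, top/bottom at the data extremes. The fit is flagged
#' unreliable when the fitted `Tm` falls outside the sampled temperature
#' range.
#'
#' @param temperature Numeric vector of challenge temperatures (deg C),
#'   at least 5 distinct values.
#' @param signal Numeric vector of quantified signals (same length).
#' @param ice_signal The on-ice reference signal (> 0); signals are
#'   divided by it. Use 1 if the signals are pre-normalised.
#' @return Object of class `melt_fit` with elements `tm`, `slope`,
#'   `top`, `bottom`, `rss`, `reliable`, `data`. Supports `print()`,
#'   `coef()`, `predict()` and `residuals()`.
#' @export
fit_melt_curve <- function(temperature, signal, ice_signal = 1) {
  stopifnot(length(temperature) == length(signal))
  if (length(unique(temperature)) < 5L) {
    stop("need at least 5 distinct temperatures to fit a melt curve")
  }
  if (ice_signal <= 0) stop("on-ice reference signal must be > 0")
  y <- signal / ice_signal
  T <- temperature
  top0 <- max(y)
  bottom0 <- min(y)
  half <- (top0 + bottom0) / 2
  ord <- order(T)
  tm0 <- tryCatch(stats::approx(y[ord], T[ord], xout = half,
                                ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (is.na(tm0)) tm0 <- stats::median(T)
  fits <- list()
  for (h0 in c(0.2, 0.5, 1.0)) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(h * (T - tm))),
        start = list(bottom = bottom0, top = top0, h = h0, tm = tm0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) > 0L) {
    rss <- vapply(fits, function(f) sum(stats::residuals(f)^2),
                  numeric(1))
    p <- stats::coef(fits[[which.min(rss)]])
    best_rss <- min(rss)
  } else {
    # degenerate data (e.g. no transition inside the grid): fall back
    # to a direct least-squares search so the caller still gets a
    # parameter set, flagged unreliable below
    obj <- function(par) {
      sum((y - (par[1] + (par[2] - par[1]) /
                  (1 + exp(par[3] * (T - par[4])))))^2)
    }
    op <- stats::optim(c(bottom0, top0, 0.5, tm0), obj,
                       control = list(maxit = 2000))
    if (op$convergence != 0 && op$value > stats::var(y) * length(y)) {
      stop("melting-curve fit failed to converge from all starts ",
           "(tm0 = ", round(tm0, 2), ", range ", min(T), "-", max(T),
           ")")
    }
    p <- c(bottom = op$par[1], top = op$par[2], h = op$par[3],
           tm = op$par[4])
    best_rss <- op$value
  }
  # reliable only when a genuine transition is bracketed by the grid:
  # Tm inside the sampled range, decreasing signal, and at least 20% of
  # the on-ice signal lost across the fitted transition
  reliable <- p[["tm"]] >= min(T) && p[["tm"]] <= max(T) &&
    p[["h"]] > 0 && (p[["top"]] - p[["bottom"]]) > 0.2
  structure(list(tm = p[["tm"]], slope = p[["h"]], top = p[["top"]],
                 bottom = p[["bottom"]], rss = best_rss,
                 reliable = reliable,
                 data = data.frame(temperature = T, signal = y)),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("4PL melt fit: Tm = %.2f C (slope %.3f, top %.3f, bottom %.3f)%s\n",
              x$tm, x$slope, x$top, x$bottom,
              if (x$reliable) "" else "  [UNRELIABLE]"))
  invisible(x)
}

#' @method coef melt_fit
#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, slope = object$slope, top = object$top,
    bottom = object$bottom)
}

#' @method predict melt_fit
#' @export
predict.melt_fit <- function(object, temperature = object$data$temperature,
                             ...) {
  with(object, bottom + (top - bottom) /
         (1 + exp(slope * (temperature - tm))))
}

#' @method residuals melt_fit
#' @export
residuals.melt_fit <- function(object, ...) {
  object$data$signal - predict(object)
}

#' Summarise per-repeat melting temperatures
#'
#' @param tms Numeric vector of per-repeat fitted Tm values (>= 1).
#' @return List with `mean_tm`, `sem_tm` (`NA` for a single repeat) and
#'   `n`.
#' @export
summarise_tm <- function(tms) {
  tms <- tms[!is.na(tms)]
  if (length(tms) == 0L) stop("no converged fits to summarise")
  n <- length(tms)
  list(mean_tm = mean(tms),
       sem_tm = if (n > 1L) stats::sd(tms) / sqrt(n) else NA_real_,
       n = n)
}

#' Melting-temperature shift with propagated error
#'
#' `dTm = mean_tm(variant) - mean_tm(wild-type)`; its standard error is
#' the quadrature sum `sqrt(sem_wt^2 + sem_var^2)`, absent when either
#' input SEM is absent.
#'
#' @param variant,wildtype Summaries from [summarise_tm()].
#' @return List with `delta_tm` and `sem_delta_tm`.
#' @export
delta_tm <- function(variant, wildtype) {
  list(delta_tm = variant$mean_tm - wildtype$mean_tm,
       sem_delta_tm = if (is.na(variant$sem_tm) || is.na(wildtype$sem_tm))
         NA_real_ else sqrt(wildtype$sem_tm^2 + variant$sem_tm^2))
}

#' Classify melting-temperature shifts for a campaign
#'
#' The campaign cutoff is the mean of the available propagated SEM
#' values. A variant is stabilising when `delta_tm >= cutoff`,
#' destabilising when `delta_tm <= -cutoff`, otherwise neutral.
#'
#' @param delta_tms Numeric vector of dTm values (deg C).
#' @param sem_delta_tms Numeric vector of propagated SEMs (NA allowed).
#' @param cutoff Optional explicit cutoff; required when no SEM is
#'   available.
#' @return List with `status` (character vector) and `cutoff`.
#' @export
classify_delta_tm <- function(delta_tms, sem_delta_tms, cutoff = NULL) {
  if (is.null(cutoff)) {
    sems <- sem_delta_tms[!is.na(sem_delta_tms)]
    if (length(sems) == 0L) {
      stop("no propagated SEMs available; supply an explicit cutoff")
    }
    cutoff <- mean(sems)
  }
  status <- rep("neutral", length(delta_tms))
  status[delta_tms >= cutoff] <- "stabilising"
  status[delta_tms <= -cutoff] <- "destabilising"
  list(status = status, cutoff = cutoff)
}

#' Analyse a melting-curve table end to end
#'
#' Reads the long-format table (columns `construct`, `repeat_id`,
#' `temperature`, `intensity`; on-ice reference rows flagged with
#' `temperature = "ice"`; multiple intensity columns, e.g. double gel
#' bands, are summed), fits every (construct, repeat) curve, averages
#' per-construct Tm, and reports dTm against the wild-type construct
#' with propagated errors and stabilising/neutral/destabilising calls.
#'
#' @param curves Data frame (or TSV path) of melt measurements.
#' @param wildtype Name of the wild-type construct.
#' @param cutoff Optional explicit classification cutoff in deg C.
#' @return Data frame, one row per construct, with `mean_tm`, `sem_tm`,
#'   `n`, `delta_tm`, `sem_delta_tm`, `status` (rounded to one decimal
#'   for reporting columns).
#' @export
melt_summary <- function(curves, wildtype = "WT", cutoff = NULL) {
  if (is.character(curves) && length(curves) == 1L) {
    curves <- utils::read.delim(curves, stringsAsFactors = FALSE)
  }
  needed <- c("construct", "repeat_id", "temperature")
  missing_cols <- setdiff(needed, names(curves))
  if (length(missing_cols) > 0L) {
    stop("melt table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  int_cols <- grep("^intensity", names(curves), value = TRUE)
  if (length(int_cols) == 0L) stop("no intensity column(s) found")
  curves$signal <- rowSums(as.data.frame(curves[, int_cols]),
                           na.rm = TRUE)
  if (!(wildtype %in% curves$construct)) {
    stop("wild-type construct '", wildtype, "' not in the table")
  }
  per_construct <- lapply(split(curves, curves$construct), function(d) {
    tms <- vapply(split(d, d$repeat_id), function(r) {
      ice <- r$signal[r$temperature == "ice"]
      if (length(ice) != 1L || ice <= 0) {
        stop("construct ", d$construct[1],
             ": each repeat needs one positive on-ice reference row")
      }
      meas <- r[r$temperature != "ice", ]
      fit <- fit_melt_curve(as.numeric(meas$temperature), meas$signal,
                            ice_signal = ice)
      if (!fit$reliable) {
        warning("unreliable fit for construct ", d$construct[1],
                " repeat ", r$repeat_id[1], call. = FALSE)
      }
      fit$tm
    }, numeric(1))
    summarise_tm(tms)
  })
  wt <- per_construct[[wildtype]]
  rows <- do.call(rbind, lapply(names(per_construct), function(nm) {
    s <- per_construct[[nm]]
    d <- delta_tm(s, wt)
    data.frame(construct = nm, mean_tm = round(s$mean_tm, 1),
               sem_tm = round(s$sem_tm, 1), n = s$n,
               delta_tm = round(d$delta_tm, 1),
               sem_delta_tm = round(d$sem_delta_tm, 1),
               stringsAsFactors = FALSE)
  }))
  is_var <- rows$construct != wildtype
  rows$status <- NA_character_
  if (any(is_var)) {
    cl <- classify_delta_tm(rows$delta_tm[is_var],
                            rows$sem_delta_tm[is_var], cutoff = cutoff)
    rows$status[is_var] <- cl$status
    attr(rows, "cutoff") <- cl$cutoff
  }
  rows[order(rows$construct != wildtype, rows$construct), ]
}

#' Single-temperature stability screen
#'
#' Each measurement is the heated-over-ice survival fraction expressed
#' relative to wild-type on the same plate. The hit cutoff is the lower
#' bound of the two-sided t-based 95% confidence interval of the pooled
#' measurement mean; variants whose median relative survival strictly
#' exceeds the cutoff are hits.
#'
#' @param construct Character vector of construct names per measurement.
#' @param survival Numeric vector of relative survival fractions.
#' @param confidence Confidence level in percent (default 95).
#' @param cutoff Optional explicit cutoff overriding the CI-derived one.
#' @return List with `cutoff`, `ci` (pooled interval), and `medians`
#'   (data frame: construct, median_survival, n, hit).
#' @export
single_temperature_screen <- function(construct, survival,
                                      confidence = 95, cutoff = NULL) {
  stopifnot(length(construct) == length(survival))
  if (length(survival) < 3L) {
    stop("need at least 3 pooled measurements for the confidence ",
         "interval")
  }
  if (is.null(cutoff)) {
    ci <- stats::t.test(survival, conf.level = confidence / 100)$conf.int
    cutoff <- ci[1]
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  med <- do.call(rbind, lapply(split(survival, construct), function(x) {
    data.frame(median_survival = stats::median(x), n = length(x))
  }))
  med$construct <- rownames(med)
  rownames(med) <- NULL
  med$hit <- med$median_survival > cutoff
  list(cutoff = cutoff, ci = as.numeric(ci),
       medians = med[, c("construct", "median_survival", "n", "hit")])
}
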