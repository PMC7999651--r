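# Non-compartmental pharmacokinetic analysis of single-dose
# concentration-time profiles: trapezoidal AUC, terminal log-linear slope,
# extrapolation to infinity, and dose/weight-scaled clearance and volume.

#' Trapezoidal area under the concentration-time curve
#'
#' Plain linear trapezoid over the retained points; an optional
#' log-linear-down variant uses the logarithmic trapezoid on strictly
#' decreasing positive segments (linear elsewhere).
#'
#' @param time Sampling times (h), strictly increasing.
#' @param conc Concentrations (ng/mL), same length, non-negative.
#' @param log_down Use the log-linear-down rule (default `FALSE`).
#' @return AUC to the last point (ng*h/mL).
#' @export
auc_trapezoid <- function(time, conc, log_down = FALSE) {
  stopifnot(length(time) == length(conc))
  if (length(time) < 2L) stop("at least two points are needed for an AUC")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- dt * (c1 + c2) / 2
  if (log_down) {
    logseg <- c2 < c1 & c2 > 0
    seg[logseg] <- dt[logseg] * (c1[logseg] - c2[logseg]) /
      log(c1[logseg] / c2[logseg])
  }
  sum(seg)
}

#' Fit the terminal elimination rate constant
#'
#' Ordinary least squares of log concentration on time over the log-linear
#' terminal phase. The window is chosen deterministically: every candidate
#' window of at least `min_points` positive concentrations starting strictly
#' after tmax and ending at the last quantifiable point is fitted, and the
#' window with the highest adjusted R-squared wins, with ties going to the
#' window with more points. Two adjusted R-squared values within `r2_tol`
#' (default 1e-4, the conventional bioequivalence tolerance) count as tied,
#' so a short window must be clearly better to displace a longer one. A
#' profile with no declining terminal phase is flagged rather than fitted.
#'
#' @param time Sampling times (h).
#' @param conc Concentrations (ng/mL); only positive values enter the fit.
#' @param min_points Minimum points in the terminal window (default 3).
#' @param r2_tol Adjusted R-squared tie tolerance (default 1e-4).
#' @return A list: `ke` (1/h), `n_points`, `r_squared_adj`, `t_first`,
#'   `t_last`, `flags` (character vector; `"no_terminal_decline"` or
#'   `"too_few_points"` mark invalid fits, with `ke = NA`).
#' @export
fit_lambda_z <- function(time, conc, min_points = 3L, r2_tol = 1e-4) {
  stopifnot(length(time) == length(conc), min_points >= 3L)
  invalid <- function(flag) {
    list(ke = NA_real_, n_points = NA_integer_, r_squared_adj = NA_real_,
         t_first = NA_real_, t_last = NA_real_, flags = flag)
  }
  pos <- conc > 0 & !is.na(conc)
  if (!any(pos)) return(invalid("too_few_points"))
  i_max <- which.max(ifelse(pos, conc, -Inf))  # earliest max among positives
  cand <- which(pos & seq_along(conc) > i_max)
  if (length(cand) < min_points) return(invalid("too_few_points"))
  t <- time[cand]
  y <- log(conc[cand])
  n <- length(t)
  best <- NULL
  for (start in 1:(n - min_points + 1L)) {
    ti <- t[start:n]
    yi <- y[start:n]
    k <- length(ti)
    slope <- stats::cov(ti, yi) / stats::var(ti)
    if (!is.finite(slope) || slope >= 0) next
    r2 <- stats::cor(ti, yi)^2
    r2adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # windows are visited longest-first, so a shorter window must beat the
    # incumbent by more than the tolerance to win: ties go to more points
    if (is.null(best) || r2adj > best$r_squared_adj + r2_tol) {
      best <- list(ke = -slope, n_points = k, r_squared_adj = r2adj,
                   t_first = ti[1], t_last = ti[k], flags = character(0))
    }
  }
  if (is.null(best)) return(invalid("no_terminal_decline"))
  best
}

#' Extrapolate the AUC to infinity
#'
#' AUC from the last quantifiable point to infinity is estimated as
#' C_last / ke and added to the observed AUC. The extrapolated fraction is
#' reported, with a flag when it exceeds 20% of the total (the conventional
#' reliability bound for single-dose exposure estimates).
#'
#' @param auc_t Observed AUC to the last quantifiable point.
#' @param c_last Last quantifiable concentration (ng/mL).
#' @param ke Terminal rate constant (1/h), positive.
#' @return A list: `auc_inf`, `extrap_frac`, `flags`.
#' @export
extrapolate_auc <- function(auc_t, c_last, ke) {
  stopifnot(auc_t >= 0, c_last >= 0, is.finite(ke), ke > 0)
  tail_area <- c_last / ke
  auc_inf <- auc_t + tail_area
  extrap_frac <- if (auc_inf > 0) tail_area / auc_inf else 0
  flags <- if (extrap_frac > 0.2) "high_extrapolation" else character(0)
  list(auc_inf = auc_inf, extrap_frac = extrap_frac, flags = flags)
}

#' Derive clearance, volume and half-life
#'
#' Apparent (bioavailability-scaled) clearance per kilogram is dose divided
#' by AUC-infinity and weight, Cl/F = D / (AUC * W); the apparent volume of
#' distribution is Vd/F = (Cl/F) / ke; half-life is ln(2)/ke. With dose in
#' mg, AUC in ng*h/mL and weight in kg, Cl/F comes out in mL/(h*kg) and
#' Vd/F in mL/kg (divide by 1000 for the L/kg presentation scale).
#'
#' @param auc_inf AUC to infinity (ng*h/mL).
#' @param ke Terminal rate constant (1/h).
#' @param dose Dose (mg).
#' @param weight Body weight (kg).
#' @return A list: `cl_f_w` (mL/(h*kg)), `vd_f_w` (mL/kg), `t_half` (h).
#' @export
derive_parameters <- function(auc_inf, ke, dose, weight) {
  stopifnot(auc_inf > 0, ke > 0, dose > 0, weight > 0)
  cl_f_w <- dose * 1e6 / (auc_inf * weight)  # mg -> ng
  list(cl_f_w = cl_f_w, vd_f_w = cl_f_w / ke, t_half = log(2) / ke)
}

# Below-quantification handling: pre-dose and pre-tmax BQL values are set to
# zero, post-tmax BQL values are dropped, and the profile ends at the last
# quantifiable point. Returns NULL if fewer than two points remain.
prepare_profile <- function(time, conc, lloq = 0) {
  conc_num <- suppressWarnings(as.numeric(conc))
  bql <- is.na(conc_num) | conc_num < lloq
  if (all(bql)) return(NULL)
  quant <- which(!bql)
  i_max <- quant[which.max(conc_num[quant])]
  keep <- !bql | seq_along(conc_num) < i_max
  keep[seq_along(keep) > max(quant)] <- FALSE
  time <- time[keep]
  conc_num <- conc_num[keep]
  conc_num[is.na(conc_num) | conc_num < lloq] <- 0
  if (length(time) < 2L) return(NULL)
  list(time = time, conc = conc_num)
}

#' Run non-compartmental analysis over a cohort of profiles
#'
#' For each subject: handle below-quantification values, read Cmax and tmax
#' (earliest time attaining the maximum), compute the trapezoidal AUC, fit
#' the terminal slope, extrapolate to infinity, and derive half-life,
#' clearance and volume scaled by dose and weight. Subjects whose terminal
#' phase cannot be fitted keep their observed quantities with the fit fields
#' `NA` and a flag.
#'
#' @param profiles Tibble `subject_id`, `time_h`, `conc_ng_ml` (the
#'   concentration column may contain the token `"BLQ"`).
#' @param subjects Tibble with `subject_id`, `dose`, `weight` (kg).
#' @param lloq Lower limit of quantification (ng/mL); values below it are
#'   treated as BQL.
#' @param log_down Use log-linear-down trapezoid (default linear).
#' @param min_points Minimum terminal-fit points (default 3).
#' @return One row per subject: `auc_t`, `auc_inf`, `extrap_frac`, `cmax`,
#'   `tmax`, `ke`, `t_half`, `cl_f_w`, `vd_f_w`, `lambda_n`, `lambda_r2_adj`,
#'   `flags` (semicolon-joined).
#' @export
run_nca <- function(profiles, subjects, lloq = 0, log_down = FALSE,
                    min_points = 3L) {
  stopifnot(all(c("subject_id", "time_h", "conc_ng_ml") %in% names(profiles)),
            all(c("subject_id", "dose", "weight") %in% names(subjects)))
  ids <- unique(profiles$subject_id)
  out <- vector("list", length(ids))
  prof_split <- split(profiles, profiles$subject_id)
  for (i in seq_along(ids)) {
    id <- ids[i]
    pr <- prof_split[[as.character(id)]]
    pr <- pr[order(pr$time_h), ]
    prep <- prepare_profile(pr$time_h, pr$conc_ng_ml, lloq = lloq)
    row <- tibble::tibble(
      subject_id = id, auc_t = NA_real_, auc_inf = NA_real_,
      extrap_frac = NA_real_, cmax = NA_real_, tmax = NA_real_,
      ke = NA_real_, t_half = NA_real_, cl_f_w = NA_real_, vd_f_w = NA_real_,
      lambda_n = NA_integer_, lambda_r2_adj = NA_real_, flags = ""
    )
    if (is.null(prep)) {
      row$flags <- "unusable_profile"
      out[[i]] <- row
      next
    }
    flags <- character(0)
    i_max <- which.max(prep$conc)
    row$cmax <- prep$conc[i_max]
    row$tmax <- prep$time[i_max]
    row$auc_t <- auc_trapezoid(prep$time, prep$conc, log_down = log_down)
    fit <- fit_lambda_z(prep$time, prep$conc, min_points = min_points)
    flags <- c(flags, fit$flags)
    if (is.finite(fit$ke)) {
      row$ke <- fit$ke
      row$lambda_n <- fit$n_points
      row$lambda_r2_adj <- fit$r_squared_adj
      ext <- extrapolate_auc(row$auc_t, prep$conc[length(prep$conc)], fit$ke)
      flags <- c(flags, ext$flags)
      row$auc_inf <- ext$auc_inf
      row$extrap_frac <- ext$extrap_frac
      sub <- subjects[subjects$subject_id == id, , drop = FALSE]
      if (nrow(sub) == 1L) {
        par <- derive_parameters(row$auc_inf, fit$ke, sub$dose, sub$weight)
        row$cl_f_w <- par$cl_f_w
        row$vd_f_w <- par$vd_f_w
        row$t_half <- par$t_half
      } else {
        flags <- c(flags, "no_subject_record")
        row$t_half <- log(2) / fit$ke
      }
    }
    row$flags <- paste(flags, collapse = ";")
    out[[i]] <- row
  }
  dplyr::bind_rows(out)
}

#' Read a profiles CSV
#'
#' Columns `subject_id`, `time_h`, `conc_ng_ml`; the token `"BLQ"` marks
#' below-quantification samples.
#'
#' @param path CSV path.
#' @return Profiles tibble.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$conc_ng_ml <- ifelse(df$conc_ng_ml %in% c("BLQ", "blq"), NA,
                          df$conc_ng_ml)
  df$conc_ng_ml <- as.numeric(df$conc_ng_ml)
  tibble::as_tibble(df)
}
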