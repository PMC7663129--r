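#' Two-way ANOVA without replication for a subject x footfall matrix
#'
#' Decomposes a complete n x k measurement matrix (n subjects, k repeated
#' footfalls) into between-subject (rows), between-footfall (columns) and
#' residual mean squares via [stats::aov()]. The column F test
#' (`F = MSC/MSE` on `(k-1, (n-1)(k-1))` df) detects systematic bias across
#' repetitions.
#'
#' @param M numeric matrix, subjects in rows, repetitions in columns; no
#'   missing values (drop incomplete rows first, see
#'   [build_measurement_matrix()]).
#' @return List `MSR`, `MSC`, `MSE`, `F_columns`, `p`, `n`, `k`. When the
#'   residual mean square is zero the F statistic and p-value are `NA`.
#' @export
two_way_anova <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 repetitions")
  if (anyNA(M)) stop("matrix must be complete; drop incomplete rows first")
  df <- data.frame(value = as.vector(M),
                   subject = factor(rep(seq_len(n), times = k)),
                   rep = factor(rep(seq_len(k), each = n)))
  sm <- summary(stats::aov(value ~ subject + rep, data = df))[[1]]
  ms <- sm[["Mean Sq"]]
  names(ms) <- trimws(rownames(sm))
  MSE <- ms[["Residuals"]]
  # treat a residual mean square at rounding-noise level as exactly zero
  if (MSE <= 1e-12 * max(1, mean(M^2))) MSE <- 0
  Fc <- if (MSE > 0) ms[["rep"]] / MSE else NA_real_
  p <- if (is.na(Fc)) NA_real_ else
    stats::pf(Fc, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(MSR = ms[["subject"]], MSC = ms[["rep"]], MSE = MSE,
       F_columns = Fc, p = p, n = n, k = k)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The
#' 95\% confidence interval uses the F-based method for absolute-agreement
#' two-way random models (McGraw-Wong convention), and the significance
#' test of ICC > 0 is `F = MSR / MSE` on `(n-1, (n-1)(k-1))` df.
#'
#' @param MSR,MSC,MSE mean squares from [two_way_anova()].
#' @param n,k numbers of subjects and repetitions.
#' @param conf confidence level, default 0.95.
#' @return List `est`, `lower`, `upper`, `F`, `p`. Degenerate mean squares
#'   give `NA` entries.
#' @export
icc_2_1 <- function(MSR, MSC, MSE, n, k, conf = 0.95) {
  den <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  est <- if (isTRUE(den > 0)) (MSR - MSE) / den else NA_real_
  lower <- upper <- Fv <- p <- NA_real_
  if (!is.na(est) && MSE > 0) {
    alpha <- 1 - conf
    Fj <- MSC / MSE
    r <- est
    vn <- ((k - 1) * (n - 1) *
             (k * r * Fj + n * (1 + (k - 1) * r) - k * r)^2)
    vd <- ((n - 1) * k^2 * r^2 * Fj^2 +
             (n * (1 + (k - 1) * r) - k * r)^2)
    v <- vn / vd
    FU <- stats::qf(1 - alpha / 2, n - 1, v)
    FL <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FU * MSE) /
      (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FL * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
    Fv <- MSR / MSE
    p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(est = est, lower = lower, upper = upper, F = Fv, p = p)
}

#' ICC(2,k): two-way random effects, absolute agreement, mean of k
#'
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`; algebraically equal
#' to [spearman_brown()] applied to ICC(2,1) with the same k.
#'
#' @inheritParams icc_2_1
#' @return Point estimate (scalar), `NA` when degenerate.
#' @export
icc_2_k <- function(MSR, MSC, MSE, n) {
  den <- MSR + (MSC - MSE) / n
  if (isTRUE(den > 0)) (MSR - MSE) / den else NA_real_
}

#' Spearman-Brown prophecy: reliability of the mean of k replicates
#'
#' `R_k = k R / (1 + (k - 1) R)` for single-replicate reliability `R`.
#'
#' @param R single-measurement reliability in \[0, 1\].
#' @param k number of replicates averaged, >= 1 (vectorized over both).
#' @return Prophesied reliability `R_k`.
#' @examples
#' spearman_brown(0.79, 7)  # 0.9634...
#' @export
spearman_brown <- function(R, k) {
  if (any(R < 0)) stop("reliability below 0 cannot be prophesied")
  if (any(k < 1)) stop("k must be >= 1")
  ifelse(R == 1, 1, k * R / (1 + (k - 1) * R))
}

#' Number of replicates needed to reach a target reliability
#'
#' Inverts the Spearman-Brown formula:
#' `k = ceiling(R_target (1 - R) / (R (1 - R_target)))`, whole replicates.
#'
#' @param R single-measurement reliability, 0 < R < 1 (vectorized).
#' @param R_target desired reliability of the k-replicate mean, default the
#'   0.50 cut-off between poor and moderate reliability.
#' @return Integer number of replicates.
#' @examples
#' required_k(0.13, 0.50)  # 7
#' @export
required_k <- function(R, R_target = 0.5) {
  if (any(R <= 0)) stop("non-positive reliability cannot reach any target")
  if (any(R_target <= 0 | R_target >= 1)) stop("R_target must be in (0, 1)")
  kk <- R_target * (1 - R) / (R * (1 - R_target))
  # guard against floating-point overshoot at exact integers
  k <- ceiling(kk - 1e-9 * pmax(1, abs(kk)))
  pmax(as.integer(k), 1L)
}

#' Within-subject coefficient of variation
#'
#' For each subject, `CV_i = 100 * SD_i / |mean_i|` across the k footfalls;
#' the reported CV is the mean over subjects (`pooled = TRUE` instead pools
#' the within-subject variances over subjects before dividing by the grand
#' mean magnitude). Not applicable to mean-location parameters, whose sign
#' changes make the mean a poor denominator; pass `location = TRUE` to get
#' `NA` for those.
#'
#' @param M numeric matrix, subjects x footfalls (complete rows).
#' @param location if `TRUE` the parameter is a mean-location type and CV
#'   is `NA`.
#' @param pooled use the pooled-variance variant.
#' @return CV in \%, or `NA` (also when any subject mean is zero).
#' @export
cv_within <- function(M, location = FALSE, pooled = FALSE) {
  if (location) return(NA_real_)
  M <- as.matrix(M)
  mns <- rowMeans(M)
  if (any(mns == 0)) return(NA_real_)
  if (pooled) {
    100 * sqrt(mean(apply(M, 1, stats::var))) / abs(mean(mns))
  } else {
    mean(100 * apply(M, 1, stats::sd) / abs(mns))
  }
}

#' Standard error of measurement for the k-footfall average
#'
#' `SEM = SD * sqrt(1 - ICC(2,k))`, with `SD` the between-subject standard
#' deviation of the k-footfall subject means, matching the reliability of
#' the averaged measurement.
#'
#' @param sd_means standard deviation of subject means (>= 0).
#' @param icc2k reliability of the k-footfall average, <= 1.
#' @return SEM on the measurement scale.
#' @export
sem <- function(sd_means, icc2k) {
  if (any(icc2k > 1)) stop("reliability cannot exceed 1")
  if (any(sd_means < 0)) stop("sd must be >= 0")
  sd_means * sqrt(1 - icc2k)
}

#' Minimal detectable change
#'
#' `MDC = SEM * sqrt(2) * z`; the default `z = 1.64` corresponds to 90\%
#' confidence, and the sqrt(2) carries the extra uncertainty of comparing
#' two repeated measurements.
#'
#' @param sem_value standard error of measurement (>= 0).
#' @param z z-score of the confidence level, default 1.64.
#' @return MDC on the measurement scale.
#' @examples
#' mdc(3.84)  # 8.906... -> 8.91
#' @export
mdc <- function(sem_value, z = 1.64) {
  if (any(sem_value < 0)) stop("SEM must be >= 0")
  sem_value * sqrt(2) * z
}

#' Minimum number of subjects for an ICC reliability study
#'
#' Fisher-type approximation for testing that reliability exceeds a minimal
#' acceptable level: with `Z(rho) = 0.5 log((1 + (k-1) rho) / (1 - rho))`,
#' `n = ceiling(2 + k (z_alpha + z_beta)^2 / (2 (k-1) (Z(rho1) - Z(rho0))^2))`.
#'
#' @param rho0 minimally acceptable reliability (null).
#' @param rho1 expected reliability (alternative), `> rho0`.
#' @param alpha one-tailed significance level, default 0.05.
#' @param power target power, default 0.80.
#' @param k repetitions per subject.
#' @return Integer minimum sample size.
#' @export
sample_size_icc <- function(rho0, rho1, alpha = 0.05, power = 0.80, k) {
  if (rho1 <= rho0) stop("rho1 must exceed rho0")
  if (rho0 <= 0 || rho1 >= 1) stop("need 0 < rho0 < rho1 < 1")
  if (k < 2) stop("k must be >= 2")
  Z <- function(rho) 0.5 * log((1 + (k - 1) * rho) / (1 - rho))
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  as.integer(ceiling(2 + k * (za + zb)^2 /
                       (2 * (k - 1) * (Z(rho1) - Z(rho0))^2)))
}

#' Assemble a subject x footfall measurement matrix from a parameter table
#'
#' Selects one parameter / condition / side, takes each subject's first `k`
#' footfalls in repetition order, and drops subjects with fewer than `k`
#' values or any missing value (the unreplicated two-way ANOVA requires a
#' complete matrix).
#'
#' @param params a [parameter_table()]-style data.frame.
#' @param parameter column name of the measurement.
#' @param condition,side row filters (ignored when `NULL`).
#' @param k repetitions per subject.
#' @return n x k numeric matrix with subject rownames (possibly 0 rows).
#' @export
build_measurement_matrix <- function(params, parameter, condition = NULL,
                                     side = NULL, k = 7) {
  d <- params
  if (!is.null(condition)) d <- d[d$condition %in% condition, , drop = FALSE]
  if (!is.null(side)) d <- d[d$side %in% side, , drop = FALSE]
  if (!parameter %in% names(d)) stop("unknown parameter: ", parameter)
  d <- d[order(d$subject, d$footfall), , drop = FALSE]
  rows <- lapply(split(d, d$subject, drop = TRUE), function(s) {
    v <- s[[parameter]][seq_len(min(k, nrow(s)))]
    if (length(v) < k || anyNA(v)) NULL else v
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(matrix(numeric(), 0, k))
  }
  M <- do.call(rbind, rows)
  rownames(M) <- names(rows)
  M
}

is_location_parameter <- function(parameter) grepl("mloc", parameter)

#' Intra-session reliability report over a COP parameter table
#'
#' For every parameter column and condition, builds the dominant-foot
#' subject x footfall matrix (first `k` complete footfalls per subject) and
#' reports descriptive statistics (mean and SD of the subject means),
#' relative reliability (ICC(2,1) with its confidence interval and the
#' ICC > 0 significance test, ICC(2,k), the column-bias ANOVA F and p) and
#' absolute reliability (within-subject CV for the dominant and
#' non-dominant foot, SEM and MDC of the k-footfall average, and the number
#' of footfalls required to reach `r_target`). Mean-location parameters get
#' `NA` CVs. Parameters/conditions with fewer than 2 complete subjects are
#' reported as missing with a reason.
#'
#' @param params a [parameter_table()]-style data.frame.
#' @param k footfalls per subject entering the reliability analysis.
#' @param r_target reliability cut-off for the required footfall count.
#' @param z z-score for the MDC confidence level.
#' @param conf confidence level of the ICC interval.
#' @param dominant named character vector mapping subject to dominant side
#'   (`"left"`/`"right"`), or a single side applied to everyone (default
#'   `"right"`).
#' @param parameters which columns to report; defaults to every measurement
#'   column of the table.
#' @return data.frame with one row per parameter x condition:
#'   `parameter`, `subphase`, `condition`, `n`, `mean`, `sd`, `icc21`,
#'   `icc21_lo`, `icc21_hi`, `icc21_sig`, `icc2k`, `F`, `p`, `cv_dom`,
#'   `cv_nondom`, `sem`, `mdc`, `required_k`, `note`.
#' @export
reliability_report <- function(params, k = 7, r_target = 0.5, z = 1.64,
                               conf = 0.95, dominant = "right",
                               parameters = NULL) {
  id_cols <- c("subject", "condition", "side", "footfall",
               "first_contact_ms", "theta_c_deg", "foot_length_mm",
               "foot_width_mm")
  parameters <- parameters %||% setdiff(names(params), id_cols)
  conditions <- unique(params$condition)
  subj <- as.character(params$subject)
  dom_side <- if (length(dominant) == 1 && is.null(names(dominant))) {
    stats::setNames(rep(dominant, length(unique(subj))), unique(subj))
  } else dominant
  is_dom <- params$side == dom_side[subj]
  rows <- list()
  for (cond in conditions) {
    for (par in parameters) {
      Md <- build_measurement_matrix(params[is_dom, , drop = FALSE],
                                     par, condition = cond, k = k)
      Mn <- build_measurement_matrix(params[!is_dom, , drop = FALSE],
                                     par, condition = cond, k = k)
      loc <- is_location_parameter(par)
      row <- data.frame(parameter = par, subphase = subphase_of(par),
                        condition = cond, n = nrow(Md),
                        mean = NA_real_, sd = NA_real_,
                        icc21 = NA_real_, icc21_lo = NA_real_,
                        icc21_hi = NA_real_, icc21_sig = NA,
                        icc2k = NA_real_, F = NA_real_, p = NA_real_,
                        cv_dom = NA_real_, cv_nondom = NA_real_,
                        sem = NA_real_, mdc = NA_real_,
                        required_k = NA_integer_, note = "")
      if (nrow(Md) < 2) {
        row$note <- "fewer than 2 subjects with k complete footfalls"
        rows[[length(rows) + 1]] <- row
        next
      }
      mns <- rowMeans(Md)
      an <- two_way_anova(Md)
      i1 <- icc_2_1(an$MSR, an$MSC, an$MSE, an$n, an$k, conf = conf)
      ik <- icc_2_k(an$MSR, an$MSC, an$MSE, an$n)
      row$mean <- mean(mns)
      row$sd <- stats::sd(mns)
      row$icc21 <- i1$est
      row$icc21_lo <- i1$lower
      row$icc21_hi <- i1$upper
      row$icc21_sig <- !is.na(i1$p) && i1$p < 0.001
      row$icc2k <- ik
      row$F <- an$F_columns
      row$p <- an$p
      row$cv_dom <- cv_within(Md, location = loc)
      row$cv_nondom <- if (nrow(Mn) >= 1) cv_within(Mn, location = loc)
                       else NA_real_
      if (!is.na(ik)) {
        row$sem <- sem(row$sd, ik)
        row$mdc <- mdc(row$sem, z = z)
      }
      if (!is.na(i1$est) && i1$est > 0 && i1$est < 1) {
        row$required_k <- required_k(i1$est, r_target)
      } else if (isTRUE(i1$est >= 1)) {
        row$required_k <- 1L
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

subphase_of <- function(parameter) {
  first <- sub("_.*$", "", parameter)
  ifelse(first %in% subphase_names(), first, NA_character_)
}
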