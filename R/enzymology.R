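# Biochemical quantification: CPM normalisation against in-plate
# controls, turnover numbers (kcat), 4-parameter-logistic dose-response
# (EC50), fold activation, and fluorescence-polarization Kd with exact
# ligand depletion.

#' Normalise scintillation counts against in-plate controls
#'
#' Within each dataset, the mean CPM of the no-compound control wells
#' defines 100% activity and the mean CPM of the no-enzyme background
#' wells defines 0%:
#' `percent = 100 * (cpm - mean_bg) / (mean_ctrl - mean_bg)`.
#'
#' @param wells data.frame with at least columns `cpm`, `role` (one of
#'   `sample`, `no_compound_control`, `no_enzyme_background`) and `dataset`
#'   (grouping label; added as a single dataset when absent).
#' @return `wells` with a `percent_activity` column added; per-dataset
#'   control/background means in `attr(, "provenance")`.
#' @export
normalize_activity <- function(wells) {
  stopifnot(is.data.frame(wells), all(c("cpm", "role") %in% names(wells)))
  if (any(wells$cpm < 0)) stop("negative CPM counts")
  if (!"dataset" %in% names(wells)) wells$dataset <- "dataset1"
  prov <- list()
  wells$percent_activity <- NA_real_
  for (ds in unique(wells$dataset)) {
    sel <- wells$dataset == ds
    ctrl <- wells$cpm[sel & wells$role == "no_compound_control"]
    bg <- wells$cpm[sel & wells$role == "no_enzyme_background"]
    if (length(ctrl) == 0L || length(bg) == 0L) {
      stop("dataset '", ds, "' lacks a no_compound_control or ",
           "no_enzyme_background well")
    }
    m_ctrl <- mean(ctrl)
    m_bg <- mean(bg)
    if (m_ctrl <= m_bg) {
      stop("degenerate assay window in dataset '", ds,
           "': control CPM <= background CPM")
    }
    wells$percent_activity[sel] <- 100 * (wells$cpm[sel] - m_bg) /
      (m_ctrl - m_bg)
    prov[[ds]] <- list(mean_control_cpm = m_ctrl, mean_background_cpm = m_bg)
  }
  attr(wells, "provenance") <- prov
  wells
}

#' Convert scintillation counts to product concentration
#'
#' Linear conversion: `cpm / counts_per_pmol` pmol of product in
#' `volume_ul` microlitres, expressed in nM.
#'
#' @param cpm counts per minute (background-subtracted).
#' @param counts_per_pmol counting efficiency, counts per pmol of
#'   incorporated label.
#' @param volume_ul reaction volume in microlitres.
#' @return Product concentration in nM.
#' @export
cpm_to_product <- function(cpm, counts_per_pmol, volume_ul) {
  if (!is.numeric(counts_per_pmol) || counts_per_pmol <= 0) {
    stop("counts_per_pmol must be positive")
  }
  if (!is.numeric(volume_ul) || volume_ul <= 0) {
    stop("volume_ul must be positive")
  }
  # pmol / uL = umol / L; *1000 -> nmol / L
  cpm / counts_per_pmol / volume_ul * 1000
}

#' Turnover number from an initial-rate timecourse
#'
#' kcat is the least-squares slope of product concentration versus time,
#' divided by the enzyme concentration. With observations at a single
#' time point (the endpoint-assay design) the line is forced through the
#' origin; multi-timepoint input fits a free intercept unless
#' `zero_intercept = TRUE`.
#'
#' @param product_nM product concentrations (nM).
#' @param time_h matching times (h).
#' @param enzyme_nM enzyme concentration (nM), > 0.
#' @param zero_intercept force the regression through the origin; default
#'   automatic (TRUE iff a single distinct positive time).
#' @param substrate,complex_id,compound_id optional labels carried into
#'   the result for bookkeeping and comparison checks.
#' @return A `kinetic_result`: list with `kcat` (1/h), `sd`, `slope_nM_h`,
#'   `clipped` (TRUE when a negative slope was clipped to zero) and the
#'   labels.
#' @export
fit_kcat <- function(product_nM, time_h, enzyme_nM, zero_intercept = NULL,
                     substrate = NA_character_, complex_id = NA_character_,
                     compound_id = NA_character_) {
  stopifnot(length(product_nM) == length(time_h), length(product_nM) >= 1L)
  if (!is.numeric(enzyme_nM) || enzyme_nM <= 0) {
    stop("enzyme concentration must be positive")
  }
  if (is.null(zero_intercept)) {
    zero_intercept <- length(unique(time_h[time_h > 0])) == 1L
  }
  fit <- if (zero_intercept) {
    lm(product_nM ~ 0 + time_h)
  } else {
    lm(product_nM ~ time_h)
  }
  co <- suppressWarnings(summary(fit))$coefficients  # noiseless input trips
                                                     # the perfect-fit warning
  slope <- co["time_h", "Estimate"]
  slope_se <- co["time_h", "Std. Error"]
  clipped <- slope < 0
  kcat <- max(slope, 0) / enzyme_nM
  sd_kcat <- if (is.finite(slope_se)) slope_se / enzyme_nM else NA_real_
  structure(
    list(kcat = kcat, sd = sd_kcat, slope_nM_h = slope, clipped = clipped,
         enzyme_nM = enzyme_nM, substrate = substrate,
         complex_id = complex_id, compound_id = compound_id),
    class = "kinetic_result"
  )
}

#' @export
print.kinetic_result <- function(x, ...) {
  cat(sprintf("kcat = %.3g +/- %.2g 1/h (%s, %s, %s)%s\n", x$kcat,
              x$sd, x$complex_id, x$compound_id, x$substrate,
              if (x$clipped) " [negative slope clipped]" else ""))
  invisible(x)
}

#' Fold change between two turnover numbers
#'
#' @param kcat_treated,kcat_control `kinetic_result` objects for the same
#'   substrate and complex; control kcat must be positive.
#' @return List with `ratio` and `sd` (first-order error propagation).
#' @export
fold_change <- function(kcat_treated, kcat_control) {
  stopifnot(inherits(kcat_treated, "kinetic_result"),
            inherits(kcat_control, "kinetic_result"))
  same <- function(a, b) (is.na(a) && is.na(b)) || identical(a, b)
  if (!same(kcat_treated$substrate, kcat_control$substrate) ||
      !same(kcat_treated$complex_id, kcat_control$complex_id)) {
    stop("comparison error: substrate or complex mismatch")
  }
  if (kcat_control$kcat <= 0) stop("control kcat must be positive")
  ratio <- kcat_treated$kcat / kcat_control$kcat
  rel <- function(x) {
    if (is.na(x$sd) || x$kcat == 0) 0 else (x$sd / x$kcat)^2
  }
  list(ratio = ratio,
       sd = ratio * sqrt(rel(kcat_treated) + rel(kcat_control)))
}

# 4-parameter logistic; hill > 0, top is the high-concentration asymptote.
.four_pl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Fit a 4-parameter logistic dose-response
#'
#' `percent = bottom + (top - bottom) / (1 + (EC50 / conc)^hill)` fitted by
#' least squares on all replicate points jointly (not on means). The Hill
#' slope is bounded to (0.2, 5); the direction (activation vs inhibition)
#' is inferred from the sign of `top - bottom`. Zero-concentration control
#' points are excluded from the fit.
#'
#' @param conc compound concentrations (uM), > 0 for fitted points.
#' @param percent matching normalised activities (% of control).
#' @return A `dose_response_fit`: list with `ec50` (uM), `hill`, `top`,
#'   `bottom`, `se_ec50`, `direction`, `wide_interval` (TRUE when no clear
#'   plateau constrains the fit and the EC50 interval is wide).
#' @export
fit_dose_response <- function(conc, percent) {
  keep <- conc > 0
  conc <- conc[keep]
  percent <- percent[keep]
  if (length(unique(conc)) < 5L) {
    stop("need >= 5 distinct positive concentrations")
  }
  means <- tapply(percent, conc, mean)
  ord <- order(as.numeric(names(means)))
  means <- means[ord]
  start <- list(
    bottom = unname(means[1L]),
    top = unname(means[length(means)]),
    ec50 = exp(mean(log(range(conc)))),
    hill = 1
  )
  df <- data.frame(conc = conc, percent = percent)
  fit <- minpack.lm::nlsLM(
    percent ~ bottom + (top - bottom) / (1 + (ec50 / conc)^hill),
    data = df, start = start,
    lower = c(bottom = -Inf, top = -Inf, ec50 = min(conc) / 100, hill = 0.2),
    upper = c(bottom = Inf, top = Inf, ec50 = max(conc) * 100, hill = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- summary(fit)$coefficients
  p <- co[, "Estimate"]
  se_ec50 <- co["ec50", "Std. Error"]
  wide <- !is.finite(se_ec50) || se_ec50 > p[["ec50"]] ||
    p[["ec50"]] < min(conc) || p[["ec50"]] > max(conc)
  if (wide) {
    warning("dose-response fit poorly constrained: wide EC50 interval")
  }
  structure(
    list(ec50 = unname(p[["ec50"]]), hill = unname(p[["hill"]]),
         top = unname(p[["top"]]), bottom = unname(p[["bottom"]]),
         se_ec50 = unname(se_ec50),
         direction = if (p[["top"]] >= p[["bottom"]]) "activation"
                     else "inhibition",
         wide_interval = wide, fit = fit),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("EC50 = %.3g +/- %.2g uM (hill %.2f, %s, %g -> %g%%)\n",
              x$ec50, x$se_ec50, x$hill, x$direction, x$bottom, x$top))
  invisible(x)
}

#' Bound tracer fraction under ligand depletion
#'
#' Exact quadratic solution of `P + L <-> PL` at total protein `P`, total
#' tracer `L` and dissociation constant `Kd` (all same units):
#' `fb = (P + L + Kd - sqrt((P + L + Kd)^2 - 4 P L)) / (2 L)`.
#'
#' @param protein total protein concentration(s).
#' @param tracer total tracer concentration.
#' @param kd dissociation constant.
#' @return Bound fraction of tracer in \[0, 1\].
#' @export
bound_fraction <- function(protein, tracer, kd) {
  s <- protein + tracer + kd
  disc <- pmax(s^2 - 4 * protein * tracer, 0)
  (s - sqrt(disc)) / (2 * tracer)
}

#' Fit a fluorescence-polarization saturation titration
#'
#' `fp = fp_min + (fp_max - fp_min) * fb`, with the bound fraction `fb`
#' from the exact ligand-depletion quadratic ([bound_fraction()]) at fixed
#' total tracer. Appropriate when the tracer concentration is comparable
#' to Kd, where the hyperbolic approximation biases the estimate.
#'
#' @param protein_nM total protein concentrations (nM), >= 6 points.
#' @param fp matching polarization readings.
#' @param tracer_nM total tracer concentration (nM), > 0.
#' @return A `binding_fit`: list with `kd` (nM), `se_kd`, `fp_min`,
#'   `fp_max`, `tracer_nM`, `wide_interval` (TRUE when saturation is not
#'   approached, max fitted bound fraction < 0.5).
#' @export
fit_fp_binding <- function(protein_nM, fp, tracer_nM) {
  stopifnot(length(protein_nM) == length(fp))
  if (length(unique(protein_nM)) < 6L) {
    stop("need >= 6 protein concentrations")
  }
  if (!is.numeric(tracer_nM) || tracer_nM <= 0) {
    stop("tracer concentration must be positive")
  }
  fp_min0 <- min(fp)
  fp_max0 <- max(fp)
  half <- fp_min0 + 0.5 * (fp_max0 - fp_min0)
  kd0 <- protein_nM[which.min(abs(fp - half))]
  if (kd0 <= 0) kd0 <- median(protein_nM[protein_nM > 0])
  df <- data.frame(p = protein_nM, fp = fp)
  fit <- minpack.lm::nlsLM(
    fp ~ fp_min + (fp_max - fp_min) *
      bound_fraction(p, tracer_nM, kd),
    data = df,
    start = list(fp_min = fp_min0, fp_max = fp_max0, kd = kd0),
    lower = c(fp_min = -Inf, fp_max = -Inf, kd = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- summary(fit)$coefficients
  p <- co[, "Estimate"]
  fb_max <- bound_fraction(max(protein_nM), tracer_nM, p[["kd"]])
  se_kd <- co["kd", "Std. Error"]
  wide <- fb_max < 0.5 || !is.finite(se_kd) || se_kd > 0.5 * p[["kd"]]
  if (wide) {
    warning("titration does not approach saturation: Kd interval is wide")
  }
  structure(
    list(kd = unname(p[["kd"]]), se_kd = unname(co["kd", "Std. Error"]),
         fp_min = unname(p[["fp_min"]]), fp_max = unname(p[["fp_max"]]),
         tracer_nM = tracer_nM, wide_interval = wide, fit = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Kd = %.3g +/- %.2g nM (tracer %g nM, FP %g -> %g)%s\n",
              x$kd, x$se_kd, x$tracer_nM, x$fp_min, x$fp_max,
              if (x$wide_interval) " [wide interval]" else ""))
  invisible(x)
}
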