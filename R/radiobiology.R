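#' Radiobiological parameter set for one structure
#'
#' Tumour structures need `alpha_beta`, `tcd50` (the homogeneous dose
#' controlling 50% of tumours), `gamma50` (the change in TCP per 1% dose
#' change about TCD50) and the gEUD exponent `a`. Organs at risk need
#' `alpha_beta`, `td50` (uniform whole-organ dose giving 50% complication
#' risk), `m` (sigmoid slope of the probit curve) and `n` (volume-effect
#' exponent, in (0, 1]).
#'
#' @param role Structure role label.
#' @param type `"tumor"` or `"oar"`.
#' @param alpha_beta Linear-quadratic alpha/beta ratio (Gy), > 0.
#' @param tcd50,gamma50,a Tumour parameters (TCD50 in Gy).
#' @param td50,m,n OAR parameters (TD50 in Gy).
#' @return An object of class `radbio_params`.
#' @export
radbio_params <- function(role, type = c("tumor", "oar"), alpha_beta,
                          tcd50 = NULL, gamma50 = NULL, a = NULL,
                          td50 = NULL, m = NULL, n = NULL) {
  type <- match.arg(type)
  if (!is.numeric(alpha_beta) || alpha_beta <= 0)
    stop("radbio_params: alpha_beta must be > 0")
  if (type == "tumor") {
    if (is.null(tcd50) || is.null(gamma50))
      stop(sprintf("radbio_params: tumor parameters incomplete for '%s'", role))
    if (tcd50 <= 0) stop("radbio_params: tcd50 must be > 0")
    if (is.null(a)) a <- -10
  } else {
    if (is.null(td50) || is.null(m) || is.null(n))
      stop(sprintf("radbio_params: OAR parameters incomplete for '%s'", role))
    if (td50 <= 0 || m <= 0) stop("radbio_params: td50 and m must be > 0")
    if (n <= 0 || n > 1) stop("radbio_params: n must be in (0, 1]")
  }
  structure(list(role = role, type = type, alpha_beta = alpha_beta,
                 tcd50 = tcd50, gamma50 = gamma50, a = a,
                 td50 = td50, m = m, n = n), class = "radbio_params")
}

#' Default radiobiological parameter table
#'
#' Reads the parameter file shipped with the package
#' (`inst/extdata/radbio_params.json`): alpha/beta = 3 Gy for normal
#' tissues, probit-volume (TD50, m, n) values for the serial organs, and a
#' tumour parameter set for 1-year local control of brain metastases. The
#' shipped values are placeholders for methodological testing, clearly
#' marked non-clinical; users supply their own table for any real analysis.
#' Spinal cord NTCP is excluded by default (`exclude = true` in the file)
#' because the probit model does not reliably predict cord tolerance at
#' stereotactic doses; override by editing the table.
#'
#' @param path Optional path to a user JSON table with the same layout.
#' @return Named list of [radbio_params()] plus attribute `excluded` (roles
#'   present but flagged excluded).
#' @export
read_radbio_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "radbio_params.json", package = "pctqa")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  excluded <- character()
  for (role in names(raw)) {
    if (startsWith(role, "_")) next
    e <- raw[[role]]
    if (isTRUE(e$exclude)) {
      excluded <- c(excluded, role)
      next
    }
    out[[role]] <- if (identical(e$type, "tumor")) {
      radbio_params(role, "tumor", e$alpha_beta, tcd50 = e$tcd50,
                    gamma50 = e$gamma50, a = e$a)
    } else {
      radbio_params(role, "oar", e$alpha_beta, td50 = e$td50, m = e$m, n = e$n)
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' `EQD2 = D (d + alpha/beta) / (2 + alpha/beta)` with per-fraction dose
#' `d = D / n_fractions` under the linear-quadratic model. Vectorised over
#' `total_dose`, so it applies bin-wise to differential DVH doses (uniform
#' fractionation assumed: every bin is divided into the plan's fraction
#' number).
#'
#' @param total_dose Total physical dose (Gy), >= 0; may be a vector.
#' @param n_fractions Number of fractions, >= 1.
#' @param alpha_beta Alpha/beta ratio (Gy), > 0.
#' @return EQD2 (Gy), same length as `total_dose`.
#' @examples
#' eqd2(20, 1, 3)  # 92 Gy
#' eqd2(21, 3, 3)  # 42 Gy
#' @export
eqd2 <- function(total_dose, n_fractions, alpha_beta) {
  if (alpha_beta <= 0) stop("eqd2: alpha_beta must be > 0")
  stopifnot(n_fractions >= 1, all(total_dose >= 0))
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

#' Convert a DVH to EQD2 bin doses
#' @param dvh A `dvh`.
#' @param n_fractions Fraction number of the plan.
#' @param alpha_beta Alpha/beta ratio (Gy).
#' @return A `dvh` with bin doses converted to EQD2.
#' @export
dvh_to_eqd2 <- function(dvh, n_fractions, alpha_beta) {
  stopifnot(inherits(dvh, "dvh"))
  differential_dvh(eqd2(dvh$bin_dose, n_fractions, alpha_beta),
                   dvh$diff_cc, role = dvh$role)
}

#' Generalised equivalent uniform dose (gEUD)
#'
#' Power mean of the DVH dose distribution:
#' `EUD = (sum_i v_i D_i^a)^(1/a)` with fractional bin volumes `v_i`.
#' Homogeneous irradiation gives EUD = dose for any `a`; `a = 1` gives the
#' mean dose. The geometric-mean limit `a = 0` is not implemented.
#'
#' @param dvh A `dvh` (conventionally EQD2-converted).
#' @param a Volume-effect exponent, nonzero.
#' @return gEUD in Gy.
#' @export
geud <- function(dvh, a) {
  stopifnot(inherits(dvh, "dvh"))
  if (a == 0) stop("geud: a = 0 (geometric-mean limit) is not implemented")
  v <- dvh$diff_cc / sum(dvh$diff_cc)
  d <- dvh$bin_dose
  keep <- v > 0
  if (a < 0 && any(d[keep] == 0)) return(0) # any cold bin kills a negative-a EUD
  sum(v[keep] * d[keep]^a)^(1 / a)
}

#' EUD-logistic tumour control probability
#'
#' `TCP = 1 / (1 + (TCD50 / EUD)^(4 gamma50))`. At EUD = TCD50 the model
#' returns exactly 0.5, and the slope at that point is gamma50 per 1% dose
#' change, the defining property of the gamma50 parameter.
#'
#' @param eud gEUD of the tumour (Gy, EQD2 space).
#' @param params Tumour [radbio_params()].
#' @return Probability in `[0, 1]`.
#' @export
tcp_logistic <- function(eud, params) {
  stopifnot(inherits(params, "radbio_params"))
  if (params$type != "tumor") stop("tcp_logistic: tumor parameters required")
  if (eud <= 0) {
    warning("tcp_logistic: nonpositive EUD, returning 0")
    return(0)
  }
  1 / (1 + (params$tcd50 / eud)^(4 * params$gamma50))
}

#' Lyman-Kutcher-Burman normal-tissue complication probability
#'
#' `Deff = (sum_i v_i D_i^(1/n))^n`, `t = (Deff - TD50) / (m TD50)`,
#' `NTCP = Phi(t)` with `Phi` the standard normal CDF. Uniform whole-organ
#' irradiation at TD50 gives exactly 0.5; `n = 1` reduces `Deff` to the mean
#' dose, and `n -> 0` to the serial-organ maximum-dose limit.
#'
#' @param dvh Differential `dvh` of the organ (conventionally
#'   EQD2-converted).
#' @param params OAR [radbio_params()].
#' @return Probability in `[0, 1]`.
#' @export
ntcp_lkb <- function(dvh, params) {
  stopifnot(inherits(dvh, "dvh"), inherits(params, "radbio_params"))
  if (params$type != "oar") stop("ntcp_lkb: OAR parameters required")
  if (params$n <= 0) stop("ntcp_lkb: n must be > 0")
  v <- dvh$diff_cc / sum(dvh$diff_cc)
  d <- dvh$bin_dose
  keep <- v > 0 & d > 0
  if (!any(keep)) {
    deff <- 0
  } else {
    # factor out the maximum dose so d^(1/n) cannot overflow for small n
    v <- v[keep]; d <- d[keep]
    dmax <- max(d)
    deff <- dmax * sum(v * exp(log(d / dmax) / params$n))^params$n
  }
  t <- (deff - params$td50) / (params$m * params$td50)
  stats::pnorm(t)
}

#' TCP/NTCP outcome table for a cohort
#'
#' Per case and structure: TCP of the PTV (EUD-logistic) and NTCP of the
#' OARs (LKB) for the CT dose and the pseudo-CT dose, from EQD2-converted
#' differential DVHs, plus the CT-minus-pCT deviation. Values below 1e-6
#' are additionally rendered as `"<1e-6"` in the `display` columns.
#'
#' @param cases List of `phantom_case` objects.
#' @param params Named parameter list from [read_radbio_params()].
#' @param bin_width DVH bin width (Gy).
#' @return Data.frame: `case_id`, `structure`, `model`, `value_ct`,
#'   `value_pct`, `deviation`, `abs_deviation`, `display_ct`, `display_pct`.
#' @export
outcome_table <- function(cases, params = read_radbio_params(),
                          bin_width = 0.01) {
  rows <- list()
  fmt <- function(x) ifelse(x < 1e-6, "<1e-6", sprintf("%.6f", x))
  for (case in cases) {
    doses <- list(ct = case$dose_ct, pct = case$dose_pct)
    targets <- list()
    if (!is.null(params$PTV)) targets$PTV <- ptv_union(case)
    oar_roles <- intersect(names(params), names(case$structures))
    for (r in setdiff(oar_roles, "PTV")) targets[[r]] <- case$structures[[r]]
    missing_par <- setdiff(setdiff(names(case$structures), c("body", "brain")),
                           c(names(params), "brain_minus_GTV",
                             grep("^(GTV|PTV)", names(case$structures),
                                  value = TRUE)))
    if (length(missing_par))
      message(sprintf("outcome_table: no parameters for %s (case %s), skipped",
                      paste(missing_par, collapse = ", "), case$case_id))
    for (r in names(targets)) {
      par <- params[[r]]
      vals <- vapply(doses, function(dg) {
        dvh <- compute_dvh(dg, targets[[r]], bin_width)
        e <- dvh_to_eqd2(dvh, case$fractions, par$alpha_beta)
        if (par$type == "tumor") tcp_logistic(geud(e, par$a), par)
        else ntcp_lkb(e, par)
      }, 0.0)
      rows[[length(rows) + 1]] <- data.frame(
        case_id = case$case_id, structure = r,
        model = if (par$type == "tumor") "TCP" else "NTCP",
        value_ct = vals[1], value_pct = vals[2],
        deviation = vals[1] - vals[2],
        abs_deviation = abs(vals[1] - vals[2]),
        display_ct = fmt(vals[1]), display_pct = fmt(vals[2]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarise an outcome table as mean / range / mean absolute deviation
#' @param tab Result of [outcome_table()].
#' @return Data.frame per structure: mean and range for both images, MAD.
#' @export
outcome_summary <- function(tab) {
  sp <- split(tab, tab$structure)
  do.call(rbind, lapply(sp, function(s) {
    data.frame(structure = s$structure[1], model = s$model[1], n = nrow(s),
               mean_ct = mean(s$value_ct), min_ct = min(s$value_ct),
               max_ct = max(s$value_ct), mean_pct = mean(s$value_pct),
               min_pct = min(s$value_pct), max_pct = max(s$value_pct),
               mad = mean(s$abs_deviation), stringsAsFactors = FALSE)
  }))
}
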