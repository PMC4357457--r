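# Parameter set and initial state for the closed-loop circulation.

.PARAM_NAMES <- c(
  # left atrium (passive: constant elastance)
  "E_la", "V0_la",
  # left ventricle
  "Emax_lv", "Emin_lv", "V0_lv",
  # right atrium (passive)
  "E_ra", "V0_ra",
  # right ventricle
  "Emax_rv", "Emin_rv", "V0_rv",
  # valve open-state resistances; mitral blood inertance
  "R_mi", "L_mi", "R_ao", "R_ti", "R_po",
  # systemic arteries / veins
  "C_sas", "V0_sas", "R_sys", "L_sys", "C_svn", "V0_svn", "R_svn",
  # pulmonary arteries / veins
  "C_pas", "V0_pas", "R_pul", "L_pul", "C_pvn", "V0_pvn", "R_pvn",
  # systolic-duration law T_sys = k_sys * rr^alpha_sys; contraction fraction
  "k_sys", "alpha_sys", "sys_split",
  # closed-loop blood volume
  "total_volume")

.PARAM_UNITS <- c(
  E_la = "mmHg/mL", V0_la = "mL",
  Emax_lv = "mmHg/mL", Emin_lv = "mmHg/mL", V0_lv = "mL",
  E_ra = "mmHg/mL", V0_ra = "mL",
  Emax_rv = "mmHg/mL", Emin_rv = "mmHg/mL", V0_rv = "mL",
  R_mi = "mmHg.s/mL", L_mi = "mmHg.s2/mL",
  R_ao = "mmHg.s/mL", R_ti = "mmHg.s/mL", R_po = "mmHg.s/mL",
  C_sas = "mL/mmHg", V0_sas = "mL", R_sys = "mmHg.s/mL", L_sys = "mmHg.s2/mL",
  C_svn = "mL/mmHg", V0_svn = "mL", R_svn = "mmHg.s/mL",
  C_pas = "mL/mmHg", V0_pas = "mL", R_pul = "mmHg.s/mL", L_pul = "mmHg.s2/mL",
  C_pvn = "mL/mmHg", V0_pvn = "mL", R_pvn = "mmHg.s/mL",
  k_sys = "s^(1-alpha)", alpha_sys = "dimensionless",
  sys_split = "dimensionless", total_volume = "mL")

#' Default circulation parameter set
#'
#' A closed-loop four-chamber parameter set (mmHg, mL, s) of the classic
#' pumping-heart + systemic + pulmonary family, calibrated so that a regular
#' rhythm at 70 bpm produces textbook-normal left-heart hemodynamics
#' (systolic systemic pressure 100-130 mmHg, ejection fraction 55-70%).
#' Atria are passive (constant elastance), mimicking the loss of atrial kick
#' in atrial fibrillation. Ventricular systole lasts
#' \code{T_sys = k_sys * sqrt(rr)}.
#'
#' @param ... named overrides of individual parameters.
#' @return an object of class \code{cv_params} (named list).
#' @examples
#' p <- default_parameters()
#' p$Emax_lv
#' p2 <- default_parameters(R_sys = 1.3)
#' @export
default_parameters <- function(...) {
  p <- list(
    E_la = 0.165, V0_la = 4,
    Emax_lv = 2.6, Emin_lv = 0.10, V0_lv = 5,
    E_ra = 0.12, V0_ra = 4,
    Emax_rv = 0.55, Emin_rv = 0.045, V0_rv = 10,
    R_mi = 0.006, L_mi = 5e-4, R_ao = 0.010, R_ti = 0.011, R_po = 0.008,
    C_sas = 1.75, V0_sas = 600, R_sys = 1.08, L_sys = 0.0025,
    C_svn = 70, V0_svn = 3400, R_svn = 0.05,
    C_pas = 5.0, V0_pas = 120, R_pul = 0.13, L_pul = 0.0008,
    C_pvn = 15, V0_pvn = 150, R_pvn = 0.008,
    k_sys = 0.4726, alpha_sys = 0.40, sys_split = 0.5,
    total_volume = 5740)
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), .PARAM_NAMES)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(override)] <- override
  }
  validate_parameters(structure(p, class = "cv_params"))
}

#' Validate a circulation parameter set
#'
#' Checks completeness, positivity of all compliances, resistances,
#' inertances and elastances, and that ventricular \code{Emax >= Emin}.
#'
#' @param params a \code{cv_params} list.
#' @return the validated object, invisibly usable.
#' @export
validate_parameters <- function(params) {
  if (!is.list(params)) stop("`params` must be a list")
  missing <- setdiff(.PARAM_NAMES, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), .PARAM_NAMES)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  num <- vapply(params, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("non-numeric or non-finite parameter(s): ",
         paste(names(params)[!num], collapse = ", "))
  pos <- c("E_la", "Emax_lv", "Emin_lv", "E_ra", "Emax_rv", "Emin_rv",
           "R_mi", "L_mi", "R_ao", "R_ti", "R_po",
           "C_sas", "R_sys", "L_sys", "C_svn", "R_svn",
           "C_pas", "R_pul", "L_pul", "C_pvn", "R_pvn",
           "k_sys", "total_volume")
  bad <- pos[vapply(pos, function(nm) params[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (params$Emax_lv < params$Emin_lv || params$Emax_rv < params$Emin_rv)
    stop("ventricular Emax must be >= Emin")
  if (params$sys_split <= 0 || params$sys_split >= 1)
    stop("`sys_split` must lie in (0, 1)")
  if (params$alpha_sys <= 0 || params$alpha_sys > 1)
    stop("`alpha_sys` must lie in (0, 1]")
  if (!inherits(params, "cv_params")) class(params) <- "cv_params"
  params
}

#' @export
print.cv_params <- function(x, ...) {
  cat("Closed-loop circulation parameters (mmHg, mL, s):\n")
  for (nm in .PARAM_NAMES)
    cat(sprintf("  %-12s %10.4g  [%s]\n", nm, x[[nm]], .PARAM_UNITS[[nm]]))
  invisible(x)
}

#' Write a parameter set to YAML
#'
#' Every parameter is emitted with its unit annotation as a
#' \code{value}/\code{unit} pair, so the file is self-documenting.
#'
#' @param params a \code{cv_params} object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  params <- validate_parameters(params)
  out <- lapply(.PARAM_NAMES, function(nm)
    list(value = params[[nm]], unit = .PARAM_UNITS[[nm]]))
  names(out) <- .PARAM_NAMES
  yaml::write_yaml(list(circulation = out), path)
  invisible(path)
}

#' Read a parameter set from YAML
#'
#' Accepts files written by [write_params_yaml()] (value/unit pairs) or plain
#' name-value maps. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a validated \code{cv_params}.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$circulation)) raw <- raw$circulation
  vals <- lapply(raw, function(x) if (is.list(x)) x$value else x)
  validate_parameters(structure(vals, class = "cv_params"))
}

#' Consistent initial state for the closed loop
#'
#' Fills chambers and compartments at plausible pressures, then assigns the
#' residual blood volume to the systemic venous reservoir so that the state
#' carries exactly \code{params$total_volume} mL. The simulation discards a
#' warm-up, so only rough plausibility matters here.
#'
#' @param params a \code{cv_params} object.
#' @return named numeric state vector (volumes mL, flows mL/s).
#' @export
initial_state <- function(params) {
  params <- validate_parameters(params)
  v <- c(
    V_la = 60, V_lv = 130, V_ra = 60, V_rv = 130,
    V_sas = params$V0_sas + 85 * params$C_sas,
    V_svn = NA_real_,
    V_pas = params$V0_pas + 16 * params$C_pas,
    V_pvn = params$V0_pvn + 10 * params$C_pvn,
    Q_sys = 70, Q_pul = 70, Q_mi = 0)
  vol_named <- sum(v[c("V_la", "V_lv", "V_ra", "V_rv", "V_sas", "V_pas", "V_pvn")])
  v["V_svn"] <- params$total_volume - vol_named
  if (v["V_svn"] <= params$V0_svn)
    warning("initial systemic venous pressure is not positive; ",
            "check `total_volume` against unstressed volumes")
  v
}

.state_names <- c("V_la", "V_lv", "V_ra", "V_rv",
                  "V_sas", "V_svn", "V_pas", "V_pvn",
                  "Q_sys", "Q_pul", "Q_mi")

# parameter vector in the layout the C right-hand side expects
.parms_vector <- function(params, rr, t_sys) {
  c(rr, t_sys, params$sys_split,
    params$E_la, params$V0_la,
    params$Emax_lv, params$Emin_lv, params$V0_lv,
    params$E_ra, params$V0_ra,
    params$Emax_rv, params$Emin_rv, params$V0_rv,
    params$R_mi, params$L_mi, params$R_ao, params$R_ti, params$R_po,
    params$C_sas, params$V0_sas, params$R_sys, params$L_sys,
    params$C_svn, params$V0_svn, params$R_svn,
    params$C_pas, params$V0_pas, params$R_pul, params$L_pul,
    params$C_pvn, params$V0_pvn, params$R_pvn)
}
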