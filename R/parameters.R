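REGULATION_PAIRS <- c("h12", "h13", "h23", "h21", "h42")

#' Model parameter set
#'
#' Bundles every constant of the autophagy regulation + pharmacokinetics model:
#' the timescale, the two physiological inputs (energy and nutrient supply),
#' the four kinetic constants, drug clearance rates, drug availability flags,
#' the five kinase-kinase regulation curves and the six drug-effect curves.
#'
#' The regulation curves are named after the (target, regulator) kinase pair
#' with states numbered x1 = MTORC1, x2 = ULK1, x3 = AMPK, x4 = VPS34:
#' `h12` (ULK1 represses MTORC1), `h13` (AMPK represses MTORC1), `h23` (AMPK
#' activates ULK1), `h21` (MTORC1 represses ULK1) and `h42` (ULK1 activates
#' VPS34). Drug curves `H[[i]]` give the multiplier of drug i = 1..6 applied
#' to the rate term it targets: 1 MTORC1 inhibitor, 2 dual MTORC1+VPS34
#' inhibitor, 3 ULK1 inhibitor, 4 drug suppressing AMPK activation, 5 drug
#' suppressing AMPK deactivation (raising AMPK activity), 6 VPS34 inhibitor.
#'
#' @param timescale Timescale T in minutes (default 1).
#' @param C_En,C_Nu Energy and nutrient supplies, each in `[0, 1]`; low values
#'   correspond to severe starvation stress.
#' @param k1 Basal AMPK activation rate constant.
#' @param k2 VPS34 deactivation rate constant.
#' @param k3 Maximal VPS34-dependent AV synthesis rate.
#' @param k4 AV clearance rate constant; `k3 / k4` is the reachable AV-count
#'   ceiling.
#' @param delta Length-6 vector of positive drug clearance rate constants.
#' @param b Length-6 vector of 0/1 drug availability flags.
#' @param regulation Named list of five [hill_curve()]s, names
#'   `h12`, `h13`, `h23`, `h21`, `h42`.
#' @param drugs List of six [hill_curve()]s, one per drug.
#' @return An object of class `av_parameters`.
#' @seealso [default_parameters()], [load_parameters()]
#' @export
av_parameters <- function(timescale = 1, C_En, C_Nu, k1, k2, k3, k4,
                          delta, b = rep(1, 6), regulation, drugs) {
  p <- structure(list(timescale = timescale, C_En = C_En, C_Nu = C_Nu,
                      k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                      delta = as.numeric(delta), b = as.numeric(b),
                      regulation = regulation, drugs = drugs),
                 class = "av_parameters")
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  if (!inherits(p, "av_parameters")) stop("not an 'av_parameters' object")
  num1 <- function(v, nm, lo = NULL, hi = NULL, strict_lo = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite number", nm))
    if (!is.null(lo) && (v < lo || (strict_lo && v <= lo)))
      stop(sprintf("parameter '%s' out of range", nm))
    if (!is.null(hi) && v > hi)
      stop(sprintf("parameter '%s' out of range", nm))
  }
  num1(p$timescale, "timescale", 0, strict_lo = TRUE)
  num1(p$C_En, "C_En", 0, 1); num1(p$C_Nu, "C_Nu", 0, 1)
  for (k in c("k1", "k2", "k3", "k4")) num1(p[[k]], k, 0)
  num1(p$k4, "k4", 0, strict_lo = TRUE)
  if (length(p$delta) != 6L || any(!is.finite(p$delta)) || any(p$delta <= 0))
    stop("'delta' must be six positive clearance rates")
  if (length(p$b) != 6L || !all(p$b %in% c(0, 1)))
    stop("'b' must be six 0/1 availability flags")
  if (!is.list(p$regulation) ||
      !identical(sort(names(p$regulation)), sort(REGULATION_PAIRS)))
    stop("'regulation' must hold exactly the curves ",
         toString(REGULATION_PAIRS))
  if (!all(vapply(p$regulation, is_hill_curve, TRUE)))
    stop("all regulation entries must be hill_curve objects")
  if (!is.list(p$drugs) || length(p$drugs) != 6L ||
      !all(vapply(p$drugs, is_hill_curve, TRUE)))
    stop("'drugs' must be a list of six hill_curve objects")
  invisible(p)
}

#' @export
print.av_parameters <- function(x, ...) {
  cat(sprintf(paste0("<av_parameters C_En=%g C_Nu=%g k1=%g k2=%g k3=%g ",
                     "k4=%g ceiling=%g>\n"),
              x$C_En, x$C_Nu, x$k1, x$k2, x$k3, x$k4, x$k3 / x$k4))
  invisible(x)
}

#' AV-count ceiling
#'
#' The reachable upper bound on the AV count, `k3 / k4`.
#' @param params An [av_parameters()] object.
#' @return A single number.
#' @export
av_ceiling <- function(params) params$k3 / params$k4

#' Packaged default parameterization
#'
#' Returns the calibrated default parameter set shipped with the package
#' (see `inst/extdata/default_parameters.yaml`). The set is tuned so that the
#' drug-free model reproduces the reference behaviors: a stationary AV count
#' of about 37 under severe stress (`C_En = C_Nu = 0.1`), oscillations with
#' envelope about `[20, 27]` under moderate stress (0.6), and a low stationary
#' count under replete conditions (1.0), with drugs 1 and 5 raising and drugs
#' 2, 3, 4 and 6 lowering the long-time AV count. See [verify_calibration()].
#'
#' @param C_En,C_Nu Optional physiological condition overrides.
#' @return An [av_parameters()] object.
#' @export
default_parameters <- function(C_En = NULL, C_Nu = NULL) {
  path <- system.file("extdata", "default_parameters.yaml", package = "avctrl")
  p <- load_parameters(path)
  if (!is.null(C_En)) p$C_En <- C_En
  if (!is.null(C_Nu)) p$C_Nu <- C_Nu
  validate_parameters(p)
  p
}

PARAM_SCALAR_KEYS <- c("timescale", "C_En", "C_Nu", "k1", "k2", "k3", "k4")

#' Read a parameter configuration file
#'
#' The configuration is a YAML mapping with scalar keys `timescale`, `C_En`,
#' `C_Nu`, `k1`..`k4`, six-element sequences `delta` and `b`, a `regulation`
#' mapping with entries `h12`, `h13`, `h23`, `h21`, `h42`, and a `drugs`
#' mapping with entries `H1`..`H6`; every curve is a mapping with keys `rb`,
#' `rm`, `theta`, `n`. Unknown keys are rejected and missing keys reported by
#' name.
#'
#' @param path Path to a YAML parameter file.
#' @return An [av_parameters()] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c(PARAM_SCALAR_KEYS, "delta", "b", "regulation", "drugs")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown parameter keys: ", toString(extra))
  missing <- setdiff(known, names(raw))
  if (length(missing)) stop("missing parameter keys: ", toString(missing))
  curve <- function(x, nm) {
    # YAML 1.1 treats a bare `n` key as a boolean; accept either spelling
    names(x)[names(x) %in% c("FALSE", "no")] <- "n"
    need <- c("rb", "rm", "theta", "n")
    if (!is.list(x) || !all(need %in% names(x)))
      stop("curve '", nm, "' must provide rb, rm, theta, n")
    hill_curve(x$rb, x$rm, x$theta, x$n)
  }
  reg_missing <- setdiff(REGULATION_PAIRS, names(raw$regulation))
  if (length(reg_missing))
    stop("missing regulation curves: ", toString(reg_missing))
  regulation <- lapply(REGULATION_PAIRS, function(nm)
    curve(raw$regulation[[nm]], nm))
  names(regulation) <- REGULATION_PAIRS
  drug_names <- paste0("H", 1:6)
  drug_missing <- setdiff(drug_names, names(raw$drugs))
  if (length(drug_missing)) stop("missing drug curves: ",
                                 toString(drug_missing))
  drugs <- lapply(drug_names, function(nm) curve(raw$drugs[[nm]], nm))
  av_parameters(timescale = raw$timescale, C_En = raw$C_En, C_Nu = raw$C_Nu,
                k1 = raw$k1, k2 = raw$k2, k3 = raw$k3, k4 = raw$k4,
                delta = unlist(raw$delta), b = unlist(raw$b),
                regulation = regulation, drugs = drugs)
}

#' Write a parameter configuration file
#'
#' Serializes an [av_parameters()] object to the YAML schema read by
#' [load_parameters()]; a write-then-read round trip reproduces the values.
#'
#' @param params An [av_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  as_plain <- function(cv) list(rb = cv$rb, rm = cv$rm, theta = cv$theta,
                                n = cv$n)
  out <- c(params[PARAM_SCALAR_KEYS],
           list(delta = params$delta, b = params$b,
                regulation = lapply(params$regulation, as_plain),
                drugs = stats::setNames(lapply(params$drugs, as_plain),
                                        paste0("H", 1:6))))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
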