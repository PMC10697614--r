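#' Game parameter set
#'
#' Constructs the full parameter set of the elderly-care differential game:
#' discounting, state decay, service benefits, infection harm, quadratic
#' service/resource costs, extra costs of the two special-care modes,
#' credibility-gain rates and treatment-efficacy parameters. Defaults are the
#' reference scenario used throughout the package's numerical analysis.
#'
#' @param rho discount rate, in (0, 1].
#' @param delta1 decay rate of elderly satisfaction (> 0).
#' @param delta2 decay rate of government credibility (> 0).
#' @param b benefit per unit of medical service received by the elderly.
#' @param b_G extra per-unit benefit when a hospital "green channel" is open.
#' @param l1 welfare weight of the elderly health state.
#' @param l2 welfare weight of the government credibility state.
#' @param c_I bodily damage per unit infection.
#' @param c_M quadratic cost coefficient of medical service.
#' @param c_F quadratic cost coefficient of government resource input.
#' @param c_H extra cost of the home-care mode (adds to both c_M and c_F).
#' @param c_G extra cost of the green-channel mode (adds to both c_M and c_F).
#' @param alpha1 reduction of cross-infection harm under home care.
#' @param lambda1 health damage rate from squared infection.
#' @param lambda2 credibility gained per unit resource invested.
#' @param lambda3 extra credibility-channel rate without special care.
#' @param lambda4 queue-induced credibility-loss rate without special care.
#' @param lambda_H extra credibility rate for providing home care.
#' @param lambda_G extra credibility rate for providing the green channel.
#' @param beta baseline treatment efficacy.
#' @param beta_H extra efficacy of home care.
#' @param beta_G extra efficacy of the green channel.
#' @param validate validate the set before returning it?
#'
#' @return An object of class `game_parameters` (a named list).
#' @seealso [validate_parameters()], [effective_params()],
#'   [baseline_parameters()]
#' @export
#' @examples
#' p <- game_parameters()          # reference scenario
#' p2 <- game_parameters(b_G = 0.5)
game_parameters <- function(rho = 0.9, delta1 = 0.1, delta2 = 0.1,
                            b = 3, b_G = 1, l1 = 1, l2 = 1,
                            c_I = 1.5, c_M = 2, c_F = 2, c_H = 1, c_G = 1,
                            alpha1 = 0.5,
                            lambda1 = 1, lambda2 = 1, lambda3 = 2, lambda4 = 2,
                            lambda_H = 0.3, lambda_G = 0.3,
                            beta = 3.49, beta_H = 28.7, beta_G = 7.71,
                            validate = TRUE) {
  p <- structure(
    list(rho = rho, delta1 = delta1, delta2 = delta2,
         b = b, b_G = b_G, l1 = l1, l2 = l2,
         c_I = c_I, c_M = c_M, c_F = c_F, c_H = c_H, c_G = c_G,
         alpha1 = alpha1,
         lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         lambda4 = lambda4, lambda_H = lambda_H, lambda_G = lambda_G,
         beta = beta, beta_H = beta_H, beta_G = beta_G),
    class = "game_parameters")
  if (validate) validate_parameters(p) else p
}

#' Field names of a game parameter set
#' @keywords internal
parameter_fields <- function() {
  c("rho", "delta1", "delta2", "b", "b_G", "l1", "l2",
    "c_I", "c_M", "c_F", "c_H", "c_G", "alpha1",
    "lambda1", "lambda2", "lambda3", "lambda4", "lambda_H", "lambda_G",
    "beta", "beta_H", "beta_G")
}

#' Validate a game parameter set
#'
#' Checks every sign constraint of the model: `rho` in (0, 1] (a zero
#' discount rate would make the infinite-horizon welfare integrals diverge),
#' strictly positive decay rates, costs, benefits and rate parameters,
#' `c_I - alpha1 >= 0` (a negative effective infection harm would flip the
#' sign of the elderly infection control), and a positive no-special-care
#' credibility-gain rate `lambda2 + lambda3 - lambda4 > 0`.
#'
#' @param params a [game_parameters()] object or a named list with the same
#'   fields.
#' @param allow_degenerate if `TRUE`, permit `lambda2 + lambda3 - lambda4
#'   <= 0` (and the analogous mode-specific rates) for exploratory use; the
#'   optimal resource input is then zero or negative.
#' @return `params`, unchanged, invisibly classed as `game_parameters`.
#'   Errors name the violated inequality.
#' @export
validate_parameters <- function(params, allow_degenerate = FALSE) {
  fields <- parameter_fields()
  missing_f <- setdiff(fields, names(params))
  if (length(missing_f))
    stop("missing parameter field(s): ", paste(missing_f, collapse = ", "))
  extra <- setdiff(names(params), fields)
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "))
  for (f in fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  if (!(params$rho > 0 && params$rho <= 1))
    stop("constraint violated: 0 < rho <= 1 (discount rate; rho = ",
         params$rho, ")")
  # mode-specific add-ons may be zero (a zero add-on collapses that aspect
  # of the special-care mode onto no special care); everything else is
  # strictly positive
  nonneg <- c("b_G", "c_H", "c_G", "alpha1", "lambda_H", "lambda_G",
              "beta_H", "beta_G")
  for (f in setdiff(fields, c("rho", nonneg))) {
    if (params[[f]] <= 0)
      stop("constraint violated: ", f, " > 0 (got ", params[[f]], ")")
  }
  for (f in nonneg) {
    if (params[[f]] < 0)
      stop("constraint violated: ", f, " >= 0 (got ", params[[f]], ")")
  }
  if (params$c_I - params$alpha1 < 0)
    stop("constraint violated: c_I - alpha1 >= 0 ",
         "(effective infection harm under home care must be nonnegative; ",
         "c_I = ", params$c_I, ", alpha1 = ", params$alpha1, ")")
  if (!allow_degenerate) {
    kN <- params$lambda2 + params$lambda3 - params$lambda4
    if (kN <= 0)
      stop("constraint violated: lambda2 + lambda3 - lambda4 > 0 ",
           "(no-special-care credibility-gain rate; got ", kN,
           "). Use allow_degenerate = TRUE to explore this regime.")
  }
  p <- params[fields]
  class(p) <- "game_parameters"
  invisible(p)
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("Elderly-care differential game parameters\n")
  v <- unlist(x)
  print(noquote(format(v, digits = 4)))
  invisible(x)
}

#' The three medical-service modes
#'
#' `"N"` no special care, `"H"` home medical care, `"G"` hospital green
#' channel, in the fixed reporting order N < H < G.
#' @return Character vector of the three mode tags.
#' @export
game_modes <- function() c("N", "H", "G")

match_mode <- function(mode) {
  match.arg(toupper(mode), game_modes())
}

match_agent <- function(agent) {
  match.arg(agent, c("elderly", "government"))
}

#' Mode-effective coefficients
#'
#' Collapses the three service modes into one parametric family. Each mode
#' differs from the others only through six coefficients: the effective
#' service benefit, the effective infection harm, the effective quadratic
#' service and government-resource costs, the credibility-gain rate per unit
#' resource, and the log-efficacy of treatment.
#'
#' \describe{
#'   \item{N}{`(b, c_I, c_M, c_F, lambda2 + lambda3 - lambda4, ln(beta + 1))`}
#'   \item{H}{`(b, c_I - alpha1, c_M + c_H, c_F + c_H, lambda2 + lambda_H,
#'     ln(beta + beta_H + 1))`}
#'   \item{G}{`(b + b_G, c_I, c_M + c_G, c_F + c_G, lambda2 + lambda_G,
#'     ln(beta + beta_G + 1))`}
#' }
#'
#' @param params validated [game_parameters()].
#' @param mode one of `"N"`, `"H"`, `"G"`.
#' @return An object of class `effective_params` with fields `b_eff`,
#'   `c_inf_eff`, `c_treat_eff`, `c_gov_eff`, `kappa`, `log_efficacy` plus
#'   pass-through `rho`, `delta1`, `delta2`, `l1`, `l2`, `lambda1`, `mode`.
#' @export
effective_params <- function(params, mode) {
  mode <- match_mode(mode)
  p <- params
  eff <- switch(mode,
    N = list(b_eff = p$b, c_inf_eff = p$c_I,
             c_treat_eff = p$c_M, c_gov_eff = p$c_F,
             kappa = p$lambda2 + p$lambda3 - p$lambda4,
             log_efficacy = log(p$beta + 1)),
    H = list(b_eff = p$b, c_inf_eff = p$c_I - p$alpha1,
             c_treat_eff = p$c_M + p$c_H, c_gov_eff = p$c_F + p$c_H,
             kappa = p$lambda2 + p$lambda_H,
             log_efficacy = log(p$beta + p$beta_H + 1)),
    G = list(b_eff = p$b + p$b_G, c_inf_eff = p$c_I,
             c_treat_eff = p$c_M + p$c_G, c_gov_eff = p$c_F + p$c_G,
             kappa = p$lambda2 + p$lambda_G,
             log_efficacy = log(p$beta + p$beta_G + 1)))
  eff <- c(eff, list(rho = p$rho, delta1 = p$delta1, delta2 = p$delta2,
                     l1 = p$l1, l2 = p$l2, lambda1 = p$lambda1, mode = mode))
  stopifnot(eff$c_treat_eff > 0, eff$c_gov_eff > 0, eff$log_efficacy > 0)
  structure(eff, class = "effective_params")
}

#' @export
print.effective_params <- function(x, ...) {
  cat("Mode-effective coefficients (mode ", x$mode, ")\n", sep = "")
  v <- unlist(x[c("b_eff", "c_inf_eff", "c_treat_eff", "c_gov_eff",
                  "kappa", "log_efficacy")])
  print(noquote(format(v, digits = 6)))
  invisible(x)
}

#' Read a parameter file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) file whose keys match the
#' [game_parameters()] field names exactly. Unknown keys are an error; missing
#' keys fall back to the reference-scenario defaults only if
#' `complete = TRUE`.
#'
#' @param path file path.
#' @param complete fill unspecified fields with the defaults?
#' @return A validated `game_parameters` object.
#' @export
read_parameters <- function(path, complete = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- parse_config_file(path)
  extra <- setdiff(names(raw), parameter_fields())
  if (length(extra))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  if (complete) {
    p <- game_parameters(validate = FALSE)
    p[names(raw)] <- raw
  } else {
    missing_f <- setdiff(parameter_fields(), names(raw))
    if (length(missing_f))
      stop("parameter file ", path, " is missing key(s): ",
           paste(missing_f, collapse = ", "))
    p <- structure(raw[parameter_fields()], class = "game_parameters")
  }
  validate_parameters(p)
  p
}

#' Write a parameter file
#'
#' @param params a `game_parameters` object.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  x <- lapply(unclass(params), identity)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 17L)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported parameter file extension: .", ext)
  }
  invisible(path)
}

parse_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config file extension: .", ext)
  }
}
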