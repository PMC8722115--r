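#' Read a trial scenario from a YAML or JSON file
#'
#' The file format mirrors [trial_scenario()]: top-level keys `endpoint`,
#' `theta_t`, `delta`, `control_cap`, `comparison`, optional `priors`
#' (`experimental`/`control`, each `[alpha, beta]`), optional `accrual`
#' (`kind`, `rate`), optional `reps` and `seed` defaults, and `arms`, a list
#' with `arm_id`, `role`, `true_rate`, `planned_n`, `open_time`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A [trial_scenario()]; any `reps`/`seed` entries are attached as
#'   attributes `reps` and `seed`.
#' @export
read_scenario <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("scenario file must be .yaml, .yml or .json", call. = FALSE)
  scenario_from_list(cfg)
}

#' @rdname read_scenario
#' @param cfg A list with the schema described above (already parsed).
#' @export
scenario_from_list <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$arms), !is.null(cfg$theta_t))
  arms_in <- cfg$arms
  if (is.data.frame(arms_in))
    arms_in <- lapply(seq_len(nrow(arms_in)), function(i)
      as.list(arms_in[i, , drop = FALSE]))
  arms <- lapply(arms_in, function(a)
    arm_spec(arm_id = as.character(a$arm_id), role = a$role,
             true_rate = a$true_rate,
             planned_n = if (is.null(a$planned_n)) 30 else a$planned_n,
             open_time = if (is.null(a$open_time)) 0 else a$open_time))
  pr <- function(x, default) if (is.null(x)) default
        else beta_prior(x[[1L]], x[[2L]])
  acc <- if (is.null(cfg$accrual)) accrual_model()
         else accrual_model(cfg$accrual$kind, cfg$accrual$rate)
  sc <- trial_scenario(
    arms = arms,
    endpoint = if (is.null(cfg$endpoint)) "MPR" else cfg$endpoint,
    rule = decision_rule(if (is.null(cfg$delta)) 0.05 else cfg$delta,
                         cfg$theta_t),
    prior_e = pr(cfg$priors$experimental, beta_prior(1, 1)),
    prior_c = pr(cfg$priors$control, beta_prior(1, 1)),
    accrual = acc,
    control_cap = if (is.null(cfg$control_cap)) 30 else cfg$control_cap,
    comparison = if (is.null(cfg$comparison)) "final" else cfg$comparison)
  attr(sc, "reps") <- cfg$reps
  attr(sc, "seed") <- cfg$seed
  sc
}

#' Write a trial scenario to a YAML or JSON file
#'
#' @param scenario A [trial_scenario()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "trial_scenario"))
  cfg <- list(
    endpoint = scenario$endpoint,
    theta_t = scenario$rule$theta_t,
    delta = scenario$rule$delta,
    control_cap = scenario$control_cap,
    comparison = scenario$comparison,
    priors = list(
      experimental = c(scenario$prior_e$alpha, scenario$prior_e$beta),
      control = c(scenario$prior_c$alpha, scenario$prior_c$beta)),
    accrual = list(kind = scenario$accrual$kind,
                   rate = scenario$accrual$rate),
    arms = lapply(scenario$arms, function(a)
      list(arm_id = a$arm_id, role = a$role, true_rate = a$true_rate,
           planned_n = a$planned_n, open_time = a$open_time)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("scenario file must be .yaml, .yml or .json", call. = FALSE)
  invisible(path)
}
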