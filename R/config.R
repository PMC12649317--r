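# Structured-text (YAML) tuning configuration for the command-line
# interface and for scripted runs.

#' Read and validate a tuning configuration file
#'
#' The configuration is a YAML document with up to three blocks:
#' \describe{
#'   \item{`instrument`}{Any of `noise_cv`, `mca`, `interaction`,
#'     `interaction_rho`, plus optional `parameters` / `peaks` tables
#'     (lists of rows) overriding the built-in defaults.}
#'   \item{`optimizer`}{Any argument of [optimizer_config()] except
#'     dimension and bounds, which come from the instrument.}
#'   \item{`evaluation`}{`weights`, `floor`, `peaks` for
#'     [evaluation_spec()]; `resolution_target` for the calibration loops.}
#' }
#' Unknown keys are rejected with an explicit message.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `instrument` (a [virtual_instrument()]),
#'   `optimizer_args` (list), and `evaluation` (an [evaluation_spec()]).
#' @export
read_tuning_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known_top <- c("instrument", "optimizer", "evaluation")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(known_top, collapse = ", "), call. = FALSE)
  }
  inst_cfg <- cfg$instrument %||% list()
  known_inst <- c("noise_cv", "mca", "interaction", "interaction_rho",
                  "interaction_pair", "parameters", "peaks")
  bad <- setdiff(names(inst_cfg), known_inst)
  if (length(bad)) {
    stop("unknown instrument config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inst_args <- inst_cfg[setdiff(names(inst_cfg), c("parameters", "peaks"))]
  if (!is.null(inst_cfg$parameters)) {
    inst_args$parameters <- do.call(rbind, lapply(inst_cfg$parameters,
                                                  as.data.frame))
  }
  if (!is.null(inst_cfg$peaks)) {
    inst_args$peaks <- do.call(rbind, lapply(inst_cfg$peaks, as.data.frame))
  }
  instrument <- do.call(virtual_instrument, inst_args)

  opt_args <- cfg$optimizer %||% list()
  # YAML 1.1 resolves a bare `N` key to a boolean; map it back
  names(opt_args)[names(opt_args) == "FALSE"] <- "N"
  allowed <- setdiff(names(formals(optimizer_config)),
                     c("D", "lower", "upper"))
  bad <- setdiff(names(opt_args), allowed)
  if (length(bad)) {
    stop("unknown optimizer config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  ev_cfg <- cfg$evaluation %||% list()
  known_ev <- c("weights", "floor", "peaks", "resolution_target")
  bad <- setdiff(names(ev_cfg), known_ev)
  if (length(bad)) {
    stop("unknown evaluation config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  spec_args <- ev_cfg[setdiff(names(ev_cfg), "resolution_target")]
  spec_args$weights <- if (!is.null(spec_args$weights))
    as.numeric(spec_args$weights)
  spec <- do.call(evaluation_spec, Filter(Negate(is.null), spec_args))

  list(instrument = instrument, optimizer_args = opt_args, evaluation = spec,
       resolution_target = ev_cfg$resolution_target %||% 0.7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
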