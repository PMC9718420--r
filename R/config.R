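# Configuration, reproducibility plumbing and fixture generation. Configs are
# flat YAML sections, one per parameter block, with keys named exactly as the
# constructor arguments; omitted keys take the standard working-point
# defaults. Unknown keys are rejected by name.

config_sections <- function() {
  list(circuit = names(formals(ff_params)),
       plasticity = names(formals(plasticity_params)),
       drive = names(formals(drive_spec)),
       multi_input = names(formals(multi_input_params)),
       recurrent = names(formals(recurrent_params)),
       run = c("experiment", "seed", "T", "T_baseline", "T_post",
               "init_w_EE", "init_w_EI", "disinhibit", "rho_base",
               "rho_disr", "n_draws", "out_dir"))
}

#' Load and validate a run configuration
#'
#' Reads a YAML config with optional sections \code{circuit},
#' \code{plasticity}, \code{drive}, \code{multi_input}, \code{recurrent} and
#' \code{run}. Every omitted key takes its default (the standard working
#' point); unknown sections or keys raise an error naming the offender, as do
#' invariant violations (via the constructors). An empty file yields the
#' all-defaults configuration.
#'
#' @param path path to a YAML file, or \code{NULL} for all defaults.
#' @return A list of class \code{"run_config"} with elements \code{circuit}
#'   (\code{\link{ff_params}}), \code{plasticity}
#'   (\code{\link{plasticity_params}}), \code{drive} (\code{NULL} or a
#'   \code{\link{drive_spec}}), \code{multi_input}, \code{recurrent},
#'   \code{run} and \code{$raw} (the resolved flat values).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- config_sections()
  bad_sec <- setdiff(names(raw), names(known))
  if (length(bad_sec)) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  build <- function(ctor, args) do.call(ctor, args %||% list())
  cfg <- list(
    circuit = build(ff_params, raw$circuit),
    plasticity = build(plasticity_params, raw$plasticity),
    drive = if (is.null(raw$drive)) NULL else build(drive_spec, raw$drive),
    multi_input = build(multi_input_params, raw$multi_input),
    recurrent = build(recurrent_params, raw$recurrent),
    run = utils::modifyList(list(experiment = "simulate", seed = 1L, T = 100,
                                 T_baseline = 10, T_post = 10,
                                 init_w_EE = 1.5, init_w_EI = 0.5,
                                 disinhibit = "specific",
                                 rho_base = 2, rho_disr = 2.5,
                                 n_draws = 200, out_dir = "."),
                            raw$run %||% list()))
  cfg$raw <- raw
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a resolved-config snapshot
#'
#' Serializes the fully resolved configuration (every key explicit) as YAML
#' next to a run's outputs, so the run can be reproduced from the snapshot
#' plus its seed. Reloading a snapshot yields an identical configuration
#' (round-trip idempotence).
#'
#' @param cfg a \code{"run_config"} from \code{\link{load_config}}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_config_snapshot <- function(cfg, path) {
  strip <- function(x) {
    x <- unclass(x)
    # drop derived fields not accepted by the constructors
    x[intersect(names(x), c("n_pre_E", "n_spec_per_pop"))] <- NULL
    x
  }
  out <- list(circuit = strip(cfg$circuit),
              plasticity = strip(cfg$plasticity),
              multi_input = strip(cfg$multi_input),
              recurrent = strip(cfg$recurrent),
              run = cfg$run)
  out$plasticity$rule <- cfg$plasticity$rule
  if (!is.null(cfg$drive)) out$drive <- strip(cfg$drive)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Generate seeded fixture files
#'
#' Writes reproducible CSV fixtures: \code{"weight_draws"} (n rows of initial
#' \code{w_EE}, \code{w_EI} drawn uniformly from [0, 3], the random-initial-
#' weight protocol) or \code{"pattern_matrix"} (n windows of the multi-input
#' rate matrix). Identical seeds give byte-identical files.
#'
#' @param kind \code{"weight_draws"} or \code{"pattern_matrix"}.
#' @param n number of rows / windows.
#' @param seed integer seed.
#' @param path output CSV path.
#' @param params a \code{\link{multi_input_params}} (pattern fixtures only).
#' @return \code{path}, invisibly.
#' @export
make_fixtures <- function(kind = c("weight_draws", "pattern_matrix"),
                          n = 100, seed = 1, path,
                          params = multi_input_params()) {
  kind <- match.arg(kind)
  set.seed(seed)
  df <- switch(kind,
    weight_draws = data.frame(w_EE = stats::runif(n, 0, 3),
                              w_EI = stats::runif(n, 0, 3)),
    pattern_matrix = {
      m <- pattern_sequence(params, n_windows = n, expand = TRUE)$rates
      as.data.frame(m)
    })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
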