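#' Default run configuration
#'
#' The structured configuration consumed by the command-line entry point and
#' convenient for scripted runs. Every value is overridable from a YAML file.
#'
#' @return nested list with blocks `loss` (component and channel weights,
#'   `kl_floor`), `schedule` (`T_initial`, `T_final`, `n_steps`, `mode`),
#'   `moves` (`substitute`, `insert`, `delete` probabilities), `predictor`
#'   (registry `name`, surrogate `kappa`), `alphabet` (with `exclude_cysteine`
#'   toggle), and `background` (`n_sequences`, optional separation `bands`).
#' @export
default_config <- function() {
  list(
    loss = list(w_restraint = 1, w_confidence = 1,
                channel_weights = list(d = 1, omega = 1, theta = 1, phi = 1),
                kl_floor = 1e-8),
    schedule = list(T_initial = 0.1, T_final = 0.001, n_steps = 1000,
                    mode = "geometric"),
    moves = list(substitute = 0.85, insert = 0.075, delete = 0.075),
    predictor = list(name = "surrogate", kappa = 3),
    alphabet = list(exclude_cysteine = FALSE),
    background = list(n_sequences = 100, bands = NULL)
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Expand a configuration into typed objects
#'
#' @param cfg nested configuration list (see [read_config()]).
#' @return list with `loss_cfg` (a `loss_config`), `schedule` (an
#'   `anneal_schedule`), `move_probs`, and `alphabet`.
#' @export
config_objects <- function(cfg) {
  cw <- unlist(cfg$loss$channel_weights)
  alphabet <- DEFAULT_ALPHABET
  if (isTRUE(cfg$alphabet$exclude_cysteine)) {
    alphabet <- setdiff(alphabet, "C")
  }
  list(
    loss_cfg = loss_config(cfg$loss$w_restraint, cfg$loss$w_confidence,
                           cw, cfg$loss$kl_floor),
    schedule = anneal_schedule(cfg$schedule$T_initial, cfg$schedule$T_final,
                               cfg$schedule$n_steps, cfg$schedule$mode),
    move_probs = c(cfg$moves$substitute, cfg$moves$insert, cfg$moves$delete),
    alphabet = alphabet
  )
}
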