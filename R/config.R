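# Flat YAML run configuration shared by the command-line driver and scripted
# runs. Keys mirror the function arguments.

.config_keys <- c("q_max", "alpha", "hyper_a", "hyper_b", "wt", "knn_k",
                  "rho", "max_iter", "n_restarts", "seed", "prune_tol",
                  "ch_variant", "n_pcs", "b_grid", "alpha_grid")

#' Default run configuration
#'
#' @return Named list of all pipeline parameters at their defaults,
#'   including the sweep grids `b_grid` and `alpha_grid`.
#' @export
default_run_config <- function() {
  ctrl <- pgm_control()
  list(q_max = ctrl$q_max, alpha = ctrl$alpha, hyper_a = ctrl$hyper_a,
       hyper_b = ctrl$hyper_b, wt = 0.5, knn_k = 10L, rho = ctrl$rho,
       max_iter = ctrl$max_iter, n_restarts = ctrl$n_restarts,
       seed = ctrl$seed, prune_tol = ctrl$prune_tol,
       ch_variant = "standard", n_pcs = NULL,
       b_grid = seq(0.1, 0.6, by = 0.1),
       alpha_grid = seq(50, 950, by = 100))
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys raise an error; missing keys fall back to the defaults.
#'
#' @param path Path to a flat YAML file.
#' @return Named list as in [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- default_run_config()
  cfg[names(user)] <- user
  cfg
}

#' Write a run configuration to a YAML file
#'
#' @param cfg Named list of configuration values (unknown keys error).
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a [pgm_control()] from a run configuration
#'
#' @param cfg Named list as returned by [read_run_config()].
#' @return A `pgm_control` object.
#' @export
config_to_control <- function(cfg) {
  pgm_control(q_max = cfg$q_max, alpha = cfg$alpha, hyper_a = cfg$hyper_a,
              hyper_b = cfg$hyper_b, rho = cfg$rho,
              max_iter = cfg$max_iter, n_restarts = cfg$n_restarts,
              seed = cfg$seed, prune_tol = cfg$prune_tol)
}
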