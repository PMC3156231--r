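# Configuration: YAML key-value files override package defaults; command
# line flags override the config (precedence: flags > config > defaults).

#' Default configuration
#'
#' @return Nested list with entries \code{weights} (dc, cf, fsc),
#'   \code{grid} (K, m vectors), \code{min_length}, and
#'   \code{property_scales} (path or NULL for the shipped table).
#' @export
default_config <- function() {
  list(
    weights = list(dc = 20, cf = 1, fsc = 1),
    grid = list(K = default_grid_K(), m = default_grid_m()),
    min_length = 21L,
    property_scales = NULL
  )
}

#' Load a configuration file over the defaults
#'
#' @param path YAML config path, or NULL for pure defaults. Recognized keys
#'   mirror \code{\link{default_config}}; unknown keys are rejected.
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

#' Build fusion weights from a configuration
#'
#' @param cfg Configuration list from \code{\link{load_config}}.
#' @return A \code{\link{fusion_weights}} object.
#' @export
config_weights <- function(cfg) {
  fusion_weights(w_dc = cfg$weights$dc, w_cf = cfg$weights$cf,
                 w_fsc = cfg$weights$fsc)
}

#' Load the property scales named by a configuration
#'
#' @param cfg Configuration list from \code{\link{load_config}}.
#' @return A \code{\link{property_scales}} object.
#' @export
config_scales <- function(cfg) {
  property_scales(cfg$property_scales)
}
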