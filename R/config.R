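#' Read a declarative campaign configuration from YAML
#'
#' A campaign is fully described by a small YAML file: design-space bounds
#' and constraint windows, initialization size, acquisition settings and
#' seeds, plus (optionally) the virtual-lab noise model. Every key is
#' optional and defaults to the package defaults, so `{}` is a valid
#' configuration.
#'
#' Recognized top-level keys: `space` (with `sorbitol`, `arginine`, `ph`,
#' `fractions`, `histidine`, `osmolality`, `acid_cap_mM`), `n_init`,
#' `restarts`, `seed`, `acquisition` (with `p_exploit`, `batch_size`,
#' `explore_starts`, `distance_weight`, `retry_cap`, `pop`, `gens`,
#' `explore_maxit`) and `lab` (with `tm_noise_C`, `kd_noise`,
#' `rm_noise_pct`, `dls_noise_rel`, `replicates`).
#'
#' @param path YAML file path.
#' @return A list with elements `campaign` (a [campaign_config()]) and
#'   `lab` (a [lab_config()]).
#' @export
read_campaign_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  call_with <- function(fun, args) {
    do.call(fun, args[intersect(names(args), names(formals(fun)))])
  }
  sp_args <- raw$space %||% list()
  for (nm in c("sorbitol", "arginine", "ph", "fractions", "osmolality")) {
    if (!is.null(sp_args[[nm]])) sp_args[[nm]] <- as.numeric(sp_args[[nm]])
  }
  space <- call_with(design_space, sp_args)
  acq <- call_with(acquisition_config, raw$acquisition %||% list())
  camp_args <- raw[intersect(names(raw), c("n_init", "restarts", "seed",
                                           "init_retry_cap"))]
  campaign <- do.call(campaign_config,
                      c(list(space = space, acquisition = acq), camp_args))
  lab <- call_with(lab_config, raw$lab %||% list())
  list(campaign = campaign, lab = lab)
}
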