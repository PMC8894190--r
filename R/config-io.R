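# Structured-config (YAML) serialisation shared by causal systems,
# distribution specs, mixtures and scenarios. The schema is documented in
# inst/extdata/config-schema.md and exercised by the shipped example configs.

dist_to_config <- function(d) {
  if (d$family == "threshold") {
    p <- d$params
    return(list(family = "threshold",
                params = list(onset = dist_to_config(p$onset),
                              rate = dist_to_config(p$rate),
                              threshold = dist_to_config(p$threshold),
                              n_grid = p$n_grid)))
  }
  drop <- if (d$family == "fixed") "terminus" else character()
  list(family = d$family, params = d$params[setdiff(names(d$params), drop)])
}

config_to_dist <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$family))
  p <- cfg$params %||% list()
  switch(cfg$family,
    gompertz = dist_gompertz(p$lam, p$theta, p$terminus %||% 0),
    weibull = dist_weibull(p$alpha, p$gamma, p$terminus %||% 0),
    makeham = dist_makeham(p$lam, p$theta, p$c, p$terminus %||% 0),
    flat = dist_flat(p$b, p$terminus %||% 0),
    regvar = dist_regvar(p$c, p$rho, p$terminus %||% 0, p$cap_age),
    lognormal_shifted = dist_lognormal(p$meanlog, p$sdlog, p$terminus %||% 0),
    gamma_shifted = dist_gamma(p$shape, p$rate, p$terminus %||% 0),
    fixed = dist_fixed(p$value),
    threshold = dist_threshold(config_to_dist(p$onset), config_to_dist(p$rate),
                               config_to_dist(p$threshold),
                               n_grid = p$n_grid %||% 64),
    stop("unknown distribution family in config: ", cfg$family, call. = FALSE)
  )
}

#' Read and write causal systems as structured configs
#'
#' Causal systems serialise to a YAML document with sections `components`
#' (id, category, distribution family + parameters), `sufficient_causes`
#' (id, component id list) and `earliest_reproduction_age`. See
#' `system.file("extdata", "config-schema.md", package = "ebmc")` and the
#' shipped example `system.file("extdata", "example-system.yaml", package =
#' "ebmc")`.
#'
#' @param path File path.
#' @param system A [causal_system()].
#' @return `read_causal_system()` returns a [causal_system()];
#'   `write_causal_system()` returns `path` invisibly.
#' @export
read_causal_system <- function(path) {
  cfg <- yaml::read_yaml(path)
  causal_system_from_config(cfg)
}

causal_system_from_config <- function(cfg) {
  stopifnot(!is.null(cfg$components), !is.null(cfg$sufficient_causes))
  comps <- lapply(cfg$components, function(cc) {
    component_cause(cc$id, cc$category, config_to_dist(cc$distribution))
  })
  scs <- lapply(cfg$sufficient_causes, function(sc) {
    sufficient_cause(sc$id, unlist(sc$components))
  })
  causal_system(comps, scs,
                earliest_reproduction_age = cfg$earliest_reproduction_age %||% 10)
}

#' @rdname read_causal_system
#' @export
write_causal_system <- function(system, path) {
  stopifnot(inherits(system, "causal_system"))
  cfg <- list(
    earliest_reproduction_age = system$earliest_reproduction_age,
    components = lapply(seq_len(nrow(system$components)), function(i) {
      list(id = system$components$id[i],
           category = system$components$category[i],
           distribution = dist_to_config(system$components$timing[[i]]))
    }),
    sufficient_causes = lapply(seq_len(nrow(system$sufficient_causes)), function(i) {
      list(id = system$sufficient_causes$id[i],
           components = as.list(system$sufficient_causes$components[[i]]))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

mixture_from_config <- function(cfg) {
  mixture_params(
    p = cfg$p,
    gompertz = config_to_dist(list(family = "gompertz", params = cfg$gompertz)),
    weibull = config_to_dist(list(family = "weibull", params = cfg$weibull))
  )
}

mixture_to_config <- function(mp) {
  list(p = mp$params$p,
       gompertz = mp$params$gompertz$params,
       weibull = mp$params$weibull$params)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
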