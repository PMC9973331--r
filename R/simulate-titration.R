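#' Configuration for the EMSA titration simulator
#'
#' @param params_4pl named vector `c(b =, c =, d =, e =)` of four-parameter
#'   log-logistic parameters: slope `b` (negative for curves rising with
#'   concentration under the LL.4 convention), lower asymptote `c`, upper
#'   asymptote `d`, and EC50 `e` in nM.
#' @param concentrations protein concentrations in nM.
#' @param noise_sd Gaussian noise standard deviation in fraction-bound units.
#' @param replicates number of technical replicates.
#' @param seed integer seed.
#' @return object of class `titration_sim_config`.
#' @export
titration_sim_config <- function(params_4pl = c(b = -1.5, c = 0, d = 1,
                                                e = 40),
                                 concentrations = c(0, 5, 10, 25, 50, 100,
                                                    250, 500),
                                 noise_sd = 0.05, replicates = 3L,
                                 seed = 1L) {
  p <- params_4pl
  stopifnot(all(c("b", "c", "d", "e") %in% names(p)),
            p[["e"]] > 0, p[["c"]] < p[["d"]],
            all(concentrations >= 0), noise_sd >= 0, replicates >= 1)
  structure(
    list(params = p[c("b", "c", "d", "e")],
         concentrations = concentrations,
         noise_sd = noise_sd, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "titration_sim_config"
  )
}

#' Simulate an EMSA titration series
#'
#' Fraction bound is the four-parameter log-logistic curve evaluated at each
#' concentration plus Gaussian noise, clipped to `[0, 1]`.
#'
#' @param config a [titration_sim_config()].
#' @return tibble `replicate, conc_nM, fraction_bound`.
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "titration_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  p <- config$params
  out <- expand.grid(replicate = seq_len(config$replicates),
                     conc_nM = config$concentrations)
  f <- four_param_loglogistic(out$conc_nM, p[["b"]], p[["c"]], p[["d"]],
                              p[["e"]])
  if (config$noise_sd > 0) {
    f <- f + stats::rnorm(length(f), 0, config$noise_sd)
  }
  tibble::tibble(replicate = out$replicate, conc_nM = out$conc_nM,
                 fraction_bound = pmin(pmax(f, 0), 1))
}
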