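#' Packaged synthetic study collection specification
#'
#' The argument list for [sim_config()] that defines the packaged
#' demonstration collection: six lung-cancer and four other-lung-disease
#' studies of 2000 genes, 60 up- and 40 down-planted consensus winners
#' perturbed in every study (penetrance 1), with a planted effect of 2.5
#' glog2 units on baselines well above the additive-noise floor — a
#' regime where the consensus rule should recover the planted signature
#' exactly. Used by the worked examples and the acceptance script.
#'
#' @return a named list of [sim_config()] arguments.
#' @export
demo_collection_spec <- function() {
  list(n_genes = 2000, samples_per_group = c(10, 20),
       n_winner_up = 60, n_winner_down = 40,
       effect_size = 2.5, winner_penetrance = 1.0,
       baseline_meanlog = log(500), baseline_sdlog = 0.6)
}
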