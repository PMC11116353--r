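#' Full default JSON configuration
#'
#' The resolved configuration tree with sections `signal`, `controller`,
#' `pig`, `cohort` and `scenario`, mirroring the constructor arguments
#' field for field. Use [write_config()] / [read_config()] for JSON I/O.
#'
#' @return nested named list
#' @export
refit_config <- function() {
  list(
    signal = unclass(signal_config()),
    controller = unclass(controller_config()),
    pig = unclass(pig_params()),
    cohort = list(n = 12, cv = 0.10, seed = 1),
    scenario = list(name = "lab", seed = 1, baseline_min = 30,
                    trigger_delay_to_resus_min = 30,
                    resus_duration_min = 180, follow_untreated_min = 180,
                    max_trigger_wait_min = 60, treatment_enabled = TRUE,
                    sao2 = NULL, disturbances = list())
  )
}

#' Write a configuration to JSON
#'
#' @param cfg nested list (e.g. [refit_config()])
#' @param path output path
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and validate a JSON configuration
#'
#' Unknown keys raise an error before any run; known sections are merged
#' over the defaults and re-validated through the typed constructors.
#'
#' @param path JSON file path
#' @return a [scenario_config()] ready for [run_scenario()] /
#'   [run_cohort()], with the cohort section attached as attribute `cohort`
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- refit_config()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  merge_over <- function(base, over, section) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) {
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    }
    base[names(over)] <- over
    base
  }
  sig <- merge_over(defaults$signal, raw$signal %||% list(), "signal")
  ctl <- merge_over(defaults$controller, raw$controller %||% list(),
                    "controller")
  # pig carries derived fields in the resolved tree; they are re-derived by
  # the constructor, so drop them before validation
  pig_args <- raw$pig %||% list()
  derived <- c("V_blood0", "svr0", "starling_k", "vo2", "lactate_prod0")
  pig_args[intersect(names(pig_args), derived)] <- NULL
  bad <- setdiff(names(pig_args), setdiff(names(defaults$pig), derived))
  if (length(bad)) stop("unknown key(s) in 'pig': ", paste(bad, collapse = ", "))
  pig <- do.call(pig_params, pig_args)
  sce <- merge_over(defaults$scenario, raw$scenario %||% list(), "scenario")
  coh <- merge_over(defaults$cohort, raw$cohort %||% list(), "cohort")
  dist <- lapply(seq_len(NROW(sce$disturbances)), function(i) {
    d <- if (is.data.frame(sce$disturbances)) {
      as.list(sce$disturbances[i, ])
    } else sce$disturbances[[i]]
    disturbance(d$kind, d$at_min_post_resus, d$duration_min,
                d$magnitude %||% 0.85)
  })
  cfg <- scenario_config(
    name = sce$name, seed = sce$seed, baseline_min = sce$baseline_min,
    trigger_delay_to_resus_min = sce$trigger_delay_to_resus_min,
    resus_duration_min = sce$resus_duration_min,
    follow_untreated_min = sce$follow_untreated_min,
    max_trigger_wait_min = sce$max_trigger_wait_min,
    treatment_enabled = sce$treatment_enabled,
    disturbances = dist, sao2 = sce$sao2, cohort_n = coh$n,
    pig = pig,
    controller = do.call(controller_config, ctl),
    signal = do.call(signal_config, sig))
  attr(cfg, "cohort") <- coh
  cfg
}
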