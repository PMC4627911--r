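#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [pipeline_config()]. Top-level keys mirror
#' the `pipeline_config` arguments; the nested mappings `terrain`,
#' `met_jan`, `met_jul`, `effect` and `forest` mirror the corresponding
#' spec constructors, with omitted keys taking the constructor defaults.
#'
#' @param path YAML file path.
#' @param out_dir,seed optional overrides of the file's values (the CLI's
#'   `--out` / `--seed` flags).
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, as.list(args))
  cfg_args <- list()
  for (key in c("out_dir", "n_sites", "points_per_site", "alpha",
                "n_permutations", "min_node", "pd_top", "stages", "seed"))
    if (!is.null(y[[key]])) cfg_args[[key]] <- y[[key]]
  if (!is.null(y$terrain)) cfg_args$terrain <- build(terrain_spec, y$terrain)
  if (!is.null(y$met_jan))
    cfg_args$met_jan <- build(met_spec,
                              c(list(month_label = "Jan"),
                                y$met_jan[names(y$met_jan) != "month_label"]))
  if (!is.null(y$met_jul))
    cfg_args$met_jul <- build(met_spec,
                              c(list(month_label = "Jul"),
                                y$met_jul[names(y$met_jul) != "month_label"]))
  if (!is.null(y$effect)) cfg_args$effect <- build(effect_spec, y$effect)
  if (!is.null(y$forest)) cfg_args$forest <- build(forest_config, y$forest)
  if (!is.null(out_dir)) cfg_args$out_dir <- out_dir
  if (!is.null(seed)) cfg_args$seed <- seed
  if (is.null(cfg_args$out_dir)) stop("config must set out_dir (or pass --out)")
  do.call(pipeline_config, cfg_args)
}
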