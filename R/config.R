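#' Structured run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' framework's standard settings: bandwidth `h = 1`, Beta shape `alpha =
#' 1` with candidate `beta` grid `{12, 25, 50, 100, 200}`,
#' single-environment sampler 12000/6000 iterations/burn-in,
#' multi-environment Kronecker regime 20000/10000, general regime
#' 100000/50000, 50 cross-validation replicates with a 70/30 split.
#'
#' @param ... overrides of the defaults (unknown keys rejected); see
#'   Details.
#' @details Keys: `h`, `alpha`, `beta_grid`, `se_iters`, `se_burnin`,
#'   `me_iters`, `me_burnin`, `me_general_iters`, `me_general_burnin`,
#'   `thin`, `reps`, `train_frac`, `holdout` (`"line"`/`"cell"`),
#'   `background` (`"identity"`/`"half_sib"`), `regime` (`"auto"`,
#'   `"kronecker"`, `"general"`), `seed`, `out_dir`, `trait`, `variants`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    h = 1, alpha = 1, beta_grid = c(12, 25, 50, 100, 200),
    se_iters = 12000L, se_burnin = 6000L,
    me_iters = 20000L, me_burnin = 10000L,
    me_general_iters = 100000L, me_general_burnin = 50000L,
    thin = 10L,
    reps = 50L, train_frac = 0.7, holdout = "line",
    background = "identity", regime = "auto",
    seed = 1L, out_dir = ".", trait = NULL, variants =
      c("SE_GK", "ME_GK", "ME_WK_MAF", "ME_WK_Pvalue", "ME_WK_MAF_Pvalue")
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (k in names(overrides)) cfg[k] <- list(overrides[[k]])
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("invalid config value for '", key, "': ", what)
  }
  chk(cfg$h > 0, "h", "must be > 0")
  chk(cfg$alpha > 0, "alpha", "must be > 0")
  chk(length(cfg$beta_grid) >= 1 && all(cfg$beta_grid > 0), "beta_grid",
      "must be a nonempty positive vector")
  for (k in c("se", "me", "me_general")) {
    it <- cfg[[paste0(k, "_iters")]]
    bu <- cfg[[paste0(k, "_burnin")]]
    chk(it > bu, paste0(k, "_burnin"), "burn-in must be < iterations")
    chk(bu >= 1, paste0(k, "_burnin"), "must be >= 1")
  }
  chk(cfg$thin >= 1, "thin", "must be >= 1")
  chk(cfg$reps >= 1, "reps", "must be >= 1")
  chk(cfg$train_frac > 0 && cfg$train_frac < 1, "train_frac",
      "must lie in (0, 1)")
  chk(cfg$holdout %in% c("line", "cell"), "holdout",
      "must be 'line' or 'cell'")
  chk(cfg$background %in% c("identity", "half_sib"), "background",
      "must be 'identity' or 'half_sib'")
  chk(cfg$regime %in% c("auto", "kronecker", "general"), "regime",
      "must be 'auto', 'kronecker' or 'general'")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  kernel: h = %g, alpha = %g, beta grid {%s}\n", x$h,
              x$alpha, paste(x$beta_grid, collapse = ", ")))
  cat(sprintf("  samplers: SE %d/%d, ME kronecker %d/%d, ME general %d/%d, thin %d\n",
              x$se_iters, x$se_burnin, x$me_iters, x$me_burnin,
              x$me_general_iters, x$me_general_burnin, x$thin))
  cat(sprintf("  CV: %d reps, train fraction %.2f, %s holdout; seed %d\n",
              x$reps, x$train_frac, x$holdout, x$seed))
  invisible(x)
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys get the standard defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  for (k in c("se_iters", "se_burnin", "me_iters", "me_burnin",
              "me_general_iters", "me_general_burnin", "thin", "reps",
              "seed")) {
    if (!is.null(vals[[k]])) vals[[k]] <- as.integer(vals[[k]])
  }
  do.call(run_config, vals)
}

#' Write a run configuration as YAML
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive per-stage seeds from one global seed
#'
#' Deterministic expansion of a global seed into independent sub-seeds so
#' pipeline stages (simulation, partitioning, samplers) can be rerun in
#' isolation. Results stay inside the 32-bit signed integer range.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (vectorized).
#' @return Integer seed(s).
#' @export
derive_seed <- function(seed, stage) {
  # splitmix-style mix, kept in double precision below 2^31
  x <- (as.numeric(seed) * 48271 + as.numeric(stage) * 30269) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x)
}

#' Run manifest: config hash, input checksums, seeds, version
#'
#' Records what produced an output directory so results can be
#' regenerated: the configuration (and its hash), md5 checksums of the
#' input files, the global seed, package version, and the produced files.
#'
#' @param config a [run_config()].
#' @param inputs character vector of input file paths.
#' @param outputs character vector of produced file paths (optional).
#' @param path optional path to write the manifest JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, inputs = character(), outputs = character(),
                         path = NULL) {
  inputs <- as.character(inputs)
  outputs <- as.character(outputs)
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "wkgs",
    version = as.character(utils::packageVersion("wkgs")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(f) list(path = f,
                                     md5 = unname(tools::md5sum(f)))),
    outputs = as.list(outputs)
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(manifest))
  }
  manifest
}
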