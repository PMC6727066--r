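#' Default run configuration
#'
#' All tunable settings with their defaults, as a flat named list keyed by
#' dotted section names. Unknown keys are rejected by [load_config()].
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    model.n_latent = 64L,
    model.lambda = 0.01,
    train.p_ratio = 3.0,
    train.epochs = 600L,
    train.lr = 0.01,
    train.seed = 1L,
    conv.dialect = "renormalized",
    conv.row_normalize_features = FALSE,
    eval.k = 5L,
    eval.repeats = 20L,
    sim.n_lnc = 120L,
    sim.n_mir = 80L,
    sim.latent_rank = 6L,
    sim.d_lnc = 22L,
    sim.d_mir = 172L,
    sim.density = 0.04,
    sim.feature_noise = 0.1,
    sim.seed = 1L,
    out.top_k = 1000L
  )
}

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_config(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$model.n_latent >= 1, "model.n_latent must be >= 1")
  chk(cfg$model.lambda >= 0, "model.lambda must be >= 0")
  chk(cfg$train.p_ratio >= 0, "train.p_ratio must be >= 0")
  chk(cfg$train.epochs >= 1, "train.epochs must be >= 1")
  chk(cfg$train.lr > 0, "train.lr must be > 0")
  chk(cfg$conv.dialect %in% c("renormalized", "plain"),
      "conv.dialect must be 'renormalized' or 'plain'")
  chk(is.logical(cfg$conv.row_normalize_features),
      "conv.row_normalize_features must be logical")
  chk(cfg$eval.k >= 2, "eval.k must be >= 2")
  chk(cfg$eval.repeats >= 1, "eval.repeats must be >= 1")
  chk(cfg$sim.density > 0 && cfg$sim.density < 1,
      "sim.density must be in (0, 1)")
  chk(cfg$out.top_k >= 1, "out.top_k must be >= 1")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration file (flat `section.key` entries or nested
#' sections; both are accepted and merged), applies the documented
#' defaults for everything left unset, then applies explicit overrides —
#' overrides win over the file, the file wins over defaults. Unknown keys
#' are an error and the message lists the valid ones.
#'
#' @param path path to a YAML file, or `NULL` for defaults only.
#' @param overrides named list of `section.key` overrides (e.g. from
#'   command-line flags).
#' @return validated named configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  from_file <- if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) list() else flatten_config(raw)
  } else {
    list()
  }
  for (src in list(from_file, flatten_config(overrides))) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           "\nvalid keys: ", paste(names(cfg), collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(src)) {
      mode_wanted <- storage.mode(cfg[[nm]])
      val <- src[[nm]]
      if (mode_wanted %in% c("integer", "double") && is.numeric(val)) {
        storage.mode(val) <- mode_wanted
      }
      cfg[[nm]] <- val
    }
  }
  validate_config(cfg)
}

#' Write a reproducibility manifest
#'
#' Records the fully resolved configuration, the MD5 checksum of every
#' input file, the master seed, the package version and a timestamp as
#' `manifest.json` in the output directory. The embedded configuration
#' round-trips through [load_config()].
#'
#' @param config resolved configuration list.
#' @param inputs character vector of input file paths (possibly empty).
#' @param out_dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
run_manifest <- function(config, inputs, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "lnclink",
    version = as.character(utils::packageVersion("lnclink")),
    seed = config$train.seed,
    config = config,
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
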