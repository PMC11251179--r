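# Model configuration files and result writers.

.config_keys <- c("N", "lambda", "s", "a", "nu", "xi", "mu", "label")

#' Read a model from a YAML or JSON configuration file
#'
#' The configuration carries the per-compartment rate arrays in 1-based
#' semantic order: keys \code{N}, \code{lambda}, \code{s}, \code{a},
#' \code{nu}, \code{xi}, \code{mu} and an optional \code{label}. Unknown
#' keys are rejected. A machine-readable schema ships with the package
#' (\code{system.file("extdata", "model-schema.json", package =
#' "cellchains")}).
#'
#' @param path file path; format chosen by extension (\code{.yaml} /
#'   \code{.yml} / \code{.json}).
#' @return A \code{compartment_model}.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else stop("config file must be .yaml, .yml or .json")
  # YAML 1.1 reads a bare key `N` as boolean false; undo that
  names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "N"
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("lambda", "mu"), names(cfg))
  if (length(missing))
    stop("config must provide at least: ", paste(missing, collapse = ", "))
  grab <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  m <- compartment_model(lambda = as.numeric(cfg$lambda),
                         s = as.numeric(grab("s", 0)),
                         a = as.numeric(grab("a", 0)),
                         nu = as.numeric(grab("nu", 0)),
                         xi = as.numeric(grab("xi", 0)),
                         mu = as.numeric(cfg$mu),
                         label = grab("label", ""))
  if (!is.null(cfg$N) && cfg$N != m$N)
    stop(sprintf("config key N = %d does not match the rate arrays (length %d)",
                 cfg$N, m$N))
  m
}

#' Write a model to a YAML or JSON configuration file
#'
#' @param model a \code{compartment_model}.
#' @param path destination; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "compartment_model"))
  cfg <- list(N = model$N, lambda = model$lambda, s = model$s, a = model$a,
              nu = model$nu, xi = model$xi, mu = model$mu,
              label = model$label)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path, precision = 15L)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else stop("config file must be .yaml, .yml or .json")
  invisible(path)
}

# CSV with '#'-prefixed header comments; floats at 12 significant digits.
.write_csv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) signif(x, 12))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mean trajectory as tidy CSV
#'
#' Long format (\code{time}, \code{compartment}, \code{mean}) with header
#' comments recording the model label, solution method and package version.
#'
#' @param trajectory a \code{mean_trajectory}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_mean_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "mean_trajectory"))
  .write_csv_commented(
    as.data.frame(trajectory), path,
    comments = c(sprintf("model: %s", trajectory$label),
                 sprintf("method: %s", trajectory$method),
                 sprintf("cellchains %s",
                         as.character(utils::packageVersion("cellchains")))))
}

.write_manifest <- function(dir, command, params, outputs, seed = NULL) {
  manifest <- list(command = command,
                   parameters = params,
                   seed = seed,
                   package_version =
                     as.character(utils::packageVersion("cellchains")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
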