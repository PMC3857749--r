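# minimal flat-YAML reader: "key: value" pairs, comments and blank lines.
# Configs use a flat schema, so a full YAML parser is optional (used when the
# yaml package is installed).
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[lines != "---"]
  out <- list()
  for (ln in lines) {
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*\\s*:", ln))
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Load a parameter configuration
#'
#' Reads a flat YAML or JSON mapping with exactly the keys
#' `A, d, beta, m, gamma, alpha, p, k` and validates it into a
#' [sirs_params()] object. Unknown keys are rejected; missing parameters are
#' listed by name.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [sirs_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (requireNamespace("yaml", quietly = TRUE))
      yaml::read_yaml(path)
    else read_flat_yaml(path)
  } else stop("unsupported config extension: .", ext, call. = FALSE)
  raw <- lapply(raw, function(v) if (is.numeric(v)) as.numeric(v) else v)
  unknown <- setdiff(names(raw), param_names())
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(param_names(), names(raw))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(sirs_params, raw[param_names()])
}

#' Write a parameter configuration
#'
#' @param params a [sirs_params()] object.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` flat
#'   mapping, or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "sirs_params"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(params[param_names()], path,
                         auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    writeLines(sprintf("%s: %s", param_names(),
                       vapply(params[param_names()],
                              function(v) format(v, digits = 17),
                              character(1))), path)
  } else stop("unsupported config extension: .", ext, call. = FALSE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Header `t,I,R` (planar variants) or `t,S,I,R` (full), full precision.
#'
#' @param trajectory a `sirs_trajectory` from [integrate_sirs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sirs_trajectory"))
  df <- as.data.frame(trajectory)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# plain-list views of report objects, used for JSON serialization
report_list <- function(x) UseMethod("report_list")

#' @export
report_list.sirs_equilibria <- function(x) {
  eqs <- x$equilibria
  list(R0 = x$R0, regime = x$regime,
       equilibria = lapply(seq_len(nrow(eqs)), function(i)
         list(I = eqs$I[i], R = eqs$R[i], in_domain = eqs$in_domain[i],
              residual = eqs$residual_rhs[i],
              multiplicity = eqs$multiplicity[i])),
       vieta_residuals = x$vieta_residuals)
}

#' @export
report_list.sirs_stability <- function(x) {
  list(R0 = x$R0,
       equilibrium = if (is.null(x$equilibrium)) NULL
                     else as.list(x$equilibrium),
       jacobian = if (is.null(x$jacobian)) NULL else as.vector(t(x$jacobian)),
       trace = x$trace, det = x$det, discriminant = x$discriminant,
       local_class = x$local_class, dulac_max = x$dulac_max,
       globally_stable = x$globally_stable, reason = x$reason)
}

#' @export
report_list.sirs_hopf <- function(x) {
  x$tol <- NULL
  x$equilibrium <- as.list(x$equilibrium)
  unclass(x)
}

#' @export
report_list.sirs_cycle <- function(x) {
  list(found = x$found, period = x$period,
       section_point = if (is.null(x$section_point)) NULL
                       else as.list(x$section_point),
       amplitude_I = x$amplitude_I,
       return_map_residual = x$return_map_residual,
       winding_number = x$winding_number,
       enclosed_equilibrium = as.list(x$enclosed_equilibrium),
       n_returns = x$n_returns, diagnostic = x$diagnostic)
}

#' Serialize an analysis report to JSON
#'
#' @param x a report object (`sirs_equilibria`, `sirs_stability`,
#'   `sirs_hopf` or `sirs_cycle`) or a plain list.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(x, path = NULL) {
  lst <- if (inherits(x, c("sirs_equilibria", "sirs_stability",
                           "sirs_hopf", "sirs_cycle"))) report_list(x) else x
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
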