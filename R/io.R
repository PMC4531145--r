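#' Write a simulation result to disk
#'
#' CSV output carries the full table at full double precision (17
#' significant digits, so a round trip through [read_timeseries()] is
#' numerically exact) plus a companion \code{<file>.meta.json} with units,
#' the protocol echo and solver diagnostics. JSON output stores the table
#' and metadata in a single file.
#'
#' @param result an \code{ikeda_result}.
#' @param destination output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return invisibly, the destination path.
#' @export
write_timeseries <- function(result, destination, format = c("csv", "json")) {
  stopifnot(inherits(result, "ikeda_result"))
  format <- match.arg(format)
  meta <- list(
    units = as.list(attr(result, "units")[names(result)]),
    protocol = protocol_echo(attr(result, "protocol")),
    diagnostics = attr(result, "diagnostics"))
  df <- as.data.frame(result)
  if (format == "csv") {
    txt <- vapply(df, function(col) formatC(col, digits = 17, format = "g"),
                  character(nrow(df)))
    if (nrow(df) == 1) txt <- t(txt)
    con <- file(destination, "w")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = ","), con)
    utils::write.table(txt, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    jsonlite::write_json(meta, paste0(destination, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(c(list(table = df), meta), destination,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(destination)
}

#' Read a time-series file written by [write_timeseries()]
#'
#' @param path CSV or JSON file path.
#' @return data.frame of the stored table (metadata, when present, in
#'   attribute \code{meta}).
#' @export
read_timeseries <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(as.data.frame(x$table),
              meta = x[setdiff(names(x), "table")])
  } else {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
    mp <- paste0(path, ".meta.json")
    if (file.exists(mp))
      attr(df, "meta") <- jsonlite::read_json(mp, simplifyVector = TRUE)
    df
  }
}

## serializable echo of a protocol
protocol_echo <- function(prot) {
  if (is.null(prot)) return(NULL)
  list(duration = prot$duration, sampling = prot$sampling,
       overrides = lapply(Filter(is_override, prot$events), function(e)
         list(target = e$target, value = e$value, window = e$window)),
       clamps = lapply(Filter(function(e) !is_override(e), prot$events),
                       function(e)
         list(target = e$target, value = e$value, window = e$window)))
}

#' Read a declarative protocol configuration
#'
#' Parses a YAML protocol file into a [protocol()] object. Schema:
#' \preformatted{
#' duration: 60        # min
#' sampling: 0.5       # min, optional
#' overrides:
#'   - {target: FCOI, value: 0.05, window: [5, 35]}
#' clamps:
#'   - {target: VI, value: 15}    # window defaults to the whole run
#' }
#' Unknown mnemonics, malformed windows and overlapping windows on one
#' target are rejected with an informative error.
#'
#' @param path YAML file path.
#' @param params parameter list (for input-name validation only).
#' @return an \code{ikeda_protocol}.
#' @export
read_protocol_config <- function(path, params = default_parameters()) {
  if (!file.exists(path)) stop("protocol config not found: ", path)
  cfg <- yaml::yaml.load_file(path)
  if (is.null(cfg)) cfg <- list()
  dur <- if (is.null(cfg$duration)) 180 else as.numeric(cfg$duration)
  one <- function(e, kind, i) {
    if (is.null(e$target) || is.null(e$value))
      stop("protocol config ", path, ": ", kind, " entry ", i,
           " needs 'target' and 'value'")
    w <- if (is.null(e$window)) c(0, Inf) else as.numeric(unlist(e$window))
    if (length(w) != 2 || anyNA(w))
      stop("protocol config ", path, ": malformed window in ", kind,
           " entry ", i)
    if (kind == "override") override(e$target, as.numeric(e$value), w)
    else clamp(e$target, as.numeric(e$value), w)
  }
  evs <- c(
    if (!is.null(cfg$overrides))
      mapply(one, cfg$overrides, "override", seq_along(cfg$overrides),
             SIMPLIFY = FALSE),
    if (!is.null(cfg$clamps))
      mapply(one, cfg$clamps, "clamp", seq_along(cfg$clamps),
             SIMPLIFY = FALSE))
  if (is.null(evs)) evs <- list()
  protocol(evs, duration = dur,
           sampling = if (is.null(cfg$sampling)) NULL
                      else as.numeric(cfg$sampling))
}

#' Write an algebraic snapshot as JSON
#'
#' @param snap named numeric vector from [snapshot()].
#' @param destination output path.
#' @param params parameter list (for units).
#' @return invisibly, the destination path.
#' @export
write_snapshot <- function(snap, destination,
                           params = default_parameters()) {
  u <- variable_units(params)
  jsonlite::write_json(
    list(values = as.list(snap),
         units = as.list(u[intersect(names(snap), names(u))])),
    destination, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(destination)
}
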