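# File formats: CSV traces/series/spectra and JSON protocols, manifests and
# fit reports. CSV dialect: comma-separated, header row, '.' decimal, UTF-8;
# times in seconds, concentrations in microM.

#' Write a trace to CSV
#'
#' Columns \code{time_s} and \code{signal}, plus one column per species
#' (microM) when trajectories are attached.
#'
#' @param trace A \code{kin_trace}.
#' @param path Output file.
#' @param species Include species trajectories when present.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, species = FALSE) {
  df <- data.frame(time_s = trace$times, signal = trace$signal)
  if (species && !is.null(trace$species))
    df <- cbind(df, as.data.frame(trace$species))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Expects at least two numeric columns; the first two are taken as time
#' (s) and signal (a.u.). Malformed input produces an error naming the file
#' and offending line.
#'
#' @param path CSV file.
#' @param noise_sigma Known noise s.d. to attach, if any.
#' @return A \code{kin_trace}.
#' @export
read_trace_csv <- function(path, noise_sigma = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("malformed trace CSV ", path, ": need >= 2 columns and >= 1 row")
  for (j in 1:2) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[j]]))))
    if (length(bad))
      stop("malformed trace CSV ", path, ": non-numeric value at line ",
           bad[1] + 1, ", column ", j)
  }
  kin_trace(as.numeric(df[[1]]), as.numeric(df[[2]]),
            noise_sigma = noise_sigma)
}

#' Write a protocol to JSON
#' @param protocol A \code{kin_protocol}.
#' @param path Output file; if NULL returns the JSON string.
#' @return \code{path} invisibly, or a JSON string.
#' @export
write_protocol_json <- function(protocol, path = NULL) {
  txt <- jsonlite::toJSON(unclass(protocol), auto_unbox = TRUE, digits = NA,
                          null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a protocol from JSON
#' @param path File path or JSON string.
#' @return A \code{kin_protocol}.
#' @export
read_protocol_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  if (is.null(o$kind)) stop("protocol JSON missing 'kind'")
  kin_protocol(o$kind, o$enzyme_total, o$ligand_total,
               dilution_factor = o$dilution_factor,
               incubation_time = o$incubation_time,
               dead_time = if (is.null(o$dead_time)) 1.5e-3 else o$dead_time,
               sample_times = o$sample_times)
}

#' Write an experiment set to a directory
#'
#' One CSV per trace plus a \code{manifest.json} recording the scheme id,
#' per-experiment protocol, group, noise sigma, and the provenance fields
#' (\code{seed}, \code{config}) so every artifact can be regenerated.
#'
#' @param dataset An \code{\link{experiment_set}}.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @param config Optional list recorded verbatim in the manifest.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir, seed = NA, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(dataset$experiments)) {
    e <- dataset$experiments[[i]]
    fn <- sprintf("trace_%02d.csv", i)
    write_trace_csv(e$trace, file.path(dir, fn))
    entries[[i]] <- list(file = fn, protocol = unclass(e$protocol),
                         group = .experiment_group(e),
                         noise_sigma = e$trace$noise_sigma)
  }
  manifest <- list(scheme = dataset$scheme_name, seed = seed,
                   config = config, experiments = entries)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read an experiment set from a directory
#' @param dir Directory written by \code{\link{write_dataset}}.
#' @return An \code{\link{experiment_set}}; the manifest is attached as
#'   attribute \code{"manifest"}.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  exps <- lapply(manifest$experiments, function(en) {
    p <- en$protocol
    protocol <- kin_protocol(p$kind, p$enzyme_total, unlist(p$ligand_total),
                             dilution_factor = p$dilution_factor,
                             incubation_time = p$incubation_time,
                             dead_time = p$dead_time,
                             sample_times = unlist(p$sample_times))
    tr <- read_trace_csv(file.path(dir, en$file),
                         noise_sigma = if (is.null(en$noise_sigma)) 0
                                       else en$noise_sigma)
    tr$protocol <- protocol
    list(protocol = protocol, trace = tr, group = en$group)
  })
  ds <- experiment_set(exps, manifest$scheme)
  attr(ds, "manifest") <- manifest
  ds
}

#' Write a fit report to JSON
#'
#' Serialises a \code{global_fit_result} (or any report list) together with
#' provenance (seed, config).
#'
#' @param fit Result object or list.
#' @param path Output file.
#' @param seed,config Provenance to embed.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(fit, path, seed = NA, config = NULL) {
  obj <- .listify(unclass(fit))
  obj$fitted <- NULL
  obj$deviance_trace <- NULL
  out <- list(seed = seed, config = config, report = obj)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), path)
  invisible(path)
}

# named atomic vectors lose their names in JSON arrays; store them as
# objects instead
.listify <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  if (is.list(x)) return(lapply(x, .listify))
  x
}
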