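## Result serialization: site traces and space-time fields as delimited
## text with unit-annotated headers, plus a JSON manifest with checksums.

#' Write a recording to a directory
#'
#' Site traces go to \code{traces.tsv} (one row per output stride), each
#' space-time field to \code{field_<name>.tsv} (time in rows, nodes in
#' columns), and \code{manifest.json} records the resolved configuration,
#' seed, package version and MD5 checksums of every file written. A
#' round-trip through \code{\link{read_recording}} returns identical
#' values.
#'
#' @param rec an \code{ictal_recording}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "ictal_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", header), con)
    utils::write.table(format(df, digits = 10, trim = TRUE, scientific = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tr_path <- file.path(dir, "traces.tsv")
  wr(rec$traces, tr_path,
     "site traces; time_s in s, K_o in mM, U/V in mV, nu in Hz, I_hold in uA/cm2")
  field_paths <- character(0)
  for (nm in names(rec$fields)) {
    fp <- file.path(dir, paste0("field_", nm, ".tsv"))
    df <- as.data.frame(rec$fields[[nm]])
    names(df) <- sprintf("x%03d", seq_along(df))
    df <- cbind(time_s = rec$field_time_s, df)
    wr(df, fp, sprintf(
      "space-time field %s; rows = time (s), columns = nodes at x_mm", nm))
    field_paths <- c(field_paths, fp)
  }
  files <- c(tr_path, field_paths)
  manifest <- list(
    scenario = rec$config$scenario,
    seed = rec$seed,
    package_version = as.character(utils::packageVersion("ictalwave")),
    config = config_as_list(rec$config),
    x_mm = rec$x_mm,
    s1 = rec$s1, s2 = rec$s2,
    diagnostics = rec$diagnostics,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$params <- unclass(out$params)
  out
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' @param dir directory containing \code{traces.tsv}, field files and
#'   \code{manifest.json}.
#' @param verify check MD5 checksums against the manifest.
#' @return An \code{ictal_recording}-like list (the config is restored as
#'   a plain list).
#' @export
read_recording <- function(dir, verify = TRUE) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (verify) {
    for (i in seq_len(nrow(man$files))) {
      fp <- file.path(dir, man$files$file[i])
      if (!file.exists(fp)) stop("missing file listed in manifest: ", fp)
      if (!identical(unname(tools::md5sum(fp)), man$files$md5[i]))
        stop("checksum mismatch for ", fp)
    }
  }
  rd <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  }
  traces <- rd(file.path(dir, "traces.tsv"))
  fieldfiles <- grep("^field_", man$files$file, value = TRUE)
  fields <- list()
  field_time <- NULL
  for (ff in fieldfiles) {
    nm <- sub("^field_(.*)\\.tsv$", "\\1", ff)
    df <- rd(file.path(dir, ff))
    field_time <- df$time_s
    fields[[nm]] <- as.matrix(df[, -1, drop = FALSE])
  }
  structure(list(traces = traces, fields = fields,
                 field_time_s = field_time,
                 x_mm = man$x_mm, s1 = man$s1, s2 = man$s2,
                 diagnostics = man$diagnostics, seed = man$seed,
                 config = man$config),
            class = "ictal_recording")
}
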