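# Delimited-text readers/writers. All numeric tables are plain
# tab-separated text with '#'-prefixed provenance headers so runs diff
# cleanly; values round-trip at 17 significant digits.

.provenance_header <- function(stage, seed = NA) {
  c(sprintf("# stage: %s", stage),
    sprintf("# package: mtscrunch %s",
            as.character(utils::packageVersion("mtscrunch"))),
    if (!is.na(seed)) sprintf("# seed: %s", format(seed)))
}

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  df_fmt <- df
  for (j in seq_along(df_fmt))
    if (is.numeric(df_fmt[[j]]) && !is.integer(df_fmt[[j]]))
      df_fmt[[j]] <- sprintf("%.17g", df_fmt[[j]])
  write.table(df_fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write and read smFRET trace sets as delimited text
#'
#' One tab-separated file per trace (columns `frame`, `I_D`, `I_A`,
#' `is_check_frame`) plus a `manifest.txt` key-value file recording the
#' master seed and simulation truth parameters when the set is synthetic.
#'
#' @param traces an `sm_trace_set` (or list of trace data.frames).
#' @param dir output directory (created if needed).
#' @return `write_trace_set()` returns the directory invisibly;
#'   `read_trace_set()` returns an `sm_trace_set`.
#' @export
write_trace_set <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- attr(traces, "manifest")
  for (i in seq_along(traces)) {
    tr <- as.data.frame(traces[[i]])[, c("frame", "I_D", "I_A",
                                         "is_check_frame")]
    .write_tsv(tr, file.path(dir, sprintf("trace_%04d.tsv", i)),
               .provenance_header("simulate",
                                  if (!is.null(m)) m$master_seed else NA))
  }
  lines <- c(sprintf("n_traces=%d", length(traces)))
  if (!is.null(m)) {
    lines <- c(lines,
               sprintf("n_frames=%d", m$n_frames),
               sprintf("master_seed=%s", format(m$master_seed)),
               sprintf("frame_interval=%.17g", m$phys$frame_interval),
               sprintf("leakage=%.17g", m$phys$leakage),
               sprintf("total_intensity=%.17g", m$phys$total_intensity),
               sprintf("fret_means=%s",
                       paste(sprintf("%.17g", m$model$fret_means),
                             collapse = ",")))
  }
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trace_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no trace files found in ", dir)
  traces <- lapply(files, function(f) {
    df <- tryCatch(
      read.table(f, header = TRUE, sep = "\t", comment.char = "#"),
      error = function(e) stop("malformed trace file ", f, ": ",
                               conditionMessage(e)))
    if (nrow(df) == 0L) stop("empty trace file: ", f)
    required <- c("frame", "I_D", "I_A")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols))
      stop("trace file ", f, " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    if (!"is_check_frame" %in% names(df)) df$is_check_frame <- FALSE
    df$is_check_frame <- as.logical(df$is_check_frame)
    class(df) <- c("sm_trace", "data.frame")
    df
  })
  manifest <- NULL
  mf <- file.path(dir, "manifest.txt")
  if (file.exists(mf)) {
    kv <- strsplit(readLines(mf), "=", fixed = TRUE)
    manifest <- setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                         vapply(kv, `[`, "", 1L))
  }
  structure(traces, class = "sm_trace_set", manifest = manifest)
}

#' Write and read titration datasets as delimited text
#'
#' Columns `x`, `y` (and `y_err` when present), with comment headers
#' naming the generating model, units and truth parameters when synthetic.
#'
#' @param data a `titration` data.frame.
#' @param path file path.
#' @export
write_titration <- function(data, path) {
  hdr <- .provenance_header("titration")
  kind <- attr(data, "kind")
  if (!is.null(kind)) hdr <- c(hdr, sprintf("# model: %s", kind))
  for (u in c("x_unit", "y_unit")) {
    v <- attr(data, u)
    if (!is.null(v) && !is.na(v)) hdr <- c(hdr, sprintf("# %s: %s", u, v))
  }
  truth <- attr(data, "truth")
  if (!is.null(truth))
    hdr <- c(hdr, sprintf("# truth: %s",
                          paste(sprintf("%s=%.17g", names(truth),
                                        as.numeric(truth)),
                                collapse = " ")))
  .write_tsv(as.data.frame(data), path, hdr)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20L), value = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("x", "y") %in% names(df)))
    stop("titration file ", path, " must have columns x and y")
  get_tag <- function(tag) {
    ln <- grep(sprintf("^# %s: ", tag), hdr, value = TRUE)
    if (length(ln)) sub(sprintf("^# %s: ", tag), "", ln[1]) else NA_character_
  }
  structure(df, class = c("titration", "data.frame"),
            kind = get_tag("model"),
            x_unit = get_tag("x_unit"), y_unit = get_tag("y_unit"))
}

#' Write a mixture fit as a delimited component table
#'
#' @param fit a `mixture_fit`.
#' @param path file path.
#' @export
write_mixture_fit <- function(fit, path) {
  df <- data.frame(component = seq_along(fit$means), mean = fit$means,
                   sigma = fit$sds, weight = fit$weights,
                   fixed = fit$fixed_mask)
  .write_tsv(df, path, .provenance_header("histfit"))
  invisible(path)
}
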