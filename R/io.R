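# TSV files carry a schema comment as the first line, e.g.
# "# wmpersist trial_table v1; times_s". Numeric columns are written with
# %.17g so a write/read cycle is bit-lossless.

format_numeric_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

write_tsv_schema <- function(df, path, schema, extra = character()) {
  header <- paste0("# wmpersist ", schema,
                   if (length(extra)) paste0("; ", paste(extra, collapse = "; "))
                   else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format_numeric_cols(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv_schema <- function(path, schema, required, numeric_cols) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, paste0("# wmpersist ", schema))) {
    stop("'", path, "' does not carry schema '", schema, "' (header: ",
         first, ")")
  }
  fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                quote = "")
  fields <- fields[!is.na(fields)]
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1]) + 1L   # +1 for the schema header line
    stop("malformed TSV '", path, "': inconsistent field count on line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "' is missing column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("'", path, "' has unknown column(s) ", paste(extra, collapse = ", "),
            "; preserved as-is")
  }
  for (col in intersect(numeric_cols, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

trial_cols <- c("trial_id", "task_id", "sequence", "load", "required_response",
                "t_s1_on", "t_s1_off", "t_s2_on", "t_s2_off", "t_end",
                "outcome", "context")

#' Write / read a trial table
#'
#' Tab-delimited UTF-8 with a schema comment header; times in seconds at full
#' float precision.
#'
#' @param trials Trial table from [generate_block()].
#' @param path File path.
#' @return `read_trials` returns the trial table; `write_trials` its path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  write_tsv_schema(trials[, trial_cols], path, "trial_table v1", "times_s")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  num <- c("trial_id", "task_id", "t_s1_on", "t_s1_off", "t_s2_on",
           "t_s2_off", "t_end")
  read_tsv_schema(path, "trial_table v1", trial_cols, num)
}

#' Write / read a spike-event table
#'
#' Columns `unit_id`, `trial_id`, `time` (seconds, full float precision).
#'
#' @param spikes Spike table (possibly several units concatenated).
#' @param path File path.
#' @export
write_spikes <- function(spikes, path) {
  write_tsv_schema(spikes[, c("unit_id", "trial_id", "time")], path,
                   "spike_events v1", "times_s")
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  read_tsv_schema(path, "spike_events v1", c("unit_id", "trial_id", "time"),
                  c("trial_id", "time"))
}

#' Write / read an LFP trace set
#'
#' Wide TSV: one row per trial (`trial_id` then one column per sample), with
#' `site_id`, `sampling_rate` and `t0` in the schema header — the columnar
#' text container for sampled traces.
#'
#' @param lfp An `lfp_set`.
#' @param path File path.
#' @export
write_lfp <- function(lfp, path) {
  df <- data.frame(trial_id = lfp$trial_id)
  df <- cbind(df, as.data.frame(lfp$samples))
  names(df) <- c("trial_id", paste0("s", seq_len(ncol(lfp$samples))))
  write_tsv_schema(df, path, "lfp_set v1",
                   c(paste0("site_id=", lfp$site_id),
                     paste0("sampling_rate=", sprintf("%.17g", lfp$sampling_rate)),
                     paste0("t0=", sprintf("%.17g", lfp$t0))))
  invisible(path)
}

parse_header_fields <- function(path) {
  first <- readLines(path, n = 1L)
  parts <- strsplit(sub("^# wmpersist [^;]*;? ?", "", first), "; ")[[1]]
  kv <- strsplit(parts[grepl("=", parts)], "=")
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  fields <- parse_header_fields(path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sr <- as.numeric(fields$sampling_rate)
  t0 <- as.numeric(fields$t0)
  samples <- as.matrix(df[, -1, drop = FALSE])
  dimnames(samples) <- NULL
  structure(
    list(site_id = fields$site_id, trial_id = df$trial_id,
         t = t0 + (seq_len(ncol(samples)) - 1) / sr,
         sampling_rate = sr, t0 = t0, samples = samples),
    class = "lfp_set"
  )
}

#' Write / read source waveforms
#'
#' Wide TSV: one row per subject-condition waveform with `subject_id` and
#' `condition` columns, sample columns, and `sampling_rate`/`t0` in the
#' header.
#'
#' @param waveforms List of `source_waveform`s sharing one time base.
#' @param path File path.
#' @export
write_waveforms <- function(waveforms, path) {
  stopifnot(length(waveforms) > 0)
  mat <- t(vapply(waveforms, function(w) w$samples,
                  numeric(length(waveforms[[1]]$samples))))
  df <- data.frame(
    subject_id = vapply(waveforms, function(w) w$subject_id, ""),
    condition = vapply(waveforms, function(w) w$condition, "")
  )
  df <- cbind(df, as.data.frame(mat))
  names(df) <- c("subject_id", "condition", paste0("s", seq_len(ncol(mat))))
  w1 <- waveforms[[1]]
  write_tsv_schema(df, path, "source_waveforms v1",
                   c(paste0("sampling_rate=", sprintf("%.17g", w1$sampling_rate)),
                     paste0("t0=", sprintf("%.17g", w1$t0))))
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  fields <- parse_header_fields(path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sr <- as.numeric(fields$sampling_rate)
  t0 <- as.numeric(fields$t0)
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(subject_id = df$subject_id[i], condition = df$condition[i],
           samples = as.numeric(df[i, -(1:2)]), sampling_rate = sr, t0 = t0),
      class = "source_waveform"
    )
  })
}

#' Write / read an analysis results table
#'
#' Free-form results `data.frame` (one row per unit/site and test) under the
#' `results v1` schema; every row should carry the alpha, permutation count
#' and seed that produced it.
#'
#' @param results A `data.frame`.
#' @param path File path.
#' @export
write_results <- function(results, path) {
  write_tsv_schema(results, path, "results v1")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# wmpersist results v1")) {
    stop("'", path, "' is not a results table")
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a run configuration (JSON)
#'
#' @param config Named list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
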