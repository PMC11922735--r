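# File formats and input validation -------------------------------------------

#' Read a beat-annotation track file
#'
#' Accepts JSONL (one JSON object per line) or CSV, with fields
#' `recording_id`, `annotator`, `sample`, `beat_class`.
#'
#' @param path File path; format inferred from the extension (`.jsonl` /
#'   `.json` stream vs `.csv`) unless given.
#' @param format "jsonl", "csv" or "auto".
#' @return Data.frame of beat records.
#' @export
read_beat_track <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  }
}

#' Write a beat-annotation track file
#'
#' @param track Data.frame of beat records.
#' @param path Output path.
#' @param format "jsonl" or "csv".
#' @return `path`, invisibly.
#' @export
write_beat_track <- function(track, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(track, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(track))) {
      writeLines(jsonlite::toJSON(as.list(track[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Write an episode, strip, verdict or metric table as CSV
#'
#' @param x Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Validate beat-track input
#'
#' Schema check of a beat-record table: known beat classes, non-negative
#' samples, and strictly increasing sample order within each
#' (recording, annotator) track. Problems are reported row by row; the
#' function never raises on invalid content.
#'
#' @param track Data.frame of beat records (or a file path).
#' @return Data.frame report with columns `row`, `field`, `problem`;
#'   zero rows when the input is well formed.
#' @export
validate_inputs <- function(track) {
  if (is.character(track)) track <- read_beat_track(track)
  report <- list()
  note <- function(row, field, problem) {
    report[[length(report) + 1L]] <<- data.frame(row = row, field = field,
                                                 problem = problem)
  }
  needed <- c("sample", "beat_class")
  missing_cols <- setdiff(needed, names(track))
  for (mc in missing_cols) note(NA_integer_, mc, "missing column")
  if (length(missing_cols) == 0) {
    bad_class <- which(!(track$beat_class %in% .beat_classes))
    for (i in bad_class) {
      note(i, "beat_class", paste0("unknown token '", track$beat_class[i], "'"))
    }
    neg <- which(track$sample < 0)
    for (i in neg) note(i, "sample", "negative sample index")
    key <- if (all(c("recording_id", "annotator") %in% names(track))) {
      paste(track$recording_id, track$annotator)
    } else {
      rep("", nrow(track))
    }
    for (k in unique(key)) {
      idx <- which(key == k)
      d <- diff(track$sample[idx])
      for (j in which(d <= 0)) {
        note(idx[j + 1L], "sample", "not strictly increasing within track")
      }
    }
  }
  if (length(report) == 0) {
    return(data.frame(row = integer(0), field = character(0),
                      problem = character(0)))
  }
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the evaluation pipeline. The
#' defaults reproduce the prespecified analysis constants: 30 s AF/SVT and
#' 10 s / 120 bpm VT thresholds, the 2.0-3.5 s pause band, 34-s strips,
#' quotas of 500 critical / 250 noncritical strips, 0.80/0.90 overlap
#' fractions with the +/-45-sample ectopic tolerance, and 1,000 bootstrap
#' replications.
#'
#' @param taxonomy A [rhythm_taxonomy()].
#' @param rules An [overlap_rules()].
#' @param quota_critical,quota_noncritical Strip quotas per class.
#' @param n_boot Bootstrap replications.
#' @param variant Verdict variant, see [apply_variant()].
#' @param cohort_size Full cohort size for prevalence weighting (`NULL`
#'   uses the analysed cohort itself).
#' @param seed Integer seed driving sampling and bootstrap.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(taxonomy = rhythm_taxonomy(),
                            rules = overlap_rules(),
                            quota_critical = 500, quota_noncritical = 250,
                            n_boot = 1000, variant = "primary",
                            cohort_size = NULL, seed = 1) {
  structure(list(taxonomy = taxonomy, rules = rules,
                 quota_critical = quota_critical,
                 quota_noncritical = quota_noncritical,
                 n_boot = n_boot, variant = variant,
                 cohort_size = cohort_size, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration override file (YAML or JSON)
#'
#' Scalar fields override [pipeline_config()] defaults; taxonomy and rule
#' fields override the corresponding constructor arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  tax <- do.call(rhythm_taxonomy, raw$taxonomy %||% list())
  rules <- do.call(overlap_rules, raw$rules %||% list())
  args <- raw[setdiff(names(raw), c("taxonomy", "rules"))]
  do.call(pipeline_config, c(list(taxonomy = tax, rules = rules), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
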