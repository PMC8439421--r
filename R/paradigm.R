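#' Condition labels of the contrast-adaptation design
#'
#' The design crosses two BOLD response types (contrast increment to 100%,
#' contrast decrement to 6.25%, both from a 25% adapted baseline) with three
#' test-stimulus durations (1, 3, 6 s), giving six conditions.
#'
#' @return A data frame with columns `response_type` and `test_duration_s`
#'   (6 rows).
#' @export
condition_labels <- function() {
  expand.grid(
    response_type = c("increment", "decrement"),
    test_duration_s = c(1, 3, 6),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
}

new_paradigm <- function(events, run_length_s, tr_s, kind) {
  structure(
    list(events = events, run_length_s = run_length_s, tr_s = tr_s,
         kind = kind),
    class = "paradigm"
  )
}

#' Generate a localizer or contrast-adaptation paradigm
#'
#' The localizer run alternates 30-s rest and 30-s full-contrast stimulus
#' blocks four times (240 s). The adaptation run starts with a 30-s blank
#' baseline and a 60-s adaptation phase (25% contrast), then presents 24
#' test trials in seeded random order: each trial is a test stimulus
#' (1, 3 or 6 s, increment or decrement; 4 repetitions of each of the 6
#' conditions) followed by 30 s of adaptation stimulus, for a total run
#' length of 890 s.
#'
#' @param kind `"localizer"` or `"adaptation"`.
#' @param seed Integer seed for the trial-order shuffle (ignored for the
#'   localizer, whose timing is fixed).
#' @param tr_s Repetition time in seconds (default 1).
#' @return A `paradigm` object: list with `events` (data frame of `onset_s`,
#'   `duration_s`, `response_type`, `test_duration_s`), `run_length_s`,
#'   `tr_s`, `kind`.
#' @export
generate_paradigm <- function(kind = c("adaptation", "localizer"), seed = 0L,
                              tr_s = 1) {
  kind <- match.arg(kind)
  stopifnot_scalar(tr_s, "tr_s", positive = TRUE)
  if (kind == "localizer") {
    onsets <- c(30, 90, 150, 210)
    events <- data.frame(
      onset_s = onsets,
      duration_s = 30,
      response_type = "increment",
      test_duration_s = 30,
      stringsAsFactors = FALSE
    )
    return(new_paradigm(events, run_length_s = 240, tr_s = tr_s,
                        kind = "localizer"))
  }
  conds <- condition_labels()
  trials <- conds[rep(seq_len(nrow(conds)), each = 4L), ]
  order_idx <- with_seed(seed, sample.int(nrow(trials)))
  trials <- trials[order_idx, , drop = FALSE]
  onset <- 30 + 60  # 30-s blank baseline + 60-s adaptation phase
  onsets <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    onsets[i] <- onset
    onset <- onset + trials$test_duration_s[i] + 30
  }
  events <- data.frame(
    onset_s = onsets,
    duration_s = trials$test_duration_s,
    response_type = trials$response_type,
    test_duration_s = trials$test_duration_s,
    stringsAsFactors = FALSE
  )
  rownames(events) <- NULL
  new_paradigm(events, run_length_s = onset, tr_s = tr_s, kind = "adaptation")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("<paradigm> kind=%s, %d events, run_length=%g s, TR=%g s\n",
              x$kind, nrow(x$events), x$run_length_s, x$tr_s))
  invisible(x)
}

validate_paradigm <- function(paradigm) {
  ev <- paradigm$events
  if (any(ev$onset_s < 0) || any(ev$onset_s %% paradigm$tr_s != 0)) {
    stop("event onsets must be non-negative multiples of tr_s")
  }
  if (is.unsorted(ev$onset_s, strictly = TRUE)) {
    stop("event onsets must be strictly increasing")
  }
  ends <- ev$onset_s + ev$duration_s
  if (any(ends > paradigm$run_length_s)) {
    stop("an event extends past the run end")
  }
  if (any(ev$onset_s[-1] < ends[-length(ends)])) stop("events overlap")
  invisible(paradigm)
}

#' Write / read a paradigm as CSV or JSON
#'
#' The CSV has columns `onset_s,duration_s,response_type,test_duration_s`;
#' run length, TR and kind travel in a JSON sidecar (or in the JSON file
#' itself for [write_paradigm_json()]).
#'
#' @param paradigm A `paradigm` object.
#' @param path Output file path.
#' @return `path`, invisibly (writers); a `paradigm` (readers).
#' @export
write_paradigm_csv <- function(paradigm, path) {
  utils::write.csv(paradigm$events, path, row.names = FALSE)
  meta <- list(run_length_s = paradigm$run_length_s, tr_s = paradigm$tr_s,
               kind = paradigm$kind)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_paradigm_csv
#' @export
read_paradigm_csv <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_paradigm(events, meta$run_length_s, meta$tr_s, meta$kind)
}

#' @rdname write_paradigm_csv
#' @export
write_paradigm_json <- function(paradigm, path) {
  jsonlite::write_json(unclass(paradigm), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_paradigm_csv
#' @export
read_paradigm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_paradigm(as.data.frame(x$events), x$run_length_s, x$tr_s, x$kind)
}
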