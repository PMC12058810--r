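#' Construct a trial set
#'
#' The package's central container: a validated fixation table plus the
#' stimulus table, interest-area table and display geometry it refers to.
#'
#' @param fixations `data.table` with columns `subject_id`, `trial_id`,
#'   `item_id`, `condition`, `fix_index`, `x_px`, `y_px`, `duration_ms`,
#'   `ia_index` (integer, `NA` = outside all interest areas).
#' @param items stimulus table (at least `item_id`, `condition`; usually
#'   also `target_ia_index` as produced by [generate_stimuli()]).
#' @param geometry list with `pixels_per_degree` (required) and optionally
#'   `char_width_px`.
#' @param ia optional interest-area table (see [build_ia_table()]).
#' @param validate check invariants (positive durations, contiguous
#'   1-based `fix_index` per trial, known items).
#' @return an object of class `trialset`.
#' @export
trialset <- function(fixations, items, geometry, ia = NULL, validate = TRUE) {
  fixations <- as.data.table(fixations)
  items <- as.data.table(items)
  if (validate) {
    req <- c("subject_id", "trial_id", "item_id", "condition", "fix_index",
             "x_px", "y_px", "duration_ms", "ia_index")
    miss <- setdiff(req, names(fixations))
    if (length(miss)) stop("fixation table is missing column(s): ",
                           paste(miss, collapse = ", "))
    if (nrow(fixations)) {
      if (any(fixations$duration_ms <= 0)) stop("durations must be positive")
      bad <- fixations[, .(ok = identical(fix_index, seq_len(.N))), by = trial_id][ok == FALSE]
      if (nrow(bad)) stop("fix_index not contiguous from 1 in trial(s): ",
                          paste(head(bad$trial_id, 5), collapse = ", "))
      if (!all(fixations$item_id %in% items$item_id))
        stop("fixation table refers to items absent from the item table")
    }
    if (is.null(geometry$pixels_per_degree) || geometry$pixels_per_degree <= 0)
      stop("geometry$pixels_per_degree must be a positive number")
  }
  structure(list(fixations = fixations, items = items,
                 geometry = geometry, ia = ia),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  cat(sprintf("<trialset> %d fixations, %d trials, %d subjects, %d items\n",
              nrow(x$fixations), uniqueN(x$fixations$trial_id),
              uniqueN(x$fixations$subject_id), nrow(x$items)))
  invisible(x)
}

## canonical column order of the fixation report dialect
.fix_cols <- c("subject_id", "trial_id", "item_id", "condition", "fix_index",
               "x_px", "y_px", "duration_ms", "ia_index")

## EyeLink Data Viewer fixation-report aliases accepted in permissive mode
.dv_aliases <- c(
  RECORDING_SESSION_LABEL = "subject_id",
  TRIAL_INDEX = "trial_id",
  CURRENT_FIX_INDEX = "fix_index",
  CURRENT_FIX_X = "x_px",
  CURRENT_FIX_Y = "y_px",
  CURRENT_FIX_DURATION = "duration_ms",
  CURRENT_FIX_INTEREST_AREA_INDEX = "ia_index",
  item = "item_id")

#' Fixation-report dialect
#'
#' @param sep field separator (the canonical dialect is tab-delimited
#'   UTF-8 with `.` decimals).
#' @param aliases accept EyeLink Data Viewer column names (e.g.
#'   `CURRENT_FIX_DURATION`) and map them onto the canonical schema.
#' @param renumber renumber `fix_index` within each trial on read instead
#'   of requiring contiguity.
#' @return a list of class `fixation_dialect`.
#' @export
fixation_dialect <- function(sep = "\t", aliases = TRUE, renumber = FALSE) {
  structure(list(sep = sep, aliases = aliases, renumber = renumber),
            class = "fixation_dialect")
}

#' Read a fixation report
#'
#' Loads a delimited fixation report into a validated [trialset()].
#' Schema errors are total: a missing column, a non-numeric duration, or a
#' duplicate `(subject, trial, fix_index)` aborts the load with an
#' informative error; no partial data is returned.
#'
#' @param path file path.
#' @param dialect a [fixation_dialect()].
#' @param items optional item table (see [read_item_table()]); when absent
#'   a minimal one (`item_id`, `condition`) is reconstructed from the rows.
#' @param geometry display geometry; defaults to the generator's
#'   (40 px/degree).
#' @return a [trialset()].
#' @export
read_fixation_report <- function(path, dialect = fixation_dialect(),
                                 items = NULL,
                                 geometry = list(pixels_per_degree = 40)) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = dialect$sep, colClasses = "character",
              na.strings = NULL, header = TRUE)
  if (dialect$aliases) {
    hit <- names(dt) %in% names(.dv_aliases)
    setnames(dt, names(dt)[hit], unname(.dv_aliases[names(dt)[hit]]))
  }
  miss <- setdiff(.fix_cols, names(dt))
  if (length(miss))
    stop("fixation report is missing required column(s): ",
         paste(miss, collapse = ", "))
  dt <- dt[, .SD, .SDcols = .fix_cols]

  num <- function(col, integer = FALSE, allow_empty = FALSE) {
    v <- dt[[col]]
    empty <- !nzchar(v)
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x) & !empty)
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d: '%s'",
                   col, bad[1], v[bad[1]]))
    if (!allow_empty && any(empty))
      stop(sprintf("empty value in column '%s' at data line %d", col,
                   which(empty)[1]))
    if (integer) as.integer(x) else x
  }
  out <- data.table(
    subject_id = utils::type.convert(dt$subject_id, as.is = TRUE),
    trial_id = utils::type.convert(dt$trial_id, as.is = TRUE),
    item_id = utils::type.convert(dt$item_id, as.is = TRUE),
    condition = dt$condition,
    fix_index = num("fix_index", integer = TRUE),
    x_px = num("x_px"), y_px = num("y_px"),
    duration_ms = num("duration_ms"),
    ia_index = num("ia_index", integer = TRUE, allow_empty = TRUE))
  if (anyDuplicated(out[, .(subject_id, trial_id, fix_index)]))
    stop("duplicate (subject, trial, fix_index) rows in fixation report")
  if (dialect$renumber) out[, fix_index := seq_len(.N), by = trial_id]
  if (is.null(items))
    items <- unique(out[, .(item_id, condition)])[order(item_id)]
  trialset(out, items, geometry)
}

#' Write a fixation report
#'
#' Serializes a trial set's fixation table with deterministic row order
#' (subject, trial, fix_index), fixed column order, and fixed numeric
#' precision, so equal trial sets produce byte-identical files.  Missing
#' `ia_index` is written as an empty field, never 0.
#'
#' @param ts a [trialset()].
#' @param path output path.
#' @param dialect a [fixation_dialect()] (separator only).
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(ts, path, dialect = fixation_dialect()) {
  fx <- as.data.table(ts$fixations)
  s <- dialect$sep
  header <- paste(.fix_cols, collapse = s)
  if (!nrow(fx)) { writeLines(header, path); return(invisible(path)) }
  fx <- fx[order(subject_id, trial_id, fix_index)]
  lines <- paste(
    as.character(fx$subject_id), as.character(fx$trial_id),
    as.character(fx$item_id), fx$condition, fx$fix_index,
    sprintf("%.2f", fx$x_px), sprintf("%.2f", fx$y_px),
    sprintf("%.3f", fx$duration_ms),
    ifelse(is.na(fx$ia_index), "", as.character(fx$ia_index)),
    sep = s)
  con <- file(path, open = "wb")  # fixed LF endings for byte determinism
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Read / write an interest-area table
#'
#' Tab-delimited: `item_id`, `ia_index`, `x_min_px`, `x_max_px`,
#' `y_min_px`, `y_max_px`; bounds half-open `[min, max)`.
#'
#' @param path file path.
#' @return `read_ia_table`: a `data.table`.
#' @export
read_ia_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  req <- c("item_id", "ia_index", "x_min_px", "x_max_px", "y_min_px", "y_max_px")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("interest-area table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(dt$x_min_px >= dt$x_max_px)) stop("degenerate interest area: x_min >= x_max")
  dt
}

#' @rdname read_ia_table
#' @param ia interest-area table.
#' @export
write_ia_table <- function(ia, path) {
  ia <- as.data.table(ia)[order(item_id, ia_index)]
  lines <- paste(ia$item_id, ia$ia_index,
                 sprintf("%.2f", ia$x_min_px), sprintf("%.2f", ia$x_max_px),
                 sprintf("%.2f", ia$y_min_px), sprintf("%.2f", ia$y_max_px),
                 sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("item_id", "ia_index", "x_min_px", "x_max_px",
                       "y_min_px", "y_max_px"), collapse = "\t"), lines),
             con, sep = "\n")
  invisible(path)
}

#' Read / write an item (stimulus) table
#'
#' Tab-delimited: `item_id`, `condition`, `target_ia_index`, and optional
#' calibration columns (`target_len`, `zipf_target`, `n_words`).
#'
#' @param path file path.
#' @return `read_item_table`: a `data.table`.
#' @export
read_item_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  req <- c("item_id", "condition", "target_ia_index")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("item table is missing column(s): ",
                         paste(miss, collapse = ", "))
  dt
}

#' @rdname read_item_table
#' @param items item table.
#' @export
write_item_table <- function(items, path) {
  items <- as.data.table(items)
  cols <- intersect(c("item_id", "condition", "target_ia_index",
                      "target_len", "zipf_target", "n_words"), names(items))
  out <- items[order(item_id), .SD, .SDcols = cols]
  fmt <- function(v) if (is.double(v)) sprintf("%.6f", v) else as.character(v)
  body <- do.call(paste, c(lapply(out, fmt), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

#' Assign fixations to interest areas
#'
#' Sets each fixation's `ia_index` to the unique half-open box of its item
#' containing `(x, y)`, or missing when no box contains it.  A fixation on
#' the shared boundary of two adjacent words belongs to the right-hand one
#' (half-open `[min, max)` convention).  Idempotent.
#'
#' @param ts a [trialset()].
#' @param ia_table interest-area table; defaults to the one stored in `ts`.
#' @return the trial set with `ia_index` (re)assigned.
#' @export
assign_interest_areas <- function(ts, ia_table = ts$ia) {
  if (is.null(ia_table)) stop("no interest-area table available")
  ia <- as.data.table(ia_table)
  ## overlapping boxes within an item are an integrity error
  chk <- ia[order(item_id, x_min_px)]
  ov <- chk[, .(bad = .N > 1 &&
                  any(x_min_px[-1] < x_max_px[-.N] &
                        y_min_px[-1] < y_max_px[-.N] &
                        y_max_px[-1] > y_min_px[-.N])), by = item_id][bad == TRUE]
  if (nrow(ov)) stop("overlapping interest areas in item(s): ",
                     paste(ov$item_id, collapse = ", "))
  miss_items <- setdiff(unique(ts$fixations$item_id), unique(ia$item_id))
  if (length(miss_items)) stop("no interest areas defined for item(s): ",
                               paste(head(miss_items, 5), collapse = ", "))
  fx <- copy(ts$fixations)
  fx[, ia_index := {
    boxes <- ia[item_id == .BY[[1]]]
    idx <- rep(NA_integer_, .N)
    for (b in seq_len(nrow(boxes))) {
      hit <- x_px >= boxes$x_min_px[b] & x_px < boxes$x_max_px[b] &
        y_px >= boxes$y_min_px[b] & y_px < boxes$y_max_px[b]
      idx[hit] <- boxes$ia_index[b]
    }
    idx
  }, by = item_id]
  trialset(fx, ts$items, ts$geometry, ia = ia, validate = FALSE)
}
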