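CHOICE_COLUMNS <- c("bird_id", "trial_order", "color", "frequency",
                    "light_side", "choice_avoid", "latency_s", "head_events",
                    "body_events", "visible_s", "lux_on", "lux_off")

#' Validate a choice-trial table
#'
#' Checks the schema of a repeated-measures single-choice dataset: one row
#' per completed trial with bird identity, trial order (1-8), the two
#' treatment factors (colour, pulsing frequency), the lit side, the binary
#' avoidance outcome (1 = moved away from the lit side), latency, movement
#' counts with the visible duration they are rated over, and paired ambient
#' light readings. Mistrials (no choice within 10 min) are absent rows, so
#' latencies must not exceed 600 s.
#'
#' @param df A data.frame of trials.
#' @return `df`, invisibly, with factors coerced (`trial_order` is treated
#'   as categorical).
#' @export
validate_choice_data <- function(df) {
  missing_cols <- setdiff(CHOICE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("choice data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$choice_avoid %in% c(0, 1))) {
    stop("choice_avoid must be 0 (toward light) or 1 (away)", call. = FALSE)
  }
  if (any(df$latency_s < 0 | df$latency_s > 600)) {
    stop("latency_s must lie in [0, 600] seconds (10 min trial cap)",
         call. = FALSE)
  }
  if (any(df$visible_s <= 0)) {
    stop("visible_s must be positive", call. = FALSE)
  }
  if (any(df$head_events < 0 | df$body_events < 0)) {
    stop("movement counts must be non-negative", call. = FALSE)
  }
  if (any(df$lux_on < 0 | df$lux_off < 0)) {
    stop("lux readings must be non-negative", call. = FALSE)
  }
  if (!all(df$color %in% c("blue", "red"))) {
    stop("color must be 'blue' or 'red'", call. = FALSE)
  }
  if (!all(df$frequency %in% c("steady", "pulsing"))) {
    stop("frequency must be 'steady' or 'pulsing'", call. = FALSE)
  }
  if (!all(df$light_side %in% c("left", "right"))) {
    stop("light_side must be 'left' or 'right'", call. = FALSE)
  }
  tab <- table(df$bird_id)
  if (any(tab > 8)) {
    stop("no bird may have more than 8 trials", call. = FALSE)
  }
  df$bird_id <- factor(df$bird_id)
  df$trial_order <- factor(df$trial_order, levels = sort(unique(as.integer(df$trial_order))))
  df$color <- factor(df$color, levels = c("blue", "red"))
  df$frequency <- factor(df$frequency, levels = c("steady", "pulsing"))
  df$light_side <- factor(df$light_side, levels = c("left", "right"))
  invisible(df)
}

#' Read a choice-trial CSV
#'
#' @param path CSV file in the schema documented in
#'   [validate_choice_data()].
#' @return A validated data.frame of trials.
#' @export
read_choice_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_choice_data(df)
}

#' Movement rate
#'
#' Frequency of distinct head or body orientation changes per second of time
#' the animal was visible to the scoring camera.
#'
#' @param event_count Non-negative integer count of distinct movements.
#' @param visible_duration_s Seconds the animal was visible (> 0).
#' @return Events per second.
#' @export
movement_rate <- function(event_count, visible_duration_s) {
  if (any(visible_duration_s <= 0)) {
    stop("visible duration must be positive", call. = FALSE)
  }
  if (any(event_count < 0)) {
    stop("event counts must be non-negative", call. = FALSE)
  }
  event_count / visible_duration_s
}

#' Add movement-rate columns to a choice dataset
#'
#' @param df A validated choice dataset.
#' @return `df` with `head_rate` and `body_rate` columns (events/s).
#' @export
add_movement_rates <- function(df) {
  df$head_rate <- movement_rate(df$head_events, df$visible_s)
  df$body_rate <- movement_rate(df$body_events, df$visible_s)
  df
}
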