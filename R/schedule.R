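#' Japanese COVID-19 emergency-declaration schedule
#'
#' Loads the packaged schedule of prefecture-level states of emergency
#' declared between April 2020 and August 2021: one row per episode with
#' its start (declaration) date, end (lift) date and per-prefecture episode
#' number `times`. All 47 prefectures appear with a first episode; episodes
#' still in force at the end of the analysis window (31 August 2021) carry
#' their later printed end date and are flagged `truncated`.
#'
#' @param window_end Analysis window end used for the `truncated` flag.
#' @return A tibble of class `"emergency_schedule"` with columns
#'   `prefecture_en`, `emergency_start`, `emergency_end` (`Date`), `times`
#'   (integer) and `truncated` (logical), ordered by prefecture and episode.
#' @examples
#' sched <- emergency_schedule()
#' dplyr::filter(sched, prefecture_en == "Tokyo")
#' @export
emergency_schedule <- function(window_end = as.Date("2021-08-31")) {
  path <- system.file("extdata", "emergency_statement_japan.csv",
                      package = "jishuku", mustWork = TRUE)
  read_emergency_csv(path, window_end = window_end)
}

#' Read an emergency-declaration schedule CSV
#'
#' Parses a CSV in the public schedule layout (columns `prefecture_en`,
#' `emergency_start`, `emergency_end`, optional `times`). Episode numbers
#' are taken from `times` when present and otherwise inferred from the
#' per-prefecture chronological order of the episodes. The result is
#' validated: dates parse, `start <= end`, episodes within a prefecture do
#' not overlap, and numbers run consecutively from 1.
#'
#' @param path Path to the CSV file.
#' @param window_end Analysis window end used for the `truncated` flag.
#' @return An `"emergency_schedule"` tibble, see [emergency_schedule()].
#' @export
read_emergency_csv <- function(path, window_end = as.Date("2021-08-31")) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("prefecture_en", "emergency_start", "emergency_end")
  if (!all(needed %in% names(raw))) {
    stop("schedule CSV must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    prefecture_en = raw$prefecture_en,
    emergency_start = as.Date(raw$emergency_start),
    emergency_end = as.Date(raw$emergency_end)
  )
  if (anyNA(out$emergency_start) || anyNA(out$emergency_end)) {
    stop("unparseable dates in schedule CSV", call. = FALSE)
  }
  if (any(out$emergency_end < out$emergency_start)) {
    stop("schedule has an episode ending before it starts", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$prefecture_en, .data$emergency_start)
  out <- dplyr::mutate(out, times = dplyr::row_number(),
                       .by = "prefecture_en")
  if ("times" %in% names(raw)) {
    given <- as.integer(raw$times)[order(raw$prefecture_en,
                                         as.Date(raw$emergency_start))]
    if (!identical(given, out$times)) {
      stop("`times` column disagrees with per-prefecture chronological order",
           call. = FALSE)
    }
  }
  overlap <- dplyr::summarise(
    out,
    bad = any(.data$emergency_start[-1] <= .data$emergency_end[-dplyr::n()]),
    .by = "prefecture_en")
  if (any(overlap$bad)) {
    stop("overlapping episodes within a prefecture: ",
         paste(overlap$prefecture_en[overlap$bad], collapse = ", "),
         call. = FALSE)
  }
  out$truncated <- out$emergency_end > window_end
  class(out) <- c("emergency_schedule", class(out))
  out
}

#' Write an emergency schedule in the public CSV layout
#'
#' Inverse of [read_emergency_csv()]: drops the derived `truncated` column
#' and writes `prefecture_en`, `emergency_start`, `emergency_end`, `times`.
#'
#' @param schedule An `"emergency_schedule"` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emergency_csv <- function(schedule, path) {
  readr::write_csv(
    dplyr::select(tibble::as_tibble(schedule), "prefecture_en",
                  "emergency_start", "emergency_end", "times"),
    path)
  invisible(path)
}

#' Japanese holiday calendar for the analysis window
#'
#' National holidays (including the Olympic-schedule moves of 2020 and 2021
#' and substitute holidays) plus an unofficial-holiday span covering the
#' year-end/New Year and Obon periods, when much of the country is on
#' leave without a statutory holiday. The unofficial list is an
#' approximation of customary leave periods, not an official calendar.
#'
#' @return A tibble with columns `date` (`Date`), `type`
#'   (`"national"`/`"unofficial"`) and `name`.
#' @export
jp_holidays <- function() {
  path <- system.file("extdata", "jp_holidays_2020_2021.csv",
                      package = "jishuku", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    date = readr::col_date(),
                    type = readr::col_character(),
                    name = readr::col_character()))
}
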